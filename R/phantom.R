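# Synthetic two-modality head phantoms: one bright elliptical skull ring and
# a handful of low-contrast interior blobs rendered as a CT slice, plus an MR
# rendering of the SAME geometry through a stored CT->MR intensity transfer
# (dark skull, stretched soft-tissue contrast).  The phantoms reproduce the
# statistical structure the method assumes -- shared geometry within a pair,
# independent geometry across the unpaired pools -- not anatomy.

# Registry of ground-truth CT->MR intensity transfers, stored by id so tests
# can recompute the mapping.  piecewise_v1: piecewise linear, stretches the
# soft-tissue band [80, 160] to [60, 230] and inverts the skull band (bright
# CT bone -> dark MR bone).
.intensity_maps <- list(
  piecewise_v1 = list(
    x = c(0, 40, 80, 160, 200, 255),
    y = c(0, 30, 60, 230, 40, 10)
  )
)

#' Ground-truth phantom intensity transfer
#'
#' @param id Mapping identifier (currently `"piecewise_v1"`).
#' @return A list with knot vectors `x`, `y` and a vectorized function
#'   `fun` mapping CT gray levels to MR gray levels.
#' @export
intensity_map <- function(id = "piecewise_v1") {
  m <- .intensity_maps[[id]]
  if (is.null(m)) config_error(sprintf("unknown intensity map '%s'", id))
  list(id = id, x = m$x, y = m$y,
       fun = function(v) stats::approx(m$x, m$y, xout = v, rule = 2)$y)
}

#' Phantom generation parameters
#'
#' @param image_size Square slice size in pixels; at least 32 and divisible
#'   by 4 (the generator downsamples twice).
#' @param n_structures Number of interior soft-tissue blobs.
#' @param skull_thickness_range Length-2 numeric, skull ring thickness range
#'   in pixels; default scales with `image_size`.
#' @param intensity_map_id Identifier of the CT->MR transfer
#'   (see [intensity_map()]).
#' @param misalignment_px Maximum absolute random integer translation (in
#'   pixels, per axis) applied to the MR member of a pair to emulate
#'   registration error; 0 produces perfectly registered pairs.
#' @param noise_sd Standard deviation of additive Gaussian noise in gray
#'   levels, applied independently to the two members and clipped.
#' @param seed Integer seed; equal parameters give byte-identical datasets.
#' @return An object of class `ctmr_phantom_params`.
#' @export
phantom_params <- function(image_size = 256L, n_structures = 4L,
                           skull_thickness_range = NULL,
                           intensity_map_id = "piecewise_v1",
                           misalignment_px = 0L, noise_sd = 0,
                           seed = 1L) {
  image_size <- as.integer(image_size)
  if (is.na(image_size) || image_size < 32L || image_size %% 4L != 0L) {
    config_error("image_size must be >= 32 and divisible by 4")
  }
  if (misalignment_px < 0) config_error("misalignment_px must be >= 0")
  if (noise_sd < 0) config_error("noise_sd must be >= 0")
  if (n_structures < 0) config_error("n_structures must be >= 0")
  if (is.null(skull_thickness_range)) {
    skull_thickness_range <- image_size * c(0.035, 0.055)
  }
  if (length(skull_thickness_range) != 2L ||
      any(skull_thickness_range <= 0) ||
      diff(skull_thickness_range) < 0) {
    config_error("skull_thickness_range must be an increasing positive pair")
  }
  intensity_map(intensity_map_id)  # validates id
  structure(
    list(image_size = image_size, n_structures = as.integer(n_structures),
         skull_thickness_range = skull_thickness_range,
         intensity_map_id = intensity_map_id,
         misalignment_px = as.integer(misalignment_px),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "ctmr_phantom_params"
  )
}

# Evaluate a filled rotated ellipse on the pixel grid.
ellipse_mask <- function(size, cx, cy, a, b, theta = 0) {
  xs <- matrix(rep(seq_len(size), each = size), size, size)  # column index
  ys <- matrix(rep(seq_len(size), times = size), size, size) # row index
  dx <- xs - cx
  dy <- ys - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# Draw one random head geometry from the current RNG stream.
# Returns CT rendering (float, [0, 255]) with a structure-label mask
# attribute: 0 background, 1 skull, 2 interior tissue, 3 blob.
draw_geometry <- function(params) {
  s <- params$image_size
  cx <- s / 2 + runif(1, -0.02, 0.02) * s
  cy <- s / 2 + runif(1, -0.02, 0.02) * s
  a <- runif(1, 0.38, 0.44) * s
  b <- runif(1, 0.34, 0.40) * s
  thick <- runif(1, params$skull_thickness_range[1L],
                 params$skull_thickness_range[2L])
  outer_m <- ellipse_mask(s, cx, cy, a, b)
  inner_m <- ellipse_mask(s, cx, cy, a - thick, b - thick)
  ring <- outer_m & !inner_m
  ct <- matrix(0, s, s)
  mask <- matrix(0L, s, s)
  ct[inner_m] <- 100
  mask[inner_m] <- 2L
  ct[ring] <- runif(1, 215, 245)
  mask[ring] <- 1L
  for (i in seq_len(params$n_structures)) {
    bc_x <- cx + runif(1, -0.55, 0.55) * (a - thick)
    bc_y <- cy + runif(1, -0.55, 0.55) * (b - thick)
    ba <- runif(1, 0.06, 0.16) * s
    bb <- runif(1, 0.06, 0.16) * s
    bm <- ellipse_mask(s, bc_x, bc_y, ba, bb, runif(1, 0, pi)) & inner_m
    ct[bm] <- runif(1, 85, 150)
    mask[bm] <- 3L
  }
  attr(ct, "mask") <- mask
  ct
}

translate_zero <- function(m, dr, dc) {
  out <- matrix(0, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - dr
  src_c <- seq_len(ncol(m)) - dc
  ok_r <- src_r >= 1 & src_r <= nrow(m)
  ok_c <- src_c >= 1 & src_c <= ncol(m)
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Generate one registered phantom CT/MR pair
#'
#' Renders a random head geometry as a CT slice and the same geometry as an
#' MR slice through the ground-truth intensity transfer.  With zero noise
#' and zero misalignment, `mr` equals the transfer applied pixelwise to
#' `ct`, and both members carry identical structure masks.
#'
#' @param params A [phantom_params()].
#' @param seed Optional seed for this pair (defaults to the RNG stream in
#'   effect; pass a value for standalone reproducibility).
#' @param subject_id,slice_index Provenance labels.
#' @return An object of class `ctmr_paired_sample`: a list with numeric
#'   matrices `ct` and `mr` in \eqn{[0, 255]}, `subject_id`, `slice_index`,
#'   and a `mask` attribute (structure labels of the shared geometry).
#' @export
generate_phantom_pair <- function(params, seed = NULL,
                                  subject_id = "pair-001",
                                  slice_index = 1L) {
  stopifnot(inherits(params, "ctmr_phantom_params"))
  with_local_seed(seed, {
    ct <- draw_geometry(params)
    mask <- attr(ct, "mask")
    attr(ct, "mask") <- NULL
    map <- intensity_map(params$intensity_map_id)
    mr <- matrix(map$fun(ct), nrow(ct), ncol(ct))
    if (params$noise_sd > 0) {
      ct <- ct + rnorm(length(ct), sd = params$noise_sd)
      mr <- mr + rnorm(length(mr), sd = params$noise_sd)
    }
    if (params$misalignment_px > 0) {
      off <- sample(seq(-params$misalignment_px, params$misalignment_px),
                    2L, replace = TRUE)
      mr <- translate_zero(mr, off[1L], off[2L])
    }
    structure(
      list(ct = clip255(ct), mr = clip255(mr), subject_id = subject_id,
           slice_index = as.integer(slice_index)),
      mask = mask, class = "ctmr_paired_sample"
    )
  })
}

#' Generate a phantom dataset of paired and unpaired slices
#'
#' Paired samples share one geometry per pair; every unpaired slice draws a
#' fresh, independent geometry (unpaired MR slices are rendered through the
#' intensity transfer from their own geometry, and the CT rendering is
#' discarded).
#'
#' @param params A [phantom_params()]; `params$seed` fixes the dataset.
#' @param n_paired,n_unpaired_ct,n_unpaired_mr Slice counts (>= 0, not all
#'   zero).
#' @return An object of class `ctmr_phantom_dataset`: lists `paired`,
#'   `unpaired_ct`, `unpaired_mr`, the `ground_truth_map` id, `provenance`
#'   (the params) and a `manifest` tibble (role, subject id, slice index,
#'   file path -- paths filled in by [write_phantom_dataset()]).
#' @export
generate_dataset <- function(params, n_paired, n_unpaired_ct,
                             n_unpaired_mr) {
  stopifnot(inherits(params, "ctmr_phantom_params"))
  counts <- c(n_paired, n_unpaired_ct, n_unpaired_mr)
  if (any(counts < 0)) config_error("slice counts must be >= 0")
  if (sum(counts) == 0) {
    config_error("at least one of the three slice counts must be positive")
  }
  with_local_seed(params$seed, {
    paired <- lapply(seq_len(n_paired), function(i) {
      generate_phantom_pair(params, seed = NULL,
                            subject_id = sprintf("pair-%03d", i),
                            slice_index = i)
    })
    map <- intensity_map(params$intensity_map_id)
    unpaired_ct <- lapply(seq_len(n_unpaired_ct), function(i) {
      ct <- draw_geometry(params)
      mask <- attr(ct, "mask")
      attr(ct, "mask") <- NULL
      if (params$noise_sd > 0) {
        ct <- ct + rnorm(length(ct), sd = params$noise_sd)
      }
      structure(clip255(ct), mask = mask)
    })
    unpaired_mr <- lapply(seq_len(n_unpaired_mr), function(i) {
      ct <- draw_geometry(params)
      mask <- attr(ct, "mask")
      attr(ct, "mask") <- NULL
      mr <- matrix(map$fun(ct), nrow(ct), ncol(ct))
      if (params$noise_sd > 0) {
        mr <- mr + rnorm(length(mr), sd = params$noise_sd)
      }
      structure(clip255(mr), mask = mask)
    })
    manifest <- tibble::tibble(
      role = c(rep(c("paired_ct", "paired_mr"), n_paired),
               rep("unpaired_ct", n_unpaired_ct),
               rep("unpaired_mr", n_unpaired_mr)),
      subject_id = c(rep(sprintf("pair-%03d", seq_len(n_paired)), each = 2L),
                     sprintf("uct-%03d", seq_len(n_unpaired_ct)),
                     sprintf("umr-%03d", seq_len(n_unpaired_mr))),
      slice_index = c(rep(seq_len(n_paired), each = 2L),
                      seq_len(n_unpaired_ct), seq_len(n_unpaired_mr)),
      file_path = NA_character_
    )
    structure(
      list(paired = paired, unpaired_ct = unpaired_ct,
           unpaired_mr = unpaired_mr,
           ground_truth_map = params$intensity_map_id,
           provenance = params, manifest = manifest),
      class = "ctmr_phantom_dataset"
    )
  })
}

#' @export
print.ctmr_phantom_dataset <- function(x, ...) {
  cat(sprintf(
    "<ctmr_phantom_dataset> %d paired, %d unpaired CT, %d unpaired MR slices (%dx%d)\n",
    length(x$paired), length(x$unpaired_ct), length(x$unpaired_mr),
    x$provenance$image_size, x$provenance$image_size))
  invisible(x)
}
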