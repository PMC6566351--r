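#' Hounsfield-unit container
#'
#' @param voxels 3D array of Hounsfield units (rows, columns, slices); a
#'   matrix is treated as a single slice.
#' @param spacing Voxel spacing in mm, length 3, all components positive.
#' @return An object of class `ctmr_hu_volume`.
#' @export
hu_volume <- function(voxels, spacing = c(1, 1, 1)) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  if (length(dim(voxels)) != 3L) {
    shape_error("voxels must be a matrix or 3D array")
  }
  if (length(spacing) != 3L || any(spacing <= 0)) {
    validation_error("spacing must be three positive components")
  }
  structure(list(voxels = voxels, spacing = as.numeric(spacing)),
            class = "ctmr_hu_volume")
}

#' Window Hounsfield units to 8-bit gray levels
#'
#' Maps the HU interval `[center - length/2, center + length/2]` linearly
#' onto \eqn{[0, 255]}, clipping below and above.  The defaults (center 40,
#' length 80, i.e. the interval \eqn{[0, 80]} HU) are the brain soft-tissue
#' display window.  Monotone non-decreasing in HU.
#'
#' @param volume A [hu_volume()], 3D array or matrix of HU values.
#' @param center,length Window center and length in HU; `length` must be
#'   positive.
#' @return A stack of gray slices with the same spatial dimensions, values
#'   in \eqn{[0, 255]} (full precision; quantization happens on file write).
#' @export
window_hu <- function(volume, center = 40, length = 80) {
  if (length <= 0) config_error("window length must be > 0")
  vox <- if (inherits(volume, "ctmr_hu_volume")) volume$voxels else volume
  lo <- center - length / 2
  clip255((vox - lo) / length * 255)
}

#' Map gray levels to and from the network intensity domain
#'
#' The networks operate on \eqn{[-1, 1]}: `to_network_domain` maps 0 to -1
#' and 255 to +1 affinely; `from_network_domain` inverts the map.  The
#' round trip on any 8-bit integer slice is lossless.
#'
#' @param slice Numeric matrix/array in \eqn{[0, 255]}.
#' @param z Numeric matrix/array in \eqn{[-1, 1]}.
#' @return The mapped matrix/array.
#' @export
to_network_domain <- function(slice) {
  if (any(slice < 0 | slice > 255)) {
    validation_error("gray values outside [0, 255]")
  }
  slice / 127.5 - 1
}

#' @rdname to_network_domain
#' @export
from_network_domain <- function(z) {
  clip255((z + 1) * 127.5)
}

#' Sample training-time augmentation parameters
#'
#' One draw yields: a horizontal flip with probability 0.5, a uniform crop
#' offset over all admissible positions of a `target_size` crop from the
#' zero-padded image, and a rotation angle uniform in \eqn{[-5, 5]}
#' degrees.  For a 256 target the pad size is 286; other sizes scale the
#' pad margin proportionally (`round(size * 30/256)`).
#'
#' @param target_size Output slice size in pixels.
#' @param pad_to Padded size; defaults to the proportional rule above.
#' @return An object of class `ctmr_augment_params` with fields `flip`,
#'   `pad_to`, `crop_offset` (0-based row/col), `rotation_deg`,
#'   `target_size`.
#' @export
sample_augment_params <- function(target_size, pad_to = NULL) {
  if (is.null(pad_to)) {
    pad_to <- target_size + round(target_size * 30 / 256)
  }
  if (target_size > pad_to) {
    config_error("target_size must not exceed pad_to")
  }
  margin <- pad_to - target_size
  structure(
    list(flip = runif(1) < 0.5,
         pad_to = as.integer(pad_to),
         crop_offset = c(sample.int(margin + 1L, 1L) - 1L,
                         sample.int(margin + 1L, 1L) - 1L),
         rotation_deg = runif(1, -5, 5),
         target_size = as.integer(target_size)),
    class = "ctmr_augment_params"
  )
}

identity_augment_params <- function(target_size) {
  structure(
    list(flip = FALSE, pad_to = as.integer(target_size),
         crop_offset = c(0L, 0L), rotation_deg = 0,
         target_size = as.integer(target_size)),
    class = "ctmr_augment_params"
  )
}

# Bilinear rotation about the image centre, zero fill outside the support,
# output size preserved.
rotate_bilinear <- function(m, deg) {
  if (deg == 0) return(m)
  h <- nrow(m); w <- ncol(m)
  th <- deg * pi / 180
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  rows <- matrix(rep(seq_len(h), times = w), h, w) - cr
  cols <- matrix(rep(seq_len(w), each = h), h, w) - cc
  # inverse mapping: source coordinates of each output pixel
  sr <- cos(th) * rows - sin(th) * cols + cr
  sc <- sin(th) * rows + cos(th) * cols + cc
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  get_px <- function(ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    v <- numeric(length(ri))
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  v00 <- get_px(r0, c0); v01 <- get_px(r0, c0 + 1)
  v10 <- get_px(r0 + 1, c0); v11 <- get_px(r0 + 1, c0 + 1)
  out <- (1 - fr) * ((1 - fc) * v00 + fc * v01) +
    fr * ((1 - fc) * v10 + fc * v11)
  matrix(out, h, w)
}

#' Apply augmentation to a slice
#'
#' Deterministic given the parameters, composed in a fixed order: flip,
#' zero-pad to `pad_to` (centred), crop at `crop_offset` to `target_size`,
#' rotate by `rotation_deg` (bilinear, zero fill), clip to \eqn{[0, 255]}.
#' Applying the *same* parameters to both members of a registered pair
#' preserves their registration; unpaired slices should each receive an
#' independent [sample_augment_params()] draw.
#'
#' @param slice Numeric matrix in \eqn{[0, 255]}.
#' @param params A `ctmr_augment_params`.
#' @return Augmented matrix of size `target_size` x `target_size`.
#' @export
apply_augment <- function(slice, params) {
  stopifnot(inherits(params, "ctmr_augment_params"))
  m <- slice
  if (params$flip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  pad <- params$pad_to
  if (pad > nrow(m)) {
    before_r <- (pad - nrow(m)) %/% 2L
    before_c <- (pad - ncol(m)) %/% 2L
    p <- matrix(0, pad, pad)
    p[before_r + seq_len(nrow(m)), before_c + seq_len(ncol(m))] <- m
    m <- p
  }
  t <- params$target_size
  off <- params$crop_offset
  m <- m[off[1L] + seq_len(t), off[2L] + seq_len(t), drop = FALSE]
  m <- rotate_bilinear(m, params$rotation_deg)
  clip255(m)
}

#' Augment a registered pair with shared parameters
#'
#' @param pair A `ctmr_paired_sample`.
#' @param params One `ctmr_augment_params` draw applied to both members.
#' @return The pair with both slices augmented (registration preserved).
#' @export
augment_pair <- function(pair, params) {
  pair$ct <- apply_augment(pair$ct, params)
  pair$mr <- apply_augment(pair$mr, params)
  pair
}
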