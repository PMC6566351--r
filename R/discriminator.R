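#' Discriminator architecture variants
#'
#' The patch discriminator has three parts: an *extra head* (one or more
#' 4x4 stride-1 convolutions, one head per data regime), a *shared network*
#' of 4x4 stride-2 convolutions whose weights are used by both regimes, and
#' an *extra tail* of 4x4 stride-1 convolutions per regime ending in a
#' one-channel patch-score map.  Five named variants are predefined:
#'
#' | name | head | shared | tail |
#' |------|------|--------|------|
#' | D1 | (64) | (64, 128, 256, 512) | (512, 1) |
#' | D2 | (64, 64) | (64, 128, 256, 512) | (512, 512, 1) |
#' | D3 | (64, 64) | (64, 128, 256, 512) | (512, 512, 512, 1) |
#' | D4 | (64) | (128, 256, 512) | (512, 1) |
#' | D5 | (64) | (128, 256, 512) | (1) |
#'
#' @param name One of `"D1"`..`"D5"`, or `"custom"` with explicit filter
#'   lists.
#' @param head_filters,shared_filters,tail_filters Integer vectors of filter
#'   counts for a custom variant.
#' @return An object of class `ctmr_disc_variant`.
#' @export
disc_variant <- function(name = "D1", head_filters = NULL,
                         shared_filters = NULL, tail_filters = NULL) {
  presets <- list(
    D1 = list(head = 64L, shared = c(64L, 128L, 256L, 512L),
              tail = c(512L, 1L)),
    D2 = list(head = c(64L, 64L), shared = c(64L, 128L, 256L, 512L),
              tail = c(512L, 512L, 1L)),
    D3 = list(head = c(64L, 64L), shared = c(64L, 128L, 256L, 512L),
              tail = c(512L, 512L, 512L, 1L)),
    D4 = list(head = 64L, shared = c(128L, 256L, 512L),
              tail = c(512L, 1L)),
    D5 = list(head = 64L, shared = c(128L, 256L, 512L), tail = 1L)
  )
  if (name %in% names(presets)) {
    p <- presets[[name]]
    head_filters <- p$head; shared_filters <- p$shared; tail_filters <- p$tail
  } else if (!identical(name, "custom")) {
    config_error(sprintf("unknown discriminator variant '%s'", name))
  }
  if (length(head_filters) == 0 || length(shared_filters) == 0 ||
      length(tail_filters) == 0) {
    config_error("discriminator filter lists must all be non-empty")
  }
  structure(
    list(name = name, head_filters = as.integer(head_filters),
         shared_filters = as.integer(shared_filters),
         tail_filters = as.integer(tail_filters)),
    class = "ctmr_disc_variant"
  )
}

# One stack of 4x4 convolutions.  stride-1 convs use size-preserving
# asymmetric padding (1, 2); stride-2 trunk convs use symmetric padding 1.
# `first_global` marks the network's very first convolution (no norm);
# `last_global` marks the final scoring convolution (no norm, no activation).
disc_conv_stack <- function(cin, filters, stride, first_global = FALSE,
                            last_global = FALSE, norm = TRUE) {
  layers <- list()
  for (i in seq_along(filters)) {
    cout <- filters[i]
    if (stride == 1L) {
      layers <- c(layers, list(new_conv(cin, cout, 4L, 1L, 1L, 2L)))
    } else {
      layers <- c(layers, list(new_conv(cin, cout, 4L, 2L, 1L, 1L)))
    }
    is_first <- first_global && i == 1L
    is_last <- last_global && i == length(filters)
    if (!is_last) {
      if (norm && !is_first) layers <- c(layers, list(new_inorm(cout)))
      layers <- c(layers, list(new_act("lrelu")))
    }
    cin <- cout
  }
  layers
}

#' Build a dual-head patch discriminator
#'
#' Constructs a patch discriminator with two heads sharing one trunk: the
#' unpaired head consumes a single-channel image and its tail emits raw
#' patch scores (least-squares regime); the paired head consumes a
#' two-channel (CT, candidate MR) concatenation and its tail feeds a sigmoid
#' (log-likelihood regime).  Trunk weights are shared between the two paths.
#'
#' @param variant A [disc_variant()].
#' @param norm Use instance normalization (default `TRUE`).
#' @return An object of class `ctmr_discriminator`.
#' @export
build_discriminator <- function(variant = disc_variant("D1"), norm = TRUE) {
  stopifnot(inherits(variant, "ctmr_disc_variant"))
  hf <- variant$head_filters
  head_out <- hf[length(hf)]
  sf <- variant$shared_filters
  trunk_out <- sf[length(sf)]
  heads <- list(
    unpaired = disc_conv_stack(1L, hf, 1L, first_global = TRUE, norm = norm),
    paired = disc_conv_stack(2L, hf, 1L, first_global = TRUE, norm = norm)
  )
  trunk <- disc_conv_stack(head_out, sf, 2L, norm = norm)
  tails <- list(
    unpaired = disc_conv_stack(trunk_out, variant$tail_filters, 1L,
                               last_global = TRUE, norm = norm),
    paired = disc_conv_stack(trunk_out, variant$tail_filters, 1L,
                             last_global = TRUE, norm = norm)
  )
  structure(list(variant = variant, heads = heads, trunk = trunk,
                 tails = tails),
            class = "ctmr_discriminator")
}

#' Run a discriminator forward
#'
#' @param disc A `ctmr_discriminator`.
#' @param x For `mode = "unpaired"` a single-channel image (matrix or
#'   H-by-W-by-1 array) in the network domain; for `mode = "paired"` an
#'   H-by-W-by-2 array with the CT conditioning image in channel 1 and the
#'   real or synthesized MR candidate in channel 2.
#' @param mode `"unpaired"` or `"paired"`.
#' @return A matrix of raw patch scores (no sigmoid applied).
#' @export
discriminator_forward <- function(disc, x, mode = c("unpaired", "paired")) {
  mode <- match.arg(mode)
  x <- as_fmap(x)
  want <- if (mode == "unpaired") 1L else 2L
  if (dim(x)[3L] != want) {
    shape_error(sprintf("%s head expects %d channel(s), got %d",
                        mode, want, dim(x)[3L]))
  }
  path <- c(disc$heads[[mode]], disc$trunk, disc$tails[[mode]])
  y <- seq_forward(path, x)
  y[, , 1L]
}

discriminator_backward <- function(disc, dy, mode = c("unpaired", "paired")) {
  mode <- match.arg(mode)
  path <- c(disc$heads[[mode]], disc$trunk, disc$tails[[mode]])
  seq_backward(path, as_fmap(dy))
}

#' Patch score map
#'
#' Per-patch real/fake scores for an image (unpaired head, raw least-squares
#' scores) or for a CT/MR pair (paired head, probabilities via sigmoid).
#'
#' @param disc A `ctmr_discriminator`.
#' @param image Single-channel candidate image in the network domain.
#' @param ct Optional CT conditioning image; when supplied the paired head
#'   is used and the result is passed through a sigmoid.
#' @return A numeric matrix of patch scores.
#' @export
patch_score_map <- function(disc, image, ct = NULL) {
  if (is.null(ct)) {
    discriminator_forward(disc, image, "unpaired")
  } else {
    image <- if (is.matrix(image)) image else image[, , 1L]
    ct <- if (is.matrix(ct)) ct else ct[, , 1L]
    if (!all(dim(image) == dim(ct))) {
      shape_error("ct and candidate image sizes differ")
    }
    x <- array(c(ct, image), c(dim(ct), 2L))
    stats::plogis(discriminator_forward(disc, x, "paired"))
  }
}

#' Layer filter counts along the unpaired scoring path
#'
#' @param disc A `ctmr_discriminator`.
#' @return A list with integer vectors `head`, `shared`, `tail` read off the
#'   built convolution layers (not the variant description).
#' @export
disc_filter_sequence <- function(disc) {
  seq_of <- function(layers) {
    unlist(lapply(layers, function(l) {
      if (identical(l$type, "conv")) l$cout else NULL
    }))
  }
  list(head = seq_of(disc$heads$unpaired), shared = seq_of(disc$trunk),
       tail = seq_of(disc$tails$unpaired))
}
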