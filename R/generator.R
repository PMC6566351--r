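#' Generator (synthesis network) specification
#'
#' Describes the fully convolutional residual translation network used for
#' both synthesis directions (CT to MR and MR to CT): a 7x7 convolution,
#' two stride-2 downsampling convolutions, a chain of residual blocks at the
#' bottleneck resolution, two fractionally strided (transposed) upsampling
#' convolutions, and a final 7x7 convolution with a tanh output into
#' \eqn{[-1, 1]}.  Instance normalization and ReLU follow every convolution
#' except the last.
#'
#' @param in_channels,out_channels Number of input/output image channels.
#' @param base_filters Filter count of the first convolution; doubled at each
#'   downsampling stage.
#' @param n_residual_blocks Number of residual blocks at the bottleneck
#'   (default 9).
#' @param norm Use instance normalization (default `TRUE`).
#' @param upsample `"fractional"` for transposed convolutions (the default)
#'   or `"resize"` for nearest-neighbour upsampling followed by a 3x3
#'   convolution.
#' @return An object of class `ctmr_generator_spec`.
#' @export
generator_spec <- function(in_channels = 1L, out_channels = 1L,
                           base_filters = 64L, n_residual_blocks = 9L,
                           norm = TRUE,
                           upsample = c("fractional", "resize")) {
  upsample <- match.arg(upsample)
  if (n_residual_blocks < 1L) {
    config_error("n_residual_blocks must be at least 1")
  }
  if (base_filters < 1L) config_error("base_filters must be positive")
  structure(
    list(in_channels = as.integer(in_channels),
         out_channels = as.integer(out_channels),
         base_filters = as.integer(base_filters),
         n_residual_blocks = as.integer(n_residual_blocks),
         norm = isTRUE(norm), upsample = upsample),
    class = "ctmr_generator_spec"
  )
}

#' Build a synthesis network
#'
#' @param spec A [generator_spec()].
#' @return An object of class `ctmr_generator` holding the trainable layers.
#' @export
build_generator <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "ctmr_generator_spec"))
  f <- spec$base_filters
  norm <- spec$norm
  layers <- list(new_conv(spec$in_channels, f, 7L, 1L, 3L,
                          pad_mode = "reflect"))
  add_norm_act <- function(layers, ch) {
    if (norm) layers <- c(layers, list(new_inorm(ch)))
    c(layers, list(new_act("relu")))
  }
  layers <- add_norm_act(layers, f)
  layers <- c(layers, list(new_conv(f, 2L * f, 3L, 2L, 1L)))
  layers <- add_norm_act(layers, 2L * f)
  layers <- c(layers, list(new_conv(2L * f, 4L * f, 3L, 2L, 1L)))
  layers <- add_norm_act(layers, 4L * f)
  for (i in seq_len(spec$n_residual_blocks)) {
    layers <- c(layers, list(new_resblock(4L * f, use_norm = norm)))
  }
  up <- function(cin, cout) {
    if (spec$upsample == "fractional") {
      list(new_convt(cin, cout, 3L, 2L, pad = 1L, out_pad = 1L))
    } else {
      list(new_upsample2(), new_conv(cin, cout, 3L, 1L, 1L))
    }
  }
  layers <- c(layers, up(4L * f, 2L * f))
  layers <- add_norm_act(layers, 2L * f)
  layers <- c(layers, up(2L * f, f))
  layers <- add_norm_act(layers, f)
  layers <- c(layers, list(
    new_conv(f, spec$out_channels, 7L, 1L, 3L, pad_mode = "reflect"),
    new_act("tanh")
  ))
  structure(list(spec = spec, layers = layers), class = "ctmr_generator")
}

#' Run a generator forward
#'
#' @param gen A `ctmr_generator`.
#' @param x A numeric matrix (or H-by-W-by-1 array) in the network domain
#'   \eqn{[-1, 1]}; height and width must be divisible by 4.
#' @return A matrix of the same spatial size, values in \eqn{[-1, 1]}.
#' @export
generator_forward <- function(gen, x) {
  x <- as_fmap(x)
  d <- dim(x)
  if (d[1L] %% 4L != 0L || d[2L] %% 4L != 0L) {
    shape_error(sprintf("generator input size %dx%d not divisible by 4",
                        d[1L], d[2L]))
  }
  y <- seq_forward(gen$layers, x)
  y[, , 1L]
}

generator_backward <- function(gen, dy) {
  seq_backward(gen$layers, as_fmap(dy))
}

#' Count residual blocks in a built generator
#' @param gen A `ctmr_generator`.
#' @return Integer count.
#' @export
n_residual_blocks <- function(gen) {
  sum(vapply(gen$layers, function(l) identical(l$type, "resblock"),
             logical(1)))
}
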