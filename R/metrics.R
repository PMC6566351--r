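#' Metric configuration
#'
#' @param max_intensity Peak intensity MAX for PSNR (default 255).
#' @param C1,C2 SSIM stabilizers; defaults \eqn{(0.01\,MAX)^2} and
#'   \eqn{(0.03\,MAX)^2}.
#' @param mae_per_pixel Divide the per-slice L1 norm by the pixel count
#'   (default `TRUE`); `FALSE` leaves the raw per-slice L1 sum.
#' @return An object of class `ctmr_metric_config`.
#' @export
metric_config <- function(max_intensity = 255, C1 = (0.01 * max_intensity)^2,
                          C2 = (0.03 * max_intensity)^2,
                          mae_per_pixel = TRUE) {
  if (max_intensity <= 0) config_error("max_intensity must be > 0")
  if (C1 <= 0 || C2 <= 0) config_error("C1 and C2 must be > 0")
  structure(list(max_intensity = max_intensity, C1 = C1, C2 = C2,
                 mae_per_pixel = isTRUE(mae_per_pixel)),
            class = "ctmr_metric_config")
}

check_stacks <- function(reference, synthesized) {
  reference <- as_slice_stack(reference)
  synthesized <- as_slice_stack(synthesized)
  if (!all(dim(reference) == dim(synthesized))) {
    shape_error("reference and synthesized stacks have different shapes")
  }
  list(ref = reference, syn = synthesized)
}

#' Mean absolute error between slice stacks
#'
#' Mean over slices of the per-slice mean absolute pixel difference (the
#' per-slice L1 distance divided by pixel count when `cfg$mae_per_pixel`).
#'
#' @param reference,synthesized Equal-shape slice stacks (H, W, N).
#' @param cfg A [metric_config()].
#' @param mask Optional logical matrix restricting the computation to a
#'   foreground region (default: full slice).
#' @return A scalar.
#' @export
mae <- function(reference, synthesized, cfg = metric_config(),
                mask = NULL) {
  s <- check_stacks(reference, synthesized)
  n_slices <- dim(s$ref)[3L]
  vals <- vapply(seq_len(n_slices), function(i) {
    d <- abs(s$syn[, , i] - s$ref[, , i])
    if (!is.null(mask)) d <- d[mask]
    if (cfg$mae_per_pixel) mean(d) else sum(d)
  }, numeric(1))
  mean(vals)
}

#' Peak signal-to-noise ratio between slice stacks
#'
#' \eqn{PSNR = 10 \log_{10}(MAX^2 / MSE)} with MSE the mean over slices of
#' the per-slice mean squared difference.  Identical stacks (MSE = 0)
#' return `Inf`; report averaging excludes such slices.
#'
#' @inheritParams mae
#' @return Decibels (possibly `Inf`).
#' @export
psnr <- function(reference, synthesized, cfg = metric_config(),
                 mask = NULL) {
  s <- check_stacks(reference, synthesized)
  n_slices <- dim(s$ref)[3L]
  mse_vals <- vapply(seq_len(n_slices), function(i) {
    d <- (s$syn[, , i] - s$ref[, , i])^2
    if (!is.null(mask)) d <- d[mask]
    mean(d)
  }, numeric(1))
  mse <- mean(mse_vals)
  if (mse == 0) return(Inf)
  10 * log10(cfg$max_intensity^2 / mse)
}

#' Structural similarity between slice stacks
#'
#' Per-slice SSIM from global (whole-slice) means, variances and
#' covariance,
#' \deqn{SSIM_i = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'   {(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)},}
#' averaged over slices.  Population (biased) variance estimators are
#' used.  `method = "windowed"` instead averages the same statistic over
#' sliding 11x11 Gaussian windows (the common image-quality convention,
#' available for comparison only -- it is *not* the default definition
#' here).
#'
#' @inheritParams mae
#' @param method `"global"` (default) or `"windowed"`.
#' @return A dimensionless scalar in \eqn{(-1, 1]}.
#' @export
ssim <- function(reference, synthesized, cfg = metric_config(),
                 mask = NULL, method = c("global", "windowed")) {
  method <- match.arg(method)
  s <- check_stacks(reference, synthesized)
  n_slices <- dim(s$ref)[3L]
  vals <- vapply(seq_len(n_slices), function(i) {
    x <- s$syn[, , i]; y <- s$ref[, , i]
    if (!is.null(mask)) { x <- x[mask]; y <- y[mask] }
    if (method == "global") {
      ssim_global(x, y, cfg$C1, cfg$C2)
    } else {
      ssim_windowed(s$syn[, , i], s$ref[, , i], cfg$C1, cfg$C2)
    }
  }, numeric(1))
  mean(vals)
}

ssim_global <- function(x, y, C1, C2) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean(x^2) - mx^2
  vy <- mean(y^2) - my^2
  cxy <- mean(x * y) - mx * my
  ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

# Sliding-window SSIM (11x11 Gaussian, sigma 1.5), mean over window centres.
ssim_windowed <- function(x, y, C1, C2, win = 11L, sigma = 1.5) {
  smallest <- min(dim(x))
  if (win > smallest) win <- smallest - (1L - smallest %% 2L)  # odd, <= size
  g <- stats::dnorm(seq(-(win %/% 2), win %/% 2), sd = sigma)
  g <- g / sum(g)
  blur <- function(m) {
    m <- apply(m, 2L, function(col) stats::filter(col, g, sides = 2L))
    t(apply(t(m), 2L, function(col) stats::filter(col, g, sides = 2L)))
  }
  mx <- blur(x); my <- blur(y)
  vx <- blur(x^2) - mx^2
  vy <- blur(y^2) - my^2
  cxy <- blur(x * y) - mx * my
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(s, na.rm = TRUE)
}
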