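# Independent flat-loop reference implementations used as oracles.  These
# deliberately avoid the package's vectorized code paths: explicit loops
# over patches, pixels and slices.

oracle_lsgan_d <- function(sr, sf) {
  acc_r <- 0
  for (v in as.numeric(sr)) acc_r <- acc_r + (v - 1)^2
  acc_f <- 0
  for (v in as.numeric(sf)) acc_f <- acc_f + v^2
  acc_r / length(sr) + acc_f / length(sf)
}

oracle_lsgan_g <- function(sf) {
  acc <- 0
  for (v in as.numeric(sf)) acc <- acc + (v - 1)^2
  acc / length(sf)
}

oracle_nll_d <- function(pr, pf, eps = 1e-7) {
  pr <- pmin(pmax(as.numeric(pr), eps), 1 - eps)
  pf <- pmin(pmax(as.numeric(pf), eps), 1 - eps)
  a <- 0
  for (v in pr) a <- a + log(v)
  b <- 0
  for (v in pf) b <- b + log(1 - v)
  a / length(pr) + b / length(pf)
}

oracle_nll_g <- function(pf, eps = 1e-7) {
  pf <- pmin(pmax(as.numeric(pf), eps), 1 - eps)
  acc <- 0
  for (v in pf) acc <- acc + log(1 - v)
  acc / length(pf)
}

oracle_l1 <- function(a, b) {
  acc <- 0
  av <- as.numeric(a); bv <- as.numeric(b)
  for (i in seq_along(av)) acc <- acc + abs(av[i] - bv[i])
  acc / length(av)
}

# Eq.-style metric oracles over (H, W, N) stacks.
oracle_mae <- function(ref, syn) {
  n <- dim(ref)[3]
  total <- 0
  for (s in seq_len(n)) {
    acc <- 0
    for (i in seq_len(dim(ref)[1])) {
      for (j in seq_len(dim(ref)[2])) {
        acc <- acc + abs(syn[i, j, s] - ref[i, j, s])
      }
    }
    total <- total + acc / (dim(ref)[1] * dim(ref)[2])
  }
  total / n
}

oracle_psnr <- function(ref, syn, max_i = 255) {
  n <- dim(ref)[3]
  total <- 0
  for (s in seq_len(n)) {
    acc <- 0
    for (i in seq_len(dim(ref)[1])) {
      for (j in seq_len(dim(ref)[2])) {
        acc <- acc + (syn[i, j, s] - ref[i, j, s])^2
      }
    }
    total <- total + acc / (dim(ref)[1] * dim(ref)[2])
  }
  mse <- total / n
  if (mse == 0) Inf else 10 * log10(max_i^2 / mse)
}

oracle_ssim <- function(ref, syn, C1 = (0.01 * 255)^2, C2 = (0.03 * 255)^2) {
  n <- dim(ref)[3]
  total <- 0
  for (s in seq_len(n)) {
    x <- as.numeric(syn[, , s]); y <- as.numeric(ref[, , s])
    np <- length(x)
    mx <- sum(x) / np; my <- sum(y) / np
    vx <- sum((x - mx)^2) / np
    vy <- sum((y - my)^2) / np
    cxy <- sum((x - mx) * (y - my)) / np
    total <- total + ((2 * mx * my + C1) * (2 * cxy + C2)) /
      ((mx^2 + my^2 + C1) * (vx + vy + C2))
  }
  total / n
}

# Small architectures used throughout the training tests.
small_gen_spec <- function(n_res = 2L) {
  generator_spec(base_filters = 8L, n_residual_blocks = n_res)
}

small_disc_variant <- function() {
  disc_variant("custom", head_filters = 16L, shared_filters = c(16L, 32L),
               tail_filters = c(16L, 1L))
}

small_train_config <- function(iters, seed = 1L, mode = "both",
                               alpha = 2e-4, augment = TRUE, ...) {
  train_config(alpha = alpha, warm_iters = iters, decay_iters = 0,
               gen_spec = small_gen_spec(),
               disc_variant = small_disc_variant(),
               image_size = 64L, seed = seed, mode = mode,
               augment = augment, ...)
}

small_phantom_dataset <- function(n_paired = 3, n_uct = 4, n_umr = 4,
                                  seed = 11, size = 64) {
  generate_dataset(phantom_params(image_size = size, seed = seed),
                   n_paired, n_uct, n_umr)
}

# Flatten all parameters of a network set into one numeric vector.
all_params_vec <- function(nets) {
  unlist(lapply(ctmrsyn:::model_layers(nets), function(layers) {
    lapply(ctmrsyn:::export_params(layers), function(p) {
      p[setdiff(names(p), c("id", "type"))]
    })
  }), use.names = FALSE)
}
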