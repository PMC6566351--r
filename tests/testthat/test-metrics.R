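rand_stack <- function(h = 4, w = 4, n = 2) {
  array(runif(h * w * n, 0, 255), c(h, w, n))
}

test_that("MAE matches the trivial cases and the brute-force oracle", {
  set.seed(20)
  ref <- rand_stack()
  expect_equal(mae(ref, ref), 0)
  expect_equal(mae(ref, pmin(ref + 10, Inf)), 10)
  for (i in 1:20) {
    a <- rand_stack(); b <- rand_stack()
    expect_equal(mae(a, b), oracle_mae(a, b), tolerance = 1e-12)
  }
  expect_error(mae(ref, rand_stack(3, 3, 2)), class = "ctmrsyn_shape_error")
  # without per-pixel normalization the value is the per-slice L1 sum
  cfg_sum <- metric_config(mae_per_pixel = FALSE)
  expect_equal(mae(ref, ref + 1, cfg_sum), 16)
})

test_that("PSNR follows the closed form and the infinity sentinel", {
  z <- array(0, c(4, 4, 2))
  full <- array(255, c(4, 4, 2))
  expect_equal(psnr(z, full), 0)          # MSE = MAX^2
  expect_equal(psnr(z, z), Inf)           # identical stacks
  # constructed MSE = MAX^2 / 10 gives exactly 10 dB
  x <- array(255 / sqrt(10), c(4, 4, 2))
  expect_equal(psnr(z, x), 10, tolerance = 1e-12)
  set.seed(21)
  for (i in 1:20) {
    a <- rand_stack(); b <- rand_stack()
    expect_equal(psnr(a, b), oracle_psnr(a, b), tolerance = 1e-10)
  }
  # strictly decreasing in MSE
  mse_seq <- c(1, 10, 100, 1000)
  vals <- vapply(mse_seq, function(m) {
    psnr(z, array(sqrt(m), c(4, 4, 2)))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("SSIM uses global per-slice statistics as specified", {
  set.seed(22)
  ref <- rand_stack(8, 8, 2)
  expect_equal(ssim(ref, ref), 1)
  # constant slices: variances vanish, closed form (2ab+C1)/(a^2+b^2+C1)
  cfg <- metric_config()
  a <- 100; b <- 150
  expect_equal(
    ssim(array(b, c(4, 4, 1)), array(a, c(4, 4, 1))),
    (2 * a * b + cfg$C1) / (a^2 + b^2 + cfg$C1))
  for (i in 1:20) {
    x <- rand_stack(8, 8, 2); y <- rand_stack(8, 8, 2)
    expect_equal(ssim(x, y), oracle_ssim(x, y), tolerance = 1e-12)
    expect_equal(ssim(x, y), ssim(y, x))  # symmetry
    expect_lte(ssim(x, y), 1)
  }
  # windowed alternative runs and agrees at the identity
  expect_equal(ssim(ref, ref, method = "windowed"), 1)
})

test_that("metrics are invariant to joint spatial permutation", {
  set.seed(23)
  a <- rand_stack(4, 4, 1); b <- rand_stack(4, 4, 1)
  perm <- sample(16)
  ap <- array(a[perm], c(4, 4, 1)); bp <- array(b[perm], c(4, 4, 1))
  expect_equal(mae(a, b), mae(ap, bp))
  expect_equal(psnr(a, b), psnr(ap, bp))
  expect_equal(ssim(a, b), ssim(ap, bp))
})

test_that("foreground masking restricts the metric support", {
  a <- array(0, c(4, 4, 1)); b <- a
  b[1, 1, 1] <- 100
  mask <- matrix(FALSE, 4, 4); mask[1, 1] <- TRUE
  expect_equal(mae(a, b), 100 / 16)
  expect_equal(mae(a, b, mask = mask), 100)
})

test_that("reports aggregate per-patient rows with column averages", {
  set.seed(24)
  p1 <- list(reference = rand_stack(), synthesized = rand_stack())
  p2 <- list(reference = rand_stack(), synthesized = rand_stack())
  r1 <- build_report(list(`Pat-01` = p1))
  expect_equal(r1$averages$mae, r1$rows$mae)
  expect_equal(r1$averages$ssim, r1$rows$ssim)

  r12 <- build_report(list(`Pat-01` = p1, `Pat-02` = p2))
  expect_equal(r12$averages$mae, mean(r12$rows$mae))
  r21 <- build_report(list(`Pat-02` = p2, `Pat-01` = p1))
  expect_equal(r21$averages, r12$averages)  # permutation invariance

  # identical stacks: infinite PSNR excluded from the average
  r3 <- build_report(list(a = p1, same = list(reference = p1$reference,
                                              synthesized = p1$reference)))
  expect_true(is.infinite(r3$rows$psnr[2]))
  expect_equal(r3$averages$psnr, r3$rows$psnr[1])
  expect_error(build_report(list()), class = "ctmrsyn_data_error")

  path <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(r12, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$patient[3], "Average")

  # broom-style accessors
  expect_equal(nrow(tidy(r12)), 2)
  expect_equal(glance(r12)$mae, r12$averages$mae)
})
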