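# Numeric gradient verification of the layer engine that everything else
# rests on: analytic backprop vs central differences.

num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

test_that("backprop matches numeric gradients through a mixed layer chain", {
  set.seed(1)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  layers <- list(
    ctmrsyn:::new_conv(2, 3, 3, 1, 1),
    ctmrsyn:::new_inorm(3),
    ctmrsyn:::new_act("relu"),
    ctmrsyn:::new_conv(3, 4, 4, 2, 1, 1),
    ctmrsyn:::new_conv(4, 4, 4, 1, 1, 2),
    ctmrsyn:::new_act("lrelu"),
    ctmrsyn:::new_convt(4, 2, 3, 2, 1, 1),
    ctmrsyn:::new_act("tanh"),
    ctmrsyn:::new_conv(2, 1, 7, 1, 3, pad_mode = "reflect")
  )
  proj <- array(rnorm(6 * 6), c(6, 6, 1))
  fwd <- function(xx) sum(ctmrsyn:::seq_forward(layers, xx) * proj)
  invisible(fwd(x))
  flat <- ctmrsyn:::collect_layers(layers)
  ctmrsyn:::zero_grads(flat)
  dx <- ctmrsyn:::seq_backward(layers, proj)
  expect_lt(max(abs(dx - num_grad(fwd, x))), 1e-6)
  # weight gradients (biases feeding instance norm have ~zero analytic
  # gradient, where central differences only give cancellation noise, so
  # compare weights and norm parameters)
  for (l in flat) {
    for (p in intersect(l$params, c("W", "gamma", "beta"))) {
      f <- function(v) {
        old <- l[[p]]
        lp <- l[[p]]; lp[seq_along(v)] <- v; l[[p]] <- lp
        r <- fwd(x)
        l[[p]] <- old
        r
      }
      err <- max(abs(num_grad(f, as.numeric(l[[p]])) -
                       as.numeric(l[[paste0("g_", p)]])))
      expect_lt(err, 1e-5)
    }
  }
})

test_that("residual blocks add a skip path with correct gradients", {
  set.seed(2)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  rb <- ctmrsyn:::new_resblock(3)
  proj <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  fwd <- function(xx) sum(ctmrsyn:::layer_forward(rb, xx) * proj)
  invisible(fwd(x))
  ctmrsyn:::zero_grads(ctmrsyn:::collect_layers(list(rb)))
  dx <- ctmrsyn:::layer_backward(rb, proj)
  expect_lt(max(abs(dx - num_grad(fwd, x))), 1e-6)
  # zeroed inner weights make the block the identity
  for (l in rb$layers) {
    if (identical(l$type, "conv")) { l$W[] <- 0; l$b[] <- 0 }
  }
  expect_equal(ctmrsyn:::layer_forward(rb, x), x, tolerance = 1e-12)
})

test_that("nearest-neighbour upsampling backward is the forward adjoint", {
  set.seed(3)
  up <- ctmrsyn:::new_upsample2()
  x <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
  y <- ctmrsyn:::layer_forward(up, x)
  expect_equal(dim(y), c(10L, 10L, 2L))
  v <- array(rnorm(10 * 10 * 2), c(10, 10, 2))
  dx <- ctmrsyn:::layer_backward(up, v)
  expect_equal(sum(y * v), sum(x * dx), tolerance = 1e-10)  # <Ax, v> = <x, A'v>
})

test_that("Adam with zero learning rate leaves parameters unchanged", {
  set.seed(4)
  l <- ctmrsyn:::new_conv(1, 2, 3, 1, 1)
  x <- array(rnorm(16), c(4, 4, 1))
  invisible(ctmrsyn:::conv_forward(l, x))
  ctmrsyn:::zero_grads(list(l))
  ctmrsyn:::conv_backward(l, array(1, c(4, 4, 2)))
  before <- l$W
  ctmrsyn:::adam_step(list(l), lr = 0)
  expect_identical(l$W, before)
  ctmrsyn:::adam_step(list(l), lr = 1e-3)
  expect_false(identical(l$W, before))
})

test_that("parameter export/import round-trips with optimizer state", {
  set.seed(5)
  gen <- build_generator(generator_spec(base_filters = 2,
                                        n_residual_blocks = 1))
  layers <- ctmrsyn:::collect_layers(gen)
  x <- array(rnorm(16 * 16), c(16, 16, 1))
  invisible(generator_forward(gen, x[, , 1]))
  ctmrsyn:::zero_grads(layers)
  ctmrsyn:::generator_backward(gen, x)
  ctmrsyn:::adam_step(layers, 1e-4)
  stored <- ctmrsyn:::export_params(layers, with_opt = TRUE)
  gen2 <- build_generator(generator_spec(base_filters = 2,
                                         n_residual_blocks = 1))
  layers2 <- ctmrsyn:::collect_layers(gen2)
  ctmrsyn:::import_params(layers2, stored, with_opt = TRUE)
  expect_equal(generator_forward(gen2, x[, , 1]),
               generator_forward(gen, x[, , 1]), tolerance = 1e-15)
  # incompatible architecture is a version error
  gen3 <- build_generator(generator_spec(base_filters = 3,
                                         n_residual_blocks = 1))
  expect_error(
    ctmrsyn:::import_params(ctmrsyn:::collect_layers(gen3), stored),
    class = "ctmrsyn_version_error"
  )
})
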