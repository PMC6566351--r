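tiny_cfg <- function(iters, seed = 1L, mode = "both", alpha = 2e-4, ...) {
  train_config(alpha = alpha, warm_iters = iters, decay_iters = 0,
               gen_spec = generator_spec(base_filters = 4L,
                                         n_residual_blocks = 1L),
               disc_variant = disc_variant("custom", head_filters = 8L,
                                           shared_filters = c(8L, 16L),
                                           tail_filters = c(8L, 1L)),
               image_size = 32L, seed = seed, mode = mode, ...)
}

tiny_data <- function(seed = 31) {
  generate_dataset(phantom_params(image_size = 32, seed = seed), 3, 4, 4)
}

test_that("the learning-rate schedule reproduces the published regime", {
  cfg <- train_config()  # warm 1e5, decay 2e5, alpha 2e-4
  expect_equal(lr_schedule(0, cfg), 2e-4)
  expect_equal(lr_schedule(12345, cfg), 2e-4)
  expect_equal(lr_schedule(1e5, cfg), 2e-4)
  expect_equal(lr_schedule(2e5, cfg), 1e-4)
  expect_equal(lr_schedule(3e5, cfg), 0)
  set.seed(30)
  its <- sample.int(3e5, 1000) - 1
  closed <- ifelse(its < 1e5, 2e-4, 2e-4 * (1 - (its - 1e5) / 2e5))
  expect_equal(lr_schedule(its, cfg), closed)
  expect_error(lr_schedule(3e5 + 1, cfg), class = "ctmrsyn_config_error")
  expect_error(lr_schedule(-1, cfg), class = "ctmrsyn_config_error")
})

test_that("zero learning rate leaves all four networks unchanged", {
  ds <- tiny_data()
  cfg <- tiny_cfg(2, alpha = 0)
  set.seed(cfg$seed)
  nets0 <- ctmrsyn:::new_model_set(cfg)
  before <- all_params_vec(nets0)
  fit <- train(ds, cfg)
  expect_identical(all_params_vec(fit$nets), before)
})

test_that("seeded runs are bit-reproducible", {
  ds <- tiny_data()
  f1 <- train(ds, tiny_cfg(3, seed = 7))
  f2 <- train(ds, tiny_cfg(3, seed = 7))
  expect_identical(f1$log, f2$log)
  expect_identical(all_params_vec(f1$nets), all_params_vec(f2$nets))
  f3 <- train(ds, tiny_cfg(3, seed = 8))
  expect_false(identical(f1$log, f3$log))
})

test_that("training emits one log row per phase per iteration", {
  ds <- tiny_data()
  fit <- train(ds, tiny_cfg(10))
  expect_equal(sum(fit$log$phase == "unpaired"), 10)
  expect_equal(sum(fit$log$phase == "paired"), 10)
  expect_true(all(fit$log$voxel_l1[fit$log$phase == "unpaired"] == 0))
  expect_true(all(fit$log$voxel_l1[fit$log$phase == "paired"] > 0))
  # the logged total respects the weighted composition
  w <- fit$config$weights
  expect_equal(fit$log$total,
               fit$log$adv_mr + fit$log$adv_ct +
                 w$lambda * fit$log$dual_cyc + w$gamma * fit$log$voxel_l1)
  # log export, tidy accessors
  path <- withr::local_tempfile(fileext = ".csv")
  write_train_log(fit, path)
  expect_equal(nrow(read.csv(path)), 20)
  expect_identical(tidy(fit), fit$log)
  expect_equal(glance(fit)$iterations, 10L)
})

test_that("degenerate modes run the corresponding baseline phases only", {
  ds <- tiny_data()
  f_un <- train(ds, tiny_cfg(2, mode = "unpaired"))
  expect_true(all(f_un$log$phase == "unpaired"))
  f_pa <- train(ds, tiny_cfg(2, mode = "paired"))
  expect_true(all(f_pa$log$phase == "paired"))
  # missing regimes are data errors
  no_pairs <- list(paired = list(), unpaired_ct = ds$unpaired_ct,
                   unpaired_mr = ds$unpaired_mr)
  expect_error(train(no_pairs, tiny_cfg(1, mode = "paired")),
               class = "ctmrsyn_data_error")
  expect_error(train(list(paired = list(), unpaired_ct = list(),
                          unpaired_mr = list()), tiny_cfg(1)),
               class = "ctmrsyn_data_error")
  # unpaired-only data under mode "both" silently skips the paired phase
  f_auto <- train(no_pairs, tiny_cfg(2))
  expect_true(all(f_auto$log$phase == "unpaired"))
})

test_that("checkpoint resume reproduces the uninterrupted trajectory", {
  ds <- tiny_data()
  dir <- withr::local_tempdir()
  full <- train(ds, tiny_cfg(8, seed = 5))
  half_cfg <- tiny_cfg(4, seed = 5, checkpoint_dir = dir)
  half <- train(ds, half_cfg)
  resumed <- train(ds, tiny_cfg(8, seed = 5), resume_from = half$checkpoint)
  expect_equal(resumed$log,
               full$log[full$log$iteration > 4, ],
               ignore_attr = TRUE, tolerance = 1e-14)
  expect_identical(all_params_vec(resumed$nets), all_params_vec(full$nets))
  # corrupted/incompatible checkpoints are version errors
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(version = "other"), bad)
  expect_error(load_checkpoint(bad), class = "ctmrsyn_version_error")
})

test_that("the generator update direction approaches pure L1 regression as gamma grows", {
  set.seed(40)
  ds <- tiny_data()
  cfg <- tiny_cfg(1)
  nets <- ctmrsyn:::new_model_set(cfg)
  lay <- ctmrsyn:::model_layers(nets)
  pair <- ds$paired[[1]]
  ct <- to_network_domain(pair$ct)
  mr <- to_network_domain(pair$mr)
  n <- length(ct)

  grad_vec <- function() {
    unlist(lapply(lay$syn_mr, function(l) {
      unlist(lapply(l$params, function(p) as.numeric(l[[paste0("g_", p)]])))
    }), use.names = FALSE)
  }
  full_grad <- function(gamma) {
    ctmrsyn:::zero_grads(unlist(lay, recursive = FALSE))
    fake <- generator_forward(nets$syn_mr, ct)
    s <- discriminator_forward(nets$dis_mr,
                               array(c(ct, fake), c(dim(ct), 2)), "paired")
    p <- stats::plogis(s)
    rec <- generator_forward(nets$syn_ct, fake)
    dfake <- ctmrsyn:::discriminator_backward(nets$dis_mr,
                                              -p / length(p), "paired")[, , 2]
    dfake <- dfake + ctmrsyn:::generator_backward(
      nets$syn_ct, cfg$weights$lambda * sign(rec - ct) / n)[, , 1]
    dfake <- dfake + gamma * sign(fake - mr) / n
    ctmrsyn:::generator_backward(nets$syn_mr, dfake)
    grad_vec()
  }
  l1_grad <- function() {
    ctmrsyn:::zero_grads(unlist(lay, recursive = FALSE))
    fake <- generator_forward(nets$syn_mr, ct)
    ctmrsyn:::generator_backward(nets$syn_mr, sign(fake - mr) / n)
    grad_vec()
  }
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  ref <- l1_grad()
  cs <- vapply(c(1, 1e2, 1e4), function(g) cosine(full_grad(g), ref),
               numeric(1))
  expect_true(all(diff(cs) > 0))
  expect_gt(cs[3], 0.999)
})

test_that("a small step against the cycle gradient decreases the cycle loss", {
  set.seed(41)
  ds <- tiny_data()
  cfg <- tiny_cfg(1)
  nets <- ctmrsyn:::new_model_set(cfg)
  lay <- ctmrsyn:::model_layers(nets)
  ct <- to_network_domain(ds$paired[[1]]$ct)
  n <- length(ct)
  fake <- generator_forward(nets$syn_mr, ct)
  rec <- generator_forward(nets$syn_ct, fake)
  c0 <- cycle_loss(ct, rec)
  ctmrsyn:::zero_grads(unlist(lay, recursive = FALSE))
  dfake <- ctmrsyn:::generator_backward(nets$syn_ct,
                                        sign(rec - ct) / n)[, , 1]
  ctmrsyn:::generator_backward(nets$syn_mr, dfake)
  for (l in lay$syn_mr) {
    for (p in l$params) l[[p]] <- l[[p]] - 1e-4 * l[[paste0("g_", p)]]
  }
  rec2 <- generator_forward(nets$syn_ct, generator_forward(nets$syn_mr, ct))
  expect_lt(cycle_loss(ct, rec2), c0)
})
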