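test_that("default generator has nine residual blocks and preserves shape", {
  # small filter count keeps the test light; block count is the default
  gen <- build_generator(generator_spec(base_filters = 2))
  expect_equal(n_residual_blocks(gen), 9L)
  set.seed(1)
  x <- matrix(runif(64 * 64, -1, 1), 64, 64)
  y <- generator_forward(gen, x)
  expect_equal(dim(y), c(64L, 64L))
  x32 <- matrix(runif(32 * 32, -1, 1), 32, 32)
  expect_equal(dim(generator_forward(gen, x32)), c(32L, 32L))
  expect_error(generator_forward(gen, matrix(0, 30, 30)),
               class = "ctmrsyn_shape_error")
  expect_error(generator_spec(n_residual_blocks = 0),
               class = "ctmrsyn_config_error")
})

test_that("generator output is bounded by tanh for extreme inputs", {
  set.seed(2)
  gen <- build_generator(generator_spec(base_filters = 2,
                                        n_residual_blocks = 2))
  for (scale in c(1, 50)) {
    y <- generator_forward(gen, matrix(rnorm(32 * 32, sd = scale), 32, 32))
    expect_true(all(y >= -1 & y <= 1))
  }
})

test_that("resize-upsampling generator variant builds and preserves shape", {
  set.seed(3)
  gen <- build_generator(generator_spec(base_filters = 2,
                                        n_residual_blocks = 1,
                                        upsample = "resize"))
  y <- generator_forward(gen, matrix(runif(32 * 32, -1, 1), 32, 32))
  expect_equal(dim(y), c(32L, 32L))
})

test_that("the five named discriminator variants match their filter tables", {
  expected <- list(
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
  set.seed(4)
  x <- matrix(runif(64 * 64, -1, 1), 64, 64)
  for (nm in names(expected)) {
    d <- build_discriminator(disc_variant(nm))
    seqs <- disc_filter_sequence(d)
    expect_equal(seqs$head, expected[[nm]]$head)
    expect_equal(seqs$shared, expected[[nm]]$shared)
    expect_equal(seqs$tail, expected[[nm]]$tail)
    s <- discriminator_forward(d, x, "unpaired")
    expect_true(all(is.finite(s)))
    expect_true(all(dim(s) < 64))  # patch map strictly smaller than input
  }
  expect_length(build_discriminator(disc_variant("D5"))$tails$unpaired, 1L)
  expect_error(disc_variant("D9"), class = "ctmrsyn_config_error")
  expect_error(disc_variant("custom", head_filters = integer(0),
                            shared_filters = 1L, tail_filters = 1L),
               class = "ctmrsyn_config_error")
})

test_that("paired and unpaired paths share trunk parameters", {
  d <- build_discriminator(disc_variant("custom", head_filters = 4L,
                                        shared_filters = c(4L, 8L),
                                        tail_filters = c(4L, 1L)))
  un_path <- c(d$heads$unpaired, d$trunk, d$tails$unpaired)
  pr_path <- c(d$heads$paired, d$trunk, d$tails$paired)
  un_ids <- vapply(ctmrsyn:::collect_layers(un_path), `[[`, integer(1), "id")
  pr_ids <- vapply(ctmrsyn:::collect_layers(pr_path), `[[`, integer(1), "id")
  shared_ids <- intersect(un_ids, pr_ids)
  trunk_ids <- vapply(ctmrsyn:::collect_layers(d$trunk), `[[`, integer(1),
                      "id")
  expect_setequal(shared_ids, trunk_ids)  # trunk, and only trunk, is shared
  # deduplicated parameter collection counts trunk once
  all_layers <- ctmrsyn:::collect_layers(d)
  expect_equal(length(all_layers),
               length(un_ids) + length(pr_ids) - length(trunk_ids))
  # perturbing a trunk weight changes both paths' outputs
  set.seed(5)
  x1 <- matrix(runif(32 * 32, -1, 1), 32, 32)
  x2 <- array(runif(32 * 32 * 2, -1, 1), c(32, 32, 2))
  s_un <- discriminator_forward(d, x1, "unpaired")
  s_pr <- discriminator_forward(d, x2, "paired")
  d$trunk[[1]]$W <- d$trunk[[1]]$W + 0.5
  expect_false(identical(discriminator_forward(d, x1, "unpaired"), s_un))
  expect_false(identical(discriminator_forward(d, x2, "paired"), s_pr))
})

test_that("patch score maps have the documented ranges and determinism", {
  set.seed(6)
  d <- build_discriminator(disc_variant("custom", head_filters = 4L,
                                        shared_filters = c(4L, 8L),
                                        tail_filters = c(4L, 1L)))
  img <- matrix(runif(32 * 32, -1, 1), 32, 32)
  ct <- matrix(runif(32 * 32, -1, 1), 32, 32)
  p <- patch_score_map(d, img, ct = ct)
  expect_true(all(p > 0 & p < 1))  # sigmoid probabilities
  u <- patch_score_map(d, img)
  expect_true(all(is.finite(u)))   # raw least-squares scores
  expect_identical(p, patch_score_map(d, img, ct = ct))
  expect_identical(u, patch_score_map(d, img))
  # channel mismatch between head and input
  expect_error(discriminator_forward(d, array(0, c(32, 32, 2)), "unpaired"),
               class = "ctmrsyn_shape_error")
  expect_error(patch_score_map(d, img, ct = matrix(0, 16, 16)),
               class = "ctmrsyn_shape_error")
})
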