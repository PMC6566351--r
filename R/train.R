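#' Training configuration
#'
#' All hyperparameters of the alternating paired/unpaired training
#' procedure.  Defaults follow the published regime: Adam (beta1 = 0.5,
#' beta2 = 0.999) with batch size 1, learning rate 2e-4 held for
#' `warm_iters` iterations then decayed linearly to zero over
#' `decay_iters`, loss weights lambda = 10 and gamma = 100, and one
#' unpaired-phase pass plus one paired-phase pass per iteration
#' (`niter = 1`).  The total iteration budget is
#' `warm_iters + decay_iters`; desk-scale runs shrink those two numbers.
#'
#' @param alpha Initial learning rate.
#' @param batch_size Batch size m (>= 1).
#' @param niter Alternation block length (>= 1): number of consecutive
#'   unpaired steps, then paired steps, per outer iteration.
#' @param warm_iters,decay_iters Iterations at constant `alpha`, then
#'   linearly decaying to zero.
#' @param weights A [loss_weights()].
#' @param gen_spec A [generator_spec()] used for both synthesis networks.
#' @param disc_variant A [disc_variant()] used for both discriminators.
#' @param image_size Slice size the networks are trained on.
#' @param seed Integer seed controlling all trainer randomness.
#' @param checkpoint_every Save a checkpoint every this many iterations
#'   (0 = only at the end when `checkpoint_dir` is set).
#' @param checkpoint_dir Directory for checkpoints (`NULL` = none).
#' @param mode `"both"`, `"unpaired"` (cycle-consistency-only baseline) or
#'   `"paired"` (conditional adversarial + L1 baseline).
#' @param augment Apply training-time augmentation (shared draw per pair,
#'   independent draws per unpaired slice).
#' @param use_history_pool Feed the unpaired discriminators from a small
#'   history pool of previously synthesized images instead of only the
#'   current fake (off by default).
#' @return An object of class `ctmr_train_config`.
#' @export
train_config <- function(alpha = 2e-4, batch_size = 1L, niter = 1L,
                         warm_iters = 1e5, decay_iters = 2e5,
                         weights = loss_weights(),
                         gen_spec = generator_spec(),
                         disc_variant = ctmrsyn::disc_variant("D1"),
                         image_size = 256L, seed = 1L,
                         checkpoint_every = 0L, checkpoint_dir = NULL,
                         mode = c("both", "unpaired", "paired"),
                         augment = TRUE, use_history_pool = FALSE) {
  mode <- match.arg(mode)
  if (warm_iters < 0 || decay_iters < 0) {
    config_error("warm_iters and decay_iters must be >= 0")
  }
  if (batch_size < 1L) config_error("batch_size must be >= 1")
  if (niter < 1L) config_error("niter must be >= 1")
  stopifnot(inherits(weights, "ctmr_loss_weights"),
            inherits(gen_spec, "ctmr_generator_spec"),
            inherits(disc_variant, "ctmr_disc_variant"))
  structure(
    list(alpha = alpha, batch_size = as.integer(batch_size),
         niter = as.integer(niter), warm_iters = warm_iters,
         decay_iters = decay_iters, weights = weights,
         gen_spec = gen_spec, disc_variant = disc_variant,
         image_size = as.integer(image_size), seed = as.integer(seed),
         checkpoint_every = as.integer(checkpoint_every),
         checkpoint_dir = checkpoint_dir, mode = mode,
         augment = isTRUE(augment),
         use_history_pool = isTRUE(use_history_pool)),
    class = "ctmr_train_config"
  )
}

#' Learning-rate schedule
#'
#' Constant `alpha` for the first `warm_iters` iterations, then linear
#' decay to exactly zero at iteration `warm_iters + decay_iters`.
#' Iterations are counted from 0.
#'
#' @param iteration 0-based iteration index, at most
#'   `warm_iters + decay_iters`.
#' @param cfg A [train_config()].
#' @return The learning rate.
#' @export
lr_schedule <- function(iteration, cfg) {
  total <- cfg$warm_iters + cfg$decay_iters
  if (any(iteration < 0 | iteration > total)) {
    ctmr_abort(sprintf("iteration outside [0, %g]", total),
               "ctmrsyn_config_error")
  }
  ifelse(iteration < cfg$warm_iters, cfg$alpha,
         if (cfg$decay_iters == 0) 0 else {
           cfg$alpha * (1 - (iteration - cfg$warm_iters) / cfg$decay_iters)
         })
}

# --- internal training state ------------------------------------------------

new_model_set <- function(cfg) {
  list(
    syn_mr = build_generator(cfg$gen_spec),
    syn_ct = build_generator(cfg$gen_spec),
    dis_mr = build_discriminator(cfg$disc_variant),
    dis_ct = build_discriminator(cfg$disc_variant)
  )
}

model_layers <- function(nets) {
  lapply(nets, collect_layers)
}

new_history_pool <- function(capacity = 50L) {
  p <- new.env(parent = emptyenv())
  p$items <- list()
  p$capacity <- capacity
  p
}

history_query <- function(pool, fake) {
  if (is.null(pool)) return(fake)
  if (length(pool$items) < pool$capacity) {
    pool$items[[length(pool$items) + 1L]] <- fake
    return(fake)
  }
  if (runif(1) < 0.5) {
    i <- sample.int(length(pool$items), 1L)
    out <- pool$items[[i]]
    pool$items[[i]] <- fake
    out
  } else fake
}

sign0 <- function(x) sign(x)

# Gray slice -> augmented network-domain matrix.
prep_slice <- function(slice, cfg, params = NULL) {
  if (cfg$augment) {
    if (is.null(params)) params <- sample_augment_params(cfg$image_size)
    slice <- apply_augment(slice, params)
  }
  to_network_domain(slice)
}

# One unpaired-phase pass: DisMR, SynMR, DisCT, SynCT updates in order.
unpaired_phase_step <- function(st, batch_ct, batch_mr, cfg, lr) {
  nets <- st$nets; lay <- st$layers
  m <- length(batch_ct)
  w <- cfg$weights
  d_mr_v <- adv_mr_v <- cyc_f_v <- d_ct_v <- adv_ct_v <- cyc_b_v <- 0

  # DisMR: least-squares on real MR vs SynMR(CT)
  zero_grads(lay$dis_mr)
  for (i in seq_len(m)) {
    fake <- generator_forward(nets$syn_mr, batch_ct[[i]])
    fake_d <- history_query(st$pool_mr, fake)
    s_real <- discriminator_forward(nets$dis_mr, batch_mr[[i]], "unpaired")
    s_fake <- discriminator_forward(nets$dis_mr, fake_d, "unpaired")
    # note: forward caches are per-layer; backprop each term right away
    d_mr_v <- d_mr_v + lsgan_d_loss(s_real, s_fake) / m
    discriminator_backward(nets$dis_mr, 2 * s_fake / length(s_fake) / m,
                           "unpaired")
    s_real <- discriminator_forward(nets$dis_mr, batch_mr[[i]], "unpaired")
    discriminator_backward(nets$dis_mr,
                           2 * (s_real - 1) / length(s_real) / m, "unpaired")
  }
  adam_step(lay$dis_mr, lr)

  # SynMR: fool DisMR + forward cycle CT -> MR -> CT
  zero_grads(lay$syn_mr); zero_grads(lay$syn_ct); zero_grads(lay$dis_mr)
  for (i in seq_len(m)) {
    ct <- batch_ct[[i]]
    fake <- generator_forward(nets$syn_mr, ct)
    s_fake <- discriminator_forward(nets$dis_mr, fake, "unpaired")
    rec <- generator_forward(nets$syn_ct, fake)
    adv_mr_v <- adv_mr_v + lsgan_g_loss(s_fake) / m
    cyc_f_v <- cyc_f_v + cycle_loss(ct, rec) / m
    dfake <- discriminator_backward(
      nets$dis_mr, 2 * (s_fake - 1) / length(s_fake) / m, "unpaired")[, , 1L]
    dfake <- dfake + generator_backward(
      nets$syn_ct,
      w$lambda * sign0(rec - ct) / length(rec) / m)[, , 1L]
    generator_backward(nets$syn_mr, dfake)
  }
  adam_step(lay$syn_mr, lr)

  # DisCT: least-squares on real CT vs SynCT(MR)
  zero_grads(lay$dis_ct); zero_grads(lay$syn_ct)
  for (i in seq_len(m)) {
    fake <- generator_forward(nets$syn_ct, batch_mr[[i]])
    fake_d <- history_query(st$pool_ct, fake)
    s_fake <- discriminator_forward(nets$dis_ct, fake_d, "unpaired")
    s_real <- discriminator_forward(nets$dis_ct, batch_ct[[i]], "unpaired")
    d_ct_v <- d_ct_v + lsgan_d_loss(s_real, s_fake) / m
    discriminator_backward(nets$dis_ct,
                           2 * (s_real - 1) / length(s_real) / m, "unpaired")
    s_fake <- discriminator_forward(nets$dis_ct, fake_d, "unpaired")
    discriminator_backward(nets$dis_ct, 2 * s_fake / length(s_fake) / m,
                           "unpaired")
  }
  adam_step(lay$dis_ct, lr)

  # SynCT: fool DisCT + backward cycle MR -> CT -> MR
  zero_grads(lay$syn_ct); zero_grads(lay$syn_mr); zero_grads(lay$dis_ct)
  for (i in seq_len(m)) {
    mr <- batch_mr[[i]]
    fake <- generator_forward(nets$syn_ct, mr)
    s_fake <- discriminator_forward(nets$dis_ct, fake, "unpaired")
    rec <- generator_forward(nets$syn_mr, fake)
    adv_ct_v <- adv_ct_v + lsgan_g_loss(s_fake) / m
    cyc_b_v <- cyc_b_v + cycle_loss(mr, rec) / m
    dfake <- discriminator_backward(
      nets$dis_ct, 2 * (s_fake - 1) / length(s_fake) / m, "unpaired")[, , 1L]
    dfake <- dfake + generator_backward(
      nets$syn_mr,
      w$lambda * sign0(rec - mr) / length(rec) / m)[, , 1L]
    generator_backward(nets$syn_ct, dfake)
  }
  adam_step(lay$syn_ct, lr)

  bd <- total_objective(adv_mr_v, adv_ct_v, cyc_f_v + cyc_b_v, 0, w)
  c(bd, list(d_mr = d_mr_v, d_ct = d_ct_v))
}

# One paired-phase pass: conditional discriminators (log-likelihood) and
# generators with adversarial + cycle + voxel-wise L1 terms.
paired_phase_step <- function(st, batch_pairs, cfg, lr) {
  nets <- st$nets; lay <- st$layers
  m <- length(batch_pairs)
  w <- cfg$weights
  d_mr_v <- adv_mr_v <- cyc_f_v <- vox_mr_v <- 0
  d_ct_v <- adv_ct_v <- cyc_b_v <- vox_ct_v <- 0
  pair_in <- function(a, b) array(c(a, b), c(dim(a), 2L))

  # DisMR: ascend log D(ct, mr) + log(1 - D(ct, SynMR(ct)))
  zero_grads(lay$dis_mr)
  for (i in seq_len(m)) {
    ct <- batch_pairs[[i]]$ct; mr <- batch_pairs[[i]]$mr
    fake <- generator_forward(nets$syn_mr, ct)
    s_fake <- discriminator_forward(nets$dis_mr, pair_in(ct, fake), "paired")
    p_fake <- stats::plogis(s_fake)
    discriminator_backward(nets$dis_mr, p_fake / length(p_fake) / m,
                           "paired")
    s_real <- discriminator_forward(nets$dis_mr, pair_in(ct, mr), "paired")
    p_real <- stats::plogis(s_real)
    d_mr_v <- d_mr_v + nll_paired_d_loss(p_real, p_fake) / m
    discriminator_backward(nets$dis_mr,
                           -(1 - p_real) / length(p_real) / m, "paired")
  }
  adam_step(lay$dis_mr, lr)

  # SynMR: descend log(1 - D(ct, fake)) + lambda*cycle + gamma*L1(mr, fake)
  zero_grads(lay$syn_mr); zero_grads(lay$syn_ct); zero_grads(lay$dis_mr)
  for (i in seq_len(m)) {
    ct <- batch_pairs[[i]]$ct; mr <- batch_pairs[[i]]$mr
    fake <- generator_forward(nets$syn_mr, ct)
    s_fake <- discriminator_forward(nets$dis_mr, pair_in(ct, fake), "paired")
    p_fake <- stats::plogis(s_fake)
    rec <- generator_forward(nets$syn_ct, fake)
    adv_mr_v <- adv_mr_v + nll_paired_g_loss(p_fake) / m
    cyc_f_v <- cyc_f_v + cycle_loss(ct, rec) / m
    vox_mr_v <- vox_mr_v + voxel_l1_loss(mr, fake) / m
    dpair <- discriminator_backward(nets$dis_mr,
                                    -p_fake / length(p_fake) / m, "paired")
    dfake <- dpair[, , 2L]
    dfake <- dfake + generator_backward(
      nets$syn_ct, w$lambda * sign0(rec - ct) / length(rec) / m)[, , 1L]
    dfake <- dfake + w$gamma * sign0(fake - mr) / length(fake) / m
    generator_backward(nets$syn_mr, dfake)
  }
  adam_step(lay$syn_mr, lr)

  # DisCT: ascend log D(mr, ct) + log(1 - D(mr, SynCT(mr)))
  zero_grads(lay$dis_ct); zero_grads(lay$syn_ct)
  for (i in seq_len(m)) {
    ct <- batch_pairs[[i]]$ct; mr <- batch_pairs[[i]]$mr
    fake <- generator_forward(nets$syn_ct, mr)
    s_fake <- discriminator_forward(nets$dis_ct, pair_in(mr, fake), "paired")
    p_fake <- stats::plogis(s_fake)
    discriminator_backward(nets$dis_ct, p_fake / length(p_fake) / m,
                           "paired")
    s_real <- discriminator_forward(nets$dis_ct, pair_in(mr, ct), "paired")
    p_real <- stats::plogis(s_real)
    d_ct_v <- d_ct_v + nll_paired_d_loss(p_real, p_fake) / m
    discriminator_backward(nets$dis_ct,
                           -(1 - p_real) / length(p_real) / m, "paired")
  }
  adam_step(lay$dis_ct, lr)

  # SynCT: descend log(1 - D(mr, fake)) + lambda*cycle + gamma*L1(ct, fake)
  zero_grads(lay$syn_ct); zero_grads(lay$syn_mr); zero_grads(lay$dis_ct)
  for (i in seq_len(m)) {
    ct <- batch_pairs[[i]]$ct; mr <- batch_pairs[[i]]$mr
    fake <- generator_forward(nets$syn_ct, mr)
    s_fake <- discriminator_forward(nets$dis_ct, pair_in(mr, fake), "paired")
    p_fake <- stats::plogis(s_fake)
    rec <- generator_forward(nets$syn_mr, fake)
    adv_ct_v <- adv_ct_v + nll_paired_g_loss(p_fake) / m
    cyc_b_v <- cyc_b_v + cycle_loss(mr, rec) / m
    vox_ct_v <- vox_ct_v + voxel_l1_loss(ct, fake) / m
    dpair <- discriminator_backward(nets$dis_ct,
                                    -p_fake / length(p_fake) / m, "paired")
    dfake <- dpair[, , 2L]
    dfake <- dfake + generator_backward(
      nets$syn_mr, w$lambda * sign0(rec - mr) / length(rec) / m)[, , 1L]
    dfake <- dfake + w$gamma * sign0(fake - ct) / length(fake) / m
    generator_backward(nets$syn_ct, dfake)
  }
  adam_step(lay$syn_ct, lr)

  bd <- total_objective(adv_mr_v, adv_ct_v, cyc_f_v + cyc_b_v,
                        vox_mr_v + vox_ct_v, w)
  c(bd, list(d_mr = d_mr_v, d_ct = d_ct_v))
}

as_train_data <- function(dataset) {
  if (is.character(dataset)) dataset <- load_slice_dataset(dataset)
  if (inherits(dataset, "ctmr_phantom_dataset") || is.list(dataset)) {
    list(paired = dataset$paired %||% list(),
         unpaired_ct = dataset$unpaired_ct %||% list(),
         unpaired_mr = dataset$unpaired_mr %||% list())
  } else {
    data_error("dataset must be a phantom dataset, a compatible list, or a manifest directory")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train the synthesis system
#'
#' Runs the alternating training procedure: per outer iteration, `niter`
#' unpaired-phase passes (least-squares adversarial + forward/backward
#' cycle consistency on the unpaired pools) followed by `niter`
#' paired-phase passes (conditional log-likelihood adversarial +
#' cycle-consistency + voxel-wise L1 on the registered pairs).  Each pass
#' updates DisMR, SynMR, DisCT, SynCT in that order with Adam at the
#' scheduled learning rate.  A phase only runs if its regime has data and
#' the configured mode allows it; `mode = "unpaired"` reproduces a
#' cycle-consistency-only baseline and `mode = "paired"` a conditional
#' adversarial + L1 baseline.
#'
#' @param dataset A `ctmr_phantom_dataset`, a list with elements `paired`,
#'   `unpaired_ct`, `unpaired_mr`, or a dataset directory with a manifest.
#' @param cfg A [train_config()].
#' @param resume_from Optional checkpoint path; training continues from the
#'   stored iteration with restored network, optimizer and RNG state
#'   (identical continuation to an uninterrupted run).
#' @return An object of class `ctmr_fit` with elements `nets`, `iteration`,
#'   `log` (tibble, one row per phase per iteration), `config`, and
#'   `checkpoint` (path of the last checkpoint or `NULL`).
#' @export
train <- function(dataset, cfg, resume_from = NULL) {
  stopifnot(inherits(cfg, "ctmr_train_config"))
  data <- as_train_data(dataset)
  use_unpaired <- cfg$mode %in% c("both", "unpaired")
  use_paired <- cfg$mode %in% c("both", "paired")
  have_unpaired <- length(data$unpaired_ct) > 0 && length(data$unpaired_mr) > 0
  have_paired <- length(data$paired) > 0
  if (cfg$mode == "unpaired" && !have_unpaired) {
    data_error("unpaired mode requested but an unpaired pool is empty")
  }
  if (cfg$mode == "paired" && !have_paired) {
    data_error("paired mode requested but there is no paired data")
  }
  run_unpaired <- use_unpaired && have_unpaired
  run_paired <- use_paired && have_paired
  if (!run_unpaired && !run_paired) {
    data_error("no usable data for any training phase")
  }

  st <- new.env(parent = emptyenv())
  total <- cfg$warm_iters + cfg$decay_iters
  if (is.null(resume_from)) {
    set.seed(cfg$seed)
    st$nets <- new_model_set(cfg)
    st$iteration <- 0L
  } else {
    ck <- load_checkpoint(resume_from)
    st$nets <- ck$nets
    st$iteration <- ck$iteration
    assign(".Random.seed", ck$rng_state, envir = globalenv())
  }
  st$layers <- model_layers(st$nets)
  st$pool_mr <- if (cfg$use_history_pool) new_history_pool() else NULL
  st$pool_ct <- if (cfg$use_history_pool) new_history_pool() else NULL

  # pre-normalized pools are only valid without augmentation; with
  # augmentation we keep gray slices and transform per draw
  log_rows <- list()
  ckpt_path <- NULL
  n_pairs <- length(data$paired)
  n_uct <- length(data$unpaired_ct)
  n_umr <- length(data$unpaired_mr)

  while (st$iteration < total) {
    it <- st$iteration
    lr <- lr_schedule(it, cfg)
    st$iteration <- it + 1L
    if (run_unpaired) {
      acc <- NULL
      for (k in seq_len(cfg$niter)) {
        idx_ct <- sample.int(n_uct, cfg$batch_size, replace = TRUE)
        idx_mr <- sample.int(n_umr, cfg$batch_size, replace = TRUE)
        batch_ct <- lapply(data$unpaired_ct[idx_ct], prep_slice, cfg = cfg)
        batch_mr <- lapply(data$unpaired_mr[idx_mr], prep_slice, cfg = cfg)
        res <- unpaired_phase_step(st, batch_ct, batch_mr, cfg, lr)
        acc <- if (is.null(acc)) res else Map(`+`, acc, res)
      }
      acc <- lapply(acc, `/`, cfg$niter)
      log_rows[[length(log_rows) + 1L]] <-
        c(list(iteration = st$iteration, phase = "unpaired"), acc,
          list(lr = lr))
    }
    if (run_paired) {
      acc <- NULL
      for (k in seq_len(cfg$niter)) {
        idx <- sample.int(n_pairs, cfg$batch_size, replace = TRUE)
        batch <- lapply(data$paired[idx], function(p) {
          if (cfg$augment) {
            ap <- sample_augment_params(cfg$image_size)
            p <- augment_pair(p, ap)
          }
          list(ct = to_network_domain(p$ct), mr = to_network_domain(p$mr))
        })
        res <- paired_phase_step(st, batch, cfg, lr)
        acc <- if (is.null(acc)) res else Map(`+`, acc, res)
      }
      acc <- lapply(acc, `/`, cfg$niter)
      log_rows[[length(log_rows) + 1L]] <-
        c(list(iteration = st$iteration, phase = "paired"), acc,
          list(lr = lr))
    }
    if (!is.null(cfg$checkpoint_dir) && cfg$checkpoint_every > 0L &&
        st$iteration %% cfg$checkpoint_every == 0L) {
      ckpt_path <- save_checkpoint(st, cfg)
    }
  }
  if (!is.null(cfg$checkpoint_dir)) {
    ckpt_path <- save_checkpoint(st, cfg)
  }
  log <- do.call(rbind, lapply(log_rows, function(r) {
    tibble::tibble(iteration = r$iteration, phase = r$phase,
                   adv_mr = r$adv_mr, adv_ct = r$adv_ct,
                   dual_cyc = r$dual_cyc, voxel_l1 = r$voxel_l1,
                   d_mr = r$d_mr, d_ct = r$d_ct, total = r$total, lr = r$lr)
  }))
  if (is.null(log)) {
    log <- tibble::tibble(iteration = integer(0), phase = character(0),
                          adv_mr = numeric(0), adv_ct = numeric(0),
                          dual_cyc = numeric(0), voxel_l1 = numeric(0),
                          d_mr = numeric(0), d_ct = numeric(0),
                          total = numeric(0), lr = numeric(0))
  }
  structure(list(nets = st$nets, iteration = st$iteration, log = log,
                 config = cfg, checkpoint = ckpt_path),
            class = "ctmr_fit")
}

#' @export
print.ctmr_fit <- function(x, ...) {
  cat(sprintf("<ctmr_fit> %d iterations, mode '%s', %d log rows\n",
              x$iteration, x$config$mode, nrow(x$log)))
  invisible(x)
}

#' Write the per-iteration loss log as CSV
#'
#' One row per iteration and phase: iteration, phase, each loss component
#' (generator adversarial terms, dual cycle, voxel L1, discriminator
#' losses), weighted total and learning rate.
#'
#' @param fit A `ctmr_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_train_log <- function(fit, path) {
  utils::write.csv(fit$log, path, row.names = FALSE)
  invisible(path)
}

# --- checkpoints ------------------------------------------------------------

CKPT_VERSION <- "ctmrsyn-checkpoint-1"

#' Save and load training checkpoints
#'
#' A checkpoint is a single self-describing archive holding the iteration
#' counter, all four networks' parameters, Adam optimizer state, the RNG
#' state, and the architecture description needed to rebuild the networks.
#'
#' @param st Internal training state (or a `ctmr_fit`).
#' @param cfg The training configuration.
#' @param path Target file; defaults to
#'   `checkpoint_dir/ckpt_<iteration>.rds`.
#' @return `save_checkpoint` returns the path; `load_checkpoint` returns a
#'   list with `nets`, `iteration`, `rng_state`, `gen_spec`,
#'   `disc_variant`.
#' @export
save_checkpoint <- function(st, cfg, path = NULL) {
  if (inherits(st, "ctmr_fit")) {
    st <- list2env(list(nets = st$nets, iteration = st$iteration,
                        layers = model_layers(st$nets)))
  }
  if (is.null(path)) {
    dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(cfg$checkpoint_dir,
                      sprintf("ckpt_%06d.rds", st$iteration))
  }
  rng <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  obj <- list(
    version = CKPT_VERSION,
    iteration = st$iteration,
    gen_spec = cfg$gen_spec,
    disc_variant = cfg$disc_variant,
    params = lapply(st$layers %||% model_layers(st$nets), export_params,
                    with_opt = TRUE),
    rng_state = rng
  )
  saveRDS(obj, path)
  path
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) data_error(sprintf("no checkpoint at '%s'", path))
  obj <- readRDS(path)
  if (!identical(obj$version, CKPT_VERSION)) {
    version_error(sprintf("unsupported checkpoint version '%s'",
                          obj$version %||% "<missing>"))
  }
  cfg_like <- list(gen_spec = obj$gen_spec, disc_variant = obj$disc_variant)
  nets <- list(
    syn_mr = build_generator(obj$gen_spec),
    syn_ct = build_generator(obj$gen_spec),
    dis_mr = build_discriminator(obj$disc_variant),
    dis_ct = build_discriminator(obj$disc_variant)
  )
  lay <- model_layers(nets)
  for (nm in names(nets)) {
    import_params(lay[[nm]], obj$params[[nm]], with_opt = TRUE)
  }
  list(nets = nets, iteration = obj$iteration, rng_state = obj$rng_state,
       gen_spec = obj$gen_spec, disc_variant = obj$disc_variant)
}
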