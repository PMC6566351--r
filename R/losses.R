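#' Loss weights of the overall objective
#'
#' `lambda` scales the dual cycle-consistency term and `gamma` the paired
#' voxel-wise L1 term in the total objective
#' \eqn{L = L_{adv,MR} + L_{adv,CT} + \lambda L_{cyc} + \gamma L_{L1}}.
#' Defaults are \eqn{\lambda = 10}, \eqn{\gamma = 100}.
#'
#' @param lambda,gamma Non-negative weights.
#' @return An object of class `ctmr_loss_weights`.
#' @export
loss_weights <- function(lambda = 10, gamma = 100) {
  if (lambda < 0 || gamma < 0) {
    config_error("loss weights must be non-negative")
  }
  structure(list(lambda = lambda, gamma = gamma),
            class = "ctmr_loss_weights")
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    numeric_error(paste("non-finite values in", what))
  }
  invisible(x)
}

#' Least-squares adversarial losses (unpaired regime)
#'
#' The discriminator targets label 1 on real images and 0 on synthesized
#' images; the generator targets 1 on its own output.  Means are taken over
#' the patch-score map.
#'
#' @param scores_real,scores_fake Raw patch-score grids.
#' @return A scalar loss.
#' @export
lsgan_d_loss <- function(scores_real, scores_fake) {
  check_finite(scores_real, "scores_real")
  check_finite(scores_fake, "scores_fake")
  mean((scores_real - 1)^2) + mean(scores_fake^2)
}

#' @rdname lsgan_d_loss
#' @export
lsgan_g_loss <- function(scores_fake) {
  check_finite(scores_fake, "scores_fake")
  mean((scores_fake - 1)^2)
}

clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Conditional log-likelihood adversarial losses (paired regime)
#'
#' `nll_paired_d_loss` is the discriminator's *ascent* objective
#' \eqn{\mathrm{mean}\,\log p_{real} + \mathrm{mean}\,\log(1 - p_{fake})}
#' (its supremum is 0); the trainer descends its negation.
#' `nll_paired_g_loss` is \eqn{\mathrm{mean}\,\log(1 - p_{fake})}, descended
#' by the generator.  Probabilities are clamped to
#' \eqn{[\epsilon, 1-\epsilon]} with \eqn{\epsilon = 10^{-7}} before logs.
#'
#' @param prob_real_pair,prob_fake_pair Probability grids from the paired
#'   (sigmoid) head.
#' @return A scalar.
#' @export
nll_paired_d_loss <- function(prob_real_pair, prob_fake_pair) {
  check_finite(prob_real_pair, "prob_real_pair")
  check_finite(prob_fake_pair, "prob_fake_pair")
  mean(log(clamp_prob(prob_real_pair))) +
    mean(log1p(-clamp_prob(prob_fake_pair)))
}

#' @rdname nll_paired_d_loss
#' @export
nll_paired_g_loss <- function(prob_fake_pair) {
  check_finite(prob_fake_pair, "prob_fake_pair")
  mean(log1p(-clamp_prob(prob_fake_pair)))
}

#' Cycle-consistency and voxel-wise L1 losses
#'
#' Both are the mean absolute difference over pixels of two equally shaped
#' grids in the network domain.  `cycle_loss` compares a round-trip
#' reconstruction with the original; `voxel_l1_loss` compares a synthesized
#' image with its registered reference.  The full dual cycle-consistency
#' term is the sum of `cycle_loss` over the four cycles (forward/backward
#' times paired/unpaired), assembled by the trainer.
#'
#' @param original,reconstructed,reference,synthesized Equal-shape numeric
#'   grids.
#' @return A scalar mean absolute difference.
#' @export
cycle_loss <- function(original, reconstructed) {
  if (!all(dim(original) == dim(reconstructed))) {
    shape_error("cycle_loss arguments have different shapes")
  }
  mean(abs(reconstructed - original))
}

#' @rdname cycle_loss
#' @export
voxel_l1_loss <- function(reference, synthesized) {
  if (!all(dim(reference) == dim(synthesized))) {
    shape_error("voxel_l1_loss arguments have different shapes")
  }
  mean(abs(synthesized - reference))
}

#' Assemble the weighted total objective
#'
#' @param adv_mr,adv_ct Adversarial components for the two synthesis
#'   directions.
#' @param dual_cyc Dual cycle-consistency component.
#' @param voxel Voxel-wise L1 component.
#' @param w A [loss_weights()].
#' @return An object of class `ctmr_loss_breakdown`: a list with the four
#'   components and `total = adv_mr + adv_ct + lambda * dual_cyc +
#'   gamma * voxel_l1`.
#' @export
total_objective <- function(adv_mr, adv_ct, dual_cyc, voxel,
                            w = loss_weights()) {
  stopifnot(inherits(w, "ctmr_loss_weights"))
  check_finite(c(adv_mr, adv_ct, dual_cyc, voxel), "loss components")
  structure(
    list(adv_mr = adv_mr, adv_ct = adv_ct, dual_cyc = dual_cyc,
         voxel_l1 = voxel,
         total = adv_mr + adv_ct + w$lambda * dual_cyc + w$gamma * voxel),
    class = "ctmr_loss_breakdown"
  )
}
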