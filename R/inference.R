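# At inference time only the CT->MR synthesis network is run; the reverse
# network is used by reconstruct_cycle() to audit cycle consistency.

as_slice_stack <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (is.list(x)) x <- simplify2array(x)
  if (length(dim(x)) != 3L) shape_error("expected a slice stack (3D array)")
  x
}

resolve_nets <- function(checkpoint) {
  if (inherits(checkpoint, "ctmr_fit")) {
    list(nets = checkpoint$nets, id = "in-memory fit")
  } else if (is.character(checkpoint)) {
    ck <- load_checkpoint(checkpoint)
    list(nets = ck$nets, id = checkpoint)
  } else if (is.list(checkpoint) && !is.null(checkpoint$nets)) {
    list(nets = checkpoint$nets, id = "network set")
  } else {
    version_error("checkpoint must be a ctmr_fit, a checkpoint path, or a network set")
  }
}

#' Synthesize MR slices from CT input
#'
#' Each CT slice is normalized to the network domain, passed through the
#' trained CT->MR synthesis network, and mapped back to \eqn{[0, 255]}.
#' Deterministic given checkpoint and input.
#'
#' @param checkpoint A `ctmr_fit`, a checkpoint file path, or a list with a
#'   `nets` element.
#' @param ct_inputs A gray slice (matrix), a list of slices, or an
#'   H-by-W-by-N stack, with H and W divisible by 4.
#' @param source_manifest Optional provenance table for the inputs, carried
#'   through to the result.
#' @return An object of class `ctmr_synthesis`: list with `slices`
#'   (H-by-W-by-N array in \eqn{[0, 255]}), `source_manifest` and
#'   `checkpoint_id`.
#' @export
synthesize <- function(checkpoint, ct_inputs, source_manifest = NULL) {
  rs <- resolve_nets(checkpoint)
  stack <- as_slice_stack(ct_inputs)
  out <- array(0, dim(stack))
  for (i in seq_len(dim(stack)[3L])) {
    z <- to_network_domain(stack[, , i])
    out[, , i] <- from_network_domain(generator_forward(rs$nets$syn_mr, z))
  }
  structure(list(slices = out, source_manifest = source_manifest,
                 checkpoint_id = rs$id),
            class = "ctmr_synthesis")
}

#' Round-trip cycle reconstruction
#'
#' Synthesizes MR from CT, translates it back to CT, and reports the
#' per-pixel relative difference \eqn{|rec - ct| / (ct + 1)} (one gray
#' level in the denominator guards division by the black background).
#'
#' @param checkpoint As in [synthesize()]; must contain both synthesis
#'   networks.
#' @param ct_inputs As in [synthesize()].
#' @return A list with `synth_mr`, `reconstructed_ct` (stacks in
#'   \eqn{[0, 255]}) and `rel_diff` (non-negative stack).
#' @export
reconstruct_cycle <- function(checkpoint, ct_inputs) {
  rs <- resolve_nets(checkpoint)
  if (is.null(rs$nets$syn_ct)) {
    version_error("checkpoint lacks the reverse (MR->CT) synthesis network")
  }
  stack <- as_slice_stack(ct_inputs)
  mr <- array(0, dim(stack))
  rec <- array(0, dim(stack))
  for (i in seq_len(dim(stack)[3L])) {
    z <- to_network_domain(stack[, , i])
    zm <- generator_forward(rs$nets$syn_mr, z)
    mr[, , i] <- from_network_domain(zm)
    rec[, , i] <- from_network_domain(generator_forward(rs$nets$syn_ct, zm))
  }
  list(synth_mr = mr, reconstructed_ct = rec,
       rel_diff = abs(rec - stack) / (stack + 1))
}
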