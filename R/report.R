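#' Per-patient metric report
#'
#' Computes MAE, PSNR and SSIM between reference and synthesized MR stacks
#' for each patient and appends column averages, the layout of a standard
#' per-patient evaluation table.  Non-finite PSNR values (identical
#' stacks) are excluded from the PSNR average.
#'
#' @param patients A named list; each element is a list with `reference`
#'   and `synthesized` slice stacks (equal shapes).
#' @param cfg A [metric_config()].
#' @return An object of class `ctmr_metric_report`: a list with `rows`
#'   (tibble: patient, mae, psnr, ssim) and `averages` (one-row tibble).
#' @export
build_report <- function(patients, cfg = metric_config()) {
  if (length(patients) == 0) data_error("no patients to evaluate")
  ids <- names(patients)
  if (is.null(ids)) ids <- sprintf("Pat-%02d", seq_along(patients))
  rows <- do.call(rbind, lapply(seq_along(patients), function(i) {
    p <- patients[[i]]
    tibble::tibble(
      patient = ids[i],
      mae = mae(p$reference, p$synthesized, cfg),
      psnr = psnr(p$reference, p$synthesized, cfg),
      ssim = ssim(p$reference, p$synthesized, cfg)
    )
  }))
  finite_psnr <- rows$psnr[is.finite(rows$psnr)]
  averages <- tibble::tibble(
    patient = "Average",
    mae = mean(rows$mae),
    psnr = if (length(finite_psnr)) mean(finite_psnr) else Inf,
    ssim = mean(rows$ssim)
  )
  structure(list(rows = rows, averages = averages, config = cfg),
            class = "ctmr_metric_report")
}

#' @export
print.ctmr_metric_report <- function(x, ...) {
  print(rbind(x$rows, x$averages))
  invisible(x)
}

#' Write a metric report as CSV
#'
#' @param report A `ctmr_metric_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(rbind(report$rows, report$averages), path,
                   row.names = FALSE)
  invisible(path)
}

# --- broom-style accessors ---------------------------------------------------

#' Tidy methods for fitted objects and reports
#'
#' `tidy()` returns the long per-unit table (per-iteration losses for a
#' fit, per-patient metrics for a report); `glance()` returns a one-row
#' summary.
#'
#' @param x A `ctmr_fit` or `ctmr_metric_report`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.ctmr_fit <- function(x, ...) x$log

#' @rdname tidiers
#' @export
tidy.ctmr_metric_report <- function(x, ...) x$rows

#' @rdname tidiers
#' @export
glance.ctmr_fit <- function(x, ...) {
  last <- x$log[x$log$iteration == max(x$log$iteration), ]
  tibble::tibble(
    iterations = x$iteration,
    mode = x$config$mode,
    final_total = mean(last$total),
    final_dual_cyc = mean(last$dual_cyc),
    final_voxel_l1 = mean(last$voxel_l1)
  )
}

#' @rdname tidiers
#' @export
glance.ctmr_metric_report <- function(x, ...) {
  tibble::tibble(n_patients = nrow(x$rows), mae = x$averages$mae,
                 psnr = x$averages$psnr, ssim = x$averages$ssim)
}

# --- plotting ----------------------------------------------------------------

#' Plot training losses or report metrics
#'
#' `autoplot.ctmr_fit` draws per-iteration loss curves facetted by
#' component; `autoplot.ctmr_metric_report` draws per-patient metric
#' points.  Requires ggplot2.
#'
#' @param object A `ctmr_fit` or `ctmr_metric_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.ctmr_fit <- function(object, ...) {
  log <- object$log
  long <- do.call(rbind, lapply(
    c("adv_mr", "adv_ct", "dual_cyc", "voxel_l1", "total"),
    function(comp) {
      tibble::tibble(iteration = log$iteration, phase = log$phase,
                     component = comp, value = log[[comp]])
    }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = "loss")
}

#' @rdname autoplot.ctmr_fit
#' @export
autoplot.ctmr_metric_report <- function(object, ...) {
  rows <- object$rows
  long <- do.call(rbind, lapply(c("mae", "psnr", "ssim"), function(mtr) {
    tibble::tibble(patient = rows$patient, metric = mtr,
                   value = rows[[mtr]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$patient, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}

#' Display a gray slice
#'
#' @param slice Matrix in \eqn{[0, 255]}.
#' @param main Plot title.
#' @return Invisibly, `slice`.
#' @export
plot_slice <- function(slice, main = "") {
  graphics::image(t(slice)[, rev(seq_len(nrow(slice)))],
                  col = grey.colors(256, 0, 1), axes = FALSE, main = main,
                  useRaster = TRUE)
  invisible(slice)
}
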