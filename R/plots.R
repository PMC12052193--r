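#' QQ plot of association p-values
#'
#' @param object a [qq_data()] tibble.
#' @param ... unused.
#' @return A ggplot: observed vs expected -log10 p with the identity line.
#' @method autoplot ratxcan_qq
#' @export
autoplot.ratxcan_qq <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' Plot association results as a Manhattan-style panel
#'
#' @param results association tibble with `gene_id`, `p` and optionally
#'   `chr`/`chrom` and `start` columns (gene index used otherwise).
#' @param threshold optional significance line (e.g. the Bonferroni level).
#' @return A ggplot.
#' @export
plot_association <- function(results, threshold = NULL) {
  results <- as_tibble(results)
  pcol <- if ("p_acat" %in% names(results)) "p_acat" else "p"
  ccol <- intersect(c("chr", "chrom"), names(results))
  df <- tibble(
    idx = seq_len(nrow(results)),
    chrom = if (length(ccol)) as.factor(results[[ccol[1]]]) else factor("all"),
    logp = -log10(results[[pcol]])
  )
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$logp,
                                         colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::labs(x = "gene", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold))
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(threshold),
                                   linetype = "dashed", colour = "grey40")
  gg
}

#' Plot a type-I-error calibration report
#'
#' @param object a [calibration_study()] report.
#' @param ... unused.
#' @return A ggplot: false-positive rate vs significance threshold, per mode
#'   and heritability, with the identity line a calibrated test follows.
#' @method autoplot calibration_report
#' @export
autoplot.calibration_report <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$alpha, y = .data$fpr,
                               colour = .data$mode, group = .data$mode)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~h2, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "significance threshold", y = "false positive rate") +
    ggplot2::theme_minimal()
}

#' Plot a mixing-parameter sweep
#'
#' @param sweep a [mixing_sweep()] tibble, optionally row-bound over genes
#'   (an extra `gene_id` column is averaged over).
#' @return A ggplot of cross-validated performance against the elastic-net
#'   mixing parameter.
#' @export
plot_mixing_sweep <- function(sweep) {
  sweep <- as_tibble(sweep)
  df <- if ("gene_id" %in% names(sweep)) {
    dplyr::summarise(dplyr::group_by(sweep, .data$alpha),
                     cv_R = mean(.data$cv_R), .groups = "drop")
  } else sweep
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha, y = .data$cv_R)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "elastic-net mixing parameter", y = "cross-validated R") +
    ggplot2::theme_minimal()
}
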