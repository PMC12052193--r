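#' Tidy a model database
#'
#' @param x a [model_db()].
#' @param ... unused.
#' @return The per-gene `extra` table as a tibble (one row per model).
#' @method tidy model_db
#' @export
tidy.model_db <- function(x, ...) as_tibble(x$extra)

#' @rdname tidy.model_db
#' @method glance model_db
#' @export
glance.model_db <- function(x, ...) {
  tibble(
    tissue = x$tissue_label, n_genes = nrow(x$extra),
    n_weights = nrow(x$weights),
    mean_cv_R2 = mean(x$extra$pred_perf_R2),
    median_n_snps = stats::median(x$extra$n_snps_in_model)
  )
}

#' Tidy a heritability fit
#'
#' @param x a [estimate_h2()] result.
#' @param ... unused.
#' @return One-row tibble with `h2`, `sigma2`, `loglik`, `n`, `identifiable`.
#' @method tidy heritability_fit
#' @export
tidy.heritability_fit <- function(x, ...) {
  tibble(h2 = x$h2, sigma2 = x$sigma2, loglik = x$loglik, n = x$n,
         identifiable = x$identifiable)
}

#' @rdname tidy.heritability_fit
#' @method glance heritability_fit
#' @export
glance.heritability_fit <- function(x, ...) tidy(x)

#' Tidy a prediction model
#'
#' @param x a [train_elastic_net()] result.
#' @param ... unused.
#' @return The weights tibble (`variant_id`, `weight`).
#' @method tidy prediction_model
#' @export
tidy.prediction_model <- function(x, ...) x$weights

#' @rdname tidy.prediction_model
#' @method glance prediction_model
#' @export
glance.prediction_model <- function(x, ...) {
  tibble(gene_id = x$gene_id, alpha = x$alpha, cv_R = x$cv_R, cv_R2 = x$cv_R2,
         n_snps = x$n_snps)
}

#' Summarize a calibration report
#'
#' @param x a [calibration_study()] report.
#' @param ... unused.
#' @return One row per mode with the worst absolute calibration error
#'   `max |fpr - alpha|` over the grid (thresholds below 1e-3 excluded from
#'   the maximum, where desk-scale counts are too small to be informative).
#' @method glance calibration_report
#' @export
glance.calibration_report <- function(x, ...) {
  x |>
    dplyr::filter(.data$alpha >= 1e-3) |>
    dplyr::group_by(.data$mode) |>
    dplyr::summarise(max_abs_error = max(abs(.data$fpr - .data$alpha)),
                     n_cells = dplyr::n(), .groups = "drop")
}

#' Write an association table as TSV
#'
#' Writes the multi-tissue association output (`gene`, `p_acat`, `chr`,
#' `start`, per-tissue p columns) or any association tibble.
#'
#' @param results a data frame of association results.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_association_tsv <- function(results, path) {
  write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
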