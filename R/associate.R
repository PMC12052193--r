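#' Estimate trait heritability from a GRM
#'
#' Maximum-likelihood fit of `y ~ N(mu, sigma2 * (h2 * GRM + (1 - h2) * I))`.
#' A one-time eigendecomposition of the GRM rotates the model to independent
#' coordinates; the likelihood is profiled over `h2` in `[0, 1]` by bounded
#' 1-D optimization, with the mean handled by generalized least squares on
#' the rotated intercept and `sigma2` closed-form given `h2`. When the GRM
#' carries no structure (all eigenvalues equal) the likelihood is flat in
#' `h2`; the fit returns `h2 = 0` with `identifiable = FALSE`.
#'
#' @param y numeric trait vector aligned to `grm` ids (or a data frame with
#'   `individual_id` and a trait column named by `trait`).
#' @param grm a [compute_grm()] result.
#' @param trait trait column name when `y` is a data frame.
#' @return An object of class `heritability_fit`: list with `h2`, `sigma2`,
#'   `loglik`, `n`, `identifiable`.
#' @export
estimate_h2 <- function(y, grm, trait = NULL) {
  stopifnot(inherits(grm, "grm"))
  if (is.data.frame(y)) {
    if (is.null(trait)) abort("supply `trait` when y is a data frame")
    idx <- match(grm$individual_ids, as.character(y$individual_id))
    if (anyNA(idx)) abort("phenotype table lacks some GRM individuals")
    y <- y[[trait]][idx]
  }
  y <- as.numeric(y)
  n <- length(y)
  if (n != length(grm$individual_ids)) abort("y not aligned to the GRM")
  if (var(y) == 0) abort("constant trait: h2 undefined")

  ed <- grm_eigen(grm)
  yt <- crossprod(ed$vectors, y)
  ot <- crossprod(ed$vectors, rep(1, n))

  prof <- function(h2) {
    d <- h2 * ed$values + 1 - h2
    if (any(d <= 1e-12)) return(list(nll = Inf))
    w <- 1 / d
    mu <- sum(ot * yt * w) / sum(ot^2 * w)
    r <- yt - mu * ot
    s2 <- sum(r^2 * w) / n
    nll <- 0.5 * (n * log(s2) + sum(log(d)) + n)
    list(nll = nll, sigma2 = s2, mu = mu)
  }

  if (diff(range(ed$values)) < 1e-8) {
    fit0 <- prof(0)
    return(structure(list(h2 = 0, sigma2 = fit0$sigma2, loglik = -fit0$nll,
                          n = n, identifiable = FALSE),
                     class = "heritability_fit"))
  }
  opt <- optimize(function(h) prof(h)$nll, interval = c(0, 1), tol = 1e-6)
  # the optimum can sit on a boundary; compare against both endpoints
  cand <- c(opt$minimum, 0, 1)
  nlls <- vapply(cand, function(h) prof(h)$nll, numeric(1))
  h2 <- cand[which.min(nlls)]
  fit <- prof(h2)
  structure(list(h2 = h2, sigma2 = fit$sigma2, loglik = -fit$nll, n = n,
                 identifiable = TRUE),
            class = "heritability_fit")
}

#' @export
print.heritability_fit <- function(x, ...) {
  cat(sprintf("<heritability_fit> h2 = %.3f, sigma2 = %.3f, loglik = %.2f (n = %d)%s\n",
              x$h2, x$sigma2, x$loglik, x$n,
              if (!x$identifiable) " [non-identifiable: GRM ~ I]" else ""))
  invisible(x)
}

# vectorized simple regression of y on [x0, each column of Tm]; returns tibble
assoc_ols <- function(y, Tm, x0, mode, tissue) {
  n <- length(y)
  df <- n - 2
  # project the intercept column out of y and every gene column
  nx0 <- sum(x0^2)
  y_r <- y - x0 * (sum(x0 * y) / nx0)
  T_r <- Tm - outer(x0, colSums(x0 * Tm) / nx0)
  sxx <- colSums(T_r^2)
  sxy <- colSums(T_r * y_r)
  zero_var <- sxx < 1e-12
  b <- ifelse(zero_var, 0, sxy / sxx)
  rss <- sum(y_r^2) - b^2 * sxx
  s2 <- rss / df
  se <- sqrt(s2 / sxx)
  stat <- b / se
  p <- 2 * pt(-abs(stat), df = df)
  out <- tibble(
    gene_id = colnames(Tm), b_hat = unname(b), se = unname(se),
    stat = unname(stat), p = unname(p), mode = mode, tissue = tissue,
    flagged = unname(zero_var)
  )
  out$p[zero_var] <- 1
  out$stat[zero_var] <- 0
  out$b_hat[zero_var] <- 0
  out$se[zero_var] <- NA_real_
  class(out) <- c("ratxcan_assoc", class(out))
  out
}

#' Mixed-effects (whitened) gene-trait association
#'
#' The trait is modeled as `Y = T b + u + e` with `cov(u + e) =
#' sigma2 * (h2 * GRM + (1 - h2) * I)`. Phenotype, predicted expression and
#' the intercept column are premultiplied by `Gamma^(-1/2)`; in the
#' transformed space the errors are uncorrelated, so each gene is tested by
#' ordinary least squares of the whitened trait on the whitened intercept
#' and whitened predicted expression, with a two-sided t test on `n - 2`
#' degrees of freedom. An intercept column is carried through the transform
#' because `Gamma^(-1/2) 1` is not constant.
#'
#' @param y trait vector aligned to `grm` (or data frame with
#'   `individual_id`; see [estimate_h2()]).
#' @param T_pred predicted `expression_set` (stage `"predicted"`).
#' @param grm the `grm` used to estimate `fit`.
#' @param fit a [estimate_h2()] result for this trait/GRM (estimated once
#'   per trait, reused for all genes). When `NULL` it is estimated here.
#' @param trait trait column name when `y` is a data frame.
#' @param tissue tissue label attached to the results.
#' @return A tibble (class `ratxcan_assoc`) with `gene_id`, `b_hat`, `se`,
#'   `stat`, `p`, `mode = "corrected"`, `tissue`, `flagged` (zero-variance
#'   whitened predictor: reported with `p = 1`).
#' @export
ratxcan_associate <- function(y, T_pred, grm, fit = NULL, trait = NULL,
                              tissue = "tissue") {
  stopifnot(inherits(T_pred, "expression_set"), inherits(grm, "grm"))
  if (is.data.frame(y)) {
    idx <- match(grm$individual_ids, as.character(y$individual_id))
    if (anyNA(idx)) abort("phenotype table lacks some GRM individuals")
    y <- y[[trait]][idx]
  }
  y <- as.numeric(y)
  if (!identical(T_pred$sample_ids, grm$individual_ids))
    abort("predicted expression and GRM are not aligned")
  if (length(y) != length(grm$individual_ids)) abort("y not aligned to the GRM")
  if (is.null(fit)) fit <- estimate_h2(y, grm)
  op <- whitening_operator(grm, h2 = fit$h2, sigma2 = fit$sigma2)
  yt <- whiten(op, y)
  Tt <- whiten(op, T_pred$values)
  it <- whiten(op, rep(1, length(y)))
  assoc_ols(yt, Tt, it, mode = "corrected", tissue = tissue)
}

#' Naive (unwhitened) gene-trait association
#'
#' Per-gene ordinary least squares of the raw trait on an intercept and the
#' predicted expression, ignoring relatedness. In related cohorts this test
#' is anticonservative; it is provided as the uncorrected baseline.
#'
#' @inheritParams ratxcan_associate
#' @return A tibble as in [ratxcan_associate()] with `mode = "naive"`.
#' @export
naive_associate <- function(y, T_pred, trait = NULL, tissue = "tissue") {
  stopifnot(inherits(T_pred, "expression_set"))
  if (is.data.frame(y)) {
    idx <- match(T_pred$sample_ids, as.character(y$individual_id))
    if (anyNA(idx)) abort("phenotype table lacks some samples")
    y <- y[[trait]][idx]
  }
  y <- as.numeric(y)
  if (length(y) != length(T_pred$sample_ids)) abort("y not aligned to T_pred")
  assoc_ols(y, T_pred$values, rep(1, length(y)), mode = "naive", tissue = tissue)
}

#' Cauchy combination (ACAT) of p-values
#'
#' Combines dependent p-values through the Cauchy transformation
#' `S = sum(w_i tan((0.5 - p_i) pi)) / sum(w_i)`, combined
#' `p = 0.5 - atan(S) / pi`. Robust to unknown correlation among the tests.
#' For `p_i < 1e-15` the tangent term is replaced by its asymptote
#' `w_i / (p_i * pi)` for numerical stability. Equal weights by default.
#'
#' @param p_values numeric vector of p-values in `(0, 1]` (NAs dropped).
#' @param weights optional non-negative weights, same length.
#' @return The combined p-value (scalar in `(0, 1)`).
#' @export
acat_combine <- function(p_values, weights = NULL) {
  keep <- is.finite(p_values)
  p <- p_values[keep]
  if (length(p) == 0L) abort("need at least one finite p-value")
  if (any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1]")
  w <- if (is.null(weights)) rep(1, length(p)) else weights[keep]
  if (length(w) != length(p) || any(w < 0)) abort("invalid weights")
  if (sum(w) == 0) abort("weights sum to zero")
  # tan((0.5 - p) * pi) computed as cot(p * pi) via tanpi() so tiny p keep
  # full relative precision; the asymptote replaces it below 1e-15
  term <- numeric(length(p)) # p = 0.5 contributes exactly 0
  small <- p < 1e-15
  term[small] <- 1 / (p[small] * pi)
  mid <- !small & p != 0.5
  term[mid] <- 1 / tanpi(p[mid])
  s <- sum(w * term) / sum(w)
  # for s > 0 use the reflection atan(1/s)/pi, exact where 0.5 - atan(s)/pi
  # would cancel catastrophically
  pc <- if (s > 0) atan(1 / s) / pi else 0.5 - atan(s) / pi
  min(max(pc, 1e-300), 1 - 1e-16)
}

#' Combine per-tissue associations across tissues with ACAT
#'
#' @param results a data frame of per-tissue association results (rows from
#'   [ratxcan_associate()] over several tissues) with columns `gene_id`,
#'   `tissue`, `p`.
#' @param weights optional named weights per tissue.
#' @return A tibble with `gene_id`, `n_tissues`, per-tissue p columns, and
#'   `p_acat`.
#' @export
acat_combine_tissues <- function(results, weights = NULL) {
  results <- as_tibble(results)
  need <- c("gene_id", "tissue", "p")
  if (!all(need %in% names(results))) abort("need columns gene_id, tissue, p")
  wide <- tidyr::pivot_wider(results[, need], names_from = "tissue",
                             values_from = "p")
  tissues <- setdiff(names(wide), "gene_id")
  wide$p_acat <- purrr::pmap_dbl(wide[tissues], function(...) {
    ps <- c(...)
    w <- if (is.null(weights)) NULL else weights[tissues][is.finite(ps)]
    acat_combine(ps, w)
  })
  wide$n_tissues <- rowSums(!is.na(wide[tissues]))
  wide[, c("gene_id", "n_tissues", tissues, "p_acat")]
}

#' Bonferroni significance threshold
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1L || n_tests < 1) abort("n_tests must be a positive integer")
  alpha / n_tests
}

#' Expected vs observed quantiles for a QQ plot
#'
#' @param p_values numeric vector of p-values.
#' @return A tibble (class `ratxcan_qq`) with `expected` and `observed`
#'   (-log10 scale; expected = rank / (n + 1)), sorted by rank.
#' @export
qq_data <- function(p_values) {
  p <- p_values[is.finite(p_values)]
  if (length(p) == 0L) abort("need at least one p-value")
  n <- length(p)
  out <- tibble(
    expected = -log10(seq_len(n) / (n + 1)),
    observed = -log10(sort(p))
  )
  class(out) <- c("ratxcan_qq", class(out))
  out
}
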