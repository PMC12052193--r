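#' Rank-based inverse-normal transform
#'
#' Maps values to normal scores `qnorm((rank - c) / (n - 2c + 1))` with the
#' Blom offset `c = 3/8`, the usual default in eQTL pipelines. Ties receive
#' average ranks, so tied inputs map to identical scores.
#'
#' @param values numeric vector, length >= 3.
#' @param offset rank offset `c`; default `3/8` (Blom).
#' @return Numeric vector of normal scores, mean approximately 0 and
#'   monotone in the ranks of `values`.
#' @export
inverse_normal_transform <- function(values, offset = 3 / 8) {
  if (length(values) < 3L) abort("need at least 3 values")
  if (anyNA(values)) abort("missing values are not supported")
  if (length(unique(values)) == 1L) abort("all values identical: ranks degenerate")
  n <- length(values)
  r <- rank(values, ties.method = "average")
  qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Filter genes failing a Shapiro-Wilk normality check
#'
#' After the inverse-normal transform a continuous expression trait must be
#' exactly normal; failures indicate excessive ties (typically many zero
#' TPMs). Genes with Shapiro-Wilk p below `alpha` are dropped.
#'
#' @param expression an `expression_set` at stage `"normalized"`.
#' @param alpha significance level for rejection (default 0.05).
#' @return A list: `expression` (the filtered `expression_set`), `rejected`
#'   (character vector of dropped gene ids) and `report` (tibble with
#'   `gene_id`, `shapiro_p`, `kept`).
#' @export
normality_filter <- function(expression, alpha = 0.05) {
  stopifnot(inherits(expression, "expression_set"))
  if (expression$stage != "normalized")
    abort("normality_filter expects stage 'normalized' expression")
  n <- nrow(expression$values)
  if (n < 3L) abort("Shapiro-Wilk test undefined for n < 3")
  pvals <- apply(expression$values, 2L, function(v) {
    if (sd(v) == 0) return(0) # constant column: maximally non-normal
    shapiro.test(v)$p.value
  })
  keep <- pvals >= alpha
  report <- tibble(gene_id = expression$gene_ids, shapiro_p = unname(pvals),
                   kept = unname(keep))
  if (!all(keep))
    inform(sprintf("normality_filter: removed %d of %d genes at alpha = %g",
                   sum(!keep), length(keep), alpha))
  filtered <- expression_set(expression$values[, keep, drop = FALSE],
                             expression$sample_ids, expression$gene_ids[keep],
                             stage = "normalized")
  list(expression = filtered, rejected = expression$gene_ids[!keep], report = report)
}

#' Residualize expression on covariates and expression PCs
#'
#' Computes principal components from the normalized expression matrix and
#' replaces each gene's values by the residuals of a least-squares regression
#' on the declared covariates plus the top `n_pcs` PCs. Mirrors the standard
#' training-stage step of removing sex/batch effects and hidden variation
#' before fitting cis prediction models.
#'
#' @param expression an `expression_set` (stage `"normalized"`).
#' @param covariates optional data frame aligned to the samples (first column
#'   or `individual_id` column holds sample ids); remaining columns are used
#'   as covariates, categorical columns expanded to indicators.
#' @param n_pcs number of top expression PCs to remove (default 7).
#' @return An `expression_set` at stage `"residual"`; per-gene mean is 0 and
#'   residuals are orthogonal to every regressed column.
#' @export
residualize_expression <- function(expression, covariates = NULL, n_pcs = 7) {
  stopifnot(inherits(expression, "expression_set"))
  n <- nrow(expression$values)
  if (n_pcs >= n) abort("n_pcs must be smaller than the number of samples")
  X <- matrix(1, n, 1)
  colnames(X) <- "(Intercept)"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    key <- if ("individual_id" %in% names(covariates)) "individual_id" else names(covariates)[1]
    idx <- match(expression$sample_ids, as.character(covariates[[key]]))
    if (anyNA(idx)) abort("covariate table lacks some expression samples")
    cov_df <- covariates[idx, setdiff(names(covariates), key), drop = FALSE]
    if (ncol(cov_df)) {
      mm <- stats::model.matrix(~., data = cov_df)
      X <- cbind(X, mm[, -1L, drop = FALSE])
    }
  }
  if (n_pcs > 0) {
    pc <- stats::prcomp(expression$values, center = TRUE, scale. = FALSE)
    k <- min(n_pcs, ncol(pc$x))
    pcs <- pc$x[, seq_len(k), drop = FALSE]
    colnames(pcs) <- paste0("PC", seq_len(k))
    X <- cbind(X, pcs)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    abort(paste0("collinear covariate column(s): ", paste(drop_cols, collapse = ", ")))
  }
  resid <- qr.resid(qx, expression$values)
  expression_set(resid, expression$sample_ids, expression$gene_ids, stage = "residual")
}

#' Screen and regress out phenotype covariates
#'
#' Each candidate covariate is tested marginally against the trait; those
#' with regression p < `p_max` that also explain more than `r2_min` of the
#' trait variance are regressed out jointly, and the trait is replaced by the
#' residuals. Defaults implement the usual screen: significant and explaining
#' more than 2% of the variance. When nothing qualifies the trait is
#' mean-centered only.
#'
#' @param pheno data frame with an `individual_id` column and the trait.
#' @param trait name of the trait column.
#' @param candidates character vector of candidate covariate column names.
#' @param p_max marginal significance cut-off (default 0.05).
#' @param r2_min minimum marginal variance explained (default 0.02).
#' @return A list: `pheno` (tibble with the trait column replaced by
#'   residuals) and `screen` (tibble with `covariate`, `p`, `r2`, `regressed`).
#' @export
regress_phenotype_covariates <- function(pheno, trait, candidates,
                                         p_max = 0.05, r2_min = 0.02) {
  pheno <- as_tibble(pheno)
  if (nrow(pheno) == 0L) abort("phenotype table has no individuals")
  if (!trait %in% names(pheno)) abort(paste0("no trait column '", trait, "'"))
  y <- pheno[[trait]]
  if (var(y) == 0) abort("trait has zero variance")
  missing_cov <- setdiff(candidates, names(pheno))
  if (length(missing_cov))
    abort(paste0("unknown covariate(s): ", paste(missing_cov, collapse = ", ")))

  screen <- purrr::map_dfr(candidates, function(cv) {
    x <- pheno[[cv]]
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    pv <- if (nrow(stats::coef(sm)) < 2) 1 else stats::coef(sm)[2, 4]
    tibble(covariate = cv, p = pv, r2 = sm$r.squared)
  })
  screen$regressed <- screen$p < p_max & screen$r2 > r2_min
  keep <- screen$covariate[screen$regressed]
  if (length(keep)) {
    mm <- stats::model.matrix(~., data = as.data.frame(pheno[, keep, drop = FALSE]))
    res <- stats::lm.fit(mm, y)$residuals
  } else {
    res <- y - mean(y)
  }
  pheno[[trait]] <- as.numeric(res)
  list(pheno = pheno, screen = screen)
}
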