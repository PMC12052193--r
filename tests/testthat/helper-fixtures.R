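# shared fixtures (memoised: built once per test run) and independent oracles

.fix <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

# small hand-buildable genotype set
tiny_gt <- function(dosages, chrom = NULL, pos = NULL) {
  m <- ncol(dosages)
  genotype_set(
    dosages,
    tibble::tibble(
      variant_id = paste0("v", seq_len(m)),
      chrom = chrom %||% rep("chr1", m),
      pos = pos %||% seq(1000, by = 1000, length.out = m),
      ref_allele = "A", eff_allele = "G"
    ),
    paste0("ind", seq_len(nrow(dosages)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force double-loop GRM oracle, straight from the estimator definition
grm_oracle <- function(X) {
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  X <- X[, keep, drop = FALSE]; p <- p[keep]
  n <- nrow(X); M <- ncol(X)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_len(M))
      s <- s + (X[i, k] - 2 * p[k]) * (X[j, k] - 2 * p[k]) / (2 * p[k] * (1 - p[k]))
    G[i, j] <- s / M
  }
  G
}

# exact two-sided Fisher p by hypergeometric enumeration (independent of
# fisher.test): sum of all table probabilities <= that of the observed table
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  sum(probs[probs <= stats::dhyper(a, c1, n - c1, r1) * (1 + 1e-7)])
}

# a modest cohort reused by several module tests
small_cohort <- function() memo("small_cohort", function() {
  simulate_cohort(n = 120, n_families = 20, m = 80, n_chrom = 2, n_genes = 20,
                  seed = 7)
})

small_models <- function() memo("small_models", function() {
  co <- small_cohort()
  sp <- split_cohort(co, 0.5, seed = 7)
  gt_tr <- subset_genotypes(co$genotypes, individuals = sp$train_ids)
  ex_tr <- expression_set(
    co$expression$values[match(sp$train_ids, co$expression$sample_ids), , drop = FALSE],
    sp$train_ids, co$expression$gene_ids, stage = "residual"
  )
  db <- train_models(gt_tr, ex_tr, co$annotation, seed = 11)
  list(cohort = co, split = sp, db = db, filtered = filter_models(db))
})

# study-scale fixture for the calibration experiments: n = 600 in 100
# families, models trained on a disjoint half, ~300 filtered gene models
acceptance_fixture <- function() memo("acceptance_fixture", function() {
  co <- simulate_cohort(seed = 101)
  sp <- split_cohort(co, 0.5, seed = 101)
  gt_tr <- subset_genotypes(co$genotypes, individuals = sp$train_ids)
  ex_tr <- expression_set(
    co$expression$values[match(sp$train_ids, co$expression$sample_ids), , drop = FALSE],
    sp$train_ids, co$expression$gene_ids, stage = "residual"
  )
  db <- filter_models(train_models(gt_tr, ex_tr, co$annotation, seed = 101))
  genes <- head(db$extra$gene, 300)
  list(cohort = co, split = sp, db = db, genes = genes)
})

acceptance_calibration <- function() memo("acceptance_calibration", function() {
  fx <- acceptance_fixture()
  calibration_study(fx$cohort, fx$db, target_ids = fx$split$target_ids,
                    h2_grid = 0.4, n_reps = 30, genes = fx$genes, seed = 101)
})
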