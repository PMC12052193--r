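test_that("h2 is non-identifiable when the GRM is the identity", {
  gI <- structure(list(individual_ids = paste0("i", 1:30), values = diag(30),
                       M_used = 10L), class = "grm")
  set.seed(41)
  fit <- estimate_h2(rnorm(30), gI)
  expect_equal(fit$h2, 0)
  expect_false(fit$identifiable)
  expect_error(estimate_h2(rep(1, 30), gI), "constant")
})

test_that("h2 estimates recover truth on a family GRM", {
  co <- memo("h2_cohort", function()
    simulate_cohort(n = 400, n_families = 80, m = 60, n_chrom = 3, n_genes = 1,
                    h2_expr = 0, seed = 44))
  g <- memo("h2_grm", function() compute_grm(co$genotypes))
  set.seed(45)
  S <- grm_sqrt(g)
  est <- replicate(25, {
    y <- sqrt(0.4) * as.numeric(S %*% rnorm(400)) + rnorm(400, sd = sqrt(0.6))
    estimate_h2(y, g)$h2
  })
  expect_lt(abs(mean(est) - 0.4), 0.1)

  null_est <- replicate(25, estimate_h2(rnorm(400), g)$h2)
  expect_lt(median(null_est), 0.1)
})

test_that("whitened association reduces to naive OLS when Gamma is the identity", {
  sm <- small_models()
  sp <- sm$split
  gt <- subset_genotypes(sm$cohort$genotypes, individuals = sp$target_ids)
  pred <- suppressWarnings(predict_expression(gt, sm$filtered))
  g <- compute_grm(gt)
  set.seed(46)
  y <- rnorm(length(sp$target_ids))
  fit0 <- structure(list(h2 = 0, sigma2 = 1, loglik = 0, n = length(y),
                         identifiable = TRUE), class = "heritability_fit")
  corr <- ratxcan_associate(y, pred, g, fit0)
  naiv <- naive_associate(y, pred)
  expect_equal(corr$b_hat, naiv$b_hat, tolerance = 1e-10)
  expect_equal(corr$p, naiv$p, tolerance = 1e-10)
})

test_that("a noiseless linear relation is recovered exactly", {
  sm <- small_models()
  gt <- subset_genotypes(sm$cohort$genotypes, individuals = sm$split$target_ids)
  pred <- suppressWarnings(predict_expression(gt, sm$filtered))
  g1 <- pred$gene_ids[1]
  y <- 2 * pred$values[, g1]
  fit0 <- structure(list(h2 = 0, sigma2 = 1, loglik = 0, n = length(y),
                         identifiable = TRUE), class = "heritability_fit")
  res <- ratxcan_associate(y, pred, compute_grm(gt), fit0)
  r1 <- res[res$gene_id == g1, ]
  expect_equal(r1$b_hat, 2, tolerance = 1e-8)
  expect_lt(r1$p, 1e-100)
})

test_that("whitened association equals naive association on pre-whitened data", {
  sm <- small_models()
  gt <- subset_genotypes(sm$cohort$genotypes, individuals = sm$split$target_ids)
  pred <- suppressWarnings(predict_expression(gt, sm$filtered))
  g <- compute_grm(gt)
  set.seed(47)
  y <- simulate_null_phenotype(g, h2 = 0.5, seed = 47)
  fit <- estimate_h2(y, g)
  corr <- ratxcan_associate(y, pred, g, fit)
  # transform by hand, then run plain OLS with the transformed intercept
  op <- whitening_operator(g, fit$h2)
  yt <- whiten(op, y); Tt <- whiten(op, pred$values)
  it <- whiten(op, rep(1, length(y)))
  manual <- ratxcan:::assoc_ols(yt, Tt, it, "corrected", "tissue")
  expect_equal(corr$b_hat, manual$b_hat)
  expect_equal(corr$p, manual$p)
})

test_that("ACAT combination matches its defining formula and invariants", {
  # all-equal p-values return that p
  for (p0 in c(1e-8, 0.01, 0.3, 0.97))
    expect_equal(acat_combine(rep(p0, 7)), p0, tolerance = 1e-12)
  expect_equal(acat_combine(0.5), 0.5, tolerance = 1e-14)
  # direct evaluation of the Cauchy formula for [0.01, 0.5]
  s <- mean(tan((0.5 - c(0.01, 0.5)) * pi))
  expect_equal(acat_combine(c(0.01, 0.5)), 0.5 - atan(s) / pi, tolerance = 1e-12)
  expect_equal(acat_combine(c(0.01, 0.5)), 0.0200, tolerance = 1e-3)

  # permutation invariance and monotonicity
  set.seed(48)
  for (i in 1:20) {
    p <- runif(5)
    expect_equal(acat_combine(p), acat_combine(sample(p)), tolerance = 1e-14)
    j <- sample(5, 1)
    q <- p; q[j] <- p[j] / 2
    expect_lte(acat_combine(q), acat_combine(p))
  }
  # small-p stabilization stays finite and ordered
  expect_gt(acat_combine(c(1e-300, 0.5)), 0)
  expect_lt(acat_combine(c(1e-300, 0.5)), acat_combine(c(1e-10, 0.5)))

  expect_error(acat_combine(c(0, 0.5)), "p-values")
  expect_error(acat_combine(1.2), "p-values")
  expect_error(acat_combine(NA_real_), "finite")
})

test_that("per-tissue p-values combine into one ACAT p per gene", {
  res <- dplyr::bind_rows(
    tibble::tibble(gene_id = c("g1", "g2"), tissue = "A", p = c(0.01, 0.8)),
    tibble::tibble(gene_id = c("g1", "g2"), tissue = "B", p = c(0.04, 0.9)),
    tibble::tibble(gene_id = "g1", tissue = "C", p = 0.20)
  )
  out <- acat_combine_tissues(res)
  expect_equal(out$n_tissues, c(3, 2))
  expect_equal(out$p_acat[1], acat_combine(c(0.01, 0.04, 0.20)), tolerance = 1e-12)
  expect_equal(out$p_acat[2], acat_combine(c(0.8, 0.9)), tolerance = 1e-12)
})

test_that("Bonferroni thresholds reproduce the published arithmetic", {
  expect_equal(signif(bonferroni_threshold(8272), 3), 6.04e-6)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(signif(bonferroni_threshold(5388), 3), 9.28e-6)
  expect_error(bonferroni_threshold(0), "positive")
})

test_that("QQ data uses rank/(n+1) expected quantiles", {
  q <- qq_data(c(0.75, 0.25, 0.5))
  expect_equal(q$expected, -log10(c(0.25, 0.5, 0.75)))
  expect_equal(q$observed, -log10(c(0.25, 0.5, 0.75)))
  q1 <- qq_data(0.1)
  expect_equal(q1$expected, -log10(0.5))

  set.seed(49)
  u <- runif(10000)
  qu <- qq_data(u)
  expect_lt(max(abs(10^(-qu$observed) - 10^(-qu$expected))), 0.03)
})

test_that("zero-variance predictors are flagged with p = 1", {
  es <- expression_set(cbind(gA = rep(1, 25), gB = rnorm(25)),
                       paste0("i", 1:25), c("gA", "gB"), stage = "predicted")
  set.seed(50)
  res <- naive_associate(rnorm(25), es)
  expect_true(res$flagged[res$gene_id == "gA"])
  expect_equal(res$p[res$gene_id == "gA"], 1)
  expect_false(res$flagged[res$gene_id == "gB"])
})
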