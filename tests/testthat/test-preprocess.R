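test_that("inverse-normal transform yields symmetric, rank-invariant normal scores", {
  s3 <- inverse_normal_transform(c(1, 2, 3))
  expect_equal(s3[2], 0)
  expect_equal(s3[1], -s3[3])
  expect_gt(s3[3], 0)

  x <- sort(rexp(25)) + seq_len(25) * 1e-9 # strictly increasing
  expect_equal(inverse_normal_transform(x), inverse_normal_transform(seq_len(25)))

  # ties share the average-rank score; matches a direct quantile computation
  tied <- inverse_normal_transform(c(5, 5, 1))
  c_ <- 3 / 8
  expect_equal(tied[1], tied[2])
  expect_equal(tied[3], qnorm((1 - c_) / (3 - 2 * c_ + 1)))
  expect_equal(tied[1], qnorm((2.5 - c_) / (3 - 2 * c_ + 1)))

  expect_error(inverse_normal_transform(rep(2, 5)), "identical")
  expect_error(inverse_normal_transform(c(1, 2)), "at least 3")
})

test_that("inverse-normal scores pass Shapiro-Wilk for tie-free inputs", {
  set.seed(42)
  pass <- replicate(100, {
    x <- rexp(30)^3 # heavily skewed input
    shapiro.test(inverse_normal_transform(x))$p.value >= 0.01
  })
  expect_gte(mean(pass), 0.99)
})

test_that("normality filter keeps normal-score genes and rejects tie-heavy genes", {
  set.seed(1)
  n <- 60
  good <- inverse_normal_transform(rnorm(n))
  many_zero <- c(rep(0, 35), rexp(n - 35)) # >50% zeros pre-transform
  bad <- inverse_normal_transform(many_zero)
  es <- expression_set(cbind(good = good, bad = bad), paste0("s", 1:n),
                       c("good", "bad"), stage = "normalized")
  out <- normality_filter(es, alpha = 0.05)
  expect_true("good" %in% out$expression$gene_ids)
  expect_true("bad" %in% out$rejected)
  expect_named(out$report, c("gene_id", "shapiro_p", "kept"))

  none <- normality_filter(es, alpha = 0)
  expect_equal(ncol(none$expression$values), 2L)

  tiny <- expression_set(matrix(rnorm(4), 2, 2), c("a", "b"), c("g1", "g2"),
                         stage = "normalized")
  expect_error(normality_filter(tiny), "n < 3")
})

test_that("residualization removes covariates, PCs, and injected batch structure", {
  set.seed(2)
  n <- 80
  ids <- paste0("s", 1:n)
  grp <- rep(c(0, 1), each = n / 2)
  vals <- matrix(rnorm(n * 5), n, 5, dimnames = list(ids, paste0("g", 1:5)))
  es <- expression_set(vals, ids, paste0("g", 1:5), stage = "normalized")
  cov <- tibble::tibble(individual_id = ids, grp = grp)

  # n_pcs = 0 with one binary covariate is within-group centering
  r0 <- residualize_expression(es, cov, n_pcs = 0)
  manual <- apply(vals, 2, function(v) v - ave(v, grp))
  expect_equal(unname(r0$values), unname(manual), tolerance = 1e-10)
  expect_equal(colMeans(r0$values), setNames(rep(0, 5), paste0("g", 1:5)),
               tolerance = 1e-10)

  # a covariate orthogonal to a gene leaves it unchanged up to centering
  orth <- vals[, 1] - ave(vals[, 1], grp) # orthogonal to grp by construction
  es2 <- expression_set(cbind(g1 = orth), ids, "g1", stage = "normalized")
  r2 <- residualize_expression(es2, cov, n_pcs = 0)
  expect_equal(unname(r2$values[, 1]), unname(orth - mean(orth)), tolerance = 1e-10)

  # residuals are exactly orthogonal to every regressed covariate column
  r7 <- residualize_expression(es, cov, n_pcs = 3)
  expect_lt(max(abs(crossprod(grp - mean(grp), r7$values))) /
              sqrt(sum((grp - mean(grp))^2)), 1e-8)

  # injected batch shift disappears after residualization
  shift <- matrix(2 * grp, n, 5)
  es3 <- expression_set(vals + shift, ids, paste0("g", 1:5), stage = "normalized")
  r3 <- residualize_expression(es3, cov, n_pcs = 0)
  rs <- abs(cor(grp, r3$values))
  expect_lt(max(rs), 0.05)

  # collinear design is reported
  cov_bad <- tibble::tibble(individual_id = ids, grp = grp, grp2 = grp * 2)
  expect_error(residualize_expression(es, cov_bad, n_pcs = 0), "collinear")
})

test_that("phenotype covariates are screened on significance and variance explained", {
  set.seed(3)
  n <- 1000
  x <- rnorm(n)
  y <- x + rnorm(n) # x explains ~50% of variance
  ph <- tibble::tibble(individual_id = as.character(1:n), y = y, x = x)
  out <- regress_phenotype_covariates(ph, "y", "x")
  expect_true(out$screen$regressed)
  expect_lt(var(out$pheno$y) / var(y), 0.6)
  expect_gt(var(out$pheno$y) / var(y), 0.4)

  # a covariate explaining exactly 1% of sample variance is retained
  x2 <- rnorm(n)
  x2s <- scale(x2)[, 1]
  e <- rnorm(n)
  e <- e - x2s * sum(e * x2s) / sum(x2s^2) # orthogonal noise
  e <- e / sd(e)
  y2 <- sqrt(0.01) * x2s + sqrt(0.99) * e
  ph2 <- tibble::tibble(individual_id = as.character(1:n), y = y2, x = x2)
  out2 <- regress_phenotype_covariates(ph2, "y", "x")
  expect_false(out2$screen$regressed)
  expect_equal(out2$pheno$y, y2 - mean(y2)) # mean-centered only

  expect_error(regress_phenotype_covariates(ph[0, ], "y", "x"), "no individuals")
})
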