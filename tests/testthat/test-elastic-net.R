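test_that("cis windows are gene span +/- 1 Mb, clipped at 1", {
  ann <- tibble::tibble(gene_id = c("g1", "g2"), gene_name = c("g1", "g2"),
                        chrom = "chr1", start = c(2000000L, 500000L),
                        end = c(2010000L, 510000L), strand = "+")
  w <- cis_window(ann)
  expect_equal(w$lo, c(1000000, 1))
  expect_equal(w$hi, c(3010000, 1510000))
  w0 <- cis_window(ann, window_bp = 0)
  expect_equal(w0$lo, ann$start)
  expect_equal(w0$hi, ann$end)
})

test_that("elastic net recovers a strong single-variant signal", {
  set.seed(21)
  n <- 50
  X <- matrix(rbinom(n * 20, 2, 0.5), n, 20,
              dimnames = list(NULL, paste0("v", 1:20)))
  y <- 1.0 * X[, 7] + rnorm(n, sd = 0.01)
  m <- train_elastic_net(y, X, seed = 5)
  expect_gt(m$cv_R2, 0.9)
  top <- m$weights$variant_id[which.max(abs(m$weights$weight))]
  expect_equal(top, "v7")
})

test_that("null expression yields near-zero cross-validated performance", {
  set.seed(22)
  n <- 50
  X <- matrix(rbinom(n * 20, 2, 0.5), n, 20)
  low <- replicate(100, {
    y <- rnorm(n)
    train_elastic_net(y, X, seed = 1)$cv_R2 < 0.1
  })
  expect_gte(mean(low), 0.95)
})

test_that("lasso is no denser than ridge and training is seed-reproducible", {
  set.seed(23)
  n <- 60
  X <- matrix(rbinom(n * 30, 2, 0.4), n, 30,
              dimnames = list(NULL, paste0("v", 1:30)))
  y <- X[, 3] - 0.8 * X[, 17] + rnorm(n, sd = 0.5)
  m_lasso <- train_elastic_net(y, X, alpha = 1, seed = 9)
  m_ridge <- train_elastic_net(y, X, alpha = 0, seed = 9)
  expect_lte(m_lasso$n_snps, m_ridge$n_snps)

  m_a <- train_elastic_net(y, X, seed = 31)
  m_b <- train_elastic_net(y, X, seed = 31)
  expect_identical(m_a$weights, m_b$weights)
  expect_identical(m_a$cv_R, m_b$cv_R)

  expect_error(train_elastic_net(rep(1, n), X), "zero-variance")
  zero <- train_elastic_net(y, matrix(1, n, 3))
  expect_equal(zero$n_snps, 0L)
  expect_equal(zero$cv_R, 0)
})

test_that("mixing sweep is flat for a single cis variant", {
  set.seed(24)
  n <- 40
  X <- matrix(rbinom(n, 2, 0.5), ncol = 1, dimnames = list(NULL, "v1"))
  y <- X[, 1] + rnorm(n, sd = 0.3)
  sw <- mixing_sweep(y, X, alphas = c(0, 0.5, 1), seed = 3)
  expect_equal(nrow(sw), 3L)
  expect_lt(diff(range(sw$cv_R)), 0.05)
})

test_that("infinitesimal architectures show no drop toward the ridge end", {
  set.seed(27)
  n <- 100; M <- 60
  res <- purrr::map_dfr(1:8, function(g) {
    X <- matrix(rbinom(n * M, 2, 0.5), n, M,
                dimnames = list(NULL, paste0("v", 1:M)))
    gval <- as.numeric(X %*% rnorm(M, sd = 1 / sqrt(M))) # every variant tiny
    y <- gval + rnorm(n, sd = sqrt(var(gval) * 0.6 / 0.4))
    sw <- mixing_sweep(y, X, alphas = c(0, 1), seed = g)
    sw$gene_id <- g
    sw
  })
  avg <- tapply(res$cv_R, res$alpha, mean)
  expect_gt(avg[["0"]], avg[["1"]] - 0.05) # ridge end does not underperform
})

test_that("model filtering enforces the R2 threshold and non-negative correlation", {
  mk <- function(gene, R, R2, n = 2L) {
    structure(list(gene_id = gene,
                   weights = tibble::tibble(variant_id = "v1", weight = 0.5),
                   alpha = 0.5, cv_R = R, cv_R2 = R2, n_snps = n),
              class = "prediction_model")
  }
  db <- model_db(list(mk("a", 0.3, 0.09), mk("b", 0.095, 0.009),
                      mk("c", -0.15, 0.02)))
  f <- filter_models(db)
  expect_equal(f$extra$gene, "a")
  f0 <- filter_models(db, r2_min = 0)
  expect_setequal(f0$extra$gene, c("a", "b")) # only the negative-R model drops
})

test_that("predicted expression is the dot product of weights and dosages", {
  set.seed(25)
  n <- 12
  X <- matrix(rbinom(n * 10, 2, 0.5), n, 10)
  gt <- tiny_gt(X, pos = seq_len(10) * 1000)
  wt <- tibble::tibble(
    gene = rep(c("gA", "gB", "gC"), times = c(4, 3, 3)),
    rsid = paste0("v", c(1:4, 5:7, 8:10)),
    varID = paste0("v", c(1:4, 5:7, 8:10)),
    ref_allele = "A", eff_allele = "G",
    weight = round(rnorm(10), 3)
  )
  db <- structure(list(
    weights = wt,
    extra = tibble::tibble(gene = c("gA", "gB", "gC"), genename = c("gA", "gB", "gC"),
                           pred_perf_R2 = 0.1, pred_perf_R = 0.3,
                           n_snps_in_model = c(4L, 3L, 3L), pred_perf_pval = 0.01,
                           alpha = 0.5),
    tissue_label = "t", provenance = list()
  ), class = "model_db")
  pred <- predict_expression(gt, db)
  for (g in c("gA", "gB", "gC")) {
    w <- wt[wt$gene == g, ]
    oracle <- as.numeric(X[, match(w$varID, gt$variants$variant_id)] %*% w$weight)
    expect_equal(unname(pred$values[, g]), oracle, tolerance = 1e-12)
  }

  # single unit weight reproduces the dosage vector; linearity in the dosages
  db1 <- db
  db1$weights <- tibble::tibble(gene = "gA", rsid = "v2", varID = "v2",
                                ref_allele = "A", eff_allele = "G", weight = 1)
  db1$extra <- db$extra[1, ]
  p1 <- predict_expression(gt, db1)
  expect_equal(unname(p1$values[, "gA"]), unname(X[, 2]))

  pa <- predict_expression(gt, db)
  gt_flip <- tiny_gt(2 - X, pos = seq_len(10) * 1000)
  pb <- predict_expression(gt_flip, db)
  # linearity: predictions on (X + (2-X))/2 equal the average of predictions
  ph <- predict_expression(tiny_gt((X + (2 - X)) / 2, pos = seq_len(10) * 1000), db)
  expect_equal(ph$values, (pa$values + pb$values) / 2, tolerance = 1e-10)
})

test_that("swapped alleles are flipped and unmatched variants are reported", {
  X <- cbind(c(0, 1, 2), c(2, 1, 0))
  gt <- tiny_gt(X, pos = c(1000, 2000))
  db <- structure(list(
    weights = tibble::tibble(gene = "g", rsid = c("v1", "v2", "v9"),
                             varID = c("v1", "v2", "v9"),
                             ref_allele = c("A", "G", "A"),
                             eff_allele = c("G", "A", "G"), # v2 swapped, v9 absent
                             weight = c(1, 1, 5)),
    extra = tibble::tibble(gene = "g", genename = "g", pred_perf_R2 = 0.1,
                           pred_perf_R = 0.3, n_snps_in_model = 3L,
                           pred_perf_pval = 0.01, alpha = 0.5),
    tissue_label = "t", provenance = list()
  ), class = "model_db")
  pred <- predict_expression(gt, db)
  expect_equal(unname(pred$values[, "g"]), unname(X[, 1] + (2 - X[, 2])))
  cov <- attr(pred, "coverage")
  expect_equal(cov$n_model, 3L)
  expect_equal(cov$n_used, 2L)
})

test_that("cross-species performance correlation behaves on exact, degenerate and noisy maps", {
  pa <- tibble::tibble(gene = paste0("a", 1:10), cv_R = seq(0.1, 1, 0.1))
  pb <- tibble::tibble(gene = paste0("b", 1:10), cv_R = seq(0.1, 1, 0.1))
  map <- tibble::tibble(gene_a = paste0("a", 1:10), gene_b = paste0("b", 1:10))
  out <- performance_correlation(pa, pb, map)
  expect_equal(out$R, 1, tolerance = 1e-12)

  pb_const <- tibble::tibble(gene = paste0("b", 1:10), cv_R = 0.5)
  expect_warning(outc <- performance_correlation(pa, pb_const, map), "degenerate")
  expect_true(is.na(outc$R))

  expect_error(performance_correlation(pa[1:2, ], pb[1:2, ], map[1:2, ]), "at least 3")

  set.seed(26)
  n <- 500
  shared <- rnorm(n)
  va <- sqrt(0.3) * shared + sqrt(0.7) * rnorm(n)
  vb <- sqrt(0.3) * shared + sqrt(0.7) * rnorm(n)
  sim <- performance_correlation(
    tibble::tibble(gene = paste0("a", 1:n), cv_R = va),
    tibble::tibble(gene = paste0("b", 1:n), cv_R = vb),
    tibble::tibble(gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n))
  )
  expect_lt(abs(sim$R - 0.3), 0.1)
})

test_that("model databases round-trip through SQLite and TSV dialects", {
  sm <- small_models()
  db <- sm$filtered
  sq <- tempfile(fileext = ".db")
  write_model_db(db, sq)
  back <- read_model_db(sq)
  expect_equal(as.data.frame(back$weights), as.data.frame(db$weights))
  expect_equal(as.data.frame(back$extra), as.data.frame(db$extra))

  base <- tempfile()
  write_model_db(db, base)
  back2 <- read_model_db(base)
  expect_equal(back2$weights$weight, db$weights$weight, tolerance = 1e-10)
  expect_equal(back2$extra$gene, db$extra$gene)
})

test_that("cross-validated R2 stays below true cis heritability on average", {
  co <- memo("h2bound_cohort", function()
    simulate_cohort(n = 150, n_families = 25, m = 60, n_chrom = 2, n_genes = 50,
                    h2_expr = 0.3, n_causal_per_gene = 2, seed = 33))
  db <- memo("h2bound_db", function()
    train_models(co$genotypes, co$expression, co$annotation, seed = 33))
  expect_lt(mean(db$extra$pred_perf_R2), 0.3)
})
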