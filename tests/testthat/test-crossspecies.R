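test_that("ortholog maps load, deduplicate, and drop incomplete pairs", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("ensembl_gene_id\trnorvegicus_homolog_ensembl_gene",
               "ENSG1\tENSR1", "ENSG2\tENSR2", "ENSG3\tENSR3"), f)
  map <- load_ortholog_map(f)
  expect_equal(nrow(map), 3L)
  expect_named(map, c("gene_a", "gene_b"))

  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "g1\th1", "g1\th2", "g2\t", "g3\th3"), f2)
  expect_warning(map2 <- load_ortholog_map(f2), "duplicate")
  expect_equal(nrow(map2), 2L) # g1 kept once, g2 dropped (empty b), g3 kept
  expect_equal(map2$gene_b[map2$gene_a == "g1"], "h1")

  f3 <- tempfile(fileext = ".tsv")
  writeLines("a\tb", f3)
  expect_error(load_ortholog_map(f3), "empty")
})

test_that("Fisher enrichment matches the hypergeometric oracle", {
  # construct results realizing the 2x2 table [[10, 90], [100, 9800]]
  n <- 10000
  genes_a <- paste0("a", 1:n); genes_b <- paste0("b", 1:n)
  sig_a <- c(rep(TRUE, 100), rep(FALSE, n - 100))
  sig_b <- c(rep(TRUE, 10), rep(FALSE, 90), rep(TRUE, 100), rep(FALSE, n - 200))
  ra <- tibble::tibble(gene_id = genes_a, p = ifelse(sig_a, 1e-8, 0.5))
  rb <- tibble::tibble(gene_id = genes_b, p = ifelse(sig_b, 1e-8, 0.5))
  map <- tibble::tibble(gene_a = genes_a, gene_b = genes_b)
  out <- enrichment_fisher(ra, rb, map, alpha_a = 1e-6, alpha_b = 1e-6)
  expect_equal(c(out$n_ab, out$n_a_only, out$n_b_only, out$n_neither),
               c(10, 90, 100, 9800))
  expect_equal(out$odds_ratio, (10 * 9800) / (90 * 100), tolerance = 1e-12)
  tab <- matrix(c(10, 90, 100, 9800), 2, byrow = TRUE)
  expect_equal(out$p, fisher_oracle(tab), tolerance = 1e-6)
})

test_that("Fisher p equals the exact hypergeometric oracle on small tables", {
  set.seed(71)
  for (i in 1:20) {
    tot <- sample(20:200, 1)
    a <- sample(0:10, 1); b <- sample(0:20, 1); c_ <- sample(0:20, 1)
    d <- tot - a - b - c_
    if (d < 0) next
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    ra <- tibble::tibble(
      gene_id = paste0("a", 1:tot),
      p = rep(c(1e-9, 1e-9, 0.5, 0.5), times = c(a, b, c_, d))
    )
    rb <- tibble::tibble(
      gene_id = paste0("b", 1:tot),
      p = rep(c(1e-9, 0.5, 1e-9, 0.5), times = c(a, b, c_, d))
    )
    map <- tibble::tibble(gene_a = paste0("a", 1:tot), gene_b = paste0("b", 1:tot))
    out <- suppressWarnings(enrichment_fisher(ra, rb, map, alpha_a = 0.01, alpha_b = 0.01))
    expect_equal(out$p, fisher_oracle(tab), tolerance = 1e-10)
  }
})

test_that("independent p-values show no enrichment; empty margins are flagged", {
  set.seed(72)
  n <- 5000
  ra <- tibble::tibble(gene_id = paste0("a", 1:n), p = runif(n))
  rb <- tibble::tibble(gene_id = paste0("b", 1:n), p = runif(n))
  map <- tibble::tibble(gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n))
  out <- enrichment_fisher(ra, rb, map, alpha_a = 0.05, alpha_b = 0.05)
  expect_gt(out$odds_ratio, 0.5)
  expect_lt(out$odds_ratio, 2)
  expect_gt(out$p, 0.001)

  ra0 <- tibble::tibble(gene_id = paste0("a", 1:n), p = 0.9)
  expect_warning(out0 <- enrichment_fisher(ra0, rb, map, alpha_a = 0.05,
                                           alpha_b = 0.05), "degenerate")
  expect_true(out0$degenerate)
})

test_that("planted cross-species overlap increases the odds ratio monotonically", {
  set.seed(73)
  n <- 2000
  or_at <- function(f) {
    mean(replicate(20, {
      shared <- seq_len(round(f * n))
      pa <- runif(n); pb <- runif(n)
      pa[shared] <- rbeta(length(shared), 0.1, 8)
      pb[shared] <- rbeta(length(shared), 0.1, 8)
      ra <- tibble::tibble(gene_id = paste0("a", 1:n), p = pa)
      rb <- tibble::tibble(gene_id = paste0("b", 1:n), p = pb)
      map <- tibble::tibble(gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n))
      suppressWarnings(
        enrichment_fisher(ra, rb, map, alpha_a = 0.05, alpha_b = 0.05)$odds_ratio
      )
    }))
  }
  ors <- c(or_at(0), or_at(0.1), or_at(0.3))
  expect_true(all(diff(ors) > 0))
})

test_that("enrichment QQ separates an enriched subset from the background", {
  set.seed(74)
  n <- 1000
  pb <- runif(n)
  # species-a significant genes are exactly the smallest decile of b p-values
  ord <- order(pb)
  pa <- rep(0.5, n); pa[ord[1:100]] <- 1e-8
  ra <- tibble::tibble(gene_id = paste0("a", 1:n), p = pa)
  rb <- tibble::tibble(gene_id = paste0("b", 1:n), p = pb)
  map <- tibble::tibble(gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n))
  qq <- enrichment_qq(ra, rb, map, alpha_a = 1e-6)
  expect_equal(nrow(qq$subset), 100L)
  expect_true(all(qq$subset$observed > qq$subset$expected))
  expect_gt(mean(qq$subset$observed), mean(qq$background$observed))

  # a random subset is indistinguishable from the background
  pa_rand <- rep(0.5, n); pa_rand[sample(n, 100)] <- 1e-8
  qq_r <- enrichment_qq(tibble::tibble(gene_id = paste0("a", 1:n), p = pa_rand),
                        rb, map, alpha_a = 1e-6)
  ks <- suppressWarnings(stats::ks.test(10^(-qq_r$subset$observed), pb))
  expect_gt(ks$p.value, 0.05)

  # one-gene subset sits at the median expectation
  pa_one <- rep(0.5, n); pa_one[1] <- 1e-8
  qq_1 <- enrichment_qq(tibble::tibble(gene_id = paste0("a", 1:n), p = pa_one),
                        rb, map, alpha_a = 1e-6)
  expect_equal(qq_1$subset$expected, -log10(0.5))

  # empty subset is flagged
  expect_warning(
    qq_e <- enrichment_qq(tibble::tibble(gene_id = paste0("a", 1:n), p = 0.9),
                          rb, map, alpha_a = 1e-6),
    "empty subset"
  )
  expect_equal(nrow(qq_e$subset), 0L)
})
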