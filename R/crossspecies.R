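#' Load a two-species ortholog map
#'
#' Reads a TSV whose first two gene-id columns pair species-a genes with
#' species-b genes (biomart-style exports work as-is: the first column and
#' the first `*_homolog_ensembl_gene` column are used when present). Rows
#' with an empty or missing id on either side are dropped; duplicate a-genes
#' are resolved by keeping the first occurrence, so after deduplication each
#' a-gene maps to at most one b-gene.
#'
#' @param path TSV path with a header row.
#' @return A tibble with columns `gene_a`, `gene_b`.
#' @export
load_ortholog_map <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) abort("empty ortholog map")
  if (ncol(tab) < 2L) abort("ortholog map needs at least two gene-id columns")
  homol <- grep("homolog_ensembl_gene$", names(tab), value = TRUE)
  col_b <- if (length(homol)) homol[1] else names(tab)[2]
  map <- tibble(gene_a = as.character(tab[[1]]), gene_b = as.character(tab[[col_b]]))
  map <- map[!is.na(map$gene_a) & !is.na(map$gene_b) &
               nzchar(map$gene_a) & nzchar(map$gene_b), ]
  if (nrow(map) == 0L) abort("no complete ortholog pairs after dropping empty ids")
  dup <- duplicated(map$gene_a)
  if (any(dup)) {
    warn(sprintf("%d duplicate a-gene row(s) collapsed to first occurrence", sum(dup)))
    map <- map[!dup, ]
  }
  map
}

# sample odds ratio with Haldane 0.5 correction when any cell is zero
sample_odds_ratio <- function(tab) {
  if (any(tab == 0)) tab <- tab + 0.5
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

#' Cross-species enrichment of trait-associated genes (Fisher test)
#'
#' Over mapped orthologs with association p-values in both species, builds
#' the 2x2 table of (significant in a) x (significant in b) and tests
#' enrichment with Fisher's exact test. The a-side threshold defaults to
#' the Bonferroni level in species a; the b-side threshold defaults to a
#' nominal 0.05 (configurable).
#'
#' @param results_a,results_b data frames with columns `gene_id` (or `gene`)
#'   and `p`.
#' @param map ortholog map from [load_ortholog_map()] (columns
#'   `gene_a`, `gene_b`), a-genes keyed to `results_a`.
#' @param alpha_a significance threshold in species a; default
#'   `0.05 / nrow(results_a)` (Bonferroni).
#' @param alpha_b significance threshold in species b (default 0.05).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return A tibble of class `enrichment_result`: `n_mapped`, cell counts
#'   `n_ab`, `n_a_only`, `n_b_only`, `n_neither`, `odds_ratio` (sample OR,
#'   Haldane-corrected on zero cells), `p`, `alpha_a`, `alpha_b`, and
#'   `degenerate` (TRUE when a margin is empty).
#' @export
enrichment_fisher <- function(results_a, results_b, map,
                              alpha_a = NULL, alpha_b = 0.05,
                              alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  getp <- function(df) {
    df <- as.data.frame(df)
    key <- if ("gene_id" %in% names(df)) "gene_id" else "gene"
    setNames(df$p, as.character(df[[key]]))
  }
  pa <- getp(results_a); pb <- getp(results_b)
  if (is.null(alpha_a)) alpha_a <- bonferroni_threshold(length(pa))
  va <- pa[map$gene_a]; vb <- pb[map$gene_b]
  ok <- !is.na(va) & !is.na(vb)
  if (!any(ok)) abort("no mapped genes with p-values in both species")
  sa <- va[ok] < alpha_a; sb <- vb[ok] < alpha_b
  tab <- matrix(c(sum(sa & sb), sum(sa & !sb), sum(!sa & sb), sum(!sa & !sb)),
                2, 2, byrow = TRUE)
  degenerate <- sum(sa) == 0 || sum(sb) == 0
  if (degenerate)
    warn("degenerate enrichment table: no significant genes on one margin")
  ft <- fisher.test(tab, alternative = alternative)
  out <- tibble(
    n_mapped = sum(ok), n_ab = tab[1, 1], n_a_only = tab[1, 2],
    n_b_only = tab[2, 1], n_neither = tab[2, 2],
    odds_ratio = sample_odds_ratio(tab), p = ft$p.value,
    alpha_a = alpha_a, alpha_b = alpha_b, degenerate = degenerate
  )
  class(out) <- c("enrichment_result", class(out))
  out
}

#' QQ curves for cross-species enrichment
#'
#' Builds two [qq_data()] tables over species-b p-values of the mapped
#' genes: the background (all mapped genes) and the subset whose species-a
#' ortholog is significant at `alpha_a`. An enriched subset curve lies above
#' the background.
#'
#' @inheritParams enrichment_fisher
#' @return A list with tibbles `background` and `subset` (the latter empty,
#'   with a warning, when no a-gene is significant).
#' @export
enrichment_qq <- function(results_a, results_b, map, alpha_a = NULL) {
  getp <- function(df) {
    df <- as.data.frame(df)
    key <- if ("gene_id" %in% names(df)) "gene_id" else "gene"
    setNames(df$p, as.character(df[[key]]))
  }
  pa <- getp(results_a); pb <- getp(results_b)
  if (is.null(alpha_a)) alpha_a <- bonferroni_threshold(length(pa))
  va <- pa[map$gene_a]; vb <- pb[map$gene_b]
  ok <- !is.na(va) & !is.na(vb)
  if (!any(ok)) abort("no mapped genes with p-values in both species")
  background <- qq_data(vb[ok])
  sub_p <- vb[ok][va[ok] < alpha_a]
  subset_tab <- if (length(sub_p)) qq_data(sub_p) else {
    warn("empty subset: no species-a gene passes alpha_a")
    tibble(expected = numeric(0), observed = numeric(0))
  }
  list(background = background, subset = subset_tab)
}
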