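#' Read / write an expression matrix TSV
#'
#' Layout: header `sample_id <gene1> <gene2> ...`, one sample per row,
#' tab-separated.
#'
#' @param path TSV path.
#' @param stage processing stage tag for the loaded matrix (see
#'   [expression_set()]).
#' @return An `expression_set` (read) or `path` invisibly (write).
#' @export
read_expression_tsv <- function(path, stage = "raw_tpm") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id")
    abort("expression TSV must start with a sample_id column")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) abort("non-numeric expression values")
  expression_set(m, as.character(tab$sample_id), colnames(m), stage = stage)
}

#' @rdname read_expression_tsv
#' @param x an `expression_set`.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expression_set"))
  tab <- data.frame(sample_id = x$sample_ids, x$values, check.names = FALSE)
  colnames(tab)[-1L] <- x$gene_ids
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype / covariate table
#'
#' TSV with `individual_id` as the first column; remaining columns are the
#' trait(s) and covariates.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (names(tab)[1] != "individual_id")
    abort("phenotype TSV must start with an individual_id column")
  tab$individual_id <- as.character(tab$individual_id)
  as_tibble(tab)
}
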