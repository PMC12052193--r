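#' Genotype container
#'
#' A `genotype_set` bundles an `n x M` dosage matrix (individuals in rows,
#' variants in columns, entries in `[0, 2]` counting copies of the effect
#' allele) with per-variant metadata. Effect-allele frequencies are computed
#' from the loaded sample (`p = mean(dosage) / 2`), the same convention GCTA
#' uses when no external frequencies are supplied.
#'
#' @param dosages numeric matrix, individuals x variants, entries in `[0, 2]`.
#'   `NA` entries are mean-imputed per variant.
#' @param variants a data frame with columns `variant_id`, `chrom`, `pos`,
#'   `ref_allele`, `eff_allele` (one row per column of `dosages`).
#' @param individual_ids character vector, one per row of `dosages`.
#'
#' @return An object of class `genotype_set`: a list with elements
#'   `individual_ids`, `variants` (a tibble gaining columns `p` and
#'   `monomorphic`), and `dosages`.
#' @export
genotype_set <- function(dosages, variants, individual_ids) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  variants <- as_tibble(variants)
  individual_ids <- as.character(individual_ids)
  if (nrow(dosages) == 0L) abort("empty input: no individuals")
  if (ncol(dosages) == 0L || nrow(variants) == 0L) abort("empty input: no variants (M must be >= 1)")
  if (nrow(dosages) != length(individual_ids))
    abort("dosage rows do not match the number of individual ids")
  if (ncol(dosages) != nrow(variants))
    abort("dosage columns do not match the number of variant records")
  need <- c("variant_id", "chrom", "pos", "ref_allele", "eff_allele")
  missing_cols <- setdiff(need, names(variants))
  if (length(missing_cols))
    abort(paste0("variant table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(variants$variant_id))
    abort("variant_id values must be unique within a genotype_set")
  if (any(variants$pos < 1)) abort("variant positions must be 1-based (pos >= 1)")
  if (anyDuplicated(individual_ids)) abort("individual ids must be unique")

  # per-variant mean imputation keeps every downstream formula total
  if (anyNA(dosages)) {
    mu <- colMeans(dosages, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(dosages), arr.ind = TRUE)
    dosages[idx] <- mu[idx[, 2L]]
  }
  if (any(dosages < -1e-9 | dosages > 2 + 1e-9))
    abort("dosages must lie in [0, 2]")
  dosages[dosages < 0] <- 0
  dosages[dosages > 2] <- 2

  variants$pos <- as.integer(variants$pos)
  variants$p <- unname(colMeans(dosages)) / 2
  variants$monomorphic <- variants$p <= 0 | variants$p >= 1
  dimnames(dosages) <- list(individual_ids, variants$variant_id)

  structure(
    list(individual_ids = individual_ids, variants = variants, dosages = dosages),
    class = "genotype_set"
  )
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf(
    "<genotype_set> %d individuals x %d variants (%d monomorphic)\n",
    length(x$individual_ids), nrow(x$variants), sum(x$variants$monomorphic)
  ))
  invisible(x)
}

#' @export
dim.genotype_set <- function(x) dim(x$dosages)

#' Subset a genotype set
#'
#' @param x a `genotype_set`.
#' @param individuals,variants index vectors (ids, logicals or positions);
#'   `NULL` keeps everything. Allele frequencies are recomputed on the
#'   retained individuals.
#' @return A `genotype_set`.
#' @export
subset_genotypes <- function(x, individuals = NULL, variants = NULL) {
  stopifnot(inherits(x, "genotype_set"))
  ri <- if (is.null(individuals)) seq_along(x$individual_ids) else individuals
  ci <- if (is.null(variants)) seq_len(nrow(x$variants)) else variants
  if (is.character(ri)) ri <- match(ri, x$individual_ids)
  if (is.character(ci)) ci <- match(ci, x$variants$variant_id)
  if (anyNA(ri)) abort("unknown individual id in subset")
  if (anyNA(ci)) abort("unknown variant id in subset")
  genotype_set(
    x$dosages[ri, ci, drop = FALSE],
    x$variants[ci, c("variant_id", "chrom", "pos", "ref_allele", "eff_allele")],
    x$individual_ids[ri]
  )
}

#' Read genotype dosages
#'
#' Reads either a VCF (v4.x; the `DS` FORMAT field when present, otherwise
#' dosages coded from `GT`) or a tab-separated dosage matrix with header
#' `variant_id chrom pos ref eff <id1> <id2> ...` and one variant per row.
#' Multiallelic VCF records are skipped with a warning; missing entries are
#' mean-imputed per variant.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage_tsv"`.
#' @return A [genotype_set()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "dosage_tsv"
  }
  switch(format,
    vcf = read_genotypes_vcf(path),
    dosage_tsv = read_genotypes_tsv(path)
  )
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) abort("empty input: VCF has no records")
  alt <- v@fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE)
  n_multi <- sum(!biallelic)
  if (n_multi > 0L)
    warn(sprintf("skipped %d multiallelic record(s)", n_multi))
  if (!any(biallelic)) abort("no biallelic records in VCF")
  v <- v[biallelic, ]
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if ("DS" %in% fmt) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else if ("GT" %in% fmt) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(col) {
      sapply(strsplit(col, "[/|]"), function(a) {
        if (length(a) == 0L || anyNA(a) || any(a == ".")) NA_real_ else sum(a != "0")
      })
    })
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(v@fix))
  } else {
    abort("VCF has neither GT nor DS in FORMAT")
  }
  ids <- v@fix[, "ID"]
  bad <- is.na(ids) | ids == "."
  ids[bad] <- paste0(v@fix[bad, "CHROM"], "_", v@fix[bad, "POS"])
  samples <- colnames(v@gt)[-1L]
  genotype_set(
    t(ds),
    tibble(
      variant_id = ids, chrom = v@fix[, "CHROM"], pos = as.integer(v@fix[, "POS"]),
      ref_allele = v@fix[, "REF"], eff_allele = v@fix[, "ALT"]
    ),
    samples
  )
}

read_genotypes_tsv <- function(path) {
  tab <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) abort(paste0("malformed dosage_tsv '", path, "': ", conditionMessage(e)))
  )
  need <- c("variant_id", "chrom", "pos", "ref", "eff")
  if (ncol(tab) < 6L || !identical(names(tab)[1:5], need))
    abort("dosage_tsv header must start with: variant_id chrom pos ref eff")
  sample_ids <- names(tab)[-(1:5)]
  dos <- as.matrix(tab[, -(1:5), drop = FALSE])
  if (!is.numeric(dos)) {
    bad_row <- which(apply(dos, 1, function(r) any(is.na(suppressWarnings(as.numeric(r))) & r != "NA")))[1]
    abort(sprintf("malformed record at data line %d of %s", bad_row, path))
  }
  genotype_set(
    t(dos),
    tibble(
      variant_id = as.character(tab$variant_id), chrom = as.character(tab$chrom),
      pos = tab$pos, ref_allele = tab$ref, eff_allele = tab$eff
    ),
    sample_ids
  )
}

#' Write a dosage matrix as dosage_tsv
#'
#' @param x a `genotype_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path) {
  stopifnot(inherits(x, "genotype_set"))
  tab <- data.frame(
    variant_id = x$variants$variant_id, chrom = x$variants$chrom,
    pos = x$variants$pos, ref = x$variants$ref_allele, eff = x$variants$eff_allele,
    t(x$dosages), check.names = FALSE, stringsAsFactors = FALSE
  )
  colnames(tab)[-(1:5)] <- x$individual_ids
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation
#'
#' For GTF input the gene span is taken as the min/max coordinate over the
#' gene's features. TSV input needs columns
#' `gene_id, chrom, start, end, strand` (a `gene_name` column is optional).
#' Coordinates are 1-based inclusive throughout the package.
#'
#' @param path file path.
#' @param format `"auto"`, `"gtf"` or `"tsv"`.
#' @return A tibble with columns `gene_id`, `gene_name`, `chrom`, `start`,
#'   `end`, `strand`, one row per gene.
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto")
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "tsv"
  ann <- if (format == "gtf") read_annotation_gtf(path) else read_annotation_tsv(path)
  dup <- unique(ann$gene_id[duplicated(ann$gene_id)])
  if (length(dup))
    abort(paste0("duplicate gene_id(s): ", paste(dup, collapse = ", ")))
  if (any(ann$start > ann$end))
    abort(paste0("start > end for gene(s): ",
                 paste(ann$gene_id[ann$start > ann$end], collapse = ", ")))
  if (any(ann$start < 1)) abort("coordinates must be 1-based (start >= 1)")
  ann
}

read_annotation_tsv <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    abort(paste0("annotation TSV lacks column(s): ", paste(missing_cols, collapse = ", ")))
  if (!"gene_name" %in% names(tab)) tab$gene_name <- tab$gene_id
  tibble(
    gene_id = as.character(tab$gene_id), gene_name = as.character(tab$gene_name),
    chrom = as.character(tab$chrom), start = as.integer(tab$start),
    end = as.integer(tab$end), strand = as.character(tab$strand)
  )
}

read_annotation_gtf <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gtf")
    df <- as.data.frame(gr)
    if (!"gene_id" %in% names(df)) abort("GTF lacks gene_id attributes")
    if (!"gene_name" %in% names(df)) df$gene_name <- df$gene_id
    out <- df |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(
        gene_name = .data$gene_name[1] %||% .data$gene_id[1],
        chrom = as.character(.data$seqnames[1]),
        start = min(.data$start), end = max(.data$end),
        strand = as.character(.data$strand[1]), .groups = "drop"
      )
    out$gene_name[is.na(out$gene_name)] <- out$gene_id[is.na(out$gene_name)]
    out$strand[!out$strand %in% c("+", "-")] <- "+"
    return(as_tibble(out))
  }
  # minimal fallback: attribute-field scan of the 9-column GTF layout
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 9L)
  if (length(bad)) abort(sprintf("malformed GTF record at line %d", bad[1]))
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, ' "([^"]+)"'), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
  }
  attrs <- vapply(f, `[[`, character(1), 9L)
  tibble(
    gene_id = get_attr(attrs, "gene_id"),
    gene_name = dplyr::coalesce(get_attr(attrs, "gene_name"), get_attr(attrs, "gene_id")),
    chrom = vapply(f, `[[`, character(1), 1L),
    start = as.integer(vapply(f, `[[`, character(1), 4L)),
    end = as.integer(vapply(f, `[[`, character(1), 5L)),
    strand = vapply(f, `[[`, character(1), 7L)
  ) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      gene_name = .data$gene_name[1], chrom = .data$chrom[1],
      start = min(.data$start), end = max(.data$end),
      strand = .data$strand[1], .groups = "drop"
    )
}

#' Expression container
#'
#' @param values numeric matrix, samples x genes.
#' @param sample_ids,gene_ids row / column identities (taken from dimnames
#'   when omitted).
#' @param stage one of `"raw_tpm"`, `"normalized"`, `"residual"`,
#'   `"predicted"` — where the matrix sits in the processing chain.
#' @return An object of class `expression_set`.
#' @export
expression_set <- function(values, sample_ids = rownames(values),
                           gene_ids = colnames(values),
                           stage = c("raw_tpm", "normalized", "residual", "predicted")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (is.null(sample_ids) || is.null(gene_ids))
    abort("sample_ids and gene_ids are required (or supply dimnames)")
  if (nrow(values) != length(sample_ids) || ncol(values) != length(gene_ids))
    abort("expression matrix dimensions do not match id vectors")
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(
    list(sample_ids = as.character(sample_ids), gene_ids = as.character(gene_ids),
         values = values, stage = stage),
    class = "expression_set"
  )
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("<expression_set> %d samples x %d genes [stage: %s]\n",
              length(x$sample_ids), length(x$gene_ids), x$stage))
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$values)

#' Restrict genotypes and a sample table to their common individuals
#'
#' Both objects are restricted to the ordered intersection of their
#' individual ids (order taken from the genotype set), so that rows align
#' one-to-one downstream.
#'
#' @param genotypes a `genotype_set`.
#' @param table an `expression_set`, or a data frame whose first column (or a
#'   column named `individual_id`) holds individual ids.
#' @return A list with elements `genotypes` and `table`, both reordered.
#' @export
align_cohorts <- function(genotypes, table) {
  stopifnot(inherits(genotypes, "genotype_set"))
  ids_b <- if (inherits(table, "expression_set")) {
    table$sample_ids
  } else if (is.data.frame(table)) {
    key <- if ("individual_id" %in% names(table)) "individual_id" else names(table)[1]
    as.character(table[[key]])
  } else {
    abort("table must be an expression_set or a data frame")
  }
  common <- intersect(genotypes$individual_ids, ids_b)
  if (length(common) == 0L) abort("no individuals in common between the two objects")
  g <- subset_genotypes(genotypes, individuals = common)
  if (inherits(table, "expression_set")) {
    idx <- match(common, table$sample_ids)
    tb <- expression_set(table$values[idx, , drop = FALSE], common, table$gene_ids,
                         stage = table$stage)
  } else {
    key <- if ("individual_id" %in% names(table)) "individual_id" else names(table)[1]
    tb <- table[match(common, as.character(table[[key]])), , drop = FALSE]
    tb <- as_tibble(tb)
  }
  list(genotypes = g, table = tb)
}
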