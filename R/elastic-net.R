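#' Cis window around a gene
#'
#' The cis region runs from `window_bp` upstream of the transcription start
#' to `window_bp` downstream of the transcription end (1-based inclusive,
#' clipped at 1). Strand is carried in annotations but ignored here: the
#' window is defined on start/end only.
#'
#' @param genes a gene-annotation tibble (see [read_annotation()]) or a
#'   single-row data frame with `gene_id`, `chrom`, `start`, `end`.
#' @param window_bp flank size in base pairs (default 1e6).
#' @return A tibble with `gene_id`, `chrom`, `lo`, `hi`.
#' @export
cis_window <- function(genes, window_bp = 1e6) {
  genes <- as_tibble(genes)
  tibble(
    gene_id = genes$gene_id, chrom = genes$chrom,
    lo = pmax(1, genes$start - window_bp), hi = genes$end + window_bp
  )
}

# ids of polymorphic variants inside one cis window
cis_variant_ids <- function(genotypes, window) {
  v <- genotypes$variants
  v$variant_id[v$chrom == window$chrom & v$pos >= window$lo & v$pos <= window$hi &
                 !v$monomorphic]
}

# deterministic fold assignment without disturbing the caller's RNG stream
make_folds <- function(n, k, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Train a cis elastic-net prediction model for one gene
#'
#' Fits a penalized linear model of expression residuals on cis dosages at a
#' fixed elastic-net mixing parameter `alpha`. The penalty is chosen by
#' glmnet's internal 10-fold cross-validation; reported performance (`cv_R`,
#' `cv_R2`) is the out-of-fold Pearson correlation between predicted and
#' observed expression over an outer 10-fold cross-validation, with fold
#' assignment derived from `seed` (shared across alphas in
#' [mixing_sweep()]). Final weights come from a fit on all samples at the
#' selected penalty, on the dosage scale.
#'
#' @param y numeric vector of expression residuals for one gene.
#' @param X_cis dosage submatrix (samples x cis variants), column names are
#'   variant ids.
#' @param alpha elastic-net mixing parameter in `[0, 1]` (0 = ridge,
#'   1 = lasso); default 0.5.
#' @param n_folds folds for both CV levels (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param gene_id optional gene label stored in the result.
#' @return An object of class `prediction_model`: list with `gene_id`,
#'   `weights` (tibble `variant_id`, `weight`), `alpha`, `cv_R`, `cv_R2`,
#'   `n_snps`. Undefined correlations (zero-variance predictions) are
#'   recorded as `cv_R = cv_R2 = 0`.
#' @export
train_elastic_net <- function(y, X_cis, alpha = 0.5, n_folds = 10, seed = 1,
                              gene_id = "gene") {
  y <- as.numeric(y)
  X_cis <- as.matrix(X_cis)
  n <- length(y)
  if (nrow(X_cis) != n) abort("y and X_cis have different numbers of samples")
  if (ncol(X_cis) == 0L) abort("X_cis is empty")
  if (var(y) == 0) abort("zero-variance expression trait")
  if (n < 2 * n_folds) abort("need n >= 2 * n_folds samples")
  if (is.null(colnames(X_cis))) colnames(X_cis) <- paste0("v", seq_len(ncol(X_cis)))

  col_var <- apply(X_cis, 2L, var)
  if (all(col_var == 0)) {
    return(structure(
      list(gene_id = gene_id,
           weights = tibble(variant_id = character(0), weight = numeric(0)),
           alpha = alpha, cv_R = 0, cv_R2 = 0, n_snps = 0L),
      class = "prediction_model"
    ))
  }

  # glmnet needs >= 2 predictors; a zero pad column never enters the model
  pad <- ncol(X_cis) == 1L
  Xfit <- if (pad) cbind(X_cis, `..pad..` = 0) else X_cis

  fold_outer <- make_folds(n, n_folds, seed)
  pred <- rep(NA_real_, n)
  for (f in seq_len(n_folds)) {
    tr <- fold_outer != f
    fold_inner <- make_folds(sum(tr), n_folds, seed + 1000L * f)
    cvfit <- glmnet::cv.glmnet(Xfit[tr, , drop = FALSE], y[tr], alpha = alpha,
                               foldid = fold_inner, standardize = TRUE)
    # out-of-fold prediction of the *genetic* component only: fold-specific
    # intercepts carry no genotype information and, left in, induce spurious
    # anti-correlation with the held-out fold means on null genes
    bfold <- as.numeric(coef(cvfit, s = "lambda.min"))[-1L]
    pred[!tr] <- as.numeric(Xfit[!tr, , drop = FALSE] %*% bfold)
  }
  cv_R <- if (sd(pred) > 0) cor(pred, y) else 0
  # a negative out-of-fold correlation is no predictive ability, not
  # negative-squared ability; such models fail the performance filter anyway
  cv_R2 <- max(cv_R, 0)^2

  fold_full <- make_folds(n, n_folds, seed + 99991L)
  cvfit <- glmnet::cv.glmnet(Xfit, y, alpha = alpha, foldid = fold_full,
                             standardize = TRUE)
  b <- as.numeric(coef(cvfit, s = "lambda.min"))[-1L]
  names(b) <- colnames(Xfit)
  if (pad) b <- b[names(b) != "..pad.."]
  nz <- b != 0
  structure(
    list(gene_id = gene_id,
         weights = tibble(variant_id = names(b)[nz], weight = unname(b[nz])),
         alpha = alpha, cv_R = cv_R, cv_R2 = cv_R2, n_snps = sum(nz)),
    class = "prediction_model"
  )
}

#' @export
print.prediction_model <- function(x, ...) {
  cat(sprintf("<prediction_model> %s: %d SNPs, alpha = %.2f, cv_R = %.3f (R2 = %.3f)\n",
              x$gene_id, x$n_snps, x$alpha, x$cv_R, x$cv_R2))
  invisible(x)
}

#' Sweep the elastic-net mixing parameter
#'
#' Evaluates [train_elastic_net()] over a grid of mixing parameters (default
#' 11 values from 0 to 1 in steps of 0.1) with a shared, seeded fold
#' assignment so performance differences reflect the penalty family, not the
#' folds. Sparse cis architectures show a performance drop toward the ridge
#' end; infinitesimal architectures do not.
#'
#' @inheritParams train_elastic_net
#' @param alphas numeric grid of mixing parameters.
#' @return A tibble with columns `alpha`, `cv_R`, `cv_R2`, `n_snps`.
#' @export
mixing_sweep <- function(y, X_cis, alphas = seq(0, 1, by = 0.1), n_folds = 10,
                         seed = 1) {
  purrr::map_dfr(alphas, function(a) {
    m <- train_elastic_net(y, X_cis, alpha = a, n_folds = n_folds, seed = seed)
    tibble(alpha = a, cv_R = m$cv_R, cv_R2 = m$cv_R2, n_snps = m$n_snps)
  })
}

#' Model database
#'
#' A `model_db` collects per-gene prediction models in the predictdb table
#' layout: a `weights` table (gene, rsid, varID, ref_allele, eff_allele,
#' weight) and an `extra` table (gene, genename, pred_perf_R2, pred_perf_R,
#' n_snps_in_model, pred_perf_pval, alpha).
#'
#' @param models list of `prediction_model` objects.
#' @param genotypes the training `genotype_set` (supplies alleles for the
#'   weights table).
#' @param tissue_label tissue tag stored with the database.
#' @param gene_names optional named character vector gene_id -> gene name.
#' @param n_train training sample size (used for the performance p-value).
#' @return An object of class `model_db`.
#' @export
model_db <- function(models, genotypes = NULL, tissue_label = "tissue",
                     gene_names = NULL, n_train = NA_integer_) {
  ids <- vapply(models, function(m) m$gene_id, character(1))
  if (anyDuplicated(ids)) abort("one model per gene_id required")
  wt <- purrr::map_dfr(models, function(m) {
    if (nrow(m$weights) == 0L) return(tibble())
    tibble(gene = m$gene_id, rsid = m$weights$variant_id,
           varID = m$weights$variant_id, weight = m$weights$weight)
  })
  if (nrow(wt) > 0L && !is.null(genotypes)) {
    idx <- match(wt$varID, genotypes$variants$variant_id)
    wt$ref_allele <- genotypes$variants$ref_allele[idx]
    wt$eff_allele <- genotypes$variants$eff_allele[idx]
  } else if (nrow(wt) > 0L) {
    wt$ref_allele <- NA_character_; wt$eff_allele <- NA_character_
  } else {
    wt <- tibble(gene = character(0), rsid = character(0), varID = character(0),
                 weight = numeric(0), ref_allele = character(0), eff_allele = character(0))
  }
  wt <- wt[, c("gene", "rsid", "varID", "ref_allele", "eff_allele", "weight")]
  extra <- purrr::map_dfr(models, function(m) {
    pval <- if (is.finite(n_train) && abs(m$cv_R) < 1 && m$cv_R != 0 && n_train > 2) {
      tt <- m$cv_R * sqrt((n_train - 2) / (1 - m$cv_R^2))
      2 * pt(-abs(tt), df = n_train - 2)
    } else NA_real_
    gname <- if (!is.null(gene_names) && m$gene_id %in% names(gene_names))
      gene_names[[m$gene_id]] else m$gene_id
    tibble(gene = m$gene_id, genename = gname, pred_perf_R2 = m$cv_R2,
           pred_perf_R = m$cv_R, n_snps_in_model = m$n_snps,
           pred_perf_pval = pval, alpha = m$alpha)
  })
  structure(list(weights = wt, extra = extra, tissue_label = tissue_label,
                 provenance = list(created = as.character(Sys.time()),
                                   n_train = n_train)),
            class = "model_db")
}

#' @export
print.model_db <- function(x, ...) {
  cat(sprintf("<model_db> %s: %d gene models, %d weights\n",
              x$tissue_label, nrow(x$extra), nrow(x$weights)))
  invisible(x)
}

#' Train cis prediction models for all genes
#'
#' Convenience driver: for every annotated gene with expression, extracts the
#' polymorphic cis dosage submatrix and fits [train_elastic_net()]. Genes
#' with no cis variants are skipped with a warning.
#'
#' @param genotypes training `genotype_set`.
#' @param expression `expression_set` of residualized expression.
#' @param annotation gene annotation tibble.
#' @param window_bp cis flank (default 1e6).
#' @inheritParams train_elastic_net
#' @param tissue_label tissue tag for the resulting database.
#' @return A [model_db()].
#' @export
train_models <- function(genotypes, expression, annotation, window_bp = 1e6,
                         alpha = 0.5, n_folds = 10, seed = 1,
                         tissue_label = "tissue") {
  stopifnot(inherits(genotypes, "genotype_set"), inherits(expression, "expression_set"))
  al <- align_cohorts(genotypes, expression)
  genotypes <- al$genotypes; expression <- al$table
  genes <- intersect(expression$gene_ids, annotation$gene_id)
  if (length(genes) == 0L) abort("no genes shared by expression and annotation")
  wins <- cis_window(annotation[match(genes, annotation$gene_id), ], window_bp)
  skipped <- character(0)
  models <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    ids <- cis_variant_ids(genotypes, wins[i, ])
    if (length(ids) == 0L) { skipped <- c(skipped, genes[i]); next }
    models[[i]] <- train_elastic_net(
      expression$values[, genes[i]], genotypes$dosages[, ids, drop = FALSE],
      alpha = alpha, n_folds = n_folds, seed = seed + i, gene_id = genes[i]
    )
  }
  if (length(skipped))
    warn(sprintf("skipped %d gene(s) with no cis variants", length(skipped)))
  models <- models[!vapply(models, is.null, logical(1))]
  gn <- setNames(annotation$gene_name, annotation$gene_id)
  model_db(models, genotypes, tissue_label, gene_names = gn,
           n_train = length(genotypes$individual_ids))
}

#' Filter prediction models on cross-validated performance
#'
#' Retains models whose cross-validated R-squared exceeds `r2_min` and whose
#' cross-validated correlation is non-negative.
#'
#' @param db a `model_db`.
#' @param r2_min minimum `pred_perf_R2` (default 0.01, strict inequality).
#' @return A filtered `model_db`.
#' @export
filter_models <- function(db, r2_min = 0.01) {
  stopifnot(inherits(db, "model_db"))
  keep <- db$extra$pred_perf_R2 > r2_min & db$extra$pred_perf_R >= 0
  genes <- db$extra$gene[keep]
  db$extra <- db$extra[keep, ]
  db$weights <- db$weights[db$weights$gene %in% genes, ]
  db
}

#' Predict genetically regulated expression
#'
#' Computes, per gene, the linear combination of genotype dosages with the
#' trained cis weights. Model variants are matched to the target genotypes
#' by variant id; when ref/eff alleles are swapped relative to the model the
#' dosage is flipped (`2 - X`). Strand-ambiguous pairs (A/T, C/G) are kept
#' as-is with a warning. Model variants absent from the genotypes contribute
#' zero and are tallied in the coverage report; genes with no overlapping
#' variants are dropped with a warning.
#'
#' @param genotypes target `genotype_set`.
#' @param db a `model_db`.
#' @return An `expression_set` (stage `"predicted"`, individuals x genes)
#'   with attribute `coverage`: a tibble `gene`, `n_model`, `n_used`.
#' @export
predict_expression <- function(genotypes, db) {
  stopifnot(inherits(genotypes, "genotype_set"), inherits(db, "model_db"))
  wt <- db$weights
  if (nrow(wt) == 0L) abort("model_db has no weights")
  idx <- match(wt$varID, genotypes$variants$variant_id)
  found <- !is.na(idx)
  gref <- genotypes$variants$ref_allele[idx]
  geff <- genotypes$variants$eff_allele[idx]
  same <- found & gref == wt$ref_allele & geff == wt$eff_allele
  swapped <- found & gref == wt$eff_allele & geff == wt$ref_allele & !same
  ambiguous <- found & paste0(wt$ref_allele, wt$eff_allele) %in% c("AT", "TA", "CG", "GC")
  if (any(ambiguous & (same | swapped)))
    warn(sprintf("%d strand-ambiguous (A/T or C/G) model variant(s) kept as-is",
                 sum(ambiguous & (same | swapped))))
  usable <- same | swapped
  mismatched <- found & !usable & !(is.na(wt$ref_allele) & is.na(wt$eff_allele))
  na_alleles <- found & is.na(wt$ref_allele) & is.na(wt$eff_allele)
  usable <- usable | na_alleles

  n <- length(genotypes$individual_ids)
  genes <- unique(wt$gene)
  pred <- matrix(0, n, length(genes), dimnames = list(genotypes$individual_ids, genes))
  gcol <- match(wt$gene, genes)
  for (r in which(usable)) {
    x <- genotypes$dosages[, idx[r]]
    if (swapped[r]) x <- 2 - x
    pred[, gcol[r]] <- pred[, gcol[r]] + wt$weight[r] * x
  }
  coverage <- tibble(gene = genes,
                     n_model = as.integer(table(factor(wt$gene, levels = genes))),
                     n_used = as.integer(table(factor(wt$gene[usable], levels = genes))))
  empty <- coverage$gene[coverage$n_used == 0L]
  if (length(empty)) {
    warn(sprintf("dropped %d gene(s) with no overlapping model variants", length(empty)))
    pred <- pred[, setdiff(genes, empty), drop = FALSE]
    coverage <- coverage[coverage$n_used > 0L, ]
  }
  out <- expression_set(pred, genotypes$individual_ids, colnames(pred),
                        stage = "predicted")
  attr(out, "coverage") <- coverage
  if (any(mismatched))
    warn(sprintf("%d model variant(s) with irreconcilable alleles ignored", sum(mismatched)))
  out
}

#' Correlate prediction performance across two model sets
#'
#' Pearson correlation of per-gene cross-validated performance between two
#' model sets (e.g. two species) over an ortholog map.
#'
#' @param perf_a,perf_b data frames with columns `gene` and `cv_R` (extra
#'   columns ignored; `pred_perf_R` accepted as an alias).
#' @param map data frame whose first two columns pair `perf_a` genes with
#'   `perf_b` genes.
#' @return A tibble with `n_pairs`, `R`, `p`.
#' @export
performance_correlation <- function(perf_a, perf_b, map) {
  getcol <- function(df) {
    df <- as.data.frame(df)
    cn <- if ("cv_R" %in% names(df)) "cv_R" else if ("pred_perf_R" %in% names(df)) "pred_perf_R" else
      abort("need a cv_R or pred_perf_R column")
    setNames(df[[cn]], df$gene)
  }
  a <- getcol(perf_a); b <- getcol(perf_b)
  map <- as.data.frame(map)
  va <- a[as.character(map[[1]])]; vb <- b[as.character(map[[2]])]
  ok <- !is.na(va) & !is.na(vb)
  if (sum(ok) < 3L) abort("need at least 3 mapped gene pairs with both values")
  if (sd(va[ok]) == 0 || sd(vb[ok]) == 0) {
    warn("degenerate (constant) performance vector: correlation undefined")
    return(tibble(n_pairs = sum(ok), R = NA_real_, p = NA_real_))
  }
  ct <- cor.test(va[ok], vb[ok])
  tibble(n_pairs = sum(ok), R = unname(ct$estimate), p = ct$p.value)
}

#' Write / read a model database
#'
#' `path` ending in `.db` or `.sqlite` selects the predictdb-style SQLite
#' layout (tables `weights` and `extra`); any other path writes the plain
#' TSV dialect as `<path>.weights.tsv` and `<path>.extra.tsv` with identical
#' columns.
#'
#' @param db a `model_db`.
#' @param path output path (base path for the TSV dialect).
#' @return `path` invisibly (write) or a `model_db` (read).
#' @export
write_model_db <- function(db, path) {
  stopifnot(inherits(db, "model_db"))
  if (grepl("\\.(db|sqlite)$", path)) {
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    on.exit(DBI::dbDisconnect(con))
    DBI::dbWriteTable(con, "weights", as.data.frame(db$weights), overwrite = TRUE)
    DBI::dbWriteTable(con, "extra", as.data.frame(db$extra), overwrite = TRUE)
    DBI::dbWriteTable(con, "provenance",
                      data.frame(tissue_label = db$tissue_label,
                                 n_train = db$provenance$n_train %||% NA_integer_),
                      overwrite = TRUE)
  } else {
    write.table(as.data.frame(db$weights), paste0(path, ".weights.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(db$extra), paste0(path, ".extra.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_model_db
#' @export
read_model_db <- function(path) {
  if (grepl("\\.(db|sqlite)$", path)) {
    if (!file.exists(path)) abort(paste0("file not found: ", path))
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    on.exit(DBI::dbDisconnect(con))
    wt <- as_tibble(DBI::dbReadTable(con, "weights"))
    ex <- as_tibble(DBI::dbReadTable(con, "extra"))
    tl <- tryCatch(DBI::dbReadTable(con, "provenance")$tissue_label[1],
                   error = function(e) "tissue")
  } else {
    wtp <- paste0(path, ".weights.tsv"); exp_ <- paste0(path, ".extra.tsv")
    if (!file.exists(wtp) || !file.exists(exp_))
      abort(paste0("model TSV pair not found at base path: ", path))
    wt <- as_tibble(read.delim(wtp, stringsAsFactors = FALSE))
    ex <- as_tibble(read.delim(exp_, stringsAsFactors = FALSE))
    tl <- "tissue"
  }
  structure(list(weights = wt, extra = ex, tissue_label = tl,
                 provenance = list()), class = "model_db")
}
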