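#' Genetic relatedness matrix (GCTA estimator)
#'
#' Computes `GRM_ij = (1/M) * sum_k (X_ik - 2 p_k)(X_jk - 2 p_k) / (2 p_k (1 - p_k))`
#' over retained polymorphic variants, with `p_k` the sample frequency of the
#' effect allele. Monomorphic variants are excluded and `M` reflects the
#' exclusion. The default uses all genome-wide variants, unpruned — the
#' recommended choice for the whitening correction; leave-one-chromosome-out
#' and pruned variants are explicit opt-ins.
#'
#' @param genotypes a [genotype_set()].
#' @param exclude_chrom optional chromosome to leave out (LOCO).
#' @param variant_subset optional character vector of variant ids to restrict
#'   to (e.g. the output of [ld_prune()]).
#' @return An object of class `grm`: list with `individual_ids`, `values`
#'   (n x n symmetric matrix) and `M_used`.
#' @export
compute_grm <- function(genotypes, exclude_chrom = NULL, variant_subset = NULL) {
  stopifnot(inherits(genotypes, "genotype_set"))
  keep <- !genotypes$variants$monomorphic
  if (!is.null(exclude_chrom))
    keep <- keep & !(genotypes$variants$chrom %in% exclude_chrom)
  if (!is.null(variant_subset))
    keep <- keep & genotypes$variants$variant_id %in% variant_subset
  if (!any(keep)) abort("no polymorphic variants left after exclusions")
  X <- genotypes$dosages[, keep, drop = FALSE]
  p <- genotypes$variants$p[keep]
  Z <- sweep(X, 2L, 2 * p, "-")
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  M <- ncol(Z)
  G <- tcrossprod(Z) / M
  G <- (G + t(G)) / 2
  structure(
    list(individual_ids = genotypes$individual_ids, values = G, M_used = M),
    class = "grm"
  )
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d individuals, %d variants used\n",
              length(x$individual_ids), x$M_used))
  invisible(x)
}

#' @export
dim.grm <- function(x) dim(x$values)

#' Greedy sliding-window LD pruning
#'
#' Per chromosome, a window of `window_kb` kilobases slides in steps of
#' `step` variants; within each window, for every pair of still-retained
#' variants with squared dosage correlation above `r2_threshold` the variant
#' with the larger position index is dropped. Mirrors the usual
#' `--indep-pairwise` behaviour (e.g. 500 kb window, step 5, r2 0.95).
#'
#' @param genotypes a `genotype_set` (variants need not be pre-sorted; they
#'   are sorted by position per chromosome internally).
#' @param window_kb window width in kb (default 500).
#' @param step number of variants the window advances by (default 5).
#' @param r2_threshold pairwise r-squared above which the later variant is
#'   dropped; must lie in (0, 1].
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(genotypes, window_kb = 500, step = 5, r2_threshold = 0.95) {
  stopifnot(inherits(genotypes, "genotype_set"))
  if (r2_threshold <= 0 || r2_threshold > 1)
    abort("r2_threshold must lie in (0, 1]")
  v <- genotypes$variants
  retained <- character(0)
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    idx <- idx[order(v$pos[idx])]
    pos <- v$pos[idx]
    X <- genotypes$dosages[, idx, drop = FALSE]
    keep <- !v$monomorphic[idx]
    m <- length(idx)
    start <- 1L
    repeat {
      in_win <- which(keep & pos >= pos[start] & pos <= pos[start] + window_kb * 1000 &
                        seq_len(m) >= start)
      if (length(in_win) > 1L) {
        r2 <- suppressWarnings(cor(X[, in_win, drop = FALSE]))^2
        for (a in seq_len(length(in_win) - 1L)) {
          if (!keep[in_win[a]]) next
          for (b in seq((a + 1L), length(in_win))) {
            if (!keep[in_win[b]]) next
            if (is.finite(r2[a, b]) && r2[a, b] > r2_threshold) keep[in_win[b]] <- FALSE
          }
        }
      }
      start <- start + step
      if (start > m) break
    }
    retained <- c(retained, v$variant_id[idx][keep])
  }
  retained
}

# symmetric eigendecomposition with eigenvalues clamped at zero:
# the GRM is PSD by construction, negatives are floating-point noise
grm_eigen <- function(grm) {
  ed <- eigen(grm$values, symmetric = TRUE)
  ed$values <- pmax(ed$values, 0)
  ed
}

#' Whitening operator for the relatedness-structured error covariance
#'
#' The error covariance of a trait under the polygenic null is
#' `sigma2 * Gamma` with `Gamma = h2 * GRM + (1 - h2) * I`. This builds the
#' symmetric inverse square root `Gamma^(-1/2)` from a one-time
#' eigendecomposition of the GRM; premultiplying data by it decorrelates the
#' errors so ordinary least squares applies.
#'
#' @param grm a [compute_grm()] result (or any `grm` object).
#' @param h2 heritability in `[0, 1]`.
#' @param sigma2 total variance scale (default 1; does not affect the
#'   operator, carried for reconstruction of `Sigma`).
#' @param tol eigenvalue floor: transformed eigenvalues
#'   `h2 * lambda + 1 - h2` at or below `tol` make `Gamma` singular.
#' @return An object of class `whiten_operator` with elements `U`
#'   (eigenvectors), `lambda` (clamped GRM eigenvalues), `h2`, `sigma2`,
#'   `individual_ids`.
#' @export
whitening_operator <- function(grm, h2, sigma2 = 1, tol = 1e-10) {
  stopifnot(inherits(grm, "grm"))
  if (h2 < 0 || h2 > 1) abort("h2 must lie in [0, 1]")
  if (sigma2 <= 0) abort("sigma2 must be positive")
  ed <- grm_eigen(grm)
  d <- h2 * ed$values + 1 - h2
  if (any(d <= tol))
    abort("Gamma = h2*GRM + (1-h2)*I is singular at this h2")
  structure(
    list(U = ed$vectors, lambda = ed$values, h2 = h2, sigma2 = sigma2,
         individual_ids = grm$individual_ids),
    class = "whiten_operator"
  )
}

#' Apply (powers of) Gamma to vectors or matrices
#'
#' `whiten()` applies `Gamma^(-1/2)` (the default `power = -1/2`); other
#' powers give `Gamma` itself (`power = 1`) or its square root.
#'
#' @param op a [whitening_operator()].
#' @param x numeric vector or matrix with `n` rows.
#' @param power exponent applied to `Gamma`'s eigenvalues (default `-1/2`).
#' @return Transformed vector/matrix of the same shape.
#' @export
whiten <- function(op, x, power = -1 / 2) {
  stopifnot(inherits(op, "whiten_operator"))
  d <- (op$h2 * op$lambda + 1 - op$h2)^power
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  if (nrow(x) != nrow(op$U)) abort("dimension mismatch in whiten()")
  out <- op$U %*% (d * crossprod(op$U, x))
  if (vec) drop(out) else out
}

#' Matrix square root of the GRM
#'
#' Symmetric PSD square root via eigendecomposition (negative eigenvalues
#' clamped to zero), used to draw correlated random effects.
#'
#' @param grm a `grm` object.
#' @return An n x n matrix `S` with `S %*% S = GRM` (up to clamping).
#' @export
grm_sqrt <- function(grm) {
  stopifnot(inherits(grm, "grm"))
  ed <- grm_eigen(grm)
  ed$vectors %*% (sqrt(ed$values) * t(ed$vectors))
}

#' Write / read a GRM in triplet text form
#'
#' The triplet file holds the lower triangle as `id1 id2 value` (tab
#' separated, GCTA-compatible layout); the companion `.ids` file lists the
#' individual ids in order.
#'
#' @param grm a `grm` object.
#' @param path base path for the triplet file (ids written to `<path>.ids`).
#' @return `path` invisibly (write) or a `grm` (read).
#' @export
write_grm <- function(grm, path) {
  stopifnot(inherits(grm, "grm"))
  n <- length(grm$individual_ids)
  ij <- which(lower.tri(grm$values, diag = TRUE), arr.ind = TRUE)
  tab <- data.frame(
    id1 = grm$individual_ids[ij[, 1]], id2 = grm$individual_ids[ij[, 2]],
    value = grm$values[ij]
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(c(as.character(n), as.character(grm$M_used), grm$individual_ids),
             paste0(path, ".ids"))
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  meta <- readLines(paste0(path, ".ids"))
  n <- as.integer(meta[1]); M_used <- as.integer(meta[2])
  ids <- meta[-(1:2)]
  tab <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  G <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(tab[[1]], ids); j <- match(tab[[2]], ids)
  G[cbind(i, j)] <- tab[[3]]
  G[cbind(j, i)] <- tab[[3]]
  structure(list(individual_ids = ids, values = G, M_used = M_used), class = "grm")
}
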