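# run code under a fixed seed, restoring the caller's RNG stream afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

ar1_series <- function(m, rho) {
  z <- numeric(m)
  z[1] <- rnorm(1)
  if (m > 1) {
    e <- rnorm(m - 1)
    for (k in 2:m) z[k] <- rho * z[k - 1] + sqrt(1 - rho^2) * e[k - 1]
  }
  z
}

# one founder haplotype: thresholded AR(1) Gaussian copula, so marginal
# allele frequencies are preserved while adjacent variants are in LD
founder_haplotype <- function(p, rho) {
  as.integer(ar1_series(length(p), rho) < qnorm(p))
}

# transmit one gamete from a parent's two haplotypes with Haldane crossovers
# (1 cM/Mb); returns a haplotype vector
meiosis <- function(h1, h2, pos) {
  m <- length(h1)
  r <- if (m > 1) 0.5 * (1 - exp(-2 * diff(pos) * 1e-8)) else numeric(0)
  cross <- c(rbinom(1, 1, 0.5), rbinom(m - 1, 1, r))
  phase <- cumsum(cross) %% 2L
  ifelse(phase == 0L, h1, h2)
}

#' Simulate a related cohort with sparse cis-regulated expression
#'
#' Emulates an outbred, family-structured cohort: founder allele frequencies
#' are drawn uniformly, founder haplotypes carry local LD (thresholded AR(1)
#' Gaussian copula with parameter `ld_rho`), and each family's sibs are
#' produced by gene-dropping two recombined founder gametes. Gene expression
#' has a sparse cis architecture: each gene gets `n_causal_per_gene` causal
#' variants inside its cis window with normal effects, and noise scaled so
#' the cis component explains `h2_expr` of the expression variance.
#'
#' @param n number of individuals (sibs; founders are not retained).
#' @param n_families number of sibships; `n` is spread as evenly as possible.
#' @param m variants per chromosome.
#' @param n_chrom number of chromosomes.
#' @param n_genes number of genes (assigned to chromosomes round-robin).
#' @param h2_expr cis heritability of expression in `[0, 1)`; 0 gives pure
#'   noise expression.
#' @param n_causal_per_gene causal cis variants per gene.
#' @param ld_rho AR(1) copula parameter controlling founder LD (default 0.9);
#'   a vector is recycled across chromosomes, so LD density can vary along
#'   the genome (e.g. one near-1 chromosome emulates a dense high-LD region).
#' @param chrom_length chromosome length in bp (default 30 Mb).
#' @param maf_range founder allele-frequency range (default `c(0.05, 0.95)`).
#' @param seed integer seed; cohorts are bit-reproducible from it.
#' @return An object of class `synthetic_cohort`: list with `genotypes`
#'   ([genotype_set()]), `family_labels`, `annotation` (gene tibble),
#'   `true_eqtl` (tibble `gene_id`, `variant_id`, `effect`), `expression`
#'   (residual-stage [expression_set()]), `h2_expr`, `seed`.
#' @export
simulate_cohort <- function(n = 600, n_families = 100, m = 150, n_chrom = 5,
                            n_genes = 340, h2_expr = 0.3, n_causal_per_gene = 2,
                            ld_rho = 0.9, chrom_length = 30e6,
                            maf_range = c(0.05, 0.95), seed = 1) {
  if (n < 2 * n_families) abort("need n >= 2 * n_families")
  if (m < 1 || n_chrom < 1 || n_genes < 1) abort("parameters must be positive")
  if (h2_expr < 0 || h2_expr >= 1) abort("h2_expr must lie in [0, 1)")
  if (n_causal_per_gene > m) abort("n_causal_per_gene cannot exceed variants per chromosome")
  with_seed(seed, {
    pos <- round(seq(1e5, chrom_length, length.out = m))
    fam_sizes <- rep(n %/% n_families, n_families)
    if (n %% n_families) fam_sizes[seq_len(n %% n_families)] <-
        fam_sizes[seq_len(n %% n_families)] + 1L

    chroms <- paste0("chr", seq_len(n_chrom))
    rho_by_chrom <- rep_len(ld_rho, n_chrom)
    # allele frequencies drift smoothly along the chromosome (linked variants
    # share genealogy, so their frequencies are similar); without matched
    # frequencies adjacent binary variants could never reach high r2
    p_by_chrom <- lapply(seq_len(n_chrom), function(c_) {
      maf_range[1] + diff(maf_range) * pnorm(ar1_series(m, rho_by_chrom[c_]))
    })

    # per chromosome: gene-drop within each family
    dos_by_chrom <- lapply(seq_len(n_chrom), function(c_) {
      p <- p_by_chrom[[c_]]
      out <- matrix(0L, n, m)
      row <- 1L
      for (f in seq_len(n_families)) {
        fh <- replicate(4, founder_haplotype(p, rho_by_chrom[c_]), simplify = FALSE)
        for (s in seq_len(fam_sizes[f])) {
          g1 <- meiosis(fh[[1]], fh[[2]], pos)
          g2 <- meiosis(fh[[3]], fh[[4]], pos)
          out[row, ] <- g1 + g2
          row <- row + 1L
        }
      }
      out
    })
    dosages <- do.call(cbind, dos_by_chrom)
    variants <- purrr::map_dfr(seq_len(n_chrom), function(c_) {
      tibble(variant_id = sprintf("%s_%d", chroms[c_], pos),
             chrom = chroms[c_], pos = pos,
             ref_allele = "A", eff_allele = "G")
    })
    ids <- sprintf("ind%04d", seq_len(n))
    fam <- rep(sprintf("fam%03d", seq_len(n_families)), fam_sizes)
    gt <- genotype_set(dosages, variants, ids)

    # genes round-robin across chromosomes, starts spread along the chromosome
    g_chrom <- ((seq_len(n_genes) - 1L) %% n_chrom) + 1L
    per_chrom <- tabulate(g_chrom, n_chrom)
    g_start <- numeric(n_genes)
    ctr <- integer(n_chrom)
    spread <- lapply(seq_len(n_chrom), function(c_)
      round(seq(1.5e6, chrom_length - 1.5e6, length.out = max(per_chrom[c_], 1))))
    for (g in seq_len(n_genes)) {
      c_ <- g_chrom[g]; ctr[c_] <- ctr[c_] + 1L
      g_start[g] <- spread[[c_]][ctr[c_]]
    }
    annotation <- tibble(
      gene_id = sprintf("GENE%04d", seq_len(n_genes)),
      gene_name = sprintf("Gene%04d", seq_len(n_genes)),
      chrom = chroms[g_chrom], start = as.integer(g_start),
      end = as.integer(g_start + 10000), strand = "+"
    )

    wins <- cis_window(annotation)
    expr <- matrix(0, n, n_genes, dimnames = list(ids, annotation$gene_id))
    eqtl <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      if (h2_expr == 0) { expr[, g] <- rnorm(n); next }
      cand <- cis_variant_ids(gt, wins[g, ])
      if (length(cand) < n_causal_per_gene)
        abort("infeasible parameters: fewer cis variants than n_causal_per_gene")
      cvs <- sample(cand, n_causal_per_gene)
      beta <- rnorm(n_causal_per_gene)
      gval <- gt$dosages[, cvs, drop = FALSE] %*% beta
      vg <- var(as.numeric(gval))
      if (vg == 0) { expr[, g] <- rnorm(n); next }
      eps <- rnorm(n, sd = sqrt(vg * (1 - h2_expr) / h2_expr))
      expr[, g] <- as.numeric(gval) + eps
      eqtl[[g]] <- tibble(gene_id = annotation$gene_id[g], variant_id = cvs,
                          effect = beta)
    }
    expr <- scale(expr, center = TRUE, scale = FALSE)
    structure(
      list(genotypes = gt, family_labels = fam, annotation = annotation,
           true_eqtl = dplyr::bind_rows(eqtl),
           expression = expression_set(expr, ids, annotation$gene_id,
                                       stage = "residual"),
           h2_expr = h2_expr, seed = seed),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d individuals (%d families), %d variants, %d genes (h2_expr = %.2f, seed = %d)\n",
              length(x$genotypes$individual_ids), length(unique(x$family_labels)),
              nrow(x$genotypes$variants), nrow(x$annotation), x$h2_expr, x$seed))
  invisible(x)
}

#' Split a cohort into disjoint training and target sets
#'
#' Families are kept intact: whole sibships are assigned to the training
#' split until it reaches approximately `prop` of the individuals.
#'
#' @param cohort a `synthetic_cohort`.
#' @param prop approximate fraction of individuals in the training split.
#' @param seed seed for the family shuffle.
#' @return A list with `train_ids` and `target_ids`.
#' @export
split_cohort <- function(cohort, prop = 0.5, seed = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  fams <- unique(cohort$family_labels)
  with_seed(seed, {
    fams <- sample(fams)
  })
  sizes <- table(cohort$family_labels)[fams]
  ntrain_target <- prop * length(cohort$genotypes$individual_ids)
  cum <- cumsum(sizes)
  k <- which.min(abs(cum - ntrain_target))
  train_fams <- fams[seq_len(k)]
  train <- cohort$family_labels %in% train_fams
  list(train_ids = cohort$genotypes$individual_ids[train],
       target_ids = cohort$genotypes$individual_ids[!train])
}

#' Simulate a null phenotype with a relatedness-structured random effect
#'
#' Draws `Y = u + e` with no gene-expression effect. The correlated term `u`
#' can be drawn either by multiplying iid normals by the matrix square root
#' of the GRM (`mode = "matrix_sqrt"`) or, equivalently in covariance, as a
#' fully polygenic sum of standardized genotype dosages weighted by iid
#' normal effects `delta_k` with variance `sigma2 * h2 / M`
#' (`mode = "polygenic"`). Either way `cov(u) = sigma2 * h2 * GRM` and
#' `e ~ N(0, sigma2 * (1 - h2) I)`.
#'
#' @param x a `grm` (matrix_sqrt mode) or `genotype_set` (either mode; the
#'   GRM is computed from it when needed).
#' @param h2 heritability of the null trait in `[0, 1]`.
#' @param sigma2 total variance (default 1).
#' @param mode `"matrix_sqrt"` or `"polygenic"`.
#' @param seed integer seed.
#' @return Numeric trait vector (named by individual); polygenic draws carry
#'   the effect vector as attribute `delta`.
#' @export
simulate_null_phenotype <- function(x, h2, sigma2 = 1,
                                    mode = c("matrix_sqrt", "polygenic"),
                                    seed = 1) {
  mode <- match.arg(mode)
  if (h2 < 0 || h2 > 1) abort("h2 must lie in [0, 1]")
  if (mode == "polygenic" && !inherits(x, "genotype_set"))
    abort("polygenic mode needs a genotype_set")
  with_seed(seed, {
    if (mode == "matrix_sqrt") {
      grm <- if (inherits(x, "grm")) x else compute_grm(x)
      n <- length(grm$individual_ids)
      u <- if (h2 > 0) {
        S <- grm_sqrt(grm)
        if (max(abs(S)) < 1e-12) abort("degenerate GRM: cannot draw the random effect")
        sqrt(sigma2 * h2) * as.numeric(S %*% rnorm(n))
      } else numeric(n)
      y <- u + rnorm(n, sd = sqrt(sigma2 * (1 - h2)))
      names(y) <- grm$individual_ids
      y
    } else {
      keep <- !x$variants$monomorphic
      if (!any(keep)) abort("degenerate genotypes: no polymorphic variants")
      X <- x$dosages[, keep, drop = FALSE]
      p <- x$variants$p[keep]
      W <- sweep(sweep(X, 2L, 2 * p, "-"), 2L, sqrt(2 * p * (1 - p)), "/")
      M <- ncol(W)
      delta <- rnorm(M, sd = sqrt(sigma2 * h2 / M))
      u <- as.numeric(W %*% delta)
      y <- u + rnorm(nrow(W), sd = sqrt(sigma2 * (1 - h2)))
      names(y) <- x$individual_ids
      attr(y, "delta") <- delta
      y
    }
  })
}

# profile ML for h2 given a precomputed GRM eigendecomposition (see
# estimate_h2 for the model); returns list(h2, sigma2)
h2_profile_fast <- function(y, ed) {
  n <- length(y)
  yt <- crossprod(ed$vectors, y)
  ot <- crossprod(ed$vectors, rep(1, n))
  prof <- function(h2) {
    d <- h2 * ed$values + 1 - h2
    if (any(d <= 1e-12)) return(Inf)
    w <- 1 / d
    mu <- sum(ot * yt * w) / sum(ot^2 * w)
    s2 <- sum((yt - mu * ot)^2 * w) / n
    0.5 * (n * log(s2) + sum(log(d)) + n)
  }
  opt <- optimize(prof, interval = c(0, 1), tol = 1e-6)
  cand <- c(opt$minimum, 0, 1)
  h2 <- cand[which.min(vapply(cand, prof, numeric(1)))]
  d <- h2 * ed$values + 1 - h2
  w <- 1 / d
  mu <- sum(ot * yt * w) / sum(ot^2 * w)
  list(h2 = h2, sigma2 = sum((yt - mu * ot)^2 * w) / n)
}

#' Null-phenotype type-I-error calibration study
#'
#' For each heritability value and replicate, simulates a null phenotype on
#' the target individuals, estimates its heritability, and runs both the
#' whitened (corrected) and the naive association of the trait against
#' predicted expression. P-values are pooled over genes and replicates and
#' tallied against each significance threshold: a calibrated test shows a
#' false-positive rate equal to the threshold.
#'
#' @param cohort a `synthetic_cohort`.
#' @param db a filtered [model_db()] trained on a disjoint split of the
#'   cohort (see [split_cohort()]).
#' @param target_ids individuals to run the association on (default: all
#'   cohort individuals; pass the held-out split for an honest study).
#' @param h2_grid heritability values for the null trait (default
#'   `c(0.1, 0.2, 0.4, 0.6, 0.8)`).
#' @param n_reps null replicates per heritability value (default 100).
#' @param thresholds significance levels tallied (default
#'   `c(1e-6, 0.01, 0.05, 0.10)`).
#' @param null_mode how the random effect is drawn; see
#'   [simulate_null_phenotype()].
#' @param grm optional pre-computed `grm` for the target individuals (e.g. a
#'   LOCO or LD-pruned GRM); defaults to the full genome-wide GRM. The
#'   polygenic null always uses all variants, so an under-covering GRM here
#'   reproduces the under-correction seen with LOCO/pruned GRMs.
#' @param genes optional subset of model genes to test.
#' @param sigma2 total null-trait variance (default 1).
#' @param seed integer seed.
#' @return A tibble of class `calibration_report` with columns `mode`, `h2`,
#'   `alpha`, `n_tests`, `n_below`, `fpr`; the pooled p-values per
#'   (mode, h2) cell are attached as attribute `pvalues` (a named list) for
#'   QQ inspection.
#' @export
calibration_study <- function(cohort, db, target_ids = NULL,
                              h2_grid = c(0.1, 0.2, 0.4, 0.6, 0.8),
                              n_reps = 100, thresholds = c(1e-6, 0.01, 0.05, 0.10),
                              null_mode = c("matrix_sqrt", "polygenic"),
                              grm = NULL, genes = NULL, sigma2 = 1, seed = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"), inherits(db, "model_db"))
  null_mode <- match.arg(null_mode)
  if (n_reps < 1) abort("n_reps must be >= 1")
  if (is.null(target_ids)) target_ids <- cohort$genotypes$individual_ids
  gt <- subset_genotypes(cohort$genotypes, individuals = target_ids)
  if (is.null(grm)) grm <- compute_grm(gt)
  if (!identical(grm$individual_ids, gt$individual_ids))
    abort("grm is not aligned to the target individuals")
  if (!is.null(genes)) {
    db$extra <- db$extra[db$extra$gene %in% genes, ]
    db$weights <- db$weights[db$weights$gene %in% genes, ]
  }
  T_pred <- suppressWarnings(predict_expression(gt, db))
  ed <- grm_eigen(grm)
  S <- if (null_mode == "matrix_sqrt") ed$vectors %*% (sqrt(ed$values) * t(ed$vectors)) else NULL
  W <- if (null_mode == "polygenic") {
    keep <- !gt$variants$monomorphic
    X <- gt$dosages[, keep, drop = FALSE]
    p <- gt$variants$p[keep]
    sweep(sweep(X, 2L, 2 * p, "-"), 2L, sqrt(2 * p * (1 - p)), "/")
  } else NULL
  n <- length(target_ids)
  ones <- rep(1, n)

  cells <- list()
  pooled <- list()
  for (h2 in h2_grid) {
    pc <- vector("list", n_reps); pn <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      rep_seed <- seed + round(1e4 * h2) * 1000L + r
      y <- with_seed(rep_seed, {
        u <- if (h2 == 0) numeric(n)
        else if (null_mode == "matrix_sqrt") sqrt(sigma2 * h2) * as.numeric(S %*% rnorm(n))
        else as.numeric(W %*% rnorm(ncol(W), sd = sqrt(sigma2 * h2 / ncol(W))))
        u + rnorm(n, sd = sqrt(sigma2 * (1 - h2)))
      })
      fit <- h2_profile_fast(y, ed)
      dinv <- (fit$h2 * ed$values + 1 - fit$h2)^(-0.5)
      wmul <- function(x) ed$vectors %*% (dinv * crossprod(ed$vectors, as.matrix(x)))
      yt <- as.numeric(wmul(y)); Tt <- wmul(T_pred$values); it <- as.numeric(wmul(ones))
      pc[[r]] <- assoc_ols(yt, Tt, it, "corrected", db$tissue_label)$p
      pn[[r]] <- assoc_ols(y, T_pred$values, ones, "naive", db$tissue_label)$p
    }
    for (mode_ in c("corrected", "naive")) {
      pv <- unlist(if (mode_ == "corrected") pc else pn)
      pooled[[paste(mode_, h2, sep = "_")]] <- pv
      cells[[length(cells) + 1L]] <- tibble(
        mode = mode_, h2 = h2, alpha = thresholds,
        n_tests = length(pv),
        n_below = vapply(thresholds, function(a) sum(pv < a), integer(1))
      )
    }
  }
  out <- dplyr::bind_rows(cells)
  out$fpr <- out$n_below / out$n_tests
  class(out) <- c("calibration_report", class(out))
  attr(out, "pvalues") <- pooled
  out
}
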