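# hash a config sub-list plus the content of any *_path inputs it names
stage_hash <- function(params) {
  paths <- unlist(params[grepl("_path$", names(params))], use.names = FALSE)
  hashes <- vapply(paths, function(p)
    if (file.exists(p)) tools::md5sum(p)[[1]] else "missing", character(1))
  digest_input <- paste(
    paste(names(params), vapply(params, function(x) paste(format(x), collapse = ","),
                                character(1)), collapse = ";"),
    paste(hashes, collapse = ";"), sep = "|"
  )
  tf <- tempfile(); writeLines(digest_input, tf); on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

read_manifest <- function(path) {
  if (file.exists(path)) yaml::read_yaml(path) else list(stages = list())
}

#' Run the analysis pipeline from a config file
#'
#' Executes the declared stages in dependency order:
#' `simulate_cohort` -> `train` -> `predict` -> `assoc` / `calibrate`, and
#' `enrich`. Every run writes a manifest (package version, seed, per-stage
#' input hashes) into the output directory; a re-run skips stages whose
#' configuration and inputs are unchanged and whose outputs exist, unless
#' `force = TRUE`. Missing declared inputs fail before any stage runs; a
#' stage failure renames the outputs it had produced with a `.partial`
#' suffix and signals an error.
#'
#' Config is YAML: top-level `output_dir`, `seed`, `stages` (list of stage
#' names) and one section per stage with its parameters; file inputs use
#' keys ending in `_path`. All tuning thresholds of the other modules are
#' surfaced here (`alpha`, `r2_min`, `n_pcs`, `h2_grid`, the Bonferroni
#' universe `n_tests`).
#'
#' @param config_path path to the YAML config (or an equivalent named list).
#' @param force re-run stages even when up to date.
#' @return Invisibly, the output directory; stage outputs and
#'   `manifest.yaml` inside it.
#' @export
run_pipeline <- function(config_path, force = FALSE) {
  cfg <- if (is.list(config_path)) config_path else yaml::read_yaml(config_path)
  if (is.null(cfg$output_dir)) abort("config must declare output_dir")
  if (is.null(cfg$stages)) abort("config must declare stages")
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed %||% 1L

  known <- c("simulate_cohort", "train", "predict", "assoc", "calibrate", "enrich")
  stages <- unlist(cfg$stages)
  bad <- setdiff(stages, known)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  stages <- known[known %in% stages]

  # pre-flight: every declared *_path must exist before anything runs
  for (st in stages) {
    params <- cfg[[st]] %||% list()
    paths <- as.character(unlist(params[grepl("_path$", names(params))],
                                 use.names = FALSE))
    missing_in <- paths[!file.exists(paths)]
    if (length(missing_in))
      abort(paste0("stage '", st, "': missing input file(s): ",
                   paste(missing_in, collapse = ", ")))
  }

  manifest_path <- file.path(out_dir, "manifest.yaml")
  manifest <- read_manifest(manifest_path)
  manifest$package <- as.character(utils::packageVersion("ratxcan"))
  manifest$seed <- seed

  state <- new.env(parent = emptyenv())
  for (st in stages) {
    params <- cfg[[st]] %||% list()
    h <- stage_hash(params)
    outs <- pipeline_stage_outputs(st, out_dir, params)
    rec <- manifest$stages[[st]]
    up_to_date <- !force && !is.null(rec) && identical(rec$hash, h) &&
      all(file.exists(outs))
    if (up_to_date) {
      inform(paste0("stage '", st, "' up to date; skipped"))
      pipeline_stage_load(st, out_dir, params, state)
      next
    }
    inform(paste0("running stage '", st, "' (seed ", seed, ")"))
    ok <- FALSE
    tryCatch({
      pipeline_stage_run(st, out_dir, params, seed, state)
      ok <- TRUE
    }, error = function(e) {
      for (f in outs[file.exists(outs)]) file.rename(f, paste0(f, ".partial"))
      abort(paste0("stage '", st, "' failed: ", conditionMessage(e)))
    })
    if (ok) {
      manifest$stages[[st]] <- list(hash = h, finished = as.character(Sys.time()),
                                    outputs = as.list(outs))
      yaml::write_yaml(manifest, manifest_path)
    }
  }
  invisible(out_dir)
}

pipeline_stage_outputs <- function(st, out_dir, params) {
  switch(st,
    simulate_cohort = file.path(out_dir, c("cohort_genotypes.tsv", "cohort_expression.tsv",
                                           "cohort_annotation.tsv", "cohort_families.tsv")),
    train = file.path(out_dir, c("models.weights.tsv", "models.extra.tsv")),
    predict = file.path(out_dir, "predicted_expression.tsv"),
    assoc = file.path(out_dir, "association.tsv"),
    calibrate = file.path(out_dir, c("calibration_report.tsv", "calibration_qq.tsv")),
    enrich = file.path(out_dir, c("enrichment.json", "enrichment_qq_background.tsv",
                                  "enrichment_qq_subset.tsv"))
  )
}

# rebuild in-memory state from the outputs of a skipped stage
pipeline_stage_load <- function(st, out_dir, params, state) {
  if (st == "simulate_cohort") {
    state$cohort_seed <- params$seed
    state$cohort_params <- params
  }
  invisible(NULL)
}

get_cohort <- function(state, params, seed) {
  if (is.null(state$cohort)) {
    sp <- state$cohort_params %||% params %||% list()
    sp$seed <- sp$seed %||% seed
    state$cohort <- do.call(simulate_cohort, sp)
  }
  state$cohort
}

pipeline_stage_run <- function(st, out_dir, params, seed, state) {
  if (st == "simulate_cohort") {
    params$seed <- params$seed %||% seed
    state$cohort_params <- params
    co <- do.call(simulate_cohort, params)
    state$cohort <- co
    write_genotypes(co$genotypes, file.path(out_dir, "cohort_genotypes.tsv"))
    write_expression_tsv(co$expression, file.path(out_dir, "cohort_expression.tsv"))
    write.table(as.data.frame(co$annotation), file.path(out_dir, "cohort_annotation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(individual_id = co$genotypes$individual_ids,
                           family = co$family_labels),
                file.path(out_dir, "cohort_families.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (st == "train") {
    if (!is.null(params$genotypes_path)) {
      gt <- read_genotypes(params$genotypes_path)
      ex <- read_expression_tsv(params$expression_path, stage = "residual")
      ann <- read_annotation(params$annotation_path)
      train_ids <- gt$individual_ids
    } else {
      co <- get_cohort(state, NULL, seed)
      sp <- split_cohort(co, prop = params$train_prop %||% 0.5, seed = seed)
      state$split <- sp
      gt <- subset_genotypes(co$genotypes, individuals = sp$train_ids)
      ex <- expression_set(co$expression$values[match(sp$train_ids, co$expression$sample_ids), ,
                                                drop = FALSE],
                           sp$train_ids, co$expression$gene_ids, stage = "residual")
      ann <- co$annotation
      train_ids <- sp$train_ids
    }
    db <- train_models(gt, ex, ann, alpha = params$alpha %||% 0.5,
                       n_folds = params$n_folds %||% 10, seed = seed,
                       tissue_label = params$tissue %||% "tissue")
    db <- filter_models(db, r2_min = params$r2_min %||% 0.01)
    state$db <- db
    write_model_db(db, file.path(out_dir, "models"))
  } else if (st == "predict") {
    gt <- if (!is.null(params$genotypes_path)) read_genotypes(params$genotypes_path)
          else {
            co <- get_cohort(state, NULL, seed)
            ids <- state$split$target_ids %||% co$genotypes$individual_ids
            subset_genotypes(co$genotypes, individuals = ids)
          }
    db <- state$db %||% read_model_db(params$models_path %||% file.path(out_dir, "models"))
    pred <- predict_expression(gt, db)
    state$pred <- pred; state$target_gt <- gt
    write_expression_tsv(pred, file.path(out_dir, "predicted_expression.tsv"))
  } else if (st == "assoc") {
    gt <- state$target_gt %||% read_genotypes(params$genotypes_path)
    pred <- state$pred %||% read_expression_tsv(
      params$predicted_path %||% file.path(out_dir, "predicted_expression.tsv"),
      stage = "predicted")
    pheno <- read_phenotypes(params$pheno_path)
    trait <- params$trait %||% setdiff(names(pheno), "individual_id")[1]
    al <- align_cohorts(gt, pheno)
    grm <- compute_grm(al$genotypes)
    idx <- match(al$genotypes$individual_ids, pred$sample_ids)
    if (anyNA(idx)) abort("predicted expression lacks some phenotype individuals")
    pred <- expression_set(pred$values[idx, , drop = FALSE],
                           al$genotypes$individual_ids, pred$gene_ids,
                           stage = "predicted")
    fit <- estimate_h2(al$table, grm, trait = trait)
    res <- ratxcan_associate(al$table, pred, grm, fit, trait = trait,
                             tissue = params$tissue %||% "tissue")
    write_association_tsv(res, file.path(out_dir, "association.tsv"))
  } else if (st == "calibrate") {
    co <- get_cohort(state, params, seed)
    db <- state$db %||% read_model_db(params$models_path %||% file.path(out_dir, "models"))
    target_ids <- state$split$target_ids %||% NULL
    rep_ <- calibration_study(
      co, db, target_ids = target_ids,
      h2_grid = params$h2_grid %||% c(0.1, 0.2, 0.4, 0.6, 0.8),
      n_reps = params$n_reps %||% 100,
      thresholds = params$thresholds %||% c(1e-6, 0.01, 0.05, 0.10),
      null_mode = params$null_mode %||% "matrix_sqrt", seed = seed
    )
    write.table(as.data.frame(rep_), file.path(out_dir, "calibration_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    pv <- attr(rep_, "pvalues")
    qq <- purrr::map_dfr(names(pv), function(nm) {
      q <- qq_data(pv[[nm]])
      q$cell <- nm
      q
    })
    write.table(as.data.frame(qq), file.path(out_dir, "calibration_qq.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (st == "enrich") {
    ra <- read.delim(params$results_a_path, stringsAsFactors = FALSE)
    rb <- read.delim(params$results_b_path, stringsAsFactors = FALSE)
    map <- load_ortholog_map(params$map_path)
    enr <- enrichment_fisher(ra, rb, map,
                             alpha_a = params$alpha_a %||% NULL,
                             alpha_b = params$alpha_b %||% 0.05)
    jsonlite::write_json(as.list(enr), file.path(out_dir, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
    qq <- enrichment_qq(ra, rb, map, alpha_a = params$alpha_a %||% NULL)
    write.table(as.data.frame(qq$background),
                file.path(out_dir, "enrichment_qq_background.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(qq$subset),
                file.path(out_dir, "enrichment_qq_subset.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
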