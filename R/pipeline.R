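# End-to-end orchestration: simulate -> deg -> overlap -> train ->
# validate -> predict -> delta, driven by a single config whose root seed
# is split deterministically per stage. Every output file carries a
# provenance header (config hash + seed); stages communicate through the
# artifact tree so each is runnable alone.

STAGES <- c("simulate", "deg", "overlap", "train", "validate", "predict",
            "delta")

# per-stage seed offsets, so stages are independent but all flow from the
# root seed
STAGE_SEED_OFFSET <- c(simulate = 0L, deg = 0L, overlap = 0L,
                       train = 1000L, validate = 2000L, predict = 0L,
                       delta = 0L)

#' Build a pipeline configuration
#'
#' @param out_dir artifact directory.
#' @param matrix_path,metadata_path input files; when `NULL` the
#'   `simulate` stage's outputs are used.
#' @param fdr_cutoff,fc_cutoff regulated-gene thresholds.
#' @param excluded_genes gene ids excluded from the entire analysis
#'   (e.g. a gene knocked out in some underlying studies).
#' @param exposure_group treated arm contrasted against sham (default
#'   `"cs"`).
#' @param clock list of clock settings: `k`, `n_lambda`, `min_ratio`,
#'   `missing_policy`, `missing_threshold`.
#' @param cv list of validation settings: `runs`, `train_frac`.
#' @param simulation a [sim_config()], or `"paper_like"` for the preset.
#' @param seed root seed; each stage derives its own from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "txclock_out",
                            matrix_path = NULL, metadata_path = NULL,
                            fdr_cutoff = 0.05, fc_cutoff = log2(1.5),
                            excluded_genes = character(0),
                            exposure_group = "cs",
                            clock = list(),
                            cv = list(),
                            simulation = "paper_like",
                            seed = 1L) {
  clock <- modifyList(list(k = 5, n_lambda = 100, min_ratio = 0.001,
                           missing_policy = "impute_training_mean",
                           missing_threshold = 0.2), clock)
  cv <- modifyList(list(runs = 100, train_frac = 0.75), cv)
  structure(list(out_dir = out_dir, matrix_path = matrix_path,
                 metadata_path = metadata_path, fdr_cutoff = fdr_cutoff,
                 fc_cutoff = fc_cutoff,
                 excluded_genes = excluded_genes,
                 exposure_group = exposure_group, clock = clock, cv = cv,
                 simulation = simulation, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#' @param path config file (`.json`, or `.yml`/`.yaml` when the yaml
#'   package is available).
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required to read ", path)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$simulation) && is.list(raw$simulation)) {
    raw$simulation <- do.call(sim_config, raw$simulation)
  }
  do.call(pipeline_config, raw)
}

# hash of the scientific settings only: filesystem locations do not
# change results, so they are excluded and identical analyses hash alike
config_hash <- function(config) {
  cfg <- unclass_deep(config)
  cfg$out_dir <- NULL
  cfg$matrix_path <- NULL
  cfg$metadata_path <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

provenance <- function(config, stage) {
  sprintf("txclock stage=%s seed=%d config_hash=%s", stage,
          config$seed + STAGE_SEED_OFFSET[[stage]], config_hash(config))
}

write_tsv_artifact <- function(df, path, header) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

need_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing artifact '", path, "'; run the '", producer,
         "' stage first", call. = FALSE)
  }
  path
}

pipeline_inputs <- function(config) {
  sim_dir <- file.path(config$out_dir, "simulate")
  mpath <- config$matrix_path %||% file.path(sim_dir, "expression.tsv")
  dpath <- config$metadata_path %||% file.path(sim_dir, "metadata.csv")
  need_artifact(mpath, "simulate")
  need_artifact(dpath, "simulate")
  list(matrix = read_expression_matrix(mpath), metadata = read_metadata(dpath))
}

#' Run the analysis pipeline
#'
#' Stages: `simulate` (synthetic dataset + truth), `deg` (age and
#' exposure contrasts, regulated gene sets), `overlap` (Venn, signed
#' maximum fold change, PC1 loadings), `train` (clock on sham samples),
#' `validate` (random-holdout + leave-one-study-out CV), `predict`
#' (all samples through the trained clock), `delta` (per-group residual
#' summaries and tests). `stages = "all"` chains everything. Identical
#' configs (including seed) produce byte-identical artifacts.
#'
#' @param config a [pipeline_config()] or path to a JSON/YAML config.
#' @param stages character vector of stage names, or `"all"`.
#' @return invisibly, a named list of artifact paths (attribute
#'   `results` holds the in-memory stage outputs).
#' @export
run_pipeline <- function(config, stages = "all") {
  if (is.character(config) && length(config) == 1) {
    config <- read_pipeline_config(config)
  }
  if (identical(stages, "all")) stages <- STAGES
  bad <- setdiff(stages, STAGES)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass_deep(config),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  artifacts <- c(config = file.path(config$out_dir, "config.json"))
  results <- list()
  log_lines <- c(provenance(config, stages[1]))

  for (stage in stages) {
    fn <- get(paste0("stage_", stage), mode = "function")
    out <- fn(config)
    artifacts <- c(artifacts, out$artifacts)
    results[[stage]] <- out$results
    log_lines <- c(log_lines, out$log)
  }
  writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))
  invisible(structure(artifacts, results = results))
}

stage_simulate <- function(config) {
  dir <- file.path(config$out_dir, "simulate")
  sim <- config$simulation
  if (identical(sim, "paper_like")) {
    cfg <- paper_like_config(seed = config$seed)
  } else if (inherits(sim, "sim_config")) {
    cfg <- sim
    cfg$seed <- config$seed
  } else {
    stop("simulation must be 'paper_like' or a sim_config")
  }
  ds <- generate_dataset(cfg)
  paths <- write_dataset(ds, dir, header_comment = provenance(config, "simulate"))
  list(artifacts = paths, results = ds,
       log = sprintf("simulate: %d genes x %d samples (%d sham)",
                     nrow(ds$matrix), ncol(ds$matrix),
                     sum(ds$metadata$exposure_group == "sham")))
}

stage_deg <- function(config) {
  dir <- file.path(config$out_dir, "deg")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inp <- pipeline_inputs(config)
  hdr <- provenance(config, "deg")
  age_specs <- build_age_contrasts(inp$metadata)
  exp_specs <- build_exposure_contrasts(inp$metadata, config$exposure_group)
  age_res <- run_contrasts(inp$matrix, age_specs)
  exp_res <- run_contrasts(inp$matrix, exp_specs)
  age_set <- identify_regulated(age_res, config$fc_cutoff, config$fdr_cutoff,
                                config$excluded_genes)
  exp_set <- identify_regulated(exp_res, config$fc_cutoff, config$fdr_cutoff,
                                config$excluded_genes)
  arts <- c(
    age_contrasts = write_tsv_artifact(age_res,
      file.path(dir, "age_contrasts.tsv"), hdr),
    exposure_contrasts = write_tsv_artifact(exp_res,
      file.path(dir, "exposure_contrasts.tsv"), hdr),
    age_regulated = write_tsv_artifact(
      data.frame(gene_id = age_set$gene_ids),
      file.path(dir, "age_regulated_genes.tsv"), hdr),
    exposure_regulated = write_tsv_artifact(
      data.frame(gene_id = exp_set$gene_ids),
      file.path(dir, "exposure_regulated_genes.tsv"), hdr))
  list(artifacts = arts,
       results = list(age_results = age_res, exposure_results = exp_res,
                      age_set = age_set, exposure_set = exp_set),
       log = sprintf("deg: %d age contrasts -> %d genes; %d exposure contrasts -> %d genes",
                     length(age_specs), length(age_set$gene_ids),
                     length(exp_specs), length(exp_set$gene_ids)))
}

stage_overlap <- function(config) {
  dir <- file.path(config$out_dir, "overlap")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance(config, "overlap")
  deg_dir <- file.path(config$out_dir, "deg")
  age_res <- read_contrast_tsv(need_artifact(
    file.path(deg_dir, "age_contrasts.tsv"), "deg"))
  exp_res <- read_contrast_tsv(need_artifact(
    file.path(deg_dir, "exposure_contrasts.tsv"), "deg"))
  age_set <- identify_regulated(age_res, config$fc_cutoff, config$fdr_cutoff,
                                config$excluded_genes)
  exp_set <- identify_regulated(exp_res, config$fc_cutoff, config$fdr_cutoff,
                                config$excluded_genes)
  venn <- venn_overlap(age_set, exp_set)
  prof_age <- fold_change_profile(age_res, "age")
  prof_exp <- fold_change_profile(exp_res, "exposure")
  mfc <- data.frame(gene_id = rownames(prof_age$values),
                    mfc_age = unname(signed_max_fold_change(prof_age)),
                    mfc_exposure = unname(
                      signed_max_fold_change(prof_exp)[rownames(prof_age$values)]))
  pc_age <- pc1_loadings(prof_age)
  pc_exp <- pc1_loadings(prof_exp)
  cmp <- compare_loadings(pc_age, pc_exp)
  arts <- c(
    venn = write_tsv_artifact(as.data.frame(venn),
      file.path(dir, "venn.tsv"), hdr),
    mfc = write_tsv_artifact(mfc, file.path(dir, "mfc.tsv"), hdr),
    pc1 = write_tsv_artifact(
      data.frame(gene_id = cmp$table$gene_id,
                 loading_age = cmp$table$loading_a,
                 loading_exposure = cmp$table$loading_b),
      file.path(dir, "pc1_loadings.tsv"), hdr),
    pc1_summary = write_tsv_artifact(
      data.frame(inertia_age = pc_age$inertia,
                 inertia_exposure = pc_exp$inertia,
                 loading_correlation = cmp$r, p_value = cmp$p_value),
      file.path(dir, "pc1_summary.tsv"), hdr))
  list(artifacts = arts,
       results = list(venn = venn, mfc = mfc, pc1_age = pc_age,
                      pc1_exposure = pc_exp, loading_comparison = cmp),
       log = sprintf("overlap: %.1f%% of age set exposure-regulated; PC1 r = %.3f",
                     venn$percent_a_in_b, cmp$r))
}

read_contrast_tsv <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

stage_train <- function(config) {
  dir <- file.path(config$out_dir, "train")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance(config, "train")
  inp <- pipeline_inputs(config)
  sham <- inp$metadata[inp$metadata$exposure_group == "sham", ]
  model <- fit_clock(inp$matrix, sham,
                     excluded_genes = config$excluded_genes,
                     k = config$clock$k, seed = config$seed + 1000L,
                     n_lambda = config$clock$n_lambda,
                     min_ratio = config$clock$min_ratio)
  mpath <- file.path(dir, "model.json")
  save_model(model, mpath)
  coefs <- data.frame(gene_id = names(model$coefficients),
                      coefficient_months_per_log2 = unname(model$coefficients))
  coefs <- coefs[order(-abs(coefs$coefficient_months_per_log2)), ]
  arts <- c(model = mpath,
            coefficients = write_tsv_artifact(coefs,
              file.path(dir, "predictor_genes.tsv"), hdr))
  list(artifacts = arts, results = model,
       log = sprintf("train: %d predictor genes, lambda %.4g, %d sham samples",
                     length(model$coefficients), model$lambda_selected,
                     model$training_sample_count))
}

stage_validate <- function(config) {
  dir <- file.path(config$out_dir, "validate")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance(config, "validate")
  inp <- pipeline_inputs(config)
  hold <- random_holdout_cv(inp$matrix, inp$metadata,
                            runs = config$cv$runs,
                            train_frac = config$cv$train_frac,
                            seed = config$seed + 2000L,
                            k = config$clock$k,
                            n_lambda = config$clock$n_lambda,
                            min_ratio = config$clock$min_ratio)
  loso <- leave_one_study_out_cv(inp$matrix, inp$metadata,
                                 seed = config$seed + 2000L,
                                 k = config$clock$k,
                                 n_lambda = config$clock$n_lambda,
                                 min_ratio = config$clock$min_ratio)
  arts <- c(
    holdout = write_tsv_artifact(hold$runs,
      file.path(dir, "holdout_cv.tsv"), hdr),
    loso = write_tsv_artifact(loso$runs,
      file.path(dir, "loso_cv.tsv"), hdr),
    summary = write_tsv_artifact(
      data.frame(scheme = c("random_holdout", "leave_one_study_out"),
                 pooled_validation_mae = c(hold$pooled_mae, loso$pooled_mae)),
      file.path(dir, "cv_summary.tsv"), hdr))
  list(artifacts = arts, results = list(holdout = hold, loso = loso),
       log = sprintf("validate: holdout MAE %.3f, LOSO MAE %.3f months",
                     hold$pooled_mae, loso$pooled_mae))
}

stage_predict <- function(config) {
  dir <- file.path(config$out_dir, "predict")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance(config, "predict")
  inp <- pipeline_inputs(config)
  model <- load_model(need_artifact(
    file.path(config$out_dir, "train", "model.json"), "train"))
  preds <- predict_age(model, inp$matrix, inp$metadata,
                       missing_policy = config$clock$missing_policy,
                       missing_threshold = config$clock$missing_threshold)
  arts <- c(predictions = write_tsv_artifact(preds,
    file.path(dir, "predictions.tsv"), hdr))
  list(artifacts = arts, results = preds,
       log = sprintf("predict: %d samples", nrow(preds)))
}

stage_delta <- function(config) {
  dir <- file.path(config$out_dir, "delta")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance(config, "delta")
  inp <- pipeline_inputs(config)
  ppath <- need_artifact(
    file.path(config$out_dir, "predict", "predictions.tsv"), "predict")
  preds <- read_contrast_tsv(ppath)
  tab <- delta_age_table(preds, inp$metadata)
  inference <- group_inference(tab$deltas, reference_group = "sham")
  arts <- c(
    by_group = write_tsv_artifact(tab$by_group,
      file.path(dir, "delta_by_group.tsv"), hdr),
    by_timepoint = write_tsv_artifact(tab$by_timepoint,
      file.path(dir, "delta_by_timepoint.tsv"), hdr),
    tests = write_tsv_artifact(inference$comparisons,
      file.path(dir, "group_tests.tsv"), hdr),
    anova = write_tsv_artifact(as.data.frame(inference$anova),
      file.path(dir, "anova.tsv"), hdr))
  list(artifacts = arts,
       results = list(table = tab, inference = inference),
       log = sprintf("delta: ANOVA F = %.2f, p = %.3g",
                     inference$anova$F, inference$anova$p))
}
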