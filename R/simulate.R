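# Multi-study expression simulator with planted ground truth.
#
# Generative model, per gene g and sample s:
#
#   x_gs = b_g + m_g * f(effective_age_s)        (age-trending genes)
#        + step_g * e_s                           (exposure-only genes)
#        + u_{g, study(s)} + eps_gs,  eps ~ N(0, sigma^2)
#
# effective_age_s = age_s + Delta_s, where Delta_s is the planted aging
# acceleration: Delta for continuously smoke-exposed samples, 0 for sham,
# a configurable fraction for heated-tobacco arms, and an exponentially
# decaying value after the switch time for cessation/switch arms.
#
# Exposure genes drawn from the age-gene set (the overlap fraction) carry
# no separate step effect: their exposure response IS the effective-age
# shift Delta * m_g along their own slope, with slopes drawn from a higher
# range so that shift clears a typical fold-change cutoff. This makes
# "recovered group mean delta age ~ Delta" an exact target for the clock,
# and mirrors the empirical pattern that the genes most up-regulated with
# age are also the most exposure-responsive.

#' Simulation configuration
#'
#' @param n_genes total genes in the universe.
#' @param n_age_genes genes with an age trend.
#' @param n_exposure_genes exposure-responsive genes; a fraction
#'   `overlap_fraction` of them is drawn from the age genes.
#' @param overlap_fraction fraction of exposure genes that are also age
#'   genes, in `[0, 1]`.
#' @param slope_range absolute slope range (log2 units per month) for
#'   age-only genes; signs are random.
#' @param overlap_slope_range absolute slope range for age genes that are
#'   also exposure genes (higher, so the acceleration shift
#'   `exposure_shift_months * |slope|` is detectable as a fold change).
#' @param exposure_step_range absolute step-effect range (log2 units) for
#'   exposure-only genes; signs are random.
#' @param exposure_shift_months planted acceleration Delta: months of
#'   extra effective age for continuously smoke-exposed samples.
#' @param study_designs list of study descriptions; each a list with
#'   `study_id` and `design`, a data.frame with columns `arm` (exposure
#'   group label), `timepoint` (months of exposure) and `n` (samples).
#' @param batch_sd sd of per-gene, per-study batch offsets (log2 units).
#' @param noise_sd residual sd sigma (log2 units).
#' @param baseline_age_months age at the start of exposure (months).
#' @param trend_shape `"linear"` (f(a) = a) or `"saturating"`
#'   (f(a) = tau * (1 - exp(-a / tau))).
#' @param saturating_tau time scale tau of the saturating trend, months.
#' @param htp_delta_scale fraction of Delta applied to heated-tobacco
#'   arms (default 0: no acceleration, matching their near-sham behavior).
#' @param htp_step_scale fraction of the step effect applied to
#'   heated-tobacco arms (weak direct response).
#' @param switch_month exposure month at which cessation/switch arms stop
#'   smoke exposure.
#' @param decay_half_life half-life (months) of the exponential decay of
#'   Delta after the switch.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline
#'   log2 expression.
#' @param seed integer; every random draw flows from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_age_genes = 300,
                       n_exposure_genes = 300,
                       overlap_fraction = 0.6,
                       slope_range = c(0.1, 0.15),
                       overlap_slope_range = c(0.35, 0.6),
                       exposure_step_range = c(0.8, 1.5),
                       exposure_shift_months = 2,
                       study_designs = default_study_designs(),
                       batch_sd = 0.3,
                       noise_sd = 0.25,
                       baseline_age_months = 2,
                       trend_shape = c("linear", "saturating"),
                       saturating_tau = 6,
                       htp_delta_scale = 0,
                       htp_step_scale = 0.15,
                       switch_month = 2,
                       decay_half_life = 1,
                       baseline_mean = 7,
                       baseline_sd = 1.5,
                       seed = 1L) {
  trend_shape <- match.arg(trend_shape)
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  n_overlap <- round(cfg$overlap_fraction * cfg$n_exposure_genes)
  if (cfg$overlap_fraction < 0 || cfg$overlap_fraction > 1) {
    stop("overlap_fraction must be in [0, 1]")
  }
  if (n_overlap > cfg$n_age_genes) {
    stop("infeasible gene counts: overlap genes (", n_overlap,
         ") exceed age genes (", cfg$n_age_genes, ")")
  }
  needed <- cfg$n_age_genes + cfg$n_exposure_genes - n_overlap
  if (needed > cfg$n_genes) {
    stop("infeasible gene counts: ", needed, " signal genes > ",
         cfg$n_genes, " total genes")
  }
  if (cfg$batch_sd < 0 || cfg$noise_sd < 0) stop("sds must be >= 0")
  if (cfg$exposure_shift_months < 0) stop("exposure_shift_months must be >= 0")
  if (cfg$baseline_age_months <= 0) stop("baseline_age_months must be > 0")
  for (sd_ in cfg$study_designs) {
    if (is.null(sd_$study_id) || is.null(sd_$design)) {
      stop("each study design needs study_id and design")
    }
    if (!all(c("arm", "timepoint", "n") %in% names(sd_$design))) {
      stop("study design table needs columns arm, timepoint, n")
    }
    bad <- setdiff(unique(sd_$design$arm), EXPOSURE_GROUPS)
    if (length(bad) > 0) stop("unknown arm(s): ", paste(bad, collapse = ", "))
  }
  invisible(cfg)
}

# single two-arm study, used as a minimal default
default_study_designs <- function() {
  list(list(
    study_id = "study1",
    design = expand.grid(arm = c("sham", "cs"),
                         timepoint = c(1, 4, 8), n = 8,
                         stringsAsFactors = FALSE)
  ))
}

trend_fun <- function(cfg) {
  if (cfg$trend_shape == "linear") {
    function(a) a
  } else {
    tau <- cfg$saturating_tau
    function(a) tau * (1 - exp(-a / tau))
  }
}

# planted acceleration (months of extra effective age) for one sample
delta_for_sample <- function(arm, timepoint, cfg) {
  D <- cfg$exposure_shift_months
  switch(arm,
    sham = 0,
    other = 0,
    cs = D,
    htp = D * cfg$htp_delta_scale,
    cessation = ,
    switch = {
      if (timepoint <= cfg$switch_month) D
      else D * 2^(-(timepoint - cfg$switch_month) / cfg$decay_half_life)
    })
}

# direct step-effect multiplier for exposure-only genes
step_scale_for_sample <- function(arm, timepoint, cfg) {
  switch(arm,
    sham = 0,
    other = 0,
    cs = 1,
    htp = cfg$htp_step_scale,
    cessation = ,
    switch = {
      if (timepoint <= cfg$switch_month) 1
      else 2^(-(timepoint - cfg$switch_month) / cfg$decay_half_life)
    })
}

#' Generate a simulated multi-study dataset with known ground truth
#'
#' Deterministic given `config$seed`: the same config always yields
#' bit-identical output.
#'
#' @param config a [sim_config()].
#' @return list with elements `matrix` (genes x samples, log2),
#'   `metadata` (one row per sample) and `truth` (planted parameters:
#'   age gene ids and slopes, exposure gene ids and effects, overlap gene
#'   ids, per-sample effective ages and deltas, batch offsets).
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  # --- sample sheet (no RNG) ---
  rows <- list()
  for (st in config$study_designs) {
    d <- st$design
    for (i in seq_len(nrow(d))) {
      if (d$n[i] < 1) next
      rows[[length(rows) + 1]] <- data.frame(
        study_id = st$study_id,
        exposure_group = d$arm[i],
        exposure_months = d$timepoint[i],
        replicate = seq_len(d$n[i]),
        stringsAsFactors = FALSE)
    }
  }
  md <- do.call(rbind, rows)
  md$sample_id <- sprintf("%s_%s_%gm_r%d", md$study_id, md$exposure_group,
                          md$exposure_months, md$replicate)
  md$age_months <- config$baseline_age_months + md$exposure_months
  md$replicate <- NULL
  md <- md[, c("sample_id", "study_id", "age_months", "exposure_group",
               "exposure_months")]
  validate_metadata(md)
  n_s <- nrow(md)
  study_ids <- vapply(config$study_designs, `[[`, "", "study_id")

  # --- gene roles ---
  n_g <- config$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n_g))
  n_overlap <- round(config$overlap_fraction * config$n_exposure_genes)
  n_step <- config$n_exposure_genes - n_overlap
  age_idx <- sort(sample.int(n_g, config$n_age_genes))
  overlap_idx <- sort(sample(age_idx, n_overlap))
  step_idx <- sort(sample(setdiff(seq_len(n_g), age_idx), n_step))

  rsign <- function(n) sample(c(-1, 1), n, replace = TRUE)
  runif_in <- function(n, rng) runif(n, rng[1], rng[2])
  slopes <- setNames(numeric(config$n_age_genes), gene_ids[age_idx])
  is_ov <- age_idx %in% overlap_idx
  slopes[!is_ov] <- rsign(sum(!is_ov)) *
    runif_in(sum(!is_ov), config$slope_range)
  slopes[is_ov] <- rsign(sum(is_ov)) *
    runif_in(sum(is_ov), config$overlap_slope_range)
  steps <- setNames(
    rsign(n_step) * runif_in(n_step, config$exposure_step_range),
    gene_ids[step_idx])

  baselines <- rnorm(n_g, config$baseline_mean, config$baseline_sd)
  batch <- matrix(rnorm(n_g * length(study_ids), 0, config$batch_sd),
                  nrow = n_g, dimnames = list(gene_ids, study_ids))

  # --- per-sample planted effects ---
  deltas <- mapply(delta_for_sample, as.character(md$exposure_group),
                   md$exposure_months, MoreArgs = list(cfg = config))
  step_scales <- mapply(step_scale_for_sample,
                        as.character(md$exposure_group),
                        md$exposure_months, MoreArgs = list(cfg = config))
  effective_age <- md$age_months + deltas
  f <- trend_fun(config)

  # --- assemble matrix ---
  x <- matrix(baselines, nrow = n_g, ncol = n_s,
              dimnames = list(gene_ids, md$sample_id))
  x[age_idx, ] <- x[age_idx, ] + slopes %o% f(effective_age)
  if (n_step > 0) x[step_idx, ] <- x[step_idx, ] + steps %o% step_scales
  x <- x + batch[, md$study_id, drop = FALSE]
  if (config$noise_sd > 0) {
    x <- x + matrix(rnorm(n_g * n_s, 0, config$noise_sd), nrow = n_g)
  }

  truth <- list(
    age_gene_ids = gene_ids[age_idx],
    age_slopes = slopes,
    exposure_gene_ids = gene_ids[sort(c(overlap_idx, step_idx))],
    overlap_gene_ids = gene_ids[overlap_idx],
    exposure_steps = steps,
    effective_age_months = setNames(effective_age, md$sample_id),
    delta_months = setNames(deltas, md$sample_id),
    batch_offsets = batch,
    config_seed = config$seed
  )
  list(matrix = x, metadata = md, truth = truth)
}

#' Paper-like three-study preset
#'
#' Emits a dataset shaped like the three murine inhalation studies the
#' package's analysis design targets: 3 studies of female mice, all aged
#' 2 months at exposure start; arms sham / cigarette smoke (cs) / heated
#' tobacco (htp) / cessation / switch; dissection time points spanning
#' 1-8 months of exposure; exactly 111 sham samples overall. Within-study
#' sham time-point pairs give 28 age contrasts and smoke-vs-sham pairs
#' give 14 exposure contrasts.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [sim_config()] (e.g. `noise_sd`,
#'   `exposure_shift_months`).
#' @return list(matrix, metadata, truth) as in [generate_dataset()].
#' @export
scenario_paper_like <- function(seed = 1L, ...) {
  generate_dataset(paper_like_config(seed = seed, ...))
}

#' Configuration of the paper-like preset
#' @inheritParams scenario_paper_like
#' @return a [sim_config()].
#' @export
paper_like_config <- function(seed = 1L, ...) {
  grid <- function(arms, tps, n) {
    expand.grid(arm = arms, timepoint = tps, n = n,
                stringsAsFactors = FALSE)
  }
  s1 <- rbind(grid(c("sham", "cs"), c(1, 2, 3, 4, 6, 8), 8),
              grid(c("cessation", "switch"), c(3, 4, 6, 8), 8))
  s2 <- grid(c("sham", "cs", "htp"), c(1, 2, 4, 6, 8), 8)
  s3 <- grid(c("sham", "cs", "htp"), c(1, 4, 6), 8)
  s3$n[s3$arm == "sham" & s3$timepoint == 6] <- 7  # 48 + 40 + 23 = 111 sham
  designs <- list(list(study_id = "study1", design = s1),
                  list(study_id = "study2", design = s2),
                  list(study_id = "study3", design = s3))
  args <- modifyList(
    list(study_designs = designs, overlap_fraction = 0.62, seed = seed),
    list(...))
  do.call(sim_config, args)
}

#' Write a simulated dataset to an output directory
#'
#' Writes the standard TSV/CSV formats plus a ground-truth JSON.
#'
#' @param dataset list(matrix, metadata, truth).
#' @param dir output directory (created if needed).
#' @param header_comment optional provenance line for the TSV/CSV headers.
#' @return named character vector of file paths.
#' @export
write_dataset <- function(dataset, dir, header_comment = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "metadata.csv"),
             truth = file.path(dir, "truth.json"))
  write_expression_matrix(dataset$matrix, paths["matrix"],
                          header_comment = header_comment)
  write_metadata(dataset$metadata, paths["metadata"],
                 header_comment = header_comment)
  tr <- dataset$truth
  tr$batch_offsets <- NULL  # bulky; regenerate from seed when needed
  jsonlite::write_json(
    lapply(tr, function(v) if (is.null(names(v))) v else as.list(v)),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  paths
}
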