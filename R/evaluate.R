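# Cross-validation designs for the clock, and delta-age group inference.
#
# Delta age = predicted minus chronological age (months); positive values
# indicate premature transcriptomic aging. Group inference uses Welch
# two-sample t-tests of each group against the reference (sham) plus a
# classical one-way ANOVA across all groups; per-comparison significance
# stars are reported without multiplicity correction (each comparison
# stands alone, as in the figures this mirrors).

#' Mean absolute error
#' @param predicted,actual equal-length numeric vectors (months).
#' @return mean of absolute residuals.
#' @export
mae <- function(predicted, actual) {
  if (length(predicted) != length(actual) || length(predicted) == 0) {
    stop("predicted and actual must be equal nonzero length")
  }
  mean(abs(predicted - actual))
}

#' Random-holdout cross-validation of the clock
#'
#' Repeats, `runs` times: split the (sham) samples into training and
#' validation fractions stratified by study, fit the clock on the
#' training part, record MAE on both parts. Deterministic given `seed`
#' (run r uses derived seed `seed + r`). Runs whose training part has
#' fewer than 2 distinct ages are skipped with a warning and recorded.
#'
#' @param matrix expression matrix.
#' @param metadata metadata of the samples to use (typically sham only;
#'   rows are filtered to `groups`).
#' @param runs number of repetitions (default 100).
#' @param train_frac training fraction in (0, 1) (default 0.75).
#' @param seed integer root seed.
#' @param groups exposure groups retained (default `"sham"`).
#' @param ... passed to [fit_clock()] (e.g. `n_lambda`, `k`).
#' @return object of class `cv_report`: `scheme`, `runs` (per-run
#'   data.frame with seeds, sizes, train/validation MAE, skipped flag),
#'   `pooled_mae` (mean of per-run validation MAEs), `seed`.
#' @export
random_holdout_cv <- function(matrix, metadata, runs = 100,
                              train_frac = 0.75, seed = 1L,
                              groups = "sham", ...) {
  validate_metadata(metadata)
  md <- metadata[metadata$exposure_group %in% groups, ]
  if (nrow(md) < 8) stop("need >= 8 samples for holdout CV")
  if (!is.finite(train_frac) || train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must be strictly inside (0, 1)")
  }
  per_study <- split(seq_len(nrow(md)), md$study_id)
  if (any(vapply(per_study, function(i) floor(length(i) * train_frac),
                 0) < 1)) {
    stop("train_frac leaves a study without training samples")
  }
  rows <- vector("list", runs)
  for (r in seq_len(runs)) {
    run_seed <- seed + r
    tr_idx <- with_seed(run_seed, {
      unlist(lapply(per_study, function(i) {
        sample(i, floor(length(i) * train_frac))
      }), use.names = FALSE)
    })
    va_idx <- setdiff(seq_len(nrow(md)), tr_idx)
    if (length(va_idx) == 0) stop("empty validation set (train_frac too high)")
    md_tr <- md[tr_idx, ]
    md_va <- md[va_idx, ]
    if (length(unique(md_tr$age_months)) < 2) {
      warning("run ", r, " skipped: < 2 distinct training ages")
      rows[[r]] <- data.frame(run = r, seed = run_seed,
                              n_train = nrow(md_tr), n_val = nrow(md_va),
                              mae_train = NA_real_, mae_val = NA_real_,
                              skipped = TRUE)
      next
    }
    model <- fit_clock(matrix, md_tr, seed = run_seed, ...)
    pr_tr <- predict_age(model, matrix[, md_tr$sample_id, drop = FALSE], md_tr)
    pr_va <- predict_age(model, matrix[, md_va$sample_id, drop = FALSE], md_va)
    rows[[r]] <- data.frame(
      run = r, seed = run_seed,
      n_train = nrow(md_tr), n_val = nrow(md_va),
      mae_train = mae(pr_tr$predicted_age_months, pr_tr$chronological_age_months),
      mae_val = mae(pr_va$predicted_age_months, pr_va$chronological_age_months),
      skipped = FALSE)
  }
  runs_df <- do.call(rbind, rows)
  structure(list(scheme = "random_holdout",
                 runs = runs_df,
                 pooled_mae = mean(runs_df$mae_val[!runs_df$skipped]),
                 per_study = NULL,
                 seed = seed),
            class = "cv_report")
}

#' Leave-one-study-out cross-validation of the clock
#'
#' One round per study: the clock is trained on all other studies and
#' validated on the held-out one. Captures cross-batch generalization:
#' with per-study batch shifts, LOSO error is expected to exceed the
#' random-holdout error on the same data.
#'
#' @param matrix expression matrix.
#' @param metadata metadata (filtered to `groups`).
#' @param seed integer seed (round for study i uses `seed + i`).
#' @param groups exposure groups retained (default `"sham"`).
#' @param ... passed to [fit_clock()].
#' @return `cv_report` with `per_study` validation MAEs; `pooled_mae` is
#'   the mean of per-round validation MAEs.
#' @export
leave_one_study_out_cv <- function(matrix, metadata, seed = 1L,
                                   groups = "sham", ...) {
  validate_metadata(metadata)
  md <- metadata[metadata$exposure_group %in% groups, ]
  studies <- sort(unique(md$study_id))
  if (length(studies) < 2) stop("LOSO needs >= 2 studies")
  rows <- vector("list", length(studies))
  for (i in seq_along(studies)) {
    md_tr <- md[md$study_id != studies[i], ]
    md_va <- md[md$study_id == studies[i], ]
    model <- fit_clock(matrix, md_tr, seed = seed + i, ...)
    pr_tr <- predict_age(model, matrix[, md_tr$sample_id, drop = FALSE], md_tr)
    pr_va <- predict_age(model, matrix[, md_va$sample_id, drop = FALSE], md_va)
    rows[[i]] <- data.frame(
      run = i, seed = seed + i, study_id = studies[i],
      n_train = nrow(md_tr), n_val = nrow(md_va),
      mae_train = mae(pr_tr$predicted_age_months, pr_tr$chronological_age_months),
      mae_val = mae(pr_va$predicted_age_months, pr_va$chronological_age_months),
      skipped = FALSE)
  }
  runs_df <- do.call(rbind, rows)
  per_study <- setNames(runs_df$mae_val, runs_df$study_id)
  structure(list(scheme = "leave_one_study_out",
                 runs = runs_df,
                 pooled_mae = mean(runs_df$mae_val),
                 per_study = per_study,
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  ok <- !x$runs$skipped
  cat(sprintf("cv_report (%s): %d runs (%d skipped), pooled validation MAE %.3f months\n",
              x$scheme, nrow(x$runs), sum(!ok), x$pooled_mae))
  if (!is.null(x$per_study)) {
    for (s in names(x$per_study)) {
      cat(sprintf("  %s: MAE %.3f\n", s, x$per_study[s]))
    }
  }
  invisible(x)
}

#' Per-group delta-age summaries
#'
#' Pools residuals per exposure group (a per-time-point breakdown is
#' included as `by_timepoint`).
#'
#' @param predictions data.frame from [predict_age()] with chronological
#'   ages filled.
#' @param metadata sample metadata.
#' @param strict error on samples whose group is missing from metadata
#'   (default TRUE).
#' @return list: `by_group` (group, n, mean_delta, sd_delta),
#'   `by_timepoint` (group x exposure_months breakdown), `deltas` (named
#'   list of per-group delta vectors, for [group_inference()]).
#' @export
delta_age_table <- function(predictions, metadata, strict = TRUE) {
  if (anyNA(predictions$delta_age_months)) {
    stop("predictions lack chronological ages; run predict_age with metadata")
  }
  idx <- match(predictions$sample_id, metadata$sample_id)
  if (anyNA(idx)) {
    msg <- paste(head(predictions$sample_id[is.na(idx)], 5), collapse = ", ")
    if (strict) stop("samples missing from metadata: ", msg)
  }
  grp <- as.character(metadata$exposure_group[idx])
  tp <- metadata$exposure_months[idx]
  deltas <- split(predictions$delta_age_months, grp)
  by_group <- data.frame(
    exposure_group = names(deltas),
    n = vapply(deltas, length, 0L),
    mean_delta = vapply(deltas, mean, 0),
    sd_delta = vapply(deltas, sd, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  key <- paste(grp, tp, sep = "@")
  dt <- split(predictions$delta_age_months, key)
  parts <- strsplit(names(dt), "@", fixed = TRUE)
  by_tp <- data.frame(
    exposure_group = vapply(parts, `[`, "", 1),
    exposure_months = as.numeric(vapply(parts, `[`, "", 2)),
    n = vapply(dt, length, 0L),
    mean_delta = vapply(dt, mean, 0),
    sd_delta = vapply(dt, sd, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  by_tp <- by_tp[order(by_tp$exposure_group, by_tp$exposure_months), ]
  list(by_group = by_group, by_timepoint = by_tp, deltas = deltas)
}

#' Significance star code for a p-value
#'
#' `****` p<0.0001, `***` p<0.001, `**` p<0.01, `*` p<0.05, `.` p<0.1,
#' `ns` otherwise.
#' @param p p-value(s).
#' @return character vector of codes.
#' @export
star_code <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, 0.1, Inf),
      labels = c("****", "***", "**", "*", ".", "ns"),
      right = FALSE) |> as.character()
}

#' Delta-age group inference
#'
#' Welch two-sample t-test of each group's delta ages against the
#' reference group, plus a classical one-way ANOVA across all groups.
#'
#' @param deltas named list of numeric vectors (delta ages by group), as
#'   produced by [delta_age_table()]`$deltas`.
#' @param reference_group the control group (default `"sham"`).
#' @return object of class `group_comparison`: `groups` (per-group n,
#'   mean, sd), `comparisons` (group, t, df, p, star vs reference),
#'   `anova` (F, df1, df2, p, star).
#' @export
group_inference <- function(deltas, reference_group = "sham") {
  if (!reference_group %in% names(deltas)) {
    stop("reference group '", reference_group, "' absent")
  }
  if (length(deltas) < 2) stop("need >= 2 groups")
  if (any(vapply(deltas, length, 0L) < 2)) stop("every group needs n >= 2")
  ref <- deltas[[reference_group]]
  groups <- data.frame(
    exposure_group = names(deltas),
    n = vapply(deltas, length, 0L),
    mean_delta = vapply(deltas, mean, 0),
    sd_delta = vapply(deltas, sd, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  others <- setdiff(names(deltas), reference_group)
  comparisons <- do.call(rbind, lapply(others, function(g) {
    same <- isTRUE(all.equal(deltas[[g]], ref)) &&
      length(deltas[[g]]) == length(ref)
    if (same || (sd(deltas[[g]]) == 0 && sd(ref) == 0 &&
                 mean(deltas[[g]]) == mean(ref))) {
      # identical/degenerate pair: no evidence of a difference
      t_ <- 0; df_ <- length(ref) + length(deltas[[g]]) - 2; p_ <- 1
    } else {
      tt <- t.test(deltas[[g]], ref, var.equal = FALSE)
      t_ <- unname(tt$statistic); df_ <- unname(tt$parameter); p_ <- tt$p.value
    }
    data.frame(exposure_group = g, reference = reference_group,
               t = t_, df = df_, p = p_, star = star_code(p_),
               stringsAsFactors = FALSE)
  }))
  all_d <- unlist(deltas, use.names = FALSE)
  all_g <- factor(rep(names(deltas), vapply(deltas, length, 0L)))
  if (var(all_d) == 0) {
    anova_res <- list(F = 0, df1 = length(deltas) - 1,
                      df2 = length(all_d) - length(deltas), p = 1,
                      star = "ns")
  } else {
    fit <- aov(all_d ~ all_g)
    s <- summary(fit)[[1]]
    anova_res <- list(F = s[["F value"]][1],
                      df1 = s[["Df"]][1], df2 = s[["Df"]][2],
                      p = s[["Pr(>F)"]][1],
                      star = star_code(s[["Pr(>F)"]][1]))
  }
  structure(list(groups = groups, comparisons = comparisons,
                 anova = anova_res, reference_group = reference_group),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison vs '%s' (one-way ANOVA F = %.3f, p = %.3g %s)\n",
              x$reference_group, x$anova$F, x$anova$p, x$anova$star))
  for (i in seq_len(nrow(x$comparisons))) {
    cm <- x$comparisons[i, ]
    g <- x$groups[x$groups$exposure_group == cm$exposure_group, ]
    cat(sprintf("  %-10s mean delta %+.2f mo (n=%d): t = %+.2f, p = %.3g %s\n",
                cm$exposure_group, g$mean_delta, g$n, cm$t, cm$p, cm$star))
  }
  invisible(x)
}
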