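# Per-gene two-group contrasts with variance-moderated t statistics,
# Benjamini-Hochberg FDR, and the rules defining age- and
# exposure-regulated gene sets.
#
# Moderation follows the classic empirical-Bayes scheme: per-gene sample
# variances are assumed scaled-inverse-chi-square around a common prior
# (d0, s0^2), estimated by method of moments on the log variances; the
# moderated variance is the degrees-of-freedom-weighted average
# (d0 s0^2 + d_g s_g^2) / (d0 + d_g) and the t statistic gains d0 df.

#' Define a two-group contrast
#'
#' Orientation is fixed a-minus-b (oldest minus youngest for age
#' contrasts, treated minus control for exposure contrasts) and never
#' auto-detected.
#'
#' @param contrast_id character label.
#' @param group_a sample ids of the older / treated group.
#' @param group_b sample ids of the younger / control group.
#' @param kind `"age"` or `"exposure"`.
#' @return list of class `contrast_spec`.
#' @export
contrast_spec <- function(contrast_id, group_a, group_b,
                          kind = c("age", "exposure")) {
  kind <- match.arg(kind)
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each contrast group needs >= 2 samples (", contrast_id, ")")
  }
  if (length(intersect(group_a, group_b)) > 0) {
    stop("contrast groups must be disjoint (", contrast_id, ")")
  }
  structure(list(contrast_id = contrast_id,
                 group_a = as.character(group_a),
                 group_b = as.character(group_b),
                 kind = kind),
            class = "contrast_spec")
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_{j >= i} (p_(j) * n / j)`, capped at 1 and mapped back to
#' the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values, same order as input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  n <- length(p_values)
  ord <- order(p_values)
  q <- p_values[ord] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(ord)]
}

# Method-of-moments fit of the variance prior (d0, s0^2) from per-gene
# sample variances s2 with df residual degrees of freedom each.
estimate_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(d0 = 0, s0_sq = if (any(ok)) mean(s2[ok]) else 0))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e)
  excess <- evar - trigamma(df / 2)
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread beyond chi-square sampling noise: variances look
    # common, so the prior is the plain average variance
    d0 <- Inf
    s0_sq <- mean(s2[ok])
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Solve trigamma(y) = x for y > 0 by Newton iteration on 1/trigamma
# (monotone, nearly linear in 1/y), with asymptotic starts.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Per-gene two-group contrast test
#'
#' Computes, for every gene, `log2fc = mean_a - mean_b`, a pooled-variance
#' t statistic (optionally empirical-Bayes moderated), its p-value, and
#' BH-FDR across the contrast's genes. Genes with zero variance in both
#' groups (and a zero prior) get `t = 0, p = 1` so that set operations
#' stay total; the number of such genes is reported via a message.
#'
#' @param matrix expression matrix (genes x samples, log2).
#' @param spec a [contrast_spec()].
#' @param moderation `"eb"` (empirical-Bayes moderated t, default) or
#'   `"ordinary"` (pooled two-sample t).
#' @param d0,s0_sq optional prior overrides (mostly for testing limits);
#'   when `NULL` the prior is estimated from the data.
#' @return data.frame with columns `contrast_id`, `gene_id`, `log2fc`,
#'   `t_stat`, `p_value`, `fdr` (one row per gene).
#' @export
contrast_test <- function(matrix, spec, moderation = c("eb", "ordinary"),
                          d0 = NULL, s0_sq = NULL) {
  moderation <- match.arg(moderation)
  missing_s <- setdiff(c(spec$group_a, spec$group_b), colnames(matrix))
  if (length(missing_s) > 0) {
    stop("samples absent from matrix: ", paste(missing_s, collapse = ", "))
  }
  a <- matrix[, spec$group_a, drop = FALSE]
  b <- matrix[, spec$group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  fc <- rowMeans(a) - rowMeans(b)
  va <- rowSums((a - rowMeans(a))^2) / (na - 1)
  vb <- rowSums((b - rowMeans(b))^2) / (nb - 1)
  dg <- na + nb - 2
  s2 <- ((na - 1) * va + (nb - 1) * vb) / dg

  if (moderation == "eb") {
    if (is.null(d0) || is.null(s0_sq)) {
      prior <- estimate_variance_prior(s2, dg)
      if (is.null(d0)) d0 <- prior$d0
      if (is.null(s0_sq)) s0_sq <- prior$s0_sq
    }
    if (is.infinite(d0)) {
      s2_mod <- rep(s0_sq, length(s2))
      df_mod <- Inf
    } else {
      s2_mod <- (d0 * s0_sq + dg * s2) / (d0 + dg)
      df_mod <- dg + d0
    }
  } else {
    d0 <- 0; s0_sq <- 0
    s2_mod <- s2
    df_mod <- dg
  }

  se <- sqrt(s2_mod * (1 / na + 1 / nb))
  t_stat <- ifelse(se > 0, fc / se, 0)
  p <- ifelse(se > 0,
              if (is.infinite(df_mod)) 2 * pnorm(-abs(t_stat))
              else 2 * pt(-abs(t_stat), df_mod),
              1)
  n_flat <- sum(se == 0)
  if (n_flat > 0) {
    message(spec$contrast_id, ": ", n_flat,
            " zero-variance gene(s) set to t=0, p=1")
  }
  data.frame(contrast_id = spec$contrast_id,
             gene_id = rownames(matrix),
             log2fc = unname(fc),
             t_stat = unname(t_stat),
             p_value = unname(p),
             fdr = bh_adjust(unname(p)),
             stringsAsFactors = FALSE)
}

#' Enumerate within-study sham age contrasts
#'
#' For each study, every pair of sham time points is compared, oriented
#' oldest minus youngest. Pairs where either age group has fewer than 2
#' samples are dropped with a warning.
#'
#' @param metadata sample metadata.
#' @return list of [contrast_spec()] (kind `"age"`); empty with a warning
#'   if no study has two sham time points.
#' @export
build_age_contrasts <- function(metadata) {
  validate_metadata(metadata)
  sham <- metadata[metadata$exposure_group == "sham", ]
  specs <- list()
  for (st in unique(sham$study_id)) {
    ss <- sham[sham$study_id == st, ]
    tps <- sort(unique(ss$exposure_months))
    for (i in seq_along(tps)) {
      for (j in seq_along(tps)) {
        if (j <= i) next
        young <- ss$sample_id[ss$exposure_months == tps[i]]
        old <- ss$sample_id[ss$exposure_months == tps[j]]
        if (length(young) < 2 || length(old) < 2) {
          warning(sprintf("%s: sham %gm vs %gm skipped (group < 2)",
                          st, tps[j], tps[i]))
          next
        }
        id <- sprintf("%s_age_sham_%gm_vs_%gm", st, tps[j], tps[i])
        specs[[id]] <- contrast_spec(id, old, young, kind = "age")
      }
    }
  }
  if (length(specs) == 0) warning("no valid sham age contrasts found")
  unname(specs)
}

#' Enumerate exposure-vs-sham contrasts
#'
#' For each study and time point at which both the exposure arm and sham
#' are present, compares treated minus control.
#'
#' @param metadata sample metadata.
#' @param exposure_group arm to contrast against sham (default `"cs"`).
#' @return list of [contrast_spec()] (kind `"exposure"`).
#' @export
build_exposure_contrasts <- function(metadata, exposure_group = "cs") {
  validate_metadata(metadata)
  specs <- list()
  for (st in unique(metadata$study_id)) {
    ss <- metadata[metadata$study_id == st, ]
    tps <- sort(unique(ss$exposure_months[ss$exposure_group == exposure_group]))
    for (tp in tps) {
      trt <- ss$sample_id[ss$exposure_group == exposure_group &
                            ss$exposure_months == tp]
      ctl <- ss$sample_id[ss$exposure_group == "sham" &
                            ss$exposure_months == tp]
      if (length(trt) < 2 || length(ctl) < 2) next
      id <- sprintf("%s_%s_vs_sham_%gm", st, exposure_group, tp)
      specs[[id]] <- contrast_spec(id, trt, ctl, kind = "exposure")
    }
  }
  unname(specs)
}

#' Run a set of contrasts over one matrix
#'
#' @param matrix expression matrix.
#' @param specs list of [contrast_spec()].
#' @param ... passed to [contrast_test()].
#' @return single data.frame, rows stacked across contrasts.
#' @export
run_contrasts <- function(matrix, specs, ...) {
  do.call(rbind, lapply(specs, function(sp) contrast_test(matrix, sp, ...)))
}

#' Identify regulated genes across contrasts
#'
#' A gene is regulated if, in at least one contrast, `|log2fc|` exceeds
#' `fc_cutoff` AND `fdr` is below `fdr_cutoff`. The fold-change criterion
#' is applied two-sided. Excluded genes (e.g. a gene knocked out in some
#' of the underlying studies) are removed from the set unconditionally.
#'
#' @param results data.frame from [run_contrasts()] / [contrast_test()].
#' @param fc_cutoff absolute log2 fold-change threshold
#'   (default `log2(1.5)`).
#' @param fdr_cutoff BH-FDR threshold (default 0.05).
#' @param excluded_genes gene ids removed from the analysis.
#' @return object of class `regulated_gene_set`: `gene_ids` (sorted),
#'   `contributing` (named list: gene -> contrast ids in which it passed),
#'   plus the cutoffs used.
#' @export
identify_regulated <- function(results, fc_cutoff = log2(1.5),
                               fdr_cutoff = 0.05,
                               excluded_genes = character(0)) {
  if (!is.finite(fc_cutoff) || fc_cutoff < 0) {
    stop("fc_cutoff must be a non-negative number")
  }
  if (!is.finite(fdr_cutoff) || fdr_cutoff <= 0 || fdr_cutoff > 1) {
    stop("fdr_cutoff must be in (0, 1]")
  }
  hit <- abs(results$log2fc) > fc_cutoff & results$fdr < fdr_cutoff &
    !(results$gene_id %in% excluded_genes)
  hits <- results[hit, c("gene_id", "contrast_id")]
  contributing <- split(hits$contrast_id, hits$gene_id)
  structure(list(gene_ids = sort(unique(hits$gene_id)),
                 fc_cutoff = fc_cutoff,
                 fdr_cutoff = fdr_cutoff,
                 excluded_genes = as.character(excluded_genes),
                 contributing = contributing),
            class = "regulated_gene_set")
}

#' @export
print.regulated_gene_set <- function(x, ...) {
  cat(sprintf(
    "regulated_gene_set: %d genes (|log2FC| > %.3f, FDR < %g, %d excluded)\n",
    length(x$gene_ids), x$fc_cutoff, x$fdr_cutoff, length(x$excluded_genes)))
  invisible(x)
}
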