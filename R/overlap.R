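# Age-by-exposure overlap analysis: Venn counts between regulated gene
# sets, signed maximum fold change across contrasts, and first principal
# component loadings of fold-change profiles.

#' Build a fold-change profile from contrast results
#'
#' @param results data.frame from [run_contrasts()]; must cover the same
#'   gene universe in every contrast.
#' @param kind `"age"` or `"exposure"`, recorded on the object.
#' @return object of class `fc_profile`: numeric matrix `values`
#'   (genes x contrasts, complete) plus `kind`.
#' @export
fold_change_profile <- function(results, kind = c("age", "exposure")) {
  kind <- match.arg(kind)
  genes <- unique(results$gene_id)
  contrasts <- unique(results$contrast_id)
  m <- matrix(NA_real_, length(genes), length(contrasts),
              dimnames = list(genes, contrasts))
  m[cbind(match(results$gene_id, genes),
          match(results$contrast_id, contrasts))] <- results$log2fc
  if (anyNA(m)) {
    stop("incomplete profile: every contrast must cover every gene")
  }
  structure(list(values = m, kind = kind), class = "fc_profile")
}

as_profile_matrix <- function(profile) {
  if (inherits(profile, "fc_profile")) profile$values
  else if (is.matrix(profile)) profile
  else stop("profile must be an fc_profile or a genes x contrasts matrix")
}

#' Venn overlap between two regulated gene sets
#'
#' The percentage is reported relative to set a (for the age-by-exposure
#' question: the share of age-regulated genes that are also
#' exposure-regulated).
#'
#' @param set_a,set_b `regulated_gene_set` objects or character vectors.
#' @return list: `a_only`, `b_only`, `both` (counts) and
#'   `percent_a_in_b`.
#' @export
venn_overlap <- function(set_a, set_b) {
  ga <- if (inherits(set_a, "regulated_gene_set")) set_a$gene_ids else set_a
  gb <- if (inherits(set_b, "regulated_gene_set")) set_b$gene_ids else set_b
  both <- length(intersect(ga, gb))
  list(a_only = length(setdiff(ga, gb)),
       b_only = length(setdiff(gb, ga)),
       both = both,
       percent_a_in_b = if (length(ga) > 0) 100 * both / length(ga) else 0)
}

#' Signed maximum fold change across contrasts
#'
#' Per gene, the log2 fold change of maximal absolute value across the
#' profile's contrasts, sign retained. Ties in absolute value are broken
#' toward the lexicographically earlier contrast id.
#'
#' @param profile an `fc_profile` or genes x contrasts matrix.
#' @return named numeric vector, one value per gene.
#' @export
signed_max_fold_change <- function(profile) {
  m <- as_profile_matrix(profile)
  if (ncol(m) < 1) stop("profile needs at least one contrast")
  ord <- order(colnames(m) %||% as.character(seq_len(ncol(m))))
  m <- m[, ord, drop = FALSE]
  idx <- max.col(abs(m), ties.method = "first")
  setNames(m[cbind(seq_len(nrow(m)), idx)], rownames(m))
}

#' First principal component of a fold-change profile
#'
#' PCA of the column-centered profile via singular value decomposition.
#' Loadings are the per-gene entries of the first left singular vector
#' (unit Euclidean norm); inertia is the percentage of total variance
#' carried by component 1. The loading sign is oriented so that the
#' correlation with the gene-wise mean profile is non-negative, making
#' results invariant to a global sign flip of the inputs.
#'
#' @param profile an `fc_profile` or genes x contrasts matrix with >= 2
#'   genes and >= 2 contrasts.
#' @return list of class `pc1_result`: `loadings` (named, unit norm),
#'   `inertia` (percent), `orientation_sign` (+1/-1 applied).
#' @export
pc1_loadings <- function(profile) {
  m <- as_profile_matrix(profile)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("profile needs >= 2 genes and >= 2 contrasts")
  }
  centered <- sweep(m, 2, colMeans(m))
  sv <- svd(centered)
  if (sv$d[1] <= .Machine$double.eps * max(dim(m))) {
    stop("rank-0 profile: no variance after column centering")
  }
  loadings <- sv$u[, 1]
  s <- cor(loadings, rowMeans(m))
  s <- if (is.na(s) || s >= 0) 1 else -1
  structure(list(loadings = setNames(s * loadings, rownames(m)),
                 inertia = 100 * sv$d[1]^2 / sum(sv$d^2),
                 orientation_sign = s),
            class = "pc1_result")
}

#' @export
print.pc1_result <- function(x, ...) {
  cat(sprintf("pc1_result: %d gene loadings, inertia %.1f%%\n",
              length(x$loadings), x$inertia))
  invisible(x)
}

#' Correlate two sets of PC1 loadings over shared genes
#'
#' @param age,exposure `pc1_result` objects (or named numeric vectors).
#' @return list: `r` (Pearson), `p_value`, `n_genes`, and `table`
#'   (data.frame gene_id, loading_a, loading_b for plotting/export).
#' @export
compare_loadings <- function(age, exposure) {
  la <- if (inherits(age, "pc1_result")) age$loadings else age
  lb <- if (inherits(exposure, "pc1_result")) exposure$loadings else exposure
  shared <- intersect(names(la), names(lb))
  if (length(shared) < 3) stop("need >= 3 shared genes to correlate loadings")
  ct <- stats::cor.test(la[shared], lb[shared], method = "pearson")
  list(r = unname(ct$estimate),
       p_value = ct$p.value,
       n_genes = length(shared),
       table = data.frame(gene_id = shared,
                          loading_a = unname(la[shared]),
                          loading_b = unname(lb[shared]),
                          stringsAsFactors = FALSE))
}
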