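# Domain containers and file I/O shared by all stages.
#
# An expression matrix is a plain numeric matrix, genes in rows (microarray
# convention), log2 scale, with unique gene rownames and sample colnames.
# Sample metadata is a data.frame with one row per sample. A clock model is
# an S3 object serialized to JSON.

MODEL_SCHEMA_VERSION <- "txclock-model/1"

#' Validate an expression matrix
#'
#' Checks the invariants every downstream stage relies on: numeric matrix,
#' unique non-empty gene and sample identifiers, all values finite.
#'
#' @param x numeric matrix, genes in rows, log2 scale.
#' @return `x`, invisibly, if valid; otherwise an error naming the offender.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression matrix must be a numeric matrix")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix must have gene rownames and sample colnames")
  }
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g) > 0) {
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s) > 0) {
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  }
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  invisible(x)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a UTF-8 TSV whose first header field is `gene_id` followed by
#' sample ids, one gene per row. Lines starting with `#` are ignored
#' (pipeline outputs carry a provenance header). Orientation is never
#' guessed: genes are in rows unless `transposed = TRUE` is passed
#' explicitly.
#'
#' @param path TSV file path.
#' @param transposed set `TRUE` only if the file has samples in rows.
#' @param missing one of `"strict"` (any missing cell is an error) or
#'   `"impute_gene_mean"` (replace by the gene's row mean, with a warning).
#' @return validated numeric matrix, genes x samples.
#' @export
read_expression_matrix <- function(path, transposed = FALSE,
                                   missing = c("strict", "impute_gene_mean")) {
  missing <- match.arg(missing)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) {
    stop("malformed expression TSV (need gene_id column plus >=1 sample): ",
         path)
  }
  if (names(df)[1] != "gene_id") {
    stop("malformed header: first column must be 'gene_id', got '",
         names(df)[1], "'")
  }
  gene_ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      suppressWarnings(num <- as.numeric(vals[[j]]))
      bad <- which(is.na(num) & !is.na(vals[[j]]) & vals[[j]] != "NA")
      if (length(bad) > 0) {
        stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                     gene_ids[bad[1]], names(vals)[j]))
      }
      vals[[j]] <- num
    }
  }
  x <- as.matrix(vals)
  rownames(x) <- gene_ids
  if (transposed) x <- t(x)
  if (anyNA(x)) {
    if (missing == "strict") {
      bad <- which(is.na(x), arr.ind = TRUE)[1, ]
      stop(sprintf("missing value at gene '%s', sample '%s' (policy=strict)",
                   rownames(x)[bad[1]], colnames(x)[bad[2]]))
    }
    warning("imputing ", sum(is.na(x)), " missing cells with gene means")
    for (i in which(rowSums(is.na(x)) > 0)) {
      x[i, is.na(x[i, ])] <- mean(x[i, ], na.rm = TRUE)
    }
  }
  validate_expression_matrix(x)
  x
}

#' Write an expression matrix to TSV
#'
#' @param x validated expression matrix.
#' @param path output path.
#' @param digits decimal digits retained (default 6; round-trip exact at
#'   this precision).
#' @param header_comment optional `#`-prefixed provenance line(s).
#' @export
write_expression_matrix <- function(x, path, digits = 6,
                                    header_comment = NULL) {
  validate_expression_matrix(x)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  df <- data.frame(gene_id = rownames(x), round(x, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a sample metadata table
#'
#' Required columns: `sample_id`, `study_id`, `age_months`,
#' `exposure_group`, `exposure_months`. Exposure groups must be one of
#' sham, cs, htp, cessation, switch, other (case-insensitive on read).
#' Ages are real-valued months and must be positive; exposure durations
#' must be non-negative.
#'
#' @param md data.frame of sample metadata.
#' @param matrix optional expression matrix; if given, sample ids must
#'   match its columns exactly (same set).
#' @return `md`, invisibly.
#' @export
validate_metadata <- function(md, matrix = NULL) {
  req <- c("sample_id", "study_id", "age_months", "exposure_group",
           "exposure_months")
  miss <- setdiff(req, names(md))
  if (length(miss) > 0) {
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  }
  if (!is.numeric(md$age_months) || anyNA(md$age_months) ||
      any(md$age_months <= 0)) {
    stop("age_months must be positive real months")
  }
  if (!is.numeric(md$exposure_months) || anyNA(md$exposure_months) ||
      any(md$exposure_months < 0)) {
    stop("exposure_months must be non-negative real months")
  }
  bad <- setdiff(unique(as.character(md$exposure_group)), EXPOSURE_GROUPS)
  if (length(bad) > 0) {
    stop("unknown exposure group label(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(matrix)) {
    if (!setequal(md$sample_id, colnames(matrix))) {
      stop("metadata sample ids do not match expression matrix columns")
    }
  }
  invisible(md)
}

#' Read sample metadata from CSV
#'
#' @param path CSV with columns `sample_id`, `study_id`, `age_months`,
#'   `exposure_group`, `exposure_months`. Group labels are parsed
#'   case-insensitively.
#' @return validated data.frame; `exposure_group` is a factor with levels
#'   sham, cs, htp, cessation, switch, other.
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, header = TRUE, sep = ",", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!"exposure_group" %in% names(md)) {
    stop("metadata missing column(s): exposure_group")
  }
  md$exposure_group <- tolower(trimws(as.character(md$exposure_group)))
  md$sample_id <- as.character(md$sample_id)
  md$study_id <- as.character(md$study_id)
  validate_metadata(md)
  md$exposure_group <- factor(md$exposure_group, levels = EXPOSURE_GROUPS)
  md
}

#' Write sample metadata to CSV
#' @param md validated metadata data.frame.
#' @param path output path.
#' @param header_comment optional `#`-prefixed provenance line(s).
#' @export
write_metadata <- function(md, path, header_comment = NULL) {
  validate_metadata(md)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  write.table(md, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a clock model object
#'
#' A sparse linear age predictor: predicted age (months) =
#' `intercept + sum(coefficients * x[genes])` on the log2 expression scale.
#'
#' @param intercept real, months.
#' @param coefficients named numeric vector, months per log2 unit; names
#'   are gene ids, only genes with nonzero refit weight.
#' @param lambda_selected regularization value chosen by cross-validation.
#' @param training_gene_universe character vector of all genes visible to
#'   selection.
#' @param training_sample_count integer.
#' @param standardization_params list with numeric vectors `mean` and `sd`
#'   (named by gene) used during selection; training means also serve as
#'   the imputation values for missing genes at prediction time.
#' @param lambda_grid optional numeric vector, the grid searched.
#' @return object of class `clock_model`.
#' @export
clock_model <- function(intercept, coefficients = numeric(0),
                        lambda_selected = 0,
                        training_gene_universe = names(coefficients),
                        training_sample_count = 0L,
                        standardization_params = list(
                          mean = numeric(0), sd = numeric(0)),
                        lambda_grid = numeric(0)) {
  m <- structure(list(
    schema = MODEL_SCHEMA_VERSION,
    intercept = as.numeric(intercept),
    coefficients = coefficients,
    lambda_selected = as.numeric(lambda_selected),
    training_gene_universe = as.character(training_gene_universe),
    training_sample_count = as.integer(training_sample_count),
    standardization_params = standardization_params,
    lambda_grid = as.numeric(lambda_grid)
  ), class = "clock_model")
  validate_clock_model(m)
  m
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf(
    "clock_model: %d predictor genes, intercept %.3f months, lambda %.4g\n",
    length(x$coefficients), x$intercept, x$lambda_selected))
  cat(sprintf("  trained on %d samples, %d-gene universe\n",
              x$training_sample_count, length(x$training_gene_universe)))
  invisible(x)
}

#' Validate a clock model
#' @param m clock_model object.
#' @return `m`, invisibly.
#' @export
validate_clock_model <- function(m) {
  if (!inherits(m, "clock_model")) stop("not a clock_model")
  if (length(m$intercept) != 1 || !is.finite(m$intercept)) {
    stop("intercept must be a single finite number")
  }
  if (length(m$coefficients) > 0) {
    if (is.null(names(m$coefficients)) || anyDuplicated(names(m$coefficients))) {
      stop("coefficients must be uniquely named by gene id")
    }
    if (any(m$coefficients == 0)) {
      stop("coefficients map must contain only nonzero weights")
    }
    out <- setdiff(names(m$coefficients), m$training_gene_universe)
    if (length(out) > 0) {
      stop("coefficient gene(s) outside training universe: ",
           paste(out, collapse = ", "))
    }
  }
  invisible(m)
}

#' Save a clock model to JSON
#' @param model clock_model.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  validate_clock_model(model)
  obj <- list(
    schema = model$schema,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    lambda_selected = model$lambda_selected,
    training_gene_universe = model$training_gene_universe,
    training_sample_count = model$training_sample_count,
    standardization_params = list(
      mean = as.list(model$standardization_params$mean),
      sd = as.list(model$standardization_params$sd)),
    lambda_grid = model$lambda_grid
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a clock model from JSON
#'
#' Unknown future fields are ignored with a warning; a schema tag from a
#' different major version is an error.
#'
#' @param path JSON written by [save_model()].
#' @return clock_model.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$schema) || !identical(obj$schema, MODEL_SCHEMA_VERSION)) {
    stop("model schema version mismatch: expected '", MODEL_SCHEMA_VERSION,
         "', found '", if (is.null(obj$schema)) "<none>" else obj$schema, "'")
  }
  known <- c("schema", "intercept", "coefficients", "lambda_selected",
             "training_gene_universe", "training_sample_count",
             "standardization_params", "lambda_grid")
  extra <- setdiff(names(obj), known)
  if (length(extra) > 0) {
    warning("ignoring unknown model field(s): ", paste(extra, collapse = ", "))
  }
  unlist_named <- function(x) {
    if (length(x) == 0) return(numeric(0))
    setNames(vapply(x, as.numeric, numeric(1)), names(x))
  }
  clock_model(
    intercept = obj$intercept,
    coefficients = unlist_named(obj$coefficients),
    lambda_selected = obj$lambda_selected,
    training_gene_universe = unlist(obj$training_gene_universe) %||% character(0),
    training_sample_count = obj$training_sample_count,
    standardization_params = list(
      mean = unlist_named(obj$standardization_params$mean),
      sd = unlist_named(obj$standardization_params$sd)),
    lambda_grid = as.numeric(unlist(obj$lambda_grid))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
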