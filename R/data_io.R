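# Reading cohort data, building weighted allele scores, writing results.

#' Construct a cohort table
#'
#' A cohort table is the unit of all estimation in this package: one row per
#' individual with a positive continuous exposure, a continuous outcome, a
#' single instrument (a genotype dosage in [0, 2] or a weighted allele
#' score), and optionally covariate columns. Categorical covariates are
#' expanded to indicator columns with the first observed level as reference.
#'
#' @param exposure numeric vector of exposure values.
#' @param outcome numeric vector of outcome values.
#' @param instrument numeric vector (allele score or dosage), nonnegative.
#' @param covariates optional data.frame of covariate columns.
#' @param n_dropped number of rows removed during ingestion (bookkeeping).
#' @return An object of class \code{cohort_table}: a data.frame with columns
#'   \code{x}, \code{y}, \code{g} and one column per (expanded) covariate,
#'   with attributes \code{covariates} (expanded covariate names) and
#'   \code{n_dropped}.
#' @export
cohort_table <- function(exposure, outcome, instrument, covariates = NULL,
                         n_dropped = 0L) {
  n <- length(exposure)
  if (length(outcome) != n || length(instrument) != n)
    .config_error("exposure, outcome and instrument must have equal length")
  if (n == 0L)
    .data_error("no individuals remain after ingestion")
  if (any(instrument < 0))
    .data_error("instrument values must be nonnegative")
  if (sd(instrument) == 0)
    .data_error("instrument has zero variance")
  df <- data.frame(x = as.numeric(exposure), y = as.numeric(outcome),
                   g = as.numeric(instrument))
  cov_names <- character(0)
  if (!is.null(covariates) && ncol(covariates) > 0) {
    expanded <- .expand_covariates(as.data.frame(covariates))
    cov_names <- colnames(expanded)
    df <- cbind(df, expanded)
  }
  structure(df, covariates = cov_names, n_dropped = as.integer(n_dropped),
            class = c("cohort_table", "data.frame"))
}

# Indicator coding for factor/character columns, first observed level as
# reference; numeric columns pass through unchanged.
.expand_covariates <- function(covs) {
  out <- list()
  for (nm in names(covs)) {
    col <- covs[[nm]]
    if (is.numeric(col)) {
      out[[nm]] <- col
    } else {
      f <- factor(col, levels = unique(as.character(col)))
      mm <- model.matrix(~f)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(nm, "_", levels(f)[-1L])
      for (j in seq_len(ncol(mm))) out[[colnames(mm)[j]]] <- mm[, j]
    }
  }
  as.data.frame(out, optional = TRUE)
}

#' Read a cohort from a delimited text file
#'
#' Reads a CSV/TSV file (header row required, delimiter auto-detected) and
#' maps its columns onto the exposure / outcome / instrument / covariate
#' roles. Rows with a missing value in any mapped column are dropped
#' (complete-case analysis) and the drop count is recorded and messaged.
#'
#' @param path path to a delimited text file.
#' @param column_map named list with entries \code{exposure}, \code{outcome},
#'   \code{instrument} (column names, required) and optionally
#'   \code{covariates} (character vector of column names).
#' @return A \code{\link{cohort_table}}.
#' @export
read_cohort <- function(path, column_map) {
  if (!file.exists(path)) .config_error(sprintf("file not found: %s", path))
  for (role in c("exposure", "outcome", "instrument"))
    if (is.null(column_map[[role]]))
      .config_error(sprintf("column_map is missing the '%s' role", role))
  raw <- data.table::fread(path, data.table = FALSE)
  wanted <- c(column_map$exposure, column_map$outcome, column_map$instrument,
              column_map$covariates)
  missing_cols <- setdiff(wanted, names(raw))
  if (length(missing_cols))
    .config_error(sprintf("column(s) not present in %s: %s", path,
                          paste(missing_cols, collapse = ", ")))
  keep <- complete.cases(raw[, wanted, drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("read_cohort: dropped %d row(s) with missing values", n_dropped))
  raw <- raw[keep, , drop = FALSE]
  if (nrow(raw) == 0L) .data_error("all rows dropped during ingestion")
  covs <- NULL
  if (length(column_map$covariates))
    covs <- raw[, column_map$covariates, drop = FALSE]
  cohort_table(raw[[column_map$exposure]], raw[[column_map$outcome]],
               raw[[column_map$instrument]], covs, n_dropped = n_dropped)
}

#' Build a weighted allele score
#'
#' Computes, for each individual, the weighted sum of effect-allele dosages
#' across variants: \eqn{score_i = \sum_v w_v d_{vi}}. Weights are assumed
#' pre-oriented to the exposure-increasing allele. Variants present in the
#' dosage matrix but absent from the weights table are ignored with a
#' warning; a weight whose variant is missing from the dosage matrix is an
#' error.
#'
#' @param dosages numeric matrix, variants in rows (rownames = variant ids),
#'   individuals in columns; entries in [0, 2].
#' @param weights data.frame with columns \code{variant}, \code{effect_allele},
#'   \code{weight}; variant ids must be unique.
#' @return numeric vector of allele scores, one per individual.
#' @export
build_allele_score <- function(dosages, weights) {
  if (is.null(rownames(dosages)))
    .config_error("dosage matrix must have variant ids as rownames")
  if (anyDuplicated(weights$variant))
    .config_error("variant ids in the weights table must be unique")
  if (any(dosages < 0 | dosages > 2))
    .data_error("dosages must lie in [0, 2]")
  absent <- setdiff(weights$variant, rownames(dosages))
  if (length(absent))
    .config_error(sprintf("weights refer to variant(s) missing from dosages: %s",
                          paste(absent, collapse = ", ")))
  unused <- setdiff(rownames(dosages), weights$variant)
  if (length(unused))
    warning(sprintf("ignoring %d variant(s) without weights", length(unused)))
  idx <- match(weights$variant, rownames(dosages))
  as.numeric(crossprod(dosages[idx, , drop = FALSE], weights$weight))
}

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
}

#' Write analysis results to disk
#'
#' LACE tables and curve grids are written as TSV with 12 significant
#' digits; fractional-polynomial fit summaries as JSON (degree, powers,
#' coefficients, covariance, log-likelihood, tau2). A written table read
#' back reproduces the values to full printed precision.
#'
#' @param object a \code{lace_table}, \code{fp_fit}, \code{curve_estimate}
#'   or plain data.frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(object, path) {
  if (inherits(object, "fp_fit")) {
    jsonlite::write_json(summary_list(object), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  df <- as.data.frame(object)
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- .fmt_num(out[[j]])
  tryCatch(
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) .config_error(sprintf("cannot write to %s: %s",
                                              path, conditionMessage(e))))
  invisible(path)
}

#' @export
summary_list <- function(object, ...) UseMethod("summary_list")
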