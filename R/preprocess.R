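#' Quality-control filter for a subject table
#'
#' Removes variables that carry no usable information before normalisation:
#' a column is dropped when (in this order of precedence)
#' \enumerate{
#'   \item more than 50\% of its entries are missing,
#'   \item the standard deviation of its non-missing entries is zero,
#'   \item more than 95\% of its non-missing entries share a single value.
#' }
#' Each removed variable is reported with the first matching reason.
#' Thresholds are evaluated on the raw (pre-imputation) values.
#'
#' @param table a [subject_table()].
#' @return A list with elements `table` (the filtered [subject_table()]) and
#'   `report`, a data frame with columns `variable` and `reason`
#'   (`missing_gt_50pct`, `zero_sd` or `gt_95pct_identical`) plus an attribute
#'   `retained_count`.
#' @export
qc_filter <- function(table) {
  stopifnot(inherits(table, "subject_table"))
  if (ncol(table$values) < 1) stopf("table has no columns")
  vals <- table$values
  reasons <- character(0)
  removed <- character(0)
  for (j in seq_len(ncol(vals))) {
    x <- vals[, j]
    miss_frac <- mean(is.na(x))
    obs <- x[!is.na(x)]
    reason <- NULL
    if (miss_frac > 0.5) {
      reason <- "missing_gt_50pct"
    } else if (length(obs) == 0 || sd(obs) == 0) {
      reason <- "zero_sd"
    } else {
      modal_freq <- max(table(obs)) / length(obs)
      if (modal_freq > 0.95) reason <- "gt_95pct_identical"
    }
    if (!is.null(reason)) {
      removed <- c(removed, table$variable_names[j])
      reasons <- c(reasons, reason)
    }
  }
  keep <- !(table$variable_names %in% removed)
  if (!any(keep)) stopf("quality control removed every variable: empty table")
  report <- data.frame(variable = removed, reason = reasons,
                       stringsAsFactors = FALSE)
  attr(report, "retained_count") <- sum(keep)
  list(table = st_select(table, keep), report = report)
}

#' Impute residual missing values by the column median
#'
#' After quality control every column has at most 50\% missing entries; the
#' remaining holes are filled with the median of the observed values, a
#' rank-stable choice that does not disturb the subsequent rank-based
#' inverse-normal transform for the observed entries.  The missingness mask is
#' kept on the returned table for provenance.
#'
#' @param table a [subject_table()].
#' @return A [subject_table()] with no missing values.
#' @export
impute_missing <- function(table) {
  stopifnot(inherits(table, "subject_table"))
  vals <- table$values
  for (j in seq_len(ncol(vals))) {
    miss <- is.na(vals[, j])
    if (any(miss)) {
      if (all(miss)) stopf("column '%s' entirely missing", table$variable_names[j])
      vals[miss, j] <- median(vals[!miss, j])
    }
  }
  st_with_values(table, vals)
}

# Blom scores for a numeric vector: qnorm((r - 3/8) / (n + 1/4)) with
# average ranks for ties.
blom_scores <- function(x) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Rank-based inverse-normal (Blom) transformation
#'
#' Each column is independently replaced by the standard-normal quantiles of
#' its Blom-adjusted ranks, \eqn{\Phi^{-1}((r - 3/8)/(n + 1/4))}, with ties
#' assigned average ranks.  The transform is monotone within each column, so
#' rank order is preserved.
#'
#' @param table a [subject_table()] with no missing values (run
#'   [impute_missing()] first).
#' @return A [subject_table()] with each column marginally normal.
#' @export
inverse_normal_transform <- function(table) {
  stopifnot(inherits(table, "subject_table"))
  vals <- table$values
  if (anyNA(vals)) stopf("missing values present; impute before transforming")
  for (j in seq_len(ncol(vals))) {
    if (sd(vals[, j]) == 0)
      stopf("column '%s' is constant; it should have been removed by qc_filter",
            table$variable_names[j])
    vals[, j] <- blom_scores(vals[, j])
  }
  st_with_values(table, vals)
}

#' Remove confound effects by linear regression
#'
#' Replaces every variable by its residual from an ordinary least-squares
#' regression on an intercept plus the confound columns.  Confounds are
#' z-scored internally for numerical conditioning (residuals are unaffected).
#' Optionally, squared copies of selected confounds are appended before
#' fitting (useful for, e.g., age and body-mass-index effects that are not
#' linear).
#'
#' @param table a [subject_table()] of data to de-confound.
#' @param confounds a [subject_table()] of confound variables for the same
#'   subjects in the same order.
#' @param square character vector of confound names whose squared,
#'   re-centred copies are added as additional confounds.
#' @return A [subject_table()] of residuals: mean-zero columns orthogonal to
#'   every confound.
#' @export
deconfound <- function(table, confounds, square = character(0)) {
  stopifnot(inherits(table, "subject_table"), inherits(confounds, "subject_table"))
  if (nrow(table$values) != nrow(confounds$values))
    stopf("table and confounds have different numbers of subjects")
  if (!identical(table$subject_ids, confounds$subject_ids))
    stopf("table and confounds must cover the same subjects in the same order")
  C <- confounds$values
  if (anyNA(C)) stopf("confounds contain missing values")
  if (length(square)) {
    missing_sq <- setdiff(square, confounds$variable_names)
    if (length(missing_sq))
      stopf("square lists unknown confounds: %s", paste(missing_sq, collapse = ", "))
    sq <- C[, square, drop = FALSE]^2
    sq <- center_cols(sq)
    colnames(sq) <- paste0(square, "_sq")
    C <- cbind(C, sq)
  }
  Cz <- scale(C)  # z-score; constant columns become NaN
  if (anyNA(Cz)) {
    const <- colnames(C)[apply(C, 2, sd) == 0]
    stopf("constant confound column(s): %s", paste(const, collapse = ", "))
  }
  D <- cbind(`(intercept)` = 1, Cz)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dropped <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stopf("confound matrix is rank-deficient; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  resid <- qr.resid(qrD, table$values)
  dimnames(resid) <- dimnames(table$values)
  st_with_values(table, resid)
}

#' Align variable signs against a benchmark variable
#'
#' To make loadings read consistently ("higher is better"), every variable
#' whose Pearson correlation with a chosen benchmark variable is strictly
#' negative is negated.  A manual list then overrides individual variables
#' (negating them once more; a variable flipped twice is back to its original
#' sign and is not listed as flipped).
#'
#' @param table a [subject_table()].
#' @param benchmark name of the benchmark variable (a column of `table`).
#' @param manual_flips character vector of variables to negate after the
#'   correlation pass.
#' @return A list with elements `table` (signs aligned) and `record`, a list
#'   with `benchmark_variable`, `flipped_variables` (final flipped set) and
#'   `manual_flips`.
#' @export
sign_flip <- function(table, benchmark, manual_flips = character(0)) {
  stopifnot(inherits(table, "subject_table"))
  if (!benchmark %in% table$variable_names)
    stopf("benchmark variable '%s' not found", benchmark)
  if (benchmark %in% manual_flips)
    stopf("the benchmark variable cannot be manually flipped")
  unknown <- setdiff(manual_flips, table$variable_names)
  if (length(unknown))
    stopf("manual_flips lists unknown variables: %s", paste(unknown, collapse = ", "))
  vals <- table$values
  bench <- vals[, benchmark]
  flipped <- rep(FALSE, ncol(vals))
  names(flipped) <- table$variable_names
  for (j in seq_len(ncol(vals))) {
    if (table$variable_names[j] == benchmark) next
    r <- suppressWarnings(cor(vals[, j], bench, use = "pairwise.complete.obs"))
    if (!is.na(r) && r < 0) flipped[j] <- TRUE
  }
  flipped[manual_flips] <- !flipped[manual_flips]
  vals[, flipped] <- -vals[, flipped, drop = FALSE]
  record <- list(benchmark_variable = benchmark,
                 flipped_variables = names(flipped)[flipped],
                 manual_flips = manual_flips)
  list(table = st_with_values(table, vals), record = record)
}

#' Full preprocessing pipeline
#'
#' Applies, in order: quality control ([qc_filter()]), median imputation
#' ([impute_missing()]), rank-based inverse-normal transformation
#' ([inverse_normal_transform()]), de-confounding ([deconfound()]), and
#' optionally benchmark sign alignment ([sign_flip()]).
#'
#' @param table a [subject_table()] of raw data.
#' @param confounds optional [subject_table()] of confounds; skipped if `NULL`.
#' @param benchmark optional benchmark variable name for [sign_flip()];
#'   skipped if `NULL`.  If the benchmark is removed by quality control the
#'   sign-flip step errors.
#' @param manual_flips passed to [sign_flip()].
#' @param square passed to [deconfound()].
#' @return A list with elements `table` (the processed [subject_table()]),
#'   `qc_report` and `sign_flip_record` (`NULL` when the step was skipped).
#' @export
preprocess <- function(table, confounds = NULL, benchmark = NULL,
                       manual_flips = character(0), square = character(0)) {
  qc <- qc_filter(table)
  out <- impute_missing(qc$table)
  out <- inverse_normal_transform(out)
  if (!is.null(confounds)) out <- deconfound(out, confounds, square = square)
  record <- NULL
  if (!is.null(benchmark)) {
    sf <- sign_flip(out, benchmark, manual_flips)
    out <- sf$table
    record <- sf$record
  }
  list(table = out, qc_report = qc$report, sign_flip_record = record)
}
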