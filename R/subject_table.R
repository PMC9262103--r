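#' Subjects-by-variables data table
#'
#' The basic container used throughout the package: a numeric matrix with one
#' row per subject and one column per variable, plus optional family
#' identifiers (used by the family-respecting cross-validation) and a
#' missingness mask recording which entries were absent in the raw input.
#'
#' @param values numeric matrix (subjects x variables); `NA` entries mark
#'   missing data.
#' @param variable_names character vector of unique column names; defaults to
#'   `colnames(values)`.
#' @param subject_ids character vector of unique row identifiers; defaults to
#'   `rownames(values)` or `"S1", "S2", ...`.
#' @param family_ids optional character vector, one family label per subject.
#'   Subjects sharing a label are kept together by [family_kfold()].
#' @param missing_mask optional logical matrix marking originally missing
#'   entries; defaults to `is.na(values)`.
#'
#' @return An object of class `subject_table`: a list with elements `values`,
#'   `variable_names`, `subject_ids`, `family_ids` and `missing_mask`.
#' @examples
#' tab <- subject_table(matrix(rnorm(20), 5, 4))
#' dim(tab$values)
#' @export
subject_table <- function(values, variable_names = NULL, subject_ids = NULL,
                          family_ids = NULL, missing_mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  variable_names <- variable_names %||% colnames(values) %||%
    paste0("V", seq_len(ncol(values)))
  subject_ids <- subject_ids %||% rownames(values) %||%
    paste0("S", seq_len(nrow(values)))
  variable_names <- as.character(variable_names)
  subject_ids <- as.character(subject_ids)
  if (length(variable_names) != ncol(values))
    stopf("variable_names length (%d) != number of columns (%d)",
          length(variable_names), ncol(values))
  if (anyDuplicated(variable_names))
    stopf("duplicate variable names: %s",
          paste(unique(variable_names[duplicated(variable_names)]), collapse = ", "))
  if (length(subject_ids) != nrow(values))
    stopf("subject_ids length (%d) != number of rows (%d)",
          length(subject_ids), nrow(values))
  if (anyDuplicated(subject_ids))
    stopf("duplicate subject ids")
  if (!is.null(family_ids)) {
    family_ids <- as.character(family_ids)
    if (length(family_ids) != nrow(values))
      stopf("family_ids must have one entry per subject")
  }
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  missing_mask <- as.matrix(missing_mask)
  if (!identical(dim(missing_mask), dim(values)))
    stopf("missing_mask must have the same shape as values")
  dimnames(values) <- list(subject_ids, variable_names)
  dimnames(missing_mask) <- dimnames(values)
  structure(
    list(values = values, variable_names = variable_names,
         subject_ids = subject_ids, family_ids = family_ids,
         missing_mask = missing_mask),
    class = "subject_table"
  )
}

#' @export
print.subject_table <- function(x, ...) {
  cat(sprintf("subject_table: %d subjects x %d variables\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$family_ids))
    cat(sprintf("  families: %d\n", length(unique(x$family_ids))))
  n_miss <- sum(x$missing_mask)
  if (n_miss > 0)
    cat(sprintf("  missing entries: %d (%.1f%%)\n", n_miss,
                100 * n_miss / length(x$values)))
  invisible(x)
}

#' @export
dim.subject_table <- function(x) dim(x$values)

# keep a subset of columns, preserving metadata
st_select <- function(table, keep) {
  subject_table(table$values[, keep, drop = FALSE],
                variable_names = table$variable_names[keep],
                subject_ids = table$subject_ids,
                family_ids = table$family_ids,
                missing_mask = table$missing_mask[, keep, drop = FALSE])
}

# keep a subset of rows (subjects)
st_rows <- function(table, keep) {
  subject_table(table$values[keep, , drop = FALSE],
                variable_names = table$variable_names,
                subject_ids = table$subject_ids[keep],
                family_ids = if (!is.null(table$family_ids)) table$family_ids[keep],
                missing_mask = table$missing_mask[keep, , drop = FALSE])
}

# replace the value matrix, keeping metadata and (by default) the mask
st_with_values <- function(table, values, missing_mask = table$missing_mask) {
  subject_table(values,
                variable_names = table$variable_names,
                subject_ids = table$subject_ids,
                family_ids = table$family_ids,
                missing_mask = missing_mask)
}

#' Read a subjects-by-variables CSV file
#'
#' Expects a header row of variable names.  Columns named `subject_id` and
#' `family_id` are treated as identifiers and removed from the numeric data.
#' Empty fields and the string `NA` are read as missing.
#'
#' @param path path to a CSV file.
#' @return A [subject_table()].
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"))
  nm <- names(df)
  if (anyDuplicated(nm))
    stopf("duplicate variable names in %s: %s", path,
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  subject_ids <- if ("subject_id" %in% nm) as.character(df[["subject_id"]]) else NULL
  family_ids <- if ("family_id" %in% nm) as.character(df[["family_id"]]) else NULL
  data_cols <- setdiff(nm, c("subject_id", "family_id"))
  for (cn in data_cols) {
    col <- df[[cn]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stopf("non-numeric value '%s' at row %d, column '%s' of %s",
              col[bad[1]], bad[1], cn, path)
      df[[cn]] <- num
    }
  }
  subject_table(as.matrix(df[data_cols]),
                variable_names = data_cols,
                subject_ids = subject_ids,
                family_ids = family_ids)
}

#' Write a subject table to CSV
#'
#' Inverse of [read_subject_table()]: writes `subject_id` (and `family_id`
#' when present) columns followed by the numeric variables, at full precision.
#'
#' @param table a [subject_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(table, path) {
  df <- data.frame(subject_id = table$subject_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(table$family_ids)) df$family_id <- table$family_ids
  vals <- table$values
  vals[table$missing_mask & is.na(vals)] <- NA
  df <- cbind(df, as.data.frame(vals, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a variable-to-sub-domain dictionary
#'
#' Two-column CSV mapping each variable name to its sub-domain label.
#'
#' @param path CSV with columns `variable` and `subdomain` (or any two
#'   columns, taken in order).
#' @return A named character vector (names = variables, values = sub-domains)
#'   usable as the `partition` argument of [run_ddr()].
#' @export
read_domain_dictionary <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("domain dictionary needs two columns (variable, subdomain)")
  cols <- if (all(c("variable", "subdomain") %in% names(df))) {
    c("variable", "subdomain")
  } else names(df)[1:2]
  out <- as.character(df[[cols[2]]])
  names(out) <- as.character(df[[cols[1]]])
  if (anyDuplicated(names(out))) stopf("duplicate variables in domain dictionary")
  out
}
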