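#' Connectivity-matrix stack
#'
#' A set of per-subject symmetric region-by-region connectivity matrices with
#' shared region labels.
#'
#' @param matrices list of N numeric R x R matrices, one per subject;
#'   each must be symmetric within `tol`.
#' @param region_labels character vector of R region names; defaults to
#'   `"R1", ...`.
#' @param subject_ids optional character vector of N subject identifiers.
#' @param tol symmetry tolerance (default 1e-6).
#' @return Object of class `connectivity_stack`.
#' @export
connectivity_stack <- function(matrices, region_labels = NULL,
                               subject_ids = NULL, tol = 1e-6) {
  if (!length(matrices)) stopf("empty stack")
  R <- nrow(matrices[[1]])
  for (i in seq_along(matrices)) {
    M <- as.matrix(matrices[[i]])
    if (nrow(M) != R || ncol(M) != R)
      stopf("matrix %d is not %d x %d", i, R, R)
    if (max(abs(M - t(M))) > tol)
      stopf("matrix %d is asymmetric beyond tolerance %g", i, tol)
    matrices[[i]] <- M
  }
  region_labels <- region_labels %||% paste0("R", seq_len(R))
  if (length(region_labels) != R) stopf("need %d region labels", R)
  subject_ids <- subject_ids %||% paste0("S", seq_along(matrices))
  structure(list(matrices = matrices, region_labels = as.character(region_labels),
                 subject_ids = as.character(subject_ids)),
            class = "connectivity_stack")
}

#' @export
print.connectivity_stack <- function(x, ...) {
  cat(sprintf("connectivity_stack: %d subjects, %d x %d regions\n",
              length(x$matrices), length(x$region_labels), length(x$region_labels)))
  invisible(x)
}

#' Read a stack of connectivity matrices from a directory
#'
#' One whitespace-delimited R x R matrix per subject, one file per subject
#' (files taken in lexicographic order; the file stem becomes the subject id).
#'
#' @param dir directory of matrix files.
#' @param region_labels optional labels; or a path to a text file with one
#'   label per line.
#' @param pattern filename filter passed to [list.files()].
#' @return A [connectivity_stack()].
#' @export
read_connectivity_stack <- function(dir, region_labels = NULL, pattern = NULL) {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (!length(files)) stopf("no matrix files found in %s", dir)
  mats <- lapply(files, function(f) as.matrix(read.table(f)))
  if (is.character(region_labels) && length(region_labels) == 1 &&
      file.exists(region_labels)) {
    region_labels <- readLines(region_labels)
  }
  connectivity_stack(mats, region_labels = region_labels,
                     subject_ids = sub("\\.[^.]*$", "", basename(files)))
}

#' Tikhonov-regularised partial correlation
#'
#' Computes the partial-correlation matrix of a multivariate time series with
#' Tikhonov (ridge) regularisation of the covariance before inversion:
#' \deqn{\Theta = (S + \rho \bar d I)^{-1}, \qquad
#'       p_{ij} = -\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}},}
#' where \eqn{\bar d} is the mean diagonal of the sample covariance `S`.
#' The diagonal is set to 1.
#'
#' @param timeseries T x R numeric matrix (time points x regions).
#' @param rho non-negative regularisation parameter; with `rho = 0` a
#'   singular covariance is an error.
#' @return Symmetric R x R partial-correlation matrix with unit diagonal.
#' @export
tikhonov_partial_correlation <- function(timeseries, rho = 0.1) {
  X <- as.matrix(timeseries)
  if (nrow(X) < 2) stopf("need at least 2 time points")
  if (rho < 0) stopf("rho must be non-negative")
  S <- cov(X)
  Sreg <- S + rho * mean(diag(S)) * diag(ncol(S))
  prec <- tryCatch(solve(Sreg), error = function(e)
    stopf("covariance is singular%s", if (rho == 0) " (try rho > 0)" else ""))
  d <- sqrt(diag(prec))
  P <- -prec / outer(d, d)
  diag(P) <- 1
  (P + t(P)) / 2
}

#' Unroll a connectivity stack into region sub-domains
#'
#' Builds a subjects x edges table in which each region contributes its full
#' matrix row as one sub-domain: column `(a, b)` holds edge `M[a, b]` for
#' every subject, so each undirected edge appears in exactly two sub-domains
#' (once per endpoint region); that redundancy is resolved downstream by the
#' per-region dimension reduction.  Diagonal entries are retained; being
#' constant across subjects in typical data, they are removed later by the
#' zero-variance quality-control rule.
#'
#' @param stack a [connectivity_stack()].
#' @return A list with `table` (a [subject_table()] with columns named
#'   `"a|b"`) and `partition` (named character vector mapping each column to
#'   its row-region label, usable with [run_ddr()]).
#' @export
stack_to_table <- function(stack) {
  stopifnot(inherits(stack, "connectivity_stack"))
  labs <- stack$region_labels
  R <- length(labs)
  vals <- t(vapply(stack$matrices, function(M) as.numeric(t(M)),
                   numeric(R * R)))  # row-major: region a's row is contiguous
  cn <- paste0(rep(labs, each = R), "|", rep(labs, times = R))  # row-major order
  colnames(vals) <- cn
  partition <- rep(labs, each = R)
  names(partition) <- cn
  list(table = subject_table(vals, subject_ids = stack$subject_ids),
       partition = partition)
}

#' Assemble a symmetric edge-loading matrix from column loadings
#'
#' The observed-variable canonical loadings of an unrolled connectivity block
#' contain two copies of each undirected edge (`a|b` and `b|a`); this helper
#' averages the two copies into a single symmetric R x R loading matrix.
#' Missing columns (for example diagonal edges removed by quality control)
#' become `NA`.
#'
#' @param loadings named numeric vector of loadings, names `"a|b"` as produced
#'   by [stack_to_table()] plus [canonical_loadings()].
#' @param region_labels character vector of region names.
#' @return Symmetric R x R matrix of loadings.
#' @export
edge_loading_matrix <- function(loadings, region_labels) {
  R <- length(region_labels)
  L <- matrix(NA_real_, R, R, dimnames = list(region_labels, region_labels))
  for (a in seq_len(R)) for (b in seq_len(R)) {
    keys <- c(paste0(region_labels[a], "|", region_labels[b]),
              paste0(region_labels[b], "|", region_labels[a]))
    vals <- loadings[keys[keys %in% names(loadings)]]
    if (length(vals)) L[a, b] <- mean(vals)
  }
  L
}

#' Signed canonical strength per region
#'
#' Summarises an edge-loading matrix into one positive and one negative
#' strength value per region.  Each loading is first modulated by the sign of
#' the group-mean correlation of its edge (an edge negatively correlated at
#' rest weakens the positive strength and feeds the negative one).  For every
#' region, the positive strength is the mean of the `top_n` largest positive
#' modulated loadings in its row, and the negative strength is minus the mean
#' absolute value of the `top_n` most negative ones; with fewer than `top_n`
#' available the mean is over those available, and with none the strength
#' is 0.  Diagonal entries are excluded.
#'
#' @param loading_matrix symmetric R x R matrix of edge loadings (`NA`
#'   entries, e.g. the diagonal, are ignored).
#' @param mean_corr_signs R x R matrix whose signs modulate the loadings
#'   (typically the group-mean connectivity matrix).
#' @param top_n how many top edges per region enter each mean (default 20);
#'   alternatively set `top_frac` to use a fraction of R.
#' @param top_frac optional fraction of regions overriding `top_n`
#'   (`top_n = round(top_frac * R)`).
#' @return A data frame with columns `region`, `positive_strength`
#'   (non-negative) and `negative_strength` (non-positive).
#' @export
cca_strength <- function(loading_matrix, mean_corr_signs, top_n = 20,
                         top_frac = NULL) {
  L <- as.matrix(loading_matrix)
  R <- nrow(L)
  if (!is.null(top_frac)) top_n <- max(1L, round(top_frac * R))
  if (top_n < 1) stopf("top_n must be >= 1")
  if (!identical(dim(L), dim(as.matrix(mean_corr_signs))))
    stopf("loading_matrix and mean_corr_signs must have the same shape")
  modulated <- L * sign(as.matrix(mean_corr_signs))
  diag(modulated) <- NA
  pos <- neg <- numeric(R)
  for (a in seq_len(R)) {
    row <- modulated[a, ]
    row <- row[!is.na(row)]
    pr <- sort(row[row > 0], decreasing = TRUE)
    nr <- sort(row[row < 0])
    pos[a] <- if (length(pr)) mean(pr[seq_len(min(top_n, length(pr)))]) else 0
    neg[a] <- if (length(nr)) -mean(abs(nr[seq_len(min(top_n, length(nr)))])) else 0
  }
  data.frame(region = rownames(L) %||% paste0("R", seq_len(R)),
             positive_strength = pos, negative_strength = neg,
             stringsAsFactors = FALSE)
}
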