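#' Singular value decomposition of a data block
#'
#' Decomposes `block = U_PC V'` where `U_PC = U diag(d)` are the
#' singular-value-scaled left singular vectors (the principal-component
#' scores) and the columns of `V` are the orthonormal principal loadings.
#'
#' @param block numeric matrix (subjects x variables), no missing values.
#' @return A list with `U_PC` (N x r scores), `singular_values`
#'   (non-increasing, length r) and `V` (P x r loadings), r = min(N, P).
#' @export
svd_decompose <- function(block) {
  block <- as.matrix(block)
  if (anyNA(block)) stopf("block contains missing values")
  s <- svd(block)
  list(U_PC = s$u %*% diag(s$d, length(s$d)),
       singular_values = s$d,
       V = s$v)
}

#' Project held-out subjects onto held-in principal loadings
#'
#' @param X_out numeric matrix of held-out rows (M x P).
#' @param V_k P x k matrix of principal loadings estimated on held-in rows.
#' @return The M x k score matrix `X_out %*% V_k`.
#' @export
project_heldout <- function(X_out, V_k) {
  X_out <- as.matrix(X_out); V_k <- as.matrix(V_k)
  if (ncol(X_out) != nrow(V_k))
    stopf("column count of X_out (%d) != row count of V_k (%d)",
          ncol(X_out), nrow(V_k))
  X_out %*% V_k
}

#' Naive reconstruction error of held-out data
#'
#' Squared Frobenius distance between the held-out rows and their projection
#' onto the span of the first k held-in loadings,
#' \eqn{\sum_i \|x_i - x_i V_k V_k'\|^2}.  Because the held-out data are used
#' in their own reconstruction, this error can only decrease as k grows, which
#' is why it cannot select a dimensionality; it is kept as a diagnostic curve.
#'
#' @inheritParams project_heldout
#' @return A single non-negative number.
#' @export
naive_press <- function(X_out, V_k) {
  X_out <- as.matrix(X_out); V_k <- as.matrix(V_k)
  R <- X_out - (X_out %*% V_k) %*% t(V_k)
  sum(R^2)
}

#' Leave-one-variable-out reconstruction of a held-out column
#'
#' Predicts column j of the held-out block without using that column:
#' the other columns are mapped to k-dimensional scores through the
#' Moore-Penrose pseudo-inverse of the loadings with row j removed (removing a
#' row of an orthonormal matrix breaks orthogonality, hence the
#' pseudo-inverse), then mapped back through the full loadings:
#' \deqn{\tilde X = X_{-j} [V_{-j,k}']^{+} V_k',}
#' of which column j is returned.
#'
#' @param X_out M x P held-out block.
#' @param V P x r matrix of held-in principal loadings (orthonormal columns).
#' @param k number of components, 1 <= k <= P-1.
#' @param j index of the column to predict.
#' @return Length-M numeric vector: the predicted j-th column.
#' @export
loo_reconstruct <- function(X_out, V, k, j) {
  X_out <- as.matrix(X_out); V <- as.matrix(V)
  P <- ncol(X_out)
  if (nrow(V) != P) stopf("V must have one row per variable")
  if (k >= P) stopf("k must be smaller than the number of variables (k = %d, P = %d)", k, P)
  if (k < 1 || j < 1 || j > P) stopf("invalid k or j")
  V_k <- V[, seq_len(k), drop = FALSE]
  V_mj <- V_k[-j, , drop = FALSE]
  scores <- X_out[, -j, drop = FALSE] %*% pinv(t(V_mj))
  drop(scores %*% V_k[j, ])
}

# Vectorised leave-one-variable-out predictions for all columns at once.
# For orthonormal V_k with rows v_j and leverages h_j = ||v_j||^2 < 1,
# Sherman-Morrison gives [V_{-j,k}']^+ = V_{-j,k}(I - v_j v_j')^{-1} and the
# prediction collapses to (S v_j - h_j x_j) / (1 - h_j) with S = X_out V_k.
# Columns with h_j ~ 1 fall back to the explicit pseudo-inverse.
loo_reconstruct_all <- function(X_out, V_k, tol = 1e-6) {
  S <- X_out %*% V_k
  h <- rowSums(V_k^2)
  denom <- 1 - h
  Pred <- (S %*% t(V_k) - sweep(X_out, 2L, h, "*")) /
    matrix(denom, nrow(X_out), ncol(X_out), byrow = TRUE)
  bad <- which(denom < tol)
  for (j in bad) {
    Pred[, j] <- loo_reconstruct(X_out, V_k, ncol(V_k), j)
  }
  Pred
}

#' Two-way cross-validated PRESS curve for one data block
#'
#' Estimates the intrinsic dimensionality of a variable block by a two-way
#' cross-validation: subjects are split into folds (subject-wise direction),
#' and within each fold every held-out column is predicted from the remaining
#' columns via the held-in principal loadings (variable-wise,
#' leave-one-column-out direction; see [loo_reconstruct()]).  The predicted
#' residual error sum of squares
#' \deqn{\mathrm{PRESS}(k) = \sum_{\mathrm{folds}} \sum_j \|x_j^{out} - \tilde
#' x_j^{out}\|^2} attains an interior minimum on signal-plus-noise data; the
#' chosen dimension is the smallest k attaining the minimum.  The naive
#' projection error ([naive_press()]), which decreases monotonically in k, is
#' returned alongside as a diagnostic.
#'
#' @param block numeric matrix (subjects x variables), no missing values.
#' @param n_folds number of subject folds (default 5).
#' @param rng_seed integer seed for the fold assignment.
#' @param k_max largest dimension scanned; defaults to
#'   `min(P - 1, smallest held-in row count - 1)`, the largest value for which
#'   the leave-one-column-out reconstruction is defined.
#' @param center_folds if `TRUE`, held-in and held-out rows are centred by the
#'   held-in column means within each fold (off by default: blocks arriving
#'   from [preprocess()] are already near mean-zero).
#' @return An object of class `press_curve`: list with `k_values`, `press`,
#'   `naive_press`, `chosen_k`.
#' @export
two_way_press <- function(block, n_folds = 5, rng_seed = 1, k_max = NULL,
                          center_folds = FALSE) {
  block <- as.matrix(block)
  if (anyNA(block)) stopf("block contains missing values")
  N <- nrow(block); P <- ncol(block)
  if (P < 2) stopf("PRESS dimension scan needs at least 2 variables")
  if (N < 2 * n_folds) stopf("need at least 2 subjects per fold (N = %d, folds = %d)",
                             N, n_folds)
  fold_id <- with_seed(rng_seed, sample(rep(seq_len(n_folds), length.out = N)))
  if (min(table(fold_id)) < 2) stopf("a fold has fewer than 2 subjects")
  min_heldin <- N - max(table(fold_id))
  k_hi <- min(P - 1, min_heldin - 1)
  if (!is.null(k_max)) k_hi <- min(k_hi, k_max)
  if (k_hi < 1) stopf("no admissible dimension: too few subjects or variables")
  k_values <- seq_len(k_hi)
  press <- numeric(k_hi)
  naive <- numeric(k_hi)
  for (f in seq_len(n_folds)) {
    X_in <- block[fold_id != f, , drop = FALSE]
    X_out <- block[fold_id == f, , drop = FALSE]
    if (center_folds) {
      mu <- colMeans(X_in)
      X_in <- sweep(X_in, 2L, mu, "-")
      X_out <- sweep(X_out, 2L, mu, "-")
    }
    V <- svd(X_in, nu = 0)$v
    for (k in k_values) {
      V_k <- V[, seq_len(k), drop = FALSE]
      Pred <- loo_reconstruct_all(X_out, V_k)
      press[k] <- press[k] + sum((X_out - Pred)^2)
      naive[k] <- naive[k] + naive_press(X_out, V_k)
    }
  }
  chosen_k <- which.min(press)  # which.min returns the smallest index on ties
  structure(list(k_values = k_values, press = press, naive_press = naive,
                 chosen_k = chosen_k),
            class = "press_curve")
}

#' @export
print.press_curve <- function(x, ...) {
  cat(sprintf("press_curve: k scanned 1..%d, chosen k = %d\n",
              max(x$k_values), x$chosen_k))
  invisible(x)
}

#' Stabilised dimension estimate over repeated fold randomisations
#'
#' Because the PRESS curve depends on the random fold assignment, the two-way
#' cross-validation is repeated with different fold randomisations and the
#' modal chosen dimension is reported (ties broken towards the smaller
#' dimension).  Repeat i uses seed `rng_seed + i`, so a run is exactly
#' reproducible from a single integer.
#'
#' @inheritParams two_way_press
#' @param n_repeats number of fold randomisations (default 50).
#' @return A list with `k_mode` (the modal dimension), `k_votes` (named
#'   integer vector: dimension -> vote count) and `runs` (the chosen k of each
#'   repeat).
#' @export
estimate_dimension <- function(block, n_folds = 5, n_repeats = 50, rng_seed = 1,
                               k_max = NULL, center_folds = FALSE) {
  if (n_repeats < 1) stopf("n_repeats must be >= 1")
  runs <- vapply(seq_len(n_repeats), function(i) {
    two_way_press(block, n_folds = n_folds, rng_seed = rng_seed + i,
                  k_max = k_max, center_folds = center_folds)$chosen_k
  }, integer(1))
  votes <- table(runs)
  ks <- as.integer(names(votes))
  best <- ks[votes == max(votes)]
  k_mode <- min(best)
  k_votes <- as.integer(votes)
  names(k_votes) <- names(votes)
  list(k_mode = k_mode, k_votes = k_votes, runs = runs)
}

#' Varimax rotation of principal loadings
#'
#' Orthogonal rotation maximising the varimax criterion (the sum over factors
#' of the variance of squared loadings) with Kaiser row-normalisation, to
#' simplify the loading structure for interpretation.  Column signs are fixed
#' deterministically: each rotated column's largest-magnitude entry is made
#' positive.  Rotation is orthogonal, so it never changes the column space of
#' the loadings nor any downstream canonical correlation.
#'
#' @param loadings P x k numeric matrix.
#' @return A list with `rotated` (P x k, equal to `loadings %*% R`) and `R`
#'   (k x k orthogonal rotation matrix).
#' @export
varimax_rotate <- function(loadings) {
  loadings <- as.matrix(loadings)
  if (!all(is.finite(loadings))) stopf("loadings contain non-finite values")
  k <- ncol(loadings)
  if (k < 1) stopf("loadings must have at least one column")
  if (k == 1) {
    rotated <- loadings
    R <- diag(1)
  } else {
    vm <- stats::varimax(loadings, normalize = TRUE, eps = 1e-6)
    R <- vm$rotmat
    rotated <- loadings %*% R
  }
  # deterministic sign convention
  for (i in seq_len(k)) {
    top <- which.max(abs(rotated[, i]))
    if (rotated[top, i] < 0) {
      rotated[, i] <- -rotated[, i]
      R[, i] <- -R[, i]
    }
  }
  list(rotated = rotated, R = R)
}

#' Domain-driven dimension reduction
#'
#' Applies, to each variable sub-domain in turn: dimension estimation by
#' repeated two-way cross-validated PRESS ([estimate_dimension()]), SVD of the
#' full block keeping the chosen number of loadings, varimax rotation
#' ([varimax_rotate()]), and projection of the data onto the rotated loadings.
#' The rotated components of all sub-domains are concatenated, in partition
#' order, into the reduced data space.  Sub-domains with a single variable
#' bypass cross-validation with dimension 1 and contribute that variable
#' unchanged.
#'
#' @param table a preprocessed [subject_table()] (no missing values).
#' @param partition named character vector mapping every variable name of
#'   `table` to a sub-domain label (see [read_domain_dictionary()]).
#' @param n_folds,n_repeats,rng_seed,center_folds passed to
#'   [estimate_dimension()]; sub-domain d uses seed
#'   `rng_seed + 1000 * (d - 1)` so repeats never collide across domains.
#' @param k_max optional cap on the scanned dimension per sub-domain.
#' @return An object of class `reduced_data`: list with `components` (N x
#'   K_total matrix), `factor_labels` (`"subdomain::factor_i"`), and `source`,
#'   a list of per-domain reductions each containing `subdomain_label`,
#'   `n_vars`, `chosen_k`, `loadings`, `singular_values`, `rotation`,
#'   `rotated_loadings`, `rotated_components`, `k_votes`,
#'   `variance_explained_pct` and `variable_names`.
#' @export
run_ddr <- function(table, partition, n_folds = 5, n_repeats = 50, rng_seed = 1,
                    k_max = NULL, center_folds = FALSE) {
  stopifnot(inherits(table, "subject_table"))
  if (anyNA(table$values)) stopf("table contains missing values; preprocess first")
  unmapped <- setdiff(table$variable_names, names(partition))
  if (length(unmapped))
    stopf("variables missing from the domain partition: %s",
          paste(utils::head(unmapped, 5), collapse = ", "))
  labels_by_var <- partition[table$variable_names]
  domain_labels <- unique(unname(labels_by_var))
  source <- vector("list", length(domain_labels))
  comp_list <- vector("list", length(domain_labels))
  label_list <- vector("list", length(domain_labels))
  for (d in seq_along(domain_labels)) {
    lab <- domain_labels[d]
    vars <- table$variable_names[labels_by_var == lab]
    block <- table$values[, vars, drop = FALSE]
    P <- length(vars)
    if (P == 1) {
      sv <- sqrt(sum(block^2))
      red <- list(subdomain_label = lab, n_vars = 1L, chosen_k = 1L,
                  loadings = matrix(1, 1, 1), singular_values = sv,
                  rotation = matrix(1, 1, 1),
                  rotated_loadings = matrix(1, 1, 1),
                  rotated_components = block,
                  k_votes = c(`1` = 1L),
                  press_curve = NULL,
                  variance_explained_pct = 100,
                  variable_names = vars)
    } else {
      est <- estimate_dimension(block, n_folds = n_folds, n_repeats = n_repeats,
                                rng_seed = rng_seed + 1000 * (d - 1),
                                k_max = k_max, center_folds = center_folds)
      k <- est$k_mode
      s <- svd(block)
      V_k <- s$v[, seq_len(k), drop = FALSE]
      vm <- varimax_rotate(V_k)
      rc <- block %*% vm$rotated
      ve <- 100 * sum(s$d[seq_len(k)]^2) / sum(s$d^2)
      # a representative PRESS curve at the base seed, for reporting
      pc <- two_way_press(block, n_folds = n_folds,
                          rng_seed = rng_seed + 1000 * (d - 1) + 1,
                          k_max = k_max, center_folds = center_folds)
      red <- list(subdomain_label = lab, n_vars = P, chosen_k = k,
                  loadings = V_k, singular_values = s$d[seq_len(k)],
                  rotation = vm$R, rotated_loadings = vm$rotated,
                  rotated_components = rc,
                  k_votes = est$k_votes,
                  press_curve = pc,
                  variance_explained_pct = ve,
                  variable_names = vars)
    }
    rownames(red$rotated_loadings) <- vars
    source[[d]] <- red
    comp_list[[d]] <- red$rotated_components
    label_list[[d]] <- paste0(lab, "::factor_", seq_len(red$chosen_k))
  }
  components <- do.call(cbind, comp_list)
  factor_labels <- unlist(label_list)
  colnames(components) <- factor_labels
  rownames(components) <- table$subject_ids
  structure(list(components = components, factor_labels = factor_labels,
                 source = source),
            class = "reduced_data")
}

#' @export
print.reduced_data <- function(x, ...) {
  ks <- vapply(x$source, `[[`, integer(1), "chosen_k")
  cat(sprintf("reduced_data: %d subjects, %d sub-domains, %d factors (k: %s)\n",
              nrow(x$components), length(x$source), ncol(x$components),
              paste(ks, collapse = ",")))
  invisible(x)
}

#' Eigen-spectrum against a column-shuffled null
#'
#' Compares the eigenvalues of a block's covariance matrix with the mean
#' eigen-spectrum of the same block after independently permuting the rows of
#' each column (which preserves every column's mean and variance but destroys
#' inter-column structure).  Where the null spectrum first meets or exceeds
#' the actual one, background noise takes over; that crossing is a convergent
#' diagnostic for the dimension chosen by the PRESS criterion, not a selector.
#'
#' @param block numeric matrix (subjects x variables).
#' @param n_shuffles number of independent column shufflings averaged into the
#'   null spectrum (default 50).
#' @param rng_seed integer seed.
#' @return A list with `eigspec` (covariance eigenvalues, decreasing),
#'   `null_eigspec` (mean shuffled eigenvalues) and `crossing_index` (first
#'   index where null >= actual, or `NA`).
#' @export
null_eigenspectrum <- function(block, n_shuffles = 50, rng_seed = 1) {
  block <- as.matrix(block)
  N <- nrow(block); P <- ncol(block)
  eigspec <- svd(center_cols(block), nu = 0, nv = 0)$d^2 / (N - 1)
  eigspec <- c(eigspec, rep(0, P - length(eigspec)))[seq_len(P)]
  null_acc <- numeric(P)
  with_seed(rng_seed, {
    for (s in seq_len(n_shuffles)) {
      shuf <- apply(block, 2L, sample)
      d2 <- svd(center_cols(shuf), nu = 0, nv = 0)$d^2 / (N - 1)
      null_acc <- null_acc + c(d2, rep(0, P - length(d2)))[seq_len(P)]
    }
  })
  null_eigspec <- null_acc / n_shuffles
  cross <- which(null_eigspec >= eigspec)
  list(eigspec = eigspec, null_eigspec = null_eigspec,
       crossing_index = if (length(cross)) cross[1] else NA_integer_)
}
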