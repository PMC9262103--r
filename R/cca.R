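# inverse square root of a covariance matrix via eigendecomposition; a
# relative eigenvalue below `floor_rel` is treated as rank deficiency and is a
# hard error (no silent ridge) -- the caller should reduce dimension instead.
inv_sqrt_cov <- function(S, floor_rel = 1e-10, what = "block") {
  e <- eigen(S, symmetric = TRUE)
  if (any(e$values <= floor_rel * max(e$values)))
    stopf("%s covariance is (numerically) rank-deficient; reduce its dimension before CCA",
          what)
  e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
}

# centre and whiten both blocks; canonical correlations are the singular
# values of crossprod(Xw, Yw) / (N - 1)
cca_whiten <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stopf("X and Y must have the same number of rows")
  N <- nrow(X)
  if (N <= ncol(X) || N <= ncol(Y))
    stopf("CCA needs more subjects than variables in each block (N = %d, p = %d, q = %d)",
          N, ncol(X), ncol(Y))
  Xc <- center_cols(X); Yc <- center_cols(Y)
  Wx <- inv_sqrt_cov(crossprod(Xc) / (N - 1), what = "X")
  Wy <- inv_sqrt_cov(crossprod(Yc) / (N - 1), what = "Y")
  list(Xc = Xc, Yc = Yc, Xw = Xc %*% Wx, Yw = Yc %*% Wy, Wx = Wx, Wy = Wy, N = N)
}

#' Canonical correlation analysis
#'
#' Fits standard CCA between two blocks sharing subjects: finds weight
#' matrices A, B such that the canonical variables `P = X A` and `Q = Y B`
#' (columns unit-variance, mutually uncorrelated within each block) are
#' maximally correlated pair by pair.  Solved by whitening each centred block
#' by the inverse square root of its covariance and taking the SVD of the
#' whitened cross-covariance.  Weight signs are fixed so the
#' largest-magnitude entry of each column of A is positive (B flipped in
#' step, preserving non-negative canonical correlations).
#'
#' @param X,Y numeric matrices (subjects x variables), same rows; each block
#'   must have more rows than columns and full column rank.
#' @return An object of class `cca_model`: list with `weights_A` (p x m),
#'   `weights_B` (q x m), `variables_P`, `variables_Q` (N x m canonical
#'   variables), `correlations` (m non-increasing values in \[0, 1\]),
#'   `x_center`, `y_center`, and `m = min(p, q)`.
#' @export
fit_cca <- function(X, Y) {
  w <- cca_whiten(X, Y)
  m <- min(ncol(w$Xw), ncol(w$Yw))
  s <- svd(crossprod(w$Xw, w$Yw) / (w$N - 1), nu = m, nv = m)
  A <- w$Wx %*% s$u[, seq_len(m), drop = FALSE]
  B <- w$Wy %*% s$v[, seq_len(m), drop = FALSE]
  for (i in seq_len(m)) {
    top <- which.max(abs(A[, i]))
    if (A[top, i] < 0) {
      A[, i] <- -A[, i]
      B[, i] <- -B[, i]
    }
  }
  structure(list(weights_A = A, weights_B = B,
                 variables_P = w$Xc %*% A, variables_Q = w$Yc %*% B,
                 correlations = pmin(pmax(s$d[seq_len(m)], 0), 1),
                 x_center = colMeans(as.matrix(X)),
                 y_center = colMeans(as.matrix(Y)),
                 m = m),
            class = "cca_model")
}

#' @export
print.cca_model <- function(x, ...) {
  cat(sprintf("cca_model: %d canonical pairs; correlations: %s\n", x$m,
              paste(sprintf("%.3f", x$correlations), collapse = ", ")))
  invisible(x)
}

#' Further PCA reduction of a concatenated factor block
#'
#' When the concatenated domain factors of a block are too numerous for CCA
#' (for example connectivity blocks whose total domain dimension exceeds the
#' number of subjects), the block is reduced once more by ordinary PCA,
#' keeping the leading principal-component scores.  The centring vector and
#' rotation are attached as attributes so held-out subjects can be projected
#' with the training reduction.
#'
#' @param reduced a `reduced_data` object from [run_ddr()] or a plain numeric
#'   matrix.
#' @param target_dim number of principal components to keep.
#' @return N x target_dim score matrix with attributes `center` and
#'   `rotation`.
#' @export
reduce_block_pca <- function(reduced, target_dim) {
  M <- if (inherits(reduced, "reduced_data")) reduced$components else as.matrix(reduced)
  if (target_dim > ncol(M))
    stopf("target_dim (%d) exceeds available columns (%d)", target_dim, ncol(M))
  ctr <- colMeans(M)
  Mc <- sweep(M, 2L, ctr, "-")
  s <- svd(Mc, nu = 0)
  rot <- s$v[, seq_len(target_dim), drop = FALSE]
  scores <- Mc %*% rot
  colnames(scores) <- paste0("PC", seq_len(target_dim))
  attr(scores, "center") <- ctr
  attr(scores, "rotation") <- rot
  scores
}

# project new rows with a training reduce_block_pca
apply_block_pca <- function(scores_train, newdata) {
  M <- if (inherits(newdata, "reduced_data")) newdata$components else as.matrix(newdata)
  sweep(M, 2L, attr(scores_train, "center"), "-") %*% attr(scores_train, "rotation")
}

#' Canonical loadings (structure coefficients)
#'
#' Correlates each canonical variable of one side of a fitted model with
#' (a) the observed variables of that side and (b) the reduced factors fed
#' into CCA.  The observed-variable loadings drive variable-importance
#' interpretation; the factor loadings expose the contribution of each
#' sub-domain.  The per-component variance explained is the mean across
#' observed variables of the squared loading, as a percentage.
#'
#' @param model a [fit_cca()] model.
#' @param observed a [subject_table()] or matrix of observed variables (same
#'   subjects, same order as the fit); may be `NULL`.
#' @param factors a `reduced_data` object or matrix of the CCA input factors;
#'   may be `NULL`.
#' @param side `"x"` to correlate against the canonical variables `P` of the
#'   first block, `"y"` for `Q`.
#' @return A list with `observed_loadings` (variables x m or `NULL`),
#'   `factor_loadings` (factors x m or `NULL`) and `ve_pct` (length m, `NULL`
#'   without observed data).  Zero-variance variables get loading 0 with a
#'   warning.
#' @export
canonical_loadings <- function(model, observed = NULL, factors = NULL,
                               side = c("x", "y")) {
  side <- match.arg(side)
  canvar <- if (side == "x") model$variables_P else model$variables_Q
  load_against <- function(M) {
    M <- if (inherits(M, "subject_table")) M$values
    else if (inherits(M, "reduced_data")) M$components
    else as.matrix(M)
    if (nrow(M) != nrow(canvar))
      stopf("loading target has %d rows but the model was fit on %d subjects",
            nrow(M), nrow(canvar))
    sds <- apply(M, 2L, sd)
    L <- matrix(0, ncol(M), ncol(canvar),
                dimnames = list(colnames(M), paste0("CCA", seq_len(ncol(canvar)))))
    ok <- sds > 0
    if (any(!ok))
      warnf("zero-variance variable(s) get loading 0: %s",
            paste(colnames(M)[!ok], collapse = ", "))
    if (any(ok)) L[ok, ] <- cor(M[, ok, drop = FALSE], canvar)
    L
  }
  obs_L <- if (!is.null(observed)) load_against(observed)
  fac_L <- if (!is.null(factors)) load_against(factors)
  ve <- if (!is.null(obs_L)) 100 * colMeans(obs_L^2)
  list(observed_loadings = obs_L, factor_loadings = fac_L, ve_pct = ve)
}

# fold- or block-respecting row permutation of 1..N
permute_rows <- function(N, blocks = NULL, scheme = c("exchange", "within")) {
  if (is.null(blocks)) return(sample.int(N))
  scheme <- match.arg(scheme)
  idx_by_block <- split(seq_len(N), blocks)
  if (scheme == "exchange") {
    sizes <- lengths(idx_by_block)
    if (length(unique(sizes)) != 1)
      stopf("exchangeability blocks have unequal sizes; use scheme = 'within'")
    perm <- unlist(idx_by_block[sample.int(length(idx_by_block))], use.names = FALSE)
    out <- integer(N)
    out[unlist(idx_by_block, use.names = FALSE)] <- perm
    out
  } else {
    out <- seq_len(N)
    for (ib in idx_by_block) out[ib] <- ib[sample.int(length(ib))]
    out
  }
}

#' Permutation test for canonical correlations
#'
#' Rows of the second block are permuted `n_perm` times; for each permutation
#' the first canonical correlation of the refitted CCA is recorded as the
#' null statistic (max-statistic scheme, controlling family-wise error across
#' components).  Every observed canonical correlation is compared against
#' this common null:
#' \deqn{p_i = (1 + \#\{r^{null}_1 \ge r_i\}) / (1 + n_{perm}).}
#' The number of significant pairs is counted sequentially from the first
#' component, stopping at the first non-significant one.  When family blocks
#' are supplied, whole blocks are exchanged (equal sizes) or rows permuted
#' within blocks, respecting dependence.
#'
#' @param X,Y blocks as in [fit_cca()].
#' @param n_perm number of permutations (default 199).
#' @param alpha significance level (default 0.05).
#' @param blocks optional vector of family/exchangeability labels, one per
#'   subject.
#' @param scheme `"exchange"` (whole-block exchange, equal block sizes) or
#'   `"within"` (permute within blocks).
#' @param rng_seed integer seed.
#' @param per_component if `TRUE`, component i is instead compared against
#'   the null distribution of the i-th permuted canonical correlation
#'   (no family-wise control).
#' @return Object of class `permutation_result`: list with `n_perm`,
#'   `null_max_corr` (the permuted first canonical correlations),
#'   `correlations`, `p_values`, `n_significant`, `alpha`.
#' @export
permutation_test <- function(X, Y, n_perm = 199, alpha = 0.05, blocks = NULL,
                             scheme = c("exchange", "within"), rng_seed = 1,
                             per_component = FALSE) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) stopf("n_perm must be >= 1")
  w <- cca_whiten(X, Y)
  m <- min(ncol(w$Xw), ncol(w$Yw))
  robs <- svd(crossprod(w$Xw, w$Yw) / (w$N - 1), nu = 0, nv = 0)$d[seq_len(m)]
  robs <- pmin(pmax(robs, 0), 1)
  null_stat <- if (per_component) matrix(0, n_perm, m) else numeric(n_perm)
  with_seed(rng_seed, {
    for (b in seq_len(n_perm)) {
      idx <- permute_rows(w$N, blocks, scheme)
      # permuting rows of the centred, whitened block is equivalent to
      # permuting Y before centring: column means are permutation-invariant
      d <- svd(crossprod(w$Xw, w$Yw[idx, , drop = FALSE]) / (w$N - 1),
               nu = 0, nv = 0)$d
      if (per_component) null_stat[b, ] <- d[seq_len(m)] else null_stat[b] <- d[1]
    }
  })
  p_values <- vapply(seq_len(m), function(i) {
    ref <- if (per_component) null_stat[, i] else null_stat
    (1 + sum(ref >= robs[i])) / (1 + n_perm)
  }, numeric(1))
  n_sig <- 0L
  for (i in seq_len(m)) {
    if (p_values[i] < alpha) n_sig <- n_sig + 1L else break
  }
  structure(list(n_perm = n_perm,
                 null_max_corr = if (per_component) null_stat[, 1] else null_stat,
                 null_stat = null_stat,
                 correlations = robs, p_values = p_values,
                 n_significant = n_sig, alpha = alpha,
                 per_component = per_component),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: %d perms, %d significant pair(s) at alpha = %g\n",
              x$n_perm, x$n_significant, x$alpha))
  cat("  p-values:", paste(sprintf("%.4f", x$p_values), collapse = ", "), "\n")
  invisible(x)
}

#' DDR-CCA analysis of two reduced blocks
#'
#' Glues the post-reduction steps together: optionally reduces the larger
#' block further by PCA ([reduce_block_pca()]), fits CCA on the factor
#' blocks, computes canonical loadings on observed variables and on the CCA
#' input factors for both sides, and runs the permutation significance test.
#'
#' @param sm_reduced,bm_reduced `reduced_data` objects (or matrices) for the
#'   two blocks.
#' @param bm_target_dim if not `NULL`, the second block is PCA-reduced to this
#'   dimension before CCA.
#' @param n_perm,alpha,blocks,scheme,rng_seed passed to [permutation_test()].
#' @param sm_observed,bm_observed optional [subject_table()]s of
#'   post-preprocessing observed variables for loading computation.
#' @return A list with `model` ([fit_cca()]), `loadings_sm`, `loadings_bm`
#'   ([canonical_loadings()]) and `permutation` ([permutation_test()]), plus
#'   `bm_pca` (the PCA reduction, or `NULL`).
#' @export
run_cca_pipeline <- function(sm_reduced, bm_reduced, bm_target_dim = NULL,
                             n_perm = 199, alpha = 0.05, blocks = NULL,
                             scheme = c("exchange", "within"), rng_seed = 1,
                             sm_observed = NULL, bm_observed = NULL) {
  X <- if (inherits(sm_reduced, "reduced_data")) sm_reduced$components else as.matrix(sm_reduced)
  bm_pca <- NULL
  if (!is.null(bm_target_dim)) {
    bm_pca <- reduce_block_pca(bm_reduced, bm_target_dim)
    Y <- bm_pca
  } else {
    Y <- if (inherits(bm_reduced, "reduced_data")) bm_reduced$components else as.matrix(bm_reduced)
  }
  model <- fit_cca(X, Y)
  loadings_sm <- canonical_loadings(model, observed = sm_observed,
                                    factors = sm_reduced, side = "x")
  loadings_bm <- canonical_loadings(model, observed = bm_observed,
                                    factors = bm_reduced, side = "y")
  perm <- permutation_test(X, Y, n_perm = n_perm, alpha = alpha,
                           blocks = blocks, scheme = scheme, rng_seed = rng_seed)
  list(model = model, loadings_sm = loadings_sm, loadings_bm = loadings_bm,
       permutation = perm, bm_pca = bm_pca)
}
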