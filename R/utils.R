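#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cov median pnorm qnorm quantile rnorm runif sd var
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `expr` under a fixed Mersenne-Twister seed, restoring the caller's
# RNG state afterwards.  All stochastic routines in the package route their
# randomness through this helper so that one integer seed reproduces a run
# regardless of the surrounding RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  }
  force(expr)
}

# Moore-Penrose pseudo-inverse via SVD.  Singular values below
# `tol * max(d)` are treated as zero.
pinv <- function(A, tol = 1e-12) {
  A <- as.matrix(A)
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# column-wise scaling without the attr baggage of scale()
center_cols <- function(X) {
  sweep(X, 2L, colMeans(X), "-")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
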