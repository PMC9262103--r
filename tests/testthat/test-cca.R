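test_that("fit_cca recovers exact and closed-form cases", {
  set.seed(30)
  X <- matrix(rnorm(200), 50, 4)
  mXX <- fit_cca(X, X)
  expect_equal(mXX$correlations, rep(1, 4), tolerance = 1e-8)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40)
  m11 <- fit_cca(cbind(x), cbind(y))
  expect_equal(m11$correlations, abs(cor(x, y)), tolerance = 1e-10)
})

test_that("fit_cca matches the generalized-eigenproblem oracle and cancor", {
  set.seed(31)
  for (rep in 1:5) {
    X <- matrix(rnorm(150), 50, 3)
    Y <- matrix(rnorm(200), 50, 4)
    m <- fit_cca(X, Y)
    expect_equal(m$correlations, cca_eigen_oracle(X, Y), tolerance = 1e-8)
    expect_equal(m$correlations, cancor(X, Y)$cor, tolerance = 1e-8)
  }
})

test_that("canonical variables are unit variance, uncorrelated within block, paired across", {
  set.seed(32)
  X <- matrix(rnorm(300), 60, 5)
  Y <- matrix(rnorm(240), 60, 4)
  m <- fit_cca(X, Y)
  expect_equal(apply(m$variables_P, 2, sd), rep(1, 4), tolerance = 1e-6)
  expect_equal(cor(m$variables_P), diag(4), tolerance = 1e-6)
  expect_equal(cor(m$variables_Q), diag(4), tolerance = 1e-6)
  expect_equal(diag(cor(m$variables_P, m$variables_Q)), m$correlations,
               tolerance = 1e-8)
  expect_true(all(diff(m$correlations) <= 1e-12))
  # symmetry in the two blocks
  m2 <- fit_cca(Y, X)
  expect_equal(m2$correlations, m$correlations, tolerance = 1e-10)
})

test_that("CCA is invariant to invertible transforms and degrades for nested reductions", {
  set.seed(33)
  X <- matrix(rnorm(400), 80, 5)
  Y <- matrix(rnorm(320), 80, 4)
  base <- fit_cca(X, Y)$correlations
  Tx <- matrix(rnorm(25), 5); while (abs(det(Tx)) < 0.1) Tx <- matrix(rnorm(25), 5)
  expect_lt(max(abs(fit_cca(X %*% Tx, Y)$correlations - base)), 1e-10)
  signs <- diag(c(1, -1, 1, -1))
  expect_lt(max(abs(fit_cca(X, Y %*% signs)$correlations - base)), 1e-10)
  # nested PCA reduction weakly decreases every canonical correlation
  for (d in 3:4) {
    Xr <- reduce_block_pca(X, d)
    sub <- fit_cca(Xr, Y)$correlations
    expect_true(all(sub <= base[seq_along(sub)] + 1e-10))
  }
  expect_error(fit_cca(cbind(X, X[, 1]), Y), "rank-deficient")
})

test_that("reduce_block_pca keeps the top components and is lossless at full rank", {
  set.seed(34)
  M <- matrix(rnorm(200), 50, 4)
  full <- reduce_block_pca(M, 4)
  Y <- matrix(rnorm(150), 50, 3)
  expect_lt(max(abs(fit_cca(full, Y)$correlations - fit_cca(M, Y)$correlations)),
            1e-8)
  # rank-2 input reconstructs exactly from 2 components
  M2 <- matrix(rnorm(100), 50, 2) %*% matrix(rnorm(8), 2, 4)
  r2 <- reduce_block_pca(M2, 2)
  recon <- r2 %*% t(attr(r2, "rotation"))
  recon <- sweep(recon, 2, attr(r2, "center"), "+")
  expect_lt(max(abs(recon - M2)), 1e-8)
  ve <- apply(reduce_block_pca(M, 4), 2, var)
  expect_true(all(diff(ve) <= 1e-10))
  expect_error(reduce_block_pca(M, 5), "exceeds")
})

test_that("canonical loadings are correlations with the canonical variables", {
  set.seed(35)
  N <- 200
  X <- matrix(rnorm(N * 3), N, 3)
  Y <- cbind(X[, 1] + rnorm(N, sd = 0.1), matrix(rnorm(N * 2), N, 2))
  m <- fit_cca(X, Y)
  obs <- cbind(v1 = m$variables_P[, 1] * 2 + 3, v2 = rnorm(N))
  L <- canonical_loadings(m, observed = obs, side = "x")
  expect_equal(abs(L$observed_loadings["v1", 1]), 1, tolerance = 1e-10)
  expect_true(all(abs(L$observed_loadings) <= 1 + 1e-12))
  expect_equal(L$ve_pct, 100 * colMeans(L$observed_loadings^2))
  # flipping one observed variable flips exactly its loading row
  obs2 <- obs; obs2[, "v2"] <- -obs2[, "v2"]
  L2 <- canonical_loadings(m, observed = obs2, side = "x")
  expect_equal(L2$observed_loadings["v2", ], -L$observed_loadings["v2", ])
  expect_equal(L2$observed_loadings["v1", ], L$observed_loadings["v1", ])
  # zero-variance variable warns and gets loading 0
  obs3 <- cbind(obs, flat = rep(1, N))
  expect_warning(L3 <- canonical_loadings(m, observed = obs3, side = "x"),
                 "zero-variance")
  expect_equal(unname(L3$observed_loadings["flat", ]), rep(0, 3))
})

test_that("ve_pct approaches 100/P when one variable is the canonical variable", {
  set.seed(36)
  N <- 5000
  X <- matrix(rnorm(N * 2), N, 2)
  Y <- cbind(X[, 1] + rnorm(N, sd = 0.2), rnorm(N))
  m <- fit_cca(X, Y)
  P <- 5
  obs <- cbind(m$variables_P[, 1], matrix(rnorm(N * (P - 1)), N))
  L <- canonical_loadings(m, observed = obs, side = "x")
  expect_equal(unname(L$ve_pct[1]), 100 / P, tolerance = 0.2)
})

test_that("permutation test bounds, identity case, and block validation", {
  set.seed(37)
  X <- matrix(rnorm(200), 50, 4)
  pt <- permutation_test(X, X, n_perm = 99, rng_seed = 1)
  expect_equal(pt$p_values[1], 1 / 100)
  expect_true(all(pt$p_values >= 1 / 100) && all(pt$p_values <= 1))
  # max-statistic p-values are non-decreasing across components
  expect_true(all(diff(pt$p_values) >= -1e-12))
  Y <- matrix(rnorm(150), 50, 3)
  blocks_bad <- rep(c("a", "b"), c(20, 30))
  expect_error(permutation_test(X, Y, n_perm = 9, blocks = blocks_bad,
                                scheme = "exchange"), "unequal")
  # within-block scheme accepts unequal blocks
  ptw <- permutation_test(X, Y, n_perm = 9, blocks = blocks_bad,
                          scheme = "within", rng_seed = 2)
  expect_equal(length(ptw$null_max_corr), 9L)
})

test_that("whole-block exchange permutes families intact", {
  set.seed(38)
  N <- 40
  blocks <- rep(paste0("f", 1:10), each = 4)
  idx <- ddrcca:::permute_rows(N, blocks, "exchange")
  expect_equal(sort(idx), 1:N)
  # members of a family stay adjacent as a unit
  moved <- split(idx, blocks)
  for (fam in moved) expect_equal(length(unique((fam - 1) %/% 4)), 1L)
})

test_that("run_cca_pipeline is invariant to varimax rotation of its inputs", {
  set.seed(39)
  pt <- planted_tables(0.6, 300, seed = 40)
  red_sm <- run_ddr(pt$sm_table, pt$sm_partition, n_repeats = 3, rng_seed = 4)
  red_bm <- run_ddr(pt$bm_table, pt$bm_partition, n_repeats = 3, rng_seed = 5)
  res <- run_cca_pipeline(red_sm, red_bm, n_perm = 19, rng_seed = 6,
                          sm_observed = pt$sm_table, bm_observed = pt$bm_table)
  # unrotated: undo each domain rotation (orthogonal, invertible)
  unrot_sm <- do.call(cbind, lapply(red_sm$source, function(s)
    pt$sm_table$values[, s$variable_names, drop = FALSE] %*% s$loadings))
  r_unrot <- fit_cca(unrot_sm, red_bm$components)
  expect_lt(max(abs(r_unrot$correlations - res$model$correlations)), 1e-10)
  # block-role swap leaves correlations unchanged
  res_swap <- fit_cca(red_bm$components, red_sm$components)
  expect_lt(max(abs(res_swap$correlations - res$model$correlations)), 1e-10)
  expect_s3_class(res$permutation, "permutation_result")
  expect_equal(dim(res$loadings_sm$observed_loadings),
               c(ncol(pt$sm_table$values), res$model$m))
})
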