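test_that("svd_decompose reconstructs the block with scaled scores", {
  expect_equal(svd_decompose(diag(3))$singular_values, rep(1, 3))
  u <- c(1, 2, 2); v <- c(3, 4)
  s1 <- svd_decompose(u %*% t(v))
  expect_equal(s1$singular_values[1], sqrt(sum(u^2)) * sqrt(sum(v^2)))
  expect_lt(s1$singular_values[2], 1e-10)
  set.seed(10)
  X <- matrix(rnorm(24), 6, 4)
  s <- svd_decompose(X)
  expect_lt(max(abs(X - s$U_PC %*% t(s$V))), 1e-8)
  expect_equal(crossprod(s$V), diag(4), tolerance = 1e-8)
})

test_that("project_heldout is plain projection onto held-in loadings", {
  set.seed(11)
  X <- matrix(rnorm(6), 2, 3)
  expect_equal(project_heldout(X, diag(3)[, 1:2]), X[, 1:2])
  v1 <- c(1, 0, 1) / sqrt(2)
  expect_equal(project_heldout(X, matrix(v1)), X %*% v1)
})

test_that("naive_press is the squared projection residual", {
  X <- rbind(c(1, 0), c(0, 1))
  expect_equal(naive_press(X, matrix(c(1, 0))), 1)
  # full basis or in-span rows give zero error
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  set.seed(12)
  X2 <- matrix(rnorm(15), 5, 3)
  expect_lt(naive_press(X2, Q), 1e-16)
  V2 <- Q[, 1:2]
  X_in_span <- matrix(rnorm(8), 4, 2) %*% t(V2)
  expect_lt(naive_press(X_in_span, V2), 1e-16)
})

test_that("loo_reconstruct predicts a column without using it", {
  # hand case: P = 2, k = 1, V_1 = (1, 1)/sqrt(2), X = [1 1]
  V <- cbind(c(1, 1) / sqrt(2), c(1, -1) / sqrt(2))
  expect_equal(loo_reconstruct(rbind(c(1, 1)), V, k = 1, j = 1), 1)
  # prediction of column j is invariant to changes of column j
  set.seed(13)
  X <- matrix(rnorm(40), 8, 5)
  Vr <- svd(matrix(rnorm(60), 12, 5))$v
  base <- loo_reconstruct(X, Vr, k = 2, j = 3)
  X2 <- X; X2[, 3] <- rnorm(8) * 100
  expect_equal(loo_reconstruct(X2, Vr, k = 2, j = 3), base)
  # exact recovery of noiseless rank-k data
  scores <- matrix(rnorm(20), 10, 2)
  Xr <- scores %*% t(Vr[, 1:2])
  for (j in 1:5)
    expect_lt(max(abs(loo_reconstruct(Xr, Vr, k = 2, j = j) - Xr[, j])), 1e-6)
  expect_error(loo_reconstruct(X, Vr, k = 5, j = 1), "smaller")
})

test_that("loo_reconstruct agrees with an independently coded pseudo-inverse oracle", {
  set.seed(14)
  for (rep in 1:10) {
    X_in <- matrix(rnorm(100), 20, 5)
    V <- svd(X_in)$v
    X_out <- matrix(rnorm(50), 10, 5)
    k <- sample(1:4, 1); j <- sample(1:5, 1)
    expect_lt(max(abs(loo_reconstruct(X_out, V, k, j) - loo_oracle(X_out, V, k, j))),
              1e-10)
  }
})

test_that("the vectorised leave-one-out path matches the definitional one", {
  set.seed(15)
  X <- matrix(rnorm(60), 12, 5)
  V <- svd(matrix(rnorm(150), 30, 5))$v
  for (k in 1:4) {
    fast <- ddrcca:::loo_reconstruct_all(X, V[, 1:k, drop = FALSE])
    slow <- sapply(1:5, function(j) loo_reconstruct(X, V, k, j))
    expect_lt(max(abs(fast - slow)), 1e-8)
  }
})

test_that("two_way_press selects the true dimension on clean low-rank data", {
  set.seed(16)
  u <- rnorm(60); v <- rnorm(6)
  pc <- two_way_press(u %*% t(v) + matrix(rnorm(360, sd = 1e-6), 60), rng_seed = 5)
  expect_equal(pc$chosen_k, 1L)
  expect_equal(pc$k_values, 1:5)
  blk <- rank_block(120, 10, 3, seed = 17)
  pc3 <- two_way_press(blk, rng_seed = 5)
  expect_equal(pc3$chosen_k, 3L)
  # interior minimum: PRESS rises again after the truth on signal-plus-noise
  expect_gt(pc3$press[9], pc3$press[3])
})

test_that("the naive curve is non-increasing while two-way PRESS is not forced to be", {
  set.seed(18)
  for (rep in 1:5) {
    blk <- matrix(rnorm(400), 50, 8)
    pc <- two_way_press(blk, rng_seed = rep)
    expect_true(all(diff(pc$naive_press) <= 1e-10))
  }
  blk <- rank_block(100, 8, 2, seed = 19)
  pc <- two_way_press(blk, rng_seed = 1)
  expect_true(all(diff(pc$naive_press) <= 1e-10))
  expect_false(all(diff(pc$press) <= 0))
})

test_that("two_way_press is reproducible and validates its inputs", {
  blk <- rank_block(40, 5, 1, seed = 20)
  a <- two_way_press(blk, rng_seed = 9)
  b <- two_way_press(blk, rng_seed = 9)
  expect_identical(a$press, b$press)
  expect_error(two_way_press(blk[1:8, ], n_folds = 5), "2 subjects per fold")
  expect_error(two_way_press(blk[, 1, drop = FALSE]), "2 variables")
})

test_that("estimate_dimension takes the mode with ties towards the smaller k", {
  blk <- rank_block(80, 6, 2, seed = 21)
  one <- estimate_dimension(blk, n_repeats = 1, rng_seed = 30)
  expect_equal(one$k_mode, two_way_press(blk, rng_seed = 31)$chosen_k)
  many <- estimate_dimension(blk, n_repeats = 7, rng_seed = 30)
  expect_equal(sum(many$k_votes), 7L)
  votes <- table(many$runs)
  top <- as.integer(names(votes)[votes == max(votes)])
  expect_equal(many$k_mode, min(top))
})

test_that("varimax_rotate improves the criterion, stays orthogonal, fixes signs", {
  varimax_crit <- function(L) {
    # Kaiser row-normalised varimax criterion
    h <- sqrt(rowSums(L^2)); Ln <- L / h
    sum(apply(Ln^2, 2, var))
  }
  set.seed(22)
  L <- matrix(rnorm(16), 8, 2)
  res <- varimax_rotate(L)
  expect_equal(crossprod(res$R), diag(2), tolerance = 1e-8)
  expect_equal(res$rotated, L %*% res$R)
  expect_gte(varimax_crit(res$rotated) + 1e-12, varimax_crit(L))
  # grid-search oracle over the rotation angle (0.1 degree steps)
  angles <- seq(0, pi / 2, by = 0.1 * pi / 180)
  grid_best <- max(vapply(angles, function(a) {
    R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2)
    varimax_crit(L %*% R)
  }, numeric(1)))
  expect_gte(varimax_crit(res$rotated) + 1e-6, grid_best)
  # sign convention: largest-magnitude entry of each column positive
  expect_true(all(apply(res$rotated, 2, function(col) col[which.max(abs(col))] > 0)))
  # k = 1 is identity up to sign
  one <- varimax_rotate(matrix(c(-3, 1, 0)))
  expect_equal(one$rotated, matrix(c(3, -1, 0)))
})

test_that("already-simple loadings are left alone by varimax up to sign/permutation", {
  L <- rbind(c(0.9, 0), c(0.8, 0), c(0, 0.7), c(0, 0.6))
  res <- varimax_rotate(L)
  recovered <- abs(res$rotated)
  # same set of columns up to permutation
  d1 <- min(max(abs(recovered[, 1] - abs(L[, 1]))), max(abs(recovered[, 1] - abs(L[, 2]))))
  expect_lt(d1, 1e-6)
})

test_that("run_ddr reduces each sub-domain and concatenates rotated components", {
  set.seed(23)
  pt <- planted_tables(0, 120, seed = 24, P = 6, rank = 1)
  red <- run_ddr(pt$sm_table, pt$sm_partition, n_repeats = 3, rng_seed = 2)
  expect_equal(ncol(red$components), 2L)  # two rank-1 domains
  expect_equal(red$factor_labels,
               c("sm_d1::factor_1", "sm_d2::factor_1"))
  # rotated components span the unrotated score space
  src <- red$source[[1]]
  vars <- src$variable_names
  scores <- pt$sm_table$values[, vars] %*% src$loadings
  proj <- lm.fit(src$rotated_components, scores)$residuals
  expect_lt(max(abs(proj)), 1e-8)
  expect_equal(src$variance_explained_pct,
               100 * sum(src$singular_values^2) /
                 sum(svd(pt$sm_table$values[, vars])$d^2))
})

test_that("a single-variable sub-domain passes through unchanged with k = 1", {
  set.seed(25)
  vals <- cbind(a1 = rnorm(60), a2 = rnorm(60), solo = rnorm(60))
  part <- c(a1 = "A", a2 = "A", solo = "solo")
  red <- run_ddr(subject_table(vals), part, n_repeats = 3, rng_seed = 1)
  solo_col <- red$components[, red$factor_labels == "solo::factor_1"]
  expect_equal(unname(solo_col), unname(vals[, "solo"]))
  expect_equal(red$source[[2]]$chosen_k, 1L)
  expect_equal(red$source[[2]]$variance_explained_pct, 100)
})

test_that("column sign flips change neither PRESS curves nor chosen dimensions", {
  blk <- rank_block(100, 8, 2, seed = 26)
  flip <- blk %*% diag(c(1, -1, 1, -1, -1, 1, 1, -1))
  a <- two_way_press(blk, rng_seed = 3)
  b <- two_way_press(flip, rng_seed = 3)
  expect_lt(max(abs(a$press - b$press)), 1e-10)
  expect_lt(max(abs(a$naive_press - b$naive_press)), 1e-10)
  expect_identical(a$chosen_k, b$chosen_k)
})

test_that("null eigen-spectrum preserves total variance and crosses near the rank", {
  blk <- rank_block(150, 10, 3, seed = 27)
  ns <- null_eigenspectrum(blk, n_shuffles = 30, rng_seed = 5)
  expect_lt(abs(sum(ns$eigspec) - sum(ns$null_eigspec)), 1e-8)
  expect_true(ns$crossing_index %in% 3:5)
  # pure noise: background takes over within the first components in the
  # majority of seeds (the crossing fluctuates with the noise realisation)
  early <- vapply(1:10, function(s) {
    noise <- matrix(rnorm(1000), 100, 10)
    null_eigenspectrum(noise, n_shuffles = 20, rng_seed = s)$crossing_index <= 2
  }, logical(1))
  expect_gt(mean(early), 0.5)
})
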