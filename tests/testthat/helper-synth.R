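# Shared fixture builders; everything is generated in code under fixed seeds.

# A low-rank-plus-noise block with known rank.
rank_block <- function(N, P, r, seed, signal_sd = 4, noise_sd = 1) {
  make_domain_block(domain_spec("blk", P, r, signal_sd = signal_sd,
                                noise_sd = noise_sd),
                    N, rng_seed = seed)$block
}

# Two subject tables (two sub-domains each) linked by one planted mode of
# factor-level canonical correlation `rho`, carried by the first factor of
# the first domain on each side.
planted_tables <- function(rho, N, seed, P = 8, rank = 2, signal_sd = 4,
                           noise_sd = 1, families = TRUE, n_domains = 2) {
  set.seed(seed)
  z <- rnorm(N)
  mk_scores <- function() {
    s <- matrix(rnorm(N * n_domains * rank), N)
    if (rho > 0) s[, 1] <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(N)
    s
  }
  mk_table <- function(prefix, scores) {
    doms <- paste0(prefix, "_d", seq_len(n_domains))
    specs <- lapply(doms, function(d)
      domain_spec(d, P, rank, signal_sd, noise_sd))
    blocks <- lapply(seq_along(specs), function(d) {
      make_domain_block(specs[[d]], N, rng_seed = NULL,
                        scores = scores[, (d - 1) * rank + seq_len(rank),
                                        drop = FALSE])$block
    })
    vals <- do.call(cbind, blocks)
    part <- rep(doms, each = P)
    names(part) <- colnames(vals)
    fam <- if (families) paste0("F", rep(seq_len(ceiling(N / 2)), length.out = N))
    list(table = subject_table(vals, family_ids = fam), partition = part)
  }
  x <- mk_table("sm", mk_scores())
  y <- mk_table("bm", mk_scores())
  list(sm_table = x$table, sm_partition = x$partition,
       bm_table = y$table, bm_partition = y$partition)
}

# Independent generalized-eigenproblem CCA oracle: canonical correlations are
# the square roots of the eigenvalues of Sxx^-1 Sxy Syy^-1 Syx.
cca_eigen_oracle <- function(X, Y) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  n <- nrow(X) - 1
  Sxx <- crossprod(Xc) / n; Syy <- crossprod(Yc) / n
  Sxy <- crossprod(Xc, Yc) / n
  M <- solve(Sxx, Sxy) %*% solve(Syy, t(Sxy))
  ev <- sort(Re(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(pmax(ev[seq_len(min(ncol(X), ncol(Y)))], 0))
}

# Brute-force leave-one-variable-out reconstruction rebuilt from its
# definition with an independent pseudo-inverse routine (MASS::ginv).
loo_oracle <- function(X_out, V, k, j) {
  V_k <- V[, seq_len(k), drop = FALSE]
  V_mj <- V_k[-j, , drop = FALSE]
  full <- X_out[, -j, drop = FALSE] %*% MASS::ginv(t(V_mj)) %*% t(V_k)
  full[, j]
}
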