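#' Specification of one synthetic variable sub-domain
#'
#' Describes a low-rank-plus-noise block: `true_rank` latent factors with
#' per-factor signal standard deviations, random orthonormal loadings with an
#' optional sparsity mask, and i.i.d. Gaussian noise.
#'
#' @param label sub-domain name.
#' @param n_vars number of variables in the block.
#' @param true_rank number of latent factors (`<= n_vars`).
#' @param signal_sd signal standard deviation per factor (recycled to
#'   `true_rank`); all positive.
#' @param noise_sd noise standard deviation (positive).
#' @param loading_sparsity fraction in \[0, 1\] of loading entries zeroed
#'   before re-orthonormalisation.
#' @return Object of class `domain_spec`.
#' @export
domain_spec <- function(label, n_vars, true_rank, signal_sd = 4, noise_sd = 1,
                        loading_sparsity = 0) {
  if (true_rank > n_vars) stopf("true_rank (%d) exceeds n_vars (%d)", true_rank, n_vars)
  signal_sd <- rep_len(signal_sd, true_rank)
  if (any(signal_sd <= 0) || noise_sd <= 0) stopf("signal and noise sds must be positive")
  if (loading_sparsity < 0 || loading_sparsity > 1)
    stopf("loading_sparsity must be in [0, 1]")
  structure(list(label = label, n_vars = as.integer(n_vars),
                 true_rank = as.integer(true_rank), signal_sd = signal_sd,
                 noise_sd = noise_sd, loading_sparsity = loading_sparsity),
            class = "domain_spec")
}

# random orthonormal P x r loadings with an approximate sparsity mask
random_loadings <- function(P, r, sparsity) {
  G <- matrix(rnorm(P * r), P, r)
  if (sparsity > 0) {
    mask <- matrix(runif(P * r) < sparsity, P, r)
    # never empty a whole column
    for (j in seq_len(r)) if (all(mask[, j])) mask[which.max(abs(G[, j])), j] <- FALSE
    G[mask] <- 0
  }
  qr.Q(qr(G))[, seq_len(r), drop = FALSE]
}

#' Generate one synthetic sub-domain block
#'
#' `block = scores %*% t(loadings) + noise`, with standard-normal factor
#' scores scaled by the per-factor signal sd, random orthonormal loadings and
#' i.i.d. Gaussian noise.  Fully deterministic given the seed.
#'
#' @param spec a [domain_spec()].
#' @param n_subjects number of rows (`> true_rank`).
#' @param rng_seed integer seed.
#' @param scores optional pre-built N x true_rank matrix of unit-variance
#'   factor scores (used by [make_linked_dataset()] to plant cross-block
#'   modes); generated internally when `NULL`.
#' @return A list with `block` (N x n_vars), `true_loadings` (orthonormal
#'   n_vars x true_rank) and `scores` (the unscaled factor scores).
#' @export
make_domain_block <- function(spec, n_subjects, rng_seed = 1, scores = NULL) {
  stopifnot(inherits(spec, "domain_spec"))
  if (n_subjects <= spec$true_rank)
    stopf("n_subjects must exceed true_rank")
  with_seed(rng_seed, {
    V <- random_loadings(spec$n_vars, spec$true_rank, spec$loading_sparsity)
    if (is.null(scores))
      scores <- matrix(rnorm(n_subjects * spec$true_rank), n_subjects)
    scaled <- sweep(scores, 2L, spec$signal_sd, "*")
    noise <- matrix(rnorm(n_subjects * spec$n_vars, sd = spec$noise_sd),
                    n_subjects, spec$n_vars)
    block <- scaled %*% t(V) + noise
    colnames(block) <- paste0(spec$label, "_v", seq_len(spec$n_vars))
    list(block = block, true_loadings = V, scores = scores)
  })
}

#' Specification of the planted cross-block modes
#'
#' Each mode k is a shared latent variable feeding one factor in each block
#' with weight \eqn{\sqrt\rho_k}, so the two carrier factor scores correlate
#' at exactly \eqn{\rho_k} in the population.
#'
#' @param canonical_rhos strictly decreasing correlations in (0, 1), one per
#'   mode.
#' @param sm_carriers,bm_carriers integer indices of the carrier factors in
#'   each block's concatenated factor list (defaults: mode k on factor k).
#' @return Object of class `link_spec`.
#' @export
link_spec <- function(canonical_rhos, sm_carriers = NULL, bm_carriers = NULL) {
  n_modes <- length(canonical_rhos)
  if (n_modes && (any(canonical_rhos <= 0) || any(canonical_rhos >= 1)))
    stopf("canonical_rhos must lie strictly in (0, 1)")
  if (n_modes > 1 && any(diff(canonical_rhos) >= 0))
    stopf("canonical_rhos must be strictly decreasing")
  sm_carriers <- sm_carriers %||% seq_len(n_modes)
  bm_carriers <- bm_carriers %||% seq_len(n_modes)
  if (length(sm_carriers) != n_modes || length(bm_carriers) != n_modes)
    stopf("one carrier per mode per block is required")
  structure(list(n_modes = n_modes, canonical_rhos = canonical_rhos,
                 sm_carriers = as.integer(sm_carriers),
                 bm_carriers = as.integer(bm_carriers)),
            class = "link_spec")
}

# correlated pair construction: both scores unit variance, correlation rho
linked_scores <- function(z, rho) {
  sqrt(rho) * z + sqrt(1 - rho) * rnorm(length(z))
}

#' Generate a linked synthetic study
#'
#' Builds a complete synthetic data set with known ground truth: a
#' subject-measure-like table of low-rank sub-domain blocks, a stack of
#' symmetric connectivity matrices whose region blocks carry their own latent
#' factors, a confound table with additive linear effects on both data
#' blocks, family structure with a family-level random intercept, and
#' `link$n_modes` planted cross-block modes.  Mode k joins one factor of each
#' block through a shared latent variable so the two carrier factor scores
#' correlate at exactly `canonical_rhos[k]`; because the observed variables
#' add measurement noise around the factors, the population canonical
#' correlation between the *observed* blocks is attenuated by a closed-form
#' reliability factor per block, reported in `truth`.
#'
#' @param sm_specs list of [domain_spec()]s for the subject-measure block.
#' @param bm_spec list describing the connectivity block: `n_regions`,
#'   `n_factors` (latent region-pattern factors), `pattern_norm`s (Euclidean
#'   norm of each factor's region pattern, recycled), `noise_sd` (edge noise).
#' @param link a [link_spec()]; SM carriers index the concatenated SM factor
#'   list (domain order), BM carriers index the latent connectivity factors.
#' @param n_subjects number of subjects.
#' @param n_families number of families (subjects are spread over families
#'   nearly evenly); defaults to `ceiling(n_subjects / 2.5)`, emulating
#'   sibling-heavy cohorts.
#' @param family_sd standard deviation of the family-level random intercept
#'   added to every variable (0 disables).
#' @param confound_spec list with `n_confounds` and `effect_sd` (`NULL`
#'   disables confounds).
#' @param rng_seed integer seed; the run is fully reproducible from it.
#' @return A list with `sm_table` ([subject_table()] with family ids),
#'   `sm_partition`, `bm_stack` ([connectivity_stack()]), `confounds`
#'   ([subject_table()] or `NULL`), `family_ids`, and `truth` (per-domain
#'   ranks/loadings, carrier indices, factor-level and attenuated
#'   observed-level canonical correlations).
#' @export
make_linked_dataset <- function(sm_specs,
                                bm_spec = list(n_regions = 20, n_factors = 8,
                                               pattern_norm = 2, noise_sd = 1),
                                link = link_spec(numeric(0)),
                                n_subjects = 500, n_families = NULL,
                                family_sd = 0, confound_spec = NULL,
                                rng_seed = 1) {
  stopifnot(inherits(link, "link_spec"))
  if (is.null(n_families)) n_families <- ceiling(n_subjects / 2.5)
  n_sm_factors <- sum(vapply(sm_specs, function(s) s$true_rank, integer(1)))
  if (link$n_modes) {
    if (max(link$sm_carriers) > n_sm_factors)
      stopf("sm carrier index exceeds the %d available SM factors", n_sm_factors)
    if (max(link$bm_carriers) > bm_spec$n_factors)
      stopf("bm carrier index exceeds the %d available connectivity factors",
            bm_spec$n_factors)
  }
  with_seed(rng_seed, {
    N <- n_subjects
    # shared mode latents and carrier factor scores
    z <- matrix(rnorm(N * max(link$n_modes, 1)), N)
    sm_scores_all <- matrix(rnorm(N * n_sm_factors), N)
    bm_scores <- matrix(rnorm(N * bm_spec$n_factors), N)
    for (k in seq_len(link$n_modes)) {
      rho <- link$canonical_rhos[k]
      sm_scores_all[, link$sm_carriers[k]] <- linked_scores(z[, k], rho)
      bm_scores[, link$bm_carriers[k]] <- linked_scores(z[, k], rho)
    }
    # SM blocks
    offset <- 0L
    blocks <- vector("list", length(sm_specs))
    sm_loadings <- vector("list", length(sm_specs))
    for (d in seq_along(sm_specs)) {
      spec <- sm_specs[[d]]
      sc <- sm_scores_all[, offset + seq_len(spec$true_rank), drop = FALSE]
      gen <- make_domain_block(spec, N, rng_seed = NULL, scores = sc)
      blocks[[d]] <- gen$block
      sm_loadings[[d]] <- gen$true_loadings
      offset <- offset + spec$true_rank
    }
    sm_vals <- do.call(cbind, blocks)
    sm_partition <- rep(vapply(sm_specs, `[[`, character(1), "label"),
                        vapply(sm_specs, `[[`, integer(1), "n_vars"))
    names(sm_partition) <- colnames(sm_vals)
    # connectivity block: M_i = sum_k f_ik w_k w_k' + symmetric noise
    R <- bm_spec$n_regions
    norms <- rep_len(bm_spec$pattern_norm %||% 2, bm_spec$n_factors)
    W <- vapply(seq_len(bm_spec$n_factors), function(k) {
      w <- rnorm(R)
      w / sqrt(sum(w^2)) * norms[k]
    }, numeric(R))
    patterns <- lapply(seq_len(bm_spec$n_factors),
                       function(k) tcrossprod(W[, k]))
    noise_sd_bm <- bm_spec$noise_sd %||% 1
    upper <- upper.tri(matrix(0, R, R))
    mats <- lapply(seq_len(N), function(i) {
      M <- Reduce(`+`, Map(function(f, Pk) f * Pk, bm_scores[i, ], patterns))
      E <- matrix(0, R, R)
      E[upper] <- rnorm(sum(upper), sd = noise_sd_bm)
      M <- M + E + t(E)
      diag(M) <- 1
      M
    })
    # confound effects (linear, added to both blocks)
    confounds <- NULL
    if (!is.null(confound_spec)) {
      nc <- confound_spec$n_confounds %||% 3
      eff <- confound_spec$effect_sd %||% 0.5
      C <- matrix(rnorm(N * nc), N, nc,
                  dimnames = list(NULL, paste0("conf_", seq_len(nc))))
      G_sm <- matrix(rnorm(nc * ncol(sm_vals), sd = eff), nc)
      sm_vals <- sm_vals + C %*% G_sm
      G_bm <- matrix(rnorm(nc * sum(upper), sd = eff), nc)
      bm_eff <- C %*% G_bm
      for (i in seq_len(N)) {
        E <- matrix(0, R, R)
        E[upper] <- bm_eff[i, ]
        mats[[i]] <- mats[[i]] + E + t(E)
        diag(mats[[i]]) <- 1
      }
      confounds <- subject_table(C, subject_ids = paste0("S", seq_len(N)))
    }
    # families: near-even random assignment plus random intercept
    family_ids <- paste0("F", sample(rep(seq_len(n_families), length.out = N)))
    if (family_sd > 0) {
      fam_index <- match(family_ids, unique(family_ids))
      U_sm <- matrix(rnorm(length(unique(family_ids)) * ncol(sm_vals),
                           sd = family_sd), ncol = ncol(sm_vals))
      sm_vals <- sm_vals + U_sm[fam_index, , drop = FALSE]
      U_bm <- matrix(rnorm(length(unique(family_ids)) * sum(upper),
                           sd = family_sd), ncol = sum(upper))
      for (i in seq_len(N)) {
        E <- matrix(0, R, R)
        E[upper] <- U_bm[fam_index[i], ]
        mats[[i]] <- mats[[i]] + E + t(E)
        diag(mats[[i]]) <- 1
      }
    }
    subject_ids <- paste0("S", seq_len(N))
    sm_table <- subject_table(sm_vals, subject_ids = subject_ids,
                              family_ids = family_ids)
    bm_stack <- connectivity_stack(mats, subject_ids = subject_ids)
    # closed-form reliability attenuation per planted mode
    att_sm <- att_bm <- rho_observed <- numeric(link$n_modes)
    if (link$n_modes) {
      cum_ranks <- cumsum(vapply(sm_specs, `[[`, integer(1), "true_rank"))
      for (k in seq_len(link$n_modes)) {
        ci <- link$sm_carriers[k]
        d <- which(cum_ranks >= ci)[1]
        within <- ci - c(0, cum_ranks)[d]
        spec <- sm_specs[[d]]
        s <- spec$signal_sd[within]
        att_sm[k] <- s / sqrt(s^2 + spec$noise_sd^2)
        wk <- W[, link$bm_carriers[k]]
        Sk <- (sum(wk^2)^2 - sum(wk^4)) / 2
        att_bm[k] <- sqrt(Sk / (Sk + noise_sd_bm^2))
        rho_observed[k] <- link$canonical_rhos[k] * att_sm[k] * att_bm[k]
      }
    }
    truth <- list(
      sm_specs = sm_specs, bm_spec = bm_spec, link = link,
      sm_loadings = sm_loadings, bm_patterns = W,
      sm_ranks = vapply(sm_specs, `[[`, integer(1), "true_rank"),
      rho_factor = link$canonical_rhos,
      attenuation_sm = att_sm, attenuation_bm = att_bm,
      rho_observed = rho_observed,
      family_sd = family_sd, n_families = n_families
    )
    list(sm_table = sm_table, sm_partition = sm_partition,
         bm_stack = bm_stack, confounds = confounds,
         family_ids = family_ids, truth = truth)
  })
}

#' Negate a random fraction of columns
#'
#' Creates the sign-scrambled condition that [sign_flip()] is designed to
#' undo: a seeded random subset of columns is negated.
#'
#' @param table a [subject_table()].
#' @param fraction fraction of columns to negate, in \[0, 1\].
#' @param rng_seed integer seed.
#' @return A list with `table` (scrambled) and `flipped` (the column names
#'   negated).
#' @export
scramble_signs <- function(table, fraction, rng_seed = 1) {
  stopifnot(inherits(table, "subject_table"))
  if (fraction < 0 || fraction > 1) stopf("fraction must be in [0, 1]")
  P <- ncol(table$values)
  n_flip <- round(fraction * P)
  flipped <- with_seed(rng_seed, sample(table$variable_names, n_flip))
  vals <- table$values
  vals[, flipped] <- -vals[, flipped, drop = FALSE]
  list(table = st_with_values(table, vals), flipped = flipped)
}

#' Default synthetic study mimicking a large family cohort at desk scale
#'
#' Builds the package's reference simulation: 14 subject-measure sub-domains
#' whose variable counts and latent ranks span the spread seen in behavioural
#' batteries (ranks 1 to 14, domains of 5 to 44 variables, 62 latent factors
#' in total), a 20-region connectivity block with 8 latent region patterns,
#' 3 confounds, sibling-sized families with a modest family intercept, and
#' two planted cross-block modes at factor-level canonical correlations 0.85
#' and 0.70 (chosen, via the null canonical-correlation level at these
#' dimensions and sample size, to be clearly detectable but not trivial).
#'
#' @param n_subjects number of subjects (default 500).
#' @param rng_seed integer seed.
#' @param canonical_rhos planted factor-level canonical correlations.
#' @return As [make_linked_dataset()].
#' @export
simulate_study <- function(n_subjects = 500, rng_seed = 1,
                           canonical_rhos = c(0.85, 0.70)) {
  n_vars <- c(7, 8, 5, 5, 44, 12, 11, 28, 10, 9, 44, 23, 7, 5)
  ranks <- c(1, 3, 5, 2, 10, 7, 1, 5, 1, 1, 14, 8, 3, 1)
  labels <- c("demographics", "physical_health", "female_health",
              "family_history", "psychiatry", "sensory", "drug_use",
              "alcohol_use", "tobacco_use", "alertness", "cognition",
              "emotion", "motor", "personality")
  sm_specs <- Map(function(l, p, r)
    domain_spec(l, p, r, signal_sd = 4, noise_sd = 1, loading_sparsity = 0.3),
    labels, n_vars, ranks)
  names(sm_specs) <- NULL
  # modes are carried by the first factors of the two largest domains
  cum_ranks <- cumsum(ranks)
  carriers <- c(cum_ranks[10] + 1L,  # cognition factor 1
                cum_ranks[4] + 1L)   # psychiatry factor 1
  lk <- link_spec(canonical_rhos,
                  sm_carriers = carriers[seq_along(canonical_rhos)],
                  bm_carriers = seq_along(canonical_rhos))
  make_linked_dataset(
    sm_specs,
    bm_spec = list(n_regions = 20, n_factors = 8,
                   pattern_norm = seq(2.5, 1.5, length.out = 8), noise_sd = 1),
    link = lk, n_subjects = n_subjects,
    family_sd = 0.3,
    confound_spec = list(n_confounds = 3, effect_sd = 0.5),
    rng_seed = rng_seed)
}
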