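#' Family-respecting k-fold split
#'
#' Assigns whole families to folds so that no family is ever split across a
#' fold boundary: families are placed largest-first into the currently
#' smallest fold, with random (seeded) tie-breaking among equally small folds
#' and a random order among equally sized families.  Fold sizes therefore
#' differ by at most the largest family size.
#'
#' @param subject_ids character vector of subject identifiers.
#' @param family_ids one family label per subject (singletons allowed).
#' @param n_folds number of folds.
#' @param rng_seed integer seed.
#' @return A list of length `n_folds`; each element is a list with
#'   `train_ids` and `test_ids` (subject identifiers).
#' @export
family_kfold <- function(subject_ids, family_ids, n_folds = 5, rng_seed = 1) {
  if (length(subject_ids) != length(family_ids))
    stopf("subject_ids and family_ids must have the same length")
  N <- length(subject_ids)
  fam_members <- split(subject_ids, family_ids)
  sizes <- lengths(fam_members)
  if (max(sizes) > N / n_folds)
    warnf("a family (size %d) is larger than N / n_folds; folds will be unbalanced",
          max(sizes))
  assignment <- with_seed(rng_seed, {
    ord <- sample(length(fam_members))                 # random tie-break ...
    ord <- ord[order(sizes[ord], decreasing = TRUE)]   # ... within size groups
    fold_of <- integer(length(fam_members))
    fold_sizes <- integer(n_folds)
    for (fi in ord) {
      cand <- which(fold_sizes == min(fold_sizes))
      pick <- if (length(cand) == 1) cand else sample(cand, 1)
      fold_of[fi] <- pick
      fold_sizes[pick] <- fold_sizes[pick] + sizes[fi]
    }
    fold_of
  })
  lapply(seq_len(n_folds), function(f) {
    test_fams <- fam_members[assignment == f]
    test_ids <- intersect(subject_ids, unlist(test_fams, use.names = FALSE))
    list(train_ids = setdiff(subject_ids, test_ids), test_ids = test_ids)
  })
}

#' Project held-out subjects onto training-set rotated loadings
#'
#' Constructs the reduced factors of a held-out block using the rotated
#' principal loadings estimated on the training set, per sub-domain, and
#' concatenates them in the training partition order.  This is the held-out
#' half of the cross-validated reduction: no quantity is re-estimated on the
#' test subjects.
#'
#' @param test_block a [subject_table()] (or matrix with column names) with
#'   the same variables as the training data.
#' @param train_reduction a `reduced_data` object from [run_ddr()] on the
#'   training subjects.
#' @return A `reduced_data` object for the test subjects (sharing the
#'   training `source` loadings).
#' @export
project_test_factors <- function(test_block, train_reduction) {
  stopifnot(inherits(train_reduction, "reduced_data"))
  vals <- if (inherits(test_block, "subject_table")) test_block$values else as.matrix(test_block)
  comp_list <- lapply(train_reduction$source, function(red) {
    missing_vars <- setdiff(red$variable_names, colnames(vals))
    if (length(missing_vars))
      stopf("test block lacks variable(s) of sub-domain '%s': %s",
            red$subdomain_label, paste(missing_vars, collapse = ", "))
    vals[, red$variable_names, drop = FALSE] %*% red$rotated_loadings
  })
  components <- do.call(cbind, comp_list)
  colnames(components) <- train_reduction$factor_labels
  rownames(components) <- rownames(vals)
  structure(list(components = components,
                 factor_labels = train_reduction$factor_labels,
                 source = train_reduction$source),
            class = "reduced_data")
}

#' Cross-validated canonical correlations
#'
#' Projects held-out factor blocks through the training canonical weights,
#' \eqn{\tilde P = X^{out} A^{in}}, \eqn{\tilde Q = Y^{out} B^{in}}, and
#' returns the correlation of each canonical pair on the held-out subjects.
#' Values live in \[-1, 1\] and are deliberately not forced non-negative: a
#' sign inversion on held-out data is informative.
#'
#' @param train_model a [fit_cca()] model estimated on training subjects.
#' @param X_test_factors,Y_test_factors held-out factor matrices (or
#'   `reduced_data`) with the same columns as the training CCA inputs.
#' @return Numeric vector of length `train_model$m`.
#' @export
cv_canonical_correlations <- function(train_model, X_test_factors, Y_test_factors) {
  Xt <- if (inherits(X_test_factors, "reduced_data")) X_test_factors$components else as.matrix(X_test_factors)
  Yt <- if (inherits(Y_test_factors, "reduced_data")) Y_test_factors$components else as.matrix(Y_test_factors)
  Pt <- sweep(Xt, 2L, train_model$x_center, "-") %*% train_model$weights_A
  Qt <- sweep(Yt, 2L, train_model$y_center, "-") %*% train_model$weights_B
  vapply(seq_len(train_model$m), function(i) {
    if (sd(Pt[, i]) == 0 || sd(Qt[, i]) == 0) {
      warnf("degenerate variance in projected canonical variable %d; recording 0", i)
      return(0)
    }
    cor(Pt[, i], Qt[, i])
  }, numeric(1))
}

# permutation test for already-projected held-out canonical variables:
# rows of Qt are permuted against Pt; the null statistic is the largest
# per-pair correlation (max-statistic)
cv_permutation_test <- function(Pt, Qt, n_perm = 199, alpha = 0.05, rng_seed = 1) {
  m <- ncol(Pt)
  obs <- vapply(seq_len(m), function(i) {
    if (sd(Pt[, i]) == 0 || sd(Qt[, i]) == 0) 0 else cor(Pt[, i], Qt[, i])
  }, numeric(1))
  null_max <- with_seed(rng_seed, {
    vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(nrow(Qt))
      max(vapply(seq_len(m), function(i) cor(Pt[, i], Qt[idx, i]), numeric(1)))
    }, numeric(1))
  })
  p_values <- vapply(obs, function(r) (1 + sum(null_max >= r)) / (1 + n_perm),
                     numeric(1))
  n_sig <- 0L
  for (i in seq_len(m)) {
    if (p_values[i] < alpha) n_sig <- n_sig + 1L else break
  }
  structure(list(n_perm = n_perm, null_max_corr = null_max,
                 correlations = obs, p_values = p_values,
                 n_significant = n_sig, alpha = alpha),
            class = "permutation_result")
}

#' Cross-validated stability analysis of the DDR-CCA pipeline
#'
#' Runs the whole reduction-plus-CCA pipeline inside a family-respecting
#' k-fold cross-validation: for each fold the sub-domain dimensions, principal
#' loadings, rotations and canonical weights are re-estimated on the training
#' subjects only; held-out subjects are projected through the training
#' loadings and weights; training and cross-validated canonical correlations
#' are permutation-tested; and the canonical loadings are aggregated across
#' folds into occurrence counts (how many folds ranked an item in the top-T by
#' absolute loading) with per-item means and standard deviations.
#'
#' Before aggregation, each fold's canonical component i is sign-aligned to
#' the first fold's component i by the sign of the correlation of their
#' first-block loading vectors, so means and SDs are not cancelled by
#' arbitrary sign indeterminacy.
#'
#' @param table_sm,table_bm preprocessed [subject_table()]s (same subjects).
#' @param partition_sm,partition_bm named character vectors mapping variables
#'   to sub-domains.
#' @param n_folds number of cross-validation folds (default 5).
#' @param ddr_folds,ddr_repeats folds/repeats of the inner PRESS dimension
#'   estimation (defaults 5 / 50).
#' @param bm_target_dim optional further PCA dimension for the second block
#'   (estimated on training, applied to test).
#' @param n_perm,alpha permutation-test settings (defaults 199 / 0.05).
#' @param top_T number of top loadings per fold entering the occurrence count
#'   (default 20).
#' @param min_occurrence minimum occurrence kept in the aggregate tables
#'   (default 2).
#' @param rng_seed integer seed driving the split, the per-fold reductions and
#'   the permutation tests.
#' @param k_max optional cap on scanned sub-domain dimensions.
#' @return Object of class `stability_report`: list with `folds` (per fold:
#'   `fold_index`, `test_subject_ids`, `train_model`, `train_correlations`,
#'   `cv_correlations`, `train_perm`, `cv_perm`, `train_loadings_sm`,
#'   `train_loadings_bm`), `cv_correlations` (folds x m matrix),
#'   `train_correlations` (folds x m), `observed_stability` and
#'   `factor_stability` (data frames: component, item, occurrence,
#'   mean_loading, sd_loading), and `top_lists` (the per-fold top-T lists the
#'   occurrence counts are computed from).
#' @export
run_stability <- function(table_sm, table_bm, partition_sm, partition_bm,
                          n_folds = 5, ddr_folds = 5, ddr_repeats = 50,
                          bm_target_dim = NULL, n_perm = 199, alpha = 0.05,
                          top_T = 20, min_occurrence = 2, rng_seed = 1,
                          k_max = NULL) {
  stopifnot(inherits(table_sm, "subject_table"), inherits(table_bm, "subject_table"))
  if (!identical(table_sm$subject_ids, table_bm$subject_ids))
    stopf("the two tables must cover the same subjects in the same order")
  family_ids <- table_sm$family_ids %||% table_sm$subject_ids
  folds <- family_kfold(table_sm$subject_ids, family_ids, n_folds = n_folds,
                        rng_seed = rng_seed)
  fold_results <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- match(folds[[f]]$train_ids, table_sm$subject_ids)
    te <- match(folds[[f]]$test_ids, table_sm$subject_ids)
    train_sm <- st_rows(table_sm, tr); test_sm <- st_rows(table_sm, te)
    train_bm <- st_rows(table_bm, tr); test_bm <- st_rows(table_bm, te)
    seed_f <- rng_seed + 7919L * f
    ddr_sm <- run_ddr(train_sm, partition_sm, n_folds = ddr_folds,
                      n_repeats = ddr_repeats, rng_seed = seed_f, k_max = k_max)
    ddr_bm <- run_ddr(train_bm, partition_bm, n_folds = ddr_folds,
                      n_repeats = ddr_repeats, rng_seed = seed_f + 499979L,
                      k_max = k_max)
    X_train <- ddr_sm$components
    bm_pca <- NULL
    if (!is.null(bm_target_dim)) {
      bm_pca <- reduce_block_pca(ddr_bm, bm_target_dim)
      Y_train <- bm_pca
    } else {
      Y_train <- ddr_bm$components
    }
    model <- fit_cca(X_train, Y_train)
    X_test <- project_test_factors(test_sm, ddr_sm)$components
    Y_test <- project_test_factors(test_bm, ddr_bm)
    Y_test <- if (!is.null(bm_pca)) apply_block_pca(bm_pca, Y_test) else Y_test$components
    cv_corr <- cv_canonical_correlations(model, X_test, Y_test)
    Pt <- sweep(X_test, 2L, model$x_center, "-") %*% model$weights_A
    Qt <- sweep(Y_test, 2L, model$y_center, "-") %*% model$weights_B
    train_perm <- permutation_test(X_train, Y_train, n_perm = n_perm,
                                   alpha = alpha, rng_seed = seed_f + 1L)
    cv_perm <- cv_permutation_test(Pt, Qt, n_perm = n_perm, alpha = alpha,
                                   rng_seed = seed_f + 2L)
    fold_results[[f]] <- list(
      fold_index = f,
      test_subject_ids = folds[[f]]$test_ids,
      train_model = model,
      train_correlations = model$correlations,
      cv_correlations = cv_corr,
      train_perm = train_perm,
      cv_perm = cv_perm,
      train_loadings_sm = canonical_loadings(model, observed = train_sm,
                                             factors = ddr_sm, side = "x"),
      train_loadings_bm = canonical_loadings(model, observed = train_bm,
                                             factors = ddr_bm, side = "y")
    )
  }
  m_common <- min(vapply(fold_results, function(fr) fr$train_model$m, integer(1)))
  # sign-align components across folds using the SM observed-loading vectors
  ref <- fold_results[[1]]$train_loadings_sm$observed_loadings
  for (f in seq_along(fold_results)) {
    fr <- fold_results[[f]]
    L <- fr$train_loadings_sm$observed_loadings
    shared <- intersect(rownames(ref), rownames(L))
    for (i in seq_len(m_common)) {
      s <- cor(ref[shared, i], L[shared, i])
      if (!is.na(s) && s < 0) {
        fr$train_loadings_sm$observed_loadings[, i] <- -fr$train_loadings_sm$observed_loadings[, i]
        fr$train_loadings_sm$factor_loadings[, i] <- -fr$train_loadings_sm$factor_loadings[, i]
        fr$train_loadings_bm$observed_loadings[, i] <- -fr$train_loadings_bm$observed_loadings[, i]
        fr$train_loadings_bm$factor_loadings[, i] <- -fr$train_loadings_bm$factor_loadings[, i]
      }
    }
    fold_results[[f]] <- fr
  }
  aggregate_side <- function(get_loadings) {
    out <- list()
    top_lists <- list()
    for (i in seq_len(m_common)) {
      per_fold <- lapply(fold_results, function(fr) {
        L <- get_loadings(fr)
        v <- L[, i]
        names(sort(abs(v), decreasing = TRUE))[seq_len(min(top_T, length(v)))]
      })
      top_lists[[i]] <- per_fold
      items <- sort(table(unlist(per_fold)), decreasing = TRUE)
      for (item in names(items)) {
        vals <- vapply(seq_along(fold_results), function(f) {
          if (item %in% per_fold[[f]])
            get_loadings(fold_results[[f]])[item, i] else NA_real_
        }, numeric(1))
        out[[length(out) + 1L]] <- data.frame(
          component = i, item = item,
          occurrence = as.integer(items[[item]]),
          mean_loading = mean(vals, na.rm = TRUE),
          sd_loading = if (sum(!is.na(vals)) > 1) sd(vals, na.rm = TRUE) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    list(table = df[df$occurrence >= min_occurrence, , drop = FALSE],
         full = df, top_lists = top_lists)
  }
  obs_agg <- aggregate_side(function(fr) fr$train_loadings_sm$observed_loadings)
  fac_agg <- aggregate_side(function(fr) fr$train_loadings_sm$factor_loadings)
  structure(list(
    folds = fold_results,
    train_correlations = do.call(rbind, lapply(fold_results, function(fr)
      fr$train_correlations[seq_len(m_common)])),
    cv_correlations = do.call(rbind, lapply(fold_results, function(fr)
      fr$cv_correlations[seq_len(m_common)])),
    observed_stability = obs_agg$table,
    factor_stability = fac_agg$table,
    observed_stability_full = obs_agg$full,
    factor_stability_full = fac_agg$full,
    top_lists = list(observed = obs_agg$top_lists, factor = fac_agg$top_lists),
    top_T = top_T, min_occurrence = min_occurrence
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability_report: %d folds\n", length(x$folds)))
  cat("  mean training canonical correlations:",
      paste(sprintf("%.3f", colMeans(x$train_correlations)), collapse = ", "), "\n")
  cat("  mean cross-validated canonical correlations:",
      paste(sprintf("%.3f", colMeans(x$cv_correlations)), collapse = ", "), "\n")
  invisible(x)
}
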