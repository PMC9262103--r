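#' Run the full analysis pipeline
#'
#' Orchestrates preprocessing, per-sub-domain dimension reduction, optional
#' further PCA of the second block, CCA and permutation testing, end to end.
#' Every stochastic step derives its seed deterministically from `rng_seed`,
#' so a single integer reproduces the whole run.
#'
#' @param sm_table raw [subject_table()] of subject measures.
#' @param bm raw second block: a [connectivity_stack()] (unrolled into region
#'   sub-domains via [stack_to_table()]) or a [subject_table()] with
#'   `bm_partition`.
#' @param sm_partition named character vector mapping SM variables to
#'   sub-domains (variables removed by quality control are dropped
#'   automatically).
#' @param bm_partition required when `bm` is a [subject_table()].
#' @param confounds optional [subject_table()] of confounds, regressed out of
#'   both blocks.
#' @param benchmark,manual_flips,square passed to [preprocess()] for the SM
#'   block.
#' @param n_folds,n_repeats PRESS cross-validation settings (defaults 5, 50).
#' @param bm_target_dim optional PCA dimension for the reduced second block.
#' @param n_perm,alpha permutation-test settings (defaults 10000, 0.05).
#' @param rng_seed integer seed.
#' @param k_max optional cap on scanned sub-domain dimensions.
#' @return A list with `sm_pre`, `bm_pre` (preprocessing outputs), `ddr_sm`,
#'   `ddr_bm` (`reduced_data`), and `cca` (the [run_cca_pipeline()] result).
#' @export
run_all <- function(sm_table, bm, sm_partition, bm_partition = NULL,
                    confounds = NULL, benchmark = NULL,
                    manual_flips = character(0), square = character(0),
                    n_folds = 5, n_repeats = 50, bm_target_dim = NULL,
                    n_perm = 10000, alpha = 0.05, rng_seed = 1, k_max = NULL) {
  if (inherits(bm, "connectivity_stack")) {
    unrolled <- stack_to_table(bm)
    bm_table <- unrolled$table
    bm_partition <- unrolled$partition
  } else {
    bm_table <- bm
    if (is.null(bm_partition))
      stopf("bm_partition is required when bm is a subject_table")
  }
  sm_pre <- preprocess(sm_table, confounds = confounds, benchmark = benchmark,
                       manual_flips = manual_flips, square = square)
  bm_pre <- preprocess(bm_table, confounds = confounds)
  ddr_sm <- run_ddr(sm_pre$table, sm_partition, n_folds = n_folds,
                    n_repeats = n_repeats, rng_seed = rng_seed, k_max = k_max)
  ddr_bm <- run_ddr(bm_pre$table, bm_partition, n_folds = n_folds,
                    n_repeats = n_repeats, rng_seed = rng_seed + 500000L,
                    k_max = k_max)
  cca <- run_cca_pipeline(ddr_sm, ddr_bm, bm_target_dim = bm_target_dim,
                          n_perm = n_perm, alpha = alpha,
                          rng_seed = rng_seed + 900000L,
                          sm_observed = sm_pre$table, bm_observed = bm_pre$table)
  list(sm_pre = sm_pre, bm_pre = bm_pre, ddr_sm = ddr_sm, ddr_bm = ddr_bm,
       cca = cca)
}

#' Write pipeline artifacts to a directory
#'
#' Emits the standard output files of a [run_all()] result: processed tables,
#' reduced components, canonical variables, weights, loadings, and a JSON
#' summary (per-domain chosen dimensions, variance explained, permutation
#' p-values).
#'
#' @param result a [run_all()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_subject_table(result$sm_pre$table, file.path(out_dir, "sm_processed.csv"))
  wcsv <- function(M, f) write.csv(as.data.frame(M), file.path(out_dir, f))
  wcsv(result$ddr_sm$components, "sm_factors.csv")
  wcsv(result$ddr_bm$components, "bm_factors.csv")
  wcsv(result$cca$model$variables_P, "canonical_variables_sm.csv")
  wcsv(result$cca$model$variables_Q, "canonical_variables_bm.csv")
  wcsv(result$cca$model$weights_A, "weights_sm.csv")
  wcsv(result$cca$model$weights_B, "weights_bm.csv")
  if (!is.null(result$cca$loadings_sm$observed_loadings))
    wcsv(result$cca$loadings_sm$observed_loadings, "loadings_sm_observed.csv")
  if (!is.null(result$cca$loadings_sm$factor_loadings))
    wcsv(result$cca$loadings_sm$factor_loadings, "loadings_sm_factors.csv")
  domain_summary <- lapply(c(result$ddr_sm$source, result$ddr_bm$source),
                           function(red) list(
                             subdomain = red$subdomain_label,
                             n_vars = red$n_vars,
                             chosen_k = red$chosen_k,
                             k_votes = as.list(red$k_votes),
                             variance_explained_pct = red$variance_explained_pct))
  summary <- list(
    qc_removed = result$sm_pre$qc_report,
    sign_flips = result$sm_pre$sign_flip_record,
    domains = domain_summary,
    canonical_correlations = result$cca$model$correlations,
    permutation_p_values = result$cca$permutation$p_values,
    n_significant = result$cca$permutation$n_significant
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
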