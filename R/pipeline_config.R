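#' Pipeline configuration
#'
#' Collects every threshold of the pair-signature pipeline in one validated
#' object. The defaults are the published study conditions: stable pairs need
#' one ordering in at least 85% of normal samples, reversal pairs need the
#' opposite ordering in at least 85% of tumor samples, qualified pairs need
#' their tumor ordering in strictly more than 60% of tumor samples, a
#' pathway-coupled lncRNA needs |enrichment score| > 0.995 at BH FDR < 0.05,
#' the univariate Cox screen uses p < 0.05, coefficient-of-variation pruning
#' keeps the top 3 partners per anchor, and the LASSO Cox model is tuned by
#' 10-fold cross-validated partial-likelihood deviance.
#'
#' @param stable_frac Minimum fraction of normal samples that must share one
#'   ordering for a stable pair (inclusive bound, default 0.85).
#' @param reversal_frac Minimum fraction of tumor samples showing the opposite
#'   ordering for a reversal pair (inclusive bound, default 0.85).
#' @param qualify_frac Tumor-support fraction a pair must STRICTLY exceed to
#'   qualify (default 0.60).
#' @param pes_abs_threshold Absolute enrichment-score threshold for calling a
#'   pathway-coupled lncRNA (strict inequality, default 0.995).
#' @param fdr_threshold BH FDR threshold for the same call (strict, default 0.05).
#' @param cox_p_threshold Univariate Cox screen p-value threshold (default 0.05).
#' @param top_cv_partners Partners kept per anchor in CV pruning (default 3).
#' @param n_permutations Permutations for the enrichment null (default 1000).
#' @param lasso_folds Cross-validation folds for the LASSO Cox fit (default 10).
#' @param rng_seed Base seed for every stochastic step (default 1).
#' @param auc_years Horizons (years) for time-dependent AUC (default 1, 3, 5).
#' @param correlation_method Correlation used to rank mRNAs against each
#'   lncRNA; `"spearman"` (default) keeps the whole pipeline invariant to
#'   monotone transforms, `"pearson"` is available.
#' @param weight_exponent Exponent on |correlation| in the weighted-KS
#'   enrichment score (default 1, the classical GSEA weighting).
#' @param min_normal_samples Floor on normal-sample count for stable-pair
#'   detection (default 5).
#' @param min_group_frac Minimum fraction of samples per side of the optimal
#'   risk cutoff (default 0.10).
#' @param screen_all_cohorts If `TRUE`, the univariate screen requires
#'   p < `cox_p_threshold` in every cohort rather than the training cohort
#'   only (default `FALSE`).
#'
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(stable_frac = 0.85,
                            reversal_frac = 0.85,
                            qualify_frac = 0.60,
                            pes_abs_threshold = 0.995,
                            fdr_threshold = 0.05,
                            cox_p_threshold = 0.05,
                            top_cv_partners = 3L,
                            n_permutations = 1000L,
                            lasso_folds = 10L,
                            rng_seed = 1L,
                            auc_years = c(1, 3, 5),
                            correlation_method = c("spearman", "pearson"),
                            weight_exponent = 1,
                            min_normal_samples = 5L,
                            min_group_frac = 0.10,
                            screen_all_cohorts = FALSE) {
  correlation_method <- match.arg(correlation_method)
  fracs <- c(
    stable_frac = stable_frac, reversal_frac = reversal_frac,
    qualify_frac = qualify_frac
  )
  if (any(fracs <= 0 | fracs > 1)) {
    abort_validation(sprintf(
      "fractions must lie in (0, 1]; offending: %s",
      paste(names(fracs)[fracs <= 0 | fracs > 1], collapse = ", ")
    ))
  }
  if (top_cv_partners < 1) abort_validation("top_cv_partners must be >= 1")
  if (lasso_folds < 3) abort_validation("lasso_folds must be >= 3")
  if (n_permutations < 1) abort_validation("n_permutations must be >= 1")
  structure(
    list(
      stable_frac = stable_frac, reversal_frac = reversal_frac,
      qualify_frac = qualify_frac, pes_abs_threshold = pes_abs_threshold,
      fdr_threshold = fdr_threshold, cox_p_threshold = cox_p_threshold,
      top_cv_partners = as.integer(top_cv_partners),
      n_permutations = as.integer(n_permutations),
      lasso_folds = as.integer(lasso_folds),
      rng_seed = as.integer(rng_seed),
      auc_years = auc_years,
      correlation_method = correlation_method,
      weight_exponent = weight_exponent,
      min_normal_samples = as.integer(min_normal_samples),
      min_group_frac = min_group_frac,
      screen_all_cohorts = isTRUE(screen_all_cohorts)
    ),
    class = "PipelineConfig"
  )
}
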