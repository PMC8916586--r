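align_survival <- function(indicators, survival) {
  common <- intersect(colnames(indicators), survival$sample_id)
  if (!length(common)) abort_validation("no samples shared by indicators and survival")
  list(
    ind = indicators[, common, drop = FALSE],
    surv = survival[match(common, survival$sample_id), , drop = FALSE]
  )
}

#' Univariate Cox screen of pair indicators
#'
#' Fits a single-covariate Cox proportional-hazards model (Efron tie
#' handling) per pair indicator and reports the hazard ratio with Wald 95%
#' CI and p-value. Constant indicators are skipped with a warning.
#'
#' @param indicators A [encode_pairs()] result (tumor samples).
#' @param survival A [survival_table()].
#' @param min_events Minimum number of events required (default 10).
#' @return Data frame: `gene_a`, `gene_b`, `orientation` (if present), `hr`,
#'   `ci_low`, `ci_high`, `p_value`, `n`, `n_events`.
#' @export
univariate_cox_screen <- function(indicators, survival, min_events = 10L) {
  al <- align_survival(indicators$indicators, survival)
  if (sum(al$surv$event) == 0) abort_validation("all samples censored: Cox screen impossible")
  if (sum(al$surv$event) < min_events) {
    abort_validation(sprintf("need >= %d events, got %d", min_events, sum(al$surv$event)))
  }
  y <- survival::Surv(al$surv$time, al$surv$event)
  res <- lapply(seq_len(nrow(al$ind)), function(i) {
    x <- al$ind[i, ]
    if (length(unique(x)) < 2) {
      return(NULL)
    }
    fit <- survival::coxph(y ~ x, ties = "efron")
    co <- fit$coefficients[[1]]
    se <- sqrt(fit$var[1, 1])
    data.frame(
      row = i, hr = exp(co), ci_low = exp(co - 1.959964 * se),
      ci_high = exp(co + 1.959964 * se),
      p_value = 2 * stats::pnorm(-abs(co / se)),
      stringsAsFactors = FALSE
    )
  })
  skipped <- vapply(res, is.null, logical(1))
  if (any(skipped)) {
    warning(sprintf("skipped %d constant pair indicator(s): %s",
                    sum(skipped),
                    paste(utils::head(rownames(al$ind)[skipped], 5), collapse = ", ")))
  }
  res <- do.call(rbind, res)
  if (is.null(res)) abort_validation("no non-constant pair indicators to screen")
  keep_cols <- intersect(c("gene_a", "gene_b", "orientation"),
                         colnames(indicators$pairs))
  out <- cbind(indicators$pairs[res$row, keep_cols, drop = FALSE],
               res[, c("hr", "ci_low", "ci_high", "p_value")])
  out$n <- ncol(al$ind)
  out$n_events <- sum(al$surv$event)
  rownames(out) <- NULL
  out
}

#' Select pairs consistent across cohorts
#'
#' Retains pairs with univariate Cox p < `cfg$cox_p_threshold` in the
#' training cohort (or in every cohort if `cfg$screen_all_cohorts`) AND a
#' hazard ratio on the same side of 1 in all cohorts (HR exactly 1 anywhere
#' excludes the pair).
#'
#' @param screens Named list of [univariate_cox_screen()] results, one per
#'   cohort.
#' @param training_cohort Name of the training cohort within `screens`.
#' @param cfg A [pipeline_config()].
#' @return Data frame of retained pairs (`gene_a`, `gene_b`, `orientation`
#'   if present) with per-cohort `hr.<cohort>` columns.
#' @export
select_consistent_pairs <- function(screens, training_cohort,
                                    cfg = pipeline_config()) {
  if (!training_cohort %in% names(screens)) {
    abort_validation(sprintf("training cohort '%s' not among screens", training_cohort))
  }
  keys <- lapply(screens, function(s) paste(s$gene_a, s$gene_b, sep = "|"))
  common <- Reduce(intersect, keys)
  missing <- setdiff(keys[[training_cohort]], common)
  if (length(missing)) {
    abort_validation(paste0(
      "pairs not screened in every cohort: ",
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  tr <- screens[[training_cohort]]
  sel <- match(common, keys[[training_cohort]])
  hr_mat <- vapply(names(screens), function(nm) {
    screens[[nm]]$hr[match(common, keys[[nm]])]
  }, numeric(length(common)))
  hr_mat <- matrix(hr_mat, nrow = length(common),
                   dimnames = list(NULL, names(screens)))
  p_ok <- if (cfg$screen_all_cohorts) {
    p_mat <- vapply(names(screens), function(nm) {
      screens[[nm]]$p_value[match(common, keys[[nm]])]
    }, numeric(length(common)))
    p_mat <- matrix(p_mat, nrow = length(common))
    apply(p_mat < cfg$cox_p_threshold, 1, all)
  } else {
    tr$p_value[sel] < cfg$cox_p_threshold
  }
  dir_ok <- apply(hr_mat > 1, 1, all) | apply(hr_mat < 1, 1, all)
  keep <- p_ok & dir_ok
  keep_cols <- intersect(c("gene_a", "gene_b", "orientation"), colnames(tr))
  out <- tr[sel[keep], keep_cols, drop = FALSE]
  for (nm in names(screens)) out[[paste0("hr.", nm)]] <- hr_mat[keep, nm]
  rownames(out) <- NULL
  out
}

# Event-stratified fold assignment, seeded: censored and uncensored samples
# are shuffled separately and dealt round-robin so every fold sees events.
make_cv_folds <- function(event, k, seed) {
  folds <- integer(length(event))
  with_local_seed(seed, {
    for (lev in unique(event)) {
      idx <- which(event == lev)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Fit the LASSO Cox pair signature
#'
#' L1-penalized Cox partial likelihood over a descending lambda path (100
#' values, 4 decades below the smallest lambda giving the empty model);
#' lambda is chosen at the minimum of the 10-fold cross-validated
#' partial-likelihood deviance (fold assignment seeded and stratified by
#' event status). Pairs with non-zero coefficients at that lambda form the
#' model.
#'
#' @param indicators A [encode_pairs()] result for the training cohort
#'   (>= 2 pairs).
#' @param survival The training [survival_table()].
#' @param cfg A [pipeline_config()] (`lasso_folds`, `rng_seed`).
#' @return A [signature_model()] (cutoff unset; see [optimal_cutoff()]).
#' @export
fit_lasso_cox <- function(indicators, survival, cfg = pipeline_config()) {
  if (nrow(indicators$indicators) < 2) {
    abort_validation("LASSO fit needs >= 2 candidate pairs")
  }
  al <- align_survival(indicators$indicators, survival)
  if (sum(al$surv$event) < 10) {
    abort_validation("LASSO fit needs >= 10 events")
  }
  x <- t(al$ind)
  y <- survival::Surv(al$surv$time, al$surv$event)
  foldid <- make_cv_folds(al$surv$event, cfg$lasso_folds, cfg$rng_seed)
  cvfit <- glmnet::cv.glmnet(
    x, y, family = "cox", foldid = foldid,
    nlambda = 100, lambda.min.ratio = 1e-4,
    type.measure = "deviance"
  )
  beta <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
  nz <- which(beta != 0)
  if (!length(nz)) {
    abort_reopairs(
      "no pair retained at lambda.min; relax the screening thresholds or supply more candidates",
      "reopairs_empty_model_error"
    )
  }
  signature_model(
    pairs = indicators$pairs[nz, , drop = FALSE],
    coefficients = beta[nz],
    training_cohort = NA_character_,
    lasso_lambda = cvfit$lambda.min,
    seed = cfg$rng_seed
  )
}

#' Linear risk score of a pair signature
#'
#' score(s) = sum_i coefficient_i * indicator_is; no intercept.
#'
#' @param model A [signature_model()].
#' @param indicators A [encode_pairs()] result containing every model pair.
#' @return A `RiskScore` data frame: `sample_id`, `score`, `group` (`NA`
#'   until a cutoff is applied via [assign_groups()]).
#' @export
risk_score <- function(model, indicators) {
  keys <- pair_key(model$pairs)
  missing <- setdiff(keys, rownames(indicators$indicators))
  if (length(missing)) {
    abort_validation(paste0("indicator matrix missing model pair(s): ",
                            paste(missing, collapse = ", ")))
  }
  sub <- indicators$indicators[keys, , drop = FALSE]
  scores <- as.numeric(crossprod(sub, model$coefficients))
  out <- data.frame(
    sample_id = colnames(sub), score = scores, group = NA_character_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("RiskScore", "data.frame")
  if (is.finite(model$cutoff)) out <- assign_groups(out, model$cutoff)
  out
}

#' Optimal risk cutoff by maximally selected log-rank statistic
#'
#' Evaluates the two-group log-rank chi-square at every admissible split
#' (midpoints of consecutive sorted unique scores leaving at least
#' `min_group_frac` of samples on each side) and returns the split with the
#' maximal statistic; ties resolve to the lower cutoff. No multiplicity
#' correction is applied to downstream log-rank p-values.
#'
#' @param scores A `RiskScore` data frame or named numeric vector.
#' @param survival A [survival_table()].
#' @param min_group_frac Minimum group-size fraction (default 0.10).
#' @param min_samples Error below this cohort size (default 20).
#' @return The cutoff (scalar).
#' @export
optimal_cutoff <- function(scores, survival, min_group_frac = 0.10,
                           min_samples = 20L) {
  sv <- as_score_vector(scores)
  common <- intersect(names(sv), survival$sample_id)
  if (length(common) < min_samples) {
    abort_validation(sprintf("cutpoint search needs >= %d samples, got %d",
                             min_samples, length(common)))
  }
  s <- sv[common]
  surv <- survival[match(common, survival$sample_id), ]
  u <- sort(unique(s))
  if (length(u) < 2) abort_validation("all risk scores identical: no admissible cutoff")
  cand <- (u[-1] + u[-length(u)]) / 2
  n <- length(s)
  min_side <- max(1, ceiling(min_group_frac * n))
  y <- survival::Surv(surv$time, surv$event)
  scan <- function(min_side) {
    best_stat <- -Inf
    best_cut <- NA_real_
    for (cc in cand) {
      hi <- s > cc
      if (sum(hi) < min_side || sum(!hi) < min_side) next
      stat <- survival::survdiff(y ~ hi)$chisq
      if (stat > best_stat + 1e-12) {
        best_stat <- stat
        best_cut <- cc
      }
    }
    best_cut
  }
  best_cut <- scan(min_side)
  if (is.na(best_cut)) {
    # binary pair scores can concentrate almost all mass on one value, in
    # which case no split leaves min_group_frac per side; fall back to the
    # best split with two non-empty groups
    message("no split meets the minimum group size; using best non-empty split")
    best_cut <- scan(1)
  }
  if (is.na(best_cut)) {
    abort_validation("no admissible split satisfies the minimum group size")
  }
  best_cut
}

#' Assign high/low risk groups
#'
#' @param scores A `RiskScore` data frame or named numeric vector.
#' @param cutoff Finite cutoff; `group` = `"high"` iff score > cutoff
#'   (strict), else `"low"`.
#' @return A `RiskScore` data frame with `group` filled.
#' @export
assign_groups <- function(scores, cutoff) {
  if (!is.finite(cutoff)) abort_validation("cutoff must be finite")
  sv <- as_score_vector(scores)
  out <- data.frame(
    sample_id = names(sv), score = unname(sv),
    group = ifelse(sv > cutoff, "high", "low"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("RiskScore", "data.frame")
  out
}

as_score_vector <- function(scores) {
  if (inherits(scores, "RiskScore") ||
      (is.data.frame(scores) && all(c("sample_id", "score") %in% colnames(scores)))) {
    stats::setNames(scores$score, scores$sample_id)
  } else if (is.numeric(scores) && !is.null(names(scores))) {
    scores
  } else {
    abort_validation("scores must be a RiskScore data frame or a named numeric vector")
  }
}
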