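YEAR_DAYS <- 365.25

as_group_vector <- function(groups) {
  if (inherits(groups, "RiskScore") ||
      (is.data.frame(groups) && all(c("sample_id", "group") %in% colnames(groups)))) {
    stats::setNames(groups$group, groups$sample_id)
  } else if (is.character(groups) && !is.null(names(groups))) {
    groups
  } else {
    abort_validation("groups must be a RiskScore data frame or a named character vector")
  }
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' @param groups A `RiskScore` data frame (uses the `group` column) or a
#'   named character vector of group labels.
#' @param survival A [survival_table()].
#' @return List with `chisq`, `p` (1 df) and `curves` (a
#'   [survival::survfit] object).
#' @export
km_logrank <- function(groups, survival) {
  gv <- as_group_vector(groups)
  common <- intersect(names(gv), survival$sample_id)
  g <- factor(gv[common])
  if (nlevels(g) < 2) abort_validation("log-rank test needs two non-empty groups")
  surv <- survival[match(common, survival$sample_id), ]
  y <- survival::Surv(surv$time, surv$event)
  sd <- survival::survdiff(y ~ g)
  list(
    chisq = sd$chisq,
    p = stats::pchisq(sd$chisq, df = nlevels(g) - 1, lower.tail = FALSE),
    curves = survival::survfit(y ~ g)
  )
}

# Kaplan-Meier estimate of the censoring distribution G(t) = P(C > t),
# returned as a lookup closure. left = TRUE gives the left limit G(t-).
censoring_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  tt <- fit$time
  ss <- fit$surv
  function(t, left = FALSE) {
    vapply(t, function(ti) {
      idx <- if (left) which(tt < ti) else which(tt <= ti)
      if (!length(idx)) 1 else ss[max(idx)]
    }, numeric(1))
  }
}

#' Time-dependent cumulative/dynamic AUC
#'
#' Discrimination of "event by horizon t" (cases: observed events with
#' time <= t) against "event-free at t" (controls: time > t), adjusted for
#' censoring by inverse probability of censoring weights from the
#' Kaplan-Meier estimate of the censoring distribution. Cases are weighted
#' by 1/G(T_i-); the constant control weight 1/G(t) cancels. With zero
#' censoring the estimator reduces exactly to the binary Mann-Whitney AUC.
#' Tied scores count 1/2.
#'
#' @param scores A `RiskScore` data frame or named numeric vector (higher =
#'   riskier).
#' @param survival A [survival_table()] (times in days).
#' @param horizons Horizons in YEARS (1 year = 365.25 days).
#' @return Named numeric vector of AUCs, one per horizon.
#' @export
time_dependent_auc <- function(scores, survival, horizons = c(1, 3, 5)) {
  sv <- as_score_vector(scores)
  common <- intersect(names(sv), survival$sample_id)
  s <- sv[common]
  surv <- survival[match(common, survival$sample_id), ]
  ghat <- censoring_km(surv$time, surv$event)
  out <- vapply(horizons, function(yrs) {
    t0 <- yrs * YEAR_DAYS
    if (t0 >= max(surv$time)) {
      abort_validation(sprintf("horizon %g years exceeds maximum follow-up", yrs))
    }
    case <- surv$time <= t0 & surv$event == 1
    ctrl <- surv$time > t0
    if (!any(case) || !any(ctrl)) {
      abort_validation(sprintf("no cases or no controls at %g years", yrs))
    }
    wi <- 1 / ghat(surv$time[case], left = TRUE)
    sc <- s[case]
    st <- s[ctrl]
    conc <- vapply(seq_along(sc), function(i) {
      sum((sc[i] > st) + 0.5 * (sc[i] == st))
    }, numeric(1))
    sum(wi * conc) / (sum(wi) * length(st))
  }, numeric(1))
  stats::setNames(out, paste0(horizons, "y"))
}

harrell_c_core <- function(time, event, score) {
  n <- length(time)
  ti <- matrix(time, n, n)
  ei <- matrix(event == 1, n, n)
  ej <- t(ei)
  tj <- t(ti)
  comparable <- (ti < tj & ei) | (ti == tj & ei & !ej)
  si <- matrix(score, n, n)
  sj <- t(si)
  conc <- (si > sj) + 0.5 * (si == sj)
  denom <- sum(comparable)
  if (denom == 0) abort_validation("no comparable pairs for the concordance index")
  sum(conc[comparable]) / denom
}

#' Harrell's concordance index with bootstrap CI
#'
#' A pair (i, j) is usable when the sample with the shorter follow-up had an
#' event (or, at tied times, exactly one of the two had an event); it is
#' concordant when that sample has the higher risk score; tied scores count
#' 1/2. The 95% CI is a seeded percentile bootstrap over samples.
#'
#' @param scores A `RiskScore` data frame or named numeric vector.
#' @param survival A [survival_table()].
#' @param n_boot Bootstrap resamples (default 2000; 0 skips the CI).
#' @param seed RNG seed for the bootstrap.
#' @return List with `c_index`, `ci_low`, `ci_high`, `n`.
#' @export
concordance_index <- function(scores, survival, n_boot = 2000L, seed = 1L) {
  sv <- as_score_vector(scores)
  common <- intersect(names(sv), survival$sample_id)
  s <- unname(sv[common])
  surv <- survival[match(common, survival$sample_id), ]
  c_hat <- harrell_c_core(surv$time, surv$event, s)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- with_local_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(length(s), replace = TRUE)
        tryCatch(harrell_c_core(surv$time[idx], surv$event[idx], s[idx]),
                 error = function(e) NA_real_)
      }, numeric(1))
    })
    ci <- unname(stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  }
  list(c_index = c_hat, ci_low = ci[1], ci_high = ci[2], n = length(s))
}

#' Calibration of predicted vs observed survival at a horizon
#'
#' Fits a one-covariate Cox model on the risk score, predicts each sample's
#' survival probability at the horizon from the Breslow baseline, bins
#' samples into `n_bins` equal-size score bins, and compares the mean
#' predicted probability with the Kaplan-Meier observed probability per bin.
#' Bins emptied by score ties are merged with their neighbor.
#'
#' @param scores A `RiskScore` data frame or named numeric vector.
#' @param survival A [survival_table()].
#' @param horizon Horizon in years.
#' @param n_bins Number of score bins (>= 2; default 3, i.e. tertiles).
#' @return Data frame: `bin`, `mean_predicted`, `km_observed`, `n`.
#' @export
calibration_at_horizon <- function(scores, survival, horizon = 3, n_bins = 3L) {
  if (n_bins < 2) abort_validation("n_bins must be >= 2")
  sv <- as_score_vector(scores)
  common <- intersect(names(sv), survival$sample_id)
  s <- unname(sv[common])
  surv <- survival[match(common, survival$sample_id), ]
  t0 <- horizon * YEAR_DAYS
  if (t0 >= max(surv$time)) {
    abort_validation("calibration horizon exceeds maximum follow-up")
  }
  dat <- data.frame(time = surv$time, event = surv$event, score = s)
  fit <- survival::coxph(survival::Surv(time, event) ~ score, data = dat,
                         ties = "efron")
  sf <- survival::survfit(fit, newdata = dat)
  pred <- summary(sf, times = t0, extend = TRUE)$surv
  pred <- as.numeric(pred)
  qs <- stats::quantile(s, probs = seq(0, 1, length.out = n_bins + 1))
  brk <- unique(qs)
  if (length(brk) < 2) brk <- c(min(s) - 1, max(s) + 1)
  bin <- cut(s, breaks = brk, include.lowest = TRUE, labels = FALSE)
  if (length(brk) - 1 < n_bins) {
    message(sprintf("score ties: %d effective bin(s) instead of %d",
                    length(brk) - 1, n_bins))
  }
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    idx <- bin == b
    km <- survival::survfit(survival::Surv(time, event) ~ 1, data = dat[idx, ])
    obs <- summary(km, times = t0, extend = TRUE)$surv
    data.frame(bin = b, mean_predicted = mean(pred[idx]),
               km_observed = as.numeric(obs), n = sum(idx))
  }))
  rownames(out) <- NULL
  out
}

#' Multivariate Cox adjustment of the risk score
#'
#' Proportional-hazards fit of the risk score plus clinical covariates.
#' Rows with missing covariate values are dropped (complete-case, count
#' reported). Collinear covariates raise an error naming the aliased term.
#'
#' @param scores A `RiskScore` data frame or named numeric vector.
#' @param survival A [survival_table()].
#' @param covariates Data frame of covariates with a `sample_id` column, or
#'   covariate columns already present in `survival`.
#' @return Data frame: `term`, `hr`, `ci_low`, `ci_high`, `p_value`.
#' @export
multivariate_cox <- function(scores, survival, covariates = NULL) {
  sv <- as_score_vector(scores)
  common <- intersect(names(sv), survival$sample_id)
  surv <- survival[match(common, survival$sample_id), ]
  dat <- data.frame(time = surv$time, event = surv$event,
                    risk_score = unname(sv[common]))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (!"sample_id" %in% colnames(covariates)) {
      abort_validation("covariates need a sample_id column")
    }
    m <- match(common, covariates$sample_id)
    dat <- cbind(dat, covariates[m, setdiff(colnames(covariates), "sample_id"),
                                 drop = FALSE])
  } else {
    extra <- setdiff(colnames(surv), c("sample_id", "time", "event"))
    if (length(extra)) dat <- cbind(dat, surv[, extra, drop = FALSE])
  }
  cc <- stats::complete.cases(dat)
  if (any(!cc)) {
    message(sprintf("dropped %d sample(s) with missing covariates", sum(!cc)))
  }
  dat <- dat[cc, , drop = FALSE]
  terms <- setdiff(colnames(dat), c("time", "event"))
  mm <- stats::model.matrix(
    stats::reformulate(terms), data = dat
  )[, -1, drop = FALSE]
  qrx <- qr(mm)
  if (qrx$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrx$pivot[(qrx$rank + 1):ncol(mm)]]
    abort_validation(paste0("collinear covariate(s): ", paste(aliased, collapse = ", ")))
  }
  fit <- survival::coxph(
    survival::Surv(time, event) ~ ., data = dat, ties = "efron"
  )
  sm <- summary(fit)
  data.frame(
    term = rownames(sm$coefficients),
    hr = sm$coefficients[, "exp(coef)"],
    ci_low = sm$conf.int[, "lower .95"],
    ci_high = sm$conf.int[, "upper .95"],
    p_value = sm$coefficients[, "Pr(>|z|)"],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Two-group comparison of per-sample values
#'
#' Continuous values use the Wilcoxon rank-sum test (exact when both groups
#' have <= 50 samples and no ties, normal approximation with continuity
#' correction otherwise); categorical values use Fisher's exact test.
#' External per-sample scores (mutation burden, immune scores, drug response
#' measures, ...) enter the package only through this interface.
#'
#' @param values Per-sample numeric (wilcoxon) or categorical (fisher)
#'   values, named by sample id.
#' @param groups A `RiskScore` data frame or named character vector of group
#'   labels.
#' @param test `"wilcoxon_rank_sum"` or `"fisher_exact"`.
#' @return List (`GroupComparison`): `statistic`, `p_value`, `test`,
#'   `group_summaries`.
#' @export
compare_groups <- function(values, groups,
                           test = c("wilcoxon_rank_sum", "fisher_exact")) {
  test <- match.arg(test)
  gv <- as_group_vector(groups)
  common <- intersect(names(values), names(gv))
  if (!length(common)) abort_validation("no samples shared by values and groups")
  v <- values[common]
  g <- factor(gv[common])
  if (nlevels(g) != 2 || any(table(g) == 0)) {
    abort_validation("comparison needs exactly two non-empty groups")
  }
  if (test == "wilcoxon_rank_sum") {
    if (!is.numeric(v)) abort_validation("wilcoxon_rank_sum requires numeric values")
    v1 <- v[g == levels(g)[1]]
    v2 <- v[g == levels(g)[2]]
    exact <- length(v1) <= 50 && length(v2) <= 50 && !anyDuplicated(v)
    ht <- stats::wilcox.test(v1, v2, exact = exact, correct = TRUE)
    summaries <- lapply(split(v, g), function(x) {
      list(n = length(x), median = stats::median(x),
           iqr = unname(stats::quantile(x, c(0.25, 0.75))))
    })
  } else {
    if (is.numeric(v) && length(unique(v)) > 10) {
      abort_validation("fisher_exact requires categorical values")
    }
    tab <- table(g, factor(v))
    if (ncol(tab) < 2) abort_validation("fisher_exact needs >= 2 value categories")
    ht <- stats::fisher.test(tab)
    summaries <- lapply(split(as.character(v), g), function(x) as.list(table(x)))
  }
  list(
    statistic = unname(if (!is.null(ht$statistic)) ht$statistic else NA_real_),
    p_value = ht$p.value,
    test = test,
    group_summaries = summaries
  )
}

#' Full evaluation report for one cohort
#'
#' Bundles the KM/log-rank test, time-dependent AUCs, concordance index with
#' bootstrap CI, calibration bins and (when covariates are present) the
#' multivariate Cox adjustment.
#'
#' @param scores A `RiskScore` with groups assigned.
#' @param survival A [survival_table()].
#' @param cohort_id Cohort label.
#' @param auc_years AUC horizons in years (horizons beyond follow-up are
#'   dropped with a message).
#' @param n_boot Bootstrap draws for the C-index CI.
#' @param seed Seed for the bootstrap.
#' @param calibration_years Calibration horizon (years).
#' @param n_bins Calibration bins.
#' @return An `EvaluationReport` list.
#' @export
evaluate_signature <- function(scores, survival, cohort_id,
                               auc_years = c(1, 3, 5), n_boot = 2000L,
                               seed = 1L, calibration_years = 3, n_bins = 3L) {
  km <- km_logrank(scores, survival)
  sv <- as_score_vector(scores)
  common <- intersect(names(sv), survival$sample_id)
  max_fu <- max(survival$time[match(common, survival$sample_id)])
  ok_years <- auc_years[auc_years * YEAR_DAYS < max_fu]
  if (length(ok_years) < length(auc_years)) {
    message("dropped AUC horizon(s) beyond maximum follow-up")
  }
  auc <- time_dependent_auc(scores, survival, ok_years)
  ci <- concordance_index(scores, survival, n_boot = n_boot, seed = seed)
  calib <- if (calibration_years * YEAR_DAYS < max_fu) {
    calibration_at_horizon(scores, survival, calibration_years, n_bins)
  }
  mv <- NULL
  extra <- setdiff(colnames(survival), c("sample_id", "time", "event"))
  if (length(extra)) {
    mv <- tryCatch(multivariate_cox(scores, survival),
                   error = function(e) NULL)
  }
  structure(
    list(
      cohort_id = cohort_id,
      km_logrank_chisq = km$chisq,
      km_logrank_p = km$p,
      auc_by_year = auc,
      c_index = ci$c_index,
      c_index_ci = c(ci$ci_low, ci$ci_high),
      calibration_bins = calib,
      multivariate = mv
    ),
    class = "EvaluationReport"
  )
}

#' Serialize / deserialize evaluation reports as JSON
#'
#' @param report An `EvaluationReport` (or list of them).
#' @param path JSON path.
#' @return `read_report` returns the parsed list.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}
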