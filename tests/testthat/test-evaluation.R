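test_that("the log-rank test matches a hand-built risk-table oracle", {
  # two groups with mixed censoring
  time <- c(6, 7, 10, 15, 19, 25, 1, 3, 5, 8, 12, 17)
  event <- c(1, 0, 1, 1, 0, 1, 1, 1, 0, 1, 1, 1)
  grp <- setNames(rep(c("low", "high"), each = 6), sprintf("s%02d", 1:12))
  surv <- survival_table(names(grp), time, event)
  got <- km_logrank(grp, surv)
  expect_equal(got$chisq, oracle_logrank(time, event, grp), tolerance = 1e-10)
  expect_equal(got$p, pchisq(got$chisq, 1, lower.tail = FALSE))

  # extreme separation is detected
  n <- 25
  grp2 <- setNames(rep(c("high", "low"), each = n), sprintf("t%03d", 1:(2 * n)))
  surv2 <- survival_table(names(grp2),
                          c(runif(n, 10, 90), rep(100, n)),
                          c(rep(1, n), rep(0, n)))
  expect_lt(km_logrank(grp2, surv2)$p, 0.01)

  expect_error(km_logrank(setNames(rep("high", 5), sprintf("s%02d", 1:5)), surv),
               class = "reopairs_validation_error")
})

test_that("Harrell's C equals exhaustive pair enumeration and is anti-symmetric", {
  set.seed(6)
  for (r in 1:5) {
    n <- sample(15:30, 1)
    tm <- sample(1:40, n, replace = TRUE) # ties on purpose
    ev <- rbinom(n, 1, 0.7)
    sc <- setNames(round(rnorm(n), 1), sprintf("s%02d", 1:n)) # tied scores too
    surv <- survival_table(names(sc), tm, ev)
    ci <- concordance_index(sc, surv, n_boot = 0)
    expect_equal(ci$c_index, oracle_harrell(tm, ev, unname(sc)))
    ci_neg <- concordance_index(-sc, surv, n_boot = 0)
    expect_equal(ci$c_index, 1 - ci_neg$c_index)
  }

  # orientation sanity: scores ordered exactly by event time give C = 1
  tm <- c(10, 20, 30, 40)
  sc <- setNames(c(4, 3, 2, 1), letters[1:4])
  surv <- survival_table(names(sc), tm, rep(1, 4))
  expect_equal(concordance_index(sc, surv, n_boot = 0)$c_index, 1)
  expect_equal(concordance_index(-sc, surv, n_boot = 0)$c_index, 0)

  # cross-check against the survival package on tie-free data
  set.seed(8)
  n <- 40
  tm <- runif(n, 1, 100)
  ev <- rbinom(n, 1, 0.6)
  sc <- setNames(rnorm(n), sprintf("u%02d", 1:n))
  surv <- survival_table(names(sc), tm, ev)
  ref <- survival::concordance(survival::Surv(tm, ev) ~ unname(sc))$concordance
  expect_equal(concordance_index(sc, surv, n_boot = 0)$c_index, 1 - ref,
               tolerance = 1e-12)

  # bootstrap CI is seeded and brackets the estimate
  ci <- concordance_index(sc, surv, n_boot = 200, seed = 3)
  ci2 <- concordance_index(sc, surv, n_boot = 200, seed = 3)
  expect_identical(ci, ci2)
  expect_lte(ci$ci_low, ci$c_index)
  expect_gte(ci$ci_high, ci$c_index)
})

test_that("time-dependent AUC reduces to the binary AUC without censoring", {
  set.seed(11)
  n <- 120
  sc <- setNames(rnorm(n), sprintf("s%03d", 1:n))
  tm <- rexp(n, 0.002 * exp(0.9 * sc))
  surv <- survival_table(names(sc), tm, rep(1, n))
  for (yrs in c(0.5, 1, 2)) {
    t0 <- yrs * 365.25
    got <- time_dependent_auc(sc, surv, yrs)
    expect_equal(unname(got), oracle_binary_auc(unname(sc), as.numeric(tm <= t0)),
                 tolerance = 1e-10)
  }

  # a perfect risk score discriminates completely
  sc2 <- setNames(-tm, names(sc)) # higher score = earlier event
  expect_equal(unname(time_dependent_auc(sc2, surv, 1)), 1)

  # an uninformative score sits near 1/2 (with censoring in play)
  set.seed(12)
  n2 <- 500
  sc3 <- setNames(rnorm(n2), sprintf("r%03d", 1:n2))
  tm2 <- rexp(n2, 1 / 900)
  cens <- runif(n2, 0, 2500)
  surv3 <- survival_table(names(sc3), pmin(tm2, cens),
                          as.numeric(tm2 <= cens))
  auc_null <- time_dependent_auc(sc3, surv3, c(1, 2))
  expect_true(all(abs(auc_null - 0.5) < 0.05))

  expect_error(time_dependent_auc(sc, surv, 100), "follow-up",
               class = "reopairs_validation_error")
})

test_that("calibration is self-consistent on data generated from the model", {
  set.seed(13)
  n <- 1000
  sc <- setNames(rnorm(n), sprintf("s%04d", 1:n))
  tm <- rexp(n, 0.0008 * exp(0.7 * sc))
  cens <- runif(n, 0, 4000)
  surv <- survival_table(names(sc), pmin(tm, cens), as.numeric(tm <= cens))
  bins <- calibration_at_horizon(sc, surv, horizon = 3, n_bins = 3)
  expect_equal(sum(bins$n), n)
  expect_true(all(abs(bins$mean_predicted - bins$km_observed) < 0.05))

  # constant scores collapse to a single effective bin that matches the
  # marginal Kaplan-Meier
  scc <- setNames(rep(1, 200), sprintf("c%03d", 1:200))
  survc <- survival_table(names(scc), rexp(200, 1 / 1200) + 1,
                          rbinom(200, 1, 0.7))
  expect_message(binsc <- calibration_at_horizon(scc, survc, 1, 3), "bin")
  expect_equal(nrow(binsc), 1)
  km <- summary(survival::survfit(survival::Surv(survc$time, survc$event) ~ 1),
                times = 365.25, extend = TRUE)$surv
  expect_equal(binsc$km_observed, km, tolerance = 1e-10)
  expect_equal(binsc$mean_predicted, km, tolerance = 0.05)

  expect_error(calibration_at_horizon(sc, surv, 3, n_bins = 1),
               class = "reopairs_validation_error")
})

test_that("multivariate adjustment leaves an independent score untouched", {
  set.seed(14)
  n <- 500
  sc <- setNames(rnorm(n), sprintf("s%04d", 1:n))
  age <- rnorm(n, 65, 8)
  tm <- rexp(n, 0.001 * exp(0.8 * sc))
  surv <- survival_table(names(sc), tm, rbinom(n, 1, 0.85),
                         covariates = data.frame(age = age))
  fit <- multivariate_cox(sc, surv)
  uni <- multivariate_cox(sc, survival_table(names(sc), tm, surv$event))
  adj <- log(fit$hr[fit$term == "risk_score"])
  raw <- log(uni$hr[uni$term == "risk_score"])
  expect_lt(abs(adj - raw), 0.15)
  expect_true(all(c("risk_score", "age") %in% fit$term))

  # a duplicated covariate is collinear
  surv2 <- survival_table(names(sc), tm, surv$event,
                          covariates = data.frame(age = age, age2 = age))
  expect_error(multivariate_cox(sc, surv2), "collinear",
               class = "reopairs_validation_error")
})

test_that("group comparisons reproduce exact small-sample p-values", {
  g <- setNames(rep(c("low", "high"), each = 3), sprintf("s%d", 1:6))
  v <- setNames(c(1, 2, 3, 4, 5, 6), names(g))
  cmp <- compare_groups(v, g, "wilcoxon_rank_sum")
  expect_equal(cmp$p_value, 2 / choose(6, 3)) # 0.1: both extreme assignments
  expect_equal(cmp$group_summaries$low$n, 3)

  g2 <- setNames(rep(c("high", "low"), each = 10), sprintf("t%02d", 1:20))
  v2 <- setNames(rep(c("mut", "wt"), each = 10), names(g2))
  cmp2 <- compare_groups(v2, g2, "fisher_exact")
  expect_equal(cmp2$p_value, 2 / choose(20, 10), tolerance = 1e-12)

  same <- setNames(rep(1:5, 2), sprintf("u%02d", 1:10))
  gsame <- setNames(rep(c("high", "low"), each = 5), names(same))
  expect_gt(compare_groups(same, gsame, "wilcoxon_rank_sum")$p_value, 0.9)

  expect_error(compare_groups(v2, g2, "wilcoxon_rank_sum"),
               class = "reopairs_validation_error")
})

test_that("evaluation reports serialize and deserialize", {
  set.seed(15)
  n <- 150
  sc <- setNames(rnorm(n), sprintf("s%03d", 1:n))
  tm <- rexp(n, 0.001 * exp(0.8 * sc))
  surv <- survival_table(names(sc), tm, rbinom(n, 1, 0.8))
  groups <- assign_groups(sc, median(sc))
  rep1 <- evaluate_signature(groups, surv, "toy", auc_years = 1,
                             n_boot = 50, seed = 2, calibration_years = 1)
  d <- withr::local_tempdir()
  p <- file.path(d, "report.json")
  write_report(rep1, p)
  back <- read_report(p)
  expect_equal(back$km_logrank_chisq, rep1$km_logrank_chisq)
  expect_equal(back$c_index, rep1$c_index)
  expect_equal(unlist(back$auc_by_year), unlist(rep1$auc_by_year),
               ignore_attr = TRUE)
})
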