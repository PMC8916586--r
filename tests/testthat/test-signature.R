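# simulate exponential PH survival from binary indicators
sim_ph <- function(ind, beta, n, censor_at = Inf, seed = 1) {
  set.seed(seed)
  lp <- as.numeric(crossprod(ind, beta))
  t_event <- rexp(n, rate = 0.002 * exp(lp))
  time <- pmin(t_event, censor_at)
  survival_table(colnames(ind), pmax(time, 0.1), as.numeric(t_event <= censor_at))
}

make_ind <- function(mat, genes = NULL) {
  if (is.null(genes)) {
    genes <- replicate(nrow(mat), paste(sample(letters, 8), collapse = ""))
  }
  pairs <- data.frame(gene_a = paste0(genes, "_a"), gene_b = paste0(genes, "_b"),
                      orientation = "A_gt_B", stringsAsFactors = FALSE)
  rownames(mat) <- paste(pairs$gene_a, pairs$gene_b, sep = "|")
  structure(list(pairs = pairs, indicators = mat),
            class = "PairIndicatorMatrix")
}

test_that("univariate screen recovers a planted log-hazard and skips constants", {
  set.seed(5)
  n <- 300
  reps <- 8
  est <- numeric(reps)
  for (r in 1:reps) {
    x <- matrix(rbinom(n, 1, 0.5), 1, n,
                dimnames = list(NULL, sprintf("s%03d", 1:n)))
    ind <- make_ind(x, "pair1")
    surv <- sim_ph(x, beta = 1, n = n, censor_at = 1500, seed = 100 + r)
    scr <- univariate_cox_screen(ind, surv)
    est[r] <- log(scr$hr)
  }
  expect_lt(abs(mean(est) - 1), 0.25)

  x2 <- rbind(x, 1)
  colnames(x2) <- colnames(x)
  ind2 <- make_ind(x2, c("pairA", "pairB"))
  expect_warning(scr2 <- univariate_cox_screen(ind2, surv), "constant")
  expect_equal(nrow(scr2), 1)
})

test_that("cross-cohort selection requires p and a shared hazard direction", {
  mk_screen <- function(hr, p) {
    data.frame(gene_a = c("A", "C", "E"), gene_b = c("B", "D", "F"),
               orientation = "A_gt_B", hr = hr,
               ci_low = hr / 2, ci_high = hr * 2, p_value = p,
               stringsAsFactors = FALSE)
  }
  screens <- list(
    train = mk_screen(c(1.4, 1.4, 0.7), c(0.01, 0.01, 0.30)),
    val1 = mk_screen(c(1.3, 0.8, 0.6), c(0.2, 0.2, 0.2)),
    val2 = mk_screen(c(1.6, 1.6, 0.9), c(0.2, 0.2, 0.2))
  )
  sel <- select_consistent_pairs(screens, "train", pipeline_config())
  # pair A|B: consistent direction + significant; C|D flips in val1;
  # E|F consistent (<1) but p = 0.30 in training
  expect_identical(sel$gene_a, "A")

  screens$val1 <- screens$val1[1:2, ]
  expect_error(select_consistent_pairs(screens, "train", pipeline_config()),
               "every cohort", class = "reopairs_validation_error")
})

test_that("the LASSO Cox fit is deterministic and recovers planted signals", {
  set.seed(77)
  n <- 400
  p_noise <- 12
  x <- rbind(
    matrix(rbinom(3 * n, 1, 0.5), 3, n),
    matrix(rbinom(p_noise * n, 1, 0.5), p_noise, n)
  )
  colnames(x) <- sprintf("s%03d", 1:n)
  ind <- make_ind(x, sprintf("g%02d", seq_len(nrow(x))))
  beta <- c(1, -1, 1, rep(0, p_noise))
  surv <- sim_ph(x, beta, n, censor_at = 1200, seed = 9)
  cfg <- pipeline_config(rng_seed = 42)
  m1 <- fit_lasso_cox(ind, surv, cfg)
  m2 <- fit_lasso_cox(ind, surv, cfg)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(pair_keys <- paste(m1$pairs$gene_a, m1$pairs$gene_b),
                   paste(m2$pairs$gene_a, m2$pairs$gene_b))
  # the three informative pairs are retained with the planted signs
  informative <- paste(ind$pairs$gene_a, ind$pairs$gene_b)[1:3]
  got <- match(informative, paste(m1$pairs$gene_a, m1$pairs$gene_b))
  expect_false(anyNA(got))
  expect_identical(sign(m1$coefficients[got]), c(1, -1, 1))

  expect_error(fit_lasso_cox(make_ind(x[1, , drop = FALSE], "solo"), surv, cfg),
               class = "reopairs_validation_error")
})

test_that("risk scores are the plain coefficient-indicator inner product", {
  model <- published_gc_signature()
  keys <- paste(model$pairs$gene_a, model$pairs$gene_b, sep = "|")
  ind_mat <- matrix(0, 14, 3,
                    dimnames = list(keys, c("none", "first_only", "all")))
  ind_mat["LINC00607|C5orf17", "first_only"] <- 1
  ind_mat[, "all"] <- 1
  ind <- structure(list(pairs = model$pairs, indicators = ind_mat),
                   class = "PairIndicatorMatrix")
  rs <- risk_score(model, ind)
  expect_equal(rs$score[rs$sample_id == "none"], 0)
  expect_equal(rs$score[rs$sample_id == "first_only"], 0.2793)
  expect_equal(rs$score[rs$sample_id == "all"], sum(model$coefficients))

  expect_error(
    risk_score(model, structure(list(pairs = model$pairs[1:2, ],
                                     indicators = ind_mat[1:2, ]),
                                class = "PairIndicatorMatrix")),
    class = "reopairs_validation_error"
  )
})

test_that("the optimal cutoff matches an exhaustive log-rank scan", {
  set.seed(19)
  n <- 60
  sc <- setNames(rnorm(n), sprintf("s%02d", 1:n))
  surv <- survival_table(names(sc), rexp(n, 0.01 * exp(0.8 * sc)) + 1,
                         rbinom(n, 1, 0.8))
  cut <- optimal_cutoff(sc, surv, min_group_frac = 0.10, min_samples = 20)

  u <- sort(unique(sc))
  cand <- (u[-1] + u[-length(u)]) / 2
  stats <- vapply(cand, function(cc) {
    hi <- sc > cc
    if (min(sum(hi), sum(!hi)) < ceiling(0.10 * n)) return(NA_real_)
    survival::survdiff(survival::Surv(surv$time, surv$event) ~ hi)$chisq
  }, numeric(1))
  expect_equal(cut, cand[which.max(stats)])

  # a perfectly separating score puts the cutoff between the clusters
  sc2 <- setNames(c(rep(0, 15), rep(10, 15)), sprintf("q%02d", 1:30))
  surv2 <- survival_table(names(sc2), c(seq(1000, 1500, length.out = 15),
                                        seq(10, 200, length.out = 15)),
                          rep(1, 30))
  cut2 <- optimal_cutoff(sc2, surv2)
  expect_gt(cut2, 0)
  expect_lt(cut2, 10)

  # min_group_frac = 0.5 leaves only the median split
  sc3 <- setNames(1:20, sprintf("r%02d", 1:20))
  surv3 <- survival_table(names(sc3), 21 - (1:20) + 0.5, rep(1, 20))
  cut3 <- optimal_cutoff(sc3, surv3, min_group_frac = 0.5)
  expect_equal(cut3, 10.5)

  expect_error(optimal_cutoff(setNames(rep(1, 30), sprintf("c%02d", 1:30)),
                              survival_table(sprintf("c%02d", 1:30),
                                             1:30, rep(1, 30))),
               class = "reopairs_validation_error")
})

test_that("group assignment is strict at the cutoff", {
  sc <- setNames(c(1, 2, 3), c("a", "b", "c"))
  g <- assign_groups(sc, 2)
  expect_identical(g$group, c("low", "low", "high"))
  g2 <- assign_groups(sc, 0)
  expect_identical(unique(g2$group), "high")
  expect_error(assign_groups(sc, NA_real_), class = "reopairs_validation_error")
})
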