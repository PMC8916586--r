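# Independent oracles, deliberately written as plain, slow reference
# implementations so they share no code path with the package.

# full running-sum walk of the weighted-KS statistic
oracle_es <- function(correlations, hit, exponent = 1) {
  n <- length(correlations)
  nh <- sum(hit)
  w <- abs(correlations)^exponent
  steps <- ifelse(hit, w / sum(w[hit]), -1 / (n - nh))
  running <- cumsum(steps)
  running[which.max(abs(running))]
}

# Benjamini-Hochberg step-up, by the textbook definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running_min <- Inf
  for (i in m:1) {
    val <- (m / i) * p[ord[i]]
    running_min <- min(running_min, val)
    q[ord[i]] <- min(running_min, 1)
  }
  q
}

# Harrell's C by explicit double loop over ordered pairs
oracle_harrell <- function(time, event, score) {
  num <- 0
  den <- 0
  n <- length(time)
  for (i in 1:n) {
    for (j in 1:n) {
      if (i == j) next
      usable <- (time[i] < time[j] && event[i] == 1) ||
        (time[i] == time[j] && event[i] == 1 && event[j] == 0)
      if (!usable) next
      den <- den + 1
      if (score[i] > score[j]) num <- num + 1
      if (score[i] == score[j]) num <- num + 0.5
    }
  }
  num / den
}

# binary Mann-Whitney AUC
oracle_binary_auc <- function(score, y) {
  pos <- score[y == 1]
  neg <- score[y == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# two-group log-rank chi-square from explicit risk tables
oracle_logrank <- function(time, event, group) {
  group <- as.integer(factor(group))
  taus <- sort(unique(time[event == 1]))
  obs1 <- 0
  exp1 <- 0
  varsum <- 0
  for (t in taus) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    obs1 <- obs1 + d1
    exp1 <- exp1 + d * n1 / n
    if (n > 1) {
      varsum <- varsum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  (obs1 - exp1)^2 / varsum
}

# strictly increasing random transform: x -> a * f((x - m) / s) + b with f
# drawn from a family of increasing maps; per-sample variants used for the
# REO invariance suite
random_monotone_fun <- function(seed) {
  set.seed(seed)
  fam <- sample(c("affine", "exp", "cube_shift", "log_shift", "power"), 1)
  a <- runif(1, 0.5, 3)
  b <- runif(1, -5, 5)
  switch(fam,
    affine = function(x) a * x + b,
    exp = function(x) a * exp(x / runif(1, 3, 8)) + b,
    cube_shift = function(x) a * (x - b)^3 + x, # x term keeps it strict
    log_shift = function(x) a * log(x - min(x) + runif(1, 0.5, 2)) + b,
    power = function(x) (x - min(x) + 1)^runif(1, 1.1, 2.5) + b
  )
}

apply_per_sample_monotone <- function(values, seed) {
  out <- values
  for (j in seq_len(ncol(values))) {
    f <- random_monotone_fun(seed + 131 * j)
    out[, j] <- f(values[, j])
  }
  out
}

# compact hand-built cohort: deterministic values, both gene types
tiny_cohort <- function(n_lnc = 4, n_mrna = 6, n_tumor = 5, n_normal = 4,
                        seed = 42) {
  set.seed(seed)
  genes <- c(sprintf("L%02d", 1:n_lnc), sprintf("M%02d", 1:n_mrna))
  samples <- c(sprintf("T%02d", 1:n_tumor), sprintf("N%02d", 1:n_normal))
  vals <- matrix(round(runif(length(genes) * length(samples), 1, 10), 3),
                 nrow = length(genes), dimnames = list(genes, samples))
  expression_cohort(
    vals,
    gene_type = setNames(rep(c("lncRNA", "mRNA"), c(n_lnc, n_mrna)), genes),
    sample_group = setNames(rep(c("tumor", "normal"), c(n_tumor, n_normal)),
                            samples),
    cohort_id = "tiny"
  )
}

# small, fast generator configuration shared across tests
small_sim_config <- function(...) {
  simulation_config(
    n_lncrna = 40, n_mrna = 150, n_pathway_genes = 25, n_true_pdls = 18,
    n_planted_pairs = 12, n_tumor = c(160, 140), n_normal = c(30, 26),
    n_cohorts = 2, ...
  )
}

# rank matrix straight from per-sample orderings given as a genes x samples
# value matrix
ranks_of <- function(mat) apply(mat, 2, rank)
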