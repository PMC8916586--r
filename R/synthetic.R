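#' Configuration for the synthetic multi-cohort generator
#'
#' Defaults emulate the study setting: three cohorts of 348, 300 and 191
#' tumor samples (with 32/28/22 adjacent normals), a 51-gene pathway set
#' inside the mRNA space, a subset of lncRNAs coupled to the latent pathway
#' activity, planted stable-to-reversal pair structure, and exponential
#' proportional-hazards survival driven by the planted pair indicators.
#'
#' Planted pairs are realized as fully reversing gene blocks: a block of m
#' lncRNAs occupies a private baseline window, ordered g1 < ... < gm in
#' normal tissue and exactly reversed in tumors, so all m(m-1)/2 within-block
#' pairs — and no pair involving outside genes — are stable-then-reversal
#' pairs. Because a two-gene swap alone makes one member deregulate "up" and
#' the other "down" (so the same-direction filter would discard it), blocks
#' of four are the smallest unit whose rising half and falling half each
#' contribute a same-direction reversal pair; `n_planted_pairs` is composed
#' greedily from blocks of size 4 (6 pairs), 3 (3 pairs) and 2 (1 pair).
#'
#' @param n_lncrna,n_mrna Number of simulated lncRNAs / mRNAs.
#' @param n_pathway_genes Pathway set size (first mRNAs; default 51).
#' @param n_true_pdls lncRNAs coupled to the latent pathway factor (the
#'   first `n_true_pdls` lncRNAs; block members are drawn from this set when
#'   it is large enough, so planted pairs survive coupled-lncRNA discovery).
#' @param n_planted_pairs Total planted reversal pairs (default 24 = four
#'   4-gene blocks).
#' @param n_tumor,n_normal Per-cohort sample counts (recycled to
#'   `n_cohorts`).
#' @param n_cohorts Number of cohorts.
#' @param coupling_strength In [0, 1]; scales the latent-factor loading of
#'   pathway mRNAs and coupled lncRNAs (loading = 2 * coupling_strength on
#'   the log2 scale).
#' @param beta_range Magnitude range of planted log-hazard coefficients;
#'   the sign alternates per block.
#' @param censoring_rate_target Desired censoring fraction; the uniform
#'   censoring window is calibrated analytically to hit it.
#' @param baseline_hazard Baseline exponential event rate per day.
#' @param noise_sd Gene-level Gaussian noise SD (log2 scale).
#' @param pair_spacing Baseline spacing between consecutive block members;
#'   the default 0.465 with `noise_sd = 0.2` puts the per-sample orientation
#'   probability of adjacent members near 0.95, above the 0.85 support
#'   rules with margin at the default normal-sample counts.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_lncrna = 120L, n_mrna = 800L,
                              n_pathway_genes = 51L, n_true_pdls = 20L,
                              n_planted_pairs = 24L,
                              n_tumor = c(348L, 300L, 191L),
                              n_normal = c(32L, 28L, 22L),
                              n_cohorts = 3L,
                              coupling_strength = 0.9,
                              beta_range = c(0.8, 1.4),
                              censoring_rate_target = 0.40,
                              baseline_hazard = 5e-4,
                              noise_sd = 0.2,
                              pair_spacing = 0.465) {
  if (n_pathway_genes > n_mrna) abort_validation("n_pathway_genes must be <= n_mrna")
  if (n_true_pdls > n_lncrna) abort_validation("n_true_pdls must be <= n_lncrna")
  if (censoring_rate_target <= 0 || censoring_rate_target >= 1) {
    abort_validation("censoring_rate_target must lie in (0, 1)")
  }
  if (baseline_hazard <= 0 || noise_sd < 0) {
    abort_validation("baseline_hazard must be positive and noise_sd non-negative")
  }
  if (any(c(n_lncrna, n_mrna, n_cohorts) < 1) || any(n_tumor < 1) ||
      n_planted_pairs < 0) {
    abort_validation("counts must be non-negative (sample counts positive)")
  }
  sizes <- decompose_pair_blocks(n_planted_pairs)
  if (sum(sizes) > n_lncrna) {
    abort_validation(sprintf(
      "infeasible config: %d planted pairs need %d block genes but only %d lncRNAs",
      n_planted_pairs, sum(sizes), n_lncrna
    ))
  }
  windows <- allocate_block_windows(sizes, pair_spacing)
  structure(
    list(
      n_lncrna = as.integer(n_lncrna), n_mrna = as.integer(n_mrna),
      n_pathway_genes = as.integer(n_pathway_genes),
      n_true_pdls = as.integer(n_true_pdls),
      n_planted_pairs = as.integer(n_planted_pairs),
      n_tumor = rep_len(as.integer(n_tumor), n_cohorts),
      n_normal = rep_len(as.integer(n_normal), n_cohorts),
      n_cohorts = as.integer(n_cohorts),
      coupling_strength = coupling_strength,
      beta_range = beta_range,
      censoring_rate_target = censoring_rate_target,
      baseline_hazard = baseline_hazard,
      noise_sd = noise_sd,
      pair_spacing = pair_spacing,
      block_sizes = sizes,
      block_windows = windows
    ),
    class = "SimulationConfig"
  )
}

# Compose n pairs from fully reversing blocks of 4 (6 pairs), 3 (3 pairs)
# and 2 (1 pair); every n >= 0 is representable.
decompose_pair_blocks <- function(n) {
  sizes <- rep(4L, n %/% 6)
  c(sizes, switch(n %% 6 + 1L,
                  integer(0), 2L, c(2L, 2L), 3L, c(3L, 2L), c(3L, 2L, 2L)))
}

BASELINE_RANGE <- c(2, 14)
WINDOW_MARGIN <- 0.32
WINDOW_GAP <- 0.4

# Private, non-overlapping baseline windows for the blocks, stacked from the
# bottom of the baseline range; errors when they do not fit.
allocate_block_windows <- function(sizes, spacing) {
  if (!length(sizes)) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  spans <- (sizes - 1) * spacing
  start <- numeric(length(sizes))
  pos <- BASELINE_RANGE[1] + 0.5 + WINDOW_MARGIN
  for (i in seq_along(sizes)) {
    start[i] <- pos
    pos <- pos + spans[i] + WINDOW_GAP + 2 * WINDOW_MARGIN
  }
  if (start[length(sizes)] + spans[length(sizes)] + WINDOW_MARGIN >
      BASELINE_RANGE[2] - 0.5) {
    abort_validation("infeasible config: planted blocks do not fit the baseline range")
  }
  data.frame(start = start, end = start + spans)
}

# Uniform-censoring window u such that the expected censoring fraction
# mean_s (1 - exp(-rate_s * u)) / (rate_s * u) equals the target; the
# expression decreases monotonically from 1 (u -> 0) to 0 (u -> Inf).
calibrate_censoring_window <- function(rates, target) {
  f <- function(u) mean((1 - exp(-rates * u)) / (rates * u)) - target
  stats::uniroot(f, lower = 1e-9, upper = 1e12, tol = 1e-10)$root
}

COHORT_TRANSFORMS <- list(
  identity = list(fun = identity, label = "identity"),
  affine = list(fun = function(x) 1.3 * x + 2, label = "affine: 1.3x + 2"),
  expscale = list(fun = function(x) exp(x / 4), label = "exponential: exp(x/4)")
)

#' Simulate multi-cohort expression and survival data with planted truth
#'
#' Generative model, per cohort: (i) a latent pathway activity z_s ~ N(0, 1)
#' per sample; pathway mRNAs and coupled lncRNAs load on z with loading
#' 2 * `coupling_strength`, all other genes are independent noise around
#' gene-specific baselines. (ii) Planted reversal structure: each block of
#' lncRNAs occupies a private baseline window, ordered g1 < ... < gm in
#' normals and exactly reversed in tumors (see [simulation_config()]), so
#' the within-block pairs are stable pairs in normals and reversal pairs in
#' tumors and no other pair changes orientation. (iii) Tumor event times are
#' exponential with rate `baseline_hazard` * exp(sum beta_p x_ps) over the
#' planted binary pair indicators; censoring is uniform on a window
#' calibrated to the target censoring rate. (iv) Each cohort's matrix passes
#' through its own strictly increasing transform (identity / affine /
#' exponential, cycled) to emulate platform differences.
#'
#' All randomness derives from `seed` via fixed per-cohort/per-stage
#' substreams; identical (config, seed) gives bitwise-identical output.
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed.
#' @return List with `cohorts` (list of [expression_cohort()]), `survival`
#'   (list of [survival_table()], tumor samples only), `truth`
#'   (`SimulationTruth`: `true_pdl_ids`, `pathway_gene_ids`,
#'   `planted_pairs`, `true_betas`, `blocks`, `cohort_transforms`,
#'   `rng_seed`) and `gene_set` (the pathway [gene_set()]).
#' @export
simulate_cohorts <- function(cfg = simulation_config(), seed = 1L) {
  lnc_ids <- sprintf("LNC%03d", seq_len(cfg$n_lncrna))
  mrna_ids <- sprintf("MRNA%04d", seq_len(cfg$n_mrna))
  pathway_ids <- mrna_ids[seq_len(cfg$n_pathway_genes)]
  true_pdls <- lnc_ids[seq_len(cfg$n_true_pdls)]

  sizes <- cfg$block_sizes
  windows <- cfg$block_windows
  n_members <- sum(sizes)
  block_of <- rep(seq_along(sizes), sizes)
  member_ids <- lnc_ids[seq_len(n_members)]
  blocks <- split(member_ids, block_of)

  gene_ids <- c(lnc_ids, mrna_ids)
  gene_type <- stats::setNames(
    c(rep("lncRNA", cfg$n_lncrna), rep("mRNA", cfg$n_mrna)), gene_ids
  )

  # member baselines: evenly spaced inside the block window, order reversed
  # in tumors
  mu_member_normal <- unlist(lapply(seq_along(sizes), function(b) {
    windows$start[b] + (seq_len(sizes[b]) - 1) * cfg$pair_spacing
  }), use.names = FALSE)
  mu_member_tumor <- unlist(lapply(seq_along(sizes), function(b) {
    windows$start[b] + (rev(seq_len(sizes[b])) - 1) * cfg$pair_spacing
  }), use.names = FALSE)

  # all other genes: baselines uniform outside the block windows (+ margin)
  forbidden <- cbind(windows$start - WINDOW_MARGIN, windows$end + WINDOW_MARGIN)
  n_other <- length(gene_ids) - n_members
  shared <- with_local_seed(substream_seed(seed, 0L), {
    draw <- stats::runif(n_other, BASELINE_RANGE[1], BASELINE_RANGE[2])
    if (nrow(forbidden)) {
      repeat {
        inside <- rep(FALSE, n_other)
        for (b in seq_len(nrow(forbidden))) {
          inside <- inside | (draw > forbidden[b, 1] & draw < forbidden[b, 2])
        }
        if (!any(inside)) break
        draw[inside] <- stats::runif(sum(inside), BASELINE_RANGE[1],
                                     BASELINE_RANGE[2])
      }
    }
    betas <- numeric(0)
    if (cfg$n_planted_pairs > 0) {
      n_pairs_per_block <- sizes * (sizes - 1) / 2
      mags <- stats::runif(cfg$n_planted_pairs, cfg$beta_range[1],
                           cfg$beta_range[2])
      signs <- rep(rep_len(c(1, -1), length(sizes)), n_pairs_per_block)
      betas <- mags * signs
    }
    list(other_baselines = draw, betas = betas)
  })

  planted <- if (cfg$n_planted_pairs > 0) {
    per_block <- lapply(seq_along(sizes), function(b) {
      idx <- utils::combn(blocks[[b]], 2)
      data.frame(gene_a = idx[1, ], gene_b = idx[2, ], block = b,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, per_block)
    out$orientation <- "A_gt_B"          # tumor ordering
    out$normal_orientation <- "A_lt_B"
    out$beta <- shared$betas
    rownames(out) <- NULL
    out
  } else {
    data.frame(gene_a = character(0), gene_b = character(0),
               block = integer(0), orientation = character(0),
               normal_orientation = character(0), beta = numeric(0))
  }

  other_ids <- setdiff(gene_ids, member_ids)
  mu_normal <- stats::setNames(numeric(length(gene_ids)), gene_ids)
  mu_normal[member_ids] <- mu_member_normal
  mu_normal[other_ids] <- shared$other_baselines
  mu_tumor <- mu_normal
  mu_tumor[member_ids] <- mu_member_tumor

  loading <- stats::setNames(numeric(length(gene_ids)), gene_ids)
  loading[c(pathway_ids, true_pdls)] <- 2 * cfg$coupling_strength

  transform_ids <- rep_len(names(COHORT_TRANSFORMS), cfg$n_cohorts)
  cohorts <- vector("list", cfg$n_cohorts)
  survs <- vector("list", cfg$n_cohorts)
  for (ci in seq_len(cfg$n_cohorts)) {
    cohort_id <- sprintf("cohort_%d", ci)
    nt <- cfg$n_tumor[ci]
    nn <- cfg$n_normal[ci]
    tumor_ids <- sprintf("%s_T%03d", cohort_id, seq_len(nt))
    normal_ids <- if (nn > 0) sprintf("%s_N%03d", cohort_id, seq_len(nn)) else character(0)
    sample_ids <- c(tumor_ids, normal_ids)
    is_tumor <- c(rep(TRUE, nt), rep(FALSE, nn))

    gen <- with_local_seed(substream_seed(seed, 10L * ci + 1L), {
      z <- stats::rnorm(length(sample_ids))
      eps <- matrix(stats::rnorm(length(gene_ids) * length(sample_ids)),
                    nrow = length(gene_ids))
      list(z = z, eps = eps)
    })
    mu_mat <- matrix(mu_normal, nrow = length(gene_ids), ncol = length(sample_ids))
    mu_mat[, is_tumor] <- mu_tumor
    values <- mu_mat + outer(loading, gen$z) + cfg$noise_sd * gen$eps
    dimnames(values) <- list(gene_ids, sample_ids)

    if (cfg$n_planted_pairs > 0) {
      xa <- values[planted$gene_a, tumor_ids, drop = FALSE]
      xb <- values[planted$gene_b, tumor_ids, drop = FALSE]
      lp <- as.numeric(crossprod((xa > xb) + 0, planted$beta))
    } else {
      lp <- numeric(nt)
    }
    rates <- cfg$baseline_hazard * exp(lp)
    window <- calibrate_censoring_window(rates, cfg$censoring_rate_target)
    sv <- with_local_seed(substream_seed(seed, 10L * ci + 2L), {
      t_event <- stats::rexp(nt, rate = rates)
      t_cens <- stats::runif(nt, 0, window)
      age <- round(stats::rnorm(nt, 65, 10))
      sex <- sample(c("M", "F"), nt, replace = TRUE)
      list(time = pmax(pmin(t_event, t_cens), 0.5),
           event = as.numeric(t_event <= t_cens),
           age = age, sex = sex)
    })

    tf <- COHORT_TRANSFORMS[[transform_ids[ci]]]
    cohorts[[ci]] <- expression_cohort(
      tf$fun(values),
      gene_type = gene_type,
      sample_group = stats::setNames(ifelse(is_tumor, "tumor", "normal"),
                                     sample_ids),
      cohort_id = cohort_id
    )
    survs[[ci]] <- survival_table(
      tumor_ids, sv$time, sv$event,
      covariates = data.frame(age = sv$age, sex = sv$sex),
      endpoint = "OS"
    )
  }
  names(cohorts) <- names(survs) <- vapply(cohorts, `[[`, "", "cohort_id")

  truth <- structure(
    list(
      true_pdl_ids = true_pdls,
      pathway_gene_ids = pathway_ids,
      planted_pairs = planted,
      true_betas = stats::setNames(
        planted$beta, paste(planted$gene_a, planted$gene_b, sep = "|")
      ),
      blocks = blocks,
      cohort_transforms = stats::setNames(
        vapply(transform_ids, function(id) COHORT_TRANSFORMS[[id]]$label, ""),
        names(cohorts)
      ),
      rng_seed = as.integer(seed)
    ),
    class = "SimulationTruth"
  )
  list(
    cohorts = cohorts,
    survival = survs,
    truth = truth,
    gene_set = gene_set("synthetic_pathway", pathway_ids)
  )
}

#' Apply a strictly increasing transform to a cohort
#'
#' Within-sample ranks — and therefore every downstream pair statistic — are
#' unchanged by such a transform; this operation makes that claim testable.
#' The transform is validated numerically on the data's range and rejected
#' if not strictly increasing.
#'
#' @param cohort An [expression_cohort()].
#' @param transform One of the registered ids (`"identity"`,
#'   `"affine_2x_plus_1"`, `"cube"`, `"expscale"`, `"negate"` — the last
#'   fails validation by design) or any function of a numeric vector.
#' @return The transformed cohort.
#' @export
apply_monotone_transform <- function(cohort, transform) {
  registry <- list(
    identity = identity,
    affine_2x_plus_1 = function(x) 2 * x + 1,
    cube = function(x) x^3,
    expscale = function(x) exp(x / 4),
    negate = function(x) -x
  )
  f <- if (is.function(transform)) {
    transform
  } else if (is.character(transform) && transform %in% names(registry)) {
    registry[[transform]]
  } else {
    abort_validation(sprintf("unknown transform id '%s'", transform))
  }
  probe <- sort(unique(as.numeric(cohort$values)))
  if (length(probe) > 1000) {
    probe <- probe[unique(round(seq(1, length(probe), length.out = 1000)))]
  }
  out_probe <- f(probe)
  if (any(!is.finite(out_probe)) || any(diff(out_probe) <= 0)) {
    abort_validation("transform is not strictly increasing on the data's range")
  }
  vals <- f(cohort$values)
  expression_cohort(vals, cohort$gene_type, cohort$sample_group,
                    cohort$cohort_id, scale = cohort$scale)
}
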