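# rank matrix for two genes with rank(A) < rank(B) in exactly k of n samples
two_gene_ranks <- function(k, n, genes = c("A", "B")) {
  m <- matrix(0, 2, n, dimnames = list(genes, sprintf("s%03d", 1:n)))
  m[1, ] <- c(rep(1, k), rep(2, n - k))
  m[2, ] <- c(rep(2, k), rep(1, n - k))
  m
}

test_that("rank transform follows the stated conventions", {
  m <- matrix(c(2, 5, 3), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(unname(rank_transform(m)[, 1]), c(1, 3, 2))

  m2 <- matrix(c(4, 4, 1), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(unname(rank_transform(m2)[, 1]), c(2.5, 2.5, 1))

  co <- tiny_cohort()
  expect_identical(rank_transform(exp(co$values)), rank_transform(co$values))
  expect_error(rank_transform(co, "NOPE"), "NOPE",
               class = "reopairs_validation_error")
  # column sums are invariant under the average-tie convention
  rk <- rank_transform(co)
  g <- nrow(rk)
  expect_true(all(colSums(rk) == g * (g + 1) / 2))
})

test_that("stable pairs use an inclusive 85% bound", {
  expect_equal(find_stable_pairs(two_gene_ranks(100, 100))$support_normal, 1.0)

  at_boundary <- find_stable_pairs(two_gene_ranks(85, 100), stable_frac = 0.85)
  expect_equal(nrow(at_boundary), 1)
  expect_identical(at_boundary$orientation, "A_lt_B")
  expect_equal(at_boundary$support_normal, 0.85)

  expect_equal(nrow(find_stable_pairs(two_gene_ranks(60, 100))), 0)
  expect_error(find_stable_pairs(two_gene_ranks(3, 3)), "normal",
               class = "reopairs_validation_error")
})

test_that("reversal pairs need the opposite tumor ordering at 85%", {
  stable <- find_stable_pairs(two_gene_ranks(95, 100)) # stable as A < B
  rev_yes <- find_reversal_pairs(two_gene_ranks(10, 100), stable)
  expect_equal(nrow(rev_yes), 1)
  expect_identical(rev_yes$orientation, "A_gt_B")
  expect_equal(rev_yes$support_tumor, 0.90)

  rev_no <- find_reversal_pairs(two_gene_ranks(50, 100), stable)
  expect_equal(nrow(rev_no), 0)
})

test_that("noiseless planted cohorts are recovered exactly", {
  cfg <- simulation_config(
    n_lncrna = 30, n_mrna = 30, n_pathway_genes = 10, n_true_pdls = 16,
    n_planted_pairs = 12, n_tumor = 80, n_normal = 20, n_cohorts = 1,
    noise_sd = 0
  )
  sim <- simulate_cohorts(cfg, seed = 2)
  co <- sim$cohorts[[1]]
  lnc <- names(co$gene_type)[co$gene_type == "lncRNA"]
  rk_n <- rank_transform(co, lnc, cohort_samples(co, "normal"))
  rk_t <- rank_transform(co, lnc, cohort_samples(co, "tumor"))
  rev <- find_reversal_pairs(rk_t, find_stable_pairs(rk_n), 0.85)
  expect_setequal(
    paste(rev$gene_a, rev$gene_b, rev$orientation),
    paste(sim$truth$planted_pairs$gene_a, sim$truth$planted_pairs$gene_b,
          sim$truth$planted_pairs$orientation)
  )
  expect_true(all(rev$support_normal == 1) && all(rev$support_tumor == 1))
})

test_that("deregulation directions compare median ranks", {
  rk_n <- matrix(c(1, 2, 3), 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  rk_t <- matrix(c(3, 2, 1), 3, 5, dimnames = list(c("a", "b", "c"), NULL))
  d <- deregulation_directions(rk_t, rk_n)
  expect_identical(d$direction, c("up", "unchanged", "down"))
  expect_equal(d$median_rank_tumor, unname(apply(rk_t, 1, median)))
  expect_error(deregulation_directions(rk_t[1:2, ], rk_n),
               class = "reopairs_validation_error")
})

test_that("same-direction filter drops opposite and unchanged members", {
  pairs <- data.frame(
    gene_a = c("A", "A", "A"), gene_b = c("B", "D", "U"),
    orientation = "A_gt_B", stringsAsFactors = FALSE
  )
  directions <- data.frame(
    gene_id = c("A", "B", "D", "U"),
    direction = c("up", "up", "down", "unchanged"),
    stringsAsFactors = FALSE
  )
  kept <- filter_same_direction(pairs, directions)
  expect_identical(kept$gene_b, "B")
  expect_error(filter_same_direction(pairs, directions[1:2, ]),
               class = "reopairs_validation_error")
})

test_that("CV pruning keeps the top partners per anchor from either side", {
  set.seed(8)
  genes <- sprintf("G%d", 1:6)
  ranks <- matrix(sample(6 * 30), 6, 30, dimnames = list(genes, NULL))
  ranks <- apply(ranks, 2, rank)
  pairs <- enumerate_pairs(genes) # complete graph: 15 pairs
  pairs$orientation <- "A_gt_B"
  pruned <- partner_cv_prune(pairs, ranks, top_k = 2)

  # brute-force the rule: CV = sd/|mean| of the rank difference (symmetric
  # in the two genes); survivors are pairs inside the top-2 CV partners of
  # at least one member
  cv_brute <- vapply(seq_len(nrow(pairs)), function(i) {
    d <- ranks[pairs$gene_a[i], ] - ranks[pairs$gene_b[i], ]
    sd(d) / abs(mean(d))
  }, numeric(1))
  survives <- vapply(seq_len(nrow(pairs)), function(i) {
    any(vapply(c(pairs$gene_a[i], pairs$gene_b[i]), function(g) {
      mine <- which(pairs$gene_a == g | pairs$gene_b == g)
      rank_in <- rank(-cv_brute[mine], ties.method = "first")
      rank_in[match(i, mine)] <= 2
    }, logical(1)))
  }, logical(1))
  expect_setequal(paste(pruned$gene_a, pruned$gene_b),
                  paste(pairs$gene_a, pairs$gene_b)[survives])
  expect_equal(pruned$cv, cv_brute[survives], tolerance = 1e-12)
  # each gene contributes at most top_k pairs from its own side, so the
  # survivor count is bounded by top_k * n_genes
  expect_lte(nrow(pruned), 2 * length(genes))

  # single-partner anchors always survive
  single <- data.frame(gene_a = "G4", gene_b = "G5", orientation = "A_lt_B",
                       stringsAsFactors = FALSE)
  expect_equal(nrow(partner_cv_prune(single, ranks, top_k = 3)), 1)
})

test_that("qualification is strict at the 60% bound", {
  pairs <- data.frame(gene_a = "A", gene_b = "B", orientation = "A_lt_B",
                      stringsAsFactors = FALSE)
  expect_equal(nrow(qualify_pairs(pairs, two_gene_ranks(61, 100), 0.60)), 1)
  expect_equal(nrow(qualify_pairs(pairs, two_gene_ranks(60, 100), 0.60)), 0)
  q <- qualify_pairs(pairs, two_gene_ranks(100, 100), 0.60)
  expect_equal(q$support_tumor, 1.0)
})

test_that("pair indicators encode strict orderings with ties as zero", {
  vals <- matrix(c(7.1, 3.2,
                   2.0, 2.0,
                   1.0, 4.0), nrow = 2,
                 dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  pairs <- data.frame(gene_a = "A", gene_b = "B", stringsAsFactors = FALSE)
  ind <- encode_pairs(vals, pairs)
  expect_equal(unname(ind$indicators[1, ]), c(1, 0, 0))
  expect_error(encode_pairs(vals, data.frame(gene_a = "A", gene_b = "Z")),
               "Z", class = "reopairs_validation_error")

  co <- tiny_cohort()
  pr <- enumerate_pairs(rownames(co$values))
  warped <- apply_per_sample_monotone(co$values, seed = 1)
  expect_identical(encode_pairs(warped, pr)$indicators,
                   encode_pairs(co$values, pr)$indicators)
})

test_that("pair enumeration counts n(n-1)/2 canonical pairs", {
  expect_equal(nrow(enumerate_pairs(c("x", "y"))), 1)
  expect_equal(nrow(enumerate_pairs(sprintf("g%d", 1:5))), 10)
  for (n in c(2, 3, 17, 120, 350)) {
    p <- enumerate_pairs(sprintf("g%04d", seq_len(n)))
    expect_equal(nrow(p), n * (n - 1) / 2)
    expect_true(all(p$gene_a < p$gene_b))
    expect_false(any(duplicated(paste(p$gene_a, p$gene_b))))
  }
  expect_error(enumerate_pairs("only"), class = "reopairs_validation_error")
  expect_error(enumerate_pairs(c("a", "a")), class = "reopairs_validation_error")
})

test_that("pair-set intersection demands identical tumor orientation", {
  s1 <- data.frame(gene_a = c("A", "C"), gene_b = c("B", "D"),
                   orientation = c("A_gt_B", "A_lt_B"),
                   support_tumor = c(0.9, 0.88), stringsAsFactors = FALSE)
  expect_identical(intersect_pair_sets(list(x = s1, y = s1))[, 1:3], s1[, 1:3])

  s2 <- s1
  s2$orientation <- c("A_gt_B", "A_gt_B") # second pair flipped
  both <- intersect_pair_sets(list(x = s1, y = s2))
  expect_identical(both$gene_a, "A")

  # random sets match a hash-set intersection
  set.seed(14)
  universe <- enumerate_pairs(sprintf("g%02d", 1:12))
  mk <- function() {
    idx <- sample(nrow(universe), 30)
    out <- universe[idx, ]
    out$orientation <- sample(c("A_gt_B", "A_lt_B"), 30, replace = TRUE)
    out
  }
  sets <- list(a = mk(), b = mk(), c = mk())
  got <- intersect_pair_sets(sets)
  keys <- lapply(sets, function(s) paste(s$gene_a, s$gene_b, s$orientation))
  expect_setequal(paste(got$gene_a, got$gene_b, got$orientation),
                  Reduce(intersect, keys))
})

test_that("the pair stages nest as reversal >= same-direction >= pruned >= qualified", {
  sim <- simulate_cohorts(small_sim_config(), seed = 31)
  co <- sim$cohorts[[1]]
  lnc <- names(co$gene_type)[co$gene_type == "lncRNA"]
  rk_n <- rank_transform(co, lnc, cohort_samples(co, "normal"))
  rk_t <- rank_transform(co, lnc, cohort_samples(co, "tumor"))
  stable <- find_stable_pairs(rk_n)
  rev <- find_reversal_pairs(rk_t, stable)
  samedir <- filter_same_direction(rev, deregulation_directions(rk_t, rk_n))
  pruned <- partner_cv_prune(samedir, rk_t, 3)
  qual <- qualify_pairs(pruned, rk_t, 0.6)
  key <- function(p) paste(p$gene_a, p$gene_b)
  expect_true(all(key(rev) %in% key(stable)))
  expect_true(all(key(samedir) %in% key(rev)))
  expect_true(all(key(pruned) %in% key(samedir)))
  expect_true(all(key(qual) %in% key(pruned)))
})
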