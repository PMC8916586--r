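#' Rank mRNAs by correlation with a lncRNA
#'
#' All mRNAs of the cohort are ordered by decreasing correlation with the
#' given lncRNA, computed over tumor samples. Ties are broken by gene id
#' (lexicographic) so the ordering is deterministic.
#'
#' @param cohort An [expression_cohort()] containing both gene types.
#' @param lncrna_id A gene typed `lncRNA`.
#' @param method `"spearman"` (default; monotone-invariant) or `"pearson"`.
#' @return A `CorrelationRanking`: list with `lncrna_id`,
#'   `mrna_ids_ordered`, `correlations` (non-increasing, aligned).
#' @export
correlation_ranking <- function(cohort, lncrna_id,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!lncrna_id %in% rownames(cohort$values)) {
    abort_validation(sprintf("unknown gene '%s'", lncrna_id))
  }
  if (cohort$gene_type[[lncrna_id]] != "lncRNA") {
    abort_validation(sprintf("'%s' is not typed lncRNA", lncrna_id))
  }
  tumor <- cohort_samples(cohort, "tumor")
  if (length(tumor) < 3) abort_validation("need >= 3 tumor samples for correlation")
  mrna_ids <- names(cohort$gene_type)[cohort$gene_type == "mRNA"]
  if (!length(mrna_ids)) abort_validation("cohort has no mRNAs")
  x <- cohort$values[lncrna_id, tumor]
  if (stats::sd(x) == 0) {
    abort_validation(sprintf("lncRNA '%s' has zero variance in tumor samples", lncrna_id))
  }
  m <- t(cohort$values[mrna_ids, tumor, drop = FALSE])
  r <- drop(stats::cor(m, x, method = method))
  if (anyNA(r)) {
    abort_validation(paste0(
      "undefined correlation (zero-variance mRNA?): ",
      paste(utils::head(mrna_ids[is.na(r)], 5), collapse = ", ")
    ))
  }
  ord <- order(-r, mrna_ids, method = "radix")
  structure(
    list(lncrna_id = lncrna_id, mrna_ids_ordered = mrna_ids[ord],
         correlations = unname(r[ord])),
    class = "CorrelationRanking"
  )
}

# Weighted-KS running-sum enrichment statistic evaluated from the positions
# of the set genes ("hits") in the ranked list. Hits step the running sum up
# by |corr|^p / sum(|corr|^p over hits); misses step it down by 1/(N - Nh).
# The extrema of the running sum occur immediately after a hit (tops) or
# immediately before one (bottoms), so only 2*Nh candidates are examined; the
# signed value of maximal absolute deviation is returned (earliest position
# wins ties). Equivalent to the full N-step walk, which the test suite
# recomputes as an independent oracle.
es_from_positions <- function(abs_corr_pow, hit_pos, n_total) {
  k <- length(hit_pos)
  if (k == 0) abort_validation("gene set does not intersect the ranked list")
  if (k >= n_total) {
    abort_validation("gene set must be smaller than the ranked universe")
  }
  w <- abs_corr_pow[hit_pos]
  W <- sum(w)
  if (W == 0) {
    w <- rep(1, k)
    W <- k
  }
  miss_step <- 1 / (n_total - k)
  cw <- cumsum(w) / W
  miss_before <- (hit_pos - seq_len(k)) * miss_step
  tops <- cw - miss_before
  bottoms <- c(0, cw[-k]) - miss_before
  cand_val <- c(tops, bottoms)
  cand_pos <- c(hit_pos, hit_pos - 1)
  keep <- cand_pos > 0
  cand_val <- cand_val[keep]
  cand_pos <- cand_pos[keep]
  best <- max(abs(cand_val))
  at <- which(abs(cand_val) == best)
  cand_val[at[which.min(cand_pos[at])]]
}

#' Weighted-KS enrichment score of a gene set in a correlation ranking
#'
#' Classic GSEA running-sum statistic: walking the ordered mRNA list, set
#' members ("hits") increment the running sum by |corr|^`weight_exponent`
#' normalized over hits, non-members decrement it by 1/(N - Nh); the score is
#' the signed running-sum value of maximal absolute deviation from zero,
#' bounded in [-1, 1]. +1 means all set genes occupy the top of the list,
#' -1 the bottom.
#'
#' @param ranking A [correlation_ranking()].
#' @param gene_set A [gene_set()].
#' @param weight_exponent Exponent on |correlation| (default 1).
#' @return The enrichment score (scalar in [-1, 1]).
#' @export
enrichment_score <- function(ranking, gene_set, weight_exponent = 1) {
  ids <- ranking$mrna_ids_ordered
  hit_pos <- which(ids %in% gene_set$members)
  es_from_positions(abs(ranking$correlations)^weight_exponent, hit_pos,
                    length(ids))
}

#' Permutation test for the enrichment score
#'
#' The null distribution is the enrichment score of `n_perm` random gene
#' sets of the same size drawn without replacement from the ranked universe.
#' The two-sided p-value uses the add-one rule:
#' p = (1 + #\{|ES_null| >= |ES_obs|\}) / (n_perm + 1), so p is never 0.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed.
#' @return List with `pes` (observed score) and `p_value`.
#' @export
pes_permutation_test <- function(ranking, gene_set, n_perm = 1000L,
                                 seed = 1L, weight_exponent = 1) {
  if (n_perm < 100) abort_validation("n_perm must be >= 100")
  ids <- ranking$mrna_ids_ordered
  n <- length(ids)
  k <- length(intersect(gene_set$members, ids))
  if (k >= n) abort_validation("gene set must be smaller than the ranked universe")
  w <- abs(ranking$correlations)^weight_exponent
  obs <- enrichment_score(ranking, gene_set, weight_exponent)
  null_es <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      es_from_positions(w, sort.int(sample.int(n, k)), n)
    }, numeric(1))
  })
  p <- (1 + sum(abs(null_es) >= abs(obs))) / (n_perm + 1)
  list(pes = obs, p_value = p)
}

#' Identify pathway-coupled lncRNAs
#'
#' For every lncRNA in the cohort: rank all mRNAs by correlation (tumor
#' samples), compute the weighted-KS enrichment score of the pathway set,
#' assign a permutation p-value, BH-adjust across lncRNAs, and flag lncRNAs
#' with |score| > `pes_abs_threshold` AND q < `fdr_threshold` (both strict).
#' Per-lncRNA permutation streams are derived from `cfg$rng_seed` and the
#' lncRNA id's position in the sorted id list, so results do not depend on
#' the row order of the input matrix.
#'
#' @param cohort An [expression_cohort()] with both gene types.
#' @param gene_set A [gene_set()] of pathway mRNAs.
#' @param cfg A [pipeline_config()].
#' @return Data frame (`PESResult`): `lncrna_id`, `pes`, `p_value`,
#'   `q_value`, `n_permutations`, `is_pdl`.
#' @export
identify_pdls <- function(cohort, gene_set, cfg = pipeline_config()) {
  lnc_ids <- names(cohort$gene_type)[cohort$gene_type == "lncRNA"]
  if (!length(lnc_ids)) abort_validation("cohort contains no lncRNAs")
  lnc_sorted <- sort(lnc_ids, method = "radix")
  res <- lapply(lnc_sorted, function(id) {
    rk <- correlation_ranking(cohort, id, method = cfg$correlation_method)
    pt <- pes_permutation_test(
      rk, gene_set,
      n_perm = cfg$n_permutations,
      seed = substream_seed(cfg$rng_seed, match(id, lnc_sorted)),
      weight_exponent = cfg$weight_exponent
    )
    c(pes = pt$pes, p_value = pt$p_value)
  })
  res <- do.call(rbind, res)
  q <- stats::p.adjust(res[, "p_value"], method = "BH")
  data.frame(
    lncrna_id = lnc_sorted,
    pes = res[, "pes"],
    p_value = res[, "p_value"],
    q_value = q,
    n_permutations = cfg$n_permutations,
    is_pdl = abs(res[, "pes"]) > cfg$pes_abs_threshold & q < cfg$fdr_threshold,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
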