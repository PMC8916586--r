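#' Within-sample rank transform
#'
#' Converts expression to ranks per sample (column): the smallest value maps
#' to rank 1, the greatest to the maximum rank; ties take the average rank.
#' Ranks are invariant to any strictly increasing per-sample transform of the
#' expression values, which is what makes the downstream pair encoding
#' platform-robust.
#'
#' @param cohort An [expression_cohort()] or a numeric genes x samples matrix.
#' @param gene_subset Gene ids to rank over (ranks are relative to this
#'   subset only). Default: all genes.
#' @param samples Optional sample ids to keep.
#' @return A genes x samples matrix of within-sample ranks (`RankMatrix`).
#' @export
rank_transform <- function(cohort, gene_subset = NULL, samples = NULL) {
  values <- if (inherits(cohort, "ExpressionCohort")) cohort$values else cohort
  if (is.null(gene_subset)) gene_subset <- rownames(values)
  unknown <- setdiff(gene_subset, rownames(values))
  if (length(unknown)) {
    abort_validation(paste0("unknown gene ids: ", paste(unknown, collapse = ", ")))
  }
  if (!length(gene_subset)) abort_validation("gene_subset must be non-empty")
  if (!is.null(samples)) {
    unknown_s <- setdiff(samples, colnames(values))
    if (length(unknown_s)) {
      abort_validation(paste0("unknown sample ids: ", paste(unknown_s, collapse = ", ")))
    }
    values <- values[, samples, drop = FALSE]
  }
  sub <- values[gene_subset, , drop = FALSE]
  ranks <- apply(sub, 2, rank, ties.method = "average")
  if (is.null(dim(ranks))) { # single gene
    ranks <- matrix(ranks, nrow = 1, dimnames = list(gene_subset, colnames(sub)))
  }
  ranks
}

#' Enumerate all unordered gene pairs
#'
#' @param gene_ids Character vector of >= 2 unique ids.
#' @return Data frame with columns `gene_a`, `gene_b` in canonical order
#'   (`gene_a` < `gene_b` lexicographically), n(n-1)/2 rows.
#' @export
enumerate_pairs <- function(gene_ids) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) abort_validation("gene ids must be unique")
  n <- length(gene_ids)
  if (n < 2) abort_validation("need at least 2 genes to form pairs")
  ids <- sort(gene_ids, method = "radix")
  idx <- utils::combn(n, 2)
  data.frame(gene_a = ids[idx[1, ]], gene_b = ids[idx[2, ]],
             stringsAsFactors = FALSE)
}

pair_key <- function(pairs) paste(pairs$gene_a, pairs$gene_b, sep = "|")

# Fraction of samples in which rank(gene_a) < rank(gene_b), resp. >.
# Ties count toward neither orientation.
pair_supports <- function(ranks, pairs) {
  a <- ranks[pairs$gene_a, , drop = FALSE]
  b <- ranks[pairs$gene_b, , drop = FALSE]
  list(lt = rowMeans(a < b), gt = rowMeans(a > b))
}

#' Stable pairs in normal samples
#'
#' A pair is stable when one ordering (rank A < rank B or the reverse) holds
#' in at least `stable_frac` of the normal samples (inclusive bound).
#' Within-sample rank ties count toward neither ordering.
#'
#' @param ranks_normal Rank matrix over normal samples ([rank_transform()]).
#' @param stable_frac Required support fraction (default 0.85).
#' @param min_normal_samples Error below this many normal samples (default 5).
#' @return A `PairSet` data frame: `gene_a`, `gene_b` (canonical order),
#'   `orientation` (`"A_lt_B"` or `"A_gt_B"`, the normal-tissue ordering) and
#'   `support_normal`.
#' @export
find_stable_pairs <- function(ranks_normal, stable_frac = 0.85,
                              min_normal_samples = 5L) {
  if (ncol(ranks_normal) < min_normal_samples) {
    abort_validation(sprintf(
      "stable-pair detection needs >= %d normal samples, got %d",
      min_normal_samples, ncol(ranks_normal)
    ))
  }
  pairs <- enumerate_pairs(rownames(ranks_normal))
  sup <- pair_supports(ranks_normal, pairs)
  lt <- sup$lt >= stable_frac
  gt <- sup$gt >= stable_frac
  out <- pairs[lt | gt, , drop = FALSE]
  out$orientation <- ifelse(lt[lt | gt], "A_lt_B", "A_gt_B")
  out$support_normal <- ifelse(lt[lt | gt], sup$lt[lt | gt], sup$gt[lt | gt])
  rownames(out) <- NULL
  out
}

opposite_orientation <- function(x) ifelse(x == "A_lt_B", "A_gt_B", "A_lt_B")

#' Reversal pairs in tumor samples
#'
#' Subset of the stable pairs whose OPPOSITE ordering holds in at least
#' `reversal_frac` of tumor samples. The returned `orientation` is the tumor
#' ordering (the reverse of the stable one).
#'
#' @param ranks_tumor Rank matrix over tumor samples.
#' @param stable_pairs Output of [find_stable_pairs()].
#' @param reversal_frac Required tumor support (default 0.85).
#' @return A `PairSet` with tumor `orientation`, `support_normal` and
#'   `support_tumor`.
#' @export
find_reversal_pairs <- function(ranks_tumor, stable_pairs,
                                reversal_frac = 0.85) {
  if (!nrow(stable_pairs)) abort_validation("stable_pairs is empty")
  sup <- pair_supports(ranks_tumor, stable_pairs)
  tum_or <- opposite_orientation(stable_pairs$orientation)
  support_tumor <- ifelse(tum_or == "A_lt_B", sup$lt, sup$gt)
  keep <- support_tumor >= reversal_frac
  out <- stable_pairs[keep, , drop = FALSE]
  out$orientation <- tum_or[keep]
  out$support_tumor <- support_tumor[keep]
  rownames(out) <- NULL
  out
}

#' Deregulation direction of each gene
#'
#' Compares the median within-sample rank of each gene between tumor and
#' normal samples: `up` when the tumor median rank is higher, `down` when
#' lower, `unchanged` when equal.
#'
#' @param ranks_tumor,ranks_normal Rank matrices over the same gene universe.
#' @return Data frame: `gene_id`, `direction`, `median_rank_tumor`,
#'   `median_rank_normal`.
#' @export
deregulation_directions <- function(ranks_tumor, ranks_normal) {
  if (!identical(sort(rownames(ranks_tumor)), sort(rownames(ranks_normal)))) {
    abort_validation("tumor and normal rank matrices must share one gene universe")
  }
  genes <- rownames(ranks_tumor)
  med_t <- apply(ranks_tumor, 1, stats::median)
  med_n <- apply(ranks_normal[genes, , drop = FALSE], 1, stats::median)
  delta <- med_t - med_n
  data.frame(
    gene_id = genes,
    direction = ifelse(delta > 0, "up", ifelse(delta < 0, "down", "unchanged")),
    median_rank_tumor = unname(med_t),
    median_rank_normal = unname(med_n),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Keep pairs whose members deregulate in the same direction
#'
#' A pair is retained only when both members are `up` or both are `down`
#' between normal and tumor; pairs with an `unchanged` member are dropped.
#'
#' @param pairs A `PairSet`.
#' @param directions Output of [deregulation_directions()] covering all pair
#'   members.
#' @return The filtered `PairSet`.
#' @export
filter_same_direction <- function(pairs, directions) {
  if (!nrow(pairs)) return(pairs)
  dir <- stats::setNames(directions$direction, directions$gene_id)
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(dir))
  if (length(missing)) {
    abort_validation(paste0("directions missing for genes: ",
                            paste(missing, collapse = ", ")))
  }
  da <- dir[pairs$gene_a]
  db <- dir[pairs$gene_b]
  keep <- da == db & da %in% c("up", "down")
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coefficient-of-variation pruning of partner genes
#'
#' For an anchor gene and one of its partners, the per-tumor-sample statistic
#' d_s = rank_s(anchor) - rank_s(partner) measures how the pair relationship
#' varies across individual tumors; its coefficient of variation
#' CV = sd(d) / |mean(d)| is symmetric in the two genes. Every gene acts as
#' anchor for its own partners; partners are sorted by CV (descending, ties
#' broken by partner id) and the top `top_k` kept per anchor. A pair survives
#' when it is retained from EITHER side. A zero mean yields CV = +Inf
#' (maximal heterogeneity), which sorts first.
#'
#' @param pairs A `PairSet`.
#' @param ranks_tumor Rank matrix over tumor samples.
#' @param top_k Partners kept per anchor (default 3).
#' @return The pruned `PairSet` with a `cv` column appended.
#' @export
partner_cv_prune <- function(pairs, ranks_tumor, top_k = 3L) {
  if (top_k < 1) abort_validation("top_k must be >= 1")
  if (!nrow(pairs)) return(cbind(pairs, cv = numeric(0)))
  a <- ranks_tumor[pairs$gene_a, , drop = FALSE]
  b <- ranks_tumor[pairs$gene_b, , drop = FALSE]
  d <- a - b
  mu <- rowMeans(d)
  sdv <- apply(d, 1, stats::sd)
  cv <- ifelse(mu == 0, Inf, sdv / abs(mu))
  if (any(mu == 0)) {
    message(sprintf("%d pair(s) with zero mean rank difference: CV set to +Inf",
                    sum(mu == 0)))
  }
  long <- data.frame(
    anchor = c(pairs$gene_a, pairs$gene_b),
    partner = c(pairs$gene_b, pairs$gene_a),
    pair_row = rep(seq_len(nrow(pairs)), 2),
    cv = rep(cv, 2),
    stringsAsFactors = FALSE
  )
  ord <- order(long$anchor, -long$cv, long$partner, method = "radix")
  long <- long[ord, , drop = FALSE]
  pos <- stats::ave(seq_len(nrow(long)), long$anchor, FUN = seq_along)
  keep_rows <- unique(long$pair_row[pos <= top_k])
  out <- pairs[sort(keep_rows), , drop = FALSE]
  out$cv <- cv[sort(keep_rows)]
  rownames(out) <- NULL
  out
}

#' Qualify pairs by tumor support
#'
#' Retains pairs whose tumor ordering holds in STRICTLY more than
#' `qualify_frac` of tumor samples ("more than 60%").
#'
#' @param pairs A `PairSet` carrying tumor `orientation`.
#' @param ranks_tumor Rank matrix over tumor samples.
#' @param qualify_frac Fraction to exceed (default 0.60).
#' @return The qualified `PairSet` with refreshed `support_tumor`.
#' @export
qualify_pairs <- function(pairs, ranks_tumor, qualify_frac = 0.60) {
  if (!nrow(pairs)) return(pairs)
  sup <- pair_supports(ranks_tumor, pairs)
  support <- ifelse(pairs$orientation == "A_lt_B", sup$lt, sup$gt)
  keep <- support > qualify_frac
  out <- pairs[keep, , drop = FALSE]
  out$support_tumor <- support[keep]
  rownames(out) <- NULL
  out
}

#' Binary pair-indicator encoding
#'
#' For each pair, indicator = 1 when expression of `gene_a` strictly exceeds
#' `gene_b` in the sample, else 0 (ties encode as 0). The encoding depends
#' only on within-sample orderings, so it is invariant under any strictly
#' increasing per-sample transform of expression.
#'
#' @param x An [expression_cohort()], or a numeric genes x samples matrix
#'   (expression or ranks; both give the same indicators).
#' @param pairs A `PairSet` or any data frame with `gene_a`, `gene_b`.
#' @param samples Optional sample ids to encode (default: all columns).
#' @return A `PairIndicatorMatrix`: list with `pairs`, `indicators` (pairs x
#'   samples 0/1 matrix, rownames `gene_a|gene_b`).
#' @export
encode_pairs <- function(x, pairs, samples = NULL) {
  values <- if (inherits(x, "ExpressionCohort")) x$values else x
  if (!is.null(samples)) values <- values[, samples, drop = FALSE]
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), rownames(values))
  if (length(missing)) {
    abort_validation(paste0("genes absent from matrix: ",
                            paste(missing, collapse = ", ")))
  }
  a <- values[pairs$gene_a, , drop = FALSE]
  b <- values[pairs$gene_b, , drop = FALSE]
  ind <- (a > b) + 0
  dimnames(ind) <- list(pair_key(pairs), colnames(values))
  structure(list(pairs = as.data.frame(pairs), indicators = ind),
            class = "PairIndicatorMatrix")
}

#' @method print PairIndicatorMatrix
#' @export
print.PairIndicatorMatrix <- function(x, ...) {
  cat(sprintf("PairIndicatorMatrix: %d pairs x %d samples\n",
              nrow(x$indicators), ncol(x$indicators)))
  invisible(x)
}

#' Intersect pair sets across cohorts
#'
#' Keeps pairs present in every set with an IDENTICAL tumor orientation; the
#' same unordered pair with opposite orientations in two cohorts is dropped.
#' Per-cohort supports are carried as suffixed columns.
#'
#' @param pair_sets Named list (>= 2) of `PairSet` data frames.
#' @return The intersected `PairSet`.
#' @export
intersect_pair_sets <- function(pair_sets) {
  if (length(pair_sets) < 2) abort_validation("need at least 2 pair sets")
  if (is.null(names(pair_sets)) || any(!nzchar(names(pair_sets)))) {
    names(pair_sets) <- paste0("set", seq_along(pair_sets))
  }
  keys <- lapply(pair_sets, function(p) paste(pair_key(p), p$orientation))
  common <- Reduce(intersect, keys)
  base <- pair_sets[[1]]
  sel <- match(common, keys[[1]])
  out <- base[sel, c("gene_a", "gene_b", "orientation"), drop = FALSE]
  for (nm in names(pair_sets)) {
    p <- pair_sets[[nm]]
    m <- match(common, keys[[nm]])
    if ("support_normal" %in% colnames(p)) {
      out[[paste0("support_normal.", nm)]] <- p$support_normal[m]
    }
    if ("support_tumor" %in% colnames(p)) {
      out[[paste0("support_tumor.", nm)]] <- p$support_tumor[m]
    }
  }
  rownames(out) <- NULL
  out
}
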