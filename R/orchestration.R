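#' Run the full multi-cohort pair-signature pipeline
#'
#' Wires every stage together: pathway-coupled lncRNA discovery on the
#' training cohort; per-cohort stable/reversal pair detection over those
#' lncRNAs followed by the same-direction filter, coefficient-of-variation
#' pruning and tumor-support qualification; cross-cohort intersection of the
#' qualified pair sets (orientation must agree); binary encoding of the
#' common pairs in each cohort's tumor samples; per-cohort univariate Cox
#' screens with cross-cohort hazard-direction consistency; LASSO Cox fit on
#' the training cohort; risk scoring, optimal cutoff and group assignment
#' per cohort; and an evaluation report per cohort.
#'
#' Validation cohorts are scored with the training model over the common
#' pair set; per-cohort reversal sets enter only through the intersection
#' step. By default the risk cutoff is re-estimated per cohort; set
#' `fixed_cutoff = TRUE` to transfer the training cutoff.
#'
#' @param cohorts Named list of [expression_cohort()] objects, each with
#'   normal samples.
#' @param survivals Named list of [survival_table()] objects (same names).
#' @param gene_set The pathway [gene_set()].
#' @param cfg A [pipeline_config()].
#' @param training_cohort Name of the training cohort (default: first).
#' @param fixed_cutoff Transfer the training cutoff to validation cohorts
#'   instead of re-estimating (default `FALSE`).
#' @param eval_boot Bootstrap draws for the C-index CI in the reports.
#' @return A `PipelineRun` list: `manifest`, `pes` (per-lncRNA enrichment
#'   results), `pdl_ids`, `pairs_per_cohort`, `common_pairs`, `screens`,
#'   `selected_pairs`, `model`, `scores` (per cohort, groups assigned),
#'   `cutoffs`, `reports`.
#' @export
run_full_pipeline <- function(cohorts, survivals, gene_set,
                              cfg = pipeline_config(),
                              training_cohort = names(cohorts)[1],
                              fixed_cutoff = FALSE,
                              eval_boot = 500L) {
  if (is.null(names(cohorts)) || is.null(names(survivals))) {
    abort_validation("cohorts and survivals must be named lists")
  }
  if (!setequal(names(cohorts), names(survivals))) {
    abort_validation("cohorts and survivals must cover the same cohort names")
  }
  if (!training_cohort %in% names(cohorts)) {
    abort_validation(sprintf("training cohort '%s' not found", training_cohort))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_reopairs(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                     "reopairs_stage_error")
    })
  }
  for (nm in names(cohorts)) {
    if (!any(cohorts[[nm]]$sample_group == "normal")) {
      abort_reopairs(
        sprintf("stage 'find_stable_pairs' requires normal samples; cohort '%s' has none", nm),
        "reopairs_stage_error"
      )
    }
  }

  pes <- stage("identify_pdls",
               identify_pdls(cohorts[[training_cohort]], gene_set, cfg))
  pdl_ids <- pes$lncrna_id[pes$is_pdl]
  if (length(pdl_ids) < 2) {
    abort_reopairs("fewer than 2 pathway-coupled lncRNAs found; cannot form pairs",
                   "reopairs_stage_error")
  }

  pairs_per_cohort <- lapply(names(cohorts), function(nm) {
    co <- cohorts[[nm]]
    rk_n <- stage("rank_transform",
                  rank_transform(co, pdl_ids, cohort_samples(co, "normal")))
    rk_t <- stage("rank_transform",
                  rank_transform(co, pdl_ids, cohort_samples(co, "tumor")))
    stable <- stage("find_stable_pairs",
                    find_stable_pairs(rk_n, cfg$stable_frac, cfg$min_normal_samples))
    reversal <- stage("find_reversal_pairs",
                      find_reversal_pairs(rk_t, stable, cfg$reversal_frac))
    dirs <- stage("deregulation_directions", deregulation_directions(rk_t, rk_n))
    samedir <- stage("filter_same_direction", filter_same_direction(reversal, dirs))
    pruned <- stage("partner_cv_prune",
                    partner_cv_prune(samedir, rk_t, cfg$top_cv_partners))
    qualified <- stage("qualify_pairs",
                       qualify_pairs(pruned, rk_t, cfg$qualify_frac))
    list(stable = stable, reversal = reversal, same_direction = samedir,
         pruned = pruned, qualified = qualified)
  })
  names(pairs_per_cohort) <- names(cohorts)

  common_pairs <- stage("intersect_pair_sets", intersect_pair_sets(
    lapply(pairs_per_cohort, `[[`, "qualified")
  ))
  if (!nrow(common_pairs)) {
    abort_reopairs("no pairs shared by all cohorts", "reopairs_stage_error")
  }

  indicators <- lapply(names(cohorts), function(nm) {
    co <- cohorts[[nm]]
    stage("encode_pairs",
          encode_pairs(co, common_pairs, cohort_samples(co, "tumor")))
  })
  names(indicators) <- names(cohorts)

  screens <- lapply(names(cohorts), function(nm) {
    stage("univariate_cox_screen",
          suppressWarnings(univariate_cox_screen(indicators[[nm]], survivals[[nm]])))
  })
  names(screens) <- names(cohorts)

  # pairs skipped (constant indicator) in any cohort cannot be checked for
  # direction consistency; drop them before the consistency selection
  keys <- lapply(screens, function(s) paste(s$gene_a, s$gene_b, sep = "|"))
  everywhere <- Reduce(intersect, keys)
  screens_common <- lapply(screens, function(s) {
    s[match(everywhere, paste(s$gene_a, s$gene_b, sep = "|")), , drop = FALSE]
  })

  selected <- stage("select_consistent_pairs",
                    select_consistent_pairs(screens_common, training_cohort, cfg))
  if (nrow(selected) < 2) {
    abort_reopairs("fewer than 2 pairs pass the univariate screen", "reopairs_stage_error")
  }

  sel_keys <- paste(selected$gene_a, selected$gene_b, sep = "|")
  train_ind <- indicators[[training_cohort]]
  sel_rows <- match(sel_keys, pair_key(train_ind$pairs))
  train_sel <- structure(
    list(pairs = train_ind$pairs[sel_rows, , drop = FALSE],
         indicators = train_ind$indicators[sel_keys, , drop = FALSE]),
    class = "PairIndicatorMatrix"
  )
  model <- stage("fit_lasso_cox",
                 fit_lasso_cox(train_sel, survivals[[training_cohort]], cfg))
  model$training_cohort <- training_cohort

  scores <- list()
  cutoffs <- numeric(0)
  reports <- list()
  train_cut <- NULL
  for (nm in c(training_cohort, setdiff(names(cohorts), training_cohort))) {
    sc <- stage("risk_score", risk_score(model, indicators[[nm]]))
    cut <- if (fixed_cutoff && !is.null(train_cut)) {
      train_cut
    } else {
      stage("optimal_cutoff",
            optimal_cutoff(sc, survivals[[nm]], cfg$min_group_frac))
    }
    if (nm == training_cohort) train_cut <- cut
    sc <- assign_groups(sc, cut)
    scores[[nm]] <- sc
    cutoffs[nm] <- cut
    reports[[nm]] <- stage("evaluate_signature", evaluate_signature(
      sc, survivals[[nm]], cohort_id = nm, auc_years = cfg$auc_years,
      n_boot = eval_boot, seed = substream_seed(cfg$rng_seed, match(nm, names(cohorts)))
    ))
  }
  model$cutoff <- train_cut

  manifest <- list(
    package_version = as.character(utils::packageVersion("reopairs")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = cfg$rng_seed,
    config = unclass(cfg),
    training_cohort = training_cohort,
    fixed_cutoff = fixed_cutoff,
    cohort_dims = lapply(cohorts, function(co) dim(co$values)),
    input_digests = vapply(cohorts, digest_values, "")
  )

  structure(
    list(
      manifest = manifest,
      pes = pes,
      pdl_ids = pdl_ids,
      pairs_per_cohort = pairs_per_cohort,
      common_pairs = common_pairs,
      screens = screens,
      selected_pairs = selected,
      model = model,
      scores = scores,
      cutoffs = cutoffs,
      reports = reports
    ),
    class = "PipelineRun"
  )
}

# md5 digest of a cohort's values for run provenance
digest_values <- function(cohort) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  con <- file(tmp, "wb")
  serialize(cohort$values, con, version = 2)
  close(con)
  unname(tools::md5sum(tmp))
}

#' @method print PipelineRun
#' @export
print.PipelineRun <- function(x, ...) {
  cat(sprintf(
    "PipelineRun: %d cohorts, training '%s'\n  %d coupled lncRNAs -> %d common pairs -> %d screened -> %d in model\n",
    length(x$scores), x$manifest$training_cohort,
    length(x$pdl_ids), nrow(x$common_pairs), nrow(x$selected_pairs),
    nrow(x$model$pairs)
  ))
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    cat(sprintf("  %s: log-rank p = %.3g, C = %.3f, AUC(%s) = %s\n",
                nm, r$km_logrank_p, r$c_index,
                paste(names(r$auc_by_year), collapse = "/"),
                paste(sprintf("%.3f", r$auc_by_year), collapse = "/")))
  }
  invisible(x)
}
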