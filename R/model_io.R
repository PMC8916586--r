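#' Pair-signature risk model
#'
#' A linear risk score over binary pair indicators: for sample s,
#' score(s) = sum_i coefficient_i * x_is, where x_is = 1 when the expression
#' of `gene_a` exceeds that of `gene_b` in sample s and 0 otherwise. The
#' cutoff (if set) splits samples into high (> cutoff) and low risk.
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b` (and optionally
#'   `orientation`).
#' @param coefficients Numeric vector, one non-zero value per pair.
#' @param cutoff Risk cutoff; `NA` until estimated.
#' @param training_cohort Cohort id the model was fitted on.
#' @param lasso_lambda Penalty at which the coefficients were taken.
#' @param seed Seed used for cross-validation fold assignment.
#' @return A `SignatureModel`.
#' @export
signature_model <- function(pairs, coefficients, cutoff = NA_real_,
                            training_cohort = NA_character_,
                            lasso_lambda = NA_real_, seed = NA_integer_) {
  pairs <- as.data.frame(pairs)
  if (!all(c("gene_a", "gene_b") %in% colnames(pairs))) {
    abort_validation("pairs must have gene_a and gene_b columns")
  }
  if (nrow(pairs) < 1) abort_validation("a model must have at least one pair")
  if (length(coefficients) != nrow(pairs)) {
    abort_validation("one coefficient per pair required")
  }
  if (any(!is.finite(coefficients)) || any(coefficients == 0)) {
    abort_validation("coefficients must be finite and non-zero")
  }
  structure(
    list(
      pairs = pairs,
      coefficients = as.numeric(coefficients),
      cutoff = as.numeric(cutoff),
      training_cohort = training_cohort,
      lasso_lambda = as.numeric(lasso_lambda),
      seed = seed
    ),
    class = "SignatureModel"
  )
}

#' @method print SignatureModel
#' @export
print.SignatureModel <- function(x, ...) {
  cat(sprintf(
    "SignatureModel: %d pairs, cutoff %s%s\n", nrow(x$pairs),
    ifelse(is.na(x$cutoff), "unset", format(x$cutoff, digits = 4)),
    ifelse(is.na(x$training_cohort), "", paste0(", trained on ", x$training_cohort))
  ))
  df <- cbind(x$pairs[, c("gene_a", "gene_b")], coefficient = x$coefficients)
  print(utils::head(df, 20), row.names = FALSE)
  invisible(x)
}

MODEL_SCHEMA_VERSION <- 1L

#' Serialize / deserialize a signature model as JSON
#'
#' Coefficients are written at full double precision so the round trip is
#' bitwise exact.
#'
#' @param model A [signature_model()].
#' @param path JSON path.
#' @return `read_model` returns the model; `write_model` returns `path`
#'   invisibly.
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "SignatureModel")) abort_validation("not a SignatureModel")
  # numeric fields are written as 17-significant-digit strings: JSON number
  # emission rounds to 15 digits, which would break the bitwise round trip
  payload <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    pairs = model$pairs,
    coefficients = sprintf("%.17g", model$coefficients),
    cutoff = sprintf("%.17g", model$cutoff),
    training_cohort = model$training_cohort,
    lasso_lambda = sprintf("%.17g", model$lasso_lambda),
    seed = model$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$schema_version) ||
      payload$schema_version != MODEL_SCHEMA_VERSION) {
    abort_parse(sprintf(
      "unknown model schema version '%s' (expected %d)",
      payload$schema_version %||% "missing", MODEL_SCHEMA_VERSION
    ))
  }
  num <- function(x, default = NA_real_) {
    if (is.null(x)) default else suppressWarnings(as.numeric(x))
  }
  signature_model(
    pairs = payload$pairs,
    coefficients = num(payload$coefficients),
    cutoff = num(payload$cutoff),
    training_cohort = payload$training_cohort %||% NA_character_,
    lasso_lambda = num(payload$lasso_lambda),
    seed = payload$seed %||% NA_integer_
  )
}

#' The published 14-pair gastric-cancer risk model
#'
#' The printed lncRNA-pair signature for gastric cancer: 14 oriented pairs
#' with their LASSO Cox coefficients. The indicator of each pair is 1 when
#' `gene_a` expression exceeds `gene_b` within a sample. The published cutoff
#' was not printed, so `cutoff` is `NA`; estimate one with
#' [optimal_cutoff()] on your own cohort.
#'
#' @return A [signature_model()] with 14 pairs.
#' @export
published_gc_signature <- function() {
  pairs <- data.frame(
    gene_a = c("LINC00607", "TUSC8", "TRPM2-AS", "AC074286.1", "MMP25-AS1",
               "LINC01094", "AC013275.2", "MLLT4-AS1", "LINC00607",
               "C10orf91", "LINC01588", "RP3-522D1.1", "RP11-61A14.1",
               "CTD-2377D24.6"),
    gene_b = c("C5orf17", "PITRM1-AS1", "RP11-579D7.4", "AC058791.1",
               "RP11-876N24.5", "RP4-680D5.8", "RP11-567C2.1", "RP11-21L23.2",
               "RP11-109E24.1", "TRPM2-AS", "RP11-73K9.2", "LINC01094",
               "RP11-416I2.1", "LINC01169"),
    stringsAsFactors = FALSE
  )
  coefficients <- c(0.2793, 0.2525, 0.2088, 0.1802, 0.1766, 0.1616, 0.1548,
                    0.0930, 0.0700, -0.0999, -0.1337, -0.1959, -0.2067,
                    -0.3038)
  signature_model(pairs, coefficients, training_cohort = "TCGA-STAD")
}
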