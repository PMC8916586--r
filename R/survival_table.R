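#' Survival table container
#'
#' A data frame of follow-up times (days), event indicators and optional
#' clinical covariates, with the survival endpoint (`OS` overall survival or
#' `RFS` relapse-free survival) recorded as an attribute.
#'
#' @param sample_id Unique sample ids.
#' @param time Positive follow-up times in days.
#' @param event 0/1 event indicators (1 = death/relapse).
#' @param covariates Optional data frame of clinical covariates, one row per
#'   sample.
#' @param endpoint `"OS"` or `"RFS"`.
#' @return A `SurvivalTable` (also a `data.frame`).
#' @export
survival_table <- function(sample_id, time, event, covariates = NULL,
                           endpoint = c("OS", "RFS")) {
  endpoint <- match.arg(endpoint)
  sample_id <- as.character(sample_id)
  dup <- unique(sample_id[duplicated(sample_id)])
  if (length(dup)) {
    abort_validation(paste0("duplicate sample ids: ", paste(dup, collapse = ", ")))
  }
  time <- as.numeric(time)
  event <- as.numeric(event)
  bad_t <- which(!is.finite(time) | time <= 0)
  if (length(bad_t)) {
    abort_validation(paste0(
      "non-positive follow-up time for samples: ",
      paste(sample_id[utils::head(bad_t, 10)], collapse = ", ")
    ))
  }
  bad_e <- which(!event %in% c(0, 1))
  if (length(bad_e)) {
    abort_validation(paste0(
      "event must be 0 or 1; offending samples: ",
      paste(sample_id[utils::head(bad_e, 10)], collapse = ", ")
    ))
  }
  tab <- data.frame(sample_id = sample_id, time = time, event = event,
                    stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(sample_id)) {
      abort_validation("covariates must have one row per sample")
    }
    tab <- cbind(tab, covariates)
  }
  attr(tab, "endpoint") <- endpoint
  class(tab) <- c("SurvivalTable", "data.frame")
  tab
}

#' Read / write survival tables as TSV
#'
#' Columns `sample_id`, `time`, `event` are required; any further columns are
#' kept as covariates.
#'
#' @param path TSV path.
#' @param endpoint `"OS"` or `"RFS"`.
#' @return A [survival_table()].
#' @export
read_survival <- function(path, endpoint = c("OS", "RFS")) {
  endpoint <- match.arg(endpoint)
  con <- open_maybe_gz(path)
  on.exit(close(con), add = TRUE)
  tab <- utils::read.delim(con, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) {
    abort_parse(paste0("survival TSV missing columns: ", paste(miss, collapse = ", ")))
  }
  extra <- setdiff(colnames(tab), need)
  survival_table(
    tab$sample_id, tab$time, tab$event,
    covariates = if (length(extra)) tab[, extra, drop = FALSE],
    endpoint = endpoint
  )
}

#' @rdname read_survival
#' @param survival A `SurvivalTable`.
#' @export
write_survival <- function(survival, path) {
  out <- as.data.frame(survival)
  out$time <- sprintf("%.17g", out$time)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
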