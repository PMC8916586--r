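#' Expression cohort container
#'
#' A validated genes x samples expression matrix with per-gene type labels
#' (`lncRNA` / `mRNA`) and per-sample group labels (`tumor` / `normal`).
#' Values are assumed log2-scale unless `scale = "linear"` is declared; all
#' downstream pair logic is rank-based, so the scale only matters for
#' provenance and the correlation step.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   row and column names. Missing values are rejected: the rank logic of the
#'   pipeline has no NA semantics.
#' @param gene_type Named character vector mapping every gene id to
#'   `"lncRNA"` or `"mRNA"`.
#' @param sample_group Named character vector mapping every sample id to
#'   `"tumor"` or `"normal"`.
#' @param cohort_id Cohort label carried through reports.
#' @param scale `"log2"` (default) or `"linear"`; recorded, not transformed.
#'
#' @return An `ExpressionCohort` object.
#' @export
expression_cohort <- function(values, gene_type, sample_group, cohort_id,
                              scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_validation("values must be a numeric matrix")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    abort_validation("values must carry gene rownames and sample colnames")
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    abort_validation(paste0("duplicate gene ids: ", paste(dup_g, collapse = ", ")))
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    abort_validation(paste0("duplicate sample ids: ", paste(dup_s, collapse = ", ")))
  }
  if (anyNA(values)) {
    abort_validation("expression values contain NA; missing values are not permitted")
  }
  missing_type <- setdiff(gene_ids, names(gene_type))
  if (length(missing_type)) {
    abort_validation(paste0(
      "genes without a type annotation: ",
      paste(utils::head(missing_type, 10), collapse = ", ")
    ))
  }
  gene_type <- gene_type[gene_ids]
  if (!all(gene_type %in% c("lncRNA", "mRNA"))) {
    abort_validation("gene_type labels must be 'lncRNA' or 'mRNA'")
  }
  missing_grp <- setdiff(sample_ids, names(sample_group))
  if (length(missing_grp)) {
    abort_validation(paste0(
      "samples without a group annotation: ",
      paste(utils::head(missing_grp, 10), collapse = ", ")
    ))
  }
  sample_group <- sample_group[sample_ids]
  if (!all(sample_group %in% c("tumor", "normal"))) {
    abort_validation("sample_group labels must be 'tumor' or 'normal'")
  }
  if (!any(sample_group == "tumor")) {
    abort_validation("cohort must contain at least one tumor sample")
  }
  structure(
    list(
      cohort_id = as.character(cohort_id),
      values = values,
      gene_type = gene_type,
      sample_group = sample_group,
      scale = scale
    ),
    class = "ExpressionCohort"
  )
}

#' @method print ExpressionCohort
#' @export
print.ExpressionCohort <- function(x, ...) {
  cat(sprintf(
    "ExpressionCohort '%s': %d genes (%d lncRNA, %d mRNA) x %d samples (%d tumor, %d normal), %s scale\n",
    x$cohort_id, nrow(x$values),
    sum(x$gene_type == "lncRNA"), sum(x$gene_type == "mRNA"),
    ncol(x$values), sum(x$sample_group == "tumor"),
    sum(x$sample_group == "normal"), x$scale
  ))
  invisible(x)
}

#' Subset helpers for cohorts
#'
#' @param cohort An `ExpressionCohort`.
#' @param group `"tumor"` or `"normal"`.
#' @return Sample ids of the group / matrix slice.
#' @export
cohort_samples <- function(cohort, group) {
  names(cohort$sample_group)[cohort$sample_group == group]
}

#' @rdname cohort_samples
#' @export
cohort_values <- function(cohort, group = NULL) {
  if (is.null(group)) {
    return(cohort$values)
  }
  cohort$values[, cohort_samples(cohort, group), drop = FALSE]
}

open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read an expression cohort from TSV files
#'
#' The expression file is tab-separated with a header row of sample ids and
#' gene ids in the first column. The annotation files are two-column TSVs
#' (`gene_id`, `gene_type`) and (`sample_id`, `group`). Gzipped files are
#' read transparently.
#'
#' @param path Expression TSV (genes x samples).
#' @param gene_type_path Gene annotation TSV.
#' @param sample_group_path Sample annotation TSV.
#' @param cohort_id Cohort label.
#' @param scale `"log2"` or `"linear"`.
#' @return An [expression_cohort()].
#' @export
read_expression <- function(path, gene_type_path, sample_group_path, cohort_id,
                            scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  con <- open_maybe_gz(path)
  on.exit(close(con), add = TRUE)
  tab <- utils::read.delim(con, header = TRUE, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) abort_parse("expression TSV needs a gene-id column plus >= 1 sample")
  gene_ids <- tab[[1]]
  num <- as.matrix(tab[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(num), nrow = nrow(num),
                                  dimnames = list(gene_ids, colnames(num))))
  bad <- which(is.na(vals) & !(num %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad)) {
    abort_parse(sprintf(
      "non-numeric expression cell at gene '%s', sample '%s'",
      gene_ids[bad[1, 1]], colnames(num)[bad[1, 2]]
    ))
  }
  ann <- read_two_column(gene_type_path, c("gene_id", "gene_type"))
  grp <- read_two_column(sample_group_path, c("sample_id", "group"))
  expression_cohort(
    vals,
    gene_type = stats::setNames(ann[[2]], ann[[1]]),
    sample_group = stats::setNames(grp[[2]], grp[[1]]),
    cohort_id = cohort_id, scale = scale
  )
}

read_two_column <- function(path, expected) {
  con <- open_maybe_gz(path)
  on.exit(close(con), add = TRUE)
  tab <- utils::read.delim(con, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) {
    abort_parse(sprintf("'%s' must have columns %s", path, paste(expected, collapse = ", ")))
  }
  dup <- unique(tab[[1]][duplicated(tab[[1]])])
  if (length(dup)) {
    abort_validation(paste0("duplicate ids in ", path, ": ", paste(dup, collapse = ", ")))
  }
  tab
}

#' Write an expression cohort to TSV files
#'
#' Inverse of [read_expression()]; values are written with 17 significant
#' digits so the read/write round trip is exact in double precision.
#'
#' @inheritParams read_expression
#' @param cohort An `ExpressionCohort`.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(cohort, path, gene_type_path, sample_group_path) {
  vals <- cohort$values
  out <- data.frame(
    gene_id = rownames(vals),
    apply(vals, 2, function(col) sprintf("%.17g", col)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  colnames(out) <- c("gene_id", colnames(vals))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(cohort$gene_type), gene_type = unname(cohort$gene_type)),
    gene_type_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    data.frame(sample_id = names(cohort$sample_group), group = unname(cohort$sample_group)),
    sample_group_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
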