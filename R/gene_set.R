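#' Gene set container
#'
#' @param name Set name.
#' @param members Character vector of gene symbols; duplicates are removed
#'   with a warning.
#' @return A `GeneSet` object.
#' @export
gene_set <- function(name, members) {
  members <- as.character(members)
  members <- members[nzchar(members)]
  if (!length(members)) abort_validation("a gene set must have at least one member")
  dup <- unique(members[duplicated(members)])
  if (length(dup)) {
    warning(sprintf("gene set '%s': removed duplicate members: %s",
                    name, paste(dup, collapse = ", ")))
    members <- unique(members)
  }
  structure(list(name = as.character(name), members = members), class = "GeneSet")
}

#' @method print GeneSet
#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s' with %d members\n", x$name, length(x$members)))
  invisible(x)
}

#' Read a gene set from plain text or GMT
#'
#' Plain format: one gene symbol per line. GMT: the standard tab-separated
#' `name<TAB>description<TAB>member...` line (only the first record is read).
#'
#' @param path File path.
#' @param format `"plain"` or `"GMT"`.
#' @param name Set name for plain files (defaults to the file name).
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, format = c("plain", "GMT"), name = NULL) {
  format <- match.arg(format)
  con <- open_maybe_gz(path)
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort_parse(sprintf("gene set file '%s' is empty", path))
  if (format == "plain") {
    gene_set(name %||% basename(path), trimws(lines))
  } else {
    if (requireNamespace("fgsea", quietly = TRUE)) {
      sets <- fgsea::gmtPathways(path)
      gene_set(names(sets)[1], sets[[1]])
    } else {
      fields <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
      if (length(fields) < 3) abort_parse("GMT line needs name, description, >= 1 member")
      gene_set(fields[1], fields[-(1:2)])
    }
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
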