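## Tabular I/O. Everything is plain tab-separated UTF-8 text with a header
## row; gene identifiers are opaque strings with no coordinate semantics.

#' Read a gene-by-sample count table
#'
#' Expects a tab-separated file whose header row holds sample ids, whose
#' first column holds gene ids, and whose remaining cells are non-negative
#' integers.
#'
#' @param path File path.
#' @return A validated count matrix (genes x samples), preserving the file's
#'   row and column order.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, check.names = FALSE, header = TRUE,
                           colClasses = "character", sep = "\t")
  if (ncol(tab) < 2L) stop("count table needs a gene id column plus >= 1 sample",
                           call. = FALSE)
  gene_ids <- tab[[1L]]
  m <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = list(gene_ids, colnames(m))))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("parse error in %s: cell at gene '%s', sample '%s' ('%s') is not a non-negative integer",
                 path, gene_ids[bad[1L, 1L]], colnames(num)[bad[1L, 2L]],
                 m[bad[1L, 1L], bad[1L, 2L]]), call. = FALSE)
  }
  validate_count_matrix(num)
}

#' Write a count matrix as tab-separated text
#'
#' @param counts Validated count matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  counts <- validate_count_matrix(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path)
}

#' Read a sample sheet
#'
#' Tab-separated with columns `sample_id`, `protein`, `replicate`,
#' `fraction`; fraction strings are matched case-insensitively to
#' IP/Total.
#'
#' @param path File path.
#' @param counts Optional count matrix to cross-validate sample ids against.
#' @return A validated sample sheet data frame.
#' @export
read_sample_sheet <- function(path, counts = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, check.names = FALSE, header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  validate_sample_sheet(tab, counts)
}

#' Write a sample sheet
#' @param sheet Validated sample sheet.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  write_table(sheet[, c("sample_id", "protein", "replicate", "fraction")],
              path)
}

#' Read a GMT-style gene-set file
#'
#' Each line is `term_id TAB term_name TAB member1 TAB member2 ...`.
#' Duplicate members within a term are collapsed; terms with no members are
#' skipped with a warning.
#'
#' @param path File path.
#' @return A named list of gene-id character vectors; names are term ids and
#'   the `term_name` attribute on each element carries the description.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) {
      warning("skipping malformed GMT line: ", substr(ln, 1, 40))
      next
    }
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      warning("term '", parts[1L], "' has no members; skipped")
      next
    }
    attr(members, "term_name") <- parts[2L]
    sets[[parts[1L]]] <- members
  }
  sets
}

#' Write a gene-set collection in GMT format
#' @param sets Named list of member vectors (as from [read_gene_sets()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    nm <- attr(sets[[id]], "term_name")
    if (is.null(nm)) nm <- id
    paste(c(id, nm, as.character(sets[[id]])), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-gene covariate table
#'
#' Tab-separated with a `gene_id` first column and one numeric column per
#' covariate. Blank cells and `NA` become missing values, never zero.
#'
#' @param path File path.
#' @return Data frame with `gene_id` plus numeric covariate columns; gene
#'   ids are unique.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, check.names = FALSE, header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  if (names(tab)[1L] != "gene_id") {
    stop("covariate table must have 'gene_id' as its first column",
         call. = FALSE)
  }
  if (anyDuplicated(tab$gene_id)) {
    stop("duplicate gene ids in covariate table", call. = FALSE)
  }
  for (j in seq_along(tab)[-1L]) {
    tab[[j]] <- suppressWarnings(as.numeric(tab[[j]]))
    if (all(is.na(tab[[j]]))) {
      stop("covariate '", names(tab)[j], "' has no non-missing value",
           call. = FALSE)
    }
  }
  tab
}

#' Write a covariate table
#' @param covariates Data frame with a `gene_id` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covariates, path) {
  write_table(covariates, path)
}

#' Write a data frame as tab-separated text with a header
#'
#' Rows are written in the order given; callers that promise deterministic
#' output sort before calling. Never quotes, never writes row names.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
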