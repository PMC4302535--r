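#' Validate a gene-by-sample count matrix
#'
#' A count matrix is an integer-valued base matrix with unique gene
#' identifiers as row names and unique sample identifiers as column names.
#' All counts must be non-negative whole numbers and every library
#' (column) sum must be positive.
#'
#' @param counts A numeric matrix of counts with row and column names.
#' @return The validated matrix, with storage mode coerced to integer-valued
#'   double (values are checked to be whole numbers).
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "invalid count at gene '%s', sample '%s': must be a non-negative integer",
      rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]),
      call. = FALSE)
  }
  libsize <- colSums(counts)
  if (any(libsize <= 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[libsize <= 0], collapse = ", "),
         call. = FALSE)
  }
  counts
}

#' Validate a sample sheet describing the paired IP/Total design
#'
#' The sheet maps every sample to a bait protein, a replicate number and a
#' fraction (IP or Total). Each (protein, replicate) pair must contribute
#' exactly one IP and exactly one Total library, and every protein needs at
#' least two replicates so that dispersion can be estimated.
#'
#' @param sheet A data frame with columns `sample_id`, `protein`,
#'   `replicate`, `fraction`.
#' @param counts Optional count matrix; when given, the sheet's sample ids
#'   must match the matrix columns as a set (order is irrelevant).
#' @return The validated sheet with `fraction` normalized to `"IP"`/`"Total"`
#'   and `replicate` coerced to integer.
#' @export
validate_sample_sheet <- function(sheet, counts = NULL) {
  required <- c("sample_id", "protein", "replicate", "fraction")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols) > 0L) {
    stop("sample sheet is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sheet <- as.data.frame(sheet, stringsAsFactors = FALSE)
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$protein <- as.character(sheet$protein)
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample ids in sample sheet", call. = FALSE)
  }
  rep_num <- suppressWarnings(as.numeric(sheet$replicate))
  if (any(is.na(rep_num) | rep_num < 1 | rep_num != round(rep_num))) {
    stop("replicate must be a positive integer for every sample",
         call. = FALSE)
  }
  sheet$replicate <- as.integer(rep_num)
  frac <- tolower(trimws(as.character(sheet$fraction)))
  known <- c(ip = "IP", total = "Total")
  if (any(!frac %in% names(known))) {
    stop("unknown fraction value(s): ",
         paste(unique(sheet$fraction[!frac %in% names(known)]),
               collapse = ", "), "; expected IP or Total", call. = FALSE)
  }
  sheet$fraction <- unname(known[frac])

  ## exactly one IP and one Total per (protein, replicate) pair
  key <- interaction(sheet$protein, sheet$replicate, drop = TRUE)
  for (k in levels(key)) {
    sub <- sheet[key == k, ]
    n_ip <- sum(sub$fraction == "IP")
    n_tot <- sum(sub$fraction == "Total")
    if (n_ip != 1L || n_tot != 1L) {
      stop(sprintf(
        "design error: protein '%s' replicate %d has %d IP and %d Total samples (need exactly 1 of each)",
        sub$protein[1L], sub$replicate[1L], n_ip, n_tot), call. = FALSE)
    }
  }
  n_reps <- tapply(sheet$replicate, sheet$protein,
                   function(r) length(unique(r)))
  if (any(n_reps < 2L)) {
    stop("every protein needs >= 2 replicates; offending: ",
         paste(names(n_reps)[n_reps < 2L], collapse = ", "), call. = FALSE)
  }
  if (!is.null(counts)) {
    if (!setequal(sheet$sample_id, colnames(counts))) {
      stop("sample ids in sheet and count matrix differ as sets",
           call. = FALSE)
    }
  }
  sheet
}

#' Look up the samples of one bait and fraction
#'
#' @param sheet A validated sample sheet.
#' @param protein Bait name.
#' @param fraction `"IP"` or `"Total"`; `NULL` returns both.
#' @return Character vector of sample ids ordered by replicate.
#' @export
samples_of <- function(sheet, protein, fraction = NULL) {
  sub <- sheet[sheet$protein == protein, ]
  if (nrow(sub) == 0L) {
    stop("protein '", protein, "' not present in sample sheet", call. = FALSE)
  }
  if (!is.null(fraction)) sub <- sub[sub$fraction == fraction, ]
  sub$sample_id[order(sub$replicate)]
}
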