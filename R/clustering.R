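## Hierarchical clustering of per-bait enrichment profiles with the
## uncentered Pearson (cosine) similarity and average linkage, plus
## extraction of named binding groups by sign-pattern matching.

#' Uncentered Pearson correlation (cosine similarity)
#'
#' `sum(x*y) / sqrt(sum(x^2) * sum(y^2))` -- no mean-centering, so a
#' constant-sign profile correlates positively with itself regardless of
#' level. Undefined for a zero-norm vector (returns `NA` with a warning).
#'
#' @param x,y Equal-length numeric vectors.
#' @return Similarity in [-1, 1].
#' @export
uncentered_pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    warning("uncentered Pearson undefined for a zero-norm vector")
    return(NA_real_)
  }
  sum(x * y) / (nx * ny)
}

## Row-by-row cosine similarity matrix.
uncentered_pearson_matrix <- function(m) {
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) {
    stop("zero-norm profile row(s): ",
         paste(utils::head(rownames(m)[norms == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  s <- tcrossprod(m / norms)
  pmin(pmax(s, -1), 1)
}

#' Select genes for profile clustering
#'
#' Keeps genes significantly enriched or under-represented (FDR below
#' `fdr_threshold`) for at least one bait AND passing the Total-count
#' filter for all baits.
#'
#' @param enrichment Combined enrichment table over all baits (rows from
#'   [test_enrichment_all()]).
#' @param counts Validated count matrix.
#' @param sheet Validated sample sheet.
#' @param fdr_threshold FDR cutoff (default 0.01).
#' @param min_total_count Total-count threshold (default 20).
#' @return Character vector of selected gene ids (warns when empty).
#' @export
select_cluster_genes <- function(enrichment, counts, sheet,
                                 fdr_threshold = 0.01,
                                 min_total_count = 20) {
  sig <- enrichment$gene_id[!is.na(enrichment$fdr) &
                              enrichment$fdr < fdr_threshold]
  ok <- filter_by_total_counts(counts, sheet,
                               baits = unique(enrichment$bait),
                               threshold = min_total_count)
  sel <- intersect(intersect(rownames(counts), unique(sig)), ok)
  if (length(sel) == 0L) {
    warning("no gene passes the clustering selection; clustering will refuse to run")
  }
  sel
}

#' Build a profile matrix of log2 enrichment values
#'
#' One column per bait-by-replicate pair of per-replicate
#' log2((IP_cpm + c) / (Total_cpm + c)) values, or per-bait medians when
#' `aggregate = TRUE`. Column metadata (bait, replicate) is attached as
#' attributes.
#'
#' @param counts Validated count matrix.
#' @param sheet Validated sample sheet.
#' @param genes Gene ids (rows) to include.
#' @param aggregate Collapse replicates to per-bait medians.
#' @param pseudocount Pseudocount in CPM units (default 0.5).
#' @return Numeric matrix genes x profile columns with attributes
#'   `bait` and `replicate` describing the columns.
#' @export
build_profile_matrix <- function(counts, sheet, genes = rownames(counts),
                                 aggregate = FALSE, pseudocount = 0.5) {
  sheet <- validate_sample_sheet(sheet, counts)
  missing_genes <- setdiff(genes, rownames(counts))
  if (length(missing_genes) > 0L) {
    stop("unknown gene id(s): ",
         paste(utils::head(missing_genes, 5), collapse = ", "), call. = FALSE)
  }
  cpm_all <- cpm(counts)
  baits <- unique(sheet$protein)
  cols <- list()
  bait_meta <- rep_meta <- character(0)
  for (b in baits) {
    sub <- sheet[sheet$protein == b, ]
    reps <- sort(unique(sub$replicate))
    rep_cols <- sapply(reps, function(r) {
      ip <- sub$sample_id[sub$replicate == r & sub$fraction == "IP"]
      tot <- sub$sample_id[sub$replicate == r & sub$fraction == "Total"]
      log2((cpm_all[genes, ip] + pseudocount) /
             (cpm_all[genes, tot] + pseudocount))
    })
    if (aggregate) {
      cols[[b]] <- apply(rep_cols, 1L, stats::median)
      bait_meta <- c(bait_meta, b)
      rep_meta <- c(rep_meta, NA_character_)
    } else {
      colnames(rep_cols) <- sprintf("%s_r%d", b, reps)
      for (j in seq_along(reps)) {
        cols[[colnames(rep_cols)[j]]] <- rep_cols[, j]
        bait_meta <- c(bait_meta, b)
        rep_meta <- c(rep_meta, as.character(reps[j]))
      }
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- genes
  structure(m, bait = bait_meta, replicate = rep_meta)
}

#' Average-linkage hierarchical clustering of profile rows
#'
#' Distances are `1 - uncentered_pearson` between rows; the agglomerative
#' tree uses average linkage. Merge heights are non-decreasing and the
#' result is deterministic given the input.
#'
#' @param profiles Numeric matrix with finite values and row names.
#' @return Object of class `rip_hclust`: a list with the underlying
#'   `hclust` tree (`$hclust`), `labels`, `metric`, `linkage`, and the
#'   `merge`/`height`/`order` components of the tree.
#' @export
hierarchical_cluster <- function(profiles) {
  if (nrow(profiles) < 2L) stop("need >= 2 rows to cluster", call. = FALSE)
  bad <- rownames(profiles)[!apply(is.finite(profiles), 1L, all)]
  if (length(bad) > 0L) {
    stop("non-finite profile values for gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  d <- stats::as.dist(1 - uncentered_pearson_matrix(profiles))
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, labels = rownames(profiles),
                 metric = "uncentered_pearson", linkage = "average",
                 merge = hc$merge, height = hc$height, order = hc$order),
            class = "rip_hclust")
}

#' Cut a cluster tree into groups
#'
#' @param tree A `rip_hclust` object.
#' @param k Target number of groups (exclusive with `height`).
#' @param height Distance threshold for the cut.
#' @return Named integer vector gene -> group; groups are renumbered in
#'   leaf order (group 1 holds the leftmost leaf).
#' @export
cut_groups <- function(tree, k = NULL, height = NULL) {
  stopifnot(inherits(tree, "rip_hclust"))
  n <- length(tree$labels)
  if (!is.null(k)) {
    if (k < 1 || k > n) stop("k must lie in [1, number of leaves]",
                             call. = FALSE)
    raw <- stats::cutree(tree$hclust, k = k)
  } else if (!is.null(height)) {
    if (height < 0) stop("height must be >= 0", call. = FALSE)
    raw <- stats::cutree(tree$hclust, h = height)
  } else {
    stop("supply k or height", call. = FALSE)
  }
  ## renumber groups by first appearance in leaf order
  leaf_groups <- raw[tree$order]
  lvl <- unique(leaf_groups)
  out <- match(raw, lvl)
  names(out) <- tree$labels
  out
}

#' Name cut groups by matching sign-pattern archetypes
#'
#' Each cluster's per-bait median profile is compared (cosine similarity)
#' with the planted-group archetypes (I: down everywhere except the
#' poly(A) binder; II: repressors up; III: closed-loop up / repressors
#' down; IV: up everywhere); a cluster is assigned the best-matching
#' archetype when the similarity exceeds `min_similarity`, otherwise
#' `"unassigned"`. Several clusters may map to the same named group,
#' which is how a fine cut (e.g. k = 7) collapses into the four named
#' groups.
#'
#' @param profiles Profile matrix (from [build_profile_matrix()], with
#'   bait column metadata).
#' @param groups Gene -> group vector from [cut_groups()].
#' @param polyA_binder,repressors Role assignments among the baits.
#' @param min_similarity Assignment threshold (default 0.5).
#' @return Character vector gene -> group name in
#'   `c("I","II","III","IV","unassigned")`.
#' @export
match_group_archetypes <- function(profiles, groups, polyA_binder,
                                   repressors, min_similarity = 0.5) {
  bait_of_col <- attr(profiles, "bait")
  if (is.null(bait_of_col)) {
    stop("profiles must carry bait column metadata", call. = FALSE)
  }
  baits <- unique(bait_of_col)
  arch <- group_archetypes(baits, polyA_binder, repressors)
  arch <- arch[c("I", "II", "III", "IV"), , drop = FALSE]
  out <- rep("unassigned", length(groups))
  names(out) <- names(groups)
  for (g in unique(groups)) {
    idx <- names(groups)[groups == g]
    med_cols <- apply(profiles[idx, , drop = FALSE], 2L, stats::median)
    med_bait <- vapply(baits, function(b) {
      stats::median(med_cols[bait_of_col == b])
    }, numeric(1L))
    if (sqrt(sum(med_bait^2)) == 0) next
    sims <- apply(arch, 1L, function(a) {
      suppressWarnings(uncentered_pearson(med_bait, a))
    })
    if (max(sims, na.rm = TRUE) >= min_similarity) {
      out[idx] <- names(which.max(sims))
    }
  }
  out
}

#' Export an ordered profile matrix and heatmap
#'
#' Writes `<prefix>_matrix.tsv` with rows in tree leaf order and renders
#' `<prefix>.png` with a diverging blue-white-red palette centered at
#' log2 enrichment 0.
#'
#' @param profiles Profile matrix.
#' @param tree `rip_hclust` over the profile rows.
#' @param prefix Output path prefix.
#' @return Paths of the written files, invisibly.
#' @export
export_heatmap <- function(profiles, tree, prefix) {
  stopifnot(inherits(tree, "rip_hclust"))
  ord <- tree$order
  m <- profiles[ord, , drop = FALSE]
  tsv <- paste0(prefix, "_matrix.tsv")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, tsv)
  png_path <- paste0(prefix, ".png")
  lim <- max(abs(m), na.rm = TRUE)
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(255)
  grDevices::png(png_path, width = 800, height = 1000)
  graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = pal, zlim = c(-lim, lim), axes = FALSE,
                  main = "log2 enrichment (IP/Total)")
  graphics::axis(1, at = seq(0, 1, length.out = ncol(m)),
                 labels = colnames(m), las = 2, cex.axis = 0.7)
  grDevices::dev.off()
  invisible(c(tsv, png_path))
}
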