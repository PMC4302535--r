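## Statistics over transcript groups: hypergeometric over/under-
## representation of gene sets, Fisher exact cluster-vs-genome tests,
## chi-square heterogeneity across clusters, and Wilcoxon rank-sum
## comparisons of per-gene covariates between transcript sets.

#' Hypergeometric over/under-representation of gene sets
#'
#' For each term, the overlap with `gene_set` is tested under
#' Hypergeometric(universe, term intersect universe, |gene_set|):
#' `p_over = P(X >= overlap)` and `p_under = P(X <= overlap)`.
#' Benjamini-Hochberg FDRs are computed within each direction across
#' terms. Terms with empty intersection are reported with overlap 0,
#' never skipped.
#'
#' @param gene_set Character vector of gene ids; must be non-empty and a
#'   subset of `universe`.
#' @param term_sets Named list of member-id vectors (see
#'   [read_gene_sets()]).
#' @param universe Character vector of all eligible gene ids.
#' @return Data frame per term: `term_id`, `overlap`, `set_size`,
#'   `term_size`, `universe_size`, `expected`, `p_over`, `p_under`,
#'   `fdr_over`, `fdr_under`, `direction`.
#' @export
hypergeometric_enrichment <- function(gene_set, term_sets, universe) {
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (length(gene_set) == 0L) stop("empty gene set", call. = FALSE)
  outside <- setdiff(gene_set, universe)
  if (length(outside) > 0L) {
    stop("gene set not contained in universe; offending id(s): ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n <- length(gene_set)
  rows <- lapply(names(term_sets), function(id) {
    term <- intersect(unique(term_sets[[id]]), universe)
    K <- length(term)
    k <- length(intersect(gene_set, term))
    p_over <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    p_under <- stats::phyper(k, K, N - K, n)
    data.frame(term_id = id, overlap = k, set_size = n, term_size = K,
               universe_size = N, expected = n * K / N,
               p_over = p_over, p_under = p_under,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_over <- bh_fdr(out$p_over)
  out$fdr_under <- bh_fdr(out$p_under)
  out$direction <- ifelse(out$overlap >= out$expected, "over", "under")
  out
}

#' Fisher exact test of a cluster against the rest of the genome
#'
#' 2x2 exact test of cluster membership against term membership over the
#' universe. The two-sided p-value sums all tables with probability at
#' most that observed; the one-sided over-representation p-value equals
#' the hypergeometric `p_over` on the same inputs.
#'
#' @param cluster_genes Gene ids in the cluster.
#' @param term Gene ids in the term.
#' @param universe All eligible gene ids.
#' @return List: `odds_ratio` (conditional MLE; `NA` when a margin is
#'   zero), `p_two_sided` (1 when a margin is zero), `p_over`, `table`.
#' @export
fisher_cluster_vs_genome <- function(cluster_genes, term, universe) {
  universe <- unique(universe)
  cluster_genes <- intersect(unique(cluster_genes), universe)
  term <- intersect(unique(term), universe)
  a <- length(intersect(cluster_genes, term))
  b <- length(cluster_genes) - a
  c_ <- length(term) - a
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("cluster", "rest"),
                                c("in_term", "not_in_term")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p_two_sided = 1,
                p_over = 1, table = tab))
  }
  ft <- stats::fisher.test(tab)
  p_over <- stats::phyper(a - 1, length(term),
                          length(universe) - length(term),
                          length(cluster_genes), lower.tail = FALSE)
  list(odds_ratio = unname(ft$estimate), p_two_sided = ft$p.value,
       p_over = p_over, table = tab)
}

#' Chi-square heterogeneity of term membership across clusters
#'
#' Pearson chi-square on the groups x (in-term, not-in-term) contingency
#' table with `(g - 1)` degrees of freedom. Empty groups are dropped with
#' a warning; a warning is also raised when any expected count is below 5.
#'
#' @param clusters Named vector gene -> group label.
#' @param term Gene ids in the term.
#' @return List: `statistic`, `df`, `p_value`, `observed`, `expected`.
#' @export
chisq_across_clusters <- function(clusters, term) {
  groups <- unique(clusters)
  sizes <- table(clusters)
  empty <- names(sizes)[sizes == 0]
  if (length(empty) > 0L) {
    warning("dropping empty group(s): ", paste(empty, collapse = ", "))
  }
  groups <- names(sizes)[sizes > 0]
  if (length(groups) < 2L) stop("need >= 2 non-empty groups", call. = FALSE)
  in_term <- vapply(groups, function(g) {
    sum(names(clusters)[clusters == g] %in% term)
  }, numeric(1L))
  tot <- vapply(groups, function(g) sum(clusters == g), numeric(1L))
  obs <- cbind(in_term = in_term, not_in_term = tot - in_term)
  rownames(obs) <- groups
  expct <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  if (any(expct < 5)) {
    warning("expected count below 5 in the cluster-by-term table")
  }
  stat <- sum((obs - expct)^2 / expct)
  df <- length(groups) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       observed = obs, expected = expct)
}

#' Wilcoxon rank-sum comparison of two covariate value sets
#'
#' Two-sided Mann-Whitney test: exact enumeration when the combined
#' sample size is at most 20 and there are no ties, otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param values_a,values_b Numeric vectors; missing values are dropped.
#' @param name_a,name_b,covariate Labels for the output row.
#' @return One-row data frame: `set_a`, `set_b`, `covariate`, `n_a`,
#'   `n_b`, `statistic` (Mann-Whitney U for the first set), `p_value`,
#'   `median_a`, `median_b`.
#' @export
wilcoxon_compare <- function(values_a, values_b, name_a = "A",
                             name_b = "B", covariate = "covariate") {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("all values missing in one of the sets", call. = FALSE)
  }
  no_ties <- !anyDuplicated(c(a, b))
  exact <- (length(a) + length(b)) <= 20 && no_ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  data.frame(set_a = name_a, set_b = name_b, covariate = covariate,
             n_a = length(a), n_b = length(b),
             statistic = unname(wt$statistic), p_value = wt$p.value,
             median_a = stats::median(a), median_b = stats::median(b),
             stringsAsFactors = FALSE)
}

#' Per-group covariate summaries with pairwise Wilcoxon comparisons
#'
#' For every covariate and group: median, quartiles (type-7 linear
#' interpolation), whisker bounds (1.5 x IQR rule) and outlying values --
#' the numbers behind a notched box plot -- plus all pairwise Wilcoxon
#' rank-sum p-values with Benjamini-Hochberg correction across pairs
#' (within each covariate).
#'
#' @param clusters Named vector gene -> group label.
#' @param covariates Covariate data frame (see [read_covariates()]).
#' @return List: `summary` data frame (group, covariate, n, q1, median,
#'   q3, whisker_low, whisker_high, n_outliers) and `comparisons`
#'   ([wilcoxon_compare()] rows with an `fdr` column).
#' @export
summarize_groups <- function(clusters, covariates) {
  shared <- intersect(names(clusters), covariates$gene_id)
  if (length(shared) == 0L) {
    stop("clusters and covariates share no genes", call. = FALSE)
  }
  cov_names <- setdiff(names(covariates), "gene_id")
  if (length(cov_names) == 0L) stop("no covariate columns", call. = FALSE)
  groups <- sort(unique(clusters[shared]))
  summary_rows <- list()
  comp_rows <- list()
  for (cv in cov_names) {
    vals <- stats::setNames(covariates[[cv]][match(shared,
                                                   covariates$gene_id)],
                            shared)
    for (g in groups) {
      v <- vals[names(vals) %in% names(clusters)[clusters == g]]
      v <- v[is.finite(v)]
      if (length(v) == 0L) next
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      iqr <- q[3] - q[1]
      lo <- min(v[v >= q[1] - 1.5 * iqr])
      hi <- max(v[v <= q[3] + 1.5 * iqr])
      summary_rows[[paste(cv, g)]] <- data.frame(
        group = g, covariate = cv, n = length(v), q1 = q[1],
        median = q[2], q3 = q[3], whisker_low = lo, whisker_high = hi,
        n_outliers = sum(v < lo | v > hi), stringsAsFactors = FALSE)
    }
    if (length(groups) >= 2L) {
      prs <- utils::combn(as.character(groups), 2L)
      cmp <- lapply(seq_len(ncol(prs)), function(j) {
        ga <- prs[1L, j]; gb <- prs[2L, j]
        va <- vals[names(vals) %in% names(clusters)[clusters == ga]]
        vb <- vals[names(vals) %in% names(clusters)[clusters == gb]]
        wilcoxon_compare(va, vb, ga, gb, cv)
      })
      cmp <- do.call(rbind, cmp)
      cmp$fdr <- bh_fdr(cmp$p_value)
      comp_rows[[cv]] <- cmp
    }
  }
  list(summary = do.call(rbind, c(summary_rows,
                                  list(make.row.names = FALSE))),
       comparisons = if (length(comp_rows) > 0L)
         do.call(rbind, c(comp_rows, list(make.row.names = FALSE)))
       else NULL)
}
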