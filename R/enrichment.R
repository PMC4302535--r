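## Paired negative-binomial GLM enrichment statistics.
##
## Per gene, counts are modeled as NB(mu, phi) with variance mu + phi*mu^2,
## log link and a log library-size offset. The per-bait enrichment test
## fits replicate-pair block effects plus an IP-fraction coefficient and
## tests that coefficient by a 1-df likelihood-ratio chi-square. The
## pairwise bait contrast adds a fraction-by-bait interaction term.
## Fold changes are log2 ratios of counts per million; no cross-library
## normalization is applied, so fold changes are subject to composition
## ("real estate") effects, which the GLM inference itself absorbs into
## the block structure.

#' Counts per million
#'
#' Each cell is `count / library_size * 1e6`, where the library size is
#' the column sum. No other normalization is applied.
#'
#' @param counts Validated count matrix.
#' @return Numeric matrix of the same shape.
#' @export
cpm <- function(counts) {
  libsize <- colSums(counts)
  if (any(libsize <= 0)) stop("zero library size", call. = FALSE)
  t(t(counts) / libsize) * 1e6
}

#' Filter genes by Total-library counts
#'
#' The default rule (`"all_above"`) keeps genes whose count strictly
#' exceeds `threshold` in every Total sample of every listed bait. The
#' alternative rule (`"not_all_below"`) excludes only genes below the
#' threshold in each of those samples, i.e. keeps genes at or above the
#' threshold in at least one.
#'
#' @param counts Validated count matrix.
#' @param sheet Validated sample sheet.
#' @param baits Bait subset; defaults to all baits in the sheet.
#' @param threshold Count threshold (default 20).
#' @param rule `"all_above"` (strict, default) or `"not_all_below"`.
#' @return Character vector of retained gene ids, in matrix row order.
#' @export
filter_by_total_counts <- function(counts, sheet, baits = NULL,
                                   threshold = 20,
                                   rule = c("all_above", "not_all_below")) {
  rule <- match.arg(rule)
  if (is.null(baits)) baits <- unique(sheet$protein)
  if (length(baits) == 0L) stop("empty bait subset", call. = FALSE)
  if (!all(baits %in% sheet$protein)) {
    stop("unknown bait(s): ",
         paste(setdiff(baits, sheet$protein), collapse = ", "), call. = FALSE)
  }
  total_samples <- unlist(lapply(baits, samples_of, sheet = sheet,
                                 fraction = "Total"))
  sub <- counts[, total_samples, drop = FALSE]
  keep <- switch(rule,
                 all_above = rowSums(sub > threshold) == ncol(sub),
                 not_all_below = rowSums(sub < threshold) < ncol(sub))
  rownames(counts)[keep]
}

#' Estimate per-gene NB dispersions with empirical-Bayes shrinkage
#'
#' Raw per-gene dispersions come from a method-of-moments contrast of
#' within-condition (bait-by-fraction) sample variance against the mean,
#' pooled over conditions: `phi_raw = sum((n_c-1)(v_c - m_c)) /
#' sum((n_c-1) m_c^2)`, floored at 0. Raw values are shrunk toward a
#' shared prior (the pooled global estimate, or a mean-trended curve) by
#' weighting with `prior_df` pseudo-degrees of freedom against the
#' gene's residual degrees of freedom.
#'
#' @param counts Validated count matrix.
#' @param sheet Validated sample sheet.
#' @param prior_df Prior weight in pseudo-degrees of freedom (default 20).
#' @param trend `"global"` (default) or `"trended"` (lowess of raw
#'   dispersion against log mean count).
#' @return Data frame: `gene_id`, `mean_count`, `raw`, `prior`, `shrunk`,
#'   `df`. The shrunken value always lies between `raw` and `prior`.
#' @export
estimate_dispersions <- function(counts, sheet, prior_df = 20,
                                 trend = c("global", "trended")) {
  trend <- match.arg(trend)
  sheet <- validate_sample_sheet(sheet, counts)
  cond <- interaction(sheet$protein, sheet$fraction, drop = TRUE)
  if (all(table(cond) < 2L)) {
    stop("dispersion cannot be estimated without replicates: ",
         "every bait-by-fraction condition has a single sample",
         call. = FALSE)
  }
  libsize <- colSums(counts)
  num <- den <- df <- numeric(nrow(counts))
  for (lv in levels(cond)) {
    sids <- sheet$sample_id[cond == lv]
    n_c <- length(sids)
    if (n_c < 2L) next
    ## rescale to a common library size so depth differences between
    ## replicates do not masquerade as biological dispersion; the
    ## rescaling inflates the Poisson part of the variance by the mean
    ## rescaling factor, corrected below
    L <- libsize[sids]
    f <- mean(L) / L
    sub <- sweep(counts[, sids, drop = FALSE], 2L, f, "*")
    m <- rowMeans(sub)
    v <- rowSums((sub - m)^2) / (n_c - 1)
    num <- num + (n_c - 1) * (v - m * mean(f))
    den <- den + (n_c - 1) * m^2
    df <- df + (n_c - 1)
  }
  raw <- ifelse(den > 0, pmax(0, num / den), 0)
  mean_count <- rowMeans(counts)
  prior_global <- max(0, sum(num) / sum(den))
  if (trend == "global") {
    prior <- rep(prior_global, nrow(counts))
  } else {
    ok <- mean_count > 1
    lo <- stats::lowess(log10(mean_count[ok]), raw[ok], f = 0.5)
    prior <- stats::approx(lo$x, lo$y, xout = log10(pmax(mean_count, 1)),
                           rule = 2)$y
    prior <- pmax(prior, 0)
  }
  shrunk <- (prior_df * prior + df * raw) / (prior_df + df)
  data.frame(gene_id = rownames(counts), mean_count = mean_count,
             raw = raw, prior = prior, shrunk = shrunk, df = df,
             prior_df = prior_df,
             stringsAsFactors = FALSE, row.names = NULL)
}

## ---- internal NB GLM machinery ------------------------------------------

## NB deviance with fixed dispersion phi (phi = 0 reduces to Poisson).
nb_deviance <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-12)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  if (phi > 0) {
    t2 <- (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu))
  } else {
    t2 <- y - mu
  }
  2 * sum(t1 - t2)
}

## One-gene NB GLM fit by IRLS with log link and offset.
## Returns list(beta, mu, deviance, converged).
nb_glm_fit <- function(y, X, offset, phi, max_iter = 50L, tol = 1e-8) {
  mu <- pmax(y, mean(y) / 8, 1e-4)
  eta <- log(mu)
  dev <- nb_deviance(y, mu, phi)
  beta <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + phi * mu)
    z <- eta - offset + (y - mu) / mu
    sw <- sqrt(w)
    fit <- .lm.fit(X * sw, z * sw)
    beta_new <- fit$coefficients
    eta_new <- drop(X %*% beta_new) + offset
    eta_new <- pmin(pmax(eta_new, -50), 50)
    mu_new <- exp(eta_new)
    dev_new <- nb_deviance(y, mu_new, phi)
    ## step-halve if the deviance got worse or went non-finite
    if (!is.finite(dev_new) || dev_new > dev + 1e-10) {
      ok <- FALSE
      if (!is.null(beta)) {
        for (h in 1:5) {
          beta_try <- (beta + beta_new) / 2
          eta_try <- pmin(pmax(drop(X %*% beta_try) + offset, -50), 50)
          mu_try <- exp(eta_try)
          dev_try <- nb_deviance(y, mu_try, phi)
          if (is.finite(dev_try) && dev_try <= dev + 1e-10) {
            beta_new <- beta_try; eta_new <- eta_try
            mu_new <- mu_try; dev_new <- dev_try
            ok <- TRUE
            break
          }
          beta_new <- beta_try
        }
      }
      if (!ok && !is.finite(dev_new)) break
    }
    delta <- abs(dev - dev_new)
    beta <- beta_new; eta <- eta_new; mu <- mu_new
    conv_now <- is.finite(dev_new) && delta < tol * (abs(dev_new) + 0.1)
    dev <- dev_new
    if (conv_now) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, mu = mu, deviance = dev, converged = converged)
}

## Genewise LRT of the LAST column of X_alt against X_null.
## counts: genes x samples submatrix; offset: log library sizes.
## Returns data.frame(coef, lr_stat, p_value, converged, tested).
nb_lrt_genewise <- function(counts, X_alt, X_null, offset, phi) {
  n_genes <- nrow(counts)
  coef_out <- lr <- rep(NA_real_, n_genes)
  conv <- tested <- rep(FALSE, n_genes)
  p_idx <- ncol(X_alt)
  for (g in seq_len(n_genes)) {
    y <- counts[g, ]
    if (all(y == 0)) next
    tested[g] <- TRUE
    f_alt <- nb_glm_fit(y, X_alt, offset, phi[g])
    f_null <- nb_glm_fit(y, X_null, offset, phi[g])
    conv[g] <- f_alt$converged && f_null$converged
    if (!conv[g]) next
    coef_out[g] <- f_alt$beta[p_idx]
    lr[g] <- max(0, f_null$deviance - f_alt$deviance)
  }
  p <- ifelse(tested & conv, stats::pchisq(lr, df = 1, lower.tail = FALSE),
              NA_real_)
  data.frame(coef = coef_out, lr_stat = lr, p_value = p,
             converged = conv, tested = tested)
}

## ---- user-facing tests ---------------------------------------------------

#' Test per-gene IP/Total enrichment for one bait
#'
#' Fits, per gene, an NB log-linear model over the bait's IP and Total
#' libraries with a log library-size offset, one block effect per
#' replicate pair, and an IP-fraction coefficient; the fraction
#' coefficient (reported on the log2 scale as `log2_enrichment`) is tested
#' by a 1-df likelihood-ratio chi-square against the block-only null.
#' `median_log2_fc` is the median over replicates of per-replicate
#' log2((IP_cpm + c) / (Total_cpm + c)) with pseudocount `c` (descriptive
#' only; inference never uses pseudocounts).
#'
#' @param counts Validated count matrix.
#' @param sheet Validated sample sheet.
#' @param bait Bait name.
#' @param dispersions Optional output of [estimate_dispersions()];
#'   computed on the fly when `NULL`.
#' @param min_total_count Threshold for the `n_reads_ok` flag (see
#'   [filter_by_total_counts()]).
#' @param pseudocount Pseudocount in CPM units for `median_log2_fc`
#'   (default 0.5).
#' @return Data frame with one row per gene: `gene_id`, `bait`,
#'   `log2_enrichment`, `median_log2_fc`, `p_value`, `fdr`, `tested`,
#'   `converged`, `n_reads_ok`. Untested genes carry `NA` p-values, never 0.
#' @export
test_enrichment <- function(counts, sheet, bait, dispersions = NULL,
                            min_total_count = 20, pseudocount = 0.5) {
  sheet <- validate_sample_sheet(sheet, counts)
  if (!bait %in% sheet$protein) {
    stop("bait '", bait, "' not in sample sheet", call. = FALSE)
  }
  if (is.null(dispersions)) dispersions <- estimate_dispersions(counts, sheet)
  phi <- dispersions$shrunk[match(rownames(counts), dispersions$gene_id)]

  sub_sheet <- sheet[sheet$protein == bait, ]
  sub_sheet <- sub_sheet[order(sub_sheet$replicate, sub_sheet$fraction), ]
  sids <- sub_sheet$sample_id
  offset <- log(colSums(counts))[sids]
  block <- factor(sub_sheet$replicate)
  is_ip <- as.numeric(sub_sheet$fraction == "IP")
  X_null <- stats::model.matrix(~ 0 + block)
  X_alt <- cbind(X_null, fracIP = is_ip)

  res <- nb_lrt_genewise(counts[, sids, drop = FALSE], X_alt, X_null,
                         offset, phi)
  n_fail <- sum(res$tested & !res$converged)
  if (n_fail > 0L) {
    message("test_enrichment(", bait, "): ", n_fail,
            " gene(s) failed IRLS convergence; reported with NA p-values")
  }

  ## descriptive per-replicate log2 CPM ratios
  cpm_all <- cpm(counts)
  reps <- sort(unique(sub_sheet$replicate))
  ratios <- sapply(reps, function(r) {
    ip <- sub_sheet$sample_id[sub_sheet$replicate == r &
                                sub_sheet$fraction == "IP"]
    tot <- sub_sheet$sample_id[sub_sheet$replicate == r &
                                 sub_sheet$fraction == "Total"]
    log2((cpm_all[, ip] + pseudocount) / (cpm_all[, tot] + pseudocount))
  })
  med_fc <- apply(ratios, 1L, stats::median)

  ok_genes <- filter_by_total_counts(counts, sheet, baits = bait,
                                     threshold = min_total_count)
  data.frame(gene_id = rownames(counts), bait = bait,
             log2_enrichment = res$coef / log(2),
             median_log2_fc = med_fc,
             p_value = res$p_value,
             fdr = bh_fdr(res$p_value),
             tested = res$tested, converged = res$converged,
             n_reads_ok = rownames(counts) %in% ok_genes,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Test enrichment for every bait
#'
#' Convenience wrapper running [test_enrichment()] per bait and binding
#' the rows; dispersions are estimated once on the full matrix.
#'
#' @inheritParams test_enrichment
#' @param baits Baits to test; defaults to all in the sheet.
#' @return Row-bound enrichment table across baits.
#' @export
test_enrichment_all <- function(counts, sheet, baits = NULL,
                                dispersions = NULL, min_total_count = 20,
                                pseudocount = 0.5) {
  sheet <- validate_sample_sheet(sheet, counts)
  if (is.null(baits)) baits <- unique(sheet$protein)
  if (is.null(dispersions)) dispersions <- estimate_dispersions(counts, sheet)
  do.call(rbind, lapply(baits, function(b) {
    test_enrichment(counts, sheet, b, dispersions = dispersions,
                    min_total_count = min_total_count,
                    pseudocount = pseudocount)
  }))
}

#' Test differential enrichment between two baits (interaction contrast)
#'
#' Joint NB model over both baits' IP and Total libraries with one block
#' effect per replicate pair, a common IP-fraction effect and a
#' fraction-by-bait interaction coefficient. The interaction coefficient
#' equals enrichment(A) - enrichment(B) and is tested by a 1-df
#' likelihood-ratio chi-square; `delta_log2` reports it on the log2 scale.
#' Swapping the baits negates `delta_log2` and leaves p-values unchanged.
#'
#' @param counts Validated count matrix.
#' @param sheet Validated sample sheet.
#' @param baitA,baitB Distinct bait names; positive `delta_log2` means
#'   over-representation in `baitA` relative to `baitB`.
#' @param dispersions Optional output of [estimate_dispersions()].
#' @return Data frame per gene: `gene_id`, `bait_a`, `bait_b`,
#'   `delta_log2`, `p_value`, `fdr`, `direction`, `tested`, `converged`.
#' @export
test_interaction <- function(counts, sheet, baitA, baitB,
                             dispersions = NULL) {
  sheet <- validate_sample_sheet(sheet, counts)
  if (identical(baitA, baitB)) {
    stop("baitA and baitB must differ", call. = FALSE)
  }
  for (b in c(baitA, baitB)) {
    if (!b %in% sheet$protein) stop("bait '", b, "' not in sample sheet",
                                    call. = FALSE)
  }
  if (is.null(dispersions)) dispersions <- estimate_dispersions(counts, sheet)
  phi <- dispersions$shrunk[match(rownames(counts), dispersions$gene_id)]

  sub_sheet <- sheet[sheet$protein %in% c(baitA, baitB), ]
  sub_sheet <- sub_sheet[order(sub_sheet$protein, sub_sheet$replicate,
                               sub_sheet$fraction), ]
  sids <- sub_sheet$sample_id
  offset <- log(colSums(counts))[sids]
  block <- factor(paste(sub_sheet$protein, sub_sheet$replicate, sep = "."))
  is_ip <- as.numeric(sub_sheet$fraction == "IP")
  is_a <- as.numeric(sub_sheet$protein == baitA)
  X_null <- cbind(stats::model.matrix(~ 0 + block), fracIP = is_ip)
  X_alt <- cbind(X_null, fracIP_baitA = is_ip * is_a)

  res <- nb_lrt_genewise(counts[, sids, drop = FALSE], X_alt, X_null,
                         offset, phi)
  delta <- res$coef / log(2)
  data.frame(gene_id = rownames(counts), bait_a = baitA, bait_b = baitB,
             delta_log2 = delta,
             p_value = res$p_value, fdr = bh_fdr(res$p_value),
             direction = ifelse(is.na(delta), NA_character_,
                                ifelse(delta >= 0, baitA, baitB)),
             tested = res$tested, converged = res$converged,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up false discovery rates
#'
#' Missing p-values are passed through as missing and excluded from the
#' number of tests.
#'
#' @param p Numeric vector of p-values in [0, 1]; `NA` allowed.
#' @return Vector of q-values, monotone non-decreasing in p rank.
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}
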