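## Stoichiometric linear decomposition: the hub bait's enrichment profile
## modeled as a weighted sum of partner profiles by ordinary least
## squares, with externally studentized (jackknife) residuals for
## outlier transcript discovery.

#' Fit the stoichiometric linear decomposition
#'
#' Ordinary least squares of a target per-gene log2 enrichment profile on
#' partner profiles, via QR decomposition. Reports coefficients with
#' standard errors and two-sided t-test p-values, R-squared, leverages
#' (hat-matrix diagonal), and jackknife residuals
#' `t_i = e_i / (s_(i) * sqrt(1 - h_ii))` with `s_(i)` the leave-one-out
#' residual standard deviation obtained from the closed-form deletion
#' identity (no refitting).
#'
#' A perfectly collinear predictor matrix raises an error naming the
#' aliased columns; near-collinearity is reported through the condition
#' number and pairwise predictor correlations carried on the fit.
#'
#' @param target Named numeric vector (gene -> log2 enrichment) for the
#'   hub bait.
#' @param predictors Numeric matrix or data frame of partner profiles
#'   (genes x partners) with row names matching `target`'s names.
#' @param include_intercept Fit a free intercept (default `TRUE`); the
#'   strict linear-combination form is obtained with `FALSE`.
#' @param target_name,predictor_names Labels for reporting.
#' @return Object of class `stoich_fit`: coefficients table (`$coef`:
#'   term, beta, se, t, p), `$r_squared`, per-gene `$diagnostics` data
#'   frame (gene_id, observed, fitted, residual, leverage,
#'   jackknife_residual), `$n_genes`, `$df_residual`, `$condition_number`,
#'   `$predictor_cor`.
#' @export
fit_linear_decomposition <- function(target, predictors,
                                     include_intercept = TRUE,
                                     target_name = "target",
                                     predictor_names = NULL) {
  predictors <- as.matrix(predictors)
  if (!is.null(predictor_names)) colnames(predictors) <- predictor_names
  if (is.null(colnames(predictors))) {
    colnames(predictors) <- paste0("x", seq_len(ncol(predictors)))
  }
  if (is.null(names(target)) || is.null(rownames(predictors))) {
    if (length(target) != nrow(predictors)) {
      stop("target and predictors must align by gene", call. = FALSE)
    }
    genes <- if (!is.null(rownames(predictors))) rownames(predictors)
             else paste0("gene", seq_along(target))
  } else {
    genes <- intersect(names(target), rownames(predictors))
    target <- target[genes]
    predictors <- predictors[genes, , drop = FALSE]
  }
  keep <- is.finite(target) & apply(is.finite(predictors), 1L, all)
  target <- target[keep]
  predictors <- predictors[keep, , drop = FALSE]
  genes <- genes[keep]
  n <- length(target)
  p_terms <- ncol(predictors) + as.integer(include_intercept)
  if (n < ncol(predictors) + 2L) {
    stop("need at least ", ncol(predictors) + 2L,
         " genes with finite values in all profiles", call. = FALSE)
  }

  X <- if (include_intercept) {
    cbind("(Intercept)" = 1, predictors)
  } else predictors
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("rank-deficient predictor matrix; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrx, target)
  fitted <- drop(X %*% beta)
  resid <- target - fitted
  rss <- sum(resid^2)
  df_res <- n - ncol(X)
  sigma2 <- rss / df_res
  XtX_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(diag(XtX_inv) * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = df_res, lower.tail = FALSE)

  tss <- if (include_intercept) sum((target - mean(target))^2)
         else sum(target^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_

  ## leverages from the thin Q factor
  Q <- qr.Q(qrx)
  h <- rowSums(Q^2)
  h <- pmin(h, 1 - 1e-12)
  ## deletion identity for the leave-one-out residual variance
  s2_i <- (rss - resid^2 / (1 - h)) / (df_res - 1)
  s2_i <- pmax(s2_i, .Machine$double.eps)
  jack <- resid / sqrt(s2_i * (1 - h))

  sv <- svd(X, nu = 0, nv = 0)$d
  kappa_x <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  pred_cor <- if (ncol(predictors) > 1L) stats::cor(predictors) else NULL

  structure(list(
    target = target_name,
    predictors = colnames(predictors),
    include_intercept = include_intercept,
    coef = data.frame(term = colnames(X), beta = unname(beta),
                      se = unname(se), t = unname(tval), p = unname(pval),
                      stringsAsFactors = FALSE),
    r_squared = r2,
    sigma = sqrt(sigma2),
    n_genes = n,
    df_residual = df_res,
    condition_number = kappa_x,
    predictor_cor = pred_cor,
    diagnostics = data.frame(gene_id = genes, observed = unname(target),
                             fitted = unname(fitted),
                             residual = unname(resid),
                             leverage = unname(h),
                             jackknife_residual = unname(jack),
                             stringsAsFactors = FALSE)
  ), class = "stoich_fit")
}

#' @export
print.stoich_fit <- function(x, ...) {
  cat("Stoichiometric decomposition of '", x$target, "' on ",
      length(x$predictors), " predictor profile(s)\n", sep = "")
  cat(sprintf("  n = %d genes, R-squared = %.4f, residual sd = %.4f\n",
              x$n_genes, x$r_squared, x$sigma))
  cat(sprintf("  condition number of the design: %.2f\n",
              x$condition_number))
  print(x$coef, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Flag outlier transcripts by jackknife residuals
#'
#' Genes whose absolute jackknife residual exceeds the two-sided t
#' quantile at level `alpha / n` (Bonferroni outlier test with
#' `df = n - p - 1`) are flagged. The full ranking by |jackknife
#' residual| is always returned so any other cutoff can be applied.
#'
#' @param fit A `stoich_fit`.
#' @param alpha Family-wise level for the Bonferroni test (default 0.05).
#' @return Data frame ranked by decreasing |jackknife residual|:
#'   `gene_id`, `jackknife_residual`, `fitted`, `leverage`, `outlier`.
#' @export
flag_outliers <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "stoich_fit"))
  d <- fit$diagnostics
  n <- nrow(d)
  df_t <- fit$df_residual - 1L
  cut <- stats::qt(1 - alpha / (2 * n), df = df_t)
  out <- d[order(-abs(d$jackknife_residual)),
           c("gene_id", "jackknife_residual", "fitted", "leverage")]
  out$outlier <- abs(out$jackknife_residual) > cut
  rownames(out) <- NULL
  out
}

#' Plot jackknife residuals against fitted values
#'
#' Scatter of the regression diagnostic used to single out transcripts
#' escaping the stoichiometric model; flagged genes are labeled. A
#' companion TSV of the plotted values is always written.
#'
#' @param fit A `stoich_fit`.
#' @param prefix Output path prefix (writes `<prefix>.png` and
#'   `<prefix>.tsv`).
#' @param alpha Outlier level passed to [flag_outliers()].
#' @return Paths written, invisibly.
#' @export
plot_residuals <- function(fit, prefix, alpha = 0.05) {
  stopifnot(inherits(fit, "stoich_fit"))
  fl <- flag_outliers(fit, alpha = alpha)
  d <- fit$diagnostics[order(fit$diagnostics$gene_id), ]
  tsv <- paste0(prefix, ".tsv")
  write_table(d, tsv)
  png_path <- paste0(prefix, ".png")
  grDevices::png(png_path, width = 700, height = 550)
  graphics::plot(d$fitted, d$jackknife_residual,
                 xlab = "fitted log2 enrichment",
                 ylab = "jackknife residual",
                 pch = 16, col = "grey40",
                 main = paste("Residual diagnostics:", fit$target))
  graphics::abline(h = 0, lty = 2)
  flagged <- fl$gene_id[fl$outlier]
  if (length(flagged) > 0L) {
    idx <- match(flagged, d$gene_id)
    graphics::points(d$fitted[idx], d$jackknife_residual[idx],
                     col = "red", pch = 16)
    graphics::text(d$fitted[idx], d$jackknife_residual[idx],
                   labels = flagged, pos = 3, col = "red", cex = 0.8)
  }
  grDevices::dev.off()
  invisible(c(tsv, png_path))
}
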