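## Independent brute-force oracles used to validate the package's
## implementations, plus small fixture builders. Each oracle recomputes
## its quantity from first principles, never through the code path it
## checks.

## ---- fixtures -----------------------------------------------------------

## Minimal paired count matrix: one bait, `reps` replicate pairs.
make_paired_counts <- function(n_genes, reps = 3, phi = 0.1,
                               lib = 5e5, seed = 1, bait = "A") {
  set.seed(seed)
  a <- rlnorm(n_genes, 0, 1)
  a <- a / sum(a)
  sids <- as.vector(outer(c("IP", "Total"), seq_len(reps),
                          function(f, r) sprintf("%s_r%d_%s", bait, r, f)))
  mu <- outer(a, rep(lib, 2 * reps))
  y <- matrix(if (phi > 0) rnbinom(length(mu), mu = mu, size = 1 / phi)
              else rpois(length(mu), mu), nrow = n_genes)
  rownames(y) <- sprintf("g%04d", seq_len(n_genes))
  colnames(y) <- sids
  sheet <- data.frame(sample_id = sids, protein = bait,
                      replicate = rep(seq_len(reps), each = 2),
                      fraction = rep(c("IP", "Total"), reps),
                      stringsAsFactors = FALSE)
  ## guard against an all-zero column in tiny fixtures
  y[1L, colSums(y) == 0] <- 1
  list(counts = y, sheet = sheet)
}

## ---- clustering oracle --------------------------------------------------

## O(n^3) average-linkage agglomeration on a distance matrix, recomputing
## every between-cluster average distance from the original matrix at
## each step. Returns sorted merge heights and the cophenetic matrix.
average_linkage_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < best_d) {
          best_d <- dij
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    coph[clusters[[best[1]]], clusters[[best[2]]]] <- best_d
    coph[clusters[[best[2]]], clusters[[best[1]]]] <- best_d
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = sort(heights), cophenetic = coph)
}

## Adjusted Rand Index between two label vectors.
ari <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  n <- length(x)
  expected <- sum_a * sum_b / (n * (n - 1) / 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

## ---- regression oracle --------------------------------------------------

## OLS with leverages and jackknife residuals by explicit leave-one-out
## refits (normal equations, no QR).
ols_refit_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  H <- X %*% solve(XtX) %*% t(X)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  n <- length(y)
  p <- ncol(X)
  jack <- numeric(n)
  for (i in seq_len(n)) {
    bi <- solve(t(X[-i, ]) %*% X[-i, ], t(X[-i, , drop = FALSE]) %*% y[-i])
    ri <- y[-i] - drop(X[-i, ] %*% bi)
    s_i <- sqrt(sum(ri^2) / (n - 1 - p))
    jack[i] <- resid[i] / (s_i * sqrt(1 - H[i, i]))
  }
  list(beta = drop(beta), leverage = diag(H), residual = resid,
       jackknife = jack,
       r_squared = 1 - sum(resid^2) / sum((y - mean(y))^2))
}

## ---- exact-statistics oracles -------------------------------------------

## Hypergeometric tails by explicit combinatorial enumeration.
hyper_tail_oracle <- function(k, K, N, n) {
  pmf <- function(x) choose(K, x) * choose(N - K, n - x) / choose(N, n)
  xs <- max(0, n - (N - K)):min(n, K)
  c(p_over = sum(vapply(xs[xs >= k], pmf, numeric(1))),
    p_under = sum(vapply(xs[xs <= k], pmf, numeric(1))))
}

## Fisher two-sided p: sum of probabilities of all fixed-margin tables no
## more probable than the observed one (same 1e-7 relative tolerance rule
## as the exact test's reference implementation).
fisher_two_sided_oracle <- function(a, b, c_, d) {
  K <- a + c_; N <- a + b + c_ + d; n <- a + b
  xs <- max(0, n - (N - K)):min(n, K)
  pr <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  p_obs <- pr[xs == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

## Exact two-sided Wilcoxon rank-sum p by enumerating every assignment of
## the pooled ranks to group A, doubling the smaller tail as the exact
## test does.
wilcoxon_exact_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- combn(na + nb, na)
  us <- apply(combos, 2L, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

## BH step-up by direct evaluation of the running minima.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
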