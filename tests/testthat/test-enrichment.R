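test_that("cpm rescales to counts per million and nothing else", {
  m <- matrix(c(50L, 499950L, 0L, 2L, 999998L, 0L), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  x <- cpm(m)
  expect_equal(x["g1", "s1"], 100)
  expect_equal(unname(x["g3", ]), c(0, 0))
  expect_equal(unname(colSums(x)), c(1e6, 1e6))
})

test_that("the Total-count filter applies the strict greater-than rule", {
  counts <- rbind(g_in = c(5L, 21L, 9L, 21L, 7L, 21L),
                  g_border = c(1L, 20L, 2L, 25L, 3L, 30L),
                  g_zero = c(0L, 0L, 0L, 0L, 0L, 0L),
                  g_pad = c(100L, 100L, 100L, 100L, 100L, 100L))
  colnames(counts) <- sprintf("A_r%d_%s", rep(1:3, each = 2),
                              rep(c("IP", "Total"), 3))
  sheet <- data.frame(sample_id = colnames(counts), protein = "A",
                      replicate = rep(1:3, each = 2),
                      fraction = rep(c("IP", "Total"), 3))
  kept <- filter_by_total_counts(counts, sheet, threshold = 20)
  expect_true("g_in" %in% kept)       # (21, 21, 21): all strictly above
  expect_false("g_border" %in% kept)  # (20, 25, 30): 20 is not > 20
  expect_false("g_zero" %in% kept)
  ## the alternative reading keeps genes not below threshold everywhere
  kept2 <- filter_by_total_counts(counts, sheet, threshold = 20,
                                  rule = "not_all_below")
  expect_true("g_border" %in% kept2)
  expect_false("g_zero" %in% kept2)
  expect_error(filter_by_total_counts(counts, sheet, baits = character(0)),
               "empty bait")
})

test_that("dispersion estimation recovers Poisson and NB truth", {
  fx0 <- make_paired_counts(2000, reps = 3, phi = 0, seed = 101)
  d0 <- estimate_dispersions(fx0$counts, fx0$sheet)
  expect_lt(median(d0$shrunk), 0.02)

  fx1 <- make_paired_counts(2000, reps = 3, phi = 0.1, seed = 102)
  d1 <- estimate_dispersions(fx1$counts, fx1$sheet)
  expect_gt(median(d1$shrunk), 0.07)
  expect_lt(median(d1$shrunk), 0.13)

  ## a constant gene has raw moment estimate floored at zero, and the
  ## shrunken value always lies between raw and prior
  fx1$counts[1, ] <- 500L
  d2 <- estimate_dispersions(fx1$counts, fx1$sheet)
  expect_equal(d2$raw[1], 0)
  expect_true(all(d2$shrunk >= pmin(d2$raw, d2$prior) - 1e-12))
  expect_true(all(d2$shrunk <= pmax(d2$raw, d2$prior) + 1e-12))
})

test_that("a gene with IP identical to Total is a clean null", {
  set.seed(31)
  n <- 60
  base <- matrix(rnbinom(n * 3, mu = 300, size = 10), n)
  y <- cbind(base[, 1], base[, 1], base[, 2], base[, 2],
             base[, 3], base[, 3])
  rownames(y) <- sprintf("g%03d", 1:n)
  colnames(y) <- sprintf("A_r%d_%s", rep(1:3, each = 2),
                         rep(c("IP", "Total"), 3))
  sheet <- data.frame(sample_id = colnames(y), protein = "A",
                      replicate = rep(1:3, each = 2),
                      fraction = rep(c("IP", "Total"), 3))
  enr <- test_enrichment(y, sheet, "A",
                         dispersions = data.frame(gene_id = rownames(y),
                                                  shrunk = 0.1))
  expect_lt(max(abs(enr$log2_enrichment)), 1e-6)
  expect_true(all(enr$p_value > 0.5))
})

test_that("all-zero genes are reported untested with missing p-values", {
  fx <- make_paired_counts(50, reps = 3, phi = 0.1, seed = 37)
  fx$counts[5, ] <- 0L
  enr <- test_enrichment(fx$counts, fx$sheet, "A")
  expect_false(enr$tested[5])
  expect_true(is.na(enr$p_value[5]))
  expect_true(is.na(enr$fdr[5]))
})

test_that("the paired estimate matches the pooled CPM ratio at high counts", {
  ## no replicate block effect planted, so the GLM coefficient and the
  ## simple ratio of summed CPMs must agree closely for well-covered
  ## genes; dispersion is kept low because at large phi the two
  ## estimators aggregate replicate noise differently by design
  cfg <- sim_config(n_genes = 500, proteins = c("A", "B"), hub = "A",
                    partners = "B", polyA_binder = "A",
                    repressors = character(0), beta_true = 1,
                    effect_size = 1.5, hub_noise_sd = 0, n_outliers = 0,
                    group_proportions = c(I = 0.1, II = 0, III = 0.1,
                                          IV = 0),
                    dispersion = 0.01,
                    mean_library_size = 1e6, library_size_cv = 0,
                    seed = 41)
  ds <- simulate_rip_dataset(cfg)
  enr <- test_enrichment(ds$counts, ds$sheet, "B")
  cpm_all <- cpm(ds$counts)
  ip <- samples_of(ds$sheet, "B", "IP")
  tot <- samples_of(ds$sheet, "B", "Total")
  simple <- log2(rowSums(cpm_all[, ip]) / rowSums(cpm_all[, tot]))
  big <- rowMeans(ds$counts[, tot]) > 100
  expect_lt(max(abs(enr$log2_enrichment[big] - simple[big])), 0.1)
})

test_that("the LRT is invariant to relabeling replicate indices", {
  fx <- make_paired_counts(40, reps = 3, phi = 0.1, seed = 43)
  enr1 <- test_enrichment(fx$counts, fx$sheet, "A")
  relabeled <- fx$sheet
  relabeled$replicate <- c(3, 3, 1, 1, 2, 2)[match(relabeled$sample_id,
                                                   fx$sheet$sample_id)]
  enr2 <- test_enrichment(fx$counts, relabeled, "A")
  expect_equal(enr1$p_value, enr2$p_value, tolerance = 1e-6)
  expect_equal(enr1$log2_enrichment, enr2$log2_enrichment,
               tolerance = 1e-6)
})

test_that("interaction contrast is antisymmetric under bait swap", {
  cfg <- sim_config(n_genes = 150, proteins = c("A", "B"), hub = "A",
                    partners = "B", polyA_binder = "A",
                    repressors = character(0), beta_true = 0.5,
                    effect_size = 1.5, hub_noise_sd = 0.2, n_outliers = 0,
                    group_proportions = c(I = 0.1, II = 0, III = 0.1,
                                          IV = 0),
                    mean_library_size = 3e5, seed = 47)
  ds <- simulate_rip_dataset(cfg)
  ab <- test_interaction(ds$counts, ds$sheet, "A", "B")
  ba <- test_interaction(ds$counts, ds$sheet, "B", "A")
  expect_equal(ab$delta_log2, -ba$delta_log2, tolerance = 1e-6)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-6)
  expect_error(test_interaction(ds$counts, ds$sheet, "A", "A"), "differ")
})

test_that("planted between-bait differences are detected", {
  ## bait B carries planted enrichment that the hub (A) does not mirror
  ## at all (beta 0), so the interaction contrast sees the full delta
  cfg <- sim_config(n_genes = 800, proteins = c("A", "B"), hub = "A",
                    partners = "B", polyA_binder = "A",
                    repressors = character(0), beta_true = 0,
                    effect_size = 2.5, effect_jitter = 0, hub_noise_sd = 0,
                    n_outliers = 0,
                    group_proportions = c(I = 0.05, II = 0, III = 0.05,
                                          IV = 0),
                    mean_library_size = 1e6, seed = 53)
  ds <- simulate_rip_dataset(cfg)
  it <- test_interaction(ds$counts, ds$sheet, "A", "B")
  planted <- ds$truth$genes$group %in% c("I", "III")
  sig <- !is.na(it$fdr) & it$fdr < 0.05
  expect_gt(mean(sig[planted]), 0.8)
  ## direction: group III genes are higher in B than in A
  g3 <- ds$truth$genes$group == "III"
  expect_lt(median(it$delta_log2[g3]), 0)
})

test_that("BH step-up matches hand-enumerated minima and passes NA through", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.05, 10)), rep(0.05, 10))
  expect_equal(bh_fdr(c(0.01, NA, 0.04)), c(0.02, NA, 0.04))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(59)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^2
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("enrichment coefficients and p-values agree with edgeR's GLM", {
  fx <- make_paired_counts(300, reps = 3, phi = 0.1, seed = 61)
  ## plant some signal so the comparison spans the effect range
  ip_cols <- fx$sheet$sample_id[fx$sheet$fraction == "IP"]
  fx$counts[1:60, ip_cols] <- fx$counts[1:60, ip_cols] * 3L
  disp <- estimate_dispersions(fx$counts, fx$sheet)
  mine <- test_enrichment(fx$counts, fx$sheet, "A", dispersions = disp)

  d <- edgeR::DGEList(counts = fx$counts)
  d$samples$norm.factors <- 1
  design <- model.matrix(~ factor(fx$sheet$replicate) +
                           as.numeric(fx$sheet$fraction == "IP"))
  fit <- edgeR::glmFit(d, design,
                       dispersion = disp$shrunk[match(rownames(fx$counts),
                                                      disp$gene_id)])
  lrt <- edgeR::glmLRT(fit)
  expect_gt(cor(mine$log2_enrichment, lrt$table$logFC), 0.999)
  expect_lt(median(abs(mine$log2_enrichment - lrt$table$logFC)), 0.01)
  expect_gt(cor(-log10(mine$p_value), -log10(lrt$table$PValue)), 0.99)
})
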