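## End-to-end orchestration: simulate a dataset to disk, run the full
## analysis chain (enrichment -> interactions -> clustering ->
## stoichiometry -> set statistics), and render a markdown report from
## the persisted tables.

log_stage <- function(stage, ..., t0 = NULL) {
  msg <- paste0(...)
  if (!is.null(t0)) {
    msg <- sprintf("%s [%.1fs]", msg,
                   as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  message(sprintf("[%s] %s", stage, msg))
}

#' Simulate a dataset and write it to disk
#'
#' Writes `counts.tsv`, `samples.tsv`, `truth.json`, `covariates.tsv` and
#' `gene_sets.gmt` under `out_dir`. Identical configurations produce
#' byte-identical outputs.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param force Overwrite existing outputs (default `FALSE`: refuse).
#' @param covariate_strength Passed to [simulate_covariates()].
#' @param gene_set_odds Passed to [simulate_gene_sets()] as
#'   `planted_odds`.
#' @return Named vector of written paths, invisibly.
#' @export
pipeline_simulate <- function(config, out_dir, force = FALSE,
                              covariate_strength = 0.5,
                              gene_set_odds = 5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(out_dir, "counts.tsv"),
             sheet = file.path(out_dir, "samples.tsv"),
             truth = file.path(out_dir, "truth.json"),
             covariates = file.path(out_dir, "covariates.tsv"),
             gene_sets = file.path(out_dir, "gene_sets.gmt"))
  existing <- paths[file.exists(paths)]
  if (length(existing) > 0L && !force) {
    stop("outputs already exist (use force = TRUE to overwrite): ",
         paste(basename(existing), collapse = ", "), call. = FALSE)
  }
  log_stage("simulate", "seed = ", config$seed, ", n_genes = ",
            config$n_genes)
  ds <- simulate_rip_dataset(config)
  write_counts(ds$counts, paths[["counts"]])
  write_sample_sheet(ds$sheet, paths[["sheet"]])
  write_truth(ds$truth, paths[["truth"]])
  write_covariates(simulate_covariates(ds$truth,
                                       strength = covariate_strength),
                   paths[["covariates"]])
  write_gene_sets(simulate_gene_sets(ds$truth,
                                     planted_odds = gene_set_odds),
                  paths[["gene_sets"]])
  invisible(paths)
}

#' Run the full analysis chain
#'
#' Executes enrichment testing for every bait, pairwise interaction
#' contrasts, profile clustering with group naming, the stoichiometric
#' decomposition with outlier discovery, and gene-set/covariate
#' statistics over the resulting groups. All stage outputs are written
#' as tab-separated tables under `out_dir`, together with a
#' `manifest.json` recording inputs, thresholds, seed and per-stage row
#' counts.
#'
#' @param counts Validated count matrix.
#' @param sheet Validated sample sheet.
#' @param out_dir Output directory.
#' @param hub Hub bait for the stoichiometric fit.
#' @param partners Predictor baits; default all others except
#'   `polyA_binder`... supply explicitly for non-default panels.
#' @param polyA_binder,repressors Role assignments used for group naming.
#' @param gene_sets Optional named list of term member vectors.
#' @param covariates Optional covariate data frame.
#' @param enrich_fdr Per-bait enrichment FDR threshold reported in the
#'   manifest (default 0.05).
#' @param cluster_fdr FDR threshold for clustering gene selection
#'   (default 0.01).
#' @param min_total_count Total-count filter threshold (default 20).
#' @param k Number of clusters to cut before archetype naming
#'   (default 7).
#' @param outlier_alpha Level for the Bonferroni outlier test
#'   (default 0.05).
#' @param interaction_pairs `"hub"` (default: hub against each partner),
#'   `"all"` (every bait pair), `"none"`, or an explicit 2-column
#'   character matrix of pairs.
#' @param seed Seed recorded in the manifest (the chain itself is
#'   deterministic given its inputs).
#' @return A list with all stage results (`enrichment`, `interactions`,
#'   `selected_genes`, `profiles`, `tree`, `groups`, `group_names`,
#'   `stoich_fit`, `outliers`, `set_stats`, `covariate_stats`,
#'   `manifest`), invisibly writing TSVs under `out_dir`.
#' @export
pipeline_run <- function(counts, sheet, out_dir,
                         hub, partners,
                         polyA_binder, repressors,
                         gene_sets = NULL, covariates = NULL,
                         enrich_fdr = 0.05, cluster_fdr = 0.01,
                         min_total_count = 20, k = 7,
                         outlier_alpha = 0.05,
                         interaction_pairs = "hub",
                         seed = NA_integer_) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sheet <- validate_sample_sheet(sheet, counts)
  baits <- unique(sheet$protein)
  t0 <- Sys.time()
  log_stage("run", "seed = ", seed, "; baits: ",
            paste(baits, collapse = ", "))

  ## stage 1: per-bait enrichment
  disp <- estimate_dispersions(counts, sheet)
  write_table(disp, file.path(out_dir, "dispersions.tsv"))
  enrichment <- test_enrichment_all(counts, sheet, dispersions = disp,
                                    min_total_count = min_total_count)
  write_table(enrichment, file.path(out_dir, "enrichment.tsv"))
  log_stage("enrich", nrow(enrichment), " gene-by-bait rows", t0 = t0)

  ## stage 2: pairwise interaction contrasts
  pairs <- NULL
  if (is.matrix(interaction_pairs)) {
    pairs <- interaction_pairs
  } else if (identical(interaction_pairs, "all")) {
    pairs <- t(utils::combn(baits, 2L))
  } else if (identical(interaction_pairs, "hub")) {
    pairs <- cbind(hub, setdiff(baits, hub))
  }
  interactions <- NULL
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    interactions <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      test_interaction(counts, sheet, pairs[i, 1L], pairs[i, 2L],
                       dispersions = disp)
    }))
    write_table(interactions, file.path(out_dir, "interactions.tsv"))
    log_stage("interact", nrow(pairs), " bait pair(s)", t0 = t0)
  }

  ## stage 3: clustering into binding groups
  selected <- select_cluster_genes(enrichment, counts, sheet,
                                   fdr_threshold = cluster_fdr,
                                   min_total_count = min_total_count)
  groups <- NULL; group_names <- NULL; tree <- NULL; profiles <- NULL
  if (length(selected) >= 2L) {
    profiles <- build_profile_matrix(counts, sheet, genes = selected)
    tree <- hierarchical_cluster(profiles)
    groups <- cut_groups(tree, k = min(k, length(selected)))
    group_names <- match_group_archetypes(profiles, groups, polyA_binder,
                                          repressors)
    leaf_pos <- match(names(groups), names(groups)[tree$order])
    write_table(data.frame(gene_id = names(groups), cluster = groups,
                           group = group_names, leaf_position = leaf_pos,
                           stringsAsFactors = FALSE),
                file.path(out_dir, "clusters.tsv"))
    export_heatmap(profiles, tree, file.path(out_dir, "heatmap"))
    log_stage("cluster", length(selected), " genes in ",
              length(unique(groups)), " clusters", t0 = t0)
  } else {
    log_stage("cluster", "skipped: fewer than 2 selected genes")
  }

  ## stage 4: stoichiometric decomposition on the clustering universe
  univ <- filter_by_total_counts(counts, sheet,
                                 threshold = min_total_count)
  agg <- build_profile_matrix(counts, sheet, genes = univ,
                              aggregate = TRUE)
  ## pairwise scatter grid of per-bait enrichment profiles
  grDevices::png(file.path(out_dir, "pairwise_scatter.png"),
                 width = 900, height = 900)
  graphics::pairs(agg, pch = ".", col = "grey30",
                  main = "per-bait log2 enrichment (IP/Total)")
  grDevices::dev.off()
  fit <- fit_linear_decomposition(
    stats::setNames(agg[, hub], rownames(agg)),
    agg[, partners, drop = FALSE],
    target_name = hub)
  outliers <- flag_outliers(fit, alpha = outlier_alpha)
  write_table(fit$coef, file.path(out_dir, "stoichiometry_coefficients.tsv"))
  write_table(outliers, file.path(out_dir, "stoichiometry_outliers.tsv"))
  plot_residuals(fit, file.path(out_dir, "stoichiometry_residuals"),
                 alpha = outlier_alpha)
  log_stage("stoich", sprintf("R-squared = %.3f, %d flagged outlier(s)",
                              fit$r_squared, sum(outliers$outlier)),
            t0 = t0)

  ## stage 5: set and covariate statistics over the named groups
  set_stats <- NULL; covariate_stats <- NULL
  if (!is.null(group_names)) {
    named <- group_names[group_names != "unassigned"]
    if (!is.null(gene_sets) && length(named) > 0L) {
      set_stats <- do.call(rbind, lapply(sort(unique(named)), function(g) {
        res <- hypergeometric_enrichment(names(named)[named == g],
                                         gene_sets, univ)
        res$group <- g
        res
      }))
      write_table(set_stats, file.path(out_dir, "set_stats.tsv"))
    }
    if (!is.null(covariates) && length(named) > 0L) {
      covariate_stats <- summarize_groups(named, covariates)
      write_table(covariate_stats$summary,
                  file.path(out_dir, "covariate_summary.tsv"))
      if (!is.null(covariate_stats$comparisons)) {
        write_table(covariate_stats$comparisons,
                    file.path(out_dir, "covariate_comparisons.tsv"))
      }
    }
    log_stage("sets", "done", t0 = t0)
  }

  manifest <- list(
    seed = seed,
    baits = baits, hub = hub, partners = partners,
    thresholds = list(enrich_fdr = enrich_fdr, cluster_fdr = cluster_fdr,
                      min_total_count = min_total_count, k = k,
                      outlier_alpha = outlier_alpha),
    n_genes = nrow(counts), n_samples = ncol(counts),
    n_selected = length(selected),
    n_clusters = if (!is.null(groups)) length(unique(groups)) else 0L,
    r_squared = fit$r_squared,
    n_outliers_flagged = sum(outliers$outlier),
    enrichment_rows = nrow(enrichment),
    interaction_rows = if (is.null(interactions)) 0L else nrow(interactions))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(enrichment = enrichment, interactions = interactions,
                 selected_genes = selected, profiles = profiles,
                 tree = tree, groups = groups, group_names = group_names,
                 stoich_fit = fit, outliers = outliers,
                 set_stats = set_stats, covariate_stats = covariate_stats,
                 manifest = manifest))
}

#' Render a markdown report from persisted stage outputs
#'
#' Reads only the TSV/JSON files a [pipeline_run()] left under
#' `results_dir` (no recomputation) and writes `report.md`. Missing
#' stages are marked absent with a warning; regeneration is idempotent.
#'
#' @param results_dir Directory holding stage outputs.
#' @param top_n Number of top outlier rows to tabulate (default 10).
#' @return Path of the report, invisibly.
#' @export
pipeline_report <- function(results_dir, top_n = 10) {
  out <- character(0)
  add <- function(...) out <<- c(out, paste0(...))
  read_if <- function(name) {
    p <- file.path(results_dir, name)
    if (file.exists(p)) utils::read.delim(p, stringsAsFactors = FALSE)
    else NULL
  }
  add("# RIP-seq comparative analysis report", "")

  man_path <- file.path(results_dir, "manifest.json")
  if (file.exists(man_path)) {
    man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    add("## Run", "",
        sprintf("- seed: %s", man$seed),
        sprintf("- genes: %s, samples: %s", man$n_genes, man$n_samples),
        sprintf("- baits: %s", paste(man$baits, collapse = ", ")), "")
  }

  enr <- read_if("enrichment.tsv")
  if (is.null(enr)) {
    warning("enrichment output absent")
    add("## Enrichment", "", "_absent_", "")
  } else {
    tab <- stats::aggregate(fdr ~ bait, enr,
                            function(f) sum(f < 0.05, na.rm = TRUE))
    add("## Enrichment (genes at FDR < 0.05 per bait)", "",
        "| bait | n significant |", "|---|---|",
        sprintf("| %s | %d |", tab$bait, tab$fdr), "")
  }

  inter <- read_if("interactions.tsv")
  if (is.null(inter)) {
    add("## Pairwise interaction contrasts", "", "_absent_", "")
  } else {
    key <- paste(inter$bait_a, "vs", inter$bait_b)
    n_sig <- tapply(inter$fdr, key, function(f) sum(f < 0.05, na.rm = TRUE))
    add("## Pairwise interaction contrasts (FDR < 0.05)", "",
        "| pair | n significant |", "|---|---|",
        sprintf("| %s | %d |", names(n_sig), as.integer(n_sig)), "",
        "Scatter grid of per-bait profiles: `pairwise_scatter.png`.", "")
  }

  cl <- read_if("clusters.tsv")
  if (is.null(cl)) {
    warning("clustering output absent")
    add("## Binding groups", "", "_absent_", "")
  } else {
    sizes <- table(cl$group)
    add("## Binding groups", "",
        "| group | n genes |", "|---|---|",
        sprintf("| %s | %d |", names(sizes), as.integer(sizes)), "",
        "Heatmap: `heatmap.png`; ordered matrix: `heatmap_matrix.tsv`.", "")
  }

  co <- read_if("stoichiometry_coefficients.tsv")
  outl <- read_if("stoichiometry_outliers.tsv")
  if (is.null(co) || is.null(outl)) {
    warning("stoichiometry output absent")
    add("## Stoichiometric decomposition", "", "_absent_", "")
  } else {
    add("## Stoichiometric decomposition", "",
        "| term | beta | se | p |", "|---|---|---|---|",
        sprintf("| %s | %.4f | %.4f | %.3g |", co$term, co$beta, co$se,
                co$p), "",
        sprintf("Top %d transcripts by |jackknife residual|:", top_n), "",
        "| gene | jackknife residual | fitted | flagged |",
        "|---|---|---|---|",
        sprintf("| %s | %.2f | %.2f | %s |",
                utils::head(outl$gene_id, top_n),
                utils::head(outl$jackknife_residual, top_n),
                utils::head(outl$fitted, top_n),
                utils::head(outl$outlier, top_n)), "")
  }

  ss <- read_if("set_stats.tsv")
  if (is.null(ss)) {
    add("## Gene-set statistics", "", "_absent_", "")
  } else {
    top <- ss[order(ss$fdr_over), ]
    top <- utils::head(top[!duplicated(top$group), ], 8)
    add("## Gene-set statistics (top over-represented term per group)", "",
        "| group | term | overlap | expected | FDR (over) |",
        "|---|---|---|---|---|",
        sprintf("| %s | %s | %d | %.1f | %.3g |", top$group, top$term_id,
                top$overlap, top$expected, top$fdr_over), "")
  }

  path <- file.path(results_dir, "report.md")
  writeLines(out, path)
  invisible(path)
}
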