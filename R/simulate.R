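## Synthetic paired RIP-seq data with known truth: planted co-binding
## groups, a planted linear stoichiometric relation for one hub bait, and
## planted autoregulatory outlier transcripts.

#' Build a simulation configuration
#'
#' Defaults mirror the design of a six-bait yeast closed-loop RIP-seq
#' panel: six bait proteins, three biological replicates of paired IP and
#' Total libraries, thousands of genes and library depths of millions of
#' reads. Counts are negative binomial with variance `mu + phi * mu^2`.
#'
#' Four co-binding groups are planted on top of a background of unenriched
#' genes; sign patterns over the baits follow the classic closed-loop
#' archetypes (see [group_archetypes()]). The hub bait's enrichment profile
#' is generated as a linear combination of its partner baits' profiles
#' (coefficients `beta_true`) plus Gaussian noise, and `n_outliers` genes
#' additionally receive a `outlier_shift` log2 deviation from that linear
#' relation, emulating autoregulatory transcripts.
#'
#' @param n_genes Number of genes.
#' @param proteins Ordered bait names.
#' @param hub The hub bait whose profile obeys the planted linear relation.
#' @param partners Baits whose profiles the hub profile combines; order
#'   matches `beta_true`.
#' @param polyA_binder The poly(A)-binding bait (group I leaves it at 0).
#' @param repressors The two repressor baits.
#' @param n_replicates Biological replicates per bait.
#' @param mean_library_size Mean reads per library.
#' @param library_size_cv Coefficient of variation of library sizes
#'   (log-normal).
#' @param dispersion Negative-binomial dispersion phi.
#' @param group_proportions Named fractions for groups I-IV; the remainder
#'   is unenriched background.
#' @param effect_size Magnitude of planted |log2 enrichment|.
#' @param effect_jitter Relative jitter of effect magnitudes (uniform
#'   +/- this fraction), giving clusters realistic within-group spread.
#' @param beta_true Coefficients of the hub linear relation, one per
#'   partner.
#' @param hub_noise_sd Gaussian noise sd around the hub linear relation
#'   (log2 units).
#' @param hub_signal_fraction If non-`NULL`, overrides `hub_noise_sd` so
#'   that the planted relation explains this fraction of the hub profile's
#'   variance (the generative R-squared).
#' @param n_outliers Number of planted autoregulatory outlier genes.
#' @param outlier_shift Log2 deviation added to outlier genes' hub
#'   enrichment (applied exactly, without extra noise).
#' @param renormalize_ip Rescale expected IP proportions to sum to one.
#'   This deliberately induces the composition ("real estate") bias that
#'   un-normalized counts-per-million fold changes exhibit; disable for
#'   clean unit-level recovery checks.
#' @param replicate_effect_sd Sd (log scale) of a per-replicate-pair,
#'   per-gene effect shared by the IP and Total libraries of a pair;
#'   0 disables it.
#' @param seed Master seed; child seeds for each random stream are derived
#'   deterministically and recorded in the truth object.
#' @return A list of class `rip_sim_config`.
#' @export
sim_config <- function(n_genes = 6000,
                       proteins = c("eIF4E", "eIF4G1", "eIF4G2",
                                    "Pab1", "Caf20", "Eap1"),
                       hub = "eIF4E",
                       partners = c("eIF4G1", "eIF4G2", "Caf20", "Eap1"),
                       polyA_binder = "Pab1",
                       repressors = c("Caf20", "Eap1"),
                       n_replicates = 3,
                       mean_library_size = 5e6,
                       library_size_cv = 0.5,
                       dispersion = 0.1,
                       group_proportions = c(I = 0.10, II = 0.07,
                                             III = 0.10, IV = 0.18),
                       effect_size = 1.5,
                       effect_jitter = 0.25,
                       beta_true = c(1.0, 0.4, 0.2, -0.1),
                       hub_noise_sd = 0.3,
                       hub_signal_fraction = NULL,
                       n_outliers = 2,
                       outlier_shift = 3,
                       renormalize_ip = TRUE,
                       replicate_effect_sd = 0,
                       seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes), proteins = proteins, hub = hub,
              partners = partners, polyA_binder = polyA_binder,
              repressors = repressors, n_replicates = as.integer(n_replicates),
              mean_library_size = mean_library_size,
              library_size_cv = library_size_cv, dispersion = dispersion,
              group_proportions = group_proportions,
              effect_size = effect_size, effect_jitter = effect_jitter,
              beta_true = beta_true, hub_noise_sd = hub_noise_sd,
              hub_signal_fraction = hub_signal_fraction,
              n_outliers = as.integer(n_outliers),
              outlier_shift = outlier_shift,
              renormalize_ip = isTRUE(renormalize_ip),
              replicate_effect_sd = replicate_effect_sd,
              seed = as.integer(seed))
  class(cfg) <- "rip_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_genes < 10L) stop("config error: n_genes too small", call. = FALSE)
  if (anyDuplicated(cfg$proteins)) {
    stop("config error: duplicate bait names", call. = FALSE)
  }
  if (!cfg$hub %in% cfg$proteins) {
    stop("config error: hub must be one of the baits", call. = FALSE)
  }
  if (!all(cfg$partners %in% cfg$proteins) || cfg$hub %in% cfg$partners) {
    stop("config error: partners must be baits distinct from the hub",
         call. = FALSE)
  }
  if (length(cfg$beta_true) != length(cfg$partners)) {
    stop("config error: beta_true must have one coefficient per partner",
         call. = FALSE)
  }
  if (cfg$n_replicates < 2L) {
    stop("config error: need >= 2 replicates", call. = FALSE)
  }
  if (cfg$mean_library_size <= 0) {
    stop("config error: mean_library_size must be positive", call. = FALSE)
  }
  if (cfg$dispersion < 0) stop("config error: dispersion < 0", call. = FALSE)
  gp <- cfg$group_proportions
  if (any(gp < 0) || any(gp > 1) || sum(gp) > 1) {
    stop("config error: group proportions must lie in [0,1] and sum to <= 1",
         call. = FALSE)
  }
  if (cfg$effect_size < 0) stop("config error: effect_size < 0", call. = FALSE)
  if (cfg$n_outliers >= cfg$n_genes) {
    stop("config error: n_outliers must be < n_genes", call. = FALSE)
  }
  cfg
}

#' Planted group sign archetypes over the baits
#'
#' Group I: under-represented with every bait except the poly(A) binder
#' (0 there). Group II: enriched with the two repressors only. Group III:
#' enriched with the closed-loop baits, under-represented with the
#' repressors. Group IV: enriched with every bait. Background: 0
#' everywhere.
#'
#' @param proteins Bait names.
#' @param polyA_binder,repressors Role assignments among `proteins`.
#' @return A 5 x length(proteins) sign matrix with rows I, II, III, IV,
#'   background.
#' @export
group_archetypes <- function(proteins, polyA_binder, repressors) {
  arch <- matrix(0, nrow = 5, ncol = length(proteins),
                 dimnames = list(c("I", "II", "III", "IV", "background"),
                                 proteins))
  arch["I", ] <- -1
  arch["I", polyA_binder] <- 0
  arch["II", repressors] <- 1
  arch["III", ] <- 1
  arch["III", repressors] <- -1
  arch["IV", ] <- 1
  arch
}

#' Generate a synthetic paired RIP-seq dataset with known truth
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `counts` (validated count matrix), `sheet`
#'   (sample sheet), and `truth` (class `rip_truth`: per-gene group labels,
#'   true log2 enrichments per bait, outlier flags, `beta_true`,
#'   `dispersion`, seeds and a config echo).
#' @export
simulate_rip_dataset <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  child <- sample.int(.Machine$integer.max - 1L, 4L)
  names(child) <- c("truth", "counts", "covariates", "gene_sets")

  n <- cfg$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))
  proteins <- cfg$proteins

  ## ---- truth stream: abundances, groups, enrichments ----
  set.seed(child[["truth"]])
  abundance <- stats::rlnorm(n, meanlog = 0, sdlog = 1.2)
  abundance <- abundance / sum(abundance)

  gp <- cfg$group_proportions
  labels <- sample(c(names(gp), "background"), n, replace = TRUE,
                   prob = c(gp, 1 - sum(gp)))
  arch <- group_archetypes(proteins, cfg$polyA_binder, cfg$repressors)

  e <- matrix(0, nrow = n, ncol = length(proteins),
              dimnames = list(gene_ids, proteins))
  jit <- matrix(stats::runif(n * length(proteins),
                             1 - cfg$effect_jitter, 1 + cfg$effect_jitter),
                nrow = n)
  for (g in rownames(arch)) {
    idx <- which(labels == g)
    if (length(idx) == 0L) next
    e[idx, ] <- rep(arch[g, ], each = length(idx)) * cfg$effect_size *
      jit[idx, ]
  }

  ## hub profile = linear combination of partner profiles + noise;
  ## outliers deviate from the relation by exactly outlier_shift
  lin <- as.vector(e[, cfg$partners, drop = FALSE] %*% cfg$beta_true)
  noise_sd <- cfg$hub_noise_sd
  if (!is.null(cfg$hub_signal_fraction)) {
    f <- cfg$hub_signal_fraction
    stopifnot(f > 0, f <= 1)
    noise_sd <- stats::sd(lin) * sqrt((1 - f) / f)
  }
  is_outlier <- rep(FALSE, n)
  if (cfg$n_outliers > 0L) {
    is_outlier[sample.int(n, cfg$n_outliers)] <- TRUE
  }
  e_hub <- lin + stats::rnorm(n, 0, noise_sd)
  e_hub[is_outlier] <- lin[is_outlier] + cfg$outlier_shift
  e[, cfg$hub] <- e_hub

  ## ---- count stream ----
  set.seed(child[["counts"]])
  sample_ids <- character(0)
  meta <- list()
  counts_cols <- list()
  sdlog_lib <- sqrt(log(1 + cfg$library_size_cv^2))
  phi <- cfg$dispersion
  draw <- function(mu) {
    if (phi > 0) stats::rnbinom(length(mu), mu = mu, size = 1 / phi)
    else stats::rpois(length(mu), mu)
  }
  for (pr in proteins) {
    ip_prop <- abundance * 2^e[, pr]
    if (cfg$renormalize_ip) ip_prop <- ip_prop / sum(ip_prop)
    for (r in seq_len(cfg$n_replicates)) {
      pair_eff <- if (cfg$replicate_effect_sd > 0) {
        exp(stats::rnorm(n, 0, cfg$replicate_effect_sd))
      } else 1
      for (fr in c("IP", "Total")) {
        L <- stats::rlnorm(1, log(cfg$mean_library_size) - sdlog_lib^2 / 2,
                           sdlog_lib)
        mu <- L * pair_eff * (if (fr == "IP") ip_prop else abundance)
        sid <- sprintf("%s_r%d_%s", pr, r, fr)
        sample_ids <- c(sample_ids, sid)
        counts_cols[[sid]] <- draw(mu)
        meta[[sid]] <- data.frame(sample_id = sid, protein = pr,
                                  replicate = r, fraction = fr,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  counts <- do.call(cbind, counts_cols)
  rownames(counts) <- gene_ids
  sheet <- do.call(rbind, meta)
  rownames(sheet) <- NULL

  truth <- list(genes = data.frame(gene_id = gene_ids, group = labels,
                                   is_outlier = is_outlier,
                                   stringsAsFactors = FALSE),
                enrichment = e,
                beta_true = stats::setNames(cfg$beta_true, cfg$partners),
                hub = cfg$hub, partners = cfg$partners,
                polyA_binder = cfg$polyA_binder, repressors = cfg$repressors,
                dispersion = phi, hub_noise_sd = noise_sd,
                seed = cfg$seed, child_seeds = child,
                config = unclass(cfg))
  class(truth) <- "rip_truth"

  list(counts = validate_count_matrix(counts),
       sheet = validate_sample_sheet(sheet, counts),
       truth = truth)
}

#' Generate per-gene covariates correlated with poly(A)-binder enrichment
#'
#' Emits `ribosome_occupancy` (a fraction in (0,1)) and `polyA_length`
#' (nucleotide-scale) as monotone functions of the poly(A)-binding bait's
#' true enrichment, blended with independent Gaussian noise at the given
#' correlation strength (1 = deterministic monotone map, 0 = independent).
#'
#' @param truth A `rip_truth` object.
#' @param strength Correlation strength in [0, 1].
#' @param seed Seed; defaults to the truth's recorded covariate child seed.
#' @return A covariate data frame (`gene_id`, `ribosome_occupancy`,
#'   `polyA_length`).
#' @export
simulate_covariates <- function(truth, strength = 0.5,
                                seed = truth$child_seeds[["covariates"]]) {
  stopifnot(inherits(truth, "rip_truth"), strength >= 0, strength <= 1)
  set.seed(seed)
  ep <- truth$enrichment[, truth$polyA_binder]
  s <- if (stats::sd(ep) > 0) (ep - mean(ep)) / stats::sd(ep) else ep * 0
  n <- length(ep)
  blend <- function(noise) strength * s + sqrt(1 - strength^2) * noise
  z1 <- blend(stats::rnorm(n))
  z2 <- blend(stats::rnorm(n))
  data.frame(gene_id = truth$genes$gene_id,
             ribosome_occupancy = stats::plogis(0.8 * z1),
             polyA_length = 30 + 25 * exp(0.25 * z2),
             stringsAsFactors = FALSE)
}

#' Generate a gene-set collection with planted group/term associations
#'
#' One term per planted group is drawn with elevated odds from that group's
#' genes; the remaining terms are uniform draws, providing a null
#' background for over-representation statistics.
#'
#' @param truth A `rip_truth` object.
#' @param n_terms Total number of terms.
#' @param term_size Members per term.
#' @param planted_odds Sampling odds of in-group genes relative to others
#'   for the planted terms (1 = no association).
#' @param seed Seed; defaults to the truth's recorded gene-set child seed.
#' @return A named list of member vectors; planted terms are named
#'   `PLANTED_<group>`.
#' @export
simulate_gene_sets <- function(truth, n_terms = 40, term_size = 100,
                               planted_odds = 5,
                               seed = truth$child_seeds[["gene_sets"]]) {
  stopifnot(inherits(truth, "rip_truth"))
  n <- nrow(truth$genes)
  if (term_size > n) {
    stop("config error: term_size exceeds the number of genes", call. = FALSE)
  }
  set.seed(seed)
  ids <- truth$genes$gene_id
  groups <- c("I", "II", "III", "IV")
  sets <- list()
  for (g in groups) {
    w <- ifelse(truth$genes$group == g, planted_odds, 1)
    members <- sample(ids, term_size, prob = w)
    attr(members, "term_name") <- paste0("planted term for group ", g)
    sets[[paste0("PLANTED_", g)]] <- members
  }
  for (k in seq_len(max(0L, n_terms - length(groups)))) {
    members <- sample(ids, term_size)
    attr(members, "term_name") <- "background term"
    sets[[sprintf("NULL_%02d", k)]] <- members
  }
  sets
}

#' Write / read the truth record as JSON
#'
#' @param truth A `rip_truth` object.
#' @param path Output path.
#' @return `path` invisibly (writer); a `rip_truth` object (reader).
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "rip_truth"))
  out <- unclass(truth)
  out$enrichment <- as.data.frame(out$enrichment)
  ## named vectors serialize as bare arrays; force name-keyed objects
  out$beta_true <- as.list(out$beta_true)
  out$child_seeds <- as.list(out$child_seeds)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$genes <- as.data.frame(raw$genes, stringsAsFactors = FALSE)
  raw$enrichment <- as.matrix(raw$enrichment)
  rownames(raw$enrichment) <- raw$genes$gene_id
  raw$beta_true <- unlist(raw$beta_true)
  raw$child_seeds <- unlist(raw$child_seeds)
  class(raw) <- "rip_truth"
  raw
}
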