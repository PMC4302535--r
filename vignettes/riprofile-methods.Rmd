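---
title: "Comparative RIP-seq profiling with riprofile: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative RIP-seq profiling with riprofile: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riprofile)
```

# The problem

RNA immunoprecipitation sequencing (RIP-seq) quantifies the transcripts
that co-purify with a tagged RNA-binding protein (the *bait*) relative to
a matched total-RNA library. When a panel of baits is profiled — here the
archetype is the yeast closed-loop translation initiation machinery:
eIF4E, the two eIF4G isoforms, the poly(A)-binding protein, and the two
4E-BP repressors — the per-gene log2(IP/Total) *binding profiles* can be
compared across baits to reveal co-binding transcript groups, to test
whether two baits bind distinguishable transcript pools, and to ask
whether one hub protein's profile is a stoichiometric blend of its
binding partners' profiles.

`riprofile` implements this analysis chain end to end, together with a
negative-binomial simulator that plants all of the structure the chain is
supposed to recover, so every stage is validated against known truth.

# Enrichment model

For one bait, gene $g$ and replicate pair $r$, counts $y_{grf}$
($f \in \{\mathrm{IP}, \mathrm{Total}\}$) are modeled as negative
binomial with $\mathrm{Var} = \mu + \phi\mu^2$ and

$$\log \mu_{grf} = \log N_{rf} + \beta_r + \delta\,[f = \mathrm{IP}],$$

where $N_{rf}$ is the library size (column sum — counts per million is
the only scaling used, deliberately: no between-library normalization is
applied, so fold changes carry composition effects, discussed below),
$\beta_r$ is a replicate-pair block effect implementing the paired
design, and $\delta$ is the enrichment coefficient reported on the log2
scale. Each gene is fit by iteratively reweighted least squares (log
link, fixed gene-wise dispersion, convergence when the deviance change
falls below $10^{-8}$ relative, at most 50 iterations), and $\delta$ is
tested with a 1-df likelihood-ratio chi-square against the block-only
null. Genes whose IRLS fails to converge are reported with missing
p-values and counted in a log line; all-zero genes are flagged untested,
never assigned p = 0. Benjamini–Hochberg step-up FDR is computed across
tested genes.

The pairwise bait contrast fits the joint model over both baits' samples
with per-pair blocks, a common fraction effect and a fraction-by-bait
interaction; the interaction coefficient is exactly
$\delta_A - \delta_B$ and is LRT-tested the same way. Swapping the baits
negates the estimate and leaves p-values unchanged.

**Dispersion.** Per-gene dispersions come from a method-of-moments
contrast of within-condition (bait-by-fraction) variance against the
mean. Because replicate libraries differ in depth, counts are first
rescaled to the condition's mean library size and the Poisson term is
inflated by the mean rescaling factor — without this correction, depth
variation of CV 0.5 inflates the dispersion estimate by more than a
factor of two. Raw estimates (floored at zero) are shrunk toward a
pooled global estimate (or an optional mean-trended curve) with a prior
weight of 20 pseudo-degrees of freedom against the gene's own residual
degrees of freedom, so the shrunken value always lies between the raw
and prior values. With three replicate pairs, per-gene information is
weak and the global prior dominates — by design.

**Pseudocounts.** Inference never uses pseudocounts (the GLM handles
zeros natively). The descriptive `median_log2_fc` — the median over
replicates of per-replicate log2 CPM ratios — adds c = 0.5 CPM to both
numerator and denominator, as does the profile matrix used for
clustering.

**Count filter.** The selection filter keeps genes whose Total-library
count strictly exceeds 20 in *every* pertinent Total sample (the
conservative reading); a `not_all_below` rule implementing the weaker
"excluded only if below threshold in each sample" reading is available
behind a flag, since the two phrasings are not logically identical.

# Composition ("real estate") effects

Because only CPM scaling is applied, strongly enriched abundant
transcripts eat sequencing real estate in the IP library: every other
gene's measured log2(IP/Total) shifts down by
$\log_2 \sum_g a_g 2^{e_g}$ (abundance-weighted). Two consequences are
worth internalizing:

1. The shift survives even balanced planting: with equal up- and
   down-planted mass at ±1.5 log2, the compensation is imperfect
   ($2^{1.5}$ and $2^{-1.5}$ do not cancel in proportion space) and
   background genes retain a residual shift near −0.1 log2. Against
   binding-truth labels this inflates the empirical FDR of the BH-0.05
   enrichment list to about 0.10 — the rejections are *correct* about
   the measured ratios, but some of the measured signal is composition,
   not binding. Removing it would require cross-library normalization,
   which this pipeline deliberately omits.
2. The shift is otherwise a property of CPM itself. The simulator's
   `renormalize_ip` flag controls whether *expected* IP proportions are
   rescaled to sum to one; this changes expected library depth but not
   the measured enrichment of null genes, which is shifted in either
   mode. What actually bounds the shift is sign balance: planting equal
   up- and down-regulated mass keeps the compensation term near one.
   Clean recovery tests in this package therefore plant balanced signs
   rather than toggling the flag.
3. Under the planted group archetypes — which, like real closed-loop
   data, are positive-heavy — background genes acquire a genuine
   measured shift of −0.4 to −1 log2 across baits. They then pass the
   FDR < 0.01 selection *correctly* (the measurement really is
   non-null), and because the uncentered Pearson metric is
   scale-invariant, their profile direction is nearly parallel
   (cosine ≈ 0.98) to the group-I archetype. No cut of the dendrogram
   can separate them. Group recovery scored against truth labels that
   call these genes "background" therefore saturates around ARI 0.75,
   while recovery restricted to planted genes is essentially perfect.
   This is an identifiability limit of the unnormalized design itself,
   not of the implementation; we report both numbers rather than hiding
   either.

# Clustering into binding groups

Transcripts significant (FDR < 0.01) in at least one IP and passing the
count filter in all baits are clustered on their per-replicate log2
enrichment profiles with the uncentered Pearson correlation
$s(x,y) = \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}$ — cosine
similarity, no mean-centering, so constant-sign profiles are similar
regardless of level — and average linkage on $d = 1 - s$ (a simple
monotone transform; ordering is all that matters for the tree). The
agglomeration is delegated to `stats::hclust` and is asserted, in the
test suite and the acceptance script, to coincide with a brute-force
$O(n^3)$ oracle that recomputes every between-cluster average distance
at each step; exact distance ties, where tie-breaking rules could
differ, have probability zero on these continuous profiles.

The original analysis defined four binding groups manually from the
heatmap. The programmatic surrogate here cuts the tree at k = 7 (default)
and names each cluster by cosine-matching its per-bait median profile
against four sign archetypes — group I: under-represented everywhere
except the poly(A) binder; group II: repressors up; group III:
closed-loop up, repressors down; group IV: up everywhere — merging
clusters that match the same archetype and labeling poor matches
(similarity < 0.5) unassigned. The matcher is itself exercised against
cleanly planted sign patterns in the tests.

# Stoichiometric decomposition

The hub protein's profile is regressed on its partners' profiles by
ordinary least squares through a QR decomposition:
$e_{\mathrm{hub}}(g) \approx \beta_0 + \sum_f \beta_f\, e_f(g)$. An
intercept is fitted by default — the unnormalized composition shifts
make a free intercept the safer choice — and a no-intercept mode gives
the strict linear-combination form. The fit reports coefficient
standard errors and t-test p-values, $R^2$, leverages from the hat
diagonal, and *jackknife residuals* in the standard regression sense of
externally studentized residuals,
$t_i = e_i / (s_{(i)}\sqrt{1 - h_{ii}})$, with $s_{(i)}$ obtained from
the closed-form deletion identity rather than $n$ refits (the identity
is verified against literal leave-one-out refits in the tests).
Transcripts escaping the model are flagged when $|t_i|$ exceeds the
Bonferroni-corrected two-sided t quantile at level $\alpha/n$
(df = n − p − 1); the full ranking is always emitted so other cutoffs
can be applied. Perfect collinearity raises an error naming the aliased
columns; near-collinearity — expected between the two eIF4G isoforms
and between the two 4E-BPs — is surfaced via the design condition
number and pairwise predictor correlations on the fit object.

# Set and covariate statistics

Over/under-representation of a term in a transcript set uses the
hypergeometric tails $P(X \ge k)$ and $P(X \le k)$ over the analysis
universe, with BH correction within each direction; the universe
defaults to the count-filter survivors, not the whole annotation,
because the statistics are asked within the analyzed transcript space.
The Fisher cluster-versus-genome test is the two-sided exact variant of
the same machinery (its one-sided p provably equals the hypergeometric
tail, asserted in tests); cross-cluster heterogeneity uses the Pearson
chi-square on the groups × in/out table. Covariate contrasts between
transcript sets use the two-sided Wilcoxon rank-sum test — exact
enumeration when the pooled sample is ≤ 20 without ties, the
tie-corrected normal approximation with continuity correction otherwise
— and box-plot summaries pin the type-7 quartile convention with
1.5 × IQR whiskers.

# The simulator and what it does (not) emulate

`sim_config()` defaults mirror the study design: 6 baits × 3 replicate
pairs, 6000 genes, log-normal relative abundances (sdlog 1.2, spanning
the few orders of magnitude typical of a yeast transcriptome),
log-normal library sizes around 5 million reads (CV 0.5; observed depths
in such panels are highly variable), NB dispersion φ = 0.1 with a single
global value (biological replicate variability typical of tagged-strain
IPs), planted effect magnitude 1.5 log2 jittered ±25%, and group
proportions I/II/III/IV = 0.10/0.07/0.10/0.18 — about 45% of genes
differential, matching the fraction the original clustering retained.
The hub profile is generated as the β-weighted partner sum
(β = 1.0, 0.4, 0.2, −0.1) plus Gaussian noise (sd 0.3 log2, or derived
from a requested generative signal fraction), with `n_outliers = 2`
genes displaced by exactly +3 log2 — the autoregulatory-transcript
analogue. Covariates (ribosome occupancy, poly(A)-tail length) are
monotone functions of the poly(A)-binder's true enrichment blended with
noise at a configurable strength; gene sets plant one term per group at
configurable odds. One master seed drives deterministic child streams,
all recorded in the truth object.

Deliberately not emulated: read-level artifacts (mapping, positional
coverage, multi-mapping), per-gene dispersion trends (available as an
option but off by default), between-replicate correlation beyond the
paired blocks (a replicate-effect knob exists, default 0), and any
sequence features. Passing tests on this generator therefore validate
the statistical chain, not robustness to alignment-level artifacts.

# Validation scale and numerical choices

The shipped validation (tests and `scripts/acceptance.R`) runs null
calibration at 2000 genes × 3 seeds, recovery at 2000 genes × 5 seeds,
interaction nulls over 20 seeds, clustering oracle equivalence over 200
random instances, group recovery at 1500 genes × 10 seeds,
stoichiometric recovery at 3000 genes (10 seeds for β, 50 for outlier
ranking), and end-to-end runs at the 6000-gene default plus 20
term-recovery seeds at 1200 genes — sizes chosen so the whole suite
completes in ordinary desk time while keeping Monte-Carlo error well
inside the asserted bounds. Stoichiometric parameter-recovery checks
run on the generator's truth profiles, where the stated tolerances
(±0.1 on β, R² within [0.70, 0.80] at signal fraction 0.75) are
well-defined; count-level measurement error (≈0.37 log2 per profile
entry at φ = 0.1 with 3 replicates) would attenuate both by more than
those tolerances, which is precisely why the end-to-end outlier check
is scored only on rank recovery.

Other pinned numerics: IRLS convergence at relative deviance change
1e-8 (cap 50 iterations) with step-halving on deviance increase; linear
algebra through QR; BH within direction for two-sided set statistics;
deterministic output ordering for every table written to disk.

# Known limitations

- Composition effects make "background" partially unidentifiable after
  selection (see above); interpret group I's boundary with care on real
  data, exactly as one should under a no-normalization policy.
- The chi-square LRT is mildly liberal in very small samples; with three
  replicate pairs and shrunken dispersions, measured null rejection sits
  near 0.055 at nominal 0.05, inside the accepted calibration band.
- The stoichiometric β's are regression weights on observed profiles,
  not binding constants; attenuation from profile measurement error is
  not corrected (no errors-in-variables modeling).
- GO-style term statistics do not propagate the ontology graph; terms
  are tested as flat sets against a user-chosen universe.
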