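# riprofile

Comparative RIP-seq enrichment profiling, binding-group clustering and
stoichiometric decomposition of RNA-binding protein complexes.

## What it is for

RIP-seq pairs an immunoprecipitated (IP) library with a matched
total-RNA library and asks, per transcript, how strongly the transcript
co-purifies with a tagged bait protein. When several baits are profiled
— the motivating system is the yeast closed-loop translation initiation
machinery: the cap binder eIF4E, the eIF4G1/eIF4G2 scaffolds, the
poly(A)-binding protein, and the Caf20p/Eap1p repressors — comparing
the per-gene log2(IP/Total) binding profiles across baits answers three
questions:

1. **Which transcripts does each bait enrich or deplete?** Per gene, a
   paired negative-binomial GLM with a log library-size offset,
   replicate-pair block effects and an IP-fraction coefficient
   $\delta$; 1-df likelihood-ratio test, Benjamini–Hochberg FDR. Fold
   changes are log2 ratios of counts per million with no further
   normalization (so composition — "real estate" — effects are carried
   deliberately). A fraction-by-bait interaction term tests, per gene,
   whether two baits' enrichments differ.
2. **What co-binding groups exist?** Transcripts significant in at
   least one IP (FDR < 0.01) and exceeding 20 reads in every pertinent
   Total library are clustered with the uncentered Pearson (cosine)
   similarity, $s(x,y)=\sum x_iy_i/\sqrt{\sum x_i^2\sum y_i^2}$, and
   average linkage; clusters are named I–IV by matching sign-pattern
   archetypes.
3. **Is the hub's profile a blend of its partners'?** Ordinary least
   squares $e_{\mathrm{hub}} \approx \beta_0 + \sum_f \beta_f e_f$
   with coefficient inference, $R^2$, leverages and jackknife
   (externally studentized) residuals; transcripts escaping the model
   are flagged by a Bonferroni outlier test and ranked — the analysis
   that singles out autoregulatory repressor mRNAs.

Gene-set statistics (hypergeometric over/under-representation, Fisher
cluster-vs-genome, chi-square across clusters) and covariate contrasts
(Wilcoxon rank-sum, box-plot summaries) characterize the resulting
groups. A negative-binomial simulator plants all of this structure —
groups, the β relation, outliers, correlated covariates, associated
gene sets — with a machine-readable truth record.

## Worked example

```r
library(riprofile)

cfg <- sim_config(n_genes = 2000, seed = 42)   # 6 baits x 3 paired reps
ds  <- simulate_rip_dataset(cfg)

out <- pipeline_run(
  ds$counts, ds$sheet, "results_demo",
  hub = cfg$hub, partners = cfg$partners,
  polyA_binder = cfg$polyA_binder, repressors = cfg$repressors,
  gene_sets = simulate_gene_sets(ds$truth),
  covariates = simulate_covariates(ds$truth), seed = 42)

out$stoich_fit
head(out$outliers, 3)
table(out$group_names)
```

```
Stoichiometric decomposition of 'eIF4E' on 4 predictor profile(s)
  n = 1944 genes, R-squared = 0.7582, residual sd = 0.6795
  condition number of the design: 4.09
        term     beta      se       t          p
 (Intercept) -0.16487 0.01632 -10.100  2.070e-23
      eIF4G1  0.65053 0.02643  24.616 1.177e-116
      eIF4G2  0.55629 0.02611  21.303  1.180e-90
       Caf20  0.07896 0.02409   3.278  1.063e-03
        Eap1  0.06652 0.02395   2.777  5.536e-03

  gene_id jackknife_residual     fitted     leverage outlier
1  g01464           5.757845 -1.1102162 0.0044635783    TRUE
2  g00198           3.760601 -0.7072665 0.0011591636   FALSE
3  g01429          -3.146920 -0.6595943 0.0007578956   FALSE

         I         II        III         IV unassigned
       812        107        215        337          5
```

The two planted autoregulatory transcripts (check
`ds$truth$genes[ds$truth$genes$is_outlier, ]` — here g00198 and g01464)
occupy the top two ranks of the jackknife-residual table, one of them
clearing the conservative Bonferroni flag at this 2000-gene scale. The
fitted β's are regression weights on *measured* profiles: per-profile
measurement noise (≈0.4–0.7 log2 at dispersion 0.1 with three
replicates) attenuates and, between the collinear eIF4G isoforms,
blends the planted (1.0, 0.4, 0.2, −0.1); the negative intercept
absorbs the composition shift of the unnormalized fold changes. Stage
tables (`enrichment.tsv`, `clusters.tsv`,
`stoichiometry_outliers.tsv`, ...), a heatmap, the residual diagnostic
plot and a `report.md` are written under `results_demo/`.

A thin command-line wrapper with `simulate`, `run-all` and `report`
subcommands ships at `inst/cli/riprofile.R`.

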