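# nr3cseq

Integrated analysis of mineralocorticoid-receptor (MR) and
glucocorticoid-receptor (GR) genomic binding and its transcriptional
consequences in brain tissue, as an installable, testable R pipeline with a
synthetic-data generator that carries known ground truth.

## The problem

Glucocorticoid hormones act on hippocampal neurons through two receptors with
very different ligand affinities: MR (near-saturated at baseline) and GR
(recruited by the stress and circadian surges). ChIP-seq of both receptors
under a morning baseline (BLAM), 30 min after acute stress (FS30) and at the
circadian peak (BLPM) — 4 replicates per condition — combined with an
rRNA-depleted RNA-seq time course (BLAM, FS30–FS360, BLPM) lets one ask:

* which loci bind MR only, GR only, or both, reproducibly across replicates;
* which binding events are *responsive* to stress or circadian drive and
  which are *constant*;
* which sequence motifs (the glucocorticoid response element GRE, or others
  such as RFX sites) underlie each class;
* and how changes in binding relate to changes in transcription, using
  intronic (hnRNA) read counts as a direct index of transcriptional
  activity alongside exonic counts.

The package implements every analysis stage as an ordinary R function and
couples them to a generator that simulates the whole experiment — genome,
gene models, ChIP fragments, RNA fragments — with planted receptor classes,
response classes, motifs and binding–expression coupling, so each stage can
be validated against truth.

## Methods at the core

* **Peak calling** — sliding windows scored by an upper-tail Poisson test of
  the treatment fragment count against a local background rate
  λ_local = r · max(c_win, c̄_±5win, c̄_genome) estimated from input, with
  Benjamini–Hochberg (BH) control across windows and merging of adjacent
  significant windows. ENCODE narrowPeak files from an external caller can
  be substituted at any point.
* **Replicate concordance** — a locus is *selective* for a receptor when
  present in all 4 of its replicates and none of the other receptor's, and
  *overlapping* when present in all 4 of both; a Fisher's exact test (exact
  log-space hypergeometric, representable down to ~1e-300) accompanies each
  condition's Venn counts.
* **Differential binding / expression** — consensus loci (support ≥ 4 of 12
  samples) are counted by fragment midpoint; a negative-binomial log-linear
  model with offsets, Cox–Reid adjusted profile-likelihood common dispersion,
  weighted-likelihood shrinkage of per-locus dispersions and a χ²(1)
  likelihood-ratio test gives per-locus p-values, BH-adjusted per comparison
  (FS30 vs BLAM; BLPM vs BLAM). Loci significant in neither comparison are
  *constant*. The same engine drives the RNA time course per feature space
  (intronic and exonic counts, fractional 1/k overlap weighting), with the
  `>10 reads in every replicate of some group` expression filter and a
  merged maximal-stress-fold-change table.
* **Motif scanning** — JASPAR-format position weight matrices scored in bits,
  with *exact* p-values from dynamic programming over the discretized null
  score distribution (granularity 1e-3 bits); per-peak family presence and a
  GRE-present/GRE-absent composition table.
* **Integration** — genes are classed MR-only / MR-and-GR / GR-only via the
  5-kb nearest-gene rule, with per-sample exclusivity; Spearman rank
  correlation (exact permutation p for n ≤ 9, t approximation otherwise)
  relates binding fold changes to intronic expression fold changes over
  genes significant in both.

## Worked example

A small end-to-end run (60 genes on a 1.2 Mb genome; the defaults simulate
600 genes on 8 Mb):

```r
library(nr3cseq)
cfg <- simulation_config(seed = 1, n_genes = 60, chrom_length = 6e5)
sim <- simulate_experiment(cfg)
res <- run_synthetic_pipeline(sim)

res$concordance$FS30
#> ConcordanceClass [FS30]: 28 selective MR, 8 selective GR, 23 overlapping (Fisher p = 0.999)

res$diffbind$MR$response$summary
#>   n_loci n_responsive n_constant pct_responsive pct_constant
#> 1     52           39         13             75           25

res$integration$classes$summary
#>       class  n      pct n_exclusive
#> 1   MR_only 29 48.33333          24
#> 2 MR_and_GR 23 38.33333          NA
#> 3   GR_only  8 13.33333           5

res$integration$correlation_fs_mr$cor
#> Spearman rho = 0.911 (n = 22, p = 3.97e-09)

head(res$motifs$MR$composition, 4)
#>   family   pct_all pct_gre_present pct_gre_absent
#> 1    GRE 73.076923      100.000000       0.000000
#> 2    RFX 28.846154        5.263158      92.857143
#> 3     NR 15.384615       18.421053       7.142857
#> 4    EGR  7.692308       10.526316       0.000000
```

Reading the output: at FS30 the concordance classifier recovers the planted
selective-MR, selective-GR and overlapping loci; a quarter of MR loci are
constant (neither stress- nor circadian-responsive at FDR 0.05); detected
receptor-bound genes split ~48/38/13% across the MR-only / both / GR-only
classes with most MR-only genes exclusive in every individual sample; the
fold-change in MR binding after stress correlates strongly (ρ ≈ 0.9) with
the fold-change in intronic RNA; and GRE-absent MR peaks are dominated by
RFX motifs while GRE-present peaks are not.

`run_pipeline(pipeline_config(seed = 1), "out_dir")` performs the same run
at default scale and writes consensus/occupancy TSVs, differential-binding
tables, motif composition tables, DE results, gene classes, a resolved
config and an md5 manifest. A thin command-line wrapper lives at
`inst/scripts/nr3c.R` (`simulate` and `run` subcommands).

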