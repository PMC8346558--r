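---
title: "Models and methods behind nr3cseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nr3cseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

nr3cseq re-implements, as a reusable pipeline, the joint analysis of
mineralocorticoid-receptor (MR) and glucocorticoid-receptor (GR) ChIP-seq
with an intron-aware RNA-seq time course across baseline-morning (BLAM),
acute-stress (FS30) and baseline-evening (BLPM) conditions. This vignette
records the statistical models, the parameters that matter, the design
choices that were genuinely open, and what the synthetic validation does and
does not establish.

## Coordinates and annotation

Internally every interval is a `GRanges` (1-based, closed), the Bioconductor
convention; BED input/output converts to and from the on-disk 0-based
half-open form, and `genomic_interval()` accepts 0-based half-open
coordinates for interoperability with BED-style thinking. We deliberately
did not carry a private 0-based representation through the package: interval
arithmetic is delegated to IRanges, and a second convention alongside it
would reintroduce exactly the off-by-one class of bugs it was meant to
avoid.

Gene models come from GTF exon records (`gene_id`, `transcript_id`). Introns
are derived per transcript as the transcript span minus the union of *all*
exons of the parent gene, so an exon of one isoform punches a hole in
another isoform's intron; per-gene intron sets are the reduced union of
these. Promoters are TSS ± 3000 bp — a common annotation-tool default; the
window is a parameter (`promoter_upstream`/`promoter_downstream`) because
published analyses rarely state theirs. Peaks are annotated to the nearest
gene within 5000 bp edge-to-edge (gap = bases strictly between peak and gene
span), ties broken by smaller distance then lexicographic gene id. Feature
classification uses the peak midpoint under the priority promoter > 5'UTR >
3'UTR > exon > intron > downstream > distal intergenic, so every peak gets
exactly one class and percentages sum to 100.

## Peak calling

The caller is a transparent window-based stand-in for a fragment-model
caller. The genome is tiled into `window_size` (default 200 bp) windows;
fragment midpoints are counted; the treatment count in each window is tested
against Poisson(λ_local) with

λ_local = r · max( c_input,win , mean c_input over ±5 windows , genome-wide input rate ),

r the treatment/input depth ratio. Window p-values are BH-corrected
genome-wide; windows with FDR ≤ 0.05 merge with adjacent significant
windows into peaks carrying summed counts and minimum p/FDR. With zero
input depth the genome-wide treatment rate is used (with a warning).
`read_narrowpeak()` accepts externally produced ENCODE narrowPeak files so a
full-model caller's output can be substituted anywhere peaks are consumed.

## Concordance and the consensus set

Within one condition, the locus universe is the merged union of both
receptors' peaks over the 8 samples. A locus is *selective* for a receptor
when present (≥ 1 bp overlap) in all 4 of its replicates and in none of the
other receptor's, *overlapping* when present in all 4 of both, otherwise
unclassified. The accompanying Fisher's exact test (upper tail) crosses
full-concordance MR-membership with GR-membership over this universe. Note
that this universe is dominated by concordant loci, so the test has little
room to detect enrichment when nearly every locus is fully bound by at
least one receptor; the universe definition is recorded as configurable
behaviour of the report rather than a scientific claim.

The consensus set per receptor merges all peaks from its 12 samples and
keeps loci supported by at least `min_support = 4` samples.

## The negative-binomial engine

One NB engine serves binding and expression. For a comparison of groups A
and B over loci g with per-sample offsets s_j (library size × normalization
factor):

* counts y_gj ~ NB(mean μ_gj = s_j m_g(group), dispersion φ_g);
* group means are fitted by Newton iterations on log m (score
  Σ(y−μ)/(1+φμ), information Σ μ/(1+φμ));
* a common dispersion maximizes the Cox–Reid adjusted profile likelihood
  (ll − ½ log Information summed over groups) across loci. The adjustment
  matters: the unadjusted profile MLE is biased low at n = 4 + 4 (it ignores
  the two fitted means), which inflates the type-I error of the LRT;
* per-locus dispersions maximize ll_g(φ) + w · mean_g ll(φ) on a 33-point
  grid spanning ±8 doublings around the common value, `shrink_weight`
  w = 10 by default — larger w pulls every locus to the common value;
* the group effect is a likelihood-ratio χ²(1) test; p-values are
  BH-adjusted within each comparison; log2 fold changes come from the
  fitted means scaled to the mean offset, with pseudo-count 0.5, unshrunken;
* non-converged loci are flagged with p = 1, never dropped; all-zero loci
  are retained.

In the φ → 0 limit the test reproduces the Poisson GLM likelihood-ratio test
(checked exactly in the suite) and tracks the exact conditional binomial
test.

**Normalization.** For ChIP counts on consensus loci the pipeline uses
*background* (non-consensus) fragment totals as offsets. The two textbook
alternatives both fail under this design: in-peak TMM assumes most loci do
not change, but roughly three-quarters of loci truly respond to stress and
circadian drive; and the full library is itself shifted by the genuine
global gain in peak signal. Fragments outside the consensus loci estimate
sequencing depth unconfounded by binding. `tmm_factors()` (trim 30% of
M-values, 5% of A-values, precision-weighted mean, factors scaled to
geometric mean 1) is implemented, tested against an independent NB package,
and appropriate for the RNA tables, where the non-changing majority
assumption holds.

**Response taxonomy.** A locus significant (FDR ≤ 0.05) only in FS30 vs
BLAM is STRESS, only in BLPM vs BLAM is CIRC, in both STRESS_and_CIRC, in
neither NON_RES (*constant*). A coherence note: BH at FDR 0.05 tolerates
~5% false discoveries *per comparison*; with a large truly-responsive
majority this translates into several percent of the constant loci being
flagged across the two comparisons even when the test is perfectly
calibrated. The suite therefore scores the taxonomy by overall label
accuracy (≥ 90%) and bounds the constant-mislabel rate at the level this
arithmetic implies, not below it.

## Motif scanning

PWMs are read from JASPAR-format text (raw counts; a total pseudocount of 1
per column, spread uniformly, is applied when probabilities are formed).
Scores are log2 odds against a zero-order background estimated from the
scanned sequences themselves (configurable); N scores 0. Exact p-values come
from dynamic programming: per-column score distributions, discretized at
1e-3 bits, are convolved under the background, and scanning uses the same
discretized matrix, so scan p-values are exact for the discretized score;
a continuous score differs from its discretized counterpart by at most
L·granularity/2 bits. All windows on both strands at p ≤ 1e-4 are reported.
Composition tables report the percentage of peaks containing ≥ 1 hit per
motif family, partitioned into GRE-present and GRE-absent peaks. There is no
per-position q-value: composition is a peak-level statement, so multiplicity
is handled at the peak level. De novo motif discovery is out of scope; the
shipped library (`inst/extdata/motifs_synthetic.jaspar`) is a synthetic
construction for validation, not a copy of any motif database.

## Expression pipeline

Fragments are counted fractionally: a fragment overlapping k distinct
(gene, feature-space) units — per-gene merged exons and per-gene introns —
contributes 1/k to each, mirroring fraction-mode multi-overlap counting.
Counting is unstranded by default (the library in the motivating design is
strand-specific but the counting mode is a free choice; a stranded option is
a natural extension). The expression filter keeps a gene iff some design
group has strictly more than `min_reads = 10` in *every* replicate — "in a
group" is read as "in at least one group", the reading consistent with the
filter's purpose of guaranteeing one well-measured group. Outlier-sample
exclusion is not automated; the PCA projection (`top_variable_projection`,
log2(count+1), top 1000 by variance, row-centered) is the supporting QC
output and any exclusion is an explicit user decision.

Each group is compared with BLAM per feature space; RES genes are
significant in ≥ 1 comparison, the rest (having passed the filter) are CON.
The merged stress table keeps the maximum-magnitude log2FC across the FS
time points with its sign, time point and FDR. TPM uses the merged exon
length (exonic) or total intron length (intronic).

## Integration

Detected genes (expression filter in intronic *or* exonic space) annotated
to either receptor's consensus loci are classed MR-only / MR-and-GR /
GR-only; exclusivity additionally scans every individual sample's peaks
within 5 kb of the gene for the opposite receptor. Binding–expression
correlation takes genes significant in both the binding comparison and the
expression table (thresholds configurable), resolves multi-locus genes to
the smallest-FDR locus, and reports Spearman's ρ with per-gene direction
concordance. Pathway export writes one ranked gene list per
(receptor, comparison) at FDR mode 0.05 / 0.1 / 1.0 — multi-locus genes
keep the largest |log2FC| — plus a pairwise Jaccard report between
comparisons. Enrichment itself against curated knowledge bases is out of
scope; the package produces exactly the input tables such tools take.

## The synthetic experiment

The generator reproduces the statistical structure the analysis assumes,
with every stage deterministic given the seed:

* **Genome.** 2 chromosomes × 4 Mb of i.i.d. sequence (A/T 29%, C/G 21%),
  600 genes of 2–5 exons (150–400 bp) and introns of 1–3 kb packed with
  3.2–6 kb intergenic gaps (gaps exceed the promoter window so windows never
  reach into a neighbouring gene body). One transcript per gene; 5%
  single-exon.
* **Loci.** One binding locus per gene, in the promoter or (half the time,
  when available) deep in an intron, > 3.5 kb from the TSS. Receptor classes
  are allocated exactly at 48/39/13% MR-only / both / GR-only; per-class
  constant fractions are set so ~28% of MR loci and ~5.5% of GR loci are
  constant; responsive loci split 20/20/60 into stress-only, circadian-only
  and both.
* **ChIP signal.** Per sample, uniform background at 5 fragments per 200 bp
  window plus NB enrichment (~60 fragments at baseline state, BCV ≈ 0.25)
  at active loci, fragments Normal(center, 80 bp), 200 bp long — fragments,
  not reads, since all counting is fragment-level. Responsive loci scale by
  2^log2FC with log2FC ~ truncated Normal(2.4, 1.6) on [0.5, 7] in the
  responding condition; circadian responses of dual responders track the
  stress response with 0.2 log2 jitter. Motif consensus strings are written
  into the genome: GRE at responsive loci, RFX only at constant MR-only
  loci (a switch can break this association for negative controls).
* **RNA.** 7 groups × 5 replicates. Intronic baselines are log-normal
  (median ~120 fragments); exonic 1.3×. Stress responses follow a time
  profile peaking at FS30 for intronic counts and later and ~6× weaker for
  exonic counts, encoding the hnRNA rationale that intronic signal is the
  earlier, larger, more direct index of transcription. The maximal intronic
  log2FC of stress responders is coupled to the locus's binding log2FC by a
  Gaussian copula whose latent correlation is calibrated — via normal-score
  attenuation factors computed from the configured counts, dispersions and
  replicate numbers — so the *pipeline-measured* Spearman correlation hits
  the target (0.9); an unattainable target raises an error stating the
  maximum achievable. Circadian expression responses couple to stress
  responses the same way at 0.93.

Replicate numbers (4 ChIP, 5 RNA), the consensus support rule (4 of 12) and
the class proportions are the study conditions; depth, dispersion and
effect-size values were fixed once at levels a sequencing experiment of
this kind plausibly produces, scaled to a desk-size genome.

**What passing means — and does not.** Recovery of planted labels, fold
changes, motifs and correlations shows the pipeline's stages are correct
and calibrated on data satisfying their assumptions. Real data additionally
carry mappability artefacts, GC and fragment-size bias, copy-number
structure, isoform complexity, correlated replicates and batch effects, none
of which the generator emulates; passing here does not certify performance
under those violations.

## Numerical choices and degenerate inputs

* Two-sided Fisher sums the probabilities of tables no more probable than
  the observed one (with a 1e-7 relative tie guard); mid-p is *not* used.
  Degenerate margins return p = 1 with a warning. Log-space factorials keep
  p-values representable to ~1e-300.
* Spearman p uses the t approximation; for n ≤ 9 without ties the exact
  permutation distribution is enumerated (which also covers ρ = ±1, where
  the t statistic degenerates); tied boundary cases fall back to the 2/n!
  permutation floor.
* Dunnett many-to-one adjustment is seeded Monte Carlo over the max-|t|
  null (default 1e5 draws, ~1/√nsim tail accuracy), documented as an
  approximation to the exact multivariate-t quantile; the seed is a
  required argument. Zero within-group variance with unequal means returns
  p = 0 with a warning; all-identical data return F = 0, p = 1.
* Newton steps for NB means are clamped to ±3 on the log scale; convergence
  tolerance 1e-10, 50 iterations; dispersion search on [1e-6, 5] (common)
  and a ±8-doubling grid (per-locus).
* The empty-union Jaccard is defined as 1 with a warning.

## Problem sizes

The shipped validation runs the full generator at its default scale (600
genes, 8 Mb, 28 ChIP + 35 RNA samples — a few minutes on one CPU), null
error-control at 100 seeds × 2000 windows/loci, and oracle enumeration up
to 4^6 motif windows and N = 40 contingency tables; module tests use a
60-gene configuration of the same generator.

## Known limitations

Single consensus support threshold rather than per-condition calling depth;
no fragment-shift model or summit refinement in the caller; unshrunken fold
changes (no empirical-Bayes shrinkage of log2FC); no isoform-level
expression; the stranded counting option and a real-data loader for
arbitrary design tables are thin compared to the simulated path; Fisher's
concordance test inherits the universe limitation described above.
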