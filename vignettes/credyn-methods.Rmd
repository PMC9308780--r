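---
title: "Methods: models, parameters and design choices in credyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in credyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`credyn` packages the computational analyses used to characterise how a
pioneer transcription factor (GATA6) redistributes its partner factors
(NANOG, SOX2) and remodels cis-regulatory elements (CREs) while embryonic
stem cells transdifferentiate from an epiblast-like (Epi) state to
primitive endoderm (PrE). The pipeline consumes peak calls, binned signal
tracks, count tables, genome sequence, PWMs, viewpoint profiles and contact
matrices — all as plain text — and is exercised end to end on a synthetic
data generator with planted ground truth, so every stage is testable
without sequencing data.

# The statistical engine

## Size factors and the NB Wald test

Counts are normalized with median-of-ratios size factors
(`size_factors_median_of_ratios()`): \(s_j = \mathrm{median}_f\,
k_{fj}/(\prod_{j'} k_{fj'})^{1/m}\) over features with all-positive counts.
This estimator assumes a majority of features are unchanged between
conditions; the synthetic transcriptome deliberately satisfies this (see
below).

`nb_wald_test()` is an unshrunk negative-binomial Wald test:

* log2 fold change of normalized condition means with pseudocount 0.5
  (finite at zero counts);
* dispersion \(\alpha\) by method of moments from within-condition
  variances, **moderated across features**: the per-feature estimate at 2
  residual degrees of freedom is hopeless on its own, so one common value
  — the *mean* of per-feature estimates — is shared by all features.  The
  mean rather than the median is deliberate: the moment estimator is
  median-biased low (roughly chi-square with 2 df), and a low common
  dispersion inflates the Wald tails.  Negative per-feature estimates
  enter the mean unfloored for the same reason, and the pooled value is
  floored at `1e-8` only at the end, so the Poisson limit is reached
  cleanly.  `dispersion_method = "per_feature"` exposes the raw estimator;
  a `dispersion` argument accepts externally derived values.
* delta-method standard error and a two-sided normal p-value; BH-FDR over
  features with any counts (all-zero features report `p = 1` and are
  excluded from the BH universe).

Calibration is verified by simulation: on null NB data (2 vs 2, dispersion
0.1) the fraction of `p < 0.05` measures ≈ 0.056, and BH at 0.1 controls
the false-discovery proportion. This engine backs the ATAC 48 h vs 0 h
classification (`padj < 1e-4`, `|log2fc| >= 2`), the RNA comparisons
(`FDR < 0.1`, `|log2fc| >= 2`) and the Capture-C window tests.

What the test does *not* do: DESeq2's dispersion-trend and MAP shrinkage,
LFC shrinkage, independent filtering and outlier handling. With a single
shared dispersion, per-feature dispersion heterogeneity within one table is
not modelled; the synthetic worlds are homogeneous by construction, and on
real data the per-feature escape hatch exists.

## Classification thresholds

`classify_features()` applies `up` / `down` / `stable` with `>=` on the
fold change and strict `<` on the adjusted p — mirroring the published
wording in each place. All thresholds are arguments, surfaced again in
`run_config()`.

# Peak taxonomies

`top_n_by_q()` ranks peaks by MACS-style q-value (ties: score descending,
then position) with defaults N = 10,000 for GATA6 and 15,000 for NANOG.
`classify_gata6_peaks()` merges the per-timepoint ranked sets into a union
universe (1 bp overlap, `GenomicRanges::reduce`) and labels each universe
peak *early* (present at 2–8 h), *late* (only at 48 h), and splits early
peaks by overlap with ATAC peaks at 0 h into *early-open* and
*early-closed*. Cross-timepoint identity by overlap rather than exact
coordinates tolerates the small coordinate jitter real peak callers
produce; the generator plants that jitter (±30 bp) to exercise it.
`classify_nanog_2h()` assigns each NANOG 2 h peak to cluster 1
(pre-existing: overlaps a 0 h NANOG peak), cluster 2 (de novo over open
chromatin) or cluster 3 (de novo at closed sites), in that priority order.

# Redistribution score

For peaks with cluster labels, `redistribution_score()` summarises the
eviction-and-redirection phenomenon as a per-cluster median log-ratio
\(R = \mathrm{median}_p \log_2\frac{s_p(t_1)+1}{s_p(t_0)+1}\) with
`detected = (R_{c1} <= -delta) & (R_{c3} >= +delta)`. The median resists
the heavy-tailed per-peak signal distributions; the pseudocount keeps
closed sites finite; `delta = 0.5` (≈1.4-fold) is an explicit
operationalization of an effect the original work reported qualitatively
— it is a knob, not a claim. The score is scale-dependent at tiny signal
(pseudocount dominates), so tracks are assumed pre-normalized; the module
never renormalizes silently.

# Motif scanning

`scan_motifs()` is a FIMO-style scanner. Log-odds scores
\(\sum_i \log_2\frac{W_{b_i,i}+\varepsilon}{q_{b_i}}\) are integer-scaled
at 1e-3 resolution; the exact null distribution of the integer score under
the 0-order background is computed by dynamic programming over positions
(`score_distribution()`), so p-values are exact and testable by brute-force
enumeration of all \(4^k\) words for widths ≤ 8. Both strands are scanned,
windows containing N are skipped, and BH q-values use the number of
scanned windows (FIMO's multiple-testing universe), not the number of
hits. The background defaults to the composition of the scanned sequences
with a uniform fallback; the pseudocount spreads 0.25 over a position
(0.0625 per base). Motif *density* is the count of hits fully contained in
a peak (both strands); motif *strength* is the hit q-value, compared
between peak classes with a two-sided Mann-Whitney test.

# Transgene quantification

The dox-inducible transgene carries only the CDS, so CDS reads mix
transgene and endogenous transcripts while 3'UTR reads are endogenous
only. `transgene_ratio()` normalizes both segment counts per million reads
and per kb, sets \(T = \mathrm{CDS} - \mathrm{UTR}\) per sample, takes
\(E\) as the mean UTR value over designated reference samples, and reports
\(T/E\). Negative \(T\) (possible under noise, impossible biologically) is
reported with a warning flag, not clamped.

# Staging bulk samples on single-cell clusters

`stage_bulk_on_sc()` projects bulk timepoints onto blastocyst single-cell
clusters: single cells are CPM-normalized and log1p-transformed, then
averaged within (optionally merged) clusters; bulk counts are
median-of-ratios normalized and **log1p**-transformed; each gene is
regressed on the platform indicator (equivalently group-centred), and PCA
of the residuals places both platforms in one space. Each bulk sample maps
to the nearest cluster centroid in the first two PCs (Euclidean).

One deviation from the obvious construction deserves a note: using
different log bases on the two platforms (e.g. log2 for bulk, natural log
for cells) multiplies one platform's trajectory by \(1/\ln 2 = 1.44\)
relative to the other. Per-gene group-centring removes *offsets*, not
*slopes*, so the stretch survives the residual step and systematically
pushes interior clusters onto nearest-centroid decision boundaries. Both
platforms therefore use the natural-log transform. PCA uses all shared
genes, centred but not scaled; nearest-centroid (not kNN) keeps the
mapping deterministic and mirrors reading proximity off a PCA plot.

# Capture-C and Hi-C

`window_differential()` slides 5 kb windows by 500 bp across a viewpoint
profile binned at 1 kb, sums bin signal per window, and tests windows with
the NB engine at `padj < 0.01`, merging significant windows into maximal
runs. The NB dispersion is estimated at the *bin* level and propagated to
window sums (\(\alpha_w = \alpha_{bin} \sum\mu_b^2/(\sum\mu_b)^2\)):
overlapping windows share bins, so estimating dispersion from the windows
themselves has few effective degrees of freedom and was measurably
anti-conservative in one of twenty null simulations.

`compartment_eigen()` computes the standard A/B pipeline: coverage
normalization, observed/expected by distance-diagonal means, Pearson
correlation matrix, leading eigenvector. The eigenvector comes from power
iteration (tolerance 1e-10) with two deterministic starts — all-ones and
the first basis vector — keeping the larger Rayleigh quotient: on an
exactly balanced two-block matrix the all-ones start is orthogonal to the
leading eigenvector and converges to the runner-up. Signs orient so the
eigenvector correlates positively with a reference activity score
(H3K27ac-like); positive = A. `compartment_switches()` correlates each
bin's correlation-matrix row between conditions and calls a switch at
`r < 0.4` (strict), with direction from the eigenvector signs. Whether the
original HOMER script correlates correlation-matrix rows or eigenvalue
tracks is not documented; row correlation is our choice and the one place
switch calls could deviate from the original. Note that exact value-level
permutation equivariance does not hold for any distance-aware
observed/expected pipeline; compartment *calls* are permutation-stable.

# The synthetic world

`simulate_multiomics()` writes a complete dataset from one root seed, with
named substreams per component so adding one assay never perturbs another.
Defaults (all in `sim_config()`):

* **Genome** — 2 chromosomes × 10 Mb of i.i.d. uniform ACGT; big enough
  for 40 compartment bins per chromosome at 250 kb, small enough for
  seconds-scale runs. Planted GATA6 motifs are copies of a synthetic
  GATA-family consensus (`AGATAAGA`) with per-base mutation rate =
  the class's `motif_strength` (Epi 0.15, PrE 0.02) and Poisson-mean
  density (`motif_density`: Epi 1, PrE 3) — sparser and weaker at Epi
  CREs, making density/strength recovery analytic.
* **CREs** — 120 Epi, 120 early PrE (split open/closed at 0 h), 60 late
  PrE, 100 background peaks of 600 bp on a 45 kb grid, each non-background
  CRE paired with a target gene whose TSS lies 2–18 kb away (so nearest-TSS
  assignment is unambiguous); decoy/housekeeping genes live in the
  CRE-free margins and outnumber lineage genes so median-of-ratios
  normalization keeps its majority-stable assumption.
* **Trajectories** — parametric logistic rise/decay per class and assay
  with amplitudes ~20–30 (signal units): Epi sites lose NANOG/SOX2 and
  accessibility, with a transient GATA6 pulse peaking at 2 h; early PrE
  sites gain GATA6 from 2 h (sustained), open after 4 h if closed, and
  acquire H3K27ac late; late PrE sites bind GATA6 only around 48 h. The
  NANOG gained at GATA6-opened sites at 2 h is coupled to an equal-timed
  eviction factor at Epi sites — redistribution moves signal, it does not
  create it — and both scale with `nanog_relocation` (0 disables the
  phenomenon entirely, the negative control). Planted mean tracks are
  deterministic (they model replicate-pooled normalized coverage);
  stochastic NB noise lives in the count tables. The 2 h NANOG peak count
  is 2 × the 0 h count by construction (120 Epi + 120 early-PrE sites).
* **Counts** — NB with dispersion 0.05 and depth 200 at full signal,
  two replicates per timepoint.
* **Staging panel** — 600 genes, half stage-neutral; loaded genes get
  2-D Gaussian loadings (sd 0.35) around a 4-cluster latent line
  (E3.5_EPI, E3.5_ICM, E3.5_PrE, E4.5_PrE), with up- and down-markers
  balanced so total marker mass is stage-independent (CPM and
  median-of-ratios then agree on the neutral genes); 50k-count cells,
  2e6-count bulk libraries.
* **Viewpoints** — three 100 kb profiles (1 kb bins, 2 conditions × 2
  replicates): a 3-fold gain over a planted 6 kb segment, a 3-fold loss,
  and a null.
* **Contacts** — two-block checkerboard matrices
  (\(\mu_{ij} = 60(1+0.6\,v_iv_j)\), Poisson noise, symmetrized) per
  condition; two bins of chromosome 1 flip compartment in the test
  condition; the orientation reference is the true compartment sign plus
  noise.
* **Transgene** — endogenous expression rises with the PrE program;
  transgene expression starts at 3 × the endogenous reference level and
  decays; segment counts are Poisson (the NB dispersion → 0 limit) at
  ~10⁴ UTR counts. At biological dispersions (≥ 0.05) a 2% recovery of
  T/E from four replicates is statistically impossible (the per-sample
  relative error alone is >10%), so the noisy acceptance check runs in
  the near-noiseless regime and the noiseless check is exact.

What the generator does **not** emulate: read-level noise and mapping
artifacts, peak-caller false positives/negatives, fragment-model biases,
spike-in normalization error, doublets or ambient RNA, distance decay in
contact matrices beyond the flat toy, and dispersion heterogeneity across
features. A green test therefore establishes that the *analysis logic*
recovers planted structure at realistic effect sizes and noise — not that
the pipeline is robust to upstream artifacts it never sees.

# Numerical choices

* Coordinates are 0-based half-open throughout; GTF-like tables convert
  on read; overlap means ≥ 1 shared bp (bedtools default).
* Fragment cuts are strict (<120, >150, >180 bp), proximal is strict
  (<5 kb), assignment is inclusive (≤50 kb) — each following the
  published wording for that rule.
* Ties: equidistant TSSs break to the lexicographically smaller gene id;
  q-value ties in ranking break by score then position; BH ties resolve by
  stable sort.
* `track_stat()` weights partial bins by bp overlap; `sum` is the integral
  in value × bp.
* Power iteration: tolerance 1e-10, max 50,000 iterations, two
  deterministic starts (see above).

# Known limitations

The NB test is unshrunk and assumes within-table dispersion homogeneity.
GREAT-style regulatory domains, IDR, VST, footprinting bias models,
matrix balancing and TAD/loop calling are out of scope. The motif module
handles 0-order backgrounds only. Distances are midpoint-to-TSS; whether
the original used peak edges is unrecorded.
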