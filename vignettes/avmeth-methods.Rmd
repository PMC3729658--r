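---
title: "Methods: differential methylation between arterial and venous endothelial cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation between arterial and venous endothelial cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avmeth)
```

## The problem

Arterial and venous endothelial cells acquire distinct expression
programs before birth, and DNA methylation is a candidate driver of that
specification. The design this package targets is a paired two-group
comparison: arterial and venous endothelial cells isolated from the same
placentas (9 pairs in the motivating study), profiled on a two-channel
Infinium-style methylation array (~450k CpG probes) in parallel with a
gene-level log2 expression matrix. The pipeline takes raw
methylated/unmethylated intensities, detection p-values, a probe
manifest and a sample sheet, and produces differentially methylated
probes (DMPs) and regions (DMRs), quadrant ("starburst") integration of
methylation and expression differences, genomic-region attributions,
clustering, and global-methylation summaries. Because the motivating
raw data are not publicly deposited, a synthetic-data generator with a
planted-truth ledger is a first-class module: every downstream stage is
testable offline against known truth.

## Measurement model and preprocessing

Per probe and sample, the methylation fraction is summarized by
$\beta = M/(U+M)$, where $M$ and $U$ are the methylated and
unmethylated channel intensities; statistics are computed on the
M-value $\log_2(M/U)$ scale, which is approximately homoscedastic where
$\beta$ is not. `compute_beta_m()` keeps the unoffset $\beta$ formula
(offset $a_\beta = 0$) and protects the M-value with $a_M = 1$
intensity unit (negligible at array scale, but finite at zero
intensity). With both offsets zero the identity
$M\text{-value} = \log_2(\beta/(1-\beta))$ holds exactly and is tested
to $10^{-12}$.

Quality control removes (i) any probe whose detection p-value exceeds
0.05 in *any* sample, and (ii) all probes on chromosomes X and Y, with
both counts logged separately. When no detection-p matrix is supplied,
`compute_detection_p()` fits a Normal distribution to the
negative-control total intensities per sample and scores each probe's
total intensity by its upper-tail probability — an Illumina-style
background model, checked against the closed form in the tests.

Published analyses of this platform normalize the two Infinium probe
chemistries with SWAN. SWAN as published is out of scope here;
`normalize_type2()` substitutes a simpler, documented map: per sample,
type-II $\beta$ values are monotonically interpolated onto the
empirical type-I $\beta$ distribution (order statistics at plotting
positions $(i-0.5)/n$). The map is the identity when the two
distributions agree, removes a planted uniform type-II shift to below
0.01, preserves rank order within type-II probes, and is flagged in the
QC log so downstream users know the substitute ran. M-values are
recomputed from normalized $\beta$ via the logit identity.

## Inference

Per-probe two-group inference uses an empirical-Bayes moderated t. With
per-probe pooled variance $s_g^2$ on $d_g$ degrees of freedom, the
hyperparameters of the scaled inverse-chi-square prior
$(d_0, s_0^2)$ are estimated by the standard moment method on
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$: solve
$\psi'(d_0/2) = \operatorname{var}(e) - \psi'(d_g/2)$ by Newton
inversion of the trigamma function (checked against brute-force
bisection), with $d_0 = \infty$ (fully pooled) when the spread of log
variances does not exceed its sampling expectation. The moderated
statistic uses $\tilde s^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0+d_g)$ on
$d_0 + d_g$ degrees of freedom; at $d_0 = 0$ it reduces exactly to the
classical equal-variance t (tested to $10^{-10}$ against `t.test`).
Benjamini–Hochberg adjustment is the step-up rule, tested for exact
equality against an independent brute-force implementation.

A probe is a DMP iff BH-adjusted $p \le 0.05$ **and**
$|\Delta\beta| \ge 0.10$, where $\Delta\beta$ is the
arterial-minus-venous difference of group mean $\beta$. Note the
dual-scale convention: the test runs on M-values, the effect size and
its threshold on $\beta$ — the field's standard reconciliation of
statistical behaviour and interpretability. Both thresholds are
inclusive; the quadrant gates below are strict and deliberately a
separate configuration entry.

The published description of the model does not mention a pairing term,
so the default is the unpaired pooled-variance model; `paired_design =
TRUE` switches to per-pair differences ($d_g = n_{pairs}-1$) and is
recommended whenever pairs exist. Whether the original fit used
$\beta$ or M values, and whether clustering used a correlation
distance, is not stated in the source description; both are exposed as
options with the defaults documented here (M-values; Euclidean,
average linkage).

DMRs are called by greedy chaining (no published algorithm exists for
the motivating analysis, so this is package-defined): within a
chromosome, consecutive same-direction DMPs chain while the inter-probe
gap is ≤ 1 kb and they continue to share a gene symbol; chains of ≥ 3
probes are emitted. Both parameters are configurable.

## Integration with expression

For each gene with an expression record, every analysable probe
receives the gene's log2 fold change (arterial − venous) and is placed
in the $\Delta\beta \times \mathrm{logFC}$ plane. Gates sit at
$\pm 0.10$ ($\Delta\beta$) and $\pm 0.5$ (logFC) and are *strict*
(points on the gate are unclassified, as gates drawn at the limits of
technical noise should be). Q1 (hypomethylated and up-regulated in
arterial) and Q3 (the same relationship in venous) are the reciprocal
quadrants suggesting methylation-driven regulation; Q2/Q4 are
concordant. The orientation of Q2 vs Q4 is fixed by this package's
definition, since the source material never defines it textually.

Region attribution is done twice, on purpose: once *exclusively*
(`assign_region()`: promoter flag > enhancer flag > TSS tags >
5'UTR/first-exon tags > gene-body tags > intergenic — a documented,
overridable precedence, since the group list implies no tie-break), and
once as *overlapping families* (`quadrant_region_table()`: all probes;
upstream-1500/5'UTR/first-exon; TSS excluding 5'UTR/first exon;
enhancer; promoter-associated; gene-body only), because the
table-of-counts view in the motivating work uses overlapping column
families while the text describes an exclusive assignment. Both views
are emitted rather than silently reconciled.

## The synthetic world

`simulate_manifest()` and `simulate_dataset()` state the world the
tests run in:

* **Baselines**: per-probe methylation baselines are a trimodal mixture
  (modes near 0.05/0.5/0.9, mixing 0.45/0.15/0.40), matching the
  bimodal-plus-intermediate shape of real array $\beta$ distributions;
  the resulting grand mean $\beta \approx 0.45$ is in the range the
  motivating tissues show.
* **Planted DMRs**: blocks — all probes of a chosen gene share one
  $\Delta\beta$ shift, applied to one group. Planted probes draw their
  baseline from $U(0.1,\, 0.9-|\Delta\beta|)$ so the shift never clips
  at $[0,1]$; without this, effect-recovery bias would be built in at
  high baselines.
* **Global offset**: added to the venous group's latent methylation for
  every probe (default −0.045, i.e. venous hypomethylated, mirroring
  the 0.434 vs 0.479 global means of the motivating comparison).
  Clipping of extreme baselines and the additive intensity background
  attenuate the *realized* group difference slightly (measured ≈
  0.037–0.040 of the planted 0.045); the ±0.01 recovery criterion
  accommodates this structural attenuation, which is documented rather
  than tuned away.
* **Noise**: observed fractions are Beta draws with concentration 50
  around the latent mean — chosen so a planted $\Delta\beta = 0.10$ is
  detectable at roughly 80% power with 9 samples per group (the
  motivating study reports no variance components; this is a synthetic
  choice, not an estimate). Intensities are log-normal totals (median
  10,000) split by the methylation fraction, plus additive log-normal
  background that is higher for type-II probes (300 vs 100), giving the
  normalization substitute a visible artifact to remove.
* **Pairing**: a per-pair random effect (sd 0.01 on $\beta$; 0.1 on
  log2 expression) is shared by both members of a pair on both
  platforms, emulating placenta-of-origin effects.
* **Expression**: gene baselines Normal(7, 1.5) with residual sd 0.25;
  reciprocal genes get the planted logFC in the arterial group with
  sign opposite their methylation direction.
* **Second platform**: `simulate_second_platform()` averages truth over
  CpG units and adds truncated Gaussian noise, emulating a
  locus-specific mass-spectrometry assay for concordance checks.

Everything is deterministic under the seed, and the truth ledger
(including the latent matrices) makes every planted effect recoverable
by brute-force group-mean differencing — a tested invariant.

What a green test does **not** establish: the generator has no dye
bias, no batch/chip structure, no spatial artifacts, no probe
cross-reactivity or SNP-under-probe effects, and independent probes
(real arrays are locally correlated beyond the planted blocks). Power
and FDR results transfer to real data only to the extent those features
do not dominate.

## Numerical choices and degenerate inputs

* Trigamma inversion: Newton iteration from $y_0 = 0.5 + 1/x$,
  asymptotic shortcuts outside $[10^{-6}, 10^{7}]$, tolerance
  $10^{-10}$ relative.
* Ties: BH handles ties stably by construction; `top_variable()`
  breaks CV ties lexicographically by probe id so output is
  deterministic.
* Zero intensities: $\beta$ is set missing and logged when
  $M+U = 0$ with $a_\beta = 0$; probes with mean $\beta = 0$ have
  undefined CV and are excluded from variability selection, logged.
* Degenerate clustering/concordance inputs (single probe, constant
  vector) are hard errors naming the cause.
* Matrix TSV output rounds to 6 significant digits; write-then-read
  round-trips are bit-identical at that precision (tested), and BED
  exports are strictly 0-based half-open against the 1-based manifest.

## Known limitations

SWAN, background (noob-style) correction and batch correction are
deliberately absent; the normalization substitute corrects only the
marginal type-II/type-I distribution difference. The DMR chainer is a
greedy heuristic without inter-probe correlation modelling
(bump-hunting is out of scope). Only two-group contrasts are
supported. The moment estimator for $(d_0, s_0^2)$ assumes a common
$d_g$ across probes, which holds for complete matrices but would need
extension under per-probe missingness.
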