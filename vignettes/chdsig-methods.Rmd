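---
title: "Methods: transcriptome signatures of heart defects in trisomy 21"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome signatures of heart defects in trisomy 21}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chdsig)
```

# The problem

About half of the individuals born with trisomy 21 have a congenital heart
defect (CHD), most often an atrioventricular septal defect (AVSD), less often
an atrial (ASD) or ventricular (VSD) septal defect. If part of this
phenotypic variability is driven by gene-dosage effects, expression profiles
of a peripheral surrogate tissue — lymphoblastoid cell lines (LCLs) — should
separate trisomic individuals by their heart status. `chdsig` implements the
complete analysis chain for that question as a reusable, tested pipeline:

1. **Expression calls** from per-probe, per-sample detection p-values.
2. **Quantile normalization** of the retained probes.
3. **Subgroup structure**: pairwise t-tests with a global common variance
   among the defect subgroups and a p-value-uniformity **merge rule**.
4. **Probe-to-gene collapse**, **ANOVA** and case-vs-`CHD-` contrasts.
5. A four-class **dosage classification** of DE genes.
6. **Positional statistics** for runs of contiguous DE genes.
7. Hypergeometric **gene-set enrichment** with GOrilla-style factors.

A synthetic-data generator with planted ground truth stands in for the
original cohort, so every stage can be tested for calibration and recovery.

# Statistical model and procedures

## Expression calls and normalization

A probe is *expressed* when its detection p-value falls below `alpha`
(default 0.01) in at least `min_arrays` samples (default 4) of **each**
analysis group. Quantile normalization then forces all samples onto one
empirical distribution: the reference is the across-sample mean of sorted
columns; tied values within a sample receive the mean of the reference over
the tied span. The transform is idempotent and rank-preserving, and is
cross-checked against `limma::normalizeQuantiles` in the test suite.

One documented deviation: the original bead-level variance-stabilizing
transform is replaced by working on the log2 scale throughout. VST needs
chip-specific bead-level variance parameters that do not exist for synthetic
data; the downstream statistics only assume approximate variance
homogeneity, which log2 intensities provide.

## Pairwise tests with a global common variance

For transcript $g$ the within-group variance is pooled across **all** groups
of the design (not just the two being compared):

$$s_g^2 = \frac{\sum_k (n_k - 1)\, s_{gk}^2}{\sum_k (n_k - 1)}, \qquad
t_g = \frac{\bar x_{gA} - \bar x_{gB}}{\sqrt{s_g^2 (1/n_A + 1/n_B)}},$$

with $df = \sum_k (n_k - 1)$. This is the natural reading of a "global
estimate of the common variance" and distinguishes the procedure from an
ordinary two-sample pooled t-test; the `variance_groups` argument restores
the two-sample behaviour when wanted. On any two-group design the one-way
ANOVA F equals $t^2$ exactly (a regression test guards this identity to
1e-10). Ratios are geometric: $2^{\bar x_A - \bar x_B}$.

No multiple-testing correction gates any decision — DE is thresholded on raw
p (0.05), matching the procedure being reproduced; a Benjamini–Hochberg
column is attached to enrichment output for information only.

## The merge rule

Whether two defect subgroups are distinguishable is decided from the
uniformity of their pairwise p-values: with $m$ tests, $D$ p-values below
$\alpha$ and $E = \mathrm{round}(m\alpha)$ expected under the global null,
the groups are merged when $D < E$. For the canonical numbers — 11,224 tests
at the 1% level — $E = 112$; an observed $D = 33$ merges, $D = 249$ does
not. The rule is deliberately a point comparison (that is how it is stated);
a one-sided binomial p-value and the empirical CDF are attached as
diagnostics, not gates. The rule is monotone: appending sub-threshold
p-values can never flip a "keep separate" into a merge.

## Dosage classification (classes IA/IB/IIA/IIB)

Each DE gene (case vs `CHD-`, p < 0.05) is classified from two effect
magnitudes compared on the $|\log_2|$ scale:

* **Class I** — the case-vs-`CHD-` effect dominates:
  $|\log_2 r_{case/CHD^-}| > |\log_2 r_{CHD^-/2N}|$; subclass **A** when
  `CHD-` differs from `2N`, **B** when they are "equal".
* **Class II** — the `CHD-`-vs-`2N` effect dominates; subclass **A** when
  the case group differs from `2N`, **B** when it is "equal".

"Equal" is configurable because the source states it two ways: p ≥ 0.05
(`pvalue`, the default, matching the machine-readable table header), a
geometric ratio within \[0.95, 1.05\] (`ratio-band`), or `both`. An exact
magnitude tie resolves conservatively to class II and is flagged. The four
classes partition the DE set by construction.

## Positional clustering

The null model for runs of contiguous DE genes places the $d$ DE genes
uniformly without replacement among the $N$ ordered **expressed** genes of a
chromosome ("expression and regulation independent of localization").
Contiguity is adjacency in the expressed-gene order: non-expressed genes are
invisible to the statistic. The test statistic is the existence of at least
one run of length ≥ k (k = 2 doublets, k = 3 triplets); the p-value is

$$p = 1 - \frac{\#\{\text{arrangements with no run} \ge k\}}{\binom{N}{d}},$$

where the numerator comes from bounded stars-and-bars inclusion–exclusion
(ones into $N-d+1$ gaps, each gap < k). This closed form is exact at any
problem size, so it is the default; brute-force subset enumeration serves as
the independent oracle for all $N \le 12$ in the tests, and a Monte-Carlo
route (with binomial standard error) is kept for cross-validation. A run
longer than k counts once (maximal-run convention). The original triplet
probability (p = 0.039 on chromosome 21) is a plausibility reference only:
its exact null conditioning is not recoverable, so it is not asserted.

## Gene-set enrichment

For a set with $B$ of $N$ background genes and $b$ of $n$ DE genes, the
enrichment factor is $(b/n)/(B/N)$ and the p-value is the hypergeometric
upper tail $P(X \ge b)$. Sets are intersected with the expressed background
before counting, so $B$ counts only expressed members. The threshold-free
mHG machinery of GOrilla is out of scope — the DE sets here are fixed, so
the plain tail suffices to reproduce the printed factors. The published
pathway-table p-values do not match a naive hypergeometric computed from
their own printed counts (the generating test is unnamed there); they are
therefore documented as unreproducible and not asserted.

# The synthetic world

The generator's defaults mirror the target cohort: groups `2N` = 12,
`CHD-` = 22, `AVSD` = 7, `ASD` = 8, `VSD` = 6; ~10,000 genes apportioned to
chromosomes by real coding-gene shares, ~1.15 probes per gene, ~10% of genes
below the detection floor (leaving an expressed universe near 9,758); a
log2(1.5) dosage effect on 30% of expressed chromosome-21 genes in **all**
trisomic groups; planted case-specific DE effects; an optional contiguous
run of DE genes; and per-class effect pairs for the dosage classification.

Values the source does not state were fixed once, a priori:

* **Noise**: per-gene SD drawn from \[0.1, 0.3\] log2 units — the usual
  replicate range for bead-array LCL data. Intensities are additive on the
  log2 scale (log-normal intensities, the standard microarray assumption).
* **Baselines**: expressed genes Uniform(6.5, 12), low-intensity genes
  Uniform(4, 5.5) on either side of a detection floor at 6.0; detection
  p-values are drawn directly — Uniform(0, 0.005) for expressed probes,
  Uniform(0.2, 1) below the floor — because only their thresholded behaviour
  matters downstream.
* **Planted DE**: 400 (AVSD) and 450 (ASD+VSD) genes with |log2 FC| in
  \[0.3, 1.0\] and random sign, about 9% of the expressed universe, the
  order of magnitude actually observed.
* **Class effect pairs** (chd-vs-2N, case-vs-chd): IA (0.4, 0.6),
  IB (0, 0.6), IIA (0.8, −0.4), IIB (0.6, −0.55), random joint sign.
  Magnitudes sit ≥ 0.2 log2 units apart (except IIB, below) so the
  magnitude comparison is not a coin flip at realistic noise.

RNG streams are phase-labelled (structure, intensities, detection) with
fixed offsets from the master seed, so generation is bit-reproducible.

What the generator does **not** emulate: batch/chip effects, probe
cross-hybridization, covariate (age, sex) structure, correlated
co-expression modules, and heavy-tailed noise. A green recovery test
therefore establishes that the statistics recover the planted structure
under idealized independent log-normal noise — not that they are robust to
real-array artifacts.

## Known limitation: class IIB is structurally boundary

A IIB gene needs $|\delta| < |c|$ (class II; $c$ = chd-vs-2N effect,
$\delta$ = case-vs-chd effect) *and* a case-vs-2N effect "equal" to zero.
Since the case-vs-2N effect is $c + \delta$ and cancellation requires
opposite signs, the magnitude gap $|c| - |\delta|$ **equals** the residual
case-vs-2N effect. The equality call (p ≥ 0.05 with probability ≥ 0.9)
bounds that residual above by ≈ 0.26σ at n = 20/group, while the magnitude
comparison (correct with probability ≥ 0.9) bounds the gap below by
≈ 0.62σ — jointly infeasible at every noise level. Planted IIB genes are
therefore recovered at only ~60%, the corresponding acceptance assertion is
left failing by design, and the empty IIB cell in the source's own AVSD row
is consistent with this being a boundary class. The other three classes
recover at ≥ 90%.

Two further honest-calibration notes. First, quantile normalization
slightly attenuates planted effects when a noticeable fraction of genes is
dysregulated, and induces a small anti-conservative bias in `CHD-`-vs-`2N`
contrasts when the dosage-carrying chromosome is over-represented in a
small simulated genome; recovery scenarios therefore use realistic
chromosome proportions. Second, a DE set thresholded at α = 0.05 carries
~5% false positives per chromosome, which places a floor on the observed
per-chromosome DE density; a single planted triplet is then provably never
significant at 0.05 with probability ≥ 0.95 (the critical run count grows
like $N^{2/3}$ while the false-positive count grows like $N$). The
cluster-power acceptance check accordingly supplies the true DE labels to
the positional module — exactly the module's stated power scenario with
$d_c/N_c$ small — and the estimated-DE route is exercised by the
calibration (type-I) checks instead.

# Numerical and design choices

* Coordinates are 0-based half-open; chromosome names use the `chr*` form.
* Probe-to-gene collapse keeps the probe with the highest mean intensity
  (common bead-array practice); DE counts are reported at probe and gene
  level, since both units appear in the reproduced tables.
* The detection filter runs before normalization (filter first, then
  normalize retained probes); the original order is unstated.
* PCA centers transcripts and fixes component signs by forcing the
  largest-magnitude loading positive, making scores deterministic.
* Zero-variance transcripts get t = 0, p = 1 with a flag when group means
  agree, and raise an error otherwise.
* `expected_null_count` uses `round()` (112 from 11,224 × 0.01).
* Exact tail probabilities come from `phyper`; the cluster closed form works
  in log-binomial space and is clamped to \[0, 1\].
* The per-stage command-line surface is collapsed into two subcommands
  (`simulate`, `run`) over one JSON/YAML config; each stage remains an
  exported, individually testable R function.

# A worked example

```{r example, eval = FALSE}
library(chdsig)
cfg <- pipeline_config(
  sim = sim_config(n_genes = 2000,
                   planted_cluster = list(chromosome = "chr21", start = 40,
                                          k = 3, contrast = "AVSD")),
  seed = 1)
run <- run_pipeline(cfg)
run$results$merge          # D vs E and the merge verdict
run$results$scans$AVSD     # per-chromosome runs and p-values
head(run$results$enrichments$AVSD)
```

The run report (`run_report.json` when `out_dir` is set) records counts at
every stage, all thresholds, and the seed; identical configs reproduce
identical reports.
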