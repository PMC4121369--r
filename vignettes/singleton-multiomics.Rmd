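---
title: "Single-subject multi-omic outlier analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-subject multi-omic outlier analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nof1omics)
```

## The analysis problem

This package characterizes a single index individual — in the motivating
case, a post-mortem 47,XXY (Klinefelter) brain discovered through a
sex-check discrepancy — against a reference cohort across methylation,
expression and genotyping arrays. With one affected sample there is no
second group to compare, so every stage reduces to outlier statistics
against the cohort's per-feature mean and spread, plus structural
evidence (heterozygosity, allele-frequency bands) that does not need a
comparison group at all.

## The singleton test and its calibration

For a feature with reference mean $\mu$ and sample SD $s$ (computed over
$n$ references with the $n-1$ denominator, index excluded), the index
value $x$ gets

$$z = \frac{x - \mu}{s}, \qquad p = 2\,\Phi(-|z|),$$

with Bonferroni correction within each comparison family; the
multiplicity $m$ counts only testable features of that family
(features with $s = 0$ are flagged untestable and excluded). The effect
is reported as $x - \mu$: a beta difference on the methylation scale, a
log2 fold change for expression.

Two facts matter for interpretation:

* **The plain normal tail is anti-conservative.** $s$ is estimated, so
  $z/\sqrt{1+1/n}$ follows a $t_{n-1}$ distribution for Gaussian
  features, not a standard normal. At Bonferroni thresholds
  ($\alpha/m \approx 5\times10^{-6}$ for $m = 10^4$) the discrepancy is
  dramatic: with $n = 45$ references the implied family-wise error rate
  is about 0.37 rather than 0.05, and about 0.93 at $n = 20$. The
  default (`tail = "normal"`) reproduces the classical pnorm-based
  screen; `tail = "t"` applies the exact prediction-interval correction
  and is the mode under which the test suite demonstrates family-wise
  error control. The test suite also *asserts* the normal tail's
  inflation, so the behavior is documented rather than hidden.
* **Methylation betas are not Gaussian.** Bounded, skewed Beta-like
  features have standardized tail probabilities that can exceed the
  normal approximation by orders of magnitude at 4–5 SD, in either
  mode. The screen is therefore a *screen*: region-level aggregation
  (below) and orthogonal evidence carry the inferential weight.

Comparison families follow the chromosome policy: autosomal features are
tested against all references, males only and females only; X-linked
features against females only and Y-linked against males only, because
hemizygous references are not a valid baseline for the other channel.
Whether the Bonferroni multiplicity should be per-family or global is
genuinely open; per-family is used (each family is reported as its own
screen), and the level `alpha` is a parameter.

Scalar phenotypes (cerebellum mass, total brain mass) use the same z
with an outlier verdict at $|z| \ge 2$ — the "more than two standard
deviations" convention; with printed statistics 111 g vs 170 ± 24 g this
gives $z = -2.46$.

## DMR calling

Adjacent-probe aggregation uses the tested-probe grid: two significant
probes are *adjacent* only if no tested-but-nonsignificant probe lies
between them, their gap is at most `max_gap` (default 500 bp) and a
region's span is at most `max_span` (default 500 bp); the published
rule — "500 bp regions of 2 or more adjacent differentially methylated
probes" — is ambiguous about whether 500 bp bounds the gap or the span,
so both are enforced and separately configurable. Maximal runs are
emitted; over-long runs are split greedily left-to-right (deterministic
tie-break), and a terminal chunk below `min_probes` is dropped. The
region statistic is Stouffer's equal-weight combination
$Z = \sum z_i / \sqrt{k}$ reported one-sided in the region's direction.
The autocorrelation-corrected variant (Stouffer–Liptak–Kechris, as in
comb-p) needs a probe-grid ACF estimate and is deliberately not
implemented; with member probes already individually significant the
combination is descriptive ranking, not primary inference. Regions
mixing effect signs are retained but flagged `sign_mixed`. Correctness
of the run/split semantics is pinned by an exhaustive brute-force
enumeration oracle on thousands of random fixtures.

CNV screening counts any 1-bp overlap (boundary touching included), with
chromosome labels normalized (`chr17` vs `17`) at the boundary. Internal
coordinates are 1-based inclusive; BED input/output converts at the
edge.

## Karyotype evidence

* **X methylation**: per-sample mean beta over the top variance decile
  of X probes, split by 2-means with centers initialized at the observed
  extremes (deterministic; a full MDS adds nothing testable to a scalar
  separation). Higher-mean cluster = female-like.
* **XIST**: same 2-means split of log2 intensity; high = inactive X
  present.
* **Y signal**: Y-present requires at least half the Y methylation
  probes detected (boundary inclusive) *and* mean Y expression within
  2 SD of the Y-high cluster. The 2-SD clause occasionally drops an
  extreme-but-real male to `indeterminate` at small cohort sizes; this
  is accepted rather than patched, since recovery stays above the 95%
  design target.
* **X heterozygosity**: het calls / non-missing calls over non-XTR X
  SNPs. XTR-homolog SNPs are excluded here because Y cross-hybridization
  makes males look heterozygous at them.
* **BAF bands**: a 50-bin histogram on [0, 1]; a band is a local
  maximum holding > 5% of mass (bin count fixed, threshold
  configurable). A bin ties with its right neighbor when a mode sits on
  a bin edge (1/2 does, at 50 bins), so the peak rule is
  "strictly greater than the left neighbor, at least the right
  neighbor", counting a two-bin plateau once. Band counting runs on the
  X/Y-homologous (XTR-like) SNP panel, where a 46,XY male reads as
  diploid (bands at 0, 1/2, 1) and a 47,XXY individual as trisomic
  (0, 1/3, 2/3, 1) — the same contrast shown in the study's
  allele-frequency plots.
* **Decision table**: female-like X without Y → 46,XX; male-like X with
  Y → 46,XY; female-like X with Y → 47,XXY provided the genotype
  channel, when present, supports two X copies (het rate > 0.02 or 4
  bands); anything else indeterminate. Genotype evidence outranks
  methylation, which outranks expression, because it is least
  tissue-confounded. The call is a pure function of the evidence.

## Repeat-element and XCI assays

LINE-1/Alu pyrosequencing records are averaged over their three CpGs;
fully methylated/unmethylated controls must fall above 90% / below 10%.
The index direction per tissue × assay uses the same $|z| \ge 2$ rule
(configurable), with the reference SD excluding the index. The original
study described its prefrontal-cortex Alu result (25.5% vs 28.1 ± 2.6%)
as a significant hypomethylated outlier, but under this explicit rule
that combination is $z = -1.0$ and is *not* called; the workflow keeps
the explicit rule rather than guessing an unstated test, and its own
output reports the discrepancy.

The XCI ratio normalizes each allele's HpaII-digested peak by its
undigested peak (allele-specific amplification correction) before taking
the share: $R_i = h_{id}/h_{iu}$, ratio $= R_1/(R_1+R_2)$, skewing
$= |ratio - 0.5| \times 100$. The un-normalized variant is available
behind `normalize = FALSE`. MspI digests act as controls at 5% of
undigested height; triplicates are averaged (arithmetic mean of each
peak) before the ratio. Homozygous repeat lengths are rejected as
uninformative. What counts as "abnormal" skewing is population-relative
and left to the user as a threshold; no normal range is hard-coded.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions: 49 individuals (one 47,XXY index recorded male) across
prefrontal cortex and cerebellum; repeat-assay means/SDs and index
shifts set to the printed cohort statistics (e.g. PFC LINE-1
73.0 ± 2.3% with the index at 67.7%); brain masses drawn per sex around
the printed means with the index fixed at the printed values; XCI
ratios targeting 7.5% and 0.4% skewing; spiked methylation regions and
expression shifts mirroring headline effects (+0.50 and +0.13 beta
regions, −0.23/−0.19 beta regions, expression shifts up to −0.83 log2,
one spiked region deliberately overlapping a copy-number-3 segment).

Modeling choices, each made once:

* Betas draw from Beta(mean·φ, (1−μ)·φ) with precision φ = 100
  (SD ≈ 0.05 at β = 0.5) — respects the [0, 1] support and array-like
  heteroscedasticity; the original work states no noise model.
* Half the X probes are island-type (male ≈ 0.08–0.20, two-X ≈
  0.42–0.58 — the XCI intermediate) and half escape-like (low in
  everyone), reflecting variable escape behavior without claiming a
  model for it.
* Expression noise is Normal with SD 0.12 log2 — the printed fold
  changes (0.08–0.2) at p < 10⁻⁶ imply per-probe SDs of roughly
  0.01–0.17, so this is the realistic post-normalization scale.
* 47,XXY heterozygous BAFs sit exactly at {1/3, 2/3} plus Gaussian
  noise (SD 0.015); no intensity-level allelic crosstalk is modeled.
  30% of X SNPs form the XTR-homolog panel.
* Bead counts are Poisson (λ = 14) + 1 with a 0.5% stratum of low-bead
  probes; detection p values fail at 10⁻⁴ per entry plus a 0.5% stratum
  of broadly failing probes — at ~100 samples the pfilter's >1% rule
  removes a probe on a single failing entry, and this rate reproduces
  the study's ~1–2% removal scale.
* Sex ratio is balanced per tissue (cohort demographics are not
  available to emulate).

What the generator does **not** emulate — and hence what passing tests
do not show about real data: raw intensity/IDAT artifacts and dye bias,
normalization and batch structure (data are emitted on the normalized
scale), linkage disequilibrium, realistic beta bimodality within a
probe across tissues, cell-composition effects, and the heavy-tailed
probe-variance distribution of real 450K arrays. Ground-truth recovery
here validates the statistics and bookkeeping, not array preprocessing.

## Problem sizes and determinism

All randomness flows from a single config seed (`withr::with_seed`), so
a fixed seed reproduces a cohort exactly and the pipeline itself draws
no random numbers. The shipped analyses use desk-scale arrays (about
1.5k methylation probes, 500 expression probes, 800 X SNPs; test
cohorts of 16–21 individuals, 100 seeded cohorts of 20 for karyotype
recovery, 200 replicates of 10 000 Gaussian features for calibration) —
sizes chosen so the full suite runs in minutes while keeping every
asymptotic property visible at the tested scale.

## Known limitations

* The normal-tail screen is anti-conservative by design fidelity (see
  above); use `tail = "t"` when calibrated error control matters.
* Region combination ignores inter-probe correlation.
* Mosaicism, 45,X / 48,XXYY and parental-origin questions are out of
  scope: anything that is not cleanly 46,XX / 46,XY / 47,XXY lands in
  `indeterminate`.
* The per-individual evidence aggregation averages a sample's tissues;
  tissue-discordant karyotypes (chimerism) would be masked.
* Array-level results of the original study (per-probe effect sizes)
  are not reproducible without its raw data; the shipped transcriptions
  cover the printed summary statistics only.
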