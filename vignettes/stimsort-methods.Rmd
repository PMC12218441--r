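---
title: "Methods: activity-based single-cell and community statistics in stimsort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity-based single-cell and community statistics in stimsort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimsort)
```

# The problem

Substrate-stimulation experiments on gut microbial communities ask which
community members become metabolically active when a substrate (here, the
prebiotic disaccharide lactulose) is added. stimsort implements the
computational layer of one such workflow: heavy-water (D~2~O) activity
labeling read out by single-cell Raman microspectroscopy, in-silico
Raman-activated cell sorting (RACS), sorted-fraction 16S community
statistics, and isolate phenotyping. Every stage is paired with a
synthetic-data generator that records ground truth, so the full pipeline is
testable on a laptop with no external data.

# Single-cell activity: the %CD score

Cells grown in D~2~O incorporate deuterium into C–H bonds; the resulting
C–D stretching vibration appears in the otherwise silent 2040–2300 cm^-1^
region of the Raman spectrum. The degree of deuterium substitution is

$$\%CD = 100 \cdot \frac{A_{CD}}{A_{CD} + A_{CH}},$$

where $A_{CD}$ and $A_{CH}$ are the band areas over 2040–2300 and
2800–3100 cm^-1^. Areas are trapezoidal integrals after subtracting a
*local linear* baseline: the straight line through the median intensity of
5 cm^-1^ shoulder regions immediately outside each window, anchored at the
shoulder midpoints. Corrected areas are clamped at zero before the ratio,
so %CD is always in [0, 100], and a spectrum with no signal in either band
scores 0.

**Why this baseline.** Published workflows delegate the integration to
interactive tools whose preprocessing is not fully specified. A local
linear baseline removes offset and tilt without a global background model,
is exactly testable (a Gaussian band of analytic area $A$ on a tilted
offset is recovered within 1%), and makes no assumption about the shape of
the fluorescence background outside the two windows. Lorentzian/Voigt band
shapes, smoothing, and cosmic-ray despiking are out of scope.

**Activity threshold.** Cells are called active when %CD strictly exceeds
`mean + 3 * SD` of control cells incubated without labeling substrate. The
sample (n−1) standard deviation is used — control cells are a sample — and
ties classify as unlabeled (conservative). On Gaussian null scores this
cutoff converges to the upper 3-sigma tail (false-positive rate
$\approx 0.00135$), which the acceptance suite verifies at $n = 10^5$.

**Group comparison.** Condition effects on per-cell %CD are tested with
fixed-effects one-way ANOVA (F from between/within mean squares), the
standard analysis for dot-plot comparisons of single-cell activity across
donors and treatments.

# The sorting gate: Pc and PL

The in-silico sorter reproduces the two indices a RACS instrument computes
from each trapped object's spectrum, both on **raw** (not
baseline-subtracted) trapezoidal integrals:

- the **cell index** $P_c = I_{1620\text{–}1670} / I^{fluid}_{1620\text{–}1670}$,
  the protein-region integral relative to the carrier fluid; it detects
  that a cell is actually captured (the window is insensitive to PDMS and
  glass signal);
- the **labeling index**
  $P_L = I_{2040\text{–}2300} / I_{1850\text{–}1900}$, the deuterium band
  over a silent reference band; it discriminates labeled from unlabeled
  cells.

A cell is collected iff $P_c >$ 1.2 **and** $P_L >$ 5.7; ties go to waste.
The PL threshold 5.7 is the deployed calibration value from unlabeled
control cells. A featureless flat spectrum has $P_L = 260/50 = 5.2$ exactly
(the window-width ratio), sitting just below 5.7 — which only makes sense
on raw integrals, and is why the gate deliberately performs no baseline
subtraction. No numeric Pc threshold is published; 1.2 is this package's
declared, configurable default, and every accuracy figure states the value
used. The deployed instrument's tie-handling (≥ vs >) is not documented;
strict > is declared here. The sorter is a pure classifier: fluidics, dwell
times and throughput are not modeled.

# Sorted-fraction community statistics

## Enrichment factor

For genus relative abundances $a$ (treatment fraction) and $b$ (reference
fraction), the enrichment factor is the symmetric bounded contrast

$$EF = \frac{a - b}{a + b} \in [-1, 1], \qquad EF(0,0) := 0 .$$

The published analyses describe their EF only as "normalized and scaled";
this formula is normalized by total abundance, scaled to [−1, 1], and
matches the bubble-plot semantics of signed enrichment (+ enriched, −
depleted). It is a declared stand-in, not a reconstruction of an
unpublished formula. Per donor, EF compares the donor's mean treatment RA
with its mean reference RA; the **cohort EF is the unweighted mean of donor
EFs**, because donors — not samples — are the replication unit (per-donor
significance vs cohort-level significance are distinct annotations in this
type of analysis).

## Permutation inference

Parametric differential-abundance machinery (negative-binomial Wald tests)
is deliberately replaced by a permutation test on the EF statistic itself:
treat/ref group labels are permuted **within donor** (donor structure is
never broken), two-sided on $|EF|$. When the number of distinct
within-donor reassignments is at most `n_perm` the null is enumerated
exhaustively; otherwise `n_perm` random reassignments are drawn and the
add-one estimator $p = (1 + \#\{|EF_{perm}| \ge |EF_{obs}|\})/(1 + n\_perm)$
avoids zero p-values. P-values are Benjamini–Hochberg adjusted across
genera.

**Permutation resolution and BH.** With $m$ genera, the smallest attainable
adjusted p is $m/(1 + n\_perm)$ for the top-ranked genus. At the
conventional `n_perm = 999` and $m = 50$ this floor is exactly 0.05 — it
can never pass a strict $p_{adj} < 0.05$ call. The package therefore
defaults to `n_perm = 1999` (floor 0.025) in the pipeline and acceptance
analyses. This is an arithmetic property of add-one permutation p-values,
worth knowing whenever BH is applied to permutation tests.

## Ordination and PERMANOVA

Bray–Curtis dissimilarity
$d(x,y) = 1 - 2\sum_i \min(x_i, y_i) / \sum_i (x_i + y_i)$ is computed on
genus relative abundances. PCoA is classical scaling: double-center
$-D^2/2$, eigendecompose, scale eigenvectors by $\sqrt{\lambda}$. Negative
eigenvalues (expected for Bray–Curtis) are dropped and reported — no
Lingoes/Cailliez correction, the simplest declared behavior — and variance
explained is taken over the positive spectrum. On Euclidean input the
recovered coordinates reproduce the distances to $10^{-8}$.

One-way PERMANOVA is implemented from the distance partition:
$SS_{total} = \sum_{i<j} d_{ij}^2 / n$, $SS_{within}$ from within-group
pairs analogously, pseudo-$F = (SS_B/(k-1))/(SS_W/(n-k))$,
$R^2 = SS_B/SS_{total}$, with label-permutation p-values (exhaustive over
all $n!$ orderings when $n \le 8$ and $n!$ fits in `n_perm`, sampled with
the add-one estimator otherwise). It agrees with vegan's `adonis2` on F and
$R^2$ to $10^{-10}$ in the test suite — the dual-route check — but is not a
wrapper around it. Whether permutations should be stratified by donor when
testing treatment is not documented for the original analysis; the
implementation permutes freely, and donor effects are assessed as their own
grouping term.

# Phenotyping

- **Growth boost**: trapezoidal area under the OD~600~ curve (blank
  subtracted, clamped at 0) in the amended medium divided by the
  no-amendment control. Whether published boosts were blank-corrected is
  not stated; blank = 0 is the default and the choice is exposed.
- **Degradation %**: $100 (c_0 - c_t)/c_0$ clamped to [0, 100], with
  concentrations from an ordinary-least-squares HPAEC calibration line
  (signal = slope·conc + intercept). $c_t > c_0$ clamps to 0 with a
  warning.
- **Coculture fold change**: $\log_2(\overline{co}/\overline{mono})$ with a
  plain (equal-variance) Student's t-test on log2 quantities, matching the
  cited test; qPCR absolute quantification is assumed already reduced to a
  common scale by a linear standard curve.

# The synthetic world

The generators state the world the tests operate in; their defaults are
fixed once and are not tuning knobs.

- **Spectra**: 400–3200 cm^-1^ at 1 cm^-1^; Gaussian C–D (σ 25, center
  2170) and C–H (σ 30, center 2950) bands on a tilted baseline (offset 10,
  slope 0.005) with i.i.d. Gaussian noise SD 0.05 against a C–H band area
  of 400 — a moderate single-cell signal-to-noise ratio at which %CD is
  recovered with RMSE well under 1 point. The C–D area is chosen as
  $A_{CD} = \%CD/(100-\%CD) \cdot A_{CH}$ so the generated truth is exactly
  the quantity the scorer estimates; %CD = 100 with a nonzero C–H band is
  rejected as infeasible. 30–40 cells per sample is the population default.
- **Sorter streams** place PL targets directly: on a flat background of
  height $o$ a C–D band of raw area $50\,o\,(t - 5.2)$ yields
  $P_L = t$; labeled cells draw $t \sim N(9, 1)$, unlabeled
  $t \sim N(5.2, 0.2)$ around the featureless value.
- **Count tables**: ~6 donors; a shared log-normal genus profile (SD 1.5)
  plus per-donor log-normal offsets (SD 1.2, calibrated so donor identity
  dominates Bray–Curtis variance, qualitatively mirroring — not
  reproducing — the donor-dominated $R^2$ such experiments report);
  responder genera multiplied by $e^{effect}$ in treatment samples; counts
  Dirichlet-multinomial (concentration 200) at exactly 20,000 reads per
  sample. Genus labels are ordered by expected baseline abundance (g01 most
  abundant), so planting a responder at a low index models a dominant
  responding taxon — the abundance regime sorted-fraction EF analyses
  actually operate in; at rare-genus abundances (< 0.1%) replicate-level
  count noise genuinely removes permutation power, and the package does not
  pretend otherwise.
- **Growth curves**: shifted logistic $K/(1+e^{-r(t - t_{mid})})$ sampled
  every 0.5 h (a 30-min plate-reader cycle) over 24 h, additive Gaussian
  noise clamped at 0; the treatment arm's capacity is `boost * K`, so the
  noiseless AUC ratio equals the planted boost exactly.

**What a green test does not establish.** The generators use Gaussian band
shapes (no Lorentzian/Voigt tails), flat fluid backgrounds, no cosmic rays
or fluorescence transients, log-normal/Dirichlet-multinomial counts with no
contamination or ASV-inference artifacts, and logistic growth with no lag
or death phase. Green tests establish that the statistics are computed
correctly and recover planted effects in this stated world — not that the
laboratory workflow is reproduced, and not any published sample-dependent
headline numbers (mean degradation percentages, isolate counts, field
PERMANOVA $R^2$), which depend on the biological material.

# Numerical choices

- Band integrals interpolate window endpoints linearly when they fall
  between grid points; raw-mode integration is exactly linear in the
  spectrum.
- Spectra on different grids are compared after linear resampling onto a
  1 cm^-1^ grid (`resample_spectrum()`); the two gate indices integrate
  each spectrum on its own grid, so no resampling enters the ratio.
- Permutation exceedance comparisons use a $10^{-12}$ slack so ties count
  as exceedances (conservative).
- PCoA retains eigenvalues above `max(|lambda|) * 1e-9`; symmetric matrices
  are symmetrized before `eigen`.
- Equal-variance within-group ANOVA F is defined as 0 (p = 1) when both
  between- and within-group variances vanish.
- The pipeline expands one global seed into per-stage sub-seeds as
  `(seed + 1000003 * stage_index) mod (2^31 - 1)`, so any stage can be
  rerun in isolation; pipeline configs are JSON (no YAML parser is part of
  the package's dependency footprint).

# Known limitations

- The EF formula is a declared choice; published EF values produced by a
  different normalization are not comparable number-for-number.
- PERMANOVA is one-way with free permutations; stratified/restricted
  permutation schemes and multi-factor designs are not implemented.
- The %CD control set is not matched per donor; the calibration accepts
  any control vector.
- No distributional information about real %CD or PL spreads is available
  beyond the printed thresholds; the synthetic defaults are declared, not
  fitted.
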