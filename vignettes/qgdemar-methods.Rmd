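---
title: "Quantile-Gaussian deconvolution for probe-level microarray analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile-Gaussian deconvolution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qgdemar)
```

## The model

Microarray differential-expression analysis at probe level faces a
contamination problem: the distribution of any per-probe discrimination
variable — say the log-ratio between a mutant and the wild type — is a
mixture of a dominant stochastic bulk and small fractions of truly
differential probes in either tail. The package's model is that the bulk is
Gaussian, $x_i \sim N(\mu, \sigma^2)$ for non-differential probes, and that
the differential probes live beyond its tails. The operational question is
how to estimate $(\mu, \sigma)$ without letting the differential tails
inflate $\hat\sigma$.

The estimator is a probit-plot (quantile–quantile) regression restricted to
a central window. Sort the $n$ finite values, attach plotting positions
$p_k = (k - 0.5)/n$, keep the order statistics with
$q_{lo} \le p_k \le q_{hi}$, and regress them by ordinary least squares on
$\Phi^{-1}(p_k)$. For Gaussian data the population relation is exactly
$x_{(k)} \approx \mu + \sigma\,\Phi^{-1}(p_k)$, so the intercept estimates
$\mu$, the slope estimates $\sigma$, and the regression $R^2$ (reported as
`fit_r2`) diagnoses how Gaussian the window really is. Because only the
central order statistics enter, moderate tail contamination moves the
estimates very little, while the whole-sample standard deviation — the
quantity a control chart would use — is inflated by the factor
$\sqrt{1 + f(\Delta^2/\sigma^2)}$ for a contaminated fraction $f$ at offset
$\Delta$. Both estimators are exposed (`detect()` vs
`control_chart_detect()`) precisely so this contrast can be measured.

Detection is per tail. Candidate thresholds are the observed values beyond
$\hat\mu$ in the requested tail; for each candidate $t$ the tail-area FDR is

$$\mathrm{FDR}\%(t) = 100 \cdot \frac{N \cdot p_{tail}(t \mid \hat\mu, \hat\sigma)}
{\#\{x_i \text{ strictly beyond } t\}},$$

the expected null count beyond $t$ over the observed count beyond $t$,
capped at 100. Scanning outward from $\hat\mu$, the least extreme candidate
with $\mathrm{FDR}\% \le$ target is selected, which maximises detections
subject to the bound; if none qualifies the tail is NDAS ("not detectable
as significant") — an explicit, reportable outcome rather than an empty
list. The denominator $N$ counts every probe with a finite value of the
variable, not only gene-annotated probes, so the estimated FDR covers the
entire probe set under test.

### Assumptions and their limits

* The bulk is adequately Gaussian inside the window. `fit_r2` should be
  close to 1; heavy-tailed bulks (e.g. strong batch structure) would bias
  $\hat\sigma$ downward inside the window and the FDR downward with it.
* Differential probes are rare (the spike fractions must leave the window
  essentially uncontaminated). With one-sided contamination at fraction
  $f$, the window quantiles are those of the mixture, which biases
  $\hat\mu$ by roughly $\sigma\,[\Phi^{-1}(p/(1-f))-\Phi^{-1}(p)]$ averaged
  over the window — about $+0.08\sigma$ at $f = 5\%$. This is visible in
  the calibration tests and is the price of a closed-form estimator.
* The estimated FDR is a tail-area (not local) quantity: it bounds the
  expected proportion of nulls among *all* probes beyond the threshold.

## Discrimination variables

All variables are built from per-condition means: replicates are averaged
first (unweighted, ignoring missing replicates), because the method
operates on one signal per condition and the design may be unbalanced
(2 vs 3 replicates) without any stated weighting. Probes missing in every
replicate of a required condition are flagged missing and excluded from
fitting, detection and $N$.

* `log_ratio(A, B)` $= \bar x_A - \bar x_B$ (log2 units): positive means
  the numerator condition up-regulated.
* `super_ratio(M, WT, c1, c2)` $= (\bar x_{M,c_1} - \bar x_{WT,c_1}) -
  (\bar x_{M,c_2} - \bar x_{WT,c_2})$: the 2×2 interaction between the
  mutation and the condition factor (e.g. growth rate). It is exactly
  antisymmetric in $(c_1, c_2)$ and exactly the difference of the two
  log-ratios; both identities are tested to floating-point tolerance.
* `condition_difference(A, B)` $= \bar x_A - \bar x_B$: kept as a distinct
  kind because its canonical use — wild type minus the ΔN-style cloning
  control — is interpreted around zero rather than around a ratio of
  conditions.
* `log2_quotient(A, B)` $= \bar x_A / \bar x_B$: the literal division of
  log2 means, the dimensionless control-chart variable centred at 1. This
  is deliberately *not* the log-ratio: the division reading is kept as its
  own kind and never silently substituted, since the two behave
  differently (the quotient's spread shrinks as intensities grow). The
  log-ratio remains the default variable for every detection path.

`concordance()` regresses one per-probe series on another (closed-form
OLS, cross-checked against `lm()` in the test suite) and reports slope,
intercept, $R^2$ and $n$ — the identity-line diagnostic used to justify
treating one mutant's profile as background for another's.

## Corrections for spurious transcription

When a gene variant cannot be cloned at its native locus, the insertion
itself dysregulates transcription (in the emulated design, the *paaH*
locus inside the *paa* operon). Two corrections are implemented:

1. **Positional-control crossing** (`build_spurious_lists()` +
   `cross_exclude()`): detection on the difference `WT − control` yields a
   false-positive list (lower tail: over-transcribed by the insertion) and
   a false-negative list (upper tail: attenuated). Crossing removes these
   from the up-/down-regulated lists respectively, with counts and removed
   fractions reported. A `mode = "qualitative"` flag excludes by the sign
   of the control effect regardless of magnitude — deliberately
   over-protective, provided for comparison only.
2. **Operon blacklist** (`operon_exclude()`): remove only the genes of the
   hosting operon (default the 11 *paa* genes, shipped as
   `inst/extdata/paa_operon.txt`), the lighter correction appropriate when
   the quantitative crossing proves excessively protective.

Matching granularity: by probe id by default; with a probe→gene map, a
flagged gene removes all of its probes (the two lists must share one
identifier space — mixing is an error, not a silent fallback).

Degenerate self-comparison: the difference of a condition with itself is
exactly constant, which the core fit correctly rejects as a degenerate
null; `build_spurious_lists()` catches that condition and returns empty
lists, which is the scientifically meaningful answer ("nothing spurious
detectable").

## The simulator as a stated world

`simulate_factorial()` generates the world the detection machinery is
calibrated against, with defaults fixed to the emulated experiment's
structure: 10,207 probes (8,662 gene-annotated), wild type plus two
mutants, batch-exponential / batch-stationary / chemostat phases with
growth-rate metadata (0.62, ~0, 0.23 h⁻¹ — carried but never computed on),
and triplicate (first series) or duplicate (second series) cultures.

The generative model: a per-probe baseline drawn once from
$N(\mu_0, \sigma_0)$ (defaults 7.5 and 1 log2 units — a typical
Affymetrix log2-intensity centre and spread) shared across all conditions;
i.i.d. Gaussian replicate noise on top (default SD 0.2 log2 units, a
typical technical-replicate scatter — the emulated study reports no
replicate variance, so this is a stated configuration value, not an
inference); spikes as additive log2 offsets in the stated cells (numerator
condition for up-spikes, denominator for down; the $(M, c_1)$ cell for
interaction spikes; every phase of the designated strains for positional
artifacts). Each spike spec draws its probe set from its own derived RNG
stream, so adding a spec never perturbs the null draw — a property the
tests assert. The truth table records every injected (probe, contrast,
direction, effect).

Because the baseline is shared, every ratio-type variable has null SD
$\sigma_{rep}\sqrt{2/r}$ (0.2 for duplicates) — so a 2-log2 spike is a
10σ effect on the variable scale, which is what clear differential
expression looks like against technical noise. What the simulator does
*not* emulate: probe-sequence cross-hybridisation, intensity-dependent
variance (the spread of real log-ratios shrinks with intensity),
saturation, and correlated probes within a gene. A green calibration test
therefore establishes correctness of the estimator on its stated model,
not robustness to those real-data features.

The positional artifact accepts a *vector* of strains sharing the same
artifact probes: in the emulated design the mutants carry the same
insertion as the ΔN control, and the correction only has something to
correct when the artifact is shared. The default remains a single
ΔN-like strain.

## Numerical choices

* Central window default $(0.25, 0.75)$: the original method's window is
  not restated in the emulated study, so the inter-quartile window was
  fixed a priori — wide enough for stable OLS, narrow enough to tolerate
  >10% total contamination.
* Thresholds sit exactly at observed values and detection is strict
  (`>` / `<`), so ties at the threshold are excluded deterministically.
* One Gaussian is fitted jointly for both tails; the two tails then get
  independent thresholds.
* At least 50 finite values are required to fit, and at least 10 order
  statistics inside the window; fewer is an `insufficient-data` error, a
  zero-spread window a `degenerate-null` error (typed conditions, so
  callers can catch them).
* Rounding of report percentages uses base R `round()` (IEEE
  half-to-even), which reproduces the printed style of the emulated
  reports (e.g. 10/160 → 6.2%); half-away-from-zero would print 6.3.
* Seeds: one integer seed determines everything; derived per-spec seeds
  are kept below $2^{31}$.

## Scaling of the validation suites

The calibration tests run at the sizes their statements specify (10,000
probes; 20–100 seeds) and complete in seconds. The correction-efficacy
suite uses 5,000 probes per seed (50 seeds) to stay well inside the test
budget; the artifact fractions (2% over-, 1% under-expressed at 1.5 log2)
mirror the asymmetric pattern of the emulated positional distortion, where
false positives dominate the exponential phase.

## Known limitations

* The tail-area FDR is an estimate under the fitted null; it inherits the
  small positive bias of $\hat\mu,\hat\sigma$ under heavy one-sided
  contamination.
* Per-tail FDR targets are not pooled across tails; a user wanting a
  global FDR should halve the target.
* No probe-to-gene summarisation is performed anywhere; gene symbols are
  annotations carried along, and gene-level set operations collapse probes
  to symbols explicitly.
* The GEO series-matrix reader is a minimal adapter for local files
  (sample metadata must be supplied externally); it does not download, and
  deposited-accession analyses are out of the package's validated surface.
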