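---
title: "Decomposing ensemble P2 receptor calcium responses to ATP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing ensemble P2 receptor calcium responses to ATP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p2ensemble)
```

## The model

A cell that expresses several P2 receptor subtypes responds to extracellular
ATP through all of them at once. `p2ensemble` treats each receptor's ATP
dependence as a fixed Hill curve

$$\theta_i(L) = \frac{L^{h_i}}{K_{1/2,i}^{h_i} + L^{h_i}},$$

with parameters taken from published single-receptor (heterologous
overexpression) studies, and models an observed ensemble dose-response
summary $f$ — for example, the per-condition mean peak amplitude of the
calcium transient — as a signed linear combination

$$f(L) = \sum_i a_i\,\theta_i(L)\;(+\,\beta).$$

The basis $\{\theta_i\}$ is fixed, so the coefficients $a_i$ are estimated
by ordinary linear least squares; their signs are deliberately
unconstrained. A negative $a_i$ is a *phenomenological* description of an
inhibitory contribution (heterologous desensitization, receptor cross-talk,
heteromer formation — the package makes no mechanistic claim). This
phenomenology is the core scientific content: a two-peak amplitude curve
over $10^{-9}$–$10^{-2}$ M ATP cannot be reproduced by any nonnegative
combination of monotone Hill curves, but is fitted well once a mid-range
receptor (P2Y4, or alternatively P2X5 or P2X2, which have similar
$K_{1/2}$) enters with negative weight.

### Assumptions

* Single-receptor Hill parameters measured in overexpression systems carry
  over to the endogenous ensemble (the catalog's central values are used;
  published uncertainties are stored alongside).
* Rat and mouse receptor characteristics are interchangeable under the
  `"rodent"` species tag; bovine P2Y12 and human P2Y13 stand in where no
  rodent data exist and are flagged `surrogate_species`.
* The ensemble response is additive in receptor activations at the level of
  the chosen summary statistic. No kinetic (time-resolved) receptor model
  is attempted.

## Hill fitting choices

`fit_hill()` minimizes ordinary (optionally $1/\mathrm{dispersion}^2$
weighted) squared residuals over $(\log_{10} K_{1/2},\,h\,[,\beta])$.
Numerical choices:

* **Log-scale $K_{1/2}$.** Concentrations span up to seven decades;
  optimizing $\log_{10} K_{1/2}$ keeps the problem well conditioned.
* **Bounds.** $K_{1/2} \in [10^{-12}, 10^{-1}]$ M, $h \in [0.1, 10]$,
  $\beta \in [-1, 2]$ — generous margins around every catalog value.
* **Initialization.** $K_{1/2,0}$ from the log-interpolated half-maximum
  crossing of the data, $h_0 = 1$, $\beta_0 = \min(y)$; two coarse
  multistarts in $\log_{10} K$ guard against local minima.
* **Optimizer.** Bounded quasi-Newton (L-BFGS-B) followed by a damped
  Gauss–Newton polish, so noiseless synthetic data are recovered to
  essentially machine precision (the self-consistency tests require
  relative error $< 10^{-6}$; the implementation achieves $\sim 10^{-15}$).
  `stats::nls` was rejected because it aborts on zero-residual problems.
* **Confidence intervals.** Linearized covariance at the optimum,
  $\sigma^2 (J^\top W J)^{-1}$, scaled by the $t$ quantile on $n - p$
  degrees of freedom; the suite checks ≥ 85 % empirical coverage at noise
  SD 0.02 (linearized CIs are approximate, especially for steep $h$).
* **Degenerate inputs.** Zero-concentration points are legal
  ($\theta(0)=0$); constant responses make $R^2$ undefined
  (SStot $= 0$) and are flagged, never silently reported as numbers.
* **Weighting.** The source analyses give no indication of weighted
  fitting, so unweighted is the default; weights sit behind a flag.

## Trace features

Raw single-cell fluo-4 fluorescence is normalized as $(F/F_0) - 1$ with
$F_0$ the mean over the 5 s preceding the stimulus (the window length is
configurable; the underlying studies state only that a baseline precedes
application). Features:

* **Amplitude** — maximum of the normalized response after the stimulus.
* **Duration** — width at half maximum: the half-max level is half of the
  trace's own peak above the zero baseline; crossings are located by linear
  interpolation between samples. A response that never returns below
  half-max gets the width to trace end and `truncated = TRUE`
  (prolonged P2X7-type responses need this fallback).
* **AUC** — trapezoidal integral from the stimulus to trace end; negative
  excursions are included. Integrating to trace end avoids an unstated
  return-to-baseline criterion.

Outlier removal is a *single* pass per (experiment, concentration) group and
metric: drop values strictly outside mean ± 2 SD of the group. One pass (not
iterated) matches the fixed 10–25 % removal fractions the emulated study
reports. Removal precedes the per-experiment normalization (each metric's
condition means divided by their within-experiment maximum), following the
order in which the source describes its processing.

## The synthetic-data generator

`generate_experiment_set()` emulates the structure of the emulated study:
8 independent experiments; vehicle plus 11 log-spaced ATP concentrations
over $10^{-9}$–$10^{-2}$ M; 11–55 cells per condition; 0.5 s sampling over
300 s; per-experiment mean baseline drawn from 23–78 FU with ~17 %
cell-to-cell variation; a log-normal per-experiment amplitude scale
(SD 0.15).

* **Trace shape** is a unit-peak double-exponential pulse (rise
  $\tau_r = 2$ s) whose decay is calibrated — via a precomputed monotone
  lookup — so the pulse FWHM matches the duration model. The shape is an
  emulation device: any unit-peak pulse with controllable FWHM would do.
* **Amplitude model** (the default "two-peak world"): the rodent
  {P2Y1, P2Y4, P2X7} ensemble with coefficients $(1.8, -1.4, 0.6)$,
  multiplied by a non-specific high-dose suppression
  $1 - 0.4\,\theta(L;\,5\times10^{-3}\,\mathrm{M},\,3)$. The suppression
  term exists because the bare ensemble rises monotonically above
  $4\times10^{-4}$ M, whereas the emulated measurements show a drop at the
  10 mM dose (attributed to non-specific effects, and the reason that dose
  is excludable by `drop_top_concentration`). With it, the noiseless curve
  has exactly two interior peaks on the default grid: $6.3\times10^{-7}$ M
  and $2\times10^{-3}$ M.
* **Duration model**: $10 + 90\,\theta(L;\,6\times10^{-4}\,\mathrm{M},\,4)$
  seconds — brief ~10 s transients switching to prolonged ~100 s responses
  above $10^{-4}$ M, the P2X7 signature.
* **Amplitude–duration coupling**: below $10^{-4}$ M each cell's FWHM is
  $d_0\,e^{-0.6\,A}$ times 15 % log-normal jitter, where $A$ is the cell's
  amplitude — the exponential law in which the pooled single-cell
  relationship is reported. An earlier latent-jitter formulation produced a
  pooled correlation that could flip positive (a Simpson effect: the
  dose-driven amplitude rise across $10^{-9}$–$10^{-7}$ M dwarfs
  within-condition jitter), so the law is injected directly. Above
  $10^{-4}$ M duration is independent of amplitude, matching the loss of
  the correlation at P2X7-saturating doses.
* **Cell-level amplitude CV** is 0.45; amplitude is the most variable of
  the three metrics in this kind of data (its dose dependence loses
  statistical significance without per-experiment normalization).
* **Outliers**: a per-condition fraction interpolated from 25 % (lowest
  dose) to 10 % (highest) of cells is made outlying — hyper-responders
  (amplitude × uniform(3, 6), probability 0.7) or non-responders
  (× uniform(0, 0.25)). A single point-mass multiplier was rejected: a 25 %
  cluster at a fixed factor caps every member's z-score near
  $\sqrt{(1-f)/f} \approx 1.7$ and is mathematically invisible to a
  single-pass 2 SD rule, contradicting the removal fractions the rule is
  reported to achieve.
* **Vehicle artifacts**: with probability 0.2 a vehicle cell shows a small
  (amplitude 0.05) response, emulating mechanically induced responses to
  bath application; configurable off.
* **Determinism**: every cell draws from a substream seeded by a
  counter-derived 32-bit seed, so output is byte-identical for identical
  config + seed and independent of generation order.

### What a green test does not establish

The generator's variance components (cell CV, experiment scale SD, noise
levels) are stated emulation choices, not estimates — the underlying
study's true inter-experiment variance is unknowable from its text, and the
manifest labels them as such. Green end-to-end tests establish that the
pipeline recovers the structure *of this stated world* (two-peak detection,
inhibitory-sign recovery, coefficient accuracy), not that it would recover
the published coefficients from the original recordings, which are not
available. Real data also differ in ways the generator does not model:
photobleaching, drift, oscillatory responses, spatially correlated noise,
and non-Hill receptor kinetics.

## Landmark analysis

`find_landmarks()` labels a dose-response curve with the five landmark
points of a two-peak structure: initial low response, first peak, trough
between the peaks, second peak, and the lowest value after the second peak.
Peaks are interior points strictly greater than both neighbors; plateau
runs count once, at their lowest concentration (a deterministic tie-break
the sources do not specify). With more than two candidate peaks, the two
largest are kept; one-peak and zero-peak (monotone) curves return reduced
variants rather than errors, since about one experiment in eight shows a
single peak. Vehicle (0 M) points are excluded before analysis.

## Model comparison

`compare_models()` fits every candidate basis and ranks by $R^2$
(descending), breaking ties by parameter count then input order — $R^2$ is
the only criterion the emulated analysis used, so no AIC/BIC is offered.
Because the alternative mid-range receptors (P2Y4, P2X5, P2X2) have nearly
identical $K_{1/2}$, their three-receptor decompositions fit almost equally
well; the package reports all fits rather than pretending the data can
discriminate them.

## Known limitations

* Linearized CIs understate uncertainty for steep Hill coefficients near
  bounds.
* The two response scalings in the literature this mirrors (order-one
  coefficients for normalized landmark curves vs large coefficients for
  area curves) are not reconciled; each fit's scale is taken from its
  input normalization.
* No heteromeric receptors, no agonists other than ATP, no image
  processing: inputs begin at per-cell intensity series.
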