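---
title: "Methods: the sagittal-plane localization model and its analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the sagittal-plane localization model and its analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagloc)
```

## The model and its assumptions

`sagloc` treats sagittal-plane localization as probabilistic template
matching on monaural spectral cues. The listener is assumed to hold, per
sagittal plane and ear, an internal template of the positive spectral
gradient (PSG) profile of their own DTFs at every polar angle, and to judge
an incoming sound by comparing its PSG profile against all templates. Three
assumptions are doing the work:

* **Cue representation.** Localization information is carried entirely by
  the rectified across-band gradient of the band magnitude profile. The
  rectification makes the cue insensitive to broadband level and to the
  overall tilt direction of the spectrum, which is what makes comparison of
  a stimulus profile against stored templates meaningful without level
  calibration.
* **Independence of stages.** Perceptual evaluation (distance → similarity
  → binaural combination) and motor response (Gaussian scatter) factorize;
  the response distribution is the smeared, normalized similarity profile.
* **Stationarity.** The model predicts a distribution over responses, not
  single trials; all trials of a listener are exchangeable draws from the
  target's PMV.

The forward pass for one target is: band magnitude profile → PSG →
weighted L1 distance per template angle and ear → sigmoid similarity →
binaural combination → wrapped-Gaussian smearing → normalization to a PMV.

## Tunable parameters

| parameter | meaning | units | default / bounds |
|---|---|---|---|
| Γ (`gamma`) | selectivity: sigmoid slope | 1/dB | fitted, (0.1, 100) |
| S (`s`) | sensitivity: sigmoid shift | dB (weighted gradient distance) | fitted, (−20, 20) |
| ε (`epsilon`) | sensorimotor scatter SD | degrees | fitted, (3, 50) |
| `phi_scale` | binaural weighting scale | degrees | 13 |
| band grid | ERB-spaced centers | Hz | 700–18000, 1 ERB |
| bin size | polar response grid | degrees | 5 |
| PMV floor | probability floor before log | – | 1e−9 |
| boundary tolerance | "at bound" fraction of range | – | 0.01 |

The fitting bounds delimit the plausible human range while keeping the
optimization away from numerically degenerate corners. The binaural scale
of 13° is the standard logistic constant for the ipsilateral-ear weight in
sagittal-plane modelling; at the median plane both ears weigh exactly 0.5.
The 5° bin matches typical response-analysis resolution and sets the polar
grid on which templates are generated.

Weighting schemes are normalized to unit sum. Without a common scale, the
overall magnitude of the weights would trade off against Γ and S during
refitting and fitted parameters would not be comparable across variants.
The NR and DT schemes are parametric log-frequency Gaussian bumps (centers
8 and 6 kHz, SD 1 octave, floor 0.05 of the peak) — smooth stand-ins for
the emphasis regions reported in the experimental literature, adjustable via
`scheme_bump()` if a user has digitized curves. The LP decay default of 0.5
per octave gives a clearly visible low-frequency emphasis while keeping all
bands above zero weight. SV weights are population variances (divide by N)
of the template PSG across the polar grid: the grid is a census of the
listener's template directions, not a sample from a larger population.

## What the synthetic listeners emulate — and what they do not

`synthetic_listener_spec()` produces DTF magnitude sets with the features
the analysis relies on:

* a main spectral notch whose center frequency rises monotonically with
  polar angle across the frontal range (about one octave per 90°, starting
  near 6 kHz at −30°) — the dominant elevation cue of real pinnae;
* a rear trajectory mirrored from the front with an octave offset and a
  different notch shape (shallower, wider), so front and back are similar
  but not identical; this controls the attainable quadrant error rate;
* a high-frequency pinna peak near 12.5 kHz whose gain varies smoothly
  with polar angle, concentrating spatial variance above the notch region —
  in measured DTF sets the group-level SV weights peak near 11 kHz, above
  the 8 kHz notch-region emphasis, and the elevation-dependent peak is what
  reproduces that separation here;
* a small fixed inter-ear notch offset plus a lateral-angle-dependent
  spectral tilt between ears, and smooth seeded spectral jitter per
  direction and ear.

They do **not** emulate physical pinna acoustics (no torso/head
diffraction, no measurement noise, no individual cavity resonances), and
responses are sampled from the model's own PMVs. Passing tests therefore
show that the pipeline is self-consistent — parameters and generating
schemes are recoverable when the model class is correct — not that the
model describes human listeners; that question needs measured DTFs and
behavioral data, which the plain-table readers accept.

## Numerical choices

* **ERB scale.** E(f) = 21.4·log10(0.00437·f + 1). The default grid holds
  28 bands; the ERB span of 700 Hz–18 kHz is 27.669 units, so refining the
  step changes the band count by direct enumeration, not by doubling.
* **Peripheral stage in the frequency domain.** Band profiles are dB levels
  of mean squared amplitude inside a rectangular 1-ERB window around each
  center. For long stationary flat-spectrum noise this equals the expected
  output of a time-domain filterbank front end while removing
  stimulus-realization noise; `template_set()` accepts precomputed profiles
  for users who prefer a gammatone front end.
* **Wrapped-Gaussian scatter.** Polar angle is circular on [−90°, 270°), so
  the scatter is a circular convolution with a wrapped Gaussian (±2 wraps,
  ample for ε ≤ 50°), kernel normalized to preserve mass.
* **Similarity underflow.** For extreme parameter values (large Γ with S far
  below all distances) the sigmoid underflows to zero everywhere; the
  forward pass then returns a uniform PMV instead of 0/0. Relatedly, as
  S → −∞ the PMV converges to softmax(−Γd): low sensitivity does *not*
  flatten the PMV in this parameterization — only the high-S side does.
* **Response binning.** Responses map to the nearest polar bin by circular
  distance, ties toward the lower bin — an arbitrary but deterministic rule.
* **PMV floor.** Probabilities are floored at 1e−9 before the log so a
  single outlier response cannot veto an otherwise good fit.
* **Optimizer.** Likelihood maximization uses multi-start L-BFGS-B on a
  unit cube (Γ log-scaled), with the cube center, a start inside the
  plausible human range (Γ ≈ 5, S ≈ 0.5, ε ≈ 13°), and seeded random
  starts. A cleanly converged start is preferred whenever it matches the
  best objective value; an abnormal line-search exit at the same optimum is
  not treated as failure. Any bounded restart-based search would do; the
  surface is smooth but multimodal along the Γ–S trade-off (a small Γ can
  absorb large shifts of S), which is the main source of boundary-flagged
  fits.
* **Boundary flags.** A parameter within 1% of its range of either bound
  counts as non-converged; subjects with any flagged fit among compared
  variants are excluded from selection. The 1% rule is this package's
  declared stand-in for an unstated convention.

## Design choices that were genuinely open

* **BIC evidence transform.** Per-subject variant posteriors default to
  exp(−BIC/2) normalized, the standard evidence approximation. A
  `printed_ratio` mode (BIC_k / ΣBIC) is shipped for compatibility with
  analyses that normalize raw BIC values; note it assigns the larger
  posterior to the *worse* model and is nearly uniform for large BICs.
* **Random-effects selection.** Variational Dirichlet inference over group
  model frequencies (prior count 1 per variant), exceedance probabilities
  by 10⁶ seeded Dirichlet samples, BOR from the free-energy comparison with
  the equal-frequency null, PXP = EP·(1−BOR) + BOR/M, following Stephan et
  al. (2009) and Rigoux et al. (2014).
* **Smearing after binaural combination.** The scatter models a single
  motor stage and is applied once, to the combined profile. Users comparing
  against implementations that smear per ear before combination should
  expect small differences.
* **Lateral sign convention.** Positive lateral angles are to the left.
  The SV scheme's mirror symmetry makes group analyses insensitive to this
  choice; it is stated here and in the I/O documentation.
* **DTF interchange format.** DTF sets read and write as plain long-format
  CSV tables (plane, polar angle, ear, frequency, dB gain); response
  tables as CSV with angles in degrees.

## Interpreting QE under scatter

The quadrant error rate of this model is governed by front–back template
similarity, not by the scatter: smearing transports probability mass across
the ±90° error boundary in both directions, so in regimes with substantial
confusion lobes the expected QE is nearly flat — and can even decrease —
as ε grows. Only in the high-selectivity regime (e.g. Γ = 30), where
confusion lobes vanish, is QE a clean function of scatter-tail crossings
and monotone in ε. The test suite checks QE monotonicity in that regime;
PE is monotone in ε everywhere.

## Problem sizes used by the tests

The suite validates formulas against brute-force oracles on ≥1000 random
instances each; self-match (PMV mode at the target bin, Flat scheme,
ε = 3° < bin width) over all 72 median-plane targets of 17 synthetic
listeners; parameter recovery with 10 repetitions of 1000 trials at
(Γ, S, ε) = (6, 0.7, 12.79°), requiring the median ε error ≤ 2° and the
median Γ within a factor 1.5; and scheme recovery with 17 listeners × 300
trials simulated under NR, all five variants refitted, requiring
PXP(NR) > 0.9 and BOR < 0.05. These sizes keep a full run within a few
minutes on one CPU while leaving comfortable statistical margins; the same
quantities, at the same sizes, are recomputed by `scripts/acceptance.R`.

## Known limitations

* The model predicts polar-angle distributions within a plane; interaural
  time/level cues and lateral response errors are out of scope.
* Model parameters are constant across planes (median-plane fits are reused
  laterally); scatter may in reality vary with lateral angle.
* Response biases (e.g. toward the horizon) are not modelled and surface as
  apparent imprecision.
* The NR/DT bump shapes and the LP decay are parametric conventions, not
  measured weighting functions.
* SOFA containers are not read directly; convert HRTF sets to the plain
  spectral-table format (any SOFA tooling can export magnitude responses)
  and remove direction-independent components with `dtf_from_hrtf()`.
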