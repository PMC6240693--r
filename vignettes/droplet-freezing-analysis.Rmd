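---
title: "Estimating per-cell ice-nucleating particle spectra from droplet freezing assays"
author: "inpspectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating per-cell ice-nucleating particle spectra from droplet freezing assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inpspectra)
```

## The assay and the estimation problem

Immersion-freezing droplet assays distribute a washed cell suspension
over a well plate (typically 16 or 32 replicate droplets of 20--30 µL)
and cool the plate stepwise from -2 to -28 °C in 1--2 °C increments with
30-minute holds, recording at each setpoint the cumulative number of
frozen wells. Because a droplet freezes as soon as it contains at least
one ice-nucleating particle (INP) active at or above the current
temperature, the fraction of frozen droplets encodes the concentration
of INPs. Under the *singular* approximation -- freezing depends only on
the coldest temperature reached, not on time spent there -- the number
of active INPs per droplet is Poisson, and the cumulative INP
concentration per cell active at or above temperature $T$ is

$$
N_n(T) \;=\; \frac{-\ln\!\big(1 - [\mathrm{FF}_{\text{sample}}(T) -
\mathrm{FF}_{\text{control}}(T)]\big)}{c\,V},
$$

where $\mathrm{FF}$ is the frozen fraction (frozen wells / total wells),
$c$ the cell concentration in the droplet (cells µL⁻¹) and $V$ the
droplet volume (µL). Subtracting the buffer-control frozen fraction
removes background freezing from the medium and impurities.
`fit_inp_spectrum()` implements this estimator per setpoint and is the
package's central fitting function; it returns a classed object with
`print`, `summary`, `plot`, `coef`, `confint` and `as.data.frame`
methods.

The singular approximation is also the simulator's generative model
(`simulate_plate()`), so the estimator and the generator are exact
inverses up to sampling noise -- the basis of the consistency and
recovery checks in the test suite.

## Flags, censoring and detection limits

Each setpoint of a fitted spectrum carries one of four flags.

* **`negative_removed`** -- the control froze more than the sample;
  the corrected fraction is negative. Such setpoints are excluded, not
  clipped to zero: clipping would bias low-activity spectra upward at
  cold temperatures where backgrounds are largest.
* **`saturated`** -- every sample well froze. The estimator diverges at
  a corrected fraction of 1, and a fully frozen plate is right-censored
  *regardless* of what the control did: when the control is partly
  frozen, the literal corrected fraction is below 1 and would produce a
  severe spurious underestimate. We therefore flag saturation on the
  raw sample count ($k = n$) and report a lower bound evaluated at a
  corrected fraction of $(n - 0.5)/n - \mathrm{FF}_{\text{control}}$
  (a half-well continuity correction), with an infinite upper
  confidence bound.
* **`below_detection`** -- the corrected signal resolves to less than
  one well above background. The lower detection limit of a plate is
  the concentration corresponding to a single frozen well,
  $-\ln(1 - 1/n)/(cV)$; the upper limit uses the same half-well
  correction at near-saturation.
* **`ok`** -- an estimate between the detection limits.

Confidence bounds are exact Clopper--Pearson binomial intervals on the
sample frozen fraction at 95% by default, shifted by the control's
point fraction and pushed through the (monotone) estimator. The
uncertainty of the control itself is not propagated; with identical
plate sizes this makes the intervals slightly narrow in principle, but
the intervals are already conservative by construction and simulated
coverage of merged dilution-series spectra is ≈ 98% (recomputed by
`scripts/acceptance.R` at run time).

Cell-free material -- buffer controls and filtrates -- has no per-cell
scale. For such plates the spectrum is normalised by droplet volume
alone and labelled per droplet. This matters for the treatment
contrasts below.

## Dilution series and replicate quality control

A freezing profile is measured on a 10-fold dilution series so that
each temperature band falls inside some dilution's dynamic range
(concentrated plates saturate at cold setpoints; dilute plates are
below detection at warm ones). `merge_dilutions()` combines a series
per setpoint as the unweighted arithmetic mean over dilutions flagged
`ok`; saturated and below-detection dilutions are excluded. Equal
weights were chosen over inverse-variance weights for transparency:
the usable dilutions have comparable binomial information, and the
merge must remain order-invariant and auditable. Where no dilution is
usable the most informative failure propagates (saturated over
below-detection over removed).

`replicate_filter()` enforces the three-replicate design: a strain is
kept only if *every* biological replicate shows detectable activity at
at least one setpoint -- an `ok` estimate at or above its own lower
detection limit, or a saturated setpoint, which is activity beyond the
upper limit rather than absence of signal.

## Screening, onset and temperature classes

Screening calls a strain ice-nucleation active (INA) when at least 50%
of wells are frozen at -24 °C (inclusive boundary), and confirmation
requires all of at least two independent screens to be positive. The
screen operates on the raw sample frozen fraction by default: a
screening decision needs no per-cell normalisation, and correcting a
16-well screen with a 16-well control would add discreteness noise at
exactly the decision boundary; the cutoff, temperature and corrected
variant are all configurable.

The onset temperature is the warmest setpoint at which **all**
replicates show activity above background (`ok` and positive, or
saturated). "All" rather than "any" mirrors the replicate filter and
keeps single-replicate background flukes from setting onsets. Onsets
are binned into the reporting classes warm (≥ -6 °C), mid
(-6 > T ≥ -12), cool (-12 > T ≥ -18) and cold (-18 > T ≥ -24), with
boundaries assigned to the warmer class at -6 and to the colder side
at -12 and -18; the binning partitions the assay range with no gaps.

## Inferring the nature of the ice-nucleating compound

Two laboratory treatments localise the active compound:
heating (100 °C, 10 min) denatures proteins, and 0.2-µm filtration
retains only soluble material released by the cells. `infer_nature()`
pools the estimable per-setpoint estimates of each arm, runs a
Kruskal--Wallis test across the arms and Dunn's pairwise post-hoc
test, and calls each axis only when both the omnibus test and the
deciding pairwise contrast are significant (default α = 0.05) *in the
direction of reduced activity*:

* heat contrast significantly lower → **proteinaceous**, otherwise
  non-proteinaceous;
* filtrate contrast significantly lower → **cell-associated**,
  otherwise the activity is soluble (it survived filtration).

The filtrate arm is naturally on a per-droplet scale while untreated
spectra are per cell; because only a *reduction* can trigger a call,
this scale mismatch cannot create a spurious cell-associated verdict.
A missing arm yields `indeterminate` on its axis.
Temperature-resolved verdicts (compounds that differ above and below
some temperature) are obtained by passing a `setpoint_range` window.

The Dunn p-values are unadjusted by default, with Holm and
Benjamini--Hochberg available; with three arms and one deciding
contrast per axis, multiplicity is not the dominant error source, and
unadjusted values are what practitioners of this assay conventionally
report. The underlying tests are implemented in the package itself
(`prop_test_2x2()`, `kruskal_wallis()`, `dunn_posthoc()`): mid-ranks
everywhere, the standard tie corrections, and a Yates continuity
correction capped so the corrected deviation cannot go negative. The
test suite checks them against closed-form and brute-force oracles and
against the reference implementations in base R.

## The simulator

The generative family is a mixture of log-linear cumulative spectrum
components: each component contributes
$K(T) = A\,e^{\gamma (T_{\mathrm{on}} - T)}$ INP per cell below its
onset $T_{\mathrm{on}}$ and nothing above it. This is the minimal
family that reproduces how such assays are reported -- an onset plus
point concentrations -- while giving non-decreasing cumulative spectra.
Components carry a protein class and a localisation, so treatments are
exact set operations: heating removes proteinaceous components;
filtration keeps soluble ones and folds the per-cell amplitude into a
per-droplet amplitude ($A \cdot cV$); the axenic transform attenuates
components flagged as epibiont-derived. Heating and filtration are
idempotent by construction.

Every droplet additionally carries a per-droplet background component
(default: onset -24 °C, 0.02 INP per droplet at onset, steepness
0.6 °C⁻¹), tuned so a 16-well buffer control rarely freezes above
-24 °C -- about a 2% expected frozen fraction at the screening
temperature. Freezing is simulated by the exact inverse of the
estimator: each well draws one uniform variate and freezes at the
warmest setpoint where the cumulative probability
$1 - e^{-[K(T)cV + K_{bg}(T)]}$ reaches it, which makes counts
cumulative by construction and marginally binomial at each setpoint.

`generate_strain_panel()` assembles a full synthetic survey. Its
defaults *are* the emulated study design: 81 airborne and 32 aquatic
strains; 14 and 16 of them truly INA; airborne taxonomy allocated as
40 Trebouxiophyceae + 6 Chlorophyceae + 11 Stramenopiles + 24 unknown;
onset classes warmer for airborne INA strains (6 warm, 5 mid, 2 cool,
1 cold) than aquatic (2 mid, 12 cool, 2 cold); 38 airborne strains
freeze-tested with full survival, 10 of 32 aquatic survivors, 11
aquatic strains desiccation-tested with none surviving; half the
panel generalist across the three depositional media; 16-well screens
and 32-well × 3-replicate × 3-dilution profiles. Counts are allocated
exactly and then assigned to strains at random. Amplitudes are drawn
log-uniformly between 3×10⁻⁴ and 10⁻² INP cell⁻¹ at onset with
steepness 0.5 °C⁻¹, matching the order of magnitude of reported
per-cell concentrations (10⁻⁴--10⁻² INP cell⁻¹ near onset, up to ~0.3
at cold temperatures). Randomness uses one master seed with per-plate
substreams derived deterministically from (seed, strain, arm,
replicate, dilution), so the same seed and configuration reproduce a
panel byte for byte, and drawing plates in a different order cannot
change any plate's content.

What the simulator deliberately does not emulate: hold-time kinetics
(the singular approximation ignores the 30-minute holds, exactly as
the estimator does), droplet-volume variability within a plate,
cell-count uncertainty (concentrations are taken as known inputs),
spatial plate effects, and epibiont community structure beyond a
single attenuable component. Passing tests therefore demonstrate
internal consistency of estimator and generative model under these
idealisations -- not robustness to time-dependent nucleation or
miscounted cells in real plates.

## Numerical and design choices

* Temperatures are °C, negative; "warmer" means numerically greater.
  Spectra are reported on the protocol grid, never interpolated.
* Counts must be cumulative; decreasing counts are rejected with the
  offending setpoint named, not repaired.
* `log1p`/`expm1` are used throughout the hazard/fraction transforms
  to keep precision at small fractions.
* Clopper--Pearson intervals use the Beta-quantile closed form; the
  test suite checks them against a direct bisection of the binomial
  tail.
* The e-value floor for taxonomy assignment, written "e⁻¹⁸⁹" in the
  conventions this follows, is read literally as $e^{-189}$ by
  default, with the base-10 reading selectable -- the notation is
  ambiguous and the choice is surfaced as an argument rather than
  hidden.
* Percentages are rounded to one decimal in composition tables and to
  the nearest integer in survival headlines, with denominators always
  reported explicitly.

## Problem sizes used by the checks

The simulation-based checks use 500 plates for the constant-hazard
consistency check, 100 simulations × 3 replicates × 3 dilutions for
confidence-interval coverage, 200 factorial batches for
treatment-contrast inference, and 2000 Monte-Carlo replicates for
type-I-error bounds -- sizes at which Monte-Carlo error is a small
fraction of the tolerances being asserted and a full run completes in
a few minutes on one CPU.

## A worked example

```{r example}
model <- spectrum_model(
  spectrum_component("proteinaceous", "particulate",
                     onset_T = -8, amplitude_A = 1e-3,
                     slope_gamma = 0.5))
batch <- simulate_treatment_batch(model, droplet_spec(20, 100),
                                  default_protocol(), n_wells = 32,
                                  seed = 11, sample_id = "demo")
fits <- lapply(1:3, function(r)
  fit_inp_spectrum(batch$untreated[[r]], control = batch$control[[r]]))
summary(fits[[1]])
onset_temperature(fits)
temperature_class(onset_temperature(fits))
infer_nature(
  fits,
  lapply(1:3, function(r)
    fit_inp_spectrum(batch$heated[[r]], control = batch$control[[r]])),
  lapply(1:3, function(r)
    fit_inp_spectrum(batch$filtrate[[r]], control = batch$control[[r]])))
```

## Known limitations

The estimator inherits every idealisation of the singular Poisson
model; deviations (time-dependent nucleation, droplet polydispersity)
bias real-data spectra in ways the synthetic checks cannot detect.
Background correction treats the control as noise-free. The merged
confidence bounds average per-dilution bounds rather than forming a
joint interval, which is conservative but not exact. Screening at a
fixed -24 °C setpoint requires that setpoint to exist in the protocol;
protocols not containing it must screen at a caller-chosen setpoint.
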