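---
title: "Quantifying Pr/Pfr photostates and kinase output in bathy phytochromes"
author: "bathyspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Pr/Pfr photostates and kinase output in bathy phytochromes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bathyspec)
```

## The problem

Bathy phytochromes are bacterial photoreceptors whose biliverdin
chromophore interconverts between a red-absorbing Pr form
(Q-band maximum near 700 nm) and a far-red-absorbing Pfr form
(near 750 nm). Unlike prototypical phytochromes, their thermally stable
dark state is Pfr: in darkness the population relaxes completely into
Pfr by thermal *dark reversion* (DR), while any illumination sustains a
photostationary Pr/Pfr mixture set by the balance of photoconversion
and DR rates. Because only the Pr form is autokinase active, the Pr
fraction of a sample is a direct, quantitative proxy for its
histidine-kinase output. The package turns UV/Vis absorption spectra of
photostationary samples into that number.

## The mixture model and its fit

A photostationary Q-band spectrum is modelled as a two-component
mixture of the pure-state spectra at equal concentration,

$$A(\tilde\nu) \;=\; c\,\bigl[\alpha\,\mathrm{Pfr}^0(\tilde\nu)
  + (1-\alpha)\,\mathrm{Pr}^0(\tilde\nu)\bigr],$$

with $\alpha = [\mathrm{Pfr}]/([\mathrm{Pfr}]+[\mathrm{Pr}])$ the Pfr
fraction and $c>0$ an overall concentration scale. The pure spectra are
obtained from the same sample: $\mathrm{Pfr}^0$ after complete dark
reversion, $\mathrm{Pr}^0$ under a continuous far-red clamp that
suppresses DR. Working on one sample is what makes the extinction ratio
$\eta = \varepsilon(\lambda_{max,\mathrm{Pfr}})/
\varepsilon(\lambda_{max,\mathrm{Pr}})$ meaningful without absolute
concentration measurements, so no cross-normalisation is applied
between the two references.

The fit is deliberately not a generic 2-D optimisation. For fixed
$\alpha$ the optimal scale has the closed form
$c(\alpha) = \langle A, m_\alpha\rangle / \langle m_\alpha,
m_\alpha\rangle$ (clipped positive), where
$m_\alpha = \alpha\,\mathrm{Pfr}^0 + (1-\alpha)\,\mathrm{Pr}^0$; the
profiled residual sum of squares is then minimised over
$\alpha \in [0,1]$ by golden-section search. This bilinear structure
makes the fit globally convergent with no starting-point sensitivity,
and trivially checkable against a brute-force grid search (the test
suite does exactly that, at a 0.001 grid step). Optima at the interval
ends are snapped to exactly 0 or 1 and flagged as boundary solutions:
the model admits no super-mixtures. References whose windowed
evaluations are nearly collinear (cosine similarity > 0.999) are
rejected as unidentifiable.

### Background handling

Scattering adds a slowly varying baseline to measured spectra. Over the
Q-band window (550--850 nm by default) it is approximated as a straight
line through the mean (wavelength, absorbance) of two 10-nm anchor
regions at the window edges, and subtracted. Two properties of this
operator matter:

* it is *linear* in the spectrum and *annihilates* every affine
  baseline, so applying the identical operator to the evaluated
  references inside `unmixPhotostate()` preserves the mixture relation
  exactly — noiseless mixtures are recovered to machine precision and
  any added line changes $\alpha$ only through noise;
* it is idempotent, so pre-subtracted inputs (flagged in metadata) pass
  through unchanged.

The anchor width and window are configurable; the window default
reflects where the Q bands of both states carry signal while the anchor
regions are essentially band-free.

### Axis and smoothing choices

Gaussian bands are parameterised in wavenumber
($\tilde\nu = 10^7/\lambda$ cm$^{-1}$), the natural axis for band
shapes; spectra keep their instrument wavelength grid and are evaluated
pointwise, with no Jacobian rescaling when changing axis — the mixture
model is linear, hence invariant under any common axis transform.
LOESS smoothing (quadratic, proportional span, default 0.1) is applied
for peak detection and display only; the unmixing fits
background-subtracted raw data, since least squares already averages
zero-mean noise and smoothing before fitting would correlate residuals.

### Uncertainty

The residual bootstrap (default 200 replicates, seed mandatory) refits
the model on `fitted + resampled residuals` and reports the standard
deviation and 2.5/97.5 percentile interval of $\alpha$. A
covariance-matrix interval would be misleading at the frequent boundary
solutions; percentiles are not.

## Pure-state models

Each pure spectrum is fitted as a superposition of 1--4 Gaussian bands
(up to 6 allowed) by bounded least squares: amplitudes nonnegative,
widths 100--5000 cm$^{-1}$, five deterministic multistarts from
quantile-spaced centers, model order by BIC. One dominant Q-band
Gaussian plus at most a shoulder is the physically expected result; the
BIC cap keeps the model identifiable on noisy data.

## The two-state photocycle

The photocycle is reduced to two limiting species with three rates:
photochemical $k_{\mathrm{Pr}\to\mathrm{Pfr}}$ and
$k_{\mathrm{Pfr}\to\mathrm{Pr}}$, and thermal
$k_{DR}$ (Pr $\to$ Pfr). The Pfr fraction obeys

$$\dot\alpha = (k_{\mathrm{Pr}\to\mathrm{Pfr}} + k_{DR})(1-\alpha)
             - k_{\mathrm{Pfr}\to\mathrm{Pr}}\,\alpha,$$

whose fixed point
$\alpha^\ast = (k_{\mathrm{Pr}\to\mathrm{Pfr}}+k_{DR}) /
(k_{\mathrm{Pr}\to\mathrm{Pfr}}+k_{DR}+k_{\mathrm{Pfr}\to\mathrm{Pr}})$
is the photostationary state; in darkness it is exactly 1 (pure Pfr).
Illumination schedules are integrated with the exact per-segment
exponential solution rather than a numeric stepper — exactness is
testable, and the suite cross-checks against an independent ODE solver
at tolerance $10^{-7}$. Photochemical rates derive from a source via
standard photochemistry, $k = \sigma\,\Phi\,F$ with cross-section
$\sigma = 1000\,\ln 10\,\varepsilon/N_A$ and photon flux
$F = E\lambda/(hc)$, under a monochromatic approximation at the
nominal wavelength (adequate for laser diodes of a few nm bandwidth;
broadband LEDs would require a convolution that is out of scope).
No quantum yields or photochemical rates are bundled for specific
proteins — they are user inputs; the presets make no claim to reproduce
measured light-condition mixtures mechanistically.

## Dark-reversion kinetics and the half-life

DR time courses $\alpha(t)$ are fitted with
$\alpha(t) = \alpha_\infty - \sum_{i} a_i e^{-k_i t}$, orders 1--3,
bounded least squares (amplitudes $\ge 0$, rates
$10^{-6}$--$10$ s$^{-1}$, $\alpha_\infty \in [0.5, 1]$), multistarts
from log-spaced rate grids, order selection by small-sample-corrected
AIC. $\alpha_\infty$ is fitted rather than pinned at 1 because some
bathy phytochromes plateau well below full Pfr occupancy (the XccBphP
preset plateaus at 72%); forcing $\alpha_\infty=1$ would bias the
half-life. The half-life $t_{1/2}$ is defined as the *absolute*
50%-Pfr crossing, located by bisection — not $\ln 2/k$ of any single
exponential; the two coincide only for a mono-exponential rise from
$\alpha(0)=0$. Its uncertainty comes from a residual bootstrap, since
$t_{1/2}$ is a nonlinear functional of the fit.

## Kinase output

With only Pr autokinase-active, the predicted active fraction is simply
$1-\alpha$, linearly — no dimer cooperativity is assumed, because
whether Pr/Pfr heterodimers retain activity is unresolved; the linear
map is the minimal defensible model and is trivially replaced if that
question settles.

## The synthetic-data generator

No machine-readable instrument spectra accompany the study conditions
this package targets, so a seeded generator stands in. Each preset
builds pure-state models from published band maxima
(e.g. PaBphP: Pr 398/702 nm, Pfr 410/752 nm), the Q-band amplitude
ratio $\eta$ (e.g. 0.65 for PaBphP; 1.0 with an explicit "assumed"
flag where it was not determined) and the DR half-life (4 s to 2.3 h
across the six presets). Defaults chosen once where no value was
published: Q-band $\sigma$ = 550 cm$^{-1}$ and Soret $\sigma$ =
1300 cm$^{-1}$ (a sharper Q band over a broad Soret, matching typical
biliprotein spectra), Soret amplitude 0.55 of the Q amplitude, Pr
Q-band peak normalised to 1 AU. Mixtures add a uniform random linear
baseline (slope $\pm 10^{-4}$ AU/nm, offset 0--0.02 AU) emulating
scattering, and additive Gaussian noise, default sd 1% of the Q-band
peak — the scale of a well-behaved benchtop spectrophotometer. All
draws are reproducible from a mandatory seed, and every generated
object records its ground truth in metadata.

What the generator does *not* emulate: vibronic lineshape asymmetry,
wavelength-dependent (non-linear) scattering, photocycle intermediates
(Lumi/Meta states) that transiently violate the two-state assumption,
and detector nonlinearity. Passing tests therefore demonstrate
correctness of the estimators under the stated noise model, not
robustness to every instrumental artefact.

## Numerical choices and degenerate inputs

* Golden-section tolerance $10^{-9}$ in $\alpha$; fits at the ends
  snapped to exact 0/1 with a boundary flag.
* Duplicate wavelengths averaged on read; interpolation is linear;
  extrapolation is always refused.
* Fit floors: a sample or pure-state peak below $10^{-6}$ AU is
  rejected as signal-free; a flat window ($< 10^{-9}$ AU range) has no
  defined maximum; a constant series has no decay to fit.
* Peak refinement: quadratic interpolation through the three points
  around the discrete argmax, ties broken toward the longer wavelength,
  edge maxima returned unrefined.
* Half-life bisection runs to $10^{-9}$ relative and errors clearly
  when the series starts at or above 50% Pfr or never crosses it.
* Raw spectra with substantial negative absorbance (beyond $-0.05$ AU)
  are rejected unless flagged as difference, background-subtracted or
  noisy data; small noise-level negatives are tolerated.

## Problem sizes

The bundled checks run on sizes a laptop handles in about a minute:
50 noisy mixtures for the recovery bound, 100 mixtures for the
grid-search equivalence, 50 series (60 log-spaced points over 24 h) for
half-life recovery, 200 bootstrap replicates by default. Larger runs
only tighten the same estimates.

## Known limitations

Three-or-more-component unmixing (photocycle intermediates) is out of
scope, as are absolute concentrations, polychromatic sources, and the
temperature/pH dependence of dark reversion. The kinase map is linear
by assumption. The asymmetry sometimes quoted between Pfr- and
Pr-fraction error magnitudes cannot refer to a single fit (the two
percentages of one sample are complementary); the bootstrap here
reports one per-fit uncertainty and leaves regime-dependent error
budgets to the user.
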