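---
title: "Phenological Hill numbers: model, choices and limitations"
author: "phenohill"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenological Hill numbers: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenohill)
```

## The measure

Communities partition not only space and resources but also *time*:
each species concentrates a phenophase (breeding, flowering, migration)
on some portion of the year, with some intensity. `phenohill` summarises
how diverse those temporal patterns are in a single family of numbers,
the phenological Hill numbers `qPD`, built in three steps.

**1. Continuous curves.** Field records of phenological activity are
discrete, gappy and jagged. Each species' series is smoothed into a
continuous curve \(z_i(t)\) by a continuous wavelet transform (Morlet by
default), on the view that phenophases start and end gradually rather
than abruptly. Smoothing also interpolates across sampling gaps, which
is why missing cells are stored as zeros with a gap mask rather than
imputed beforehand.

**2. Pairwise temporal-niche distances.** For each species pair, a
modified Morisita–Horn overlap distance

\[
O_{ij} \;=\; 1 \;-\; \frac{2\int z_i(t)\,z_j(t)\,dt}
                        {\int z_i(t)^2\,dt + \int z_j(t)^2\,dt}
\]

measures how distinctly the two curves occupy the time axis: 0 for
pointwise-identical curves, 1 for curves with disjoint activity periods.
Unlike Jaccard- or Simpson-type overlap, it accounts for both the
overlapping and the non-overlapping area, and it is sensitive to
intensity differences: two constant curves of unequal height have a
strictly positive distance. All integrals are composite trapezoids on
the shared sampling grid — the curves are only known at grid points, so
higher-order quadrature would add no information.

**3. Distance-based Hill diversity.** With relative intensities
\(p_i = \int z_i / \sum_j \int z_j\) and the Rao-type standardising
factor \(Q = \sum_{i,j} O_{ij} p_i p_j\), the order-\(q\) diversity is

\[
{}^q\!PD = \Bigl[\sum_{i,j} \tfrac{O_{ij}}{Q}\,(p_i p_j)^q
           \Bigr]^{\frac{1}{2(1-q)}},
\qquad
{}^1\!PD = \exp\Bigl(-\tfrac{1}{2}\sum_{i,j}\tfrac{O_{ij}}{Q}\,
           p_i p_j \log (p_i p_j)\Bigr),
\]

in units of *effective phenological curves*: the number of equally
weighted, temporally disjoint curves that would give the same value.
`q` tunes sensitivity to intensity: `q = 0` is richness-like, `q = 1`
Shannon-like, `q = 2` dominance-weighted. Two structural facts anchor
interpretation:

* if all curves are identical, every distance is 0, \(Q = 0\), and the
  measure is defined to be 0 (no temporal differentiation at all);
* if \(S\) equally weighted curves are pairwise disjoint,
  \({}^q\!PD = S\) exactly, at every order.

Between these extremes the profile over `q` is non-increasing; it is
flat exactly when the \(p_i\) are equal (for equal weights the double
sum collapses to \(S^{2(1-q)}\) whenever \(Q > 0\), so the profile sits
at \(S\) regardless of *how much* the curves overlap). Because \(Q < 1\)
in real communities, \({}^0\!PD\) may exceed \(S\); that is a property
of the attribute-diversity normalisation, not an error. For \(S = 2\)
the equations collapse further, to \(1/\sqrt{p_1 p_2}\) at every order —
a two-species profile is always flat, and exceeds 2 as soon as the two
intensities differ.

```{r basics}
fit <- phenohill(simulate_case("b"))   # 40 staggered pulses, unequal intensity
fit
```

## Wavelet smoothing: parameters and numerical choices

`smoothing_config()` exposes three knobs.

* **Scaling function** (`morlet`, default; `mexican_hat` as the one
  alternative). The Morlet kernel — a Gaussian-windowed oscillation with
  centre frequency \(\omega_0 = 6\) — is the standard choice for series
  whose frequency content is unknown in advance, which is the normal
  situation for phenology records.
* **Attenuation threshold `tau`** (default 2, the conventional standard
  value; unitless). The transform analyses a dyadic ladder of scales
  from `2 * step` to `n * step` (`scales_per_octave = 12` entries per
  doubling). Smoothing retains the scales
  \(s \ge s_{\max} / (1 + \tau)\): as `tau` approaches 0 only the
  coarsest scales survive (a heavily smoothed curve); as `tau` grows the
  full ladder is retained and the reconstruction approaches the raw
  series. The literature this measure comes from describes `tau` only
  qualitatively through those two limits, so the cutoff rule is a
  declared convention of this package; results at the default should be
  compared across studies at the same `tau`.
* **`scales_per_octave`** trades resolution of the scale ladder against
  compute; 12 is dense enough that the retained-set boundary moves
  smoothly with `tau`.

Reconstruction sums the retained scale bands with the standard
\(1/\sqrt{s}\) weights and restores the series mean. One numerical
choice deserves emphasis: the summed response is normalised *per
frequency* by the full-ladder response, rather than by a single global
constant. On the short, truncated ladders that phenology series admit, a
global constant leaves 10–15% reconstruction error even on noise-free
input (the ladder's band edges are not flat), which would break the
`tau` limits stated above; the per-frequency normalisation makes
full-ladder reconstruction exact to machine precision while leaving the
scale-band structure — and hence the meaning of `tau` — unchanged.
Frequencies below the analysed band (periods longer than the series)
are treated as trend and pass through. Edge effects are controlled by
reflection padding to three times the series length; no periodic
extension is imposed, so single-cycle series work without assuming
cyclicity. Negative reconstructed values are clipped to 0, since the
curves are intensities and the `[0, 1]` range of the overlap distance
is only guaranteed for nonnegative curves; the clip is the only
nonlinear step, and can be disabled (`clip = FALSE`) for diagnostics.

Series shorter than 8 points are refused outright, and 25+ points are
recommended before the multi-scale decomposition is trustworthy.
Species whose series is identically zero carry no phenological signal
and are dropped (with a warning) before any distance is computed; a
community must keep at least two species.

```{r smoothing}
set.seed(1)
raw <- rpois(120, 4 * exp(-((0:119) - 60)^2 / 200))
sm <- smooth_curve(raw, config = smoothing_config(tau = 2))
plot(0:119, raw, type = "h", col = "grey70", xlab = "time", ylab = "intensity")
lines(0:119, sm, lwd = 2, col = "firebrick")
```

## Degenerate inputs and tie-breaks

* Both curves of a pair identically zero: the distance is undefined and
  an error is raised (upstream dropping should have prevented this).
* Exactly one curve zero: distance 1 by convention, with a warning.
* `Q = 0` (all curves identical): `qPD = 0` is returned rather than an
  error, matching the limiting interpretation of "no differentiation".
* The exponent \(1/(2(1-q))\) has a removable singularity at `q = 1`;
  within `|q - 1| < 1e-6` the Shannon-limit form is used. The two
  branches agree to a relative `1e-3` at `q = 1 ± 1e-4` (tested).
* `0 log 0` in the `q = 1` form is taken as 0; in practice all
  \(p_i > 0\) because zero-integral species are dropped first.
* Rounding can push the distance of near-identical curves a hair
  outside `[0, 1]`; values are clamped.

Time units are never interpreted: uniformly rescaling the time axis, or
multiplying all curves by a common positive constant, changes nothing
(`p`, `O`, `Q` and `qPD` are all invariant; tested as properties).

## What the simulator emulates — and what it does not

`simulate_case()` generates nine benchmark scenarios spanning the
measure's extremes: 40 staggered Gaussian activity pulses with equal
(**a**) or geometrically declining (**b**, ratio 0.9) intensities;
identical constant (**c**), identical seasonally modulated (**d**) and
unequal constant (**e**) year-round curves; and the four two-species
combinations of disjoint/overlapping pulses with equal/unequal
intensities (**f**–**i**). Functional forms are a package choice —
truncated Gaussian bumps (support ±3 sd) with peaks at
\((k - \tfrac12)T/S\), narrow enough to tile the period disjointly — so
cases a and f realise the \(qPD = S\) ceiling exactly, and each curve is
rescaled to a prescribed integral so relative intensities are exact on
any grid. With the geometric "unequal" rule at \(S = 40\) the amplitude
range spans ~60-fold, and case e (unequal constants) then scores far
*above* zero at low q: the Morisita–Horn distance between very unequal
constants approaches 1. A milder amplitude spread would bring case e
near zero; we keep one documented inequality rule rather than tuning it
per case, and note that case e's value is an amplitude-spread statement,
not a fixed benchmark.

`simulate_random()` draws random-pulse communities (uniform peaks,
log-normal widths, equal/geometric/user amplitudes) for property
testing. What none of this emulates: observation noise after smoothing,
within-species interannual variation, multimodal phenophases beyond
what random pulse placement produces, and presence/absence (binary)
records — the measure requires intensities, and binary data are out of
scope. Passing the simulation-based tests therefore shows the estimator
is faithful to the defining equations under clean unimodal conditions;
it does not certify behaviour on noisy multimodal field data beyond
what the wavelet-smoothing tests cover.

## Problem sizes used in the test suite

The suite exercises communities up to \(S = 40\) on grids of 80–360
points, 100 random communities for the profile-shape property, and
explicit-loop oracle comparisons on \(S \le 4\) step-curve fixtures —
sizes at which every closed form is checkable by hand while still
covering the regimes (disjoint, nested, partial overlap, identical) that
drive the measure.

## Known limitations

* `tau`'s numerical meaning is a package convention (scale-cutoff); other
  smoothing software parameterises attenuation differently, so `tau = 2`
  here and elsewhere need not coincide.
* The overlap distance compares *shapes and intensities* on the common
  grid; it does not model lags explicitly (a cross-correlation analysis
  is a different tool).
* `^0PD` is not bounded by `S` when `Q < 1`, and for `S = 2` the whole
  profile is flat at \(1/\sqrt{p_1 p_2}\) — readers comparing few-species
  communities should compare `Q` and the distances alongside `qPD`.
* Estimation uncertainty (bootstrap intervals, rarefaction) is not
  provided.
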