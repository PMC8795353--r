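---
title: "Methods: modelling a laser-driven proton FLASH radiobiology platform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling a laser-driven proton FLASH radiobiology platform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonflash)
```

protonflash reimplements, as tested reusable code, the computational chain
behind an in-vitro radiobiology platform driven by a petawatt-laser proton
source: beam physics and dosimetry corrections, radiochromic-film dose
reconstruction, automated colony counting, and clonogenic-survival fitting.
No raw experimental data accompany the platform's published characterisation,
so every stage is exercised end to end on synthetic inputs with known ground
truth, generated by the package itself.

## Beam model

**Source spectrum.** Target-normal-sheath acceleration produces a
quasi-exponential spectrum; the packaged default is the film-calibrated
form dN/dE = 5.15e9 exp(-E / 1.04 MeV) protons/MeV with a 7 MeV sampling
ceiling. Sampling is by inverse CDF of the truncated exponential, so a fixed
seed reproduces a bunch bit for bit.

**Stopping powers.** Energy loss uses per-material mass stopping-power
tables on a log grid from 0.05 to 10 MeV, authored from the Bethe stopping
formula with standard Z/A and mean excitation energies (water 75 eV, air
85.7 eV, kapton 79.6 eV, mylar 78.7 eV; the film active layer is treated as
a water-like polymer, Z/A = 0.543). The bare Bethe formula is unreliable
below a few hundred keV, so below 0.3 MeV a Bragg-peak-shaped branch
S ∝ E^-0.35 is used down to 0.08 MeV and a velocity-proportional branch
S ∝ E^0.45 below that, continuous at the joins. A small transcription of
standard water values ships as a plain-text reference grid and is checked in
the test suite at 5% tolerance; sub-0.3 MeV protons carry so little residual
range that this branch contributes only marginally to any scored quantity.

**Propagation.** Two routes are implemented and cross-checked: a
layer-by-layer midpoint integrator with steps capped at 1% of residual range
(`propagate_energy()`), and an exact continuous-slowing-down range-inversion
method on precomputed range-energy splines (`propagate_stack()`, vectorised;
used by the Monte-Carlo stages). Protons falling below the 0.05 MeV table
floor are STOPPED values, not errors.

**Transport.** The plasma lens is reduced to a chromatic thin lens,
1/f = kappa / p (p in MeV/c), at the centre of the capillary, with a 1 mm
channel aperture, a uniform angular source over the 11 mrad acceptance (the
260 mrad FWHM divergence is flat to better than 1% over that cone), a 100 um
FWHM Gaussian source, and a small-angle 264 mT x 138 mm dipole kick whose
chromatic dispersion displaces each energy vertically. The dipole's position
along the line is not part of the published geometry; the default (centre at
1.2 m) is a layout choice consistent with the exit window and current
transformer sitting downstream. The 10 mm irradiation cup is centred on the
fluence centroid of protons that survive the exit window and air gap — the
beam one would align on with a scintillator. Particle number is conserved
exactly: emitted = aperture-rejected + outside-map + binned.

**Lens tuning.** `tune_focusing()` encodes the platform's stated tuning
objective — a uniform spot that fills the 10 mm cup: among scanned strengths
whose fluence-spot FWHM lies in [1.0, 1.4] x cup diameter, it picks the
minimum central-field dose SD. Under the default geometry the tuned strength
lands near kappa ≈ 3400–4000 with a central dose SD of roughly 11–20%
(Monte-Carlo scan noise moves the winner between adjacent scan points; the
reported uniformity subtracts the expected Poisson sampling variance so it
reflects the beam profile, not counting noise).

**On-sample spectrum and the two printed correction anchors.** Transporting
the printed spectrum through the 25 um kapton window and 97 mm of air gives
a mean on-sample energy of ≈ 2.0 MeV. The platform's figure-level value of
2.4 MeV is not recoverable from the printed spectrum and absorber budget
alone under any stopping-power table of plausible (few-percent) accuracy; it
evidently reflects transport effects beyond the printed inputs. The
platform's own headline description of "~2 MeV protons" matches this
package's computation, and the package reports its computed value rather
than the figure value. Similarly, the cell-to-film dose ratio through the
printed intermediate stack (5 um cell, 2995 um air, 3.6 um mylar, 3000 um
air; energy-deposition scoring in a thin water cell layer and a 10 um film
active layer) evaluates to ≈ 1.0–1.04 with the transport-selected on-sample
spectrum and ≈ 1.3 without transport selection, i.e. the cells receive
*more* dose than the film — consistent with the published prose description
of the geometry but not with the printed multiplicative factor of 0.9 (< 1),
which is internally inconsistent with that prose. The dosimetry chain still
applies the printed 0.9 via `apply_cell_factor()`, exactly as the published
protocol prescribes; the physics function `cell_to_film_dose_factor()`
reports what the model actually computes. Both discrepancies are left
visible in the acceptance checks rather than papered over.

**Time structure.** Arrival times combine relativistic vacuum flight at the
source energy with the exact slowing-down transit through the entrance stack
(a per-material time integral T(E) = ∫ dE/(S v), so slow protons' terminal
crawl is not underestimated). The bunch duration is the dose-weighted
arrival span (0.1–99.9% weighted quantile width), each proton weighted by
its stopping power in the cell layer. A histogram FWHM is available as an
option, but the arrival distribution is strongly one-sided — dose piles up
at the stopping threshold — so its FWHM (~6 ns) does not describe the
bunch length that converts dose per pulse into an instantaneous dose rate;
the span (~28–29 ns) does, and reproduces the published ~30 ns bunch and
~3e7 Gy/s instantaneous dose rate at 1 Gy per shot. For tabulated dose-rate
bookkeeping, `dose_rates()` defaults to the 33 ns value implied by the
published per-shot arithmetic; both are configuration, not constants.

## Film dosimetry

Gray values convert to optical density against a white reference (in
practice the median of an unexposed border), optionally corrected by a
monotone spline through step-wedge calibration points (identity when no
wedge is supplied). netOD = OD − OD0 clamps negatives at zero and counts
them. Two calibration forms are packaged: the linear high-dose film
(D = −0.388 + 434.913 netOD, valid netOD 0–0.25) and the
linear-plus-power low-dose film (D = 0.012 + 2.797 u + 3.982 u^2.784,
valid 0–1.5); both are monotone on their valid ranges, evaluated outside
them only with an explicit extrapolation flag. Negative computed doses
(possible at tiny netOD on the linear film) are clamped to zero and counted
— doses are physically non-negative. LET quenching divides by eta = 0.7 and
the cell-position correction multiplies by 0.9, both exposed as arguments.
Dose statistics are computed after 4x4 binning (noise suppression; the bin
size is a package default, exposed as an argument) over the 10 mm ROI minus
the crescent shadow; the crescent is the circular segment above a horizontal
chord, with a closed-form area and a root-finding helper that solves the
chord offset for a requested area (12 mm^2 at the film plane, 4 mm^2 at the
cell plane in the modelled geometry).

## Colony counting

The scale-space image I(x, y; sigma) is the Gaussian convolution of the
photograph (reflective boundaries); first and second derivatives come from
moment-corrected Gaussian-derivative kernels at the same sigma in a single
pass, so polynomial images differentiate exactly. A pixel is a DARK elliptic
feature when its Hessian is positive definite (leading-minor test, verified
against the eigenvalue criterion exhaustively in the tests), BRIGHT when
negative definite. Well detection regularises the boundary by iterative
tangential voting — edge points vote along their local tangent into
double-cone kernels whose aperture narrows 60° → 20° over three iterations,
concentrating saliency on long coherent curves — followed by a direct
least-squares conic fit constrained to an ellipse (stable three-by-three
formulation) with robust trimmed refitting to reject colony-edge votes. The
exact voting-kernel design of the cited lineage is not restated in the
published description, so this implementation is a documented approximation
with the stated defaults.

Colonies are the 8-connected DARK components inside the well (eroded by
3 sigma + 3 px to keep the rim's edge response out), filtered by minimum
area and by mean intensity. The intensity threshold defaults to the Otsu
split of well-interior pixel intensities, capped by a background-proximity
guard (median − 4 MAD): a pure region-wise Otsu split degenerates on
colony-free wells, where it lands inside the noise distribution and keeps
half the noise specks. Detection scale: sigma ≈ expected colony
radius / sqrt(2); counts are invariant under positive affine intensity
rescaling because Hessian definiteness and both thresholds co-scale.

## Clonogenic survival

Plating efficiency is colonies/seeded; surviving fractions normalise to the
mean sham plating efficiency per experiment and cell line. For proton
exposures the unirradiated crescent subpopulation is estimated as the mean
surviving fraction of lethal-dose (> 30 Gy) samples per cell line and
subtracted with clamping at zero (a surviving fraction is a probability);
lethal groups are excluded from reported curves. Averaging is two-stage:
replicate plates within experiment, then mean ± SD across experiments,
grouped by nominal dose group.

The survival model y = c exp(−a x − b x^2) is fitted by orthogonal distance
regression: latent dose shifts d_i enter the stacked least-squares problem
[(y_i − f(x_i + d_i))/sy_i ; d_i/sx_i], solved by Levenberg-Marquardt, with
parameter covariance from the Jacobian of the full problem scaled by the
residual variance. As sx → 0 this reduces to weighted nonlinear least
squares (verified), and the tests cross-check against an independent
profiled-objective minimiser. Parameter-recovery studies scale a fixed error
shape (the published per-group dose uncertainties in x, relative errors in
y) by a single factor chosen so the linearised single-fit uncertainty of the
tracked parameter equals its published value; because all error bars scale
together, that match is exact and requires no iteration. Over 200 replicates
the recovered means are unbiased to well within one published standard
error, with 1-SE coverage near the nominal 68%. At realistic single-study
noise the a and b coefficients are strongly anticorrelated along the
linear-quadratic ridge — individual small-data fits can trade a against b
substantially while the 200-replicate mean stays centred.

## Synthetic data

Generators are deterministic under (config, seed) and attach their ground
truth to every artifact. Dose maps are sums of three seeded low-order
Legendre modes rescaled to an exact target mean and lateral SD inside the
field (coordinates radially clamped to the unit disc outside it, so the film
model stays invertible across the whole scan), with the crescent zeroed and
Gaussian noise added. Film scans invert the calibration to netOD, add OD0
and convert through gray = 65535 · 10^−OD with 150-count read noise. Plates
are bright wells with Gaussian-profile elliptical colonies placed without
overlap by rejection sampling (minimum centre spacing 2.2 (r_i + r_j) + 3 px
keeps the DARK regions of neighbours disjoint at the detection scale).
Survival records draw per-plate colony counts as
Binomial(seeded, PE_sham · ((1 − bg) SF + bg)) — the shadow subpopulation
plates like sham cells, so the recovered background equals the injected
fraction on the surviving-fraction scale.

What the generators do *not* emulate: film grain and lateral scanner
response, stain-intensity variation and overlapping or merging colonies,
plate-edge artefacts, experiment-to-experiment drifts in plating efficiency.
Passing recovery tests therefore demonstrates the correctness of the
algorithms under controlled conditions, not field performance on real
photographs or scans.

## Problem sizes and numerical choices

Default study sizes: 1e5–4e5 Monte-Carlo protons for transport quantities,
2e5 for on-sample spectra; 200 replicate fits per recovery study; 20 plates
(512 px, 0–300 colonies) for the counting benchmark; 128–256 px dose maps.
Calibration inversion uses a monotone grid-interpolation polish with exact
root finding for the nonlinear form; all monotone splines are Hyman-filtered
cubics. Ties and degeneracies: mono-energetic bunches return zero duration
with a warning; chords tangent to or outside the field give empty shadow
masks with a warning; fewer than six or collinear boundary points make the
ellipse fit fail loudly rather than return garbage.

## Known limitations

The transport model is deliberately minimal (thin chromatic lens, small-angle
dipole, no in-lens loss dynamics or aberrations); it reproduces the platform's
headline beam characteristics but not fine spot structure, and two printed
correction anchors (figure-level mean energy 2.4 MeV; cell-to-film factor
0.9) are not recovered from the printed inputs, as discussed above. The
colony pipeline does not declump overlapping colonies and treats colour by
luminance only. The survival fitter assumes Gaussian, independent errors in
both variables.
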