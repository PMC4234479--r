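---
title: "Dynamic Color Analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic Color Analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcamix)
```

## The measurement problem

Heavy suspensions (solids above roughly 5% w/w) are opaque, which rules out
most classical mixing-visualization techniques, and many of them are
non-Newtonian, which makes their mixing pathological in ways worth
measuring: top–bottom segregation, stagnant pockets, slow approach to
homogeneity. When the suspension contains a wide-spectrum pH indicator —
blue maize flour is the motivating example, because its native anthocyanins
change color continuously from pink through violet and blue to green across
pH 1.6–11.6 — an acid or base injection turns the mixing process into a
color field that a camera or colorimeter can read.

Dynamic Color Analysis (DCA) quantifies that color field. Every reading is
a point in a three-dimensional color space, and the deviation of a sample
at time $i$ and location $j$ from the fully mixed condition is the
Euclidean distance to a reference color representing the final mixed state:

$$D_{i,j} = \sqrt{(L_{i,j}-L_f)^2 + (a_{i,j}-a_f)^2 + (b_{i,j}-b_f)^2}.$$

Two summary curves describe an experiment. The **mean of $D_{i,j}$ over
locations** is the global deviation from mixedness at time $i$; the
**standard deviation over locations** is a direct index of spatial
heterogeneity — it stays high exactly when some regions lag the rest.

## Color spaces and conversions

CIELab is the primary space: it is approximately perceptually uniform,
device independent, and its $L$ (luminosity, 0–100), $a$ (green–red) and
$b$ (blue–yellow) axes make the Euclidean distance meaningful. The same
distance applied to HSB coordinates behaves similarly in practice; RGB does
not, and the package treats RGB distances as something to *test*, not to
rely on (see the validity criterion below).

All conversions go through the standard sRGB chain — sRGB companding, the
D65 white point, the 2° standard observer — implemented via
`grDevices::convertColor()`. Instruments rarely disclose their illuminant
assumptions, so the package fixes this one convention and records it here
rather than exposing a knob that could silently change every distance. Hue
is an angle; `hsb_distance()` therefore offers a `circular` mode using the
shortest angular difference, but defaults to `naive` plain-number
arithmetic, which is how the distance formula is conventionally reused in
HSB; the choice is recorded in the result. Lab values are printed to two
decimals, matching colorimeter output precision.

## The indicator-validity criterion

$D_{i,j}$ is a usable mixedness proxy only if it *decreases consistently*
as the system approaches the final state. For a pH indicator this must be
checked over the intended pH excursion: order the calibration colors from
the starting pH toward the set point and verify that their distances to the
set-point color are non-increasing. `validate_indicator()` implements this,
reporting the distance sequence and the first violating step.
The default tolerance is 0 (strict non-increase), because any slack weakens
the guarantee the criterion exists to provide; a tolerance argument is
available for noisy calibration data, and the value used is recorded in the
report.

Anthocyanin indicators pass this check over pH ≈ 1.6–10.6 but fail when the
range is stretched to ≈ 11.6: near strongly alkaline pH the color path
bends back toward earlier colors and a distance along the trajectory
rises. `run_validate_indicator()` repeats the check per color space; in the
bundled synthetic calibration (below), Lab and HSB pass over the valid
range while a constructed RGB case fails, mirroring the behavior reported
for real calibrations.

## From images and wells to trajectories

For transparent vessels, a frontal image is divided into an
`n_rows × n_cols` grid (default 4×4 with row codes U, A, B, L — labels
`U1`…`L4`) and each cell is sampled at its center. The sample is the mean
over a $(2w+1)^2$ pixel window, default $w = 2$ (5×5): instruments report
point colors, but a small average suppresses pixel noise without blurring
across cells. Windows that would cross the image edge are clipped, with a
warning.

For opaque vessels, samples drawn at tank ports are dispensed into well
plates and read by camera or colorimeter; the readings enter the same
pipeline as a CSV table (`time_min, location, space, c1, c2, c3`).

The final reference supports the two conventions found in practice — a
single designated well-mixed location, or the component-wise mean over all
locations at the final time — because experiments of both kinds exist; the
mode used is recorded on the result. The SD uses the sample ($n-1$)
denominator throughout. Missing readings at a time point are dropped from
that time's mean/SD with a warning rather than imputed: imputation would
manufacture mixedness evidence. Trend curves are least-squares polynomials,
degree 2 by default, the customary smooth for these gently curved
trajectories.

## Rheology

The suspensions follow, approximately and piecewise, the Ostwald–de Waele
power law $\eta = K\gamma^{\,n-1}$ with consistency index $K$ (Pa s$^n$)
and behavior index $n$. Fitting is by ordinary least squares on
$\ln\eta = \ln K + (n-1)\ln\gamma$, per user-supplied shear-rate segment —
breakpoints are an experimental judgment (regime changes visible in the
flow curve), so automatic detection is deliberately out of scope.
Independently fitted neighbours need not join at a breakpoint;
`piecewise_viscosity()` therefore reports the jump magnitude instead of
hiding it. Classification uses a Newtonian tolerance of $|n-1|\le 0.05$ by
default: published tables label $n = 1.0000$ rows Newtonian without stating
a tolerance, and 0.05 separates those rows cleanly from the clearly
thinning ($n \approx 0.53$–0.68) and thickening ($n \approx 2.1$) ones.
Evaluation outside a segment's fitted range warns but proceeds, because
tank-shear discussions routinely extrapolate below the rheometer's lowest
point. Two maximum-shear scalings with agitation speed are provided
(`33.1 N^{1.4}` and `prefactor · N^{1.5}`); the literature uses both and
they disagree by ~25% at 16 rev/s, so the package computes either and
records the mode, guessing no intent. A ten-segment published parameter set
for blue maize suspensions ships as `blue_maize_segments()` for round-trip
tests and examples.

## The synthetic experiment generator

No public dataset pairs vessel images with ground-truth pH fields, so the
package generates its own experiments. The model is deliberately minimal —
each grid cell relaxes first-order toward the set point,

$$\mathrm{pH}(c, t) = \mathrm{pH}_f + (\mathrm{pH}_0(c) - \mathrm{pH}_f)\,
  e^{-t/\tau(c)},$$

which is the simplest dynamics producing the observed approach curves; no
fluid mechanics is implied. Three patterns set $\mathrm{pH}_0$ and $\tau$
per cell:

* `uniform` — an ideally stirred excursion (all cells `ph_init`, time
  constant `tau`);
* `top_bottom_layers` — the top half starts at `ph_init` and relaxes with
  `2·tau`, the bottom half starts halfway to the set point with `tau`:
  the classic top–bottom segregation of concentric agitation, where the
  upper third mixes last;
* `stagnant_spot` — one cell pinned near strongly alkaline pH with
  `50·tau`: the high-viscosity pocket left by a badly placed base
  injection.

Defaults are chosen once to represent a realistic bench experiment: a 4×4
grid read at 13 time points over 13 minutes (denser early, when color
changes fastest); an acid-to-base excursion 3.3 → 10.6, inside the
indicator's valid range; `tau = 1.5` min, i.e. visually homogeneous within
a few minutes and essentially converged by 13, consistent with reported
mixing times for well-configured stirred tanks at this scale.

pH maps to color by component-wise linear interpolation of a calibration
table in Lab. The bundled `default_calibration()` anchors are **synthetic
stand-ins** (real calibrations are plotted in the literature but never
printed as numbers): six Lab points at pH 1.6, 3.3, 5.6, 8.0, 10.6, 11.6
following the anthocyanin hue sequence pink → magenta → violet → blue →
blue-green → green, constructed so that every anchor and interpolant lies
inside the sRGB gamut, distances to the pH 10.6 anchor decrease strictly
(the valid excursion), and the continuation to pH 11.6 violates
monotonicity (the documented failure of the wide range).

Rendering paints each cell as a uniform block and adds Gaussian noise *per
cell, channel and frame* in RGB before clipping to gamut — emulating
well-to-well illumination heterogeneity, which is the dominant reported
error source and is spatially coherent (an entire well shifts together, so
window averaging within a cell does not reduce it). The default SD of
0.005 on [0, 1] channels (≈ 1.3 of 255) keeps replicate scatter small
relative to pH-driven color differences, the regime reported for
photographs under controlled indirect lighting. Clipped values are
counted and reported. Every stochastic output is a pure function of
(config, seed); frames, ground truth and the filename→minutes map are
written as plain PNG/CSV/JSON.

What the generator does *not* emulate: advective structure within a cell
(cells are uniform blocks), camera motion and perspective, specular
highlights, the coupling of pH to viscosity and hence to the mixing rate
itself (a real confound of pH-indicator experiments, acknowledged and
deliberately omitted — adding it would require the fluid-dynamics model
this package intentionally avoids). Passing tests on synthetic scenes
therefore validate the *analysis chain*, not any claim about real tank
hydrodynamics.

## Numerical choices and degenerate inputs

* Gamut handling: Lab → RGB clips out-of-gamut channels and warns
  (rendering counts clips silently, since noise clipping at gamut edges is
  expected and logged in aggregate).
* `validate_distance_sequence` on a single point is trivially valid; empty
  trajectories are rejected.
* A single location makes `sd_D` undefined: reported as `NA` with a
  warning, never 0.
* Duplicated `(time, location)` rows are an error (they would silently
  bias the mean), as are mixed color spaces within one table.
* Trend fits require at least `degree + 1` points; otherwise the fit is
  refused (pipelines skip it with a message rather than failing the run).
* Log–log regression rejects non-positive viscosities or shear rates
  before the transform.
* Breakpoints must fall strictly inside the data's shear range; a boundary
  observation belongs to the left segment (intervals are
  $(b_{k-1}, b_k]$).

## Problem sizes

The test suite and the acceptance script run entirely on generated data at
bench scale: 4×4 grids × 13 frames for scene-level checks, 16–64 px cells,
50-point rheometry curves per segment, and 100–1000-case randomized
property checks. These sizes were chosen as representative of the actual
experiments the package targets (sixteen image sections, five tank ports,
tens of rheometer points); all results in the README were produced at
these sizes.

## Known limitations

* Distances are plain Euclidean ΔE in Lab (or HSB/RGB analogues); no
  ΔE2000 or other perceptual refinements, which the underlying method does
  not use.
* The fixed D65/2° sRGB chain is a convention, not a calibration; absolute
  Lab values from different instruments may differ by more than the
  round-trip error even when distances behave identically.
* The relaxation generator cannot produce non-monotone *true* mixedness
  (e.g. transient over-shoot of a plume past its target pH); validity
  failures must come from the color map, as they do in reality.
* Piecewise power-law fits describe flow curves only within the fitted
  shear ranges; zero-shear plateaus and yield behavior are out of scope.
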