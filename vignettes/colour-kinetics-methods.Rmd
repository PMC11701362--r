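---
title: "Methods: multi-well colour kinetics from video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-well colour kinetics from video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wellkinetics)
```

## Scientific model

A fixed camera observes a plate of reaction wells. Each frame is an
H × W × 3 array of 8-bit sRGB values; at `fps` frames per second, frame
*i* corresponds to time *t = (i − 1)/fps*. For every well we average the
pixels inside a circular region of interest (ROI) and convert the mean
colour to CIE-L\*a\*b\*:

1. decode 8-bit sRGB to linear RGB with the IEC 61966-2-1 transfer
   function (linear segment below 0.04045, exponent 2.4 above);
2. map linear RGB to CIE XYZ with the sRGB/D65 primary matrix;
3. apply the CIE-L\*a\*b\* compression with the D65 2° white.

The reference white is taken as the matrix image of RGB white (the row
sums of the sRGB→XYZ matrix) rather than a rounded published value, so
pure white maps to exactly (100, 0, 0) and conversion error is dominated
by floating point, not by truncated constants.

Colour contrast over time is the CIE76 difference against the well's own
first frame,

$$\Delta E(t) = \lVert \mathrm{Lab}(t) - \mathrm{Lab}(t_0) \rVert_2 ,$$

a Euclidean metric in Lab space. CIE76 (not CIEDE2000) is deliberate:
the quantity of interest is *relative change within one well over time*,
where the metric axioms (identity, symmetry, triangle inequality) matter
more than perceptual uniformity across distant colours.

## Averaging order

Pixels are averaged in RGB **before** conversion (`average = "rgb"`,
the default) because camera noise is approximately additive in sensor
space, so the mean of many pixels is a low-noise estimate of the true
well colour; converting that single mean is cheaper and less biased than
converting every noisy pixel through the nonlinear transfer function and
averaging after. `average = "lab"` is available for comparison.

## End-point detection

The plateau rule operates on the smoothed ΔE trace:

1. smooth with a centred moving average (`smoothing_window`, default 25
   frames; the window shrinks symmetrically at the edges so no samples
   are discarded);
2. differentiate with central differences (one-sided at the ends),
   giving a rate in ΔE·s⁻¹;
3. *activation*: the rate must first reach `gradient_threshold`
   (default 0.05 ΔE·s⁻¹) — a trace that never moves has no end point;
4. the end point is the earliest time after activation where the rate
   falls below the threshold and **stays** below for at least
   `persistence_s` seconds (default 10 s). A sub-threshold run truncated
   by the end of the recording does not count, so an unfinished reaction
   reports `NA` rather than a spurious end point.

`NA` therefore always means "no plateau observed", and it propagates as
an empty field in the CSV summary.

Induction time is, by default, the time of maximum absolute smoothed
rate (`mode = "max_rate"`); `mode = "threshold"` instead reports the
first threshold crossing. Note one subtlety verified in the tests: for a
programmed logistic trajectory the *R-channel* rate peaks exactly at the
programmed midpoint, while the ΔE profile is a nonlinear (RGB→Lab) image
of the trajectory, so its rate peak sits a second or two off the
midpoint. When you need the kinetic midpoint itself, measure it on a
channel that carries the chemistry linearly.

Area under the ΔE curve (trapezoidal, via `pracma::trapz`) summarises
slow monotone processes such as settling suspensions, where no plateau
rule applies but "how much contrast for how long" discriminates samples.

## Linking to off-line measurements

`rank_parameters()` ranks the ten colour channels (R, G, B, L, a, b, H,
S, V, ΔE) by mutual information with an external series (e.g.
chromatography concentrations) interpolated onto the frame clock. MI
uses equal-frequency (rank) binning with ⌈√n⌉ bins and the plug-in
estimator in nats. Design choices worth knowing:

* a constant channel has MI 0 by definition (the rank-based binning
  would otherwise spread ties uniformly and report spurious MI);
* the estimator is invariant under strictly *increasing* transforms of
  either variable at any n; invariance under negation is exact only when
  the bin count divides n, because rank reversal maps the
  equal-frequency partition onto itself only then;
* the plug-in estimator is biased upward for independent data (about
  (b−1)²/(2n) nats); the ranking normalises by the maximum so this bias
  cancels for the purpose of ordering channels.

`linear_fit()` provides the companion calibration line with r² computed
directly from residuals.

## Glare diagnostics

Specular glare injects near-white pixels into a well. `glare_scatter()`
plots every ROI pixel in the (L\*, b\*) plane and reports the centroid
and RMS dispersion about it; glare pixels are far from the body of the
sample colour, so dispersion rises strictly when glare is present, and
the scatter shape localises which wells are affected.

## The synthetic plate

`plate_video_spec()` + `plate_frame_source()` render a plate whose
per-well colour follows a programmed mixing curve between a start and an
end colour: constant, first-order decay (with optional lag), logistic,
step, or a clearing-turbidity decay with adjustable amplitude. Gaussian
pixel noise is optional; frames are seeded deterministically per frame,
so streaming access and in-memory rendering are bit-identical and a
given seed always reproduces the same video. `analytic_summary()`
evaluates the same plateau/induction/AUC definitions on the dense
closed-form curve, giving ground truth that shares no code path with the
measurement pipeline.

What the generator emulates: well geometry, frame clock, sensor noise,
8-bit quantisation, specular glare disks (painted over the sample,
as real glare is). What it does not: illumination drift, camera motion,
lens distortion, shadows, or inter-well optical cross-talk.

**Quantisation vs noise.** On a *noiseless* 8-bit render the well mean
is a staircase: near the 0.05 ΔE·s⁻¹ threshold the mean changes by whole
counts only every few seconds, so the gradient crossing locks onto
staircase steps and frame-level end-point recovery is physically
impossible. Two regimes are therefore tested: exact recovery (within a
frame or two) on unquantised renders, and realistic recovery on noisy
quantised renders, where the noise dithers the quantiser and spatial
averaging over ~700 pixels per well restores sub-count resolution. In
the noisy regime the smoothing window should be noise-matched: the
gradient noise scales like sd(mean ΔE)/(window · Δt), so a 20 s window
at 5 fps (101 frames) keeps the rate noise well below the threshold.

## Limitations

* No video-container decoding: supply numbered PNG/TIFF frames (e.g.
  extracted with ffmpeg) plus the frame rate.
* Row labels cover A–Z, so grids are limited to 26 rows.
* The plateau rule assumes a monotone approach to equilibrium; strongly
  oscillatory kinetics need a different end-point definition.
* The MI estimator is for ranking, not for unbiased information
  estimates; do not compare raw nats across different n.
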