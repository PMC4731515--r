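---
title: "Quantifying endosome dynamics in root hairs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying endosome dynamics in root hairs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endodance)
```

This vignette documents the models behind `endodance`, the parameters
that matter, the design choices where the design was genuinely open,
and what the synthetic validation does and does not demonstrate about
real microscope data.

## The measurement problem

Root hairs grow at their tip (about 2 µm/min for a healthy hair) while
endosomes stream through them. Two populations behave differently:
small early (TGN-associated) endosomes move mostly in straight
constant-speed excursions at up to ~9 µm/s, while larger late
endosomes (multivesicular bodies) alternate go phases (~5.5 µm/s) with
stops, and additionally interact in pairs — *dancing* (transient
synchronized co-movement at sub-micrometre range without fusion) and
*clustering/fusion* (a merge with a lasting increase of summed
fluorescence). The quantities of interest are therefore: per-marker
maximum speeds, the continuous/discontinuous composition of movements,
apparent organelle sizes near the diffraction limit, interaction event
rates per root-hair zone, and the hair's own growth rate.

No public raw movies accompany these figures, so the package pairs the
analysis with a generator that produces movies with known ground truth
at the published acquisition settings; every analysis stage is then
validated as a parameter-recovery problem.

## The synthetic root hair

The hair is a tube of radius 4 µm (default) along the x axis capped by
a hemisphere; stages differ by shank length (bulge 2 µm, growing
40 µm, mature 80 µm) and by tip advance (1.941 µm/min for the growing
stage, matching the reference line's measured elongation). Single
particles move in one of two kinds:

* **continuous** — go steps of length exactly `v·dt` whose direction
  wobbles to keep the particle near its lane; the particle reflects at
  the shank ends. Confinement to the cylindrical shank keeps wall
  reflections length-preserving.
* **stop_and_go** — alternating go and stop phases with durations
  drawn Uniform(0.5 τ, 1.5 τ) (defaults τ_go = τ_stop = 1.5 s). The
  uniform law (rather than, say, exponential) bounds the longest go
  run by 1.5 τ_go · v ≈ 12 µm, which keeps stop-and-go tracks below
  the 15 µm continuous-classification criterion *by construction* —
  the class mixture is then exactly the configured fraction.

Individual speeds are drawn from a normal distribution centred on the
marker's population speed with the reported between-particle spread
(e.g. 8.7 ± 1.1 µm/s for the fastest early marker). This matters
beyond realism: if all particles shared one exact speed, any two
co-moving particles would be perfectly "synchronized" and could
masquerade as a dancing pair.

Mixture assignment is deterministic: `round(continuous_fraction · n)`
particles are continuous, pairs are carved from the remainder, the
rest are stop-and-go — so mixture recovery can be tested exactly.

**Dancing pairs** share a centroid that travels ballistically at a
drawn 0.6–1.1 µm/s, confined to a ~10 µm stretch of the hair (dancing
endosomes travel short distances; confinement also keeps distinct
pairs from wandering into each other). The pair separation rests at
3 µm, closes at 4 µm/s to the 0.8 µm equilibrium, follows an
Ornstein–Uhlenbeck relaxation (relaxation time 2 s, stationary
separation SD ≈ 0.15 µm) for a duration drawn Uniform(10, 35) s, and
reopens at 4 µm/s. The fast approach/departure keeps the detector's
2 µm crossing within ~0.3 s of the true window boundary, so recovered
durations are comparable to the scripted ones at sub-second accuracy.
The strength of synchrony is not quantified in the literature; the
generator's choice (common ballistic centroid plus 0.01 µm independent
jitter) makes pairs distinctly synchronized, which is how the
phenomenon is described.

**Cluster/fusion pairs**: one particle rests while the second
approaches from 4 µm away at the go speed; at the fusion time both end
and a product particle continues with intensity exactly the sum of the
members (fluorophore conservation) and diameter `(d1³+d2³)^(1/3)`
(volume conservation; only size/intensity increase is documented, so
volume conservation is the package's choice). Fusion times are
staggered across the movie and sites are spaced along the hair so
events remain individually attributable.

Per-particle intensities are lognormal (meanlog 0, sdlog 0.3) — the
real intensity distribution is unreported; this gives a realistic
~2.5× bright-to-dim range. Apparent diameters are normal per marker
(early 197 ± 20.7 nm; late 336.2 ± 72 / 339.7 ± 79 nm), truncated at
60 nm. "Apparent diameter" always means the *measured FWHM* with the
PSF folded in, because that is how sizes near the diffraction limit
are reported.

## The optical model

Movies are rendered at 0.26 µm/px and 0.1 s/frame (the documented
spinning-disc calibration). Each particle is a 2-D Gaussian whose FWHM
is `max(psf_fwhm, apparent_diameter)` with PSF FWHM defaulting to
0.25 µm (≈ the diffraction limit of the NA 1.2–1.57 objectives used
for this kind of imaging). The Gaussian is integrated over each pixel
area — what a camera pixel does — which conserves photons and the
centroid exactly; noise is Poisson on (background + signal) plus
Gaussian read noise (background 10 photons/px, read noise 2 photons
RMS). The photon scale (photons per unit ground-truth intensity) is
100, chosen so that the *peak-pixel* signal-to-background-noise ratio
is ≈ 10 at unit intensity under pixel integration; at this sampling
(PSF ≈ 1 px) roughly 40 % of a spot's photons land in its central
pixel. Time is continuous internally and sampled at frame times (no
motion blur); z-sectioning is emulated by single-plane simulation.
The rendered field of view extends 1 µm beyond the hair on all sides
so that particles bouncing off the walls never enter the detector's
border margin.

SIM-like frames are rendered at 25 nm/px with a 100 nm PSF,
noise-free by default (reconstructed SIM images are effectively
noise-averaged). Early endosomes are Gaussians whose FWHM *is* the
apparent diameter. Late endosomes are thin circular shells convolved
with the PSF; the shell radius is calibrated numerically (a tabulated,
interpolated inversion of the analytic angular-integral profile) so
that the outer-extent FWHM of a line profile through the centre equals
the requested apparent diameter. Rings below the PSF resolution are
rendered as PSF-limited spots and flagged unresolvable.

## Detection

Frames are min-max normalized to the 8-bit range and band-passed by a
two-scale Difference of Gaussians with scale ratio √2; the two
Gaussian FWHMs average to the blob diameter (σ₁ = 2d/((1+√2)·2.355) ≈
d/(2√2) for the conventional `dog_diameter = 1.5 px`). The response
carries 8-bit gray-level units; local maxima above `dog_threshold` are
non-maximum-suppressed within one blob diameter (ties broken in
row-major scan order) and refined by a quadratic fit to the 3×3
response neighbourhood (bounded at ±0.5 px). Spot intensity is the
background-subtracted photon sum in a 7×7 px window.

Two defaults deserve comment:

* The conventional 3×3 **median pre-filter** is available (and on by
  default in `detection_params()`, matching standard particle-tracking
  settings) but the pipeline turns it off: at 0.26 µm/px the PSF is
  narrower than one pixel, and a 3×3 median erases a one-pixel spot
  almost completely.
* The **threshold units** for the conventional "threshold 2" are
  ambiguous in the field; here the threshold lives on the 8-bit DoG
  response. The pipeline default (`dog_threshold = NULL`) estimates a
  per-frame robust noise floor, median + 4 MAD of the response, which
  at SNR ≈ 10 rejects noise maxima at ≲ 0.5 false spots/frame while
  detecting ≳ 85 % of spots of median brightness.

Diameters come from seeded watershed-style region growing
(`EBImage::propagate`) on an Otsu-thresholded frame; the diameter is
the equivalent-circle diameter of the spot's region. Near the
diffraction limit these are apparent sizes — the SIM route is the one
validated for size recovery.

## Tracking

Frame-to-frame linking solves the gated assignment problem exactly
(Jonker–Volgenant with dual potentials, validated against exhaustive
enumeration): links cost squared displacement, births/deaths cost the
squared gate, and links beyond `max_displacement` are forbidden. Gap
closing joins track ends to later starts (gap ≤ `max_gap`, gate
scaled by the gap length) greedily by ascending displacement —
optimality matters for the frame-to-frame step where the oracle test
lives, while gap closing is a cheap repair pass; interpolated spots
are flagged and excluded from intensity-based analyses. The pipeline
uses `max_gap = 2`: at SNR ≈ 10 single- and double-frame dropouts of
dimmer particles are common and, unbridged, fragment the trajectories
on which movement classification depends. Tracks shorter than 5 µm
path length are excluded (the standard trajectory filter; path length
rather than net displacement, with a switch). The pipeline gates at
1.2 × (mean speed + 2 SD) × frame interval so the fast tail of the
individual-speed distribution still links frame to frame.

Maximum speed per track uses the same estimator as the kymograph
ridges: the track's arc-length position below the tip is segmented
piecewise-linearly (greedy growth while the least-squares residual
stays below 1 px RMS-equivalent) and the steepest segment slope wins.
A trajectory is its own kymograph ridge in (distance, time) space;
applying one estimator to both keeps the speed scale consistent and
averages localization noise over whole go phases instead of
amplifying it frame pair by frame pair, which is why the noisy
per-frame `speed_profile()` maximum is not used for reporting.

## Kymographs and movement classification

`build_kymograph()` samples intensity along a polyline (1 px steps,
bilinear interpolation, perpendicular averaging for widths > 1 px),
one column per frame. Ridges are per-column local maxima above a
median + 4 MAD floor, linked greedily across columns (jump limit 6 px
per column, gaps up to 2 columns). The historical practice of reading
steepest slopes off kymographs by eye is replaced by piecewise-linear
ridge fitting; the estimator is exact to discretization error on
noise-free single ridges in the 0.5–10 µm/s range.

A kymograph (or track) is classified **continuous** when some segment
is both straight (residual < 1 px RMS) and at least
`continuous_min_length = 15 µm` in spatial extent — the permissive end
of the conventional 15–20 µm criterion, interpreted as *ridge extent*
(the criterion's reference to line length vs. ridge length is
ambiguous; ridge extent is the measurable choice). For population
fractions, only *classifiable* tracks — path length ≥ the criterion
length — enter the denominator: a 6 µm trajectory cannot possibly
exhibit a 15 µm run, and counting such fragments as "discontinuous"
would bias the recovered fraction far below the true mixture whenever
detection dropouts fragment tracks.

## Interaction detection

**Dancing**: for each overlapping track pair, maximal windows with
distance ≤ `d_dance` (2 µm) are screened for displacement synchrony —
the pooled Pearson correlation of displacement vectors taken over a
0.3 s lag (three frames at 0.1 s). Single-frame displacements at this
frame rate are dominated by localization noise (~0.03 µm against
~0.08 µm of true motion), which would dilute the correlation of a
genuinely tethered pair below any useful threshold; the 0.3 s lag
restores the common-motion signal without blurring window boundaries.
A window qualifies when synchrony ≥ 0.5, duration ≥ 5 s (deliberately
below the observed 10–35 s range so that the range is a *measured*
output), and the pair approaches within `d_interact` (1 µm) at some
time; a physical-interaction flag additionally marks ≥ 1 s spent
below 1 µm. Windows whose combined intensity shows a sustained
(≥ 20 s) increase are routed to clustering/fusion — intensity increase
alone, without proximity, never defines dancing here.

**Clustering/fusion**: a track ending within 1 µm of a track that
continues (or starts) at the next frame is a merge candidate; it is
accepted when the continuing track's intensity matches the summed
pre-merge member intensities within ±30 % and the increase is
sustained for ≥ 20 s. Pre-merge intensities are medians over ~3 s
before the merge excluding the last second, where the members' 7×7 px
measurement windows already overlap. The reported `intensity_ratio`
normalizes the product intensity to the first member. The 20 s
persistence requirement is what separates fusion from transient
(kiss-and-run-like, ~5 s) co-localizations. When a track appears in
both a dancing and a fusion event, fusion takes precedence.

Events are assigned to the apical zone (first 10 µm below the tip) or
subapical zone by their start position; the countable population is
the number of spots in the first frame within the 30 µm tip-ROI.

## Validation: what passes, and what it shows

The acceptance experiments (`speed_recovery`,
`movement_class_recovery`, `size_recovery`, `dancing_recovery`,
`fusion_recovery`, `growth_rate_recovery`; run via
`scripts/acceptance.R`) use: 20 particles across four 200-frame movies
for speeds; 50 particles across five movies for class fractions
(mature-stage hairs — where speeds and movement classes are
conventionally measured, and long enough to keep spot density in the
regime where assignment identities are reliable); 76 early / 62 late
particles for SIM sizing; 50 scripted dancing and 30 fusion events
(track-based, with 0.03 µm localization noise — the image chain is
exercised by the speed and class experiments); and 21 tip positions
at 60 s for growth. On one CPU the full acceptance run takes about
two minutes, and the recovered values sit well within the stated
bands (speeds within ~5 %, class fractions within ~8 points, sizes
within ~2 %, dancing recall/precision ≥ 0.95, growth within 0.5 %).

What this does *not* show: the generator's hair is straight, the
cytoplasm has no organelle crowding or autofluorescent texture,
photobleaching and focus drift are absent, intensities are stationary,
and motion is strictly 2-D — so real movies will fragment more, and
watershed diameters on diffraction-limited frames remain apparent
sizes. The validation demonstrates that the *estimators* are unbiased
and correctly calibrated under the stated optical statistics, not that
real root-hair data will reach the same accuracies.

## Numerical notes and degenerate inputs

Flat frames detect nothing; featureless kymographs yield a missing
maximum speed; empty populations flow through the whole pipeline and
produce empty tables. Equal-quality detection maxima are ordered by
row-major scan position. The sub-pixel quadratic fit is clamped to
±0.5 px. `fwhm_profile()` rejects flat or saturated profiles (no
clean half-maximum crossing) rather than guessing, and measures
background from the profile endpoints. All randomness is seeded;
identical seeds give bit-identical ground truth, movies and reports,
and the RNG state of the calling session is restored afterwards.
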