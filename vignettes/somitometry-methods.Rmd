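---
title: "Quantifying somitoid organoids: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying somitoid organoids: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somitometry)
```

Somitoids are stem-cell-derived organoids that sequentially bud somite-like
epithelial blocks from a presomitic-mesoderm (PSM) tail, timed by the human
segmentation clock (HES7, period around five hours). Quantifying them means
answering four questions from images: how many somites are there and how big
are they; where do the lineage domains (neural, somite, PSM,
neuromesodermal-progenitor) sit in 3-D and how large are they; how fast does
the clock tick and do its waves travel posterior to anterior; and where along
the body does the first somite form. This vignette explains how each of those
measurements is implemented, which knobs matter, and what the synthetic-data
generator does and does not emulate.

## Segmentation

Bright-field or nuclear-stain images are resampled to an isotropic 1 µm/px
before anything else, because the cleaning parameters are pixel-denominated
at that scale. Binarization is a global histogram threshold — Otsu, triangle
or Yen on a 256-bin histogram, foreground strictly above the threshold (ties
go to background, so adding a constant to an image moves the threshold by
exactly that constant and changes nothing else). The three algorithms are
implemented on one shared histogram code path so the same functions serve
2-D images and whole 3-D stacks; the Otsu variant is cross-checked against
EBImage's implementation in the test suite.

Which algorithm suits an image depends on its histogram: Otsu for cleanly
bimodal ones, triangle for heavy-tailed unimodal ones with dim foreground.
`select_threshold_method()` automates that judgement with a candidate
comparison — all three masks are computed and the one with the smallest
boundary-length-to-area ratio wins, on the reasoning that a correct
segmentation of a compact tissue has a compact boundary while over- and
under-thresholding produce ragged or speckled masks. The choice is
deterministic and always overridable; hand-corrected masks can be supplied
wherever a computed mask is accepted.

Mask cleaning applies, in fixed order: fill interior holes smaller than
10000 px, remove foreground components smaller than 10000 px, then open
with a disk of radius 5 px. The size rule is strict (`< 10000`): a 9,999-px
speck is removed, a 10,000-px one survives. Hole filling is ordered before
debris removal; on any mask whose holes and debris are disjoint regions —
which is every realistic case — the two orders commute, so the choice is a
documented convention rather than a behavioural fork. Opening is last
because it can split thin bridges, and the split remnants should still be
visible to the caller; cleaning is idempotent on every fixture we generate
and never increases the component count.

## Midline and width-profile morphometry

The somite caller works on a width profile measured perpendicular to the
body's posterior→anterior midline:

1. **Ridge points.** The Euclidean distance transform (EDT) of the cleaned
   mask is computed and its local maxima extracted. Along a tapering body
   the EDT grows slowly toward the wide end, so exact discrete maxima are
   sparse; a point qualifies when its EDT is within half a pixel of its
   8-neighborhood maximum. That keeps the set of points within about half a
   pixel of the medial ridge (where the EDT gradient vanishes) while
   excluding off-ridge points, whose EDT falls by roughly one pixel per
   pixel. Maxima shallower than 5 µm are discarded — those are medial-axis
   spurs thrown off by residual boundary raggedness. The resulting cloud is
   dense along the body but essentially one cluster per somite center,
   because inside a ball the EDT rises steeply toward the center.

2. **Ordering.** The cloud is chained by greedy nearest-neighbour walking
   from the point closest to the user's posterior anchor; points never
   reached are dropped as outliers. The capture radius is 3× the median
   nearest-neighbour distance, floored at 80 µm so the chain can bridge the
   point-free stretch across a somite interior (up to ~70 µm for the
   largest somites). Anchors are manual by design, as in the underlying
   protocol, and are prepended/appended so the curve spans tip to tip.

3. **Spline.** A cubic smoothing spline is fitted per coordinate against a
   chord-length parameter. The smoothing value 10000 µm² is a residual
   budget: the fitted curve is the smoothest one whose total squared
   residual stays within it. Because a residual budget only means something
   at a fixed sampling density, the chain is resampled to 0.5 µm spacing
   before fitting; the penalty is then found by bisection on the spline's
   smoothness parameter. Two robust trimming passes guard the fit: points
   farther than 25 µm from a maximally smoothed reference curve are
   discarded first (this is what keeps the midline on the central axis for
   bilaterally paired strings, whose medial axis branches symmetrically to
   the two off-axis somite centers), then points more than 10 µm from the
   budget fit are dropped and the spline refitted once. The 25 µm pre-trim
   is about half the smallest somite radius and must exceed the amplitude
   of genuine midline curvature — bodies more strongly bent than that need
   a larger value.

4. **Width profile.** At 1 µm arc-length steps, rays are cast along ± the
   local normal until the bilinearly interpolated mask drops below one
   half; the crossing is located by a coarse 1 µm march refined at 0.1 µm
   over a three-step window (a grazing boundary can dip below the half
   level briefly and re-enter before the definitive exit, so the
   refinement window must reach back past the first coarse outside
   sample). Width is the sum of the two ray lengths; rays that leave the
   image are truncated and flagged. The implementation is held to within
   one pixel of an exhaustive fine-step scan at every sample in the
   acceptance suite.

5. **Extrema and calls.** Minima of the profile are somite boundaries,
   maxima somite widths. Candidates must clear a prominence of 10 µm and a
   mutual separation of 40 µm — the separation is about one third of the
   smallest measured somite width (104 µm), and the prominence is far below
   the somite-to-neck contrast yet above measurement roughness. Neither
   value is stated in the source protocol; both are overridable. Because
   inter-somite necks are flat over tens of micrometres, each extremum is
   refined to the midpoint of the contiguous region within 2 µm of its
   extreme value, which keeps boundary positions from wandering along the
   plateau under noise. Extrema within the separation distance of the
   profile ends are discarded.

   A somite call needs a maximum bracketed by two minima; the posterior
   body (NMP + PSM) is therefore never called, since its width maximum has
   no posterior bounding minimum. The anterior-most somite usually lacks an
   anterior minimum because the profile simply ends there; it is recovered
   with a virtual boundary where the profile first falls below 25 % of its
   peak width (or at the profile end) and flagged `end_capped` — without
   this rule the oldest somite would silently vanish from every analysis.
   Somites are indexed from the posterior (index 1 = newest), following the
   posterior→anterior narrative of somitoid morphometry.

6. **Shape statistics.** The protocol derives somite area and circularity
   from the inter-somite distance and width alone, without stating the
   formula; we model the somite outline as an ellipse with those axes:
   area = πLW/4, circularity = 4π·area/perimeter² with Ramanujan's
   perimeter approximation (exact enough that the circularity of a 2:1
   ellipse matches numerical quadrature to four decimals). Circularity is 1
   exactly when length equals width, and the statistic is symmetric in its
   arguments. This ellipse model is a declared stand-in and is recorded as
   such in the outputs.

First-somite geometry intersects an annotated left-right (LR) segment with
the midline: the relative position is the arc fraction of the intersection
point from the posterior end (measured somitoids form their first somite
near the 20 % position), and the formation angle is `acos(|n̂·t̂|)` between
the LR-segment normal and the midline tangent — unsigned by convention,
in [0°, 90°], since the source defines no sign.

`region_morphometrics()` provides the generic area / perimeter / axes /
circularity measurements used for cells and whole organoids. The perimeter
is a two-direction Crofton estimate, asymptotically exact for smooth round
shapes; it underestimates polygonal boundaries, so a square's circularity
computes slightly above 1 — the statistic is meant for the rounded shapes
it is used on.

## HCR volumetry

Each channel of a 3-D HCR stack is binarized with one global Otsu threshold
over the whole stack (not per slice — the acquisition is a single volume
and a global threshold is deterministic and order-free). The markers
jointly tile the somitoid, so an artificial sum channel — accumulated in
double precision, so it cannot saturate — thresholded the same way gives
the total reference mask. Volumes are voxel counts times the anisotropic
voxel volume (default Z = 2 µm, XY = 0.391 µm). Lineage domains are Boolean
voxel combinations restricted to the total mask: Neural = SOX2⁺ & BRA⁻,
PSM = BRA⁺ & SOX2⁻, NMP = BRA⁺ & SOX2⁺, Somite = UNCX4.1⁺. The somite
domain is deliberately not made exclusive of the other markers, so domain
fractions may sum above one. Two identities hold exactly in voxel counts by
construction and are asserted as such: Neural + NMP = SOX2⁺ and
PSM + NMP = BRA⁺. Whether the published domain volumes were restricted to
the total mask is not documented; restriction is our declared choice, since
it makes the fractions well defined.

## Segmentation-clock analysis

Reporter movies are registered by translating each frame so the centroid of
its thresholded foreground matches the first frame — a stand-in for the
tissue-alignment step of the original pipeline, whose algorithm is not
published. Registration confidence is the spatial coherence of the
thresholded foreground (mean fraction of foreground 8-neighbours): near 1
for a compact tissue, near the foreground fraction for structureless noise;
frames under 0.6 are flagged. Rotation or scaling drift is out of scope and
will surface as low confidence rather than being corrected.

Kymographs sample each median-filtered frame along a posterior→anterior
polyline with transverse averaging (default ± 20 µm), one row per frame in
temporal order. Traces are detrended by subtracting a centered 50-frame
moving average, the window used by the original wavelet analysis; the
moving-average filter is simpler than a wavelet detrender and fully
specified, at the cost of a known transfer function — oscillations with
periods approaching or exceeding the window are partially attenuated by
the analytic factor `1 − sin(Nπ/P)/(N sin(π/P))`, which the tests verify
directly. Imaging gaps up to 3 frames are linearly interpolated; longer
gaps split the trace into independently analyzed segments.

Phase is the analytic-signal (Hilbert) phase of the detrended trace,
unwrapped; on clean oscillations its slope recovers the period to within a
few percent, and the tests hold the peak-based and phase-based estimates to
within one frame of each other. The peak-to-peak period detects peaks and
troughs under a prominence constraint (0.3× the trace SD) and a minimum
distance (half the coarse period from the dominant FFT bin); for detection
the trace is first smoothed with a short centered moving average, about a
sixth of the coarse period, so frame-to-frame noise cannot jitter the
located peak positions — a symmetric smoother leaves the peaks of a clean
oscillation exactly in place. The reported period is the mean successive
peak interval with its SD and count.

Wave direction is measured as the circular-mean phase difference between a
posterior and an anterior region of the kymograph, converted to minutes via
the period; positive lag means the posterior leads, i.e. a
posterior→anterior traveling wave. The phase difference is defined modulo
one cycle, so the regions must sit within half a spatial wavelength of each
other — the natural usage, comparing adjacent posterior and anterior PSM
regions. Somite-formation periods come from annotated event times as mean
successive intervals; when the clock drives segmentation, one somite forms
per oscillation cycle and the two periods agree within a frame, which is
exactly what the event-coupled synthetic movies reproduce.

## The synthetic-data generator

Every analysis stage is validated against seeded synthetic data with known
ground truth, because the published headline numbers are measurements of
specific experimental images that cannot be regenerated from a desk. The
generator emits:

* **Somitoids** — a tapered capsule body (default 300 × 150 µm, posterior
  tip at half width) continued by a string of ball-like somites (default
  8 somites of 110 µm diameter, the measured paired-somite size; the
  single-somite regime up to ~160 µm is covered by the validation sweeps)
  joined by a 60 µm neck, with 10 µm inter-somite gaps so the width-profile
  minima are well defined; straight or sinusoidal midlines (default
  amplitude 15 µm, wavelength 700 µm — gentle curvature of the kind real
  somitoids show); two-level intensities with additive Gaussian noise
  (default SD 30 at a foreground–background contrast of 180, i.e. SNR 6;
  validation sweeps go down to SNR 3). Diameters can be graded along the
  string to emulate the posterior→anterior growth of somite size.
* **HCR stacks** — a spherocylindrical body with a double-positive
  posterior cap, a BRACHYURY band, anterior UNCX4.1 spheres (or a full
  band, in which case the channels tile the body exactly) and a dorsal
  SOX2 slab, at the instrument voxel size.
* **Clock movies** — `baseline + drift·t + A·cos(2π(t/period − x/λ))`
  inside a tissue band (default period 300 min, frame interval 10 min),
  with the wave direction set by the sign of λ and optional somite events
  locked to successive peaks at an anterior read-out position.
* **Event series** — jittered periodic times.

Identical spec and seed give bit-identical output. What the generator does
*not* emulate: point-spread functions, photobleaching, Poisson photon
statistics, cell-scale texture, or tissue deformation over time. Passing
the recovery suites therefore shows the algorithms are correct and
noise-robust in the additive-Gaussian regime, not that they are immune to
every real-microscopy artifact; the mask-override inputs exist precisely
because real data sometimes needs a manual fix.

## Validation problem sizes

The packaged checks run the full pipeline on 20 seeded somitoids spanning
5–10 somites and 90–160 µm diameters (count recovery, and width/spacing
errors, which land well under 5 µm); hold the width profile to within 1 px
of an exhaustive scan on 20 further masks; keep midline RMS error under
2 µm on straight and sinusoidal bodies; recover noiseless HCR domain
volumes exactly and a rasterized 50-µm sphere within 0.02 %; and recover
periods, wave-lag signs and event coupling on 90–120-frame movies. These
sizes were chosen so the whole validation runs in a few minutes while still
spanning the measured somitoid regime.

## Known limitations

* Automatic midline extraction assumes a single (unpaired) somite string;
  the source morphometry had the same restriction. Paired strings are
  supported for row counting — their 2-D projection yields one width
  maximum per pair along the central axis — but a reliable automatic
  midline through a paired string is not attempted; supply the midline (or
  a corrected mask) instead.
* The ellipse area/circularity model and the end-cap rule for the
  anterior-most somite are declared conventions where the source is silent.
* Registration is translation-only; the lag estimate aliases beyond half a
  wavelength; the moving-average detrender attenuates periods comparable to
  its window.
* Plain TIFF I/O relies on caller-supplied pixel sizes; OME metadata is not
  parsed.

```{r example, eval = FALSE}
# end-to-end example on synthetic data
gen <- generate_somitoid(somitoid_spec(seed = 0))
mask <- clean_mask(binarize(gen$image, "yen"))
pts <- midline_ridge_points(mask)
ord <- order_midline_points(pts, gen$truth$anchors$posterior,
                            gen$truth$anchors$anterior)
mid <- fit_midline_spline(ord$points)
prof <- compute_width_profile(mask, mid)
call_somites(prof, find_profile_extrema(prof))
```
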