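---
title: "Tracking and classifying zebrafish larva maneuvers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and classifying zebrafish larva maneuvers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvatrack)
```

# The problem

Zebrafish larvae at 5–7 days post-fertilization swim in a beat-and-glide
style: discrete episodes of tail undulation (bouts) separated by rest. A
high-speed camera above a multi-well dish records dark larvae on a bright,
homogeneously lit background. `larvatrack` turns such recordings into, per
larva and per frame, a core position, a heading axis, a 10-point tail
midline and a signed tail-bending angle; segments the bend-angle trace into
bouts; summarizes each bout with global kinematic parameters and a
curvature kymograph; classifies it as a slow forward swim (S), routine turn
(T) or escape (E); and quantifies the recurrence of maneuvers within and
between larvae with a Markov-chain transition index.

All coordinates are 1-based pixel centres with `dim1 = x` (rightward) and
`dim2 = y` (downward), the convention of the EBImage matrices the package
operates on. Angles increase from +x toward +y.

# Tracking

**Wells.** Wells are bright filled disks on a darker surround. They are
found by thresholding at the intensity midpoint, labelling components, and
keeping round components (99% of pixel radii within 1.25 of the equivalent
disk radius). For filled, well-separated disks this yields the same centre
and radius a voting circular Hough transform would, without the
accumulator.

**Background.** Per well, the background is the pixel-wise *maximum* over
all frames: larvae are darker than the background, so any pixel the larva
vacates at least once recovers its true value. This assumes each larva
moves at least a body length over the recording — true for minutes-long
recordings; short test clips instead pass the known clean background
explicitly (`track_well(background = )`).

**Cores.** The difference image (background − frame) is binarized at a
fixed absolute threshold (default 25 on a 0–255 scale; the recordings are
under controlled illumination, so a deterministic fixed threshold is
preferred over adaptive methods and is exposed in the configuration). A
3×3 erosion applied twice removes the tail; connected components with
area in [0.0871, 0.8712] mm² (20–200 px² at 66 µm/px) are core
candidates. Core positions are difference-intensity-weighted centroids,
which gives sub-pixel localization on anti-aliased imagery.

**Heading.** The heading axis is the principal axis of the central
second-order moments of the eroded core. The axis is made head-forward
with the third-order moment along the axis: the projected pixel
distribution of a head-plus-trunk blob has its long thin tail pointing
toward the trunk, so the heading points opposite the skewness. A
degenerate (isotropic) component keeps the previous frame's heading and is
flagged.

**Identity.** Each larva's position is predicted by constant-velocity
extrapolation from its previous two frames and matched to the nearest
candidate, greedily in increasing distance (ties toward the lower larva
id). Identities in frame 1 are seeded arbitrarily in candidate order. An
unmatched larva carries its state with the validity flag lowered.

# Tail tracking

The full body is the 4-connected component of the *pre-erosion* binary
image containing the core centroid (3×3 fallback if the weighted centroid
rounds onto background). Its outer contour comes from border following
(`EBImage::ocontour`).

The tail tip is selected by the candidate procedure: express the contour
in a frame rotated so the heading is parallel to +y with the head on top;
take A1 = contour point nearest the head centre and A2 = contour point
nearest A1's mirror image across the head axis; candidates are the
contour points with extreme x and y values caudal to A1/A2. For each
candidate, arc distances d1 and d2 to A1 and A2 are counted in contour
steps along the two flanks; candidates with |d1−d2|/(d1+d2) > 0.25 are
excluded, and the most-caudal candidate must additionally satisfy the
0.20 bound (the published description mentions both bounds without fully
resolving their roles; here the soft bound gates the max-y candidate and
the hard bound excludes any candidate — both configurable). Among
survivors the tip is the candidate with the sharpest contour turn — the
largest scalar product of the two unit vectors pointing *away* from the
candidate along the contour, equivalently the smallest scalar product of
the directed tangents before and after it.

The midline averages the two flank arcs (A1→tip and A2→tip, resampled to
equal counts), smooths with a spline (df = 6, chosen to leave ≈0.5 px
residual on 40-point arcs), prepends the head/trunk boundary point (core
centroid shifted one head radius tailward, default 0.40 mm — the
published figures place the first midline point at the head/trunk
boundary without a formula), and resamples to 10 equally arc-spaced
points. A midline whose arc length falls outside [1.32, 3.96] mm is
invalid; the previous frame's tail is carried, as are frames where no tip
candidate survives. The signed bend angle α is the angle between the
tailward heading axis and the head-centre→tip line, positive when the tip
lies counterclockwise from that axis in image coordinates; mirroring the
image negates it. Per-larva traces are gap-filled from the previous valid
frame and median-filtered over 5 frames (≈15 ms at 337 Hz — wide enough
to kill single-frame glitches, narrow enough not to blunt a 25 Hz
oscillation, whose half-period is ≈7 frames).

# Contacts between larvae

Two stages of collision handling:

* **Merged cores** (two larvae predicted onto one candidate, or matched
  candidates < 2 px apart): the merged component is eroded repeatedly
  (3×3, up to 10 iterations) until ≥ 2 components of ≥ 4 px² emerge;
  split centroids are assigned by predicted distance. If the split never
  happens, the frame keeps the *predicted* positions (flagged invalid)
  rather than the stale previous ones — prediction is already the
  matching device, and it keeps the body-separation stage viable.
* **Merged full bodies** (component area > 1.9 mm² holding two head
  centres): with cores closer than 1.32 mm, a cutting line is searched
  over 36 orientations × 1 px offsets along the inter-core axis,
  maximizing the summed area of the two largest components containing one
  head centre each (ties break toward fewer erased pixels); farther
  apart, the binarization threshold is raised in steps of 5 (cap 250)
  until the component splits with one head centre per part — the tail is
  rendered/imaged lighter than the head, so raising the threshold peels
  the overlapping tails apart first. When the line search fails, the
  intensity branch is tried as a backstop before declaring the frame
  unresolved; unresolved frames carry the previous tails.

# Bout detection

A frame is *active* when α deviates by more than 1.15° from the mean of
the ten surrounding frames (five before, five after, excluding the frame,
truncated at boundaries; the deviation test runs on the cleaned trace).
Maximal active runs are candidate bouts; bouts separated by less than
14.8 ms merge (idempotent). Candidates are kept only if the straight-line
core displacement exceeds 0.099 mm, the in-bout bend-angle range exceeds
2.86°, and the eroded-mask symmetric-difference count between consecutive
frames reaches at least 3 px in some frame pair (the published rule fixes
no count; 3 px is exposed in the configuration). Compound maneuvers with
no bend-angle stabilization in between never separate, because the trace
never goes inactive.

# Kinematics

Per bout: duration = frames / frame rate; oscillations = alternating bend
extrema exceeding 5° absolute (a plateau-robust extremum finder; the
threshold suppresses noise extrema and is configurable), divided by two;
TBF = oscillations / duration (the mean rather than instantaneous
definition; instantaneous frequency lives in the classifier features);
heading range = range of the unwrapped heading re-zeroed at onset;
distance = summed per-frame core path length (not net displacement);
speed = distance / duration.

The curvature kymograph fits each midline with cubic splines x(s), y(s)
in arc-length parameterization and evaluates
c = |x′y″ − y′x″| / (x′² + y′²)^{3/2} on 25 arc positions, in 1/mm.
Endpoint derivatives use the spline's end cubics rather than natural
boundary conditions, which would force zero curvature at the tips.

# Maneuver classification

Per bout, with t = 0 at the first bend-angle extremum: |α| sampled on
[0, 178] ms in 12 ms bins (15 samples), instantaneous frequency from
successive alternating extrema (1/(2·half-period), held
piecewise-constant) on [0, 104] ms in 7 ms bins (14), the running mean of
|α| from t = 0 on (0, 178] ms in 12 ms bins (14), and core speed on
[0, 240] ms in 24 ms bins (10) — 53 raw components (this 15+14+14+10
split is the one rounding of the stated windows that reaches exactly 53),
plus the bout duration. Series are spline-interpolated onto the grids;
bouts shorter than a window are padded with the last value and flagged,
not dropped.

The 53 components are z-scored, reduced to the first 14 principal
components, and the z-scored duration is appended. Two linear SVMs
(cost = 1, standardization before PCA — both unstated in the original
description, both exposed) run in cascade: S vs. rest, then T vs. E on
the non-S examples. A decision value of exactly zero goes to not-S
(stage 1) and E (stage 2). The separators are stored as explicit weight
vectors, so a model is a plain JSON file. Because features use |α|, the
classification is invariant to left/right mirroring.

# Interactions

Movements in a well, time-ordered, form a Markov chain. For a pair
(B1, B2), I(B1→B2) = p(second = B2 | first = B1) / p(B2); the marginal is
always taken over all movements of the data set (the windowing applies to
the conditional only). The same-larva variant pairs consecutive movements
of one larva; the different-larva variant pairs well-wide consecutive (or
windowed) movements of distinct larvae. The windowed index bins pairs by
onset-time difference and onset-position distance; cells with fewer than
20 outgoing pairs are masked (a ratio of small counts is unstable).
Window pairing can take all ordered in-window pairs or, with
`successor_only = TRUE`, only each movement's most recent in-window
predecessor.

The permutation test permutes class labels across movements (identities,
times, positions fixed; 50 iterations), recomputes the pair's maximal
index, and compares the observed value to the permutation sample with a
one-sample t-test — the published procedure compares one observed value
to the randomized sample, which this reproduces — plus an exceedance
p-value (1 + #{null ≥ obs}) / (n + 1) as the calibrated alternative. The
t-test can reach arbitrarily small p with 50 permutations but is
anti-conservative; the exceedance p is bounded below at 1/51 but is
uniform under the null. Both are reported.

# The synthetic-data generator

The generator is first-class, tested code; it defines the conditions all
quantitative guarantees are measured under, fixed at the recording
protocol: 337 Hz, 66 µm/px, circular wells, up to 7 larvae, movements at
≈0.45 Hz per larva, class marginals 0.35/0.48/0.16 (normalized — the
printed values sum to 0.99).

*Bend traces* are damped sinusoids per maneuver archetype plus Gaussian
noise, with exact event boundaries; each maneuver ends with a 15 ms
raised-cosine release that brings the tail back to rest (a muscle-
relaxation timescale), so a bout's activity genuinely stops at its
scheduled boundary rather than freezing mid-bend. The archetypes differ the way the
three maneuver types do: S 15°, 24 Hz, 200 ms, ~5° heading change,
caudally-confined curvature; T 60°, 15 Hz, 250 ms, 45°; E 85°, 35 Hz,
170 ms, 80°, fast translation. Amplitudes/frequencies were chosen once
from the published kinematic scales (mean TBF ≈ 24 Hz, durations ≈
190 ms) and the qualitative descriptions (turns and escapes differ mainly
in alternation frequency).

*Videos* render each larva as a tapered head capsule (radius 5.5→4.0 px
over a 9 px axis) plus a 45 px tail of linearly decreasing thickness
(1.6→0.7 px radius) and increasing intensity (70→110; head 50; well 230),
with anti-aliased edges. The taper is what makes heading polarity
recoverable from moments; the tail intensity ramp is what gives the
intensity-separation branch something to work with; the thin tail is
removed entirely by the double erosion, as in real imagery. The tail
midline accumulates a total turn of 2α along a curvature profile
(caudally weighted for S, uniform for T/E), so the chord — and hence the
recorded ground-truth bend angle — is computed from the rendered
geometry, not from the driving parameter. Ground truth records per frame
and larva the head-blob centroid, heading, 10-point midline, tip and bend
angle, plus event boundaries and labels. Locomotion is either
event-driven (translate/turn during maneuvers) or an explicit per-frame
path, which is how non-colliding rings and controlled crossings are
scripted.

What the generator does **not** emulate: refraction and shadows, z-plane
overlap, pigmentation variability, eye/swim-bladder substructure, wall
meniscus artefacts, model mismatch between real larval bending and a
damped sinusoid. Passing the synthetic guarantees therefore demonstrates
the algorithms' correctness under the stated imaging model, not
performance on any particular real recording; the published accuracy
figures on real videos (e.g. ≈82% agreement with a human observer)
cannot be reproduced without the original recordings, which were never
deposited.

# Validation conditions and problem sizes

The test suite and `scripts/acceptance.R` measure, from scratch:
transition-index nullity on 10⁴ i.i.d. movements; tracking fidelity on a
1000-frame, 7-larva non-colliding video (zero identity switches, < 1 px
core RMS, < 3° bend RMS); collision resolution on 20 scripted crossings
(≥ 90% of contact frames resolved); bout detection on 220 planted events
at 0.3° noise (< 5% false negatives and positives, boundaries within
±15 ms); the curvature oracle on circular arcs of radius 5–50 px (within
2%, rigid-motion invariant to 1e−9); classifier recovery on 300 training
/ 150 held-out archetype movements (≥ 90%); and a planted 3× escape-
after-escape enrichment (recovered as I_max ≈ 3 ± 0.3, permutation
p < 0.01 at 50 permutations). The planted-enrichment generator
self-calibrates by iterating the enriched conditional toward
factor × realized marginal (three label passes reach the fixed point),
so that "3×" is relative to the marginal the index actually divides by.

# Numerical choices and degenerate inputs

Ties in identity assignment break toward the lower larva id; a heading
flip relative to the previous frame is accepted only on the evidence of
the skewness sign (near-symmetric cores fall back to temporal
continuity). Empty candidate lists, bodies missing under a core, failed
tip searches and out-of-bounds tail lengths all degrade to carried state
with validity flags rather than errors; genuinely malformed inputs
(mismatched lengths, unknown labels, non-increasing bin edges) stop with
named errors. Erosion counts ("applied twice") do not scale with
resolution — the published protocol fixes them, and rescaling them would
silently change the core-area semantics.

# Limitations

Tracking is 2D; pileups of three or more larvae are not separated
(pairwise treatment only); turn directionality and prey-capture or
escape subcategories are out of scope; the first two frames assume zero
velocity for prediction; the classifier is only as good as its training
distribution — on real data it must be retrained from a manually labeled
set, for which `fit_model()`/`save_model()` are the entry points.
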