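---
title: "How flycourt recognizes courtship: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How flycourt recognizes courtship}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

flycourt scores male *Drosophila* courtship from backlit video of one
male/female pair per 11-mm circular arena. This vignette explains the
processing model stage by stage, the parameters that matter and why their
defaults are what they are, what the synthetic-scene generator does and does
not emulate, and the design decisions taken where more than one reasonable
choice existed.

## The imaging model and segmentation

Under backlighting a fly is a dark object on a bright field, with a crucial
twist: the wings are translucent, so wing pixels are markedly brighter than
the opaque torso yet darker than the open arena. Every downstream quantity
is built on this three-level intensity structure.

**Arena detection.** The circular arenas are found once, on the first frame,
by a gradient-directed circle Hough transform followed by an algebraic
(Kåsa) circle fit on the nearby edge pixels. Accumulator peaks are ranked by
the fraction of the fitted rim covered by edge inliers rather than by raw
votes, because a fly's own boundary can out-vote an arena rim while never
fitting a full circle. Arenas are static on the rig, so detection is not
repeated per frame. The pixel scale is derived from the fitted radius and
the 11-mm arena diameter, and every millimetre-valued threshold goes through
this calibration.

**Background.** A per-channel spatial maximum filter with a square window
wider than a fly (default `seg$bg_window_px = 61` px for the fixture scale;
set it above the body length in pixels for other optics) replaces every fly
pixel with nearby bright background, giving a clean background from a single
frame. The filter raises the background estimate by roughly the upper tail
of the pixel noise; this pedestal matters for thresholding, below.

**Silhouettes.** The body mask is obtained by thresholding the per-pixel,
channel-maximum difference between background and frame. The default
threshold is Otsu's method in its two-threshold (three-class) form,
binarizing at the *lower* threshold. A plain two-class Otsu is the obvious
choice but fails here for a structural reason: the difference image is
trimodal (noise pedestal, wings, torso), and the dominant valley lies
between wings and torso, so two-class Otsu amputates the wings from the
silhouette. The lower cut of the three-class form sits between the noise
pedestal and the wings, which is the boundary actually wanted. A floor of
0.2x the upper threshold keeps the cut above the pedestal when wings are
invisible, and a frame with no foreground mode at all yields an empty mask.
Small objects (< `seg$min_obj_px = 20` px) are dropped and holes filled.

**Wings and torso.** Within the silhouette, wing pixels satisfy
`round((R/k)(G/k)(B/k)) > 0` with `k = seg$wing_divisor = 80`; the constant
encodes the camera's intensity regime and is the one knob to retune on a
different rig. Legs share the wings' intermediate intensity but are one
pixel wide, so the morphological opening (disc radius 1) that cleans the
wing mask also removes them; closing (disc radius 2) heals boundary noise.
The torso is the silhouette minus the wings with the same cleanup and
largest-component-per-fly selection.

## Pose

The torso's second central moments define the moment-equivalent ellipse:
its centroid is the fly's position, the major-axis endpoints are the
head/tail candidates, and the eccentricity
`sqrt(1 - (minor/major)^2)` measures how elongated the fly is (near 1 when
straight, lower when the abdomen is bent). The candidate farther from the
whole-body centroid is the head: the wings trail behind and pull the body
centroid tailward. When the two distances tie within 0.5 px (folded wings
on a symmetric body) the call is flagged ambiguous and resolved by heading
continuity with the previous frame — ties are inevitable at this image
scale, and continuity is the only extra information available.

Wing extension angles are measured per side: edge pixels of the wing mask
are split into the fly's left and right by the sign of the cross product of
the heading with each pixel's wing vector; the farthest edge pixel per side
is the wingtip; and the angle is taken between the *tailward* major-axis
direction and the tip vector. Measuring from the tailward direction makes a
folded wing read ~0° and a right-angle extension read ~90°, which is the
geometry the 30° singing threshold presumes. Angles are reported unsigned
in [0, 180).

## Identity through overlaps

Frame-to-frame identity uses constant-velocity ("rectilinear") prediction
from the last two positions; with two detections the assignment minimizing
total distance to the predictions wins. A single merged silhouette is
disambiguated by its torso content: if torso extraction still finds two
fly-sized torsos, the flies are merely touching (for instance through a
foreleg), the body pixels are split by proximity to the nearer torso, and
behavior detection continues; if the torsos have fused it is a true
overlap, and spectral clustering (Gaussian affinity on pixel coordinates,
bandwidth 0.5x a typical torso minor axis, two leading eigenvectors,
k-means seeded at the two most separated embedded points) partitions the
blob. Subsampling to 400 pixels bounds the eigen decomposition; remaining
pixels join their nearest sampled pixel. Blobs smaller than twice the
minimum fly area are treated as one fly fully occluding the other. All
seeding is deterministic, so runs are exactly reproducible.

Because crossing trajectories can legitimately swap a motion-prediction
assignment, identities are *verified* on the first clean frame after every
overlap. The torso is rotated so its major axis is horizontal, reflected so
the head is on the left, and segmented into head/thorax/abdomen by a
watershed on its Euclidean distance map — the lobes of the body are basins
of the negated map. Shallow minima are suppressed with an automatically
chosen depth threshold of 0.3x the maximum distance value, halved once if
fewer than three segments emerge; a featureless (e.g. wall-climbing)
posture that still refuses to split defers verification to a later frame,
as does an implausible eccentricity (outside [0.5, 0.99]) or area (outside
0.5-2x the reference). A two-basin torso is accepted with an empty head
part, which lets decapitated females in headless assays match their own
references (two empty heads count as identical). Each candidate's parts are
compared to stored references by per-part, centroid-aligned Dice
coefficients — alignment removes translation so that shape is the only
signal — and a pairing is the same identity when max + min of its three
Dice values exceeds 1.6. The pairing under which both flies pass is
adopted, overriding motion prediction when necessary; references (updated
every 24 clean frames) are never swapped, since they define who the male
is. On the scripted 500-frame overlap gauntlet, most post-overlap
assignments emerge swapped and every one is corrected by verification,
which is precisely the failure mode this machinery exists for.

## Behavior recognition

Per frame, for the male only:

* **Singing** — larger wing angle strictly above 30°.
* **Orientation** — the centroid-to-head vector extended 2.5x and swung
  ±10° defines a sector; orientation when the female's centroid is inside.
* **Tapping** — a six-step cascade: bodies form one silhouette; torsos stay
  separate (re-extracted jointly from the merged silhouette, because
  closing each fly's torso independently can bridge a sub-kernel gap);
  male head within 1 mm of the female tail; then a leg-exposing skeleton
  image (the opening of the body united with its pruned skeleton, so wings
  and torso keep their filled shape while legs collapse to 1-px branches)
  is united with the torsos and eroded (disc radius 2). If the flies
  separate, the bridge was a bare leg and the question becomes where it
  ends: the leg branch — the body-with-leg-skeleton minus the
  closed wing/torso area — must connect the two torsos (leg on torso:
  tapping; leg only on a wing: not). If the flies stay connected, the
  bridge is wing-borne and a two-threshold Otsu segmentation of the
  foreground looks for a leg seen through the translucent wing: the
  middle-intensity class, dilated one pixel (legs are one pixel wide) and
  denoised jointly with the torsos, must bridge them.
* **Attempted copulation** — torso eccentricity below the calibrated
  standard (0.9x a straight male's eccentricity; `auto` mode takes the 95th
  percentile over the first 30 s, `manual` a user-chosen frame) while the
  male head is within 1 mm of the female tail, connected or not. If the
  female's own head/tail call was ambiguous the gate also accepts her head
  point, so her flip cannot invert the distance test.
* **Copulation** — any maximal run of attempted copulation longer than half
  a minute is copulation from its start, and so is the remainder of the
  recording (post-copulation behavior is not scored).

**Temporal filter.** Raw flags collapse to one candidate per frame by
priority (copulation > attempted copulation > tapping > singing >
orientation). A behavior is certified at frame *t* when its candidate
appears in more than 5 of the 12 frames ending at *t*; windows truncated at
the start use the proportional rule, and ties inherit the previous label. A
frame is labeled `none` only once 12 consecutive frames carry no candidate
at all; shorter uncertified stretches keep the previous certified label.
The window is causal (it ends at *t*), and certification counts the
priority-collapsed candidate, not raw flags — both choices keep the filter
usable online and make its closed-form behavior on steady inputs easy to
state: a behavior certifies on its 6th frame after quiet, on its 7th when
replacing another, and persists 11 frames into quiet before `none` appears.

## Ethogram analytics

Total courtship time is the seconds spent in orientation, tapping, singing,
or attempted copulation inside the observation window (copulation itself
and `none` excluded). Element proportions divide each element's frames by
the window length, with three window conventions: full recording, start to
copulation onset, or a fixed duration in seconds — the fixed duration is
data-derived in any given study, so it is a parameter, never a constant.
The transition matrix counts changes A→B with A≠B (a self-transition is not
a change) and row-normalizes; by default a `none` stretch breaks the chain
(A, none, B is not a change A→B), with `bridge_none = TRUE` to bridge gaps,
since either reading of "change" is defensible and the choice should be
explicit.

## The synthetic-scene generator

The generator draws parametric two-fly scenes with exact ground truth:
torso as three overlapping ellipse lobes (head/thorax/abdomen) whose necks
give the watershed genuine structure, optionally bent at the abdomen,
optionally decapitated; rounded wing blades whose tip sits at the commanded
extension angle at 1.2 semi-major lengths from the centroid (rounded so the
farthest boundary point stays on the tip ray after morphology); 1-px legs;
translucent composites where a wing covers a leg; channel-correlated
Gaussian noise (default sd 2 intensity units, small enough that thresholds
behave deterministically) under a private seed, so rendering is
bit-reproducible. Default paint levels (background 220, wings 140, legs 90,
torso 30) reproduce the three-level backlit structure with the leg level
chosen below the wings so the translucent-composite intensity falls in the
middle Otsu class with margin on both sides. Males are drawn 42x15 px and
females 52x20 px in the scripted scenes — the sexual size dimorphism is
what makes torso-shape verification discriminative, exactly as on the rig.

What it does **not** emulate: motion blur, specular reflection, shadows,
lens distortion, illumination drift, wall-climbing postures, grooming, or
female rejection behaviors. Passing the fixture suite therefore shows that
the implementation realizes the stated definitions and survives pixel noise
and overlap topology; it does not certify recognition rates on recorded
video, where those nuisances exist and the published figures of merit were
measured.

## Validation scale and numerical choices

The scripted validation uses a 500-frame overlap gauntlet (~10 full
crossings at 6 px/frame; identity accuracy is scored on the 180 frames
where the flies are separated) and a 264-frame courtship bout covering all
five elements plus the three leg-contact topologies. The bout runs at 2
frames/s so the half-minute copulation rule is reachable inside a short
sequence; every frame-count threshold (5-of-12, 12-frame gap) is
frame-based and unaffected by the timebase. Expected labels for the bout
are computed in closed form from the segment layout, not by re-running the
filter, so the comparison is a genuine cross-check. Boundary recovery of
the printed thresholds uses bisection to ~1e-12, far below any tolerance of
interest.

Other numerical choices: coordinates are 1-based (row, col) with the origin
top-left, angles in degrees with 0 along +col and counter-clockwise
positive as displayed; connected components use 8-connectivity wherever
contact matters (the bundled 4-connected labeler is augmented by a
diagonal-merge pass); skeleton branch pruning walks from endpoints and uses
4-connectivity for junction detection, because a spur pixel diagonally
brushing a straight backbone would otherwise masquerade as the junction
itself; moment computations use the population covariance with no
discrete-pixel correction so they agree with a literal covariance oracle to
machine precision; and the single pipeline seed (default 0) governs every
stochastic step, though after deterministic seeding none remain in
practice.

## Known limitations

Licking is not detectable at this magnification, and female behavior is
not scored — both are out of scope by design. Video containers are not
read directly (export to an image sequence first). Identity verification
needs visible wings to stabilize head/tail assignment; a fly with fully
folded wings and a symmetric body alternates canonical orientations and
defers verification more often. The tapping cascade assumes legs thin
enough to vanish under a radius-2 erosion; at much higher magnification the
erosion radius and the skeleton pruning length (defaults 2 and 5 px, both
exposed in the configuration) must scale with it.
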