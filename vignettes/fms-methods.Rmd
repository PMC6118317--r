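---
title: "Fractional mobility scoring: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional mobility scoring: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormfms)
```

## The measurement model

A well of swimming *C. elegans* is photographed twice, 500 ms apart. Over
that interval a moving worm translates by roughly its own body width,
while a paralyzed worm stays put; the pixel-level difference between the
two frames therefore separates moving from stationary animals without
tracking individuals. The fractional mobility score of a well is

$$\mathrm{FMS} = \frac{|\text{moving worm pixels}|}{|\text{all worm pixels}|} \in [0, 1].$$

Two image-processing chains feed this ratio.

**Reference mask (all worm pixels).** The designated reference frame
(frame 1 of the pair — the choice is arbitrary but must be fixed, since
the difference image credits a moved worm at both its old and new
positions and the correction below assumes a single frame's geometry) is
blurred, passed through a Sobel gradient, thresholded with a local-mean
adaptive threshold, closed twice with a 3×3 box element, and clipped to a
centred circle that removes the bright well rim. Edge detection plus
closing — rather than plain intensity thresholding — makes the
segmentation robust to uneven illumination across the well: the adaptive
threshold responds to local contrast, not absolute brightness.

**Movement partition.** The binary difference mask
$|\,f_1 - f_2\,| > \theta$ contains moved worms twice (old and new
position). Multiplying it by the reference mask keeps only the
reference-frame copy, yielding the moving mask; the stationary mask is
the reference times the complement of the moving mask. By construction
the two masks are disjoint and their union is the reference — the suite
checks this partition exactly on every processed pair, and a frame paired
with itself scores exactly 0.

Wells whose reference mask is smaller than `min_worm_pixels` (default 50)
are flagged invalid rather than scored: an empty well has no denominator.

## Parameters, defaults, and how they were set

| parameter | default | units | role |
|---|---|---|---|
| `blur_sigma` | 1 | px | noise suppression before edge detection |
| `adaptive_block` | 51 | px | window of the local-mean threshold |
| `adaptive_offset` | 0.05 | intensity | margin above the local mean |
| `closing_iterations` | 2 | – | fills worm bodies between their edges |
| `diff_threshold` | 0.01 | intensity | movement call on the difference image |
| `mask_radius_frac` | 0.95 | – | circular rim exclusion |
| `min_object_px` | 0 (150 in adult mode) | px | egg-exclusion size filter |
| `min_worm_pixels` | 50 | px | validity floor |

The closing iteration count (2) is part of the method's definition; the
thresholds are not published and were calibrated **once** against the
synthetic generator, then frozen. Two of them deserve comment:

* `adaptive_offset` must clear the Sobel response of blurred sensor
  noise (≈0.015 intensity units at noise σ = 0.01) while staying far
  below worm-edge magnitudes (≈0.8 at the default 0.4 contrast). 0.05
  leaves a wide margin on both sides, which is why a 20% global contrast
  change moves the FMS by under 0.02.
* `diff_threshold` controls how much of the blurred *halo* around a moved
  worm is counted as moving. Edge-based segmentation dilates every object
  by a 2–3 px halo, inflating both the numerator and the denominator of
  the FMS; the ratio is unbiased only if both are inflated by the same
  factor. At 0.01 the difference-mask halo matches the reference-mask
  halo and the FMS tracks the true moving fraction to within ±0.06 across
  the full range; at 0.04 the numerator halo is clipped and the score
  under-reads by up to 0.2 at full mobility.
* `min_object_px = 150` in adult mode: rendered eggs (3 px radius discs)
  segment to ~90–100 px components including halo, the smallest rendered
  worms to ~380 px, so 150 separates the two populations cleanly. The
  threshold is exposed because real egg and worm sizes depend on
  magnification.

## Dose-response fitting

Normalized responses (drug-well FMS divided by the drug-free control
mean at the same timepoint — controls therefore normalize to exactly 1)
are fitted on a **linear** concentration axis, exactly as the model is
written:

$$f(x) = A + \frac{1-A}{1 + e^{-B(M-x)}}$$

with lower asymptote $A$, slope $B > 0$ and midpoint $M$ — the EC50, the
dose at which the fitted curve passes $(1+A)/2$. A log-dose axis is a
common alternative but changes the meaning of $B$ and $M$; it is not the
default here. Fitting uses Levenberg–Marquardt least squares from a 27-
point start grid ($A \in \{0, 0.25, 0.5\}$, $M$ at the dose quartiles,
$B \in \{0.5, 2, 10\}$ divided by the dose range), best residual sum of
squares winning and ties broken toward the shallower slope. Degenerate
datasets (flat plateaus) that Levenberg–Marquardt rejects fall through to
a bounded quasi-Newton pass over the same grid, so a fit object is always
returned; $M$ is constrained to $[0.1 \cdot \min(x),\; 10 \cdot \max(x)]$
because a midpoint far outside the tested range is not identified by the
data.

Shallow datasets — no high plateau above 0.8 or no inhibition below
0.5 — are fitted instead with the exponential $f(x) = M e^{-x} + A$,
which is linear in $(M, A)$ and solved exactly by ordinary least squares.
This family has no concentration-scale parameter; $x$ enters as written,
so the parameters inherit the dose unit. That quirk is preserved
deliberately rather than silently reparameterized. The range thresholds
(0.8 / 0.5) operationalize "choose the model by the range of the data";
an explicit override always wins.

## Recovery scoring and response classes

The proportional recovery score is

$$\frac{\overline{\mathrm{FMS}}_{[T-30,\,T]} - \min_t \mathrm{FMS}}{1 - \min_t \mathrm{FMS}}$$

— the mean over the final 30-minute window (150–180 min for the standard
3 h assay; the window tracks the assay end for other durations) relative
to the deepest paralysis, rescaled so that full return to control-level
movement scores 1 and no recovery scores 0. Traces that never drop below
0.95 have nothing to recover from and are flagged undefined rather than
scored. Scores can be negative (movement still declining through the
window) and the suite checks the bounds and the exact arithmetic of the
defining formula.

`classify_response` labels traces as `no_effect` / `sustained_paralysis`
/ `transient_recovery` / `sustained_recovery` using thresholds (0.8 on
the minimum, 0.2 on the recovery score, 0.1 on window-vs-peak closeness)
that are this package's operational choices, exposed as arguments. They
are a convenience for triaging screens, not a published classification,
and no claim is made that they reproduce any particular published count
of "complex" responders.

## What the synthetic generator does and does not emulate

Scenes are a bright circular well on a dark surround containing worms
rendered as smoothed random-walk tubes (random curvature, roughly
constant width), optional egg discs, and additive Gaussian noise clipped
to [0,1]. Moving worms are re-rendered at *fully disjoint* displaced
positions, which makes the ground-truth moving fraction an unambiguous
pixel count and is what makes the oracle tests sharp. Object placement
keeps an 8 px clearance between footprints so that blur halos and closing
cannot bridge distinct objects.

Oracle scenes default to 8–10 worms per well rather than the ~100 L1
larvae of the real assay: disjoint displacement of 100 worms is
geometrically infeasible, and the oracle needs every worm resolvable.
Noise is Gaussian only (no shot noise, no illumination gradients beyond
what the adaptive threshold is built for), worms do not touch or overlap,
and motion is rigid translation rather than swimming deformation.
Passing oracle tests therefore demonstrates that the *algorithm* measures
what it claims on well-posed scenes; it does not certify performance on
crowded real wells, where partial occlusion and sub-body-width motion
blur the moving/stationary dichotomy. The per-instrument thresholds
should be re-tuned on real plates before production use.

The kinetic simulator generates normalized dose×time surfaces from a
two-phase model — exponential paralysis onset toward a dose-dependent
floor that follows the three-parameter logistic, plus optional delayed
exponential recovery — mirroring the archetypal paralysis-then-recovery
time courses. Its generating $(A, B, M)$ are returned so that fitting can
be tested for parameter recovery, including the classic
competitive-antagonist design in which a rightward EC50 shift of known
factor must be recovered from the fitted ratio.

## Problem sizes used by the test suite

Segmentation oracle checks run 20 wells per moving-fraction level at
320×320 px with 8 worms; the end-to-end check simulates a 96-well,
10-timepoint plate at 192×192 px with 5 worms per well. These sizes give
per-level standard errors well inside the ±0.1 oracle band while keeping
the whole suite at a few minutes on one CPU; the geometry (worm size
relative to well diameter) matches the 2× magnification regime the assay
targets.

## Known limitations

* Per-worm statistics, tracking and posture analysis are out of scope;
  the FMS is a population summary per well.
* The exponential family's missing dose-scale parameter makes its fits
  unit-dependent (inherited behaviour, documented above).
* Normalization is per plate; cross-plate batch structure is the user's
  responsibility.
* 12-bit acquisitions must be converted to 8- or 16-bit TIFF upstream;
  the reader rescales either to [0,1], and identical scenes stored at
  both depths agree to within threshold quantization (<0.02 FMS).
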