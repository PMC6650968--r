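---
title: "Methods: facial ROI localization and emotion recognition from paired visual/thermal imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: facial ROI localization and emotion recognition from paired visual/thermal imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Skin temperature over specific facial regions — the forehead, the
periorbital and perinasal areas, the nose tip, the cheeks and the chin —
responds to autonomic emotional arousal and can be read without contact by
an infrared thermal camera.  Low-cost thermal sensors, however, are too
blurred and too low-contrast for conventional cascade face detectors to
locate those regions reliably.  `thermoface` implements the standard remedy:
detect the face, eyes and nose on a *visual* camera rigidly paired with the
thermal one, transfer the boxes across camera planes with a homography, and
then *correct* the transferred regions of interest (ROIs) against a single
frame annotated by a trained expert.

The package operates purely on 8-bit brightness (0–255, brighter = warmer).
Radiometric conversion to degrees Celsius is out of scope: every statistic
downstream is invariant to the unknown affine brightness–temperature map
within a recording, which is what the classifier consumes.

## Pipeline

1. **Calibration.** A 3×3 homography $H$ mapping visual pixels to thermal
   pixels is estimated from chessboard point correspondences by the Direct
   Linear Transform with Hartley normalization (points translated to zero
   centroid and scaled to mean distance $\sqrt 2$ before building the
   $2n\times 9$ design matrix; the solution is the smallest right singular
   vector).  The face is not planar, so $H$ is an approximation; with the
   small camera baseline it is the standard and effective one.  A separate
   *fixed-pattern noise* reference frame — the sensor viewing a
   uniform-temperature target — records the static per-pixel offset of the
   uncooled infrared sensor.

2. **Pre-processing.** Each thermal frame has the noise reference subtracted
   pixel-to-pixel (clipped back into \[0, 255\]; the source method is silent
   on underflow, and clipping preserves the 8-bit contract) and is then
   median-filtered (3×3 by default) to remove salt-and-pepper noise.
   Borders are handled by edge replication so ROIs near the frame edge are
   not shrunk.  The two free-running cameras are paired at 2 fps by
   nearest-timestamp matching on a tick grid, dropping ticks whose best
   match in either stream is further than half a period.

3. **ROI placement.** Eleven facial ROIs are squares whose side is a fixed
   percentage of the detected head width: 6.49 % (nose), 14.28 % (forehead),
   3.24 % (periorbital), 9.74 % (cheek), 3.24 % (perinasal), 5.19 % (chin).
   Their *positions* are subject-specific: from the expert-annotated frame
   we learn, per ROI, the offset of its corner from its anchor detector box
   (eyes for the forehead, periorbital-adjacent cheek and perinasal ROIs;
   nose for the periorbital, nose-tip and chin ROIs), normalized by the
   anchor box dimensions.  Re-applying those normalized offsets to each new
   frame's detections reproduces the annotation exactly when the detections
   are unchanged and scales correctly when the head moves or re-sizes.
   Where the anchor table admits two detectors we use the more specific one
   (eyes/nose rather than head); missing eyes or nose detections reuse the
   previous frame's box, and a frame with no usable head box is flagged
   invalid rather than silently emitted.

4. **Error-probability relocation** (the methodological core).  On the
   thermal plane, each placed ROI corner $C_b^k$ is scored against the
   annotated corner $C_A^k$ in *head-normalized* coordinates via a softmax
   over the eleven ROIs, separately per axis:

   $$p_{bx}^k = \frac{\exp(-|C_{bx}^k/W_b - C_{Ax}^k/W_A|)}
     {\sum_{i=1}^{11}\exp(-|C_{bx}^i/W_b - C_{Ax}^i/W_A|)},\qquad
     p_b^k = \min(p_{bx}^k, p_{by}^k),$$

   with $W_b,H_b$ the current head box size and $W_A,H_A$ the annotated
   one.  The ROI with the **highest** $p_b^k$ — the one whose placement
   agrees most with the expert — anchors the correction: every corner is
   re-derived as

   $$C_{bx}'^k = C_{bx}^{ref} + (C_{Ax}^k - C_{Ax}^{ref})\,\frac{W_b}{W_A},$$

   and analogously in $y$.  Two readings required a decision here.  First,
   the prose of the source method says the ROI "of lower probability" is
   selected, while its own summary says the ROI of *highest* probability
   (lowest location error) anchors the rest; only the argmax reading makes
   the scheme recover ground truth when one ROI is correctly placed, so
   argmax is the default and argmin remains selectable
   (`select_reference_roi(mode = "worst")`).  Second, the correction
   formulas print bare scale factors $W, H$; dimensional analysis requires
   the head-size *ratios* $W_b/W_A$, $H_b/H_A$ (annotated-frame offsets must
   be rescaled into the current frame), which is what we implement.
   Corners are rounded to integer pixels last, with the anchor rounded
   before offsets are applied so that relocation is idempotent.

5. **Features.** Per ROI patch (an $m\times n$ brightness grid), seven
   static statistics: mean, variance (divisor $mn-1$), median, mean of
   per-row variances (divisor $n-1$), mean of per-row medians, mean of
   per-column variances (divisor $m-1$), mean of per-column medians; plus
   their seven consecutive-frame differences.  Eleven ROIs × 14 = 154
   features per frame, serialized ROI-major (`f1_1 … f1_14, f2_1 …`), an
   order the source leaves unstated and we fix and document.  Medians of
   even counts average the two middle values; degenerate divisors (1×1
   patches, single-pixel rows) define the variance as 0 for continuity at
   frame borders.  First-frame temporal differences are 0, keeping the
   vector length fixed ("no change" is the natural null); dropping the
   first frame instead is available to callers by slicing the table.

6. **Recognition.** Features are z-scored with training-set statistics
   (zero-variance features get scale 1), reduced by PCA — right singular
   vectors of the centered training matrix, default 60 components, each
   component's sign fixed so its largest-magnitude loading is positive —
   and classified by closed-form Gaussian discriminants: LDA with pooled
   full or diagonal covariance, QDA with per-class full or diagonal
   covariance, nearest-class-mean in the pooled Mahalanobis metric, and
   naive Bayes.  Covariances are regularized by adding
   $10^{-6}\cdot\mathrm{tr}(\Sigma)/d$ to the diagonal; the source is
   silent on singularity and this keeps all kinds defined for any input.
   A linear SVM appears in the interface for completeness but raises an
   error: no SVM solver is available in the supported dependency set, and
   re-implementing one is out of scope.  Evaluation uses stratified 3-fold
   cross-validation repeated over several re-randomized fold assignments
   (default 10; whether the original "several runs" re-randomized folds is
   unstated, and re-randomizing is the statistically safer reading), with
   normalization and PCA fitted inside each training fold only.  Metrics:
   accuracy, Cohen's Kappa $(p_o-p_e)/(1-p_e)$, and per-class one-vs-rest
   TPR/FPR, each reported as mean ± standard error over folds × runs.

7. **Placement evaluation.** Automatic corners are compared to manual ones
   by the Euclidean distance on left-upper corners (the corner is the only
   per-ROI coordinate the correction defines, so distances use it rather
   than centers), summarized per ROI as mean ± SE, and tested with the
   Wilcoxon signed-rank test for zero median: zeros discarded, midranks for
   ties, exact null distribution for $n \le 25$ (computed by
   generating-function convolution over sign assignments — identical to
   enumerating all $2^n$ flips, and verified against literal enumeration in
   the tests), normal approximation with continuity and tie correction
   beyond.  Stars follow the conventional thresholds (n.s., \*, \*\*,
   \*\*\*, >\*\*\* at 0.05/0.01/0.001/0.0001).

## The synthetic phantom

Recordings of children interacting with a robot cannot be redistributed, so
the package ships a generator whose defaults *are* the stated acquisition
conditions: 2 fps pairing, 8-bit thermal brightness, a single annotated
reference frame, eleven ROIs sized by the head-width proportions.  The
phantom renders a warm smooth ellipse (Gaussian-profile intensity so ROI
statistics are non-degenerate) on a cool background at 160×120 thermal /
320×240 visual resolution — a half-scale stand-in for the 384×288 sensor
that keeps tests fast while exercising a non-identity homography (the true
visual→thermal map is the 0.5× scaling).  Per-class brightness offsets
follow the directional physiology the literature reports (nose-tip cooling
under fear and disgust, periorbital warming under fear and surprise, cheek
and forehead warming under happiness, mild global cooling under sadness);
their magnitudes (2–15 brightness levels) are our choice of a realistic
effect size, made once.  Head motion is a ±5 px, 10 s-period sinusoidal
sway with a ±4 % scale oscillation; detector jitter is Gaussian (sd 2 px by
default, truncated to the frame); fixed-pattern noise is uniform per-pixel
on \[0, 6\] and identical in every frame; salt-and-pepper hits 0.2 % of
pixels.

What a green test on the phantom establishes: the geometry, probability and
feature *mechanics* are correct — placement reproduces ground truth with
exact detections, relocation recovers ground truth from one correct ROI and
does not worsen mean corner error under jitter, the emitted noise reference
cancels exactly where unclipped, features match a brute-force oracle.  What
it does not establish: performance on real faces (non-elliptical geometry,
non-planar homography residuals, occlusions, expression-driven deformation,
real cascade detector failure modes) or the published headline accuracy of
the original study, whose child feature database is external and not
redistributable.  Those numbers are therefore deliberately not acceptance
targets here.

## Numerical conventions

* Coordinates are 0-based, x rightward, y downward; boxes `(x, y, w, h)`
  with half-open extent, so adjacent boxes tile without overlap.
* Geometric rounding is half-away-from-zero (symmetric layouts stay
  symmetric); ROI sides have a floor of 1 px.
* Box projection through a homography maps the four corners and takes the
  axis-aligned bounding box, preserving the axis-aligned ROI contract under
  perspective maps.
* Softmax tie-breaks select the smallest ROI index — deterministic and
  order-stable.
* Probabilities are computed on the thermal plane (post-projection), since
  relocation corrects thermal-plane placement; the annotation is marked on
  the thermal frame and is carried to the visual plane through the inverse
  homography only to learn placement offsets.

## Limitations

* No head-pose tracking: relocation assumes the annotated inter-ROI
  geometry holds up to translation and axis-aligned scaling; out-of-plane
  rotation violates that and is an acknowledged limitation of the method.
* One homography for a non-planar face: systematic residuals off the
  calibration plane are not modelled.
* Eyeglasses (opaque in thermal imagery) are not handled.
* The cascade detector itself is not re-implemented; detections enter as
  data (ground truth plus jitter from the phantom, or CSV files from an
  external detector).
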