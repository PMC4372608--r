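---
title: "Otolith outline morphometrics: models, parameters, and design choices"
author: "otoshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Otolith outline morphometrics: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how `otoshape` models otolith shape, which parameters
matter, and the reasoning behind the numerical and design choices, in the
spirit of a methods section a maintainer can audit.

## The measurement model

An otolith photograph is reduced to a closed planar contour and then to a
fixed-length vector of shape coefficients. Two descriptor families are
offered because they make different trade-offs:

* **Wavelet coefficients of the radial profile.** After normalization
  (centroid at the origin, longest axis horizontal, area 1), the radius
  r(θ) is sampled at 1024 equidistant angles counter-clockwise from the 0°
  radial. A periodized dyadic discrete wavelet transform (Daubechies
  least-asymmetric filter with 8 vanishing moments) decomposes this
  periodic signal; the scaling coefficient plus detail levels 0–5
  (1 + 1 + 2 + 4 + 8 + 16 + 32 = 64 values) are retained. Detail levels 6–9
  describe pixel-scale structure and are discarded as noise. Because r(θ)
  is periodic, periodic boundary handling is *exact*: the transform matrix
  is orthogonal at every level, Parseval's identity holds to machine
  precision, and reconstruction from all levels reproduces the profile
  exactly (both are asserted in the test suite). Each detail coefficient is
  localized in angle, which is what lets group differences be traced to
  positions on the outline (e.g. rostrum vs. postrostrum regions).
* **Normalized elliptic Fourier descriptors.** The closed curve
  (x(t), y(t)), parameterized by cumulative chord length, is decomposed
  into 12 harmonic ellipses (Kuhl–Giardina). Normalization moves the
  parameter origin to the first-harmonic ellipse's semi-major axis, rotates
  that axis to horizontal, and divides by its length; a₁ = 1, b₁ = c₁ = 0
  are then fixed and dropped, leaving 4·12 − 3 = 45 coefficients invariant
  to position, scale, rotation, starting point and traversal direction.
  Fourier coefficients are global: good for overall shape comparison, blind
  to *where* on the outline groups differ.

The radial-profile representation assumes the outline is star-shaped about
its centroid — true for otoliths and for the synthetic blobs by
construction. Deviations are handled, not hidden: if a ray crosses the
outline more than once, the farthest crossing is used (preserving the outer
silhouette) and a warning names the condition; if the centroid falls outside
the polygon the fish is rejected with an error.

## Image processing

* **Binarization**: a pixel is foreground iff intensity > threshold
  (strictly greater; ties sit exactly at the threshold only on a measure-zero
  set of real images, and the choice is documented rather than consequential).
  Default threshold 0.2 against a ~0.05 background and ~0.8 otolith. An
  empty foreground errors with advice to lower the threshold; foreground
  touching the border warns that the contour may be clipped.
* **Contour tracing**: Moore-neighbour tracing on the selected 8-connected
  component. The walk over (pixel, backtrack) states is deterministic, so it
  terminates exactly when a state repeats; re-entering the start state is
  Jacob's stopping criterion, and any pre-cycle tail (possible when the
  start pixel sits on a one-pixel spur) is trimmed. Component selection:
  the component containing the image centre, falling back to the largest
  component; an explicit per-image seed overrides this, and a seed with no
  foreground within a search radius (default ¼ of the smaller image
  dimension) is an error. Components with fewer than 10 boundary pixels are
  rejected as specks.
* **Smoothing**: the (1,2,1)/4 moving average over three successive
  coordinate points, iterated (default 100 passes). On a regular n-gon each
  pass scales the k-th radial harmonic by (1 + cos(2πk/n))/2, so the kernel
  is shrinkage-bounded: it damps single-pixel oscillations hard while
  leaving low-order shape almost untouched (the closed-form factor is
  asserted in the tests). Smoothing is optional; measurements and
  coefficients always use the smoothed contour once smoothing has run,
  because the measured object should be the analyzed object.
* **Grayscale conversion** uses luminance weights (0.2126, 0.7152, 0.0722);
  with the high otolith/background contrast the exact weights are
  non-critical.

## Normalization details

* The centroid is the mean of the outline coordinates (not the polygon area
  centroid) — both coincide for dense, evenly traced contours, and the
  vertex mean is what the radial profile is anchored to.
* The longest axis is the maximum Feret diameter, found exactly on the
  convex hull. After rotating it horizontal, the 180° ambiguity is resolved
  by placing the longer horizontal reach from the centroid on the positive
  x side; with images oriented rostrum-left as the imaging protocol
  requires, this makes all fish comparable.
* The elliptic Fourier starting-point angle θ is defined modulo π, and the
  spatial rotation ψ absorbs the sign, so the textbook normalization leaves
  a residual two-fold ambiguity that flips every even harmonic. `otoshape`
  canonicalizes it by the sign of the first even-harmonic coefficient whose
  magnitude exceeds 10⁻⁷; traversal orientation is canonicalized first by
  reversing the parameter when the first-harmonic determinant
  a₁d₁ − b₁c₁ is negative. Without both rules the ±10⁻⁶ invariance
  contract (same shape, any pose/start/direction → same coefficients) is
  unattainable.
* **Wavelet angle map**: the centre angle attached to each detail
  coefficient is the circular energy centroid of that coefficient's basis
  function, computed once per level by inverse-transforming a unit
  coefficient. The naive bin centre 360(k + ½)/2^L ignores the phase delay
  of the filter cascade, which amounts to ~76° at level 5 — enough to point
  at the wrong part of the otolith. With the centroid map, a planted
  Gaussian bump at a coefficient's nominal angle maximizes exactly that
  coefficient (asserted in the tests). Within a level the angles remain
  equally spaced at 360/2^L.

## Allometric standardization

Fish length affects otolith shape. For each coefficient c_j the model
c_j ~ length × group is screened: if the interaction (group-specific slope)
is significant by a partial F-test at α = 0.05 (optionally α/K under
Bonferroni, K = coefficients per transform), the coefficient cannot be
adjusted by a single slope and is omitted. The rest are centred with the
pooled common slope b_j from c_j ~ length + group:
std_ij = c_ij − b_j (L_i − L̄). Re-fitting the additive model on the
standardized values returns a length slope of exactly zero (least-squares
algebra, asserted at 10⁻⁹), while group mean differences are preserved.
Pooled rather than per-group slopes is the deliberate choice: per-group
adjustment would remove part of the group signal itself. The screen's
operating characteristics are verified by simulation: null omission rate
within the binomial band around α, and ≥ 95 % power against an interaction
five standard errors wide (200 replicates each).

## Statistics

* **CAP / RDA**: on Euclidean distances, constrained ordination of the
  coefficient matrix by group equals projecting the centred matrix onto the
  group-indicator space and eigen-decomposing the fit. `cap()` wraps
  `vegan::capscale` (the field's standard tool) and is verified against a
  brute-force regression-then-eigendecomposition oracle. The precondition
  n > p (more fish than coefficients) is enforced with an explanatory error.
* **Permutation ANOVA**: pseudo-F = (SS_model/df_m)/(SS_res/df_r) computed
  directly from group means; p = (1 + #{F_perm ≥ F_obs})/(1 + P), so 1000
  permutations floor at 1/1001 → 0.001 at three decimals. The F and sums of
  squares are cross-checked against `vegan::adonis2`; the permutation
  engine is in-package so the p-value convention and seeding are explicit.
* **Cluster plot**: group means of the first two CAP site-score axes with
  ±1 SE intervals; axis labels carry each axis's share of the constrained
  (among-group) variation.
* **LDA error**: `MASS::lda` with stratified k-fold cross-validation
  (default 10; folds = n gives leave-one-out, verified against an explicit
  loop), out-of-bag bootstrap (default 1000 replicates), or the 0.632
  correction. Near-constant coefficients (sd below 10⁻⁸ of the largest) are
  dropped with a warning before fitting — high-harmonic Fourier terms of
  very smooth outlines are numerically constant and would otherwise abort
  the covariance estimate.

## Reconstruction quality

Accuracy is reported as L1 agreement: 100·(1 − Σ|r̂ − r| / Σ r) in the
radial domain for the wavelet curve (per detail level 0–10), and
100·(1 − mean planar deviation / mean radius) for Fourier (per harmonic
count), averaged over fish. The metric is bounded by 100, reaches exactly
100 at the full wavelet level (orthogonality), and is exposed through a
plain data-frame interface so another metric can be substituted. One honest
caveat: an L1 metric is not mathematically monotone under an L2-orthogonal
truncation, so individual fish can show dips on the order of 10⁻⁶ accuracy
points between adjacent levels; the mean curves are monotone in all test
data and the threshold scan (`find_threshold_level`, e.g. at 98.5 %)
operates on the means.

## The synthetic generator

`make_project()` renders star-shaped blobs
r(θ) = R(1 + Σ_k ε_k cos(kθ + φ_k)) on a dark background (foreground 0.8,
background 0.05, pixel noise sd 0.02, JPEG quality 95 so compression
artifacts stay far below the binarization contrast), with the first-harmonic
lobe pointed at 180° to honor the rostrum-left convention. The default study
design mirrors a three-population sampling campaign: 65 + 65 + 30 fish,
800 × 600 px images, lengths ~ N(30, 2.5²) cm, otolith radius proportional
to length (5.5 px/cm, i.e. allometric size), elongation ε₂ increasing with
length (0.004/cm, allometric shape), per-fish amplitude jitter sd 0.008, and
group-specific third-harmonic offsets (0 / 0.025 / 0.05) as the planted
population signal; `cal` = 100 px/mm. These choices are the generator's
definition of "realistic", fixed once; tests that need smaller or larger
problems change the explicit arguments, not the defaults.

What the generator does *not* emulate: real otolith texture, annuli,
broken or overlapping otoliths, uneven illumination, or non-star-shaped
silhouettes. Green tests therefore certify the pipeline's mathematics and
bookkeeping on idealized inputs; performance on difficult real imagery
still depends on photograph quality and threshold choice, which is why the
overlay QC images and the remove/re-detect loop exist.

## Numerical choices worth knowing

* Ray/segment intersection uses a half-open parameter window with a 10⁻⁹
  tolerance so a crossing at a shared vertex is claimed by exactly one of
  the two adjacent segments (no missed or double-counted crossings).
* The workflow orchestrator (`run_workflow`) saves the project archive
  after each stage and resumes from it; removing one outline and re-running
  re-processes exactly that fish. It skips the statistics stage with a
  warning when n ≤ p instead of failing the whole run.
* All resampling (permutations, folds, bootstrap, rendering noise) is
  seeded through explicit `seed` arguments; the RNG state of the calling
  session is saved and restored, so library calls do not perturb user code.
* Problem sizes in the test suite: the shared synthetic project uses 18
  fish at 400 × 300 px (enough for every join/filter/ICC path), simulation
  checks use 200 replicates, and one end-to-end test runs the full default
  study (160 images at 800 × 600) through the complete workflow — chosen as
  the smallest sizes at which each property is sharply testable.

## Known limitations

* No hole handling or interior structure (nuclei, annuli); the outer
  silhouette is the object of study.
* No Procrustes or landmark support; the tool is outline-only by design.
* Radial profiles require star-shaped outlines about the centroid; deeply
  folded silhouettes fall back to the outer envelope with a warning.
* The Fourier and wavelet coefficient values depend on the specific filter
  and normalization conventions documented here; they are comparable within
  this package's output, and structurally (counts, invariances) with other
  implementations, but not bitwise.
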