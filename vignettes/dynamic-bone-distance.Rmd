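---
title: "Measuring dynamic bone-to-bone distance from skin markers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dynamic bone-to-bone distance from skin markers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynifs)
```

# The model

`dynifs` estimates how far apart two bones are at every instant of a
gait cycle, using only optical skin markers and a one-time static image
(MRI) of the subject. The measurement chain has three mathematical
stages, each with explicit assumptions.

## Rigid skin-to-bone registration

Each body segment (pelvis, femur) is treated as a rigid body carrying
two corresponded point sets: surface landmarks digitized in the imaging
frame at the neutral pose (`P`, mm) and the same physical landmarks seen
by the capture system in a given frame (`Q`, mm). The pose is the
closed-form least-squares rigid transform: remove centroids,
decompose the 3×3 cross-covariance `H = P′Q′ᵀ` by SVD, take
`R = VUᵀ`, `t = −RμP + μQ`. Two numerical choices matter:

* **Reflection correction.** For noisy or nearly planar landmark sets
  the raw `VUᵀ` can be a reflection (`det = −1`). We negate the column
  of `V` paired with the smallest singular value whenever
  `det(VUᵀ) < 0`, which restores the optimal *proper* rotation. Without
  this the pipeline would silently mirror the bone on degenerate
  frames.
* **Conditioning guard.** A minimum of 3 landmarks is enforced together
  with a non-collinearity test (second singular value of the centred
  source set at least 1e−6 of the first); a collinear cluster leaves
  the rotation about the cluster axis unobservable.

Landmarks are weighted uniformly. The key biological assumption is that
the marker cluster is rigid relative to the bone: soft-tissue artifact
(STA) is exactly the violation of that assumption, and
`add_sta_perturbation()` exists to quantify how registration residuals
and downstream errors grow when it is violated (registration residuals
grow monotonically with STA amplitude; see the test suite). The method
is therefore most trustworthy for small-amplitude activities such as
walking; it does not model dynamic STA.

Bone landmarks `A` digitized in the imaging frame move with the segment:
`B = RA + t` per frame. The same transform poses the full bone mesh.

## Minimum distance between cortical surfaces

The ischiofemoral space is the minimum Euclidean distance between two
posed cortical regions of interest (ROIs): the lateral cortex of the
ischial tuberosity on the pelvis and the medial cortex of the lesser
trochanter on the femur. ROIs are user-supplied vertex-index sets;
anatomical ROI extraction is deliberately out of scope because the
anatomical phrases have no algorithmic definition. The ROI *surface* is
the set of faces whose three vertices all lie in the ROI, and the
distance is the symmetrized minimum of ROI-vertex-to-ROI-triangle
distances — point-to-triangle rather than vertex-to-vertex, because
vertex sampling of a smooth cortex biases the minimum upward. Candidate
pairs are pruned with conservative per-triangle bounding spheres, so the
accelerated result is *exactly* the brute-force minimum (enforced by an
oracle-equivalence test against an independently coded
projection-and-clamp implementation). Interpenetrating surfaces are
reported as distance 0 with an `intersecting` flag (an
edge-through-triangle test); penetration depth is not computed.

## Gait events and time normalization

Heel strikes and toe-offs are threshold crossings of the vertical
ground reaction force at 10 N (upward = heel strike, downward = toe
off). Crossings closer than 50 ms are treated as oscillation around the
threshold and annihilated in pairs, smallest gap first; the 10 N value
is the standard event threshold, the 50 ms debounce is this package's
choice. A gait cycle runs heel-strike to next ipsilateral heel-strike
and every per-frame series is linearly interpolated onto Q = 101 nodes
(0%, 1%, …, 100%), the standard grid for 1D gait statistics. Marker
gaps of at most 10 frames are bridged by a natural cubic spline before
pose fitting; longer gaps invalidate the frame (a frame needs 3 valid
markers to be fitted at all).

# Validation arithmetic

The phantom protocol quantifies accuracy against a known commanded
motion with four statistics:

* **Distance RMSE** (mm): `sqrt(mean ‖calc − ref‖²)` over frames and
  landmarks.
* **Angular RMSE** (degrees): RMS of the geodesic misorientation
  `acos((trace(R₁ᵀR₂) − 1)/2)` between estimated and reference
  rotations. (The angular-error definition is not standardized in
  validation studies; cluster misorientation is the implemented
  definition. For tiny angles the equivalent `asin` form based on the
  Frobenius norm is used, which resolves differences far below the
  ~1e−6° floor of the `acos` form.)
* **CMC**, the between-session coefficient of multiple correlation for
  repeated waveforms, in the between-day (Kadaba-style) form
  `sqrt(1 − [ΣΣ(Y_gf − Ȳ_f)²/(F(G−1))] / [ΣΣ(Y_gf − Ȳ)²/(FG−1)])`.
  When the ratio exceeds 1 (e.g. two flat waveforms at different
  levels) the statistic is undefined; we return 0 with a degenerate
  flag rather than a complex number — a package convention, stated in
  the docs.
* **LFM R²**: ordinary least squares of one waveform on the other;
  R² is the squared Pearson correlation, the slope/intercept quantify
  calibration.

Group summary tables report mean, SD, a normal-theory 95% CI
(mean ± 1.96·SD/√n; at n ≈ 1000 frames the t-based interval differs
negligibly) and RMSE per landmark group, with a **Total** row that pools
frames rather than averaging group statistics — so the pooled RMSE of
equal-sized groups is `sqrt(mean rᵢ²)`, an identity the tests assert.

# One-dimensional inference (SPM/SnPM)

Cohort comparisons operate on subjects × 101 curve matrices. The
pointwise statistic is the pooled-variance two-sample t
(df = n₁ + n₂ − 2) or the paired t on differences (df = n − 1). Tests
are two-sided on |t|; the signed curve is kept for plotting.

* **SPM (parametric).** The field-wise critical threshold solves
  `P(max T > u) ≈ alpha` with the 1D Euler-characteristic
  approximation for t fields,
  `P ≈ P(T > u) + (L/FWHM)·(sqrt(4 ln 2)/2π)·(1 + u²/ν)^(−(ν−1)/2)`,
  with `L = Q − 1` node intervals and FWHM estimated from the
  gradients of variance-normalized residuals. The tail is doubled for
  the two-sided test. Cluster p-values use the same tail at the
  cluster maximum; set-level inference is out of scope.
* **SnPM (permutation).** The threshold is the (1 − alpha) empirical
  quantile of the max-over-nodes |t| across group relabelings
  (independent design) or sign flips (paired design), enumerated
  exhaustively whenever the design admits at most `n_perm` distinct
  relabelings (default budget 10,000) and sampled with the observed
  labelling always included otherwise. Designs with fewer than 20
  distinct relabelings cannot reach alpha = 0.05 and are rejected.
  Fixed seeds give bit-identical thresholds.
* **Normality gate.** The parametric path is only used when nodewise
  D'Agostino–Pearson K² tests on the residuals do not reject. With 101
  per-node tests an uncorrected 5% level would reject somewhere in
  nearly every Gaussian dataset and the gate would never choose SPM,
  so the per-node level is Šidák-corrected,
  `alpha_node = 1 − (1 − alpha)^(1/Q)`: under normality the gate picks
  SPM with probability about `1 − alpha` regardless of Q, while heavy
  tails (simulated as t₂ noise) still push essentially every dataset
  to SnPM. Samples with fewer than 8 residuals per node fall back to
  SnPM with a warning, since the K² kurtosis transform needs n ≥ 8.
  The K² implementation follows the published transforms and
  reproduces an independent reference implementation to 10 decimal
  places (frozen values in the tests).
* **Clusters.** Supra-threshold runs are reported in percent of the
  gait cycle with endpoints linearly interpolated between the
  bracketing nodes and rounded to 2 decimals, so sub-node precision
  like "40.27%–83.81%" is a property of interpolation, not of a finer
  grid.

SnPM is the default inferential path; the random-field threshold is
provided to mirror standard practice and is validated against
Monte-Carlo family-wise error (empirical FWER within [0.03, 0.07] at
alpha = 0.05 for Q = 101, FWHM ≈ 15, n = 15 + 15), not against exact
theory.

# The synthetic-data generator

No public dataset accompanies this class of measurement, so the package
ships generators that reproduce the study conditions in silico; they
are first-class, tested code.

## Sphere phantom

`phantom_spec()` defaults encode the validation protocol: a sphere
(radius 50 mm — a free choice, the physical phantom's dimensions are
not published) carrying 5 bone landmarks on its surface, each paired
with a surface landmark raised outward along the local normal by a
distinct offset (5, 8, 11, 14, 17 mm, emulating unequal soft-tissue
thickness); a commanded 300 mm slide along an oblique (not
ground-parallel) axis over 990 frames, and a commanded 90° rotation
about an axis through the mount point over 1435 frames, at 100 Hz.
Frame counts and commanded motions are the protocol's; landmark
directions are seeded random so the pairs land on both sides of the
sphere. Marker noise is isotropic Gaussian with user-set SD; real
optical noise is hardware-specific and uncharacterized, so **no attempt
is made to match any physically measured RMSE** — the generator's
purpose is exactness under zero noise (the pipeline must recover the
commanded 300 mm and 90° to 1e−6) and known scaling under injected
noise (trajectory RMSE grows linearly in noise SD, fit R² > 0.99 over
SD ∈ {0.1, 0.2, 0.5, 1} mm; the noise sweep uses 300-frame slides,
ample for a stable RMSE estimate).

## Gait scene and cohorts

The two-body gait scene is deliberately schematic: a pelvis block and a
femur shaft, each carrying a *spherical* prominence whose vertices form
the cortical ROI. Spheres are rotation-invariant about their centres,
so by composing each segment's rotation about its own prominence centre
with a shared sway translation plus a commanded gap excursion, the true
inter-prominence distance is known analytically (neutral 30 mm — inside
the physiologic healthy range — plus a periodic excursion peaking at
+8 mm near 30% of the cycle and dipping to −8 mm near 65%, matching the
mid-stance maximum / initial-swing minimum of real IFS curves). The
mesh-based pipeline reproduces this truth to mesh-discretization
tolerance (~0.1 mm for the 162-vertex prominences). A synthetic
vertical GRF with a sinusoidal stance plateau crosses the 10 N
threshold at each cycle boundary so event detection runs on the same
data.

Cohort curves (`simulate_ifs_cohorts()`) come from the same waveform
family with per-subject amplitude (SD 8%) and phase (SD 2% of cycle)
jitter plus smooth additive noise (default SD 2 mm, FWHM 20 nodes).
The "affected" cohort's IFS is reduced by a raised-cosine window over
40–80% of the cycle with peak amplitude `effect_mm` (default 6 mm,
consistent with the reported healthy-vs-affected gap); parameters that
would drive the IFS negative are rejected. Default cohort sizes are 18
healthy and 12 affected hips, the study's sample sizes.

What the generators deliberately do **not** emulate: anatomical bone
shape, muscle-driven kinematics, correlated/fat-tailed optical noise,
dynamic soft-tissue artifact, and bilateral-hip dependence within a
subject (the affected cohort is treated as independent hips, as in the
comparison it feeds). Passing tests therefore demonstrate algorithmic
correctness and calibration under the stated model, not hardware-level
accuracy on real subjects.

## Monte-Carlo problem sizes

The calibration studies use 1,000 null datasets × 1,000 permutations
(FWER) and 200 power simulations; the mesh-distance oracle check uses
100 random 42-vertex blob pairs and the registration oracle 1,000
random instances. These sizes give Monte-Carlo standard errors
comfortably inside the asserted bands (e.g. ±0.007 on a 0.05 FWER) while
keeping the full suite around a minute on one CPU.

# Degenerate inputs and tie-breaks

* Frames with fewer than 3 valid markers, or with a collinear valid
  subset, are flagged invalid rather than fitted; downstream series
  carry NA there.
* Zero pooled variance at a node yields t = 0 (equal means) or ±Inf
  flagged via `zero_variance`.
* `cmc()` on waveforms with no frame-to-frame variance returns the
  degenerate flag; `lfm()` refuses a constant reference.
* Gait-event detection on a force series that never crosses the
  threshold warns and returns empty events; the CLI turns an
  incomplete cycle into an explicit error.
* Mesh ROIs with no complete face fall back to vertex-to-vertex
  distance for that side.
* In `spm_clusters()` a node exactly at the threshold is not
  supra-threshold (strict `>`), which makes a curve that touches the
  threshold at a node interpolate to that node exactly.

# Known limitations

* Rigid-cluster STA handling only; squat-depth motions violate it.
* The RFT path approximates cluster p-values by the max-statistic
  tail; exhaustive or sampled permutation inference is the recommended
  path.
* ROIs are user-supplied index sets; no anatomical segmentation.
* Binary C3D capture files are not read; TRC and the documented TSV
  dialect are (units honoured, gaps preserved, no silent zeros).
* The lab frame is assumed right-handed, Z-up, mm; readers do not
  reorient.
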