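---
title: "Torso shape features from 3D scans: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torso shape features from 3D scans: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torsomorph)
```

## The problem and the model

Indices such as BMI, the waist–hip ratio and the waist-by-root-height ratio
compress body geometry into one number each. A 3D torso scan contains far
more information, but in scanner coordinates it confounds four things:
where the participant stood (translation), how they faced (orientation),
how large they are (scale), and their *shape*. Following the
geometric-morphometrics definition — shape is what remains after
translation, rotation and scale are removed — `torsomorph` turns each scan
into a fixed-length, transformation-invariant shape descriptor and then
treats descriptors as ordinary multivariate data.

The chain is: anatomical frame → torso segmentation → transverse slicing →
polar waveforms → centroid-size scaling → truncated Fourier spectra → PCA.

**Anatomical frame.** The torso centre is the midpoint between the xiphoid
process and the 9th thoracic vertebra. The *transverse* axis is the unit
vector from xiphoid to T9 (note: this is the anterior–posterior direction;
the axis names follow the scanning convention rather than the conventional
anatomical planes). The *sagittal* axis is the left-to-right ASIS vector;
the *longitudinal* axis is their cross product. Two conventions had to be
fixed where the procedure is under-determined:

* The two defining vectors are generally not exactly orthogonal. We
  orthogonalise by Gram–Schmidt keeping the xiphoid→T9 direction exact
  (it is the first-named, primary axis); `orthogonalise = "keep-sagittal"`
  is available for sensitivity analysis.
* The longitudinal axis is required to point from the ASIS level toward the
  xiphoid (cranially), so slice 0 is always the ASIS level and slice 20 the
  xiphoid level. When the raw cross product points the other way we negate
  *both* the sagittal and longitudinal axes: negating only one would flip
  the handedness of the triple, and we require a right-handed (det = +1)
  frame throughout.

**Slicing.** The segment between the ASIS level (mean of the two ASIS
longitudinal coordinates) and the xiphoid level is cut into `n_slices = 21`
bands centred at 5% intervals of the segment length; each band nominally
spans `thickness_mm = 2` mm. Two millimetres preserves the external
features of a torso while tolerating small gaps in the point cloud; finer
structures (hands, feet) would need thinner slices. One deliberate
deviation from a literal absolute band: `torso_descriptor()` scales the
band with the participant's segment length relative to
`thickness_reference_mm = 381` mm (a typical xiphoid–ASIS distance). With
an absolute band, uniformly rescaling a scan changes which points fall in
each band and the descriptor is only approximately scale-invariant; with
the proportional band, slicing commutes exactly with uniform scaling and
the end-to-end invariance holds to floating-point precision. For torso
lengths in the realistic 350–420 mm range the band stays within
1.8–2.2 mm.

**Polar waveforms.** Each slice is collapsed to 2D and expressed as a
radius function of angle about the slice centroid (the arithmetic mean of
the slice's points), with the angle measured counter-clockwise from the
+sagittal axis. This requires the cross-section to be star-shaped about its
centroid — true for compliant scanning poses (arms abducted, no occlusion).
Points are averaged within `n_theta = 360` one-degree bins; empty bins are
filled by periodic linear interpolation, but an empty angular run longer
than `infill_max_deg = 15`° is treated as occlusion and rejected rather
than interpolated. A slice with fewer than `min_points_per_slice = 30` raw
points, or a segment with fewer than `min_points_segment = 1000` points, is
likewise an error, not a guess.

**Smoothing.** The binned waveform is smoothed by a *periodic cubic
smoothing spline* on the uniform angular grid. Because the grid is uniform
and circular, the exact Green–Silverman penalised-spline solution is a
circulant linear operator, diagonal in the discrete Fourier basis, and is
applied in O(N log N) via the FFT (`smooth_periodic()`). The roughness
parameter (`spline_roughness`, units rad³) trades noise suppression against
harmonic attenuation: the default `1e-4` was calibrated once on a synthetic
benchmark — a 100 mm circle sampled with 2 mm radial Gaussian noise must be
recovered with RMSE below 1 mm (measured ≈ 0.76 mm, versus ≈ 0.95 mm for
the unsmoothed binned waveform) — while attenuating the highest retained
harmonic (k = 9) by under 2%. Zero roughness reproduces the binned values
exactly; the operator always preserves constants (DC gain 1).

**Scale removal.** The centroid size of a torso is
`sqrt(sum over all 21 × 360 radius samples of r²)`, each slice's radii
measured about its own centroid. All radii and centroids are multiplied by
one factor so every participant's centroid size equals `s0 = 1`. Three
choices worth recording:

* Size is computed on the uniformly resampled radii, not the raw points, so
  scanner point-density variations do not leak into the scale estimate.
* The common target value is immaterial (descriptors are centred before
  PCA), so the dimensionless 1 is used.
* An alternative convention normalises the plain *sum* of radii instead of
  the root-sum-of-squares; it is available as
  `scale_torso(variant = "sum")`. The root-sum-of-squares is the default
  because it is the standard geometric-morphometrics centroid size.

**Fourier descriptors.** Each slice keeps
`c_k = (1/N) Σ_j r_j exp(−2πi·k·j/N)` for k = 0…9. The `1/N` normalisation
makes coefficients independent of angular sampling density. The DC term is
retained by default: after whole-torso scaling, the per-slice DC encodes
the relative girth profile along the torso (waist-to-chest taper), a
genuine shape feature; `drop_dc = TRUE` switches the band to k = 1…10. No
phase normalisation is applied — the anatomical frame already fixes
orientation, and phase carries the anterior/posterior asymmetry that shape
features must see. Rotating a cross-section by φ multiplies c_k by
e^(−ikφ); this equivariance is exercised in the tests rather than removed.
The 21 × 10 complex coefficients are flattened to 420 named reals
(`s{slice}_k{freq}_{re|im}`, slice-major, reals before imaginaries).

**Shape PCA.** Descriptors are centred but *not* per-column standardised:
all 420 values share the same dimensionless unit, and column-standardising
would inflate noise-dominated high-frequency terms (`scale = TRUE` is
available). The structurally zero imaginary DC columns are dropped before
the decomposition (399 working features) and reinstated on inversion. Sign
ambiguity is resolved by making each loading's largest-magnitude entry
positive, which keeps downstream regression coefficients reproducible.
Components are retained up to the smallest number whose cumulative
explained-variance fraction reaches `variance_threshold = 0.95`; the number
fed to the regression stage (`n_shape_regression = 11`) is deliberately
exposed as a separate knob, since a retention threshold and a regression
pool need not coincide. PC-extreme torsos are reconstructed as
`mean ± magnitude·loading`, inverted slice by slice, and lofted into a
triangle-strip tube (no end caps) whose per-vertex scalar is the signed
radial deviation from the mean torso.

**Statistics.** Analysis variables (sizes, indices, skinfold sum, shape
scores) are z-scored with the sample (n−1) SD. Pearson correlations use
pairwise-complete observations with two-sided p from the t transform on
n−2 df. Regressions are OLS with: standardized β (= raw β on z-scored
inputs), the F–R²–df identity, per-predictor t/p, tolerance
(1 − R² of that predictor on the others), VIF (its reciprocal), and the
Durbin–Watson statistic computed over residuals in input row order — on
cross-sectional data DW is order-dependent, and the participant-file order
is the documented convention. Missing skinfolds are handled by listwise
deletion per model, with `n_used` reported. Stepwise selection is the
classic forward-with-backward scheme: enter the candidate with the smallest
partial-F p-value while it is below `p_enter = 0.05`, then remove any
included predictor above `p_remove = 0.10`, until stable. The thresholds
are the classic defaults of the statistical packages this family of
analyses is usually run in; `p_enter < p_remove` is enforced to prevent
entry/removal cycling. Note that per-candidate entry at 0.05 over a pool of
11 means the *family-wise* probability of at least one spurious entry under
a global null is about 1 − 0.95¹¹ ≈ 43%; the package makes no multiplicity
correction, matching standard stepwise practice, and the null behaviour is
characterised in the test suite.

The model families mirror the three-way comparison the method is built
for: (1) each index alone plus the joint stature/mass/waist/hip model,
(2) stepwise over the leading shape components, (3) each index plus the
stepwise-selected components — ten models, each with full diagnostics.

## The synthetic cohort generator

No raw scan cohort is publicly available for this analysis, so the
generator is a first-class module, not a test fixture. It emulates exactly
the structure the pipeline assumes:

* **Surface:** `r(θ, z) = base(z)·(1 + Σ_m a_m·w_m(z)·cos(k_m θ + φ_m))`.
  The default `base()` is a smooth girth profile (148 mm at the ends,
  138 mm at mid-torso). Modes are built directly in the
  (height-weight × angular-harmonic) basis — the same space the Fourier
  descriptors measure — so generative ground truth is exact rather than
  approximate; pairwise orthogonality on the (slice, θ) grid is enforced at
  spec construction. Defaults: an anterior-weighting k = 1 mode
  (amplitude SD 0.03), an ellipticity k = 2 mode (SD 0.02), and a k = 0
  taper-redistribution mode weighted cos(πt) (SD 0.015).
* **Sampling:** points form a jittered regular (z, θ) lattice — rings every
  2 mm with 144 stratified angular samples — mimicking the near-regular
  vertex lattices structured-light scanners produce, plus radial Gaussian
  noise (`surface_noise_sd = 1` mm, matching sub-millimetre scanner error).
  Stratified angles guarantee that every 5° sector of every slice is
  occupied, so star-shape checks never fail spuriously. Ring placement
  keeps ≥ 0.3 mm clearance from slice-band and segment boundaries so that
  floating-point noise from rigid round-trips can never flip a ring in or
  out of a band — this is what makes the advertised 1e-6 invariance testable
  at machine precision. `z_sampling = "banded"` places rings only at the 21
  slice levels (≈ 3000 points per torso instead of ≈ 30 000); it is the
  economical preset used for large simulated cohorts, and the test suite's
  problem sizes (cohorts of 40–43 for structural checks, 2000 for
  statistical recovery) were chosen with it.
* **Invariance exercise:** each cloud is given a random rotation, a random
  translation and a uniform scale in [0.8, 1.25] before being returned, so
  any pipeline run on generated data implicitly exercises the invariances.
* **Anthropometrics:** stature, mass, waist and hip girths are drawn around
  published cohort-typical means/SDs (stature 179.8 ± 7.2 cm, mass
  82.9 ± 16.2 kg, waist 86.06 ± 10.19 cm, hip 100.36 ± 7.3 cm) with a
  latent adiposity factor inducing realistic mass–waist–hip correlations.
  The sum-of-skinfolds follows `ssf_model()`: in z-units,
  `ssf ~ Σ γ_m·(a_m/sd_m) + δ·waist_z + noise`, rescaled to 51.95 ± 26.33
  mm and floored at 1 mm; the implied shape-explained variance fraction
  `Σγ²/(Σγ² + δ² + σ²)` is recorded so tests can assert recovery against
  it. Presets: `"paper"` (mixed waist + shape paths, 6/43 missing skinfold
  triplets — the missingness the published regression df imply),
  `"association50"` (shape explains exactly 50%), `"null"` (no
  shape–adiposity path).

What the generator does **not** emulate, and hence what passing tests do
not show about real data: girths are drawn statistically, not measured off
the synthetic mesh, so there is no geometric consistency between a
participant's waist girth and their cloud; there is no pose variation,
breathing artefact, landmark palpation error, or non-star-shaped geometry;
and real torso shape variation is far richer than three orthogonal
harmonic modes. The generator validates the *machinery* (invariances,
recovery, identities), not the anthropometric claims themselves.

## Numerical choices and degenerate inputs

* Canonical internal unit is millimetres (scanner-native); statures and
  girths enter the index formulas in metres, skinfolds stay in mm.
* Frame axes are orthonormal to 1e-9 and right-handed by construction;
  landmark vectors within 1° of parallel are a hard error.
* Binning tie-break: a point exactly on a bin edge goes to the
  higher-index bin (`floor(θ/Δ + 0.5)`); slice bands are closed intervals.
* PCA retention uses a 1e-12 slack on the cumulative fraction so a
  threshold hit exactly is not missed to rounding; positive-variance
  components are counted above 1e-10 of total variance.
* Exact predictor collinearity is detected by rank of the augmented design
  and reported as an error naming the response; zero-variance columns fail
  z-scoring explicitly.
* Stepwise on an empty pool, non-star-shaped slices, zero centroid size,
  and sub-minimum point counts all raise typed, messageful errors rather
  than propagating NaNs.

## Known limitations

* The anatomical frame depends on manually digitised landmarks; no
  automatic landmark detection is attempted.
* Non-star-shaped cross-sections (arms touching the torso) are rejected,
  not repaired.
* The Durbin–Watson statistic on cross-sectional data depends on row
  order; it is reported for completeness of the diagnostic battery, not as
  a substantive autocorrelation test.
* Stepwise selection inherits the usual caveats (greedy, no multiplicity
  control); the package reports the selection trace so the path is
  auditable.
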