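# torsomorph

Shape-based anthropometry from 3D torso scans.

Traditional anthropometric practice reduces the human body to a handful of
size measures and derived indices — BMI (mass/stature²), the waist–hip ratio
(WHR = waist girth / hip girth) and the waist-by-root-height ratio
(WHT.5R = waist girth / √stature) — when assessing central adiposity. 3D
surface scanners capture far richer geometry, but most of it is discarded by
index-based summaries. `torsomorph` implements a geometric-morphometrics
pipeline that turns a torso point cloud into *scale-, translation- and
rotation-invariant shape features* and asks how much those features add to
the traditional indices when estimating central subcutaneous adiposity
(measured as the sum of three waist skinfolds: iliac crest, supraspinale,
abdominal).

The pipeline:

1. **Anatomical frame** — a local coordinate system is built from four bony
   landmarks (xiphoid process, 9th thoracic vertebra, left/right ASIS),
   removing translation and orientation differences between participants.
2. **Slicing** — the torso segment between the xiphoid and ASIS levels is
   cut into 21 transverse 2 mm slices at 5% height intervals; each slice
   becomes a polar radius waveform r(θ) about its centroid, smoothed by a
   periodic cubic smoothing spline.
3. **Scale removal** — all radii are divided by the torso's centroid size
   (root sum of squared radius samples), the standard geometric-morphometrics
   scale measure, so only *shape* remains.
4. **Fourier descriptors** — each waveform keeps its first 10 complex
   Fourier coefficients c_k = (1/N) Σ_j r_j e^(−2πi k j/N); 21 slices × 10
   coefficients = 210 complex (420 real) values per participant.
5. **Shape features** — PCA over the cohort descriptor matrix yields
   independent shape features (components retained to 95% cumulative
   variance), radar-diagram feature vectors, and deviation-coloured meshes
   of the ± extremes of each component.
6. **Statistics** — Pearson correlation tables and three regression
   families for standardized sum-of-skinfolds: size/index models, a
   stepwise shape-only model, and combined index + shape models — each with
   standardized β, F/df/p, tolerance/VIF collinearity diagnostics and the
   Durbin–Watson statistic.

Because raw scan cohorts of this kind are not publicly deposited, the
package ships a first-class synthetic cohort generator
(`cohort_spec()` / `generate_cohort()`) that produces torso point clouds
with landmarks, known injected orthogonal shape modes, and matched
anthropometric records with a controllable shape–adiposity association, so
every stage of the pipeline is testable against generative ground truth.

## Worked example

```r
library(torsomorph)

spec    <- cohort_spec(n = 43)                 # cohort-realistic defaults
cohort  <- generate_cohort(spec, seed = 7)     # scans + landmarks + anthropometrics

descriptors <- dplyr::bind_rows(lapply(cohort$scans, function(s)
  torso_descriptor(s$cloud, s$landmarks)))     # 43 x 420 shape descriptors

model <- fit_shape_pca(descriptors)
model
#> <torso_pca> 43 participants, 399 features
#>   42 positive-variance components; 3 retained at 95% (cumulative 98.5%)

scores <- model$scores[, c("participant_id", paste0("PC", 1:11))]
res <- analyse_cohort(cohort$anthro, scores)
glance(res$families)
#> # A tibble: 10 x 9
#>    model             r_squared adj_r_squared f_statistic ... durbin_watson n_used
#>  1 bmi                   0.243         0.222       11.3  ...          2.16     37
#>  2 whr                   0.226         0.204       10.2  ...          2.28     37
#>  3 waist_girth           0.452         0.437       28.9  ...          1.87     37
#>  4 wht5r                 0.444         0.428       28.0  ...          2.00     37
#>  5 size_measures         0.478         0.413        7.33 ...          1.77     37
#>  6 shape_pcs             0.505         0.475       17.3  ...          2.05     37
#>  7 bmi_shape             0.671         0.641       22.5  ...          2.05     37
#>  8 whr_shape             0.737         0.713       30.8  ...          2.26     37
#>  9 waist_girth_shape     0.920         0.913     126.    ...          1.50     37
#> 10 wht5r_shape           0.914         0.906     117.    ...          1.68     37
```

Reading the output: a generic cohort of 43 yields 42 positive-variance
components (the rank of a centred 43-row matrix); with three injected
generative modes, 3 components already reach the 95% retention threshold.
In the regression table each row is one model for standardized
sum-of-skinfolds: the single-index models explain 23–45% of the variance,
the stepwise shape-only model 50% (by construction in this synthetic
preset), and combining an index with the stepwise-selected shape features
raises every index's R². `n_used = 37` reflects the 6 participants whose
skinfold triplet is missing (listwise deletion per model). `tidy(res$families)`
gives per-term standardized β, t, p, tolerance and VIF;
`autoplot(model)` draws the scree, `plot_radar()` the per-participant
feature radar, and `reconstruct_extreme()` + `write_deviation_mesh()`
export deviation-coloured ± extreme torsos for any component.

A thin command-line wrapper over the same functions is installed at
`inst/cli/torsomorph.R`:

```sh
Rscript inst/cli/torsomorph.R simulate --out demo --n 43 --seed 7
Rscript inst/cli/torsomorph.R all --scans demo --anthro demo/anthro.csv --out demo_run --seed 7
```

## Documentation

The methods vignette (`vignettes/torso-shape-methods.Rmd`) documents the
model and its assumptions, every tunable parameter with units and defaults,
what the synthetic generator does and does not emulate, and the numerical
design choices (spline roughness, angular binning, scale conventions,
stepwise thresholds).
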