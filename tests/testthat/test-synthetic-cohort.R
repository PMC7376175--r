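test_that("generation is reproducible bit-for-bit from (spec, seed)", {
  spec <- cohort_spec(n = 4, z_sampling = "banded")
  g1 <- generate_torso(spec, 2, seed = 71)
  g2 <- generate_torso(spec, 2, seed = 71)
  expect_identical(g1$cloud, g2$cloud)
  expect_identical(g1$landmarks, g2$landmarks)
  expect_identical(g1$amplitudes, g2$amplitudes)

  co1 <- generate_cohort(spec, seed = 71, geometry = FALSE)
  co2 <- generate_cohort(spec, seed = 71, geometry = FALSE)
  expect_identical(co1$anthro, co2$anthro)
  expect_identical(co1$truth, co2$truth)

  # cohort amplitudes equal the per-participant draws
  expect_identical(co1$truth$amplitudes[2, ], g1$amplitudes,
                   ignore_attr = TRUE)

  # a different seed changes the data
  g3 <- generate_torso(spec, 2, seed = 72)
  expect_false(identical(g1$cloud, g3$cloud))
})

test_that("zero amplitudes and zero noise give exact circular slices", {
  spec <- cohort_spec(n = 2, surface_noise_sd = 0, rigid = FALSE,
                      z_sampling = "banded")
  g <- generate_torso(spec, 1, seed = 73, amplitudes = c(0, 0, 0))
  fr <- build_frame(g$landmarks)
  cl <- to_anatomical(g$cloud, fr)
  lm <- g$landmarks
  lm[, c("x", "y", "z")] <- to_anatomical(lm[, c("x", "y", "z")], fr)
  seg <- segment_torso(cl, lm, min_points = 100)
  prof <- slice_profiles(seg, smoothing = 0, min_points_per_slice = 30)
  # the surface is an exact circle; the extracted waveform deviates from a
  # constant only by the finite-sample centroid estimate (~0.1 mm here)
  for (k in c(1, 11, 21)) {
    r <- prof$radii[[k]]
    expect_lt(max(abs(r - mean(r))), 0.5)
    expect_gt(min(r), 100)
  }
  # radius follows the girth profile: waist narrower than the ends
  r_mid <- mean(prof$radii[[11]])
  r_end <- mean(prof$radii[[1]])
  expect_lt(r_mid, r_end)
})

test_that("an anterior (k=1) mode bulges the anterior side of weighted slices", {
  spec <- cohort_spec(n = 2, surface_noise_sd = 0, rigid = FALSE,
                      z_sampling = "banded")
  g <- generate_torso(spec, 1, seed = 74, amplitudes = c(0.05, 0, 0))
  fr <- build_frame(g$landmarks)
  cl <- to_anatomical(g$cloud, fr)
  lm <- g$landmarks
  lm[, c("x", "y", "z")] <- to_anatomical(lm[, c("x", "y", "z")], fr)
  seg <- segment_torso(cl, lm, min_points = 100)
  prof <- slice_profiles(seg, smoothing = 0)
  # anatomical v = posterior; the generator's anterior bulge sits at
  # theta = 270 degrees (u = 0, v < 0) in every slice plane
  r <- prof$radii[[11]]
  expect_gt(r[271], r[91])
  expect_gt(r[271] - r[91], 5)  # 0.05 amplitude on a ~130 mm radius
})

test_that("descriptors are invariant to the random rigid motion and scale", {
  spec <- cohort_spec(n = 3, z_sampling = "banded")
  ref <- cohort_spec(n = 3, z_sampling = "banded", rigid = FALSE)
  for (i in 1:3) {
    d_moved <- torso_descriptor(generate_torso(spec, i, 75)$cloud,
                                generate_torso(spec, i, 75)$landmarks)
    g0 <- generate_torso(ref, i, 75)
    d_ref <- torso_descriptor(g0$cloud, g0$landmarks)
    expect_lt(max(abs(unlist(d_moved[, -1]) - unlist(d_ref[, -1]))), 1e-6)
  }
})

test_that("PCA on a noise-free multi-mode cohort recovers the mode subspace", {
  spec <- cohort_spec(n = 40, z_sampling = "banded", surface_noise_sd = 0.1)
  co <- generate_cohort(spec, seed = 76)
  desc <- dplyr::bind_rows(lapply(co$scans, function(s)
    torso_descriptor(s$cloud, s$landmarks)))
  m <- fit_shape_pca(desc)
  truth <- true_mode_directions(spec, features = m$kept_features)
  ang <- principal_angles(m$loadings[, 1:3], truth)
  expect_lt(max(ang), 5)
  # variance along each true mode direction matches the injected strength
  # (amplitude SD times descriptor-space pattern norm); eigen-order itself
  # is not compared because two injected strengths are nearly degenerate
  strength <- vapply(seq_along(spec$modes), function(j)
    spec$modes[[j]]$a_sd * sqrt(sum(truth[, j]^2)), 1)
  U <- sweep(truth, 2, sqrt(colSums(truth^2)), "/")
  X <- as.matrix(desc[, m$kept_features])
  proj <- scale(X, center = TRUE, scale = FALSE) %*% U
  v_hat <- apply(proj, 2, var)
  ratio <- v_hat / strength^2
  expect_true(all(ratio > 0.5 & ratio < 1.8))
  # the shape subspace carries almost all descriptor variance
  expect_gt(sum(m$variance[1:3]) / sum(m$variance), 0.99)
})

test_that("anthropometric marginals converge to the specified means and SDs", {
  spec <- cohort_spec(n = 5000)
  co <- generate_cohort(spec, seed = 77, geometry = FALSE)
  a <- co$anthro
  for (v in c("stature", "mass", "waist_girth", "hip_girth")) {
    mu <- spec$anthro_means[[v]]; sg <- spec$anthro_sds[[v]]
    se <- sg / sqrt(nrow(a))
    expect_lt(abs(mean(a[[v]]) - mu), 3 * se)
    expect_lt(abs(sd(a[[v]]) - sg), 4 * se)
  }
  # missingness fraction honoured
  n_miss <- sum(is.na(a$skinfold_iliac_crest))
  expect_identical(n_miss, as.integer(round(6 / 43 * 5000)))
  # missing triplets are all-or-nothing
  expect_identical(is.na(a$skinfold_iliac_crest), is.na(a$skinfold_abdominal))
})

test_that("mode orthogonality and radius positivity are enforced", {
  expect_error(
    cohort_spec(modes = list(torso_mode(1, 0.02), torso_mode(1, 0.02)),
                ssf = ssf_model(c(0.5, 0.5), 0, sqrt(0.5))),
    "not orthogonal"
  )
  spec <- cohort_spec(n = 2, z_sampling = "banded")
  expect_error(generate_torso(spec, 1, 78, amplitudes = c(2, 0, 0)),
               "negative surface radius")
  expect_error(cohort_spec(ssf = ssf_model(c(1, 1), 0, 1)), "length")
})

test_that("ssf_model records its implied shape-variance fraction", {
  m <- ssf_model(shape_coef = c(0.5, 0.5, 0), waist_coef = 0, noise_sd = sqrt(0.5))
  expect_equal(m$shape_r2, 0.5)
  m2 <- ssf_model(shape_coef = c(0, 0, 0), waist_coef = 0.7,
                  noise_sd = sqrt(0.51))
  expect_equal(m2$shape_r2, 0)
  expect_equal(cohort_spec(preset = "association50")$ssf$shape_r2, 0.5)
})

test_that("cohorts write to disk in plain-text formats", {
  spec <- cohort_spec(n = 3, z_sampling = "banded")
  co <- generate_cohort(spec, seed = 79)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("P001.ply", "P001.json",
                                               "anthro.csv", "truth.json")))))
  pc <- read_point_cloud(file.path(dir, "P002.ply"))
  expect_equal(as.matrix(pc), as.matrix(co$scans[[2]]$cloud),
               tolerance = 1e-6, ignore_attr = TRUE)
  lm <- read_landmarks(file.path(dir, "P002.json"))
  expect_setequal(lm$name, co$scans[[2]]$landmarks$name)
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_equal(truth$shape_r2_target, co$truth$shape_r2_target)
})
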