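# small synthetic descriptor matrices built directly in descriptor space
fake_descriptors <- function(n, p = 40, modes = NULL, mode_sd = NULL,
                             noise = 0.001, seed = 51) {
  set.seed(seed)
  base <- rnorm(p, 0, 0.05)
  X <- matrix(rep(base, each = n), n, p)
  if (!is.null(modes)) {
    for (m in seq_len(ncol(modes))) {
      X <- X + rnorm(n, 0, mode_sd[m]) %o% modes[, m]
    }
  }
  X <- X + matrix(rnorm(n * p, 0, noise), n, p)
  colnames(X) <- paste0("s00_k", seq_len(p), "_re")  # no structural-zero cols
  dplyr::bind_cols(tibble::tibble(participant_id = sprintf("p%02d", 1:n)),
                   tibble::as_tibble(X))
}

orthonormal_modes <- function(p, k, seed = 52) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(p * k), p, k)))
}

test_that("a single injected mode dominates and is the only retained component", {
  v <- orthonormal_modes(40, 1)
  d <- fake_descriptors(10, modes = v, mode_sd = 0.2, noise = 1e-4)
  m <- fit_shape_pca(d)
  expect_gt(m$fraction[1], 0.99)
  expect_identical(m$n_retained, 1L)
  expect_lt(min(principal_angles(m$loadings[, 1, drop = FALSE], v)), 1)
})

test_that("a generic cohort of n yields exactly n-1 positive-variance components", {
  d <- fake_descriptors(10, noise = 0.01)
  m <- fit_shape_pca(d)
  expect_identical(m$n_positive, 9L)
  expect_equal(sum(m$fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(m$fraction) <= 1e-12))
})

test_that("injected variance ratios 4:2:1 are recovered", {
  v <- orthonormal_modes(40, 3)
  d <- fake_descriptors(4000, modes = v, mode_sd = c(0.2, sqrt(2) * 0.1, 0.1),
                        noise = 1e-4, seed = 53)
  m <- fit_shape_pca(d)
  ratios <- m$variance[1:3] / m$variance[3]
  expect_equal(ratios, c(4, 2, 1), tolerance = 0.15)
  expect_lt(max(principal_angles(m$loadings[, 1:3], v)), 2)
})

test_that("loadings and variances agree with an explicit eigendecomposition", {
  set.seed(54)
  X <- matrix(rnorm(20 * 15), 20, 15)
  colnames(X) <- paste0("s00_k", 1:15, "_re")
  d <- dplyr::bind_cols(tibble::tibble(participant_id = sprintf("p%02d", 1:20)),
                        tibble::as_tibble(X))
  m <- fit_shape_pca(d)
  eg <- eigen(stats::cov(X), symmetric = TRUE)
  expect_equal(m$variance[1:15], eg$values[1:15], tolerance = 1e-9)
  for (j in 1:14) {
    expect_equal(abs(sum(m$loadings[, j] * eg$vectors[, j])), 1, tolerance = 1e-9)
  }
  expect_lt(max(abs(crossprod(m$loadings) - diag(ncol(m$loadings)))), 1e-9)
})

test_that("scores are centred, uncorrelated, and projection is consistent", {
  d <- fake_descriptors(15, modes = orthonormal_modes(40, 3),
                        mode_sd = c(0.2, 0.1, 0.05), seed = 55)
  m <- fit_shape_pca(d)
  S <- as.matrix(m$scores[, -1])
  expect_lt(max(abs(colMeans(S))), 1e-9)
  cc <- stats::cor(S[, 1:m$n_positive])
  expect_lt(max(abs(cc - diag(nrow(cc)))), 1e-9)

  # projecting the training data reproduces the stored scores
  pr <- project_descriptors(d, m, n_components = m$n_retained)
  expect_equal(as.matrix(pr[, -1]),
               S[, seq_len(m$n_retained), drop = FALSE],
               tolerance = 1e-9, ignore_attr = TRUE)

  # mean descriptor projects to zero
  mean_d <- d[1, ]
  mean_d[, -1] <- as.list(colMeans(as.matrix(d[, -1])))
  expect_lt(max(abs(as.matrix(project_descriptors(mean_d, m)[, -1]))), 1e-9)

  # mean + 2*sd along a loading scores exactly 2*sd on that component
  shift <- mean_d
  shift[, -1] <- as.list(unlist(mean_d[, -1]) +
                           2 * m$sdev[1] * m$loadings[, 1])
  sc <- project_descriptors(shift, m, n_components = 2)
  expect_equal(sc$PC1, 2 * m$sdev[1], tolerance = 1e-9)
  expect_equal(sc$PC2, 0, tolerance = 1e-9)
})

test_that("full-rank projection then inversion reproduces training rows", {
  d <- fake_descriptors(8, noise = 0.02, seed = 56)
  m <- fit_shape_pca(d)
  all_scores <- project_descriptors(d, m, n_components = ncol(m$loadings))
  for (i in c(1, 5, 8)) {
    rec <- reconstruct_descriptor(m, unlist(all_scores[i, -1]))
    expect_equal(unname(rec), unname(unlist(d[i, -1])), tolerance = 1e-9)
  }
})

test_that("PC-extreme reconstructions behave linearly around the mean torso", {
  spec <- cohort_spec(n = 12, z_sampling = "banded")
  co <- generate_cohort(spec, seed = 57)
  desc <- dplyr::bind_rows(lapply(co$scans, function(s)
    torso_descriptor(s$cloud, s$landmarks)))
  m <- fit_shape_pca(desc)

  ex0 <- reconstruct_extreme(m, 1, magnitude = 0)
  expect_lt(max(abs(ex0$deviation)), 1e-12)

  mag <- max(m$scores$PC1)
  exp_ <- reconstruct_extreme(m, 1, magnitude = mag)
  exm <- reconstruct_extreme(m, 1, magnitude = -mag)
  expect_equal(exp_$deviation, -exm$deviation, tolerance = 1e-9)

  # deviation scalars equal the brute-force nearest-radius comparison
  rad_x <- unlist(lapply(descriptor_to_spectra(exp_$descriptor),
                         reconstruct_profile, n_theta = 360))
  rad_m <- unlist(lapply(descriptor_to_spectra(m$mean),
                         reconstruct_profile, n_theta = 360))
  expect_equal(max(abs(exp_$deviation)), max(abs(rad_x - rad_m)), tolerance = 1e-12)

  # mesh is a closed 21-ring loft
  expect_identical(nrow(exp_$mesh$vertices), 21L * 360L)
  expect_identical(nrow(exp_$mesh$faces), 2L * 20L * 360L)
  expect_error(reconstruct_extreme(m, m$n_retained + 1), "retained")
})

test_that("extremes of a single-mode cohort reproduce the injected deformation", {
  spec <- cohort_spec(
    n = 12, z_sampling = "banded", surface_noise_sd = 0.05,
    modes = list(torso_mode(2, 0.04, name = "ellipticity")),
    ssf = ssf_model(shape_coef = 0.5, waist_coef = 0.5, noise_sd = sqrt(0.5))
  )
  co <- generate_cohort(spec, seed = 58)
  desc <- dplyr::bind_rows(lapply(co$scans, function(s)
    torso_descriptor(s$cloud, s$landmarks)))
  m <- fit_shape_pca(desc)
  expect_identical(m$n_retained, 1L)

  # participant with the largest positive amplitude should sit at the same
  # end of PC1 as the reconstruction built from the max score
  amp <- co$truth$amplitudes[, 1]
  expect_gt(abs(cor(amp, m$scores$PC1)), 0.999)

  ex <- reconstruct_extreme(m, 1, magnitude = max(m$scores$PC1), n_theta = 360)
  dev_mat <- matrix(ex$deviation, nrow = 21, byrow = TRUE)
  mid <- dev_mat[11, ]
  # the generator's 0-degree direction maps to 270 degrees in the slice
  # plane, so a k=2 harmonic appears as -cos(2*theta) about the slice origin;
  # sign tracks the direction of the score-amplitude association
  k2 <- cos(2 * 2 * pi * (0:359) / 360)
  expect_lt(cor(mid, k2) * sign(cor(amp, m$scores$PC1)), -0.95)
})

test_that("radar values are cohort-standardised leading scores", {
  d <- fake_descriptors(20, modes = orthonormal_modes(40, 6),
                        mode_sd = c(6:1) / 20, seed = 59, noise = 1e-3)
  m <- fit_shape_pca(d)
  rv <- radar_values(m$scores, m, n_components = min(5, m$n_retained))
  vars <- apply(as.matrix(rv[, -1]), 2, function(col)
    sum(col^2) / (nrow(rv) - 1))
  expect_equal(unname(vars), rep(1, ncol(rv) - 1), tolerance = 1e-9)
  expect_error(radar_values(m$scores, m, n_components = 50), "exceeds")
})

test_that("shape models persist to plain text and restore equivalently", {
  d <- fake_descriptors(10, modes = orthonormal_modes(40, 2),
                        mode_sd = c(0.2, 0.1), seed = 60)
  m <- fit_shape_pca(d)
  dir <- withr::local_tempdir()
  write_shape_model(m, dir)
  expect_true(all(file.exists(file.path(dir, c("mean.csv", "loadings.csv",
                                               "variance.csv", "scores.csv",
                                               "metadata.json")))))
  m2 <- read_shape_model(dir)
  expect_equal(m2$n_retained, m$n_retained)
  pr1 <- project_descriptors(d, m)
  pr2 <- project_descriptors(d, m2)
  expect_equal(as.matrix(pr1[, -1]), as.matrix(pr2[, -1]), tolerance = 1e-9)
})

test_that("degenerate and malformed cohorts are rejected", {
  d <- fake_descriptors(5, noise = 0)
  expect_error(fit_shape_pca(d), "zero total variance")
  expect_error(fit_shape_pca(fake_descriptors(2)), "at least 3")
  d2 <- fake_descriptors(6)
  m <- fit_shape_pca(d2)
  expect_error(project_descriptors(d2[, 1:10], m), "do not match")
})
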