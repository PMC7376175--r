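# Evaluate RNG-dependent code under a temporary seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

participant_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 101 + as.numeric(index) * 7919) %% 2147483647)
}

#' Define one injected torso shape mode
#'
#' A mode deforms the surface multiplicatively:
#' `r(theta, z) = base(z) * (1 + a * weight(t) * cos(k * theta + phase))`
#' with `t` the height fraction and `a` the per-participant amplitude drawn
#' from `N(0, a_sd^2)`. Modes with distinct harmonics `k` are orthogonal on
#' the (slice, angle) grid by construction; same-`k` modes must use
#' orthogonal weight functions.
#'
#' @param k Angular harmonic (0 = girth redistribution along the height,
#'   1 = anterior/posterior weighting, 2 = ellipticity, ...).
#' @param a_sd Amplitude standard deviation (dimensionless, relative radius).
#' @param weight Height-weight function of the height fraction in \[0, 1\].
#' @param phase Angular phase in radians.
#' @param name Optional label.
#' @return A `torso_mode` list.
#' @export
torso_mode <- function(k, a_sd, weight = function(t) rep(1, length(t)),
                       phase = 0, name = NULL) {
  stopifnot(k >= 0, a_sd >= 0)
  structure(list(k = k, a_sd = a_sd, weight = weight, phase = phase,
                 name = name %||% sprintf("k%d", k)),
            class = "torso_mode")
}

#' Linear model linking shape modes and waist size to sum-of-skinfolds
#'
#' In z-score units: `ssf_z ~ sum(shape_coef * a_std) + waist_coef * waist_z
#' + noise_sd * eps`, then rescaled to the cohort skinfold mean/SD. The
#' fraction of skinfold variance explained by shape is
#' `sum(shape_coef^2) / (sum(shape_coef^2) + waist_coef^2 + noise_sd^2)`.
#'
#' @param shape_coef Coefficient per mode (on the standardised amplitude).
#' @param waist_coef Coefficient on the standardised waist girth.
#' @param noise_sd Residual SD (z units).
#' @return An `ssf_model` list with the implied `shape_r2` recorded.
#' @export
ssf_model <- function(shape_coef, waist_coef = 0, noise_sd = 1) {
  v <- sum(shape_coef^2) + waist_coef^2 + noise_sd^2
  structure(list(shape_coef = shape_coef, waist_coef = waist_coef,
                 noise_sd = noise_sd, total_var = v,
                 shape_r2 = sum(shape_coef^2) / v),
            class = "ssf_model")
}

#' Specify a synthetic torso cohort
#'
#' The generator emulates the statistical structure the shape-analysis
#' pipeline assumes: a star-shaped torso surface built from a smooth girth
#' profile plus orthogonal multiplicative shape modes with participant-level
#' Gaussian amplitudes, sampled as a jittered regular (height, angle)
#' lattice — the near-regular vertex pattern structured-light scanners
#' produce — with radial Gaussian measurement noise, then moved by a random
#' rigid transform and uniform rescaling so downstream invariances are
#' exercised. Anthropometrics are drawn around the published cohort
#' means/SDs (stature 179.8 +/- 7.2 cm, mass 82.9 +/- 16.2 kg, waist
#' 86.06 +/- 10.19 cm, hip 100.36 +/- 7.3 cm) with a latent common
#' adiposity factor; the sum-of-skinfolds follows the [ssf_model()].
#'
#' @param n Number of participants (default 43, the reference cohort size).
#' @param base_radius Function of the height fraction giving the unperturbed
#'   slice radius in mm.
#' @param modes List of [torso_mode()]s.
#' @param surface_noise_sd Radial measurement noise SD in mm (default 1).
#' @param n_theta_points Angular samples per lattice ring; angles are
#'   stratified (one uniform draw per stratum) so every 5-degree sector is
#'   occupied (default 144).
#' @param z_sampling `"grid"`: rings every 2 mm over the whole scan;
#'   `"banded"`: rings only at the 21 slice levels (economical for large
#'   simulated cohorts).
#' @param segment_length Xiphoid-to-ASIS distance in mm (default 380).
#' @param scan_margin Extra scanned length beyond each landmark level in mm
#'   (default 20.5).
#' @param rigid Apply a random rigid motion + uniform scale to each cloud?
#'   Default `TRUE`.
#' @param scale_range Range of the random uniform scale factor.
#' @param anthro_means,anthro_sds Named vectors (`stature` m, `mass` kg,
#'   `waist_girth` m, `hip_girth` m) of marginal means and SDs.
#' @param ssf An [ssf_model()].
#' @param ssf_mean,ssf_sd Cohort mean/SD of the sum-of-skinfolds in mm
#'   (defaults 51.95 / 26.33).
#' @param missing_skinfold_fraction Fraction of participants whose skinfold
#'   triplet is missing (default 6/43, matching the regression sample the
#'   published degrees of freedom imply).
#' @param preset `"paper"` (default), `"association50"` (shape explains
#'   exactly 50% of skinfold variance, no waist path) or `"null"` (no
#'   shape-adiposity association).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = 43,
                        preset = c("paper", "association50", "null"),
                        base_radius = function(t) 148 - 40 * t * (1 - t),
                        modes = NULL,
                        surface_noise_sd = 1,
                        n_theta_points = 144,
                        z_sampling = c("grid", "banded"),
                        segment_length = 381,
                        scan_margin = 19.5,
                        rigid = TRUE,
                        scale_range = c(0.8, 1.25),
                        anthro_means = c(stature = 1.798, mass = 82.9,
                                         waist_girth = 0.8606, hip_girth = 1.0036),
                        anthro_sds = c(stature = 0.072, mass = 16.2,
                                       waist_girth = 0.1019, hip_girth = 0.073),
                        ssf = NULL,
                        ssf_mean = 51.95, ssf_sd = 26.33,
                        missing_skinfold_fraction = 6 / 43) {
  preset <- match.arg(preset)
  z_sampling <- match.arg(z_sampling)
  if (is.null(modes)) {
    modes <- list(
      torso_mode(1, 0.03, name = "anterior_weighting"),
      torso_mode(2, 0.02, name = "ellipticity"),
      torso_mode(0, 0.015, weight = function(t) cos(pi * t), name = "taper")
    )
  }
  if (is.null(ssf)) {
    ssf <- switch(preset,
      paper = ssf_model(shape_coef = c(0.35, 0.45, 0.25), waist_coef = 0.7,
                        noise_sd = 0.26),
      association50 = ssf_model(shape_coef = c(0.5, 0.5, 0), waist_coef = 0,
                                noise_sd = sqrt(0.5)),
      null = ssf_model(shape_coef = c(0, 0, 0), waist_coef = 0.7,
                       noise_sd = sqrt(1 - 0.49))
    )
  }
  if (length(ssf$shape_coef) != length(modes)) {
    stop("ssf shape_coef length must match the number of modes", call. = FALSE)
  }
  spec <- structure(
    list(n = n, base_radius = base_radius, modes = modes,
         surface_noise_sd = surface_noise_sd,
         n_theta_points = n_theta_points, z_sampling = z_sampling,
         segment_length = segment_length, scan_margin = scan_margin,
         rigid = rigid, scale_range = scale_range,
         anthro_means = anthro_means, anthro_sds = anthro_sds,
         ssf = ssf, ssf_mean = ssf_mean, ssf_sd = ssf_sd,
         missing_skinfold_fraction = missing_skinfold_fraction,
         preset = preset),
    class = "cohort_spec"
  )
  check_mode_orthogonality(spec)
  spec
}

# modes must be pairwise orthogonal as functions on the (slice, theta) grid
check_mode_orthogonality <- function(spec, n_slices = 21, n_theta = 360) {
  t <- (0:(n_slices - 1)) / (n_slices - 1)
  th <- 2 * pi * (0:(n_theta - 1)) / n_theta
  pats <- lapply(spec$modes, function(m) {
    outer(m$weight(t), cos(m$k * th + m$phase))
  })
  nm <- length(pats)
  if (nm < 2) return(invisible(TRUE))
  for (i in 1:(nm - 1)) {
    for (j in (i + 1):nm) {
      ni <- sqrt(sum(pats[[i]]^2)); nj <- sqrt(sum(pats[[j]]^2))
      if (abs(sum(pats[[i]] * pats[[j]])) / (ni * nj) > 1e-8) {
        stop("modes ", i, " and ", j, " are not orthogonal on the (slice, angle) grid",
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

# surface radius in the generator frame (t = height fraction over the scan)
surface_radius <- function(spec, theta, tfrac, amplitudes) {
  r <- spec$base_radius(tfrac)
  pert <- rep(1, length(theta))
  for (m in seq_along(spec$modes)) {
    md <- spec$modes[[m]]
    pert <- pert + amplitudes[m] * md$weight(tfrac) * cos(md$k * theta + md$phase)
  }
  r * pert
}

draw_amplitudes <- function(spec, index, seed) {
  sds <- vapply(spec$modes, `[[`, 1, "a_sd")
  with_seed(participant_seed(seed, index), stats::rnorm(length(sds), 0, sds))
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed, determinant forced to +1
  qrd <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(R) < 0) R[, 3] <- -R[, 3]
  R
}

#' Generate one synthetic torso scan with landmarks
#'
#' Deterministic given (`spec`, `seed`, `participant_index`): the same
#' participant drawn inside [generate_cohort()] has identical amplitudes and
#' geometry. The cloud is returned after the random rigid motion and uniform
#' scaling (if `spec$rigid`), with the landmark coordinates transformed
#' consistently.
#'
#' @param spec A [cohort_spec()].
#' @param participant_index 1-based participant number.
#' @param seed Integer master seed.
#' @param amplitudes Optional fixed mode-amplitude vector overriding the
#'   random draw (useful for constructing torsos with exactly known shape).
#' @return List: `cloud` (tibble `x`,`y`,`z` mm), `landmarks` (tibble),
#'   `amplitudes`, `participant_id`.
#' @export
generate_torso <- function(spec, participant_index, seed, amplitudes = NULL) {
  ps <- participant_seed(seed, participant_index)
  fixed_amp <- amplitudes
  with_seed(ps, {
    sds <- vapply(spec$modes, `[[`, 1, "a_sd")
    amplitudes <- stats::rnorm(length(sds), 0, sds)
    if (!is.null(fixed_amp)) {
      stopifnot(length(fixed_amp) == length(spec$modes))
      amplitudes <- fixed_amp
    }

    L_seg <- spec$segment_length
    margin <- spec$scan_margin
    L_tot <- L_seg + 2 * margin
    # Ring placement keeps at least ~0.3 mm clearance from every slice-band
    # and segment boundary so fp noise from rigid round-trips can never flip
    # a ring in or out of a band.
    z_rows <- switch(spec$z_sampling,
      grid = seq(0, 2 * floor(L_tot / 2), by = 2),
      banded = pmin(margin + (0:20) * L_seg / 20 + 0.3, margin + L_seg - 0.3)
    )
    np <- spec$n_theta_points
    strat <- 2 * pi * (0:(np - 1)) / np
    pts <- lapply(z_rows, function(z) {
      theta <- strat + stats::runif(np, 0, 2 * pi / np)
      tfrac <- z / L_tot
      r <- surface_radius(spec, theta, tfrac, amplitudes)
      if (any(r <= 0)) {
        stop("generation error: negative surface radius (mode amplitudes too large)",
             call. = FALSE)
      }
      r <- r + stats::rnorm(np, 0, spec$surface_noise_sd)
      cbind(r * cos(theta), r * sin(theta), z)
    })
    m <- do.call(rbind, pts)

    z_low_mark <- margin
    z_high_mark <- margin + L_seg
    r_top <- function(th) surface_radius(spec, th, z_high_mark / L_tot, amplitudes)
    r_bot <- function(th) surface_radius(spec, th, z_low_mark / L_tot, amplitudes)
    a <- 40 * pi / 180
    lmk <- rbind(
      xiphoid_process = c(r_top(0), 0, z_high_mark),
      t9_vertebra = c(-r_top(pi), 0, z_high_mark),
      asis_left = c(r_bot(a) * cos(a), r_bot(a) * sin(a), z_low_mark),
      asis_right = c(r_bot(-a) * cos(-a), -r_bot(-a) * sin(a), z_low_mark)
    )

    if (spec$rigid) {
      R <- random_rotation()
      tr <- stats::runif(3, -500, 500)
      sc <- stats::runif(1, spec$scale_range[1], spec$scale_range[2])
      m <- sc * (m %*% t(R)) + matrix(tr, nrow(m), 3, byrow = TRUE)
      lmk <- sc * (lmk %*% t(R)) + matrix(tr, nrow(lmk), 3, byrow = TRUE)
    }
    cloud <- tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3])
    pid <- sprintf("P%03d", participant_index)
    attr(cloud, "source_id") <- pid
    landmarks <- tibble::tibble(
      name = rownames(lmk), x = lmk[, 1], y = lmk[, 2], z = lmk[, 3]
    )
    list(cloud = cloud, landmarks = as_landmark_set(landmarks),
         amplitudes = amplitudes, participant_id = pid)
  })
}

#' Generate a full synthetic cohort
#'
#' Draws per-participant shape-mode amplitudes (reproducibly shared with
#' [generate_torso()]), anthropometrics around the specified means/SDs with
#' a latent adiposity factor correlating mass, waist and hip, and
#' sum-of-skinfolds from the spec's [ssf_model()], split over the three
#' waist sites. A `missing_skinfold_fraction` share of participants has the
#' whole skinfold triplet missing. Everything is reproducible bit-for-bit
#' from (`spec`, `seed`).
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed.
#' @param geometry Also generate the point clouds and landmark sets?
#'   (`TRUE` by default; turn off for purely statistical experiments.)
#' @return List: `anthro` (tibble, one row per participant), `truth`
#'   (amplitudes, z-score components, generative targets), and with
#'   geometry `scans` — a list of `generate_torso()` results.
#' @export
generate_cohort <- function(spec, seed, geometry = TRUE) {
  n <- spec$n
  amplitudes <- do.call(rbind, lapply(seq_len(n), function(i)
    draw_amplitudes(spec, i, seed)))
  colnames(amplitudes) <- vapply(spec$modes, `[[`, "", "name")
  sds <- vapply(spec$modes, `[[`, 1, "a_sd")
  a_std <- sweep(amplitudes, 2, sds, "/")

  mus <- spec$anthro_means; sg <- spec$anthro_sds
  anthro_truth <- with_seed(as.integer((as.numeric(seed) * 31 + 17) %% 2147483647), {
    stature <- stats::rnorm(n, mus["stature"], sg["stature"])
    f <- stats::rnorm(n)                                  # latent adiposity
    mass_z <- 0.85 * f + sqrt(1 - 0.85^2) * stats::rnorm(n)
    waist_z <- 0.90 * f + sqrt(1 - 0.90^2) * stats::rnorm(n)
    hip_z <- 0.85 * f + sqrt(1 - 0.85^2) * stats::rnorm(n)
    ssf_sig <- drop(a_std %*% spec$ssf$shape_coef) + spec$ssf$waist_coef * waist_z
    ssf_z <- (ssf_sig + spec$ssf$noise_sd * stats::rnorm(n)) /
      sqrt(spec$ssf$total_var)
    ssf <- pmax(spec$ssf_mean + spec$ssf_sd * ssf_z, 1)
    # split over the three sites, keeping the sum exact
    base_w <- c(17.4, 11.7, 22.9) / 51.95
    u <- matrix(stats::rnorm(3 * n), n, 3)
    w <- matrix(base_w, n, 3, byrow = TRUE) + 0.03 * (u - rowMeans(u))
    sites <- w * ssf
    n_missing <- round(spec$missing_skinfold_fraction * n)
    miss <- sample.int(n, n_missing)
    list(stature = stature, mass = mus["mass"] + sg["mass"] * mass_z,
         waist = mus["waist_girth"] + sg["waist_girth"] * waist_z,
         hip = mus["hip_girth"] + sg["hip_girth"] * hip_z,
         waist_z = waist_z, ssf_z = ssf_z, ssf = ssf, sites = sites,
         missing = miss)
  })

  ids <- sprintf("P%03d", seq_len(n))
  sites <- anthro_truth$sites
  sites[anthro_truth$missing, ] <- NA_real_
  anthro <- tibble::tibble(
    participant_id = ids,
    stature = anthro_truth$stature,
    mass = anthro_truth$mass,
    waist_girth = anthro_truth$waist,
    hip_girth = anthro_truth$hip,
    skinfold_iliac_crest = sites[, 1],
    skinfold_supraspinale = sites[, 2],
    skinfold_abdominal = sites[, 3]
  )
  truth <- list(
    amplitudes = amplitudes,
    amplitudes_std = a_std,
    waist_z = anthro_truth$waist_z,
    ssf_z = anthro_truth$ssf_z,
    ssf = anthro_truth$ssf,
    missing = sort(anthro_truth$missing),
    shape_r2_target = spec$ssf$shape_r2,
    seed = seed
  )
  out <- list(anthro = anthro, truth = truth)
  if (geometry) {
    out$scans <- lapply(seq_len(n), function(i) generate_torso(spec, i, seed))
  }
  out
}

#' Write a generated cohort to disk
#'
#' One PLY + landmark JSON per participant, `anthro.csv`, and `truth.json`.
#'
#' @param cohort Result of [generate_cohort()] (with geometry).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (is.null(cohort$scans)) stop("cohort was generated without geometry", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sc in cohort$scans) {
    write_point_cloud(sc$cloud, file.path(dir, paste0(sc$participant_id, ".ply")))
    lm <- sc$landmarks
    obj <- setNames(lapply(seq_len(nrow(lm)), function(i) c(lm$x[i], lm$y[i], lm$z[i])),
                    lm$name)
    jsonlite::write_json(obj, file.path(dir, paste0(sc$participant_id, ".json")),
                         digits = NA)
  }
  readr::write_csv(cohort$anthro, file.path(dir, "anthro.csv"))
  jsonlite::write_json(
    list(amplitudes = cohort$truth$amplitudes,
         ssf_z = cohort$truth$ssf_z,
         missing = cohort$truth$missing,
         shape_r2_target = cohort$truth$shape_r2_target,
         seed = cohort$truth$seed),
    file.path(dir, "truth.json"), digits = NA, matrix = "rowmajor"
  )
  invisible(dir)
}
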