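# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

# landmark quartet aligned with the canonical axes:
# transverse = +x, sagittal = +y, longitudinal = +z
aligned_landmarks <- function() {
  tibble::tibble(
    name = c("xiphoid_process", "t9_vertebra", "asis_left", "asis_right"),
    x = c(-100, 100, 0, 0),
    y = c(0, 0, -150, 150),
    z = c(0, 0, -380, -380)
  )
}

random_rigid <- function() {
  qrd <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(R) < 0) R[, 3] <- -R[, 3]
  list(R = R, t = runif(3, -300, 300))
}

apply_rigid <- function(df, rig, scale = 1) {
  m <- scale * (as.matrix(df[, c("x", "y", "z")]) %*% t(rig$R))
  m <- sweep(m, 2, rig$t, `+`)
  out <- df
  out[, c("x", "y", "z")] <- m
  out
}

# uniform cylinder point cloud (axis = z)
cylinder_cloud <- function(n, radius = 140, z_range = c(-300, 300)) {
  th <- runif(n, 0, 2 * pi)
  tibble::tibble(
    x = radius * cos(th),
    y = radius * sin(th),
    z = runif(n, z_range[1], z_range[2])
  )
}

make_segment <- function(points, z_low, z_high) {
  structure(list(points = tibble::as_tibble(points), z_low = z_low,
                 z_high = z_high, source_id = "fixture"),
            class = "torso_segment")
}

# profiles tibble built directly from a list of radius waveforms
make_profiles <- function(radii_list) {
  n <- length(radii_list)
  tibble::tibble(
    slice_index = 0:(n - 1),
    height_fraction = if (n > 1) (0:(n - 1)) / (n - 1) else 0,
    z_center = seq(0, 400, length.out = n),
    n_raw = vapply(radii_list, length, 1L),
    centroid_u = rep(0, n),
    centroid_v = rep(0, n),
    radii = radii_list
  )
}

# brute-force O(N^2) DFT oracle, 1/N convention
dft_oracle <- function(x, k) {
  n <- length(x)
  j <- 0:(n - 1)
  vapply(k, function(kk) {
    sum(x * exp(-2i * pi * kk * j / n)) / n
  }, complex(1))
}

# noise-free analytic descriptor of a torso with fixed mode amplitudes:
# dense exact surface rings through the real pipeline (oracle for mode
# recovery; jitter fixed by the shared seed so finite differences are clean)
oracle_spec <- function(spec) {
  spec$surface_noise_sd <- 0
  spec$rigid <- FALSE
  spec$z_sampling <- "banded"
  spec$n_theta_points <- 720
  spec
}

analytic_descriptor <- function(spec, amplitudes, seed = 999) {
  sp <- oracle_spec(spec)
  g <- generate_torso(sp, 1, seed, amplitudes = amplitudes)
  unlist(torso_descriptor(g$cloud, g$landmarks)[, -1])
}

# true mode directions in descriptor space by central finite differences;
# rows carry feature names so they can be matched to a model's kept columns
true_mode_directions <- function(spec, eps = 1e-3, features = NULL) {
  nm <- length(spec$modes)
  out <- sapply(seq_len(nm), function(m) {
    e <- numeric(nm); e[m] <- eps
    (analytic_descriptor(spec, e) - analytic_descriptor(spec, -e)) / (2 * eps)
  })
  if (!is.null(features)) out <- out[features, , drop = FALSE]
  out
}

# principal angles (degrees) between the column spaces of A and B
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(s, -1), 1)) * 180 / pi
}

# column vector with exact sample correlation r to a z-scored x
exact_cor_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- rnorm(n); e <- rnorm(n)
  x <- (x - mean(x)) / sd(x)
  e <- residuals(lm(e ~ x))
  e <- (e - mean(e)) / sd(e)
  y <- r * x + sqrt(1 - r^2) * e
  tibble::tibble(x = x, y = y)
}
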