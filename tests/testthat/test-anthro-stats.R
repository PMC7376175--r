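base_anthro <- function() {
  tibble::tibble(
    participant_id = c("a", "b", "c"),
    stature = c(2.0, 1.798, 1.70), mass = c(80, 82.9, 70),
    waist_girth = c(0.90, 0.8606, 0.90), hip_girth = c(0.90, 1.0036, 0.95),
    skinfold_iliac_crest = c(17, 18, NA),
    skinfold_supraspinale = c(12, 11, 10),
    skinfold_abdominal = c(23, 22, 21)
  )
}

test_that("derived indices follow their definitional formulas exactly", {
  d <- derive_indices(base_anthro())
  expect_equal(d$bmi[1], 20)                       # 80 / 2^2
  expect_equal(d$whr[1], 1)                        # waist == hip
  expect_equal(d$bmi, d$mass / d$stature^2)
  expect_equal(d$whr, d$waist_girth / d$hip_girth)
  expect_equal(d$wht5r, d$waist_girth / sqrt(d$stature))
  expect_equal(round(d$wht5r[2], 4), 0.6418)       # 0.8606 / sqrt(1.798)
  expect_equal(d$sum_skinfolds[1], 17 + 12 + 23)
  expect_true(is.na(d$sum_skinfolds[3]))           # any missing site -> missing sum
})

test_that("z-scoring centres, scales and is idempotent", {
  tbl <- tibble::tibble(participant_id = c("a", "b", "c"), v = c(1, 2, 3),
                        w = c(10, 30, 20))
  z <- zscore_table(tbl)
  expect_equal(z$v, c(-1, 0, 1))
  expect_equal(mean(z$w), 0, tolerance = 1e-12)
  expect_equal(sd(z$w), 1, tolerance = 1e-12)
  expect_identical(z$participant_id, tbl$participant_id)
  z2 <- zscore_table(z)
  expect_equal(z2$v, z$v, tolerance = 1e-12)
  expect_equal(attr(z, "centers")[["v"]], 2)
  expect_error(zscore_table(tibble::tibble(v = c(5, 5, 5))), "degenerate")
})

test_that("Pearson matrix handles exact, null and missing-pair structure", {
  set.seed(61)
  x <- rnorm(100)
  tbl <- tibble::tibble(x = x, y = 2 * x + 1, z = sample(x))
  ct <- pearson_matrix(tbl)
  expect_equal(ct$r["x", "y"], 1, tolerance = 1e-12)
  expect_lt(abs(ct$r["x", "z"]), 0.25)
  expect_true(ct$significant["x", "y"])
  expect_equal(ct$r, t(ct$r))
  expect_equal(diag(ct$r), c(x = 1, y = 1, z = 1))

  # p-values agree with cor.test
  pv <- stats::cor.test(tbl$x, tbl$z)$p.value
  expect_equal(ct$p["x", "z"], pv, tolerance = 1e-12)

  # insufficient complete pairs -> missing cell
  tbl$w <- c(1, 2, rep(NA, 98))
  ct2 <- pearson_matrix(tbl)
  expect_true(is.na(ct2$r["x", "w"]))
  td <- tidy(ct2)
  expect_identical(nrow(td), 6L)
})

test_that("the generative waist-skinfold correlation is recovered at n = 2000", {
  spec <- cohort_spec(n = 2000, preset = "null")   # corr target 0.7 via waist path
  co <- generate_cohort(spec, seed = 62, geometry = FALSE)
  d <- derive_indices(co$anthro)
  ok <- !is.na(d$sum_skinfolds)
  r <- cor(d$waist_girth[ok], d$sum_skinfolds[ok])
  expect_equal(r, 0.7, tolerance = 0.04)
})

test_that("OLS results match the closed forms and independent oracles", {
  pair <- exact_cor_pair(40, 0.6, seed = 63)
  fit <- fit_regression(pair, "y", "x")
  expect_equal(fit$r_squared, 0.36, tolerance = 1e-12)
  expect_equal(unname(fit$standardized_betas), 0.6, tolerance = 1e-12)
  expect_equal(unname(fit$tolerance), 1)
  expect_equal(unname(fit$vif), 1)

  # multivariate: coefficients equal the normal-equations solution
  set.seed(64)
  n <- 60
  X <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  y <- X %*% c(0.5, -1, 0.25) + rnorm(n)
  d <- tibble::as_tibble(cbind(as.data.frame(X), y = y))
  fit2 <- fit_regression(d, "y", c("x1", "x2", "x3"))
  Xd <- cbind(1, X)
  beta_ne <- solve(crossprod(Xd), crossprod(Xd, y))
  expect_equal(unname(c(fit2$intercept, fit2$coefficients)),
               unname(drop(beta_ne)), tolerance = 1e-9)

  # F - R^2 - df identity
  expect_equal(fit2$f_statistic,
               (fit2$r_squared / fit2$df[["regression"]]) /
                 ((1 - fit2$r_squared) / fit2$df[["residual"]]),
               tolerance = 1e-12)

  # VIF against the definitional auxiliary regressions and car::vif
  tolj <- sapply(1:3, function(j)
    1 - summary(lm(X[, j] ~ X[, -j]))$r.squared)
  expect_equal(unname(fit2$tolerance), tolj, tolerance = 1e-9)
  expect_equal(unname(fit2$vif), unname(car::vif(fit2$lm_fit)), tolerance = 1e-9)
  expect_equal(unname(fit2$tolerance * fit2$vif), rep(1, 3), tolerance = 1e-12)
  expect_true(all(fit2$vif >= 1))

  # Durbin-Watson: hand example and lmtest cross-check
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3)
  expect_equal(fit2$durbin_watson,
               unname(lmtest::dwtest(fit2$lm_fit)$statistic), tolerance = 1e-9)
})

test_that("orthogonal predictors have unit VIF; exact collinearity errors", {
  n <- 32
  x1 <- rep(c(-1, 1), n / 2); x2 <- rep(c(-1, -1, 1, 1), n / 4)
  set.seed(65)
  d <- tibble::tibble(x1 = x1, x2 = x2, x3 = x1, y = x1 + x2 + rnorm(n))
  fit <- fit_regression(d, "y", c("x1", "x2"))
  expect_equal(unname(fit$vif), c(1, 1), tolerance = 1e-12)
  expect_error(fit_regression(d, "y", c("x1", "x3")), "singular")
})

test_that("nested models never lose R-squared", {
  set.seed(66)
  n <- 50
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- d$x1 + 0.5 * d$x2 + rnorm(n)
  r2 <- sapply(1:3, function(k)
    fit_regression(d, "y", paste0("x", 1:k))$r_squared)
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("stepwise selection finds signal, stops on noise, and traces order", {
  set.seed(67)
  n <- 200
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- d$x1 + rnorm(n, 0, 0.3)
  st <- stepwise_select(d, "y", c("x1", "x2"))
  expect_identical(st$selected, "x1")
  expect_identical(st$trace$action, "enter")

  # exact linear combination: both selected, R^2 = 1
  d2 <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  d2$y <- 2 * d2$x1 - d2$x2
  st2 <- suppressWarnings(stepwise_select(d2, "y", c("x1", "x2")))  # exact fit
  expect_setequal(st2$selected, c("x1", "x2"))
  expect_equal(st2$model$r_squared, 1, tolerance = 1e-9)

  expect_error(stepwise_select(d, "y", "x1", p_enter = 0.1, p_remove = 0.05),
               "p_enter")
})

test_that("null stepwise calibration matches the per-candidate entry theory", {
  # with 11 independent null candidates at p_enter = 0.05 the empty-model
  # rate is 0.95^11 = 0.569; check the Monte-Carlo rate sits in that band
  set.seed(68)
  n <- 43
  empties <- 0L
  n_rep <- 150
  for (i in 1:n_rep) {
    Z <- matrix(rnorm(n * 12), n, 12)
    d <- tibble::as_tibble(as.data.frame(Z))
    names(d) <- c(paste0("PC", 1:11), "y")
    st <- stepwise_select(d, "y", paste0("PC", 1:11))
    if (length(st$selected) == 0) empties <- empties + 1L
  }
  rate <- empties / n_rep
  expect_gt(rate, 0.44)   # 0.569 - ~3 binomial SE
  expect_lt(rate, 0.70)
})

test_that("the ten-model family set carries full diagnostics", {
  set.seed(69)
  n <- 43
  spec <- cohort_spec(n = n)
  co <- generate_cohort(spec, seed = 70, geometry = FALSE)
  d <- derive_indices(co$anthro)
  pcs <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 11), n, 11)))
  names(pcs) <- paste0("PC", 1:11)
  # make two pseudo-components carry the true shape signal so stepwise bites
  pcs$PC2 <- co$truth$amplitudes_std[, 1] + rnorm(n, 0, 0.1)
  pcs$PC4 <- co$truth$amplitudes_std[, 2] + rnorm(n, 0, 0.1)
  tbl <- dplyr::bind_cols(
    d[, c("participant_id", "stature", "mass", "waist_girth", "hip_girth",
          "bmi", "whr", "wht5r", "sum_skinfolds")], pcs)
  z <- zscore_table(tbl)
  fam <- run_model_families(z)
  expect_identical(length(fam$models), 10L)
  expect_true(all(c("bmi", "whr", "waist_girth", "wht5r", "size_measures",
                    "shape_pcs", "bmi_shape", "whr_shape", "waist_girth_shape",
                    "wht5r_shape") %in% names(fam$models)))

  gl <- glance(fam)
  expect_true(all(gl$r_squared >= 0 & gl$r_squared <= 1))
  expect_true(all(gl$durbin_watson > 0 & gl$durbin_watson < 4))
  # listwise deletion: missing skinfold triplets drop out per model
  expect_equal(unique(gl$n_used), n - length(co$truth$missing))

  # single-predictor models: R^2 equals the squared standardised beta
  for (ix in c("bmi", "whr", "waist_girth", "wht5r")) {
    m <- fam$models[[ix]]
    expect_equal(m$r_squared, unname(m$standardized_betas)^2, tolerance = 1e-12)
  }
  # combined models never fall below their index-only counterpart
  for (ix in c("bmi", "whr", "waist_girth", "wht5r")) {
    expect_gte(fam$models[[paste0(ix, "_shape")]]$r_squared + 1e-12,
               fam$models[[ix]]$r_squared)
  }
  # determinism: identical input, identical output
  fam2 <- run_model_families(z)
  expect_identical(glance(fam2), gl)

  # JSON report mirrors the fitted values
  f <- withr::local_tempfile(fileext = ".json")
  report_model_families(fam, f)
  rep <- jsonlite::fromJSON(f, simplifyDataFrame = FALSE)
  expect_identical(length(rep$models), 10L)
  expect_equal(rep$models[[1]]$r_squared, fam$models[[1]]$r_squared)
})
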