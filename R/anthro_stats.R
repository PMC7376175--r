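#' Derive traditional anthropometric indices
#'
#' Adds the classic weight-status indices to an anthropometrics table:
#' `bmi = mass / stature^2` (kg m^-2), `whr = waist_girth / hip_girth`
#' (dimensionless), `wht5r = waist_girth / sqrt(stature)` (waist by root
#' height, both in metres), and `sum_skinfolds` = iliac crest +
#' supraspinale + abdominal skinfolds (mm). A participant missing any
#' skinfold gets a missing sum.
#'
#' @param anthro Anthropometrics tibble with `stature` (m), `mass` (kg),
#'   `waist_girth` (m), `hip_girth` (m) and the three `skinfold_*` columns
#'   (mm), as validated by [read_anthro_table()].
#' @return The input tibble with `bmi`, `whr`, `wht5r`, `sum_skinfolds`
#'   columns appended.
#' @export
derive_indices <- function(anthro) {
  anthro <- validate_anthro_table(anthro)
  sf <- c("skinfold_iliac_crest", "skinfold_supraspinale", "skinfold_abdominal")
  missing_sf <- setdiff(sf, names(anthro))
  if (length(missing_sf)) {
    stop("skinfold column(s) absent: ", paste(missing_sf, collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(
    anthro,
    bmi = .data$mass / .data$stature^2,
    whr = .data$waist_girth / .data$hip_girth,
    wht5r = .data$waist_girth / sqrt(.data$stature),
    sum_skinfolds = .data$skinfold_iliac_crest + .data$skinfold_supraspinale +
      .data$skinfold_abdominal
  )
}

#' Convert columns to standardised z-scores
#'
#' `(x - mean) / sd` per column with the sample (n-1) standard deviation,
#' computed over the non-missing values of each column. The original means
#' and SDs are kept as attributes `centers` and `scales`.
#'
#' @param tbl Data frame.
#' @param cols Columns to standardise (tidy-select); default every numeric
#'   column except `participant_id`.
#' @return Tibble with the selected columns z-scored.
#' @export
zscore_table <- function(tbl, cols = NULL) {
  tbl <- tibble::as_tibble(tbl)
  if (is.null(cols)) {
    cols <- names(tbl)[vapply(tbl, is.numeric, TRUE)]
    cols <- setdiff(cols, "participant_id")
  }
  centers <- scales <- setNames(numeric(length(cols)), cols)
  for (cc in cols) {
    v <- tbl[[cc]]
    mu <- mean(v, na.rm = TRUE)
    sdv <- sd(v, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) {
      stop("degenerate column for z-scoring (zero variance): ", cc, call. = FALSE)
    }
    tbl[[cc]] <- (v - mu) / sdv
    centers[cc] <- mu; scales[cc] <- sdv
  }
  attr(tbl, "centers") <- centers
  attr(tbl, "scales") <- scales
  tbl
}

#' Pairwise Pearson correlation table
#'
#' Pairwise-complete Pearson correlations with two-sided p-values from the
#' t transform on n - 2 degrees of freedom, and a significance flag at
#' p < 0.05. Cells with fewer than 3 complete pairs are marked missing.
#'
#' @param tbl Data frame; all numeric columns except `participant_id` are
#'   correlated.
#' @param alpha Significance level for the flag (default 0.05).
#' @return A `torso_cor` object: list of matrices `r`, `p`, `n`, logical
#'   `significant`; use [tidy()] for a long tibble.
#' @export
pearson_matrix <- function(tbl, alpha = 0.05) {
  cols <- setdiff(names(tbl)[vapply(tbl, is.numeric, TRUE)], "participant_id")
  X <- as.matrix(tbl[, cols])
  k <- length(cols)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(cols, cols))
  n <- matrix(0L, k, k, dimnames = list(cols, cols))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- stats::complete.cases(X[, c(i, j)])
      nij <- sum(ok)
      n[i, j] <- n[j, i] <- nij
      if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      if (nij < 3L) next
      rij <- cor(X[ok, i], X[ok, j])
      r[i, j] <- r[j, i] <- rij
      tt <- rij * sqrt((nij - 2) / max(1 - rij^2, .Machine$double.eps))
      pij <- 2 * pt(abs(tt), df = nij - 2, lower.tail = FALSE)
      p[i, j] <- p[j, i] <- pij
    }
  }
  structure(list(r = r, p = p, n = n, significant = !is.na(p) & p < alpha,
                 alpha = alpha),
            class = "torso_cor")
}

#' @export
print.torso_cor <- function(x, digits = 2, ...) {
  cat("<torso_cor> ", ncol(x$r), " variables; * marks p < ", x$alpha, "\n", sep = "")
  disp <- matrix(paste0(format(round(x$r, digits)),
                        ifelse(x$significant & row(x$r) != col(x$r), "*", " ")),
                 nrow(x$r), dimnames = dimnames(x$r))
  print(disp, quote = FALSE)
  invisible(x)
}

#' @export
tidy.torso_cor <- function(x, ...) {
  cols <- colnames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    var1 = cols[idx[, 1]],
    var2 = cols[idx[, 2]],
    r = x$r[idx],
    p_value = x$p[idx],
    n = x$n[idx],
    significant = x$significant[idx]
  )
}

#' First-order residual autocorrelation (Durbin-Watson) statistic
#'
#' `DW = sum_{t>=2} (e_t - e_{t-1})^2 / sum_t e_t^2`, computed over the
#' residuals in input row order. For cross-sectional data this makes the
#' statistic order-dependent; the row order of the participant file is used,
#' mirroring common statistical-package output.
#'
#' @param residuals Numeric residual vector.
#' @return The statistic (between 0 and 4; about 2 under independence).
#' @export
durbin_watson <- function(residuals) {
  sum(diff(residuals)^2) / sum(residuals^2)
}

#' Ordinary least squares with collinearity and autocorrelation diagnostics
#'
#' Fits `response ~ predictors` by OLS on the complete cases of `data` and
#' reports R-squared, standardised coefficients, the overall F test,
#' per-predictor t/p, tolerance and variance inflation factor, and the
#' Durbin-Watson statistic. Tolerance of predictor j is `1 - R^2` of its
#' regression on the other predictors; VIF is its reciprocal (1 for a single
#' predictor). Standardised betas equal raw betas when the inputs are
#' already z-scored.
#'
#' @param data Data frame.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names.
#' @return A `torso_lm` object.
#' @export
fit_regression <- function(data, response, predictors) {
  stopifnot(length(predictors) >= 1)
  use <- data[, c(response, predictors), drop = FALSE]
  cc <- stats::complete.cases(use)
  use <- use[cc, , drop = FALSE]
  n <- nrow(use)
  p <- length(predictors)
  if (n <= p + 1) {
    stop("only ", n, " complete cases for ", p, " predictor(s)", call. = FALSE)
  }
  X <- as.matrix(use[, predictors, drop = FALSE])
  if (qr(cbind(1, X))$rank < p + 1) {
    stop("singular design for response '", response,
         "': exactly collinear predictors", call. = FALSE)
  }
  fml <- stats::reformulate(sprintf("`%s`", predictors),
                            response = sprintf("`%s`", response))
  fit <- lm(fml, data = use)
  sm <- summary(fit)
  cf <- sm$coefficients
  rownames(cf) <- gsub("`", "", rownames(cf))
  sy <- sd(use[[response]])
  sx <- vapply(predictors, function(v) sd(use[[v]]), 1)
  beta_raw <- cf[predictors, "Estimate"]
  std_beta <- beta_raw * sx / sy
  tol <- vapply(seq_len(p), function(j) {
    if (p == 1) return(1)
    r2j <- summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 - r2j
  }, 1)
  vif <- 1 / tol
  r2 <- sm$r.squared
  df_reg <- p
  df_res <- n - p - 1
  f_stat <- (r2 / df_reg) / ((1 - r2) / df_res)
  structure(
    list(
      response = response,
      predictors = predictors,
      n_used = n,
      r_squared = r2,
      adj_r_squared = sm$adj.r.squared,
      intercept = unname(cf["(Intercept)", "Estimate"]),
      coefficients = setNames(unname(beta_raw), predictors),
      standardized_betas = setNames(unname(std_beta), predictors),
      t_values = setNames(unname(cf[predictors, "t value"]), predictors),
      p_values = setNames(unname(cf[predictors, "Pr(>|t|)"]), predictors),
      tolerance = setNames(unname(tol), predictors),
      vif = setNames(unname(vif), predictors),
      f_statistic = f_stat,
      df = c(regression = df_reg, residual = df_res),
      p_value = pf(f_stat, df_reg, df_res, lower.tail = FALSE),
      durbin_watson = durbin_watson(residuals(fit)),
      residuals = unname(residuals(fit)),
      fitted = unname(stats::fitted(fit)),
      lm_fit = fit
    ),
    class = "torso_lm"
  )
}

#' @export
print.torso_lm <- function(x, ...) {
  cat("<torso_lm> ", x$response, " ~ ", paste(x$predictors, collapse = " + "),
      "\n  n = ", x$n_used, ", R^2 = ", round(x$r_squared, 3),
      ", F(", x$df[1], ",", x$df[2], ") = ", round(x$f_statistic, 3),
      ", p = ", format.pval(x$p_value, digits = 3),
      ", DW = ", round(x$durbin_watson, 3), "\n", sep = "")
  print(round(cbind(std_beta = x$standardized_betas, t = x$t_values,
                    p = x$p_values, tolerance = x$tolerance, VIF = x$vif), 4))
  invisible(x)
}

#' @export
tidy.torso_lm <- function(x, ...) {
  tibble::tibble(
    term = x$predictors,
    estimate = unname(x$coefficients),
    std_beta = unname(x$standardized_betas),
    statistic = unname(x$t_values),
    p_value = unname(x$p_values),
    tolerance = unname(x$tolerance),
    vif = unname(x$vif)
  )
}

#' @export
glance.torso_lm <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared,
    adj_r_squared = x$adj_r_squared,
    f_statistic = x$f_statistic,
    df_regression = unname(x$df["regression"]),
    df_residual = unname(x$df["residual"]),
    p_value = x$p_value,
    durbin_watson = x$durbin_watson,
    n_used = x$n_used
  )
}

#' Classic forward-with-backward stepwise selection
#'
#' Repeatedly adds the candidate with the smallest partial-F p-value if it
#' is below `p_enter`, then removes any included predictor whose p-value
#' exceeds `p_remove`, until no change. For single-variable entry the
#' partial-F and coefficient-t criteria are equivalent. Returns the fitted
#' model on the selected set together with a selection trace recording entry
#' order; an empty selection returns a `torso_lm`-free result with
#' `r_squared = 0`.
#'
#' @param data Data frame.
#' @param response Response column name.
#' @param pool Character vector of candidate predictor names.
#' @param p_enter Entry threshold (default 0.05).
#' @param p_remove Removal threshold (default 0.10); must exceed `p_enter`
#'   to prevent cycling.
#' @return A `torso_step` object: `model` (a `torso_lm`, or `NULL` if
#'   nothing entered), `selected` (in entry order), `trace` tibble.
#' @export
stepwise_select <- function(data, response, pool, p_enter = 0.05, p_remove = 0.10) {
  if (p_enter >= p_remove) {
    stop("p_enter must be smaller than p_remove (prevents entry/removal cycling)",
         call. = FALSE)
  }
  if (length(pool) == 0) stop("empty candidate pool", call. = FALSE)
  cc <- stats::complete.cases(data[, c(response, pool), drop = FALSE])
  d <- data[cc, , drop = FALSE]
  selected <- character(0)
  trace <- list()
  step_i <- 0L
  repeat {
    changed <- FALSE
    # forward: best candidate by partial-F p-value
    cand <- setdiff(pool, selected)
    if (length(cand)) {
      pvals <- vapply(cand, function(v) {
        fit <- fit_regression(d, response, c(selected, v))
        fit$p_values[[v]]
      }, 1)
      best <- which.min(pvals)
      if (pvals[best] < p_enter) {
        selected <- c(selected, cand[best])
        step_i <- step_i + 1L
        trace[[length(trace) + 1L]] <- tibble::tibble(
          step = step_i, action = "enter", term = cand[best],
          p_value = unname(pvals[best])
        )
        changed <- TRUE
      }
    }
    # backward: drop anything whose p rose above p_remove
    repeat {
      if (length(selected) == 0) break
      fit <- fit_regression(d, response, selected)
      worst <- which.max(fit$p_values)
      if (fit$p_values[worst] > p_remove) {
        step_i <- step_i + 1L
        trace[[length(trace) + 1L]] <- tibble::tibble(
          step = step_i, action = "remove", term = selected[worst],
          p_value = unname(fit$p_values[worst])
        )
        selected <- selected[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  model <- if (length(selected)) fit_regression(d, response, selected) else NULL
  structure(
    list(model = model, selected = selected,
         trace = if (length(trace)) dplyr::bind_rows(trace) else
           tibble::tibble(step = integer(), action = character(),
                          term = character(), p_value = double()),
         p_enter = p_enter, p_remove = p_remove, n_used = nrow(d)),
    class = "torso_step"
  )
}

#' @export
print.torso_step <- function(x, ...) {
  cat("<torso_step> selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)", "\n")
  if (!is.null(x$model)) print(x$model)
  invisible(x)
}

#' Fit the three regression model families for central adiposity
#'
#' Builds the full model set relating the standardised sum-of-skinfolds to
#' size and shape variables: (1) size models — each anthropometric index
#' (BMI, WHR, waist girth, WHT.5R) alone plus the joint
#' stature/mass/waist/hip model; (2) a shape-only stepwise model over the
#' first `n_shape` shape principal components; (3) combined models — each
#' index together with the shape-selected components. Ten models in all,
#' every one with collinearity (tolerance/VIF) and Durbin-Watson
#' diagnostics. Complete cases are taken per model and `n_used` reported.
#'
#' @param data Standardised analysis table containing `sum_skinfolds`,
#'   `stature`, `mass`, `waist_girth`, `hip_girth`, `bmi`, `whr`, `wht5r`
#'   and `PC1..PCn` columns (see [zscore_table()]).
#' @param n_shape Number of leading shape components fed to the stepwise
#'   pool (default 11).
#' @param p_enter,p_remove Stepwise thresholds (defaults 0.05 / 0.10).
#' @param response Response column (default `"sum_skinfolds"`).
#' @return A `torso_models` object: named list of `torso_lm` fits plus the
#'   `torso_step` trace; [tidy()] and [glance()] give per-term and per-model
#'   tables.
#' @export
run_model_families <- function(data, n_shape = 11, p_enter = 0.05,
                               p_remove = 0.10, response = "sum_skinfolds") {
  indices <- c("bmi", "whr", "waist_girth", "wht5r")
  sizes <- c("stature", "mass", "waist_girth", "hip_girth")
  pcs <- paste0("PC", seq_len(n_shape))
  pcs <- pcs[pcs %in% names(data)]
  if (length(pcs) == 0) stop("no shape PC columns found in data", call. = FALSE)
  models <- list()
  for (ix in indices) {
    models[[ix]] <- fit_regression(data, response, ix)
  }
  models[["size_measures"]] <- fit_regression(data, response, sizes)
  step <- stepwise_select(data, response, pcs, p_enter, p_remove)
  if (!is.null(step$model)) models[["shape_pcs"]] <- step$model
  for (ix in indices) {
    models[[paste0(ix, "_shape")]] <- fit_regression(
      data, response, c(ix, step$selected)
    )
  }
  structure(list(models = models, step = step, response = response),
            class = "torso_models")
}

#' @export
print.torso_models <- function(x, ...) {
  cat("<torso_models> ", length(x$models), " models for response '",
      x$response, "'\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @export
glance.torso_models <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(model = names(x$models)),
    dplyr::bind_rows(lapply(x$models, glance))
  )
}

#' @export
tidy.torso_models <- function(x, ...) {
  dplyr::bind_rows(lapply(x$models, tidy), .id = "model")
}

#' Serialise a model-family report to JSON
#'
#' Mirrors the usual published layout: per model the R-squared, regression
#' equation, standardised betas, t, p, tolerance, VIF, Durbin-Watson and the
#' n actually used.
#'
#' @param families A `torso_models` object.
#' @param path Output JSON path, or `NULL` to return the list.
#' @return The report list, invisibly if written.
#' @export
report_model_families <- function(families, path = NULL) {
  rep <- lapply(names(families$models), function(nm) {
    m <- families$models[[nm]]
    eq <- paste0(
      m$response, " = ", signif(m$intercept, 4), " + ",
      paste(sprintf("(%s*%s)", signif(m$coefficients, 4), m$predictors),
            collapse = " + ")
    )
    list(
      model = nm, response = m$response, n_used = m$n_used,
      r_squared = m$r_squared, equation = eq,
      f_statistic = m$f_statistic,
      df = as.list(m$df), p_value = m$p_value,
      durbin_watson = m$durbin_watson,
      predictors = lapply(m$predictors, function(v) list(
        term = v,
        standardized_beta = m$standardized_betas[[v]],
        t = m$t_values[[v]], p = m$p_values[[v]],
        tolerance = m$tolerance[[v]], vif = m$vif[[v]]
      ))
    )
  })
  out <- list(
    response = families$response,
    stepwise = list(
      selected = as.list(families$step$selected),
      p_enter = families$step$p_enter, p_remove = families$step$p_remove,
      trace = families$step$trace
    ),
    models = rep
  )
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(out))
  }
  out
}
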