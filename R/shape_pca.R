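#' Detect independent torso shape features by PCA
#'
#' Principal components analysis of the cohort descriptor matrix. Columns
#' are centred but not variance-scaled by default: all 420 descriptor values
#' share the same dimensionless post-scaling unit, and per-column
#' standardisation would inflate noise-dominated high-frequency terms.
#' Structurally-zero imaginary DC columns (`s*_k0_im`) are dropped before
#' the decomposition and reinstated as zeros on inversion. Each loading's
#' sign is fixed so its largest-magnitude entry is positive, making
#' downstream regression coefficients reproducible.
#'
#' Components are retained up to the smallest number whose cumulative
#' explained-variance fraction reaches `threshold` (default 0.95).
#'
#' @param descriptors Descriptor tibble (`participant_id` + coefficient
#'   columns) from [assemble_descriptor()] rows bound together.
#' @param threshold Cumulative explained-variance retention threshold.
#' @param scale Use correlation-matrix PCA (z-scored columns)? Default
#'   `FALSE` (covariance PCA).
#' @return A `torso_pca` object: centre vector, orthonormal loadings,
#'   per-component variances and fractions, retention count, and the
#'   training scores.
#' @export
fit_shape_pca <- function(descriptors, threshold = 0.95, scale = FALSE) {
  feat <- setdiff(names(descriptors), "participant_id")
  if (nrow(descriptors) < 3) stop("need at least 3 participants for PCA", call. = FALSE)
  X <- as.matrix(descriptors[, feat])
  if (anyNA(X)) stop("descriptor matrix contains missing values", call. = FALSE)
  dropped <- grep("_k0_im$", feat, value = TRUE)
  keep <- setdiff(feat, dropped)
  Xk <- X[, keep, drop = FALSE]
  if (sum(apply(Xk, 2, var)) <= 1e-300) {
    stop("degenerate cohort: descriptor matrix has zero total variance", call. = FALSE)
  }
  pc <- stats::prcomp(Xk, center = TRUE, scale. = scale)
  # sign convention: largest-magnitude loading entry positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  variance <- pc$sdev^2
  fraction <- variance / sum(variance)
  cumfrac <- cumsum(fraction)
  n_retained <- which(cumfrac >= threshold - 1e-12)[1]
  n_positive <- sum(variance > 1e-10 * sum(variance))
  colnames(pc$x) <- paste0("PC", seq_len(ncol(pc$x)))
  colnames(pc$rotation) <- paste0("PC", seq_len(ncol(pc$rotation)))
  scores <- dplyr::bind_cols(
    tibble::tibble(participant_id = descriptors$participant_id),
    tibble::as_tibble(pc$x)
  )
  structure(
    list(
      mean = setNames(colMeans(X), feat),
      center = pc$center,
      loadings = pc$rotation,
      sdev = pc$sdev,
      variance = variance,
      fraction = fraction,
      cumulative = cumfrac,
      n_retained = n_retained,
      n_positive = n_positive,
      threshold = threshold,
      scaled = scale,
      scale_sd = if (scale) pc$scale else NULL,
      feature_names = feat,
      kept_features = keep,
      dropped_features = dropped,
      n = nrow(descriptors),
      scores = scores
    ),
    class = "torso_pca"
  )
}

#' @export
print.torso_pca <- function(x, ...) {
  cat("<torso_pca> ", x$n, " participants, ", length(x$kept_features),
      " features\n  ", x$n_positive, " positive-variance components; ",
      x$n_retained, " retained at ", round(100 * x$threshold), "% (cumulative ",
      round(100 * x$cumulative[x$n_retained], 1), "%)\n", sep = "")
  invisible(x)
}

#' Project descriptors onto the fitted shape feature basis
#'
#' `scores = t(loadings) %*% (descriptor - mean)`, retained components only
#' unless `n_components` says otherwise.
#'
#' @param descriptors Descriptor tibble (same columns as the training set).
#' @param model A `torso_pca`.
#' @param n_components Number of leading components to return (default: the
#'   model's retention count).
#' @return Tibble `participant_id`, `PC1` ... `PCm`.
#' @export
project_descriptors <- function(descriptors, model, n_components = NULL) {
  n_components <- n_components %||% model$n_retained
  if (!all(model$kept_features %in% names(descriptors))) {
    stop("descriptor columns do not match the fitted model", call. = FALSE)
  }
  X <- as.matrix(descriptors[, model$kept_features, drop = FALSE])
  Xc <- sweep(X, 2, model$center)
  if (model$scaled) Xc <- sweep(Xc, 2, model$scale_sd, "/")
  sc <- Xc %*% model$loadings[, seq_len(n_components), drop = FALSE]
  dplyr::bind_cols(
    tibble::tibble(participant_id = descriptors$participant_id),
    tibble::as_tibble(sc)
  )
}

#' Invert shape scores back to a flat descriptor
#'
#' @param model A `torso_pca`.
#' @param scores Named numeric vector of component scores (`PC1`, ...);
#'   components not named are taken as 0.
#' @return Named numeric descriptor vector (all original columns, dropped
#'   structural zeros reinstated).
#' @export
reconstruct_descriptor <- function(model, scores) {
  s <- setNames(numeric(ncol(model$loadings)), colnames(model$loadings))
  if (is.null(names(scores))) {
    s[seq_along(scores)] <- scores
  } else {
    s[names(scores)] <- scores
  }
  xk <- drop(model$loadings %*% s)
  if (model$scaled) xk <- xk * model$scale_sd
  xk <- xk + model$center
  out <- setNames(numeric(length(model$feature_names)), model$feature_names)
  out[model$kept_features] <- xk
  out[model$dropped_features] <- model$mean[model$dropped_features]
  out
}

#' Reconstruct the torso geometry at a principal-component extreme
#'
#' Builds the descriptor `mean + magnitude * loading`, inverts it slice by
#' slice ([reconstruct_profile()]), lofts the slices into a triangulated
#' surface (adjacent slices joined by triangle strips over the shared angle
#' grid, no end caps), and attaches the per-vertex signed radial deviation
#' from the average torso at the same (slice, angle).
#'
#' @param model A `torso_pca`.
#' @param pc_index 1-based component index (must be retained).
#' @param magnitude Score value; defaults to the cohort maximum on that
#'   component (use the cohort minimum for the opposite extreme).
#' @param n_theta Angular resolution of the lofted mesh.
#' @param aspect Mesh height as a multiple of the mean torso radius
#'   (visual proportion only; the descriptor itself is dimensionless).
#' @return List: `descriptor` (named vector), `mesh` (list `vertices`,
#'   `faces`), `deviation` (per-vertex), `magnitude`.
#' @export
reconstruct_extreme <- function(model, pc_index, magnitude = NULL,
                                n_theta = 360, aspect = 2.8) {
  if (pc_index < 1 || pc_index > model$n_retained) {
    stop("pc_index ", pc_index, " outside the retained range 1..",
         model$n_retained, call. = FALSE)
  }
  col <- paste0("PC", pc_index)
  magnitude <- magnitude %||% max(model$scores[[col]])
  desc <- reconstruct_descriptor(model, setNames(magnitude, col))
  mean_desc <- model$mean
  mesh_x <- loft_descriptor(desc, n_theta = n_theta, aspect = aspect)
  mesh_m <- loft_descriptor(mean_desc, n_theta = n_theta, aspect = aspect)
  deviation <- mesh_x$radii_flat - mesh_m$radii_flat
  list(descriptor = desc, mesh = list(vertices = mesh_x$vertices, faces = mesh_x$faces),
       deviation = deviation, magnitude = magnitude)
}

# Loft a flat descriptor into a triangulated tube surface.
loft_descriptor <- function(flat, n_theta = 360, aspect = 2.8) {
  spectra <- descriptor_to_spectra(flat)
  n_slices <- length(spectra)
  radii <- lapply(spectra, reconstruct_profile, n_theta = n_theta)
  rmean <- mean(unlist(radii))
  t <- 2 * pi * (0:(n_theta - 1)) / n_theta
  height <- aspect * rmean
  verts <- do.call(rbind, lapply(seq_len(n_slices), function(s) {
    r <- radii[[s]]
    cbind(x = r * cos(t), y = r * sin(t),
          z = rep(height * (s - 1) / (n_slices - 1), n_theta))
  }))
  faces <- do.call(rbind, lapply(seq_len(n_slices - 1), function(s) {
    a <- (s - 1) * n_theta + seq_len(n_theta)        # ring s
    b <- s * n_theta + seq_len(n_theta)              # ring s + 1
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    rbind(cbind(a, b, a2), cbind(a2, b, b2))
  }))
  list(
    vertices = tibble::tibble(x = verts[, 1], y = verts[, 2], z = verts[, 3]),
    faces = unname(faces),
    radii_flat = unlist(radii)
  )
}

#' Standardised radar values of the leading shape features
#'
#' Each participant's first `n_components` scores divided by the cohort
#' standard deviation of the corresponding component, giving the values
#' plotted on a shape radar diagram.
#'
#' @param scores Score tibble (`participant_id`, `PC1`, ...), typically
#'   `model$scores` or the output of [project_descriptors()].
#' @param model The fitted `torso_pca` (provides the cohort SDs).
#' @param n_components Number of leading components (default 5).
#' @return Tibble `participant_id` plus standardised `PC1..PCn`.
#' @export
radar_values <- function(scores, model, n_components = 5) {
  if (n_components > model$n_retained) {
    stop("n_components exceeds the number of retained components", call. = FALSE)
  }
  cols <- paste0("PC", seq_len(n_components))
  out <- scores[, c("participant_id", cols)]
  for (j in seq_len(n_components)) {
    out[[cols[j]]] <- out[[cols[j]]] / model$sdev[j]
  }
  out
}

#' @export
tidy.torso_pca <- function(x, ...) {
  tibble::tibble(
    component = paste0("PC", seq_along(x$variance)),
    std_dev = x$sdev,
    variance = x$variance,
    fraction = x$fraction,
    cumulative = x$cumulative,
    retained = seq_along(x$variance) <= x$n_retained
  )
}

#' @export
glance.torso_pca <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_features = length(x$kept_features),
    n_positive = x$n_positive,
    n_retained = x$n_retained,
    threshold = x$threshold,
    cumulative_at_retained = x$cumulative[x$n_retained],
    total_variance = sum(x$variance)
  )
}

#' Scree plot of a fitted shape PCA
#'
#' @param object A `torso_pca`.
#' @param n_components Number of leading components to show (default 20).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.torso_pca <- function(object, n_components = 20, ...) {
  d <- head(tidy(object), n_components)
  d$component <- factor(d$component, levels = d$component)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$fraction, fill = .data$retained)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative, group = 1)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative)) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue", `FALSE` = "grey70")) +
    ggplot2::labs(y = "explained variance fraction", x = NULL,
                  title = "Torso shape feature scree") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Radar diagram of one participant's leading shape features
#'
#' @param scores Score tibble (`participant_id`, `PC1`, ...).
#' @param model The fitted `torso_pca`.
#' @param participant Participant id to plot (default: first row).
#' @param n_components Number of leading components (default 5).
#' @return A ggplot object (polar coordinates).
#' @export
plot_radar <- function(scores, model, participant = NULL, n_components = 5) {
  rv <- radar_values(scores, model, n_components)
  participant <- participant %||% rv$participant_id[1]
  row <- rv[rv$participant_id == participant, , drop = FALSE]
  if (nrow(row) == 0) stop("participant not found: ", participant, call. = FALSE)
  long <- tidyr::pivot_longer(row, -"participant_id",
                              names_to = "component", values_to = "value")
  long$component <- factor(long$component, levels = paste0("PC", seq_len(n_components)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$component, y = .data$value, group = 1)) +
    ggplot2::geom_polygon(alpha = 0.3, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::labs(title = paste("Shape feature radar:", participant),
                  y = "score (cohort SD units)", x = NULL) +
    ggplot2::theme_minimal()
}

#' Persist or restore a fitted shape model as plain-text files
#'
#' Writes `mean.csv`, `loadings.csv`, `variance.csv`, `scores.csv` and
#' `metadata.json` into a directory.
#'
#' @param model A `torso_pca`.
#' @param dir Directory path (created if needed).
#' @return `write_shape_model()` the directory invisibly;
#'   `read_shape_model()` the `torso_pca`.
#' @export
write_shape_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tibble::tibble(feature = model$feature_names,
                                  mean = unname(model$mean[model$feature_names])),
                   file.path(dir, "mean.csv"))
  ld <- tibble::as_tibble(model$loadings)
  ld <- dplyr::bind_cols(tibble::tibble(feature = model$kept_features), ld)
  readr::write_csv(ld, file.path(dir, "loadings.csv"))
  readr::write_csv(tidy(model), file.path(dir, "variance.csv"))
  readr::write_csv(model$scores, file.path(dir, "scores.csv"))
  meta <- list(
    n = model$n, threshold = model$threshold, n_retained = model$n_retained,
    n_positive = model$n_positive, scaled = model$scaled,
    dropped_features = model$dropped_features,
    center = as.list(setNames(model$center, model$kept_features)),
    scale_sd = if (model$scaled) as.list(setNames(model$scale_sd, model$kept_features))
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_shape_model
#' @export
read_shape_model <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "metadata.json"))
  mean_tbl <- readr::read_csv(file.path(dir, "mean.csv"), show_col_types = FALSE)
  ld <- readr::read_csv(file.path(dir, "loadings.csv"), show_col_types = FALSE)
  vt <- readr::read_csv(file.path(dir, "variance.csv"), show_col_types = FALSE)
  scores <- readr::read_csv(file.path(dir, "scores.csv"), show_col_types = FALSE)
  kept <- ld$feature
  loadings <- as.matrix(ld[, -1])
  rownames(loadings) <- kept
  structure(
    list(
      mean = setNames(mean_tbl$mean, mean_tbl$feature),
      center = unlist(meta$center)[kept],
      loadings = loadings,
      sdev = vt$std_dev,
      variance = vt$variance,
      fraction = vt$fraction,
      cumulative = vt$cumulative,
      n_retained = meta$n_retained,
      n_positive = meta$n_positive,
      threshold = meta$threshold,
      scaled = isTRUE(meta$scaled),
      scale_sd = if (isTRUE(meta$scaled)) unlist(meta$scale_sd)[kept] else NULL,
      feature_names = mean_tbl$feature,
      kept_features = kept,
      dropped_features = meta$dropped_features,
      n = meta$n,
      scores = scores
    ),
    class = "torso_pca"
  )
}
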