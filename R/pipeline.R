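#' Pipeline run configuration
#'
#' Collects every tunable of the extraction and analysis pipeline with its
#' default, for serialisation alongside outputs (the run manifest). Defaults:
#' 21 slices of 2 mm at 5% intervals, 360 angle samples, 10 retained
#' frequency coefficients per slice, 95% explained-variance retention, and
#' stepwise thresholds 0.05 / 0.10.
#'
#' @param n_slices,thickness_mm,n_theta,spline_roughness,min_points_per_slice,min_points_segment,infill_max_deg Slicing controls (see [slice_profiles()]).
#' @param thickness_reference_mm Segment length (mm) at which `thickness_mm`
#'   is nominal: the band used for a participant is
#'   `thickness_mm * segment_length / thickness_reference_mm`, so slice
#'   membership — and with it the whole descriptor — is exactly invariant
#'   under uniform rescaling of the scan. `NULL` uses the absolute band.
#' @param scaling_variant Centroid-size variant, `"rss"` or `"sum"`.
#' @param n_coeff,drop_dc Spectrum controls (see [slice_spectrum()]).
#' @param variance_threshold PCA retention threshold.
#' @param n_shape_regression Number of leading components fed to stepwise.
#' @param p_enter,p_remove Stepwise thresholds.
#' @param seed Seed recorded in the manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(n_slices = 21, thickness_mm = 2, n_theta = 360,
                       thickness_reference_mm = 381,
                       spline_roughness = 1e-4, min_points_per_slice = 30,
                       min_points_segment = 1000, infill_max_deg = 15,
                       scaling_variant = "rss", n_coeff = 10, drop_dc = FALSE,
                       variance_threshold = 0.95, n_shape_regression = 11,
                       p_enter = 0.05, p_remove = 0.10, seed = 1L) {
  structure(
    list(n_slices = n_slices, thickness_mm = thickness_mm, n_theta = n_theta,
         thickness_reference_mm = thickness_reference_mm,
         spline_roughness = spline_roughness,
         min_points_per_slice = min_points_per_slice,
         min_points_segment = min_points_segment,
         infill_max_deg = infill_max_deg, scaling_variant = scaling_variant,
         n_coeff = n_coeff, drop_dc = drop_dc,
         variance_threshold = variance_threshold,
         n_shape_regression = n_shape_regression,
         p_enter = p_enter, p_remove = p_remove, seed = seed),
    class = "run_config"
  )
}

#' Read or write a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path YAML path.
#' @return `write_run_config()` the path invisibly; `read_run_config()` a
#'   `run_config` (unknown keys rejected).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, vals)
}

#' Extract the shape descriptor of one scan
#'
#' Runs the whole per-participant chain: anatomical frame from the
#' landmarks, transform, segmentation, 21-slice polar profiling, centroid
#' size scaling, and truncated Fourier coefficients.
#'
#' @param cloud Point-cloud tibble (scanner coordinates, mm).
#' @param landmarks Landmark tibble (same coordinates).
#' @param config A [run_config()].
#' @param participant_id Identifier; defaults to the cloud's `source_id`.
#' @return One-row descriptor tibble (see [assemble_descriptor()]).
#' @export
torso_descriptor <- function(cloud, landmarks, config = run_config(),
                             participant_id = NULL) {
  participant_id <- participant_id %||% attr(cloud, "source_id") %||% "unknown"
  frame <- build_frame(landmarks)
  cl <- to_anatomical(cloud, frame)
  lm <- landmarks
  lm[, c("x", "y", "z")] <- to_anatomical(lm[, c("x", "y", "z")], frame)
  seg <- segment_torso(cl, lm, min_points = config$min_points_segment)
  thick <- config$thickness_mm
  if (!is.null(config$thickness_reference_mm)) {
    thick <- thick * (seg$z_high - seg$z_low) / config$thickness_reference_mm
  }
  prof <- slice_profiles(seg, n_slices = config$n_slices,
                         thickness = thick,
                         n_theta = config$n_theta,
                         smoothing = config$spline_roughness,
                         min_points_per_slice = config$min_points_per_slice,
                         infill_max_deg = config$infill_max_deg)
  scaled <- scale_torso(prof, variant = config$scaling_variant)
  assemble_descriptor(scaled, participant_id, n_coeff = config$n_coeff,
                      drop_dc = config$drop_dc)
}

#' Extract descriptors for every scan in a directory
#'
#' Scans (`.ply`/`.obj`/`.xyz`) and landmark files (`.json`/`.csv`) are
#' paired by file stem. Per-participant failures are collected and skipped
#' unless `strict = TRUE`.
#'
#' @param scan_dir Directory of point-cloud files.
#' @param landmark_dir Directory of landmark files (defaults to `scan_dir`).
#' @param config A [run_config()].
#' @param strict Fail on the first participant error instead of skipping.
#' @param out_csv Optional path for the descriptor matrix CSV.
#' @return Descriptor tibble, one row per successful participant, with a
#'   `failures` attribute (named character vector of error messages).
#' @export
extract_descriptors <- function(scan_dir, landmark_dir = scan_dir,
                                config = run_config(), strict = FALSE,
                                out_csv = NULL) {
  scans <- list.files(scan_dir, pattern = "\\.(ply|obj|xyz)$", ignore.case = TRUE)
  lmf <- list.files(landmark_dir, pattern = "\\.(json|csv)$", ignore.case = TRUE)
  lmf <- lmf[tolower(basename(lmf)) != "anthro.csv"]
  ids <- intersect(tools::file_path_sans_ext(scans), tools::file_path_sans_ext(lmf))
  if (length(ids) == 0) {
    stop("no scan/landmark pairs found in ", scan_dir, call. = FALSE)
  }
  ids <- sort(ids)
  failures <- character(0)
  rows <- list()
  for (id in ids) {
    scan_path <- file.path(scan_dir, scans[match(id, tools::file_path_sans_ext(scans))])
    lm_path <- file.path(landmark_dir, lmf[match(id, tools::file_path_sans_ext(lmf))])
    res <- tryCatch({
      cloud <- read_point_cloud(scan_path)
      lm <- read_landmarks(lm_path)
      torso_descriptor(cloud, lm, config, participant_id = id)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (strict) stop("participant ", id, ": ", conditionMessage(res), call. = FALSE)
      failures[id] <- conditionMessage(res)
      message("skipping participant ", id, ": ", conditionMessage(res))
    } else {
      rows[[id]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "failures") <- failures
  if (!is.null(out_csv)) write_descriptors(out, out_csv)
  out
}

#' Fit shape features and export model artifacts
#'
#' Fits the cohort PCA, writes (optionally) the model directory, the scores
#' CSV and the +/- extreme deviation meshes for the first `n_extreme`
#' retained components.
#'
#' @param descriptors Descriptor tibble.
#' @param config A [run_config()].
#' @param out_dir Output directory, or `NULL` to skip persistence.
#' @param n_extreme Number of leading components to loft (default 5).
#' @return The fitted `torso_pca` (scores included).
#' @export
shape_features <- function(descriptors, config = run_config(), out_dir = NULL,
                           n_extreme = 5) {
  model <- fit_shape_pca(descriptors, threshold = config$variance_threshold)
  if (!is.null(out_dir)) {
    write_shape_model(model, out_dir)
    for (pc in seq_len(min(n_extreme, model$n_retained))) {
      for (side in c("min", "max")) {
        mag <- if (side == "min") min(model$scores[[paste0("PC", pc)]])
               else max(model$scores[[paste0("PC", pc)]])
        ex <- reconstruct_extreme(model, pc, magnitude = mag,
                                  n_theta = config$n_theta)
        write_deviation_mesh(ex$mesh, ex$deviation,
                             file.path(out_dir, sprintf("PC%d_%s.ply", pc, side)))
      }
    }
  }
  model
}

#' Run the statistical analysis stage
#'
#' Joins the anthropometrics and shape-score tables by `participant_id`,
#' derives the indices, z-scores every analysis column, and produces the
#' correlation table plus the three regression model families.
#'
#' @param anthro Anthropometrics tibble (see [read_anthro_table()]).
#' @param scores Shape-score tibble (`participant_id`, `PC1`, ...).
#' @param config A [run_config()].
#' @param out_json Optional path for the machine-readable model report.
#' @param out_cor_csv Optional path for the long correlation CSV.
#' @return List: `table` (standardised analysis tibble), `correlations`
#'   (`torso_cor`), `families` (`torso_models`).
#' @export
analyse_cohort <- function(anthro, scores, config = run_config(),
                           out_json = NULL, out_cor_csv = NULL) {
  tbl <- dplyr::inner_join(derive_indices(anthro), scores, by = "participant_id")
  if (nrow(tbl) < 10) {
    stop("only ", nrow(tbl), " participants join across the anthropometrics and ",
         "score tables (need at least 10)", call. = FALSE)
  }
  drop_cols <- c("skinfold_iliac_crest", "skinfold_supraspinale", "skinfold_abdominal")
  tbl <- tbl[, setdiff(names(tbl), drop_cols)]
  z <- zscore_table(tbl)
  cors <- pearson_matrix(z)
  families <- run_model_families(
    z, n_shape = min(config$n_shape_regression,
                     sum(grepl("^PC[0-9]+$", names(z)))),
    p_enter = config$p_enter, p_remove = config$p_remove
  )
  if (!is.null(out_json)) report_model_families(families, out_json)
  if (!is.null(out_cor_csv)) readr::write_csv(tidy(cors), out_cor_csv)
  list(table = z, correlations = cors, families = families)
}
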