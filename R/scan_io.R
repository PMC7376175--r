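#' Read a 3D point cloud
#'
#' Reads scan vertices from PLY (ASCII or binary little-endian), OBJ (`v`
#' records) or whitespace-separated XYZ files. Faces, colours and normals are
#' discarded; point order is preserved and points are never deduplicated.
#'
#' @param path Path to a `.ply`, `.obj` or `.xyz` file.
#' @param unit_scale Multiplier applied to every coordinate to bring the file
#'   into millimetres (e.g. `1000` for a file stored in metres). Default 1.
#' @param source_id Participant identifier attached to the cloud; defaults to
#'   the file name without extension.
#'
#' @return A tibble with columns `x`, `y`, `z` (mm) and attribute
#'   `source_id`.
#' @export
read_point_cloud <- function(path, unit_scale = 1, source_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  pts <- switch(ext,
    ply = read_ply(path)$vertices,
    obj = read_obj_vertices(path),
    xyz = read_xyz_vertices(path),
    stop("unsupported point-cloud extension: .", ext, call. = FALSE)
  )
  if (is.null(pts) || nrow(pts) == 0L) stop("no vertices found in ", path, call. = FALSE)
  if (!all(is.finite(as.matrix(pts)))) {
    stop("non-finite coordinates in ", path, call. = FALSE)
  }
  pts <- dplyr::mutate(pts, dplyr::across(dplyr::everything(), ~ .x * unit_scale))
  attr(pts, "source_id") <- source_id %||% tools::file_path_sans_ext(basename(path))
  pts
}

#' Write a point cloud or write/read a scalar-coloured mesh
#'
#' `write_point_cloud()` writes `x`,`y`,`z` columns to ASCII PLY, OBJ or XYZ.
#' `write_deviation_mesh()` writes a triangulated surface together with one
#' signed scalar per vertex (stored in the conventional PLY `quality`
#' property, float32) so deviation-from-average torsos can be inspected in
#' any mesh viewer. `read_mesh()` reads such a file back.
#'
#' @param cloud Data frame with numeric `x`, `y`, `z` columns.
#' @param path Output path; format chosen by extension for
#'   `write_point_cloud()`, always ASCII PLY for `write_deviation_mesh()`.
#' @return The path, invisibly.
#' @export
write_point_cloud <- function(cloud, path) {
  stopifnot(all(c("x", "y", "z") %in% names(cloud)))
  m <- as.matrix(cloud[, c("x", "y", "z")])
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    write_ply(m, path)
  } else if (ext == "obj") {
    writeLines(sprintf("v %.9g %.9g %.9g", m[, 1], m[, 2], m[, 3]), path)
  } else if (ext == "xyz") {
    writeLines(sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3]), path)
  } else {
    stop("unsupported extension: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_point_cloud
#' @param mesh List with `vertices` (data frame `x`,`y`,`z`) and `faces`
#'   (integer matrix, one 1-based vertex triple per row).
#' @param deviation Numeric vector, one signed scalar per vertex (mm; positive
#'   where the surface protrudes beyond the reference torso).
#' @export
write_deviation_mesh <- function(mesh, deviation, path) {
  v <- as.matrix(mesh$vertices[, c("x", "y", "z")])
  if (length(deviation) != nrow(v)) {
    stop("deviation length (", length(deviation), ") does not match vertex count (",
         nrow(v), ")", call. = FALSE)
  }
  write_ply(v, path, quality = deviation, faces = mesh$faces)
}

#' @rdname write_point_cloud
#' @export
read_mesh <- function(path) {
  read_ply(path)
}

# ---- PLY ------------------------------------------------------------------

ply_type_size <- c(
  char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
  short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
  int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
  float = 4L, float32 = 4L, double = 8L, float64 = 8L
)

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) {
    stop("not a PLY file (line 1): ", path, call. = FALSE)
  }
  fmt <- NULL
  elements <- list()  # name -> list(count, props = list(name, type, list))
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("PLY header not terminated in ", path, call. = FALSE)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("PLY property before element in header: ", line, call. = FALSE)
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], type = tok[4], count_type = tok[3], list = TRUE)
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], type = tok[2], list = FALSE)
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    } else {
      stop("unrecognised PLY header record: ", line, call. = FALSE)
    }
  }
  if (is.null(elements$vertex)) stop("PLY file has no vertex element: ", path, call. = FALSE)
  if (identical(fmt, "ascii")) {
    read_ply_ascii(con, elements, path)
  } else if (identical(fmt, "binary_little_endian")) {
    read_ply_binary(con, elements, path)
  } else {
    stop("unsupported PLY format '", fmt, "' in ", path, call. = FALSE)
  }
}

read_ply_ascii <- function(con, elements, path) {
  out <- list(vertices = NULL, faces = NULL, quality = NULL)
  for (el in elements) {
    if (any(vapply(el$props, `[[`, TRUE, "list"))) {
      # list-property element (faces): parse line by line
      lines <- readLines(con, n = el$count)
      if (el$name == "face") {
        rows <- lapply(seq_along(lines), function(i) {
          v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
          if (anyNA(v) || length(v) < 1L || length(v) != v[1] + 1L) {
            stop("malformed PLY face record ", i, " in ", path, call. = FALSE)
          }
          v[-1] + 1L  # to 1-based
        })
        if (length(rows) && length(unique(lengths(rows))) == 1L) {
          out$faces <- do.call(rbind, rows)
        } else {
          out$faces <- rows
        }
      }
      next
    }
    pn <- vapply(el$props, `[[`, "", "name")
    lines <- readLines(con, n = el$count)
    vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(lines), "\\s+"))))
    if (anyNA(vals) || length(vals) != el$count * length(pn)) {
      bad <- which(is.na(suppressWarnings(as.numeric(unlist(strsplit(trimws(lines[1]), "\\s+"))))))
      stop("malformed ", el$name, " records in PLY ", path,
           " (expected ", length(pn), " numeric fields per line)", call. = FALSE)
    }
    m <- matrix(vals, ncol = length(pn), byrow = TRUE, dimnames = list(NULL, pn))
    if (el$name == "vertex") {
      if (!all(c("x", "y", "z") %in% pn)) {
        stop("PLY vertex element lacks x/y/z in ", path, call. = FALSE)
      }
      out$vertices <- tibble::as_tibble(as.data.frame(m[, c("x", "y", "z"), drop = FALSE]))
      if ("quality" %in% pn) out$quality <- unname(m[, "quality"])
    }
  }
  out
}

read_ply_binary <- function(con, elements, path) {
  out <- list(vertices = NULL, faces = NULL, quality = NULL)
  for (el in elements) {
    if (any(vapply(el$props, `[[`, TRUE, "list"))) {
      if (el$name != "vertex") break  # faces etc. after vertices: not needed
      stop("list properties in PLY vertex element are unsupported: ", path, call. = FALSE)
    }
    sizes <- ply_type_size[vapply(el$props, `[[`, "", "type")]
    if (anyNA(sizes)) stop("unknown PLY property type in ", path, call. = FALSE)
    stride <- sum(sizes)
    raw <- readBin(con, "raw", n = stride * el$count)
    if (length(raw) < stride * el$count) {
      stop("truncated PLY binary payload in ", path, call. = FALSE)
    }
    if (el$name != "vertex") next
    offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
    pn <- vapply(el$props, `[[`, "", "name")
    read_col <- function(j) {
      type <- el$props[[j]]$type
      sz <- sizes[j]
      idx <- as.vector(outer(seq_len(sz), (seq_len(el$count) - 1L) * stride + offs[j], `+`))
      bytes <- raw[idx]
      what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
      readBin(bytes, what, n = el$count, size = sz, endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
    }
    need <- match(c("x", "y", "z"), pn)
    if (anyNA(need)) stop("PLY vertex element lacks x/y/z in ", path, call. = FALSE)
    out$vertices <- tibble::tibble(
      x = read_col(need[1]), y = read_col(need[2]), z = read_col(need[3])
    )
    if ("quality" %in% pn) out$quality <- read_col(match("quality", pn))
  }
  out
}

write_ply <- function(vertices, path, quality = NULL, faces = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "ply", "format ascii 1.0", "comment written by torsomorph",
    sprintf("element vertex %d", nrow(vertices)),
    "property float x", "property float y", "property float z"
  )
  if (!is.null(quality)) hdr <- c(hdr, "property float quality")
  if (!is.null(faces)) {
    hdr <- c(hdr, sprintf("element face %d", nrow(faces)),
             "property list uchar int vertex_indices")
  }
  hdr <- c(hdr, "end_header")
  writeLines(hdr, con)
  body <- if (is.null(quality)) {
    sprintf("%.9g %.9g %.9g", vertices[, 1], vertices[, 2], vertices[, 3])
  } else {
    # %.9g round-trips float32 exactly
    sprintf("%.9g %.9g %.9g %.9g", vertices[, 1], vertices[, 2], vertices[, 3], quality)
  }
  writeLines(body, con)
  if (!is.null(faces)) {
    writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L), con)
  }
  invisible(path)
}

# ---- OBJ / XYZ ------------------------------------------------------------

read_obj_vertices <- function(path) {
  lines <- readLines(path)
  vi <- grep("^v(\\s)", lines)
  if (length(vi) == 0L) return(tibble::tibble(x = double(), y = double(), z = double()))
  parts <- strsplit(trimws(lines[vi]), "\\s+")
  bad <- which(lengths(parts) < 4L)
  if (length(bad)) {
    stop("malformed OBJ vertex at line ", vi[bad[1]], " in ", path, call. = FALSE)
  }
  m <- t(vapply(parts, function(p) suppressWarnings(as.numeric(p[2:4])), numeric(3)))
  if (anyNA(m)) {
    stop("non-numeric OBJ vertex at line ", vi[which(rowSums(is.na(m)) > 0)[1]],
         " in ", path, call. = FALSE)
  }
  tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3])
}

read_xyz_vertices <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:],]+")
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("malformed XYZ record at line ", bad[1], " in ", path, call. = FALSE)
  m <- t(vapply(parts, function(p) suppressWarnings(as.numeric(p[1:3])), numeric(3)))
  if (anyNA(m)) {
    stop("non-numeric XYZ record at line ", which(rowSums(is.na(m)) > 0)[1],
         " in ", path, call. = FALSE)
  }
  tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3])
}

# ---- landmarks ------------------------------------------------------------

required_landmarks <- c("xiphoid_process", "t9_vertebra", "asis_left", "asis_right")

landmark_synonyms <- c(
  xiphoid = "xiphoid_process", xiphoid_process = "xiphoid_process",
  t9 = "t9_vertebra", t9_vertebra = "t9_vertebra",
  "9th_thoracic_vertebra" = "t9_vertebra", "9th_thoracic_vertebrae" = "t9_vertebra",
  thoracic_vertebra_9 = "t9_vertebra",
  asis_left = "asis_left", left_asis = "asis_left", asis_l = "asis_left",
  anterior_superior_iliac_spine_left = "asis_left",
  asis_right = "asis_right", right_asis = "asis_right", asis_r = "asis_right",
  anterior_superior_iliac_spine_right = "asis_right"
)

normalise_landmark_name <- function(name) {
  key <- gsub("[^a-z0-9]+", "_", tolower(trimws(name)))
  key <- gsub("^_|_$", "", key)
  unname(ifelse(key %in% names(landmark_synonyms), landmark_synonyms[key], key))
}

#' Read bony landmark coordinates
#'
#' Accepts a JSON object mapping landmark name to an `[x, y, z]` triple, or a
#' CSV file with columns `name,x,y,z`. Names are normalised to a canonical
#' lower-snake-case vocabulary; the required quartet (`xiphoid_process`,
#' `t9_vertebra`, `asis_left`, `asis_right`) must each appear exactly once.
#'
#' @param path Path to a `.json` or `.csv` landmark file (coordinates in mm).
#' @return A tibble with columns `name`, `x`, `y`, `z` and logical `required`.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path)
    if (!is.list(obj) || is.null(names(obj))) {
      stop("landmark JSON must be an object of name: [x,y,z] pairs", call. = FALSE)
    }
    lm <- tibble::tibble(
      name = names(obj),
      x = vapply(obj, function(v) as.numeric(v[1]), 1),
      y = vapply(obj, function(v) as.numeric(v[2]), 1),
      z = vapply(obj, function(v) as.numeric(v[3]), 1)
    )
  } else if (ext == "csv") {
    lm <- readr::read_csv(path, show_col_types = FALSE)
    if (!all(c("name", "x", "y", "z") %in% names(lm))) {
      stop("landmark CSV needs columns name,x,y,z", call. = FALSE)
    }
    lm <- tibble::as_tibble(lm[, c("name", "x", "y", "z")])
  } else {
    stop("unsupported landmark file extension: .", ext, call. = FALSE)
  }
  as_landmark_set(lm)
}

#' Validate a landmark table
#'
#' @param lm Data frame with columns `name`, `x`, `y`, `z`.
#' @return The validated tibble with normalised names and a `required` flag.
#' @export
as_landmark_set <- function(lm) {
  lm <- tibble::as_tibble(lm)
  lm$name <- normalise_landmark_name(lm$name)
  dup <- lm$name[duplicated(lm$name)]
  if (length(dup)) {
    stop("duplicate landmark name(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(required_landmarks, lm$name)
  if (length(missing)) {
    stop("missing required landmark(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(as.matrix(lm[, c("x", "y", "z")])))) {
    stop("non-finite landmark coordinates", call. = FALSE)
  }
  lp <- landmark_point(lm, "asis_left"); rp <- landmark_point(lm, "asis_right")
  if (all(lp == rp)) stop("asis_left and asis_right coincide", call. = FALSE)
  xp <- landmark_point(lm, "xiphoid_process"); tp <- landmark_point(lm, "t9_vertebra")
  if (all(xp == tp)) stop("xiphoid_process and t9_vertebra coincide", call. = FALSE)
  lm$required <- lm$name %in% required_landmarks
  lm
}

landmark_point <- function(lm, name) {
  i <- match(name, lm$name)
  if (is.na(i)) stop("landmark not present: ", name, call. = FALSE)
  c(x = lm$x[i], y = lm$y[i], z = lm$z[i])
}

#' Read a per-participant manual anthropometrics table
#'
#' Expects a CSV with columns `participant_id`, `stature` (m), `mass` (kg),
#' `waist_girth` (m), `hip_girth` (m) and skinfold thicknesses (mm)
#' `skinfold_iliac_crest`, `skinfold_supraspinale`, `skinfold_abdominal`.
#' Missing skinfolds are encoded as empty cells. All present values must be
#' strictly positive; statures outside \[1.0, 2.5\] m trigger a warning.
#'
#' @param path CSV path.
#' @return A tibble, one row per participant.
#' @export
read_anthro_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  validate_anthro_table(tbl)
}

#' @rdname read_anthro_table
#' @param tbl Data frame to validate in place of a file.
#' @export
validate_anthro_table <- function(tbl) {
  need <- c("participant_id", "stature", "mass", "waist_girth", "hip_girth")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    stop("anthropometrics table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sf_cols <- c("skinfold_iliac_crest", "skinfold_supraspinale", "skinfold_abdominal")
  num_cols <- intersect(c(need[-1], sf_cols), names(tbl))
  for (cc in num_cols) {
    v <- tbl[[cc]]
    if (any(!is.na(v) & v <= 0)) {
      stop("non-positive value in column ", cc, call. = FALSE)
    }
  }
  out_of_range <- !is.na(tbl$stature) & (tbl$stature < 1.0 | tbl$stature > 2.5)
  if (any(out_of_range)) {
    warning(sum(out_of_range), " stature value(s) outside the plausible [1.0, 2.5] m range; ",
            "check units (statures must be in metres)", call. = FALSE)
  }
  tibble::as_tibble(tbl)
}
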