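#' Truncated Fourier spectrum of one slice radius waveform
#'
#' Computes the first `n_coeff` complex Fourier coefficients of the uniformly
#' sampled radius waveform, `c_k = (1/N) * sum_j r_j exp(-2i*pi*k*j/N)` for
#' `k = 0..n_coeff-1`. Higher frequencies are discarded as low-amplitude
#' noise. The `1/N` normalisation makes coefficients independent of the
#' angular sampling density. With `drop_dc = TRUE` the retained band is
#' `k = 1..n_coeff` instead, excluding the per-slice mean radius.
#'
#' @param radii Numeric vector of `N >= 2 * n_coeff` uniform radius samples.
#' @param n_coeff Number of retained coefficients (default 10).
#' @param drop_dc Exclude the DC term and keep `k = 1..n_coeff`? Default
#'   `FALSE`: after whole-torso scaling the per-slice DC encodes the relative
#'   girth profile along the torso, a genuine shape feature.
#' @return Complex vector of length `n_coeff`, names `k0`, `k1`, ...
#' @export
slice_spectrum <- function(radii, n_coeff = 10, drop_dc = FALSE) {
  n <- length(radii)
  if (n < 2 * n_coeff) {
    stop("resolution error: ", n, " angle samples cannot support ", n_coeff,
         " frequency coefficients (need at least ", 2 * n_coeff, ")", call. = FALSE)
  }
  co <- fft(radii)[seq_len(n_coeff + 1L)] / n
  ks <- if (drop_dc) 1:n_coeff else 0:(n_coeff - 1)
  out <- co[ks + 1L]
  if (!drop_dc) out[1] <- complex(real = Re(out[1]), imaginary = 0)
  names(out) <- paste0("k", ks)
  out
}

#' Reconstruct a radius waveform from a truncated spectrum
#'
#' Real-signal conjugate-symmetric inversion of the retained band:
#' `r_j = c_0 + 2 * sum_k (Re(c_k) cos(k t_j) - Im(c_k) sin(k t_j))` on
#' `t_j = 2*pi*j/n_theta`. For a band-limited input the forward transform
#' followed by reconstruction is exact.
#'
#' @param spectrum Complex coefficient vector named `k<freq>` (as returned by
#'   [slice_spectrum()]).
#' @param n_theta Number of output angle samples.
#' @return Numeric radius waveform of length `n_theta`.
#' @export
reconstruct_profile <- function(spectrum, n_theta = 360) {
  ks <- as.integer(sub("^k", "", names(spectrum)))
  if (anyNA(ks)) ks <- seq_along(spectrum) - 1L
  t <- 2 * pi * (0:(n_theta - 1)) / n_theta
  out <- numeric(n_theta)
  for (i in seq_along(ks)) {
    k <- ks[i]
    if (k == 0L) {
      out <- out + Re(spectrum[i])
    } else {
      out <- out + 2 * (Re(spectrum[i]) * cos(k * t) - Im(spectrum[i]) * sin(k * t))
    }
  }
  out
}

#' Column names of the flattened 420-value descriptor
#'
#' Order is slice-major: for slice `s` (0..20) the 10 real parts
#' `s{s}_k{0..9}_re` come first, then the 10 imaginary parts
#' `s{s}_k{0..9}_im`, i.e. flat index `s*20 + k` for real parts and
#' `s*20 + 10 + k` for imaginary parts (0-based).
#'
#' @param n_slices Number of slices (default 21).
#' @param n_coeff Coefficients per slice (default 10).
#' @param drop_dc Use the `k = 1..n_coeff` band (see [slice_spectrum()]).
#' @return Character vector of length `n_slices * n_coeff * 2`.
#' @export
descriptor_columns <- function(n_slices = 21, n_coeff = 10, drop_dc = FALSE) {
  ks <- if (drop_dc) 1:n_coeff else 0:(n_coeff - 1)
  unlist(lapply(0:(n_slices - 1), function(s) {
    c(sprintf("s%02d_k%d_re", s, ks), sprintf("s%02d_k%d_im", s, ks))
  }))
}

#' Assemble the per-participant shape descriptor
#'
#' Computes the truncated spectrum of each slice of a scaled profile set and
#' flattens the 21 x 10 complex coefficients to 420 named real values
#' (see [descriptor_columns()] for the layout). Imaginary parts of the DC
#' coefficients are structurally zero.
#'
#' @param profiles Scaled profile tibble from [scale_torso()] (21 rows in
#'   slice order).
#' @param participant_id Identifier stored in the leading column.
#' @param n_coeff Retained coefficients per slice (default 10).
#' @param drop_dc See [slice_spectrum()].
#' @return One-row tibble: `participant_id` plus 420 descriptor columns.
#' @export
assemble_descriptor <- function(profiles, participant_id, n_coeff = 10,
                                drop_dc = FALSE) {
  if (is.unsorted(profiles$slice_index, strictly = TRUE)) {
    stop("profiles must be in increasing slice order", call. = FALSE)
  }
  spectra <- lapply(profiles$radii, slice_spectrum, n_coeff = n_coeff,
                    drop_dc = drop_dc)
  flat <- unlist(lapply(spectra, function(sp) c(Re(sp), Im(sp))))
  names(flat) <- descriptor_columns(nrow(profiles), n_coeff, drop_dc)
  dplyr::bind_cols(
    tibble::tibble(participant_id = participant_id),
    tibble::as_tibble(as.list(flat))
  )
}

#' Split a flat descriptor back into per-slice complex spectra
#'
#' Inverse of the flattening in [assemble_descriptor()].
#'
#' @param flat Named numeric vector (or one-row data frame) of descriptor
#'   values in [descriptor_columns()] order.
#' @param n_coeff Coefficients per slice (default 10).
#' @return List of complex coefficient vectors, one per slice.
#' @export
descriptor_to_spectra <- function(flat, n_coeff = 10) {
  if (is.data.frame(flat)) {
    flat <- unlist(flat[, setdiff(names(flat), "participant_id"), drop = FALSE])
  }
  stopifnot(length(flat) %% (2 * n_coeff) == 0)
  n_slices <- length(flat) / (2 * n_coeff)
  nm <- names(flat)[seq_len(n_coeff)]
  ks <- sub("^s[0-9]+_(k[0-9]+)_re$", "\\1", nm)
  lapply(seq_len(n_slices), function(s) {
    off <- (s - 1) * 2 * n_coeff
    sp <- complex(real = flat[off + seq_len(n_coeff)],
                  imaginary = flat[off + n_coeff + seq_len(n_coeff)])
    names(sp) <- if (all(grepl("^k[0-9]+$", ks))) ks else paste0("k", 0:(n_coeff - 1))
    sp
  })
}

#' Read or write a descriptor matrix CSV
#'
#' One row per participant, `participant_id` plus the 420 named coefficient
#' columns.
#'
#' @param descriptors Descriptor tibble.
#' @param path CSV path.
#' @return `write_descriptors()` the path invisibly; `read_descriptors()` the
#'   tibble.
#' @export
write_descriptors <- function(descriptors, path) {
  readr::write_csv(descriptors, path)
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
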