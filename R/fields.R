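#' Sampled complex optical field
#'
#' Container for a square 2-D complex amplitude with its grid metadata.
#' All lengths are micrometers; intensities are |values|^2.
#'
#' @param values square complex matrix.
#' @param pixel_pitch sampling pitch in micrometers (> 0).
#' @param wavelength wavelength in micrometers (> 0).
#' @param plane_label free-text label of the plane the field lives on.
#' @return object of class `complex_field`.
#' @export
complex_field <- function(values, pixel_pitch, wavelength, plane_label = "") {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (nrow(values) != ncol(values)) stop("field grid must be square")
  if (pixel_pitch <= 0 || wavelength <= 0)
    stop("pixel_pitch and wavelength must be positive")
  if (!is.complex(values)) values <- values + 0i
  structure(list(values = values, pixel_pitch = pixel_pitch,
                 wavelength = wavelength, plane_label = plane_label),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("complex_field [%s]: %d x %d px, pitch %g um, lambda %g um, energy %.4g\n",
              x$plane_label, nrow(x$values), ncol(x$values),
              x$pixel_pitch, x$wavelength, field_energy(x)))
  invisible(x)
}

#' Total energy of a field
#'
#' \eqn{\sum |U|^2 \cdot \Delta^2} with \eqn{\Delta} the pixel pitch.
#'
#' @param field a [complex_field()].
#' @return scalar energy (arbitrary units * um^2).
#' @export
field_energy <- function(field) {
  sum(Mod(field$values)^2) * field$pixel_pitch^2
}

# --- centered FFT helpers ---------------------------------------------------
# DC-centered ("fftshift") layout everywhere: pixel (N/2, N/2) in 0-based
# coordinates is DC. Both directions are scaled 1/N so the transform pair is
# unitary and involution-free of stray constants.

fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  m[c((s1 + 1):n1, 1:s1), c((s2 + 1):n2, 1:s2), drop = FALSE]
}

ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- ceiling(n1 / 2); s2 <- ceiling(n2 / 2)
  m[c((s1 + 1):n1, 1:s1), c((s2 + 1):n2, 1:s2), drop = FALSE]
}

fft2c <- function(m) fftshift2(stats::fft(ifftshift2(m))) / nrow(m)

ifft2c <- function(m) fftshift2(stats::fft(ifftshift2(m), inverse = TRUE)) / nrow(m)

# Centered spatial-frequency axis in cycles per um, shifted layout (DC at
# index N/2, 0-based).
freq_axis <- function(n, pitch) (seq_len(n) - 1 - floor(n / 2)) / (n * pitch)

#' Save / load a complex field as float TIFF + JSON sidecar
#'
#' The real and imaginary parts are stored as two 32-bit float TIFF planes,
#' each affinely rescaled into \[0, 1\]; the offsets/scales plus the grid
#' metadata live in a JSON sidecar next to the TIFF. The round trip is exact
#' to 32-bit float precision; this is an export format, not an archival
#' double-precision dump.
#'
#' @param field a [complex_field()].
#' @param path output `.tif` path; the sidecar is `paste0(path, ".json")`.
#' @return `save_field` returns `path` invisibly; `load_field` the field.
#' @export
save_field <- function(field, path) {
  re <- Re(field$values); im <- Im(field$values)
  rng <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi <= lo) hi <- lo + 1
    c(lo, hi)
  }
  r1 <- rng(re); r2 <- rng(im)
  tiff::writeTIFF(list((re - r1[1]) / (r1[2] - r1[1]),
                       (im - r2[1]) / (r2[2] - r2[1])),
                  path, bits.per.sample = 32L)
  jsonlite::write_json(list(pixel_pitch = field$pixel_pitch,
                            wavelength = field$wavelength,
                            plane_label = field$plane_label,
                            re_range = r1, im_range = r2),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_field
#' @export
load_field <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  re <- planes[[1]] * (meta$re_range[2] - meta$re_range[1]) + meta$re_range[1]
  im <- planes[[2]] * (meta$im_range[2] - meta$im_range[1]) + meta$im_range[1]
  complex_field(matrix(complex(real = re, imaginary = im), nrow(re)),
                meta$pixel_pitch, meta$wavelength, meta$plane_label)
}

#' Export an intensity map as 16-bit PNG
#'
#' @param intensity non-negative matrix.
#' @param path output path.
#' @param normalize rescale to the full 16-bit range (default TRUE).
#' @return `path`, invisibly.
#' @export
write_intensity_png <- function(intensity, path, normalize = TRUE) {
  m <- intensity
  if (normalize) {
    lo <- min(m); hi <- max(m)
    m <- if (hi > lo) (m - lo) / (hi - lo) else m * 0
  }
  png::writePNG(pmin(pmax(m, 0), 1), path, dpi = NULL)
  invisible(path)
}
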