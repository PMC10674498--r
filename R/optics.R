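#' Optical system configuration for the simulated SA-DHM
#'
#' Defaults reproduce the simulation layout of the full-scale study: a
#' 2240 x 2240 grid at 1 um pitch, wavelength 0.532 um, objective/tube
#' focal lengths f1 = 10 mm and f2 = 200 mm, an out-of-focus observation
#' plane d = 10 mm beyond the camera, and a 224-px-diameter Fourier-plane
#' mask realizing the objective NA of 0.0266 (the full grid corresponds to
#' NA 0.266). The circular aperture that defines the Zernike domain has a
#' default radius of a quarter of the grid (560 px at full scale); its
#' physical diameter is a free parameter of the simulation and is recorded
#' in every manifest.
#'
#' All planes are sampled on the same grid in sample-referred coordinates:
#' the 4-f magnification -f2/f1 is absorbed into bookkeeping rather than
#' resampling (see the methods vignette).
#'
#' @param n_pixels grid side (default 2240).
#' @param pixel_pitch um (default 1).
#' @param wavelength um (default 0.532).
#' @param f1,f2 objective / tube focal lengths, mm.
#' @param defocus_d out-of-focus distance beyond the camera plane, mm.
#' @param fourier_mask_diameter_px NA-mask diameter in Fourier pixels.
#' @param aperture_radius_px radius of the Zernike-domain aperture, px.
#' @return object of class `optical_config`.
#' @export
optical_config <- function(n_pixels = 2240L, pixel_pitch = 1, wavelength = 0.532,
                           f1 = 10, f2 = 200, defocus_d = 10,
                           fourier_mask_diameter_px = 224L,
                           aperture_radius_px = n_pixels / 4) {
  cfg <- list(n_pixels = as.integer(n_pixels), pixel_pitch = pixel_pitch,
              wavelength = wavelength, f1 = f1, f2 = f2, defocus_d = defocus_d,
              fourier_mask_diameter_px = as.integer(fourier_mask_diameter_px),
              aperture_radius_px = aperture_radius_px)
  with(cfg, {
    if (any(c(pixel_pitch, wavelength, f1, f2) <= 0))
      stop("all lengths must be positive")
    if (fourier_mask_diameter_px > n_pixels)
      stop("Fourier mask does not fit in grid")
    if (2 * aperture_radius_px > n_pixels)
      stop("aperture does not fit in grid")
  })
  structure(cfg, class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(paste0("optical_config: %d px @ %g um, lambda %g um, f1/f2 %g/%g mm,",
                     " d %g mm, mask %d px (NA %.4f), aperture r %g px\n"),
              x$n_pixels, x$pixel_pitch, x$wavelength, x$f1, x$f2, x$defocus_d,
              x$fourier_mask_diameter_px, mask_na(x), x$aperture_radius_px))
  invisible(x)
}

#' Scaled-down configuration preserving all dimensionless ratios
#'
#' The mask-to-grid ratio (224/2240), aperture-to-grid ratio (1/4), pitch
#' and wavelength are preserved, so NA and the dark-field geometry stay
#' congruent with the full-scale layout; the out-of-focus distance scales
#' with the grid so the defocus spread stays a fixed fraction of the field
#' of view. Only the field of view shrinks.
#'
#' @param n_pixels grid side of the scaled preset (e.g. 560 or 280).
#' @param ... overrides passed to [optical_config()].
#' @return an `optical_config`.
#' @export
scaled_optical_config <- function(n_pixels = 560L, ...) {
  optical_config(n_pixels = n_pixels,
                 fourier_mask_diameter_px = as.integer(round(n_pixels / 10)),
                 aperture_radius_px = n_pixels / 4,
                 defocus_d = 10 * n_pixels / 2240, ...)
}

#' Read an optical configuration from YAML or JSON
#'
#' Any subset of the [optical_config()] fields may be given; the rest keep
#' their defaults.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return an `optical_config`.
#' @export
read_optical_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(optical_config, lst)
}

config_grid <- function(config) {
  unit_disk_grid(config$n_pixels, config$aperture_radius_px)
}

#' Numerical aperture realized by a centered Fourier-plane mask
#'
#' NA = wavelength * (mask radius in frequency units) = lambda * (d/2) /
#' (N * pitch). With the default geometry the 224-px mask gives NA 0.0266
#' and the full 2240-px grid gives NA 0.266.
#'
#' @param config an [optical_config()].
#' @param diameter_px mask diameter in pixels (default: the config's mask).
#' @return the numerical aperture (dimensionless).
#' @export
mask_na <- function(config, diameter_px = config$fourier_mask_diameter_px) {
  config$wavelength * (diameter_px / 2) / (config$n_pixels * config$pixel_pitch)
}

#' Illumination wavevector of a directional plane wave
#'
#' The micro-lens at position (xi, yi), imaged with magnification M and a
#' condenser working distance WD, produces a plane wave whose wavevector is
#' k (M xi, M yi, WD) / ||(M xi, M yi, WD)|| with k = 2 pi / lambda.
#'
#' @param M magnification factor of the relay between the lens array and the
#'   condenser; no default on purpose, callers must supply it.
#' @param xi,yi lens position, mm.
#' @param WD condenser working distance, mm (> 0).
#' @param wavelength um.
#' @return named numeric (kx, ky, kz) in rad/mm; kz > 0.
#' @export
illumination_wavevector <- function(M, xi, yi, WD, wavelength) {
  if (WD <= 0) stop("WD must be positive")
  if (wavelength <= 0) stop("wavelength must be positive")
  k <- 2 * pi / (wavelength * 1e-3)  # rad/mm
  v <- c(M * xi, M * yi, WD)
  kv <- k * v / sqrt(sum(v^2))
  names(kv) <- c("kx", "ky", "kz")
  kv
}

#' Band-limited angular-spectrum free-space propagation
#'
#' Exact transfer function exp(i kz d) with kz = 2 pi sqrt(1/lambda^2 -
#' fx^2 - fy^2); evanescent components are zeroed, and the band limit of
#' the sampled transfer function (fx up to 1 / (lambda sqrt((2 d df)^2 +
#' 1))) suppresses wrap-around aliasing for long throws. Negative distance
#' back-propagates.
#'
#' @param field a [complex_field()].
#' @param distance mm; may be negative.
#' @return the propagated `complex_field` (grid metadata preserved).
#' @export
propagate <- function(field, distance) {
  if (distance == 0) return(field)
  n <- nrow(field$values)
  key <- sprintf("asm_%d_%g_%g_%g", n, field$pixel_pitch, field$wavelength,
                 distance)
  H <- cache_get(key, cache_if = n <= 1024, function() {
    d_um <- distance * 1e3
    f <- freq_axis(n, field$pixel_pitch)
    fx2 <- matrix(rep(f^2, each = n), n, n)
    fy2 <- matrix(rep(f^2, times = n), n, n)
    arg <- 1 / field$wavelength^2 - fx2 - fy2
    kz <- 2 * pi * sqrt(pmax(arg, 0))
    H <- exp(1i * kz * d_um)
    H[arg <= 0] <- 0
    flim <- 1 / (field$wavelength *
                   sqrt((2 * d_um / (n * field$pixel_pitch))^2 + 1))
    H[fx2 > flim^2 | fy2 > flim^2] <- 0
    H
  })
  out <- ifft2c(fft2c(field$values) * H)
  complex_field(out, field$pixel_pitch, field$wavelength, field$plane_label)
}

#' Fourier transform by an ideal lens
#'
#' Centered discrete Fourier transform with output-plane sampling
#' lambda f / (N pitch); the amplitude is rescaled so total energy is
#' preserved exactly. `lens_inverse_fourier` is the inverse-direction
#' counterpart (tube lens of a 4-f pair).
#'
#' @param field a [complex_field()].
#' @param focal_length mm (> 0).
#' @return a `complex_field` in the Fourier plane.
#' @export
lens_fourier <- function(field, focal_length) {
  if (focal_length <= 0) stop("focal_length must be positive")
  n <- nrow(field$values)
  pitch_out <- field$wavelength * focal_length * 1e3 / (n * field$pixel_pitch)
  vals <- fft2c(field$values) * (field$pixel_pitch / pitch_out)
  complex_field(vals, pitch_out, field$wavelength,
                paste0(field$plane_label, " ->F"))
}

#' @rdname lens_fourier
#' @export
lens_inverse_fourier <- function(field, focal_length) {
  if (focal_length <= 0) stop("focal_length must be positive")
  n <- nrow(field$values)
  pitch_out <- field$wavelength * focal_length * 1e3 / (n * field$pixel_pitch)
  vals <- ifft2c(field$values) * (field$pixel_pitch / pitch_out)
  complex_field(vals, pitch_out, field$wavelength,
                paste0(field$plane_label, " ->Finv"))
}

#' Apply the numerical-aperture mask in the Fourier plane
#'
#' Zeroes the amplitude outside the centered circle of the given pixel
#' diameter (DC at 0-based pixel (N/2, N/2)).
#'
#' @param field Fourier-plane [complex_field()].
#' @param mask_diameter_px mask diameter in pixels.
#' @return masked `complex_field`.
#' @export
apply_na_mask <- function(field, mask_diameter_px) {
  n <- nrow(field$values)
  if (mask_diameter_px > n) stop("mask larger than grid")
  vals <- field$values * na_mask_matrix(n, mask_diameter_px)
  complex_field(vals, field$pixel_pitch, field$wavelength, field$plane_label)
}

na_mask_matrix <- function(n, diameter_px, center_px = c(n / 2, n / 2)) {
  idx <- seq_len(n) - 1
  dx2 <- matrix(rep((idx - center_px[2])^2, each = n), n, n)
  dy2 <- matrix(rep((idx - center_px[1])^2, times = n), n, n)
  (dx2 + dy2 <= (diameter_px / 2)^2) * 1
}

# 4-f imaging chain on congruent grids: aperture-plane field -> Fourier
# plane (lens f1) -> NA mask -> camera plane (lens f2, inverse transform).
# Output stays on the input grid in sample-referred coordinates (the -f2/f1
# magnification is bookkeeping only), so Fourier-domain synthesis is pure
# index arithmetic. Returns both the masked Fourier-plane field and the
# camera field.
image_through_4f <- function(field, config) {
  Fplane <- fft2c(field$values)
  Fmask <- Fplane * na_mask_matrix(nrow(Fplane), config$fourier_mask_diameter_px)
  cam <- ifft2c(Fmask)
  list(fourier = complex_field(Fmask, field$pixel_pitch, field$wavelength, "fourier"),
       camera = complex_field(cam, field$pixel_pitch, field$wavelength, "camera"))
}

#' Carrier displacement of a tilted wavefront, in Fourier pixels
#'
#' Tilt coefficients (c1, c2) in radians at the aperture rim give a plane
#' phase (c2 x + c1 y) / R, i.e. a spatial frequency (c2, c1) / (2 pi R)
#' cycles/px, which the centered FFT maps to a displacement of
#' N (c2, c1) / (2 pi R) pixels from DC (x along +columns, y upward).
#'
#' @param coeffs 10-element coefficient vector.
#' @param config an [optical_config()].
#' @return named numeric (sx, sy): displacement in Fourier pixels.
#' @export
carrier_fourier_px <- function(coeffs, config) {
  coeffs <- zernike_coefficients(coeffs)
  s <- config$n_pixels * c(coeffs[3], coeffs[2]) /
    (2 * pi * config$aperture_radius_px)
  names(s) <- c("sx", "sy")
  s
}

#' Is an illumination dark-field?
#'
#' TRUE when the carrier displacement radius exceeds the NA-mask radius, so
#' the un-diffracted beam misses the objective and only aperture-edge
#' diffraction reaches the camera.
#'
#' @inheritParams carrier_fourier_px
#' @return logical.
#' @export
is_dark_field <- function(coeffs, config) {
  s <- carrier_fourier_px(coeffs, config)
  sqrt(sum(s^2)) > config$fourier_mask_diameter_px / 2
}

#' Simulate one observation of the aberrated illumination beam
#'
#' The aberration phase map is placed on the circular aperture (amplitude =
#' aperture mask, phase = Zernike sum), imaged through the 4-f system with
#' the NA mask, and additionally observed in the out-of-focus plane d mm
#' beyond the camera. Deterministic for fixed inputs.
#'
#' @param coeffs 10-element Zernike coefficient vector (radians).
#' @param config an [optical_config()].
#' @return list with `fourier_intensity`, `focal_intensity`,
#'   `defocus_intensity` (matrices) and `camera_field` (a [complex_field()]).
#' @export
simulate_observation <- function(coeffs, config) {
  grid <- config_grid(config)
  phase <- zernike_phase_map(coeffs, grid)
  amp <- attr(phase, "mask")
  U0 <- complex_field(amp * exp(1i * phase), config$pixel_pitch,
                      config$wavelength, "aperture")
  img <- image_through_4f(U0, config)
  defoc <- propagate(img$camera, config$defocus_d)
  list(fourier_intensity = Mod(img$fourier$values)^2,
       focal_intensity = Mod(img$camera$values)^2,
       defocus_intensity = Mod(defoc$values)^2,
       camera_field = img$camera)
}
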