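#' One illumination's measurement record
#'
#' Bundles what aperture synthesis needs from a single angular illumination:
#' the recovered camera-plane field and the coefficient vectors that place
#' and correct its spectral tile.
#'
#' @param index illumination index.
#' @param field recovered object field (a [complex_field()]).
#' @param coeffs_true ground-truth coefficients (optional).
#' @param coeffs_pred predicted coefficients (optional).
#' @return object of class `illumination_record`.
#' @export
illumination_record <- function(index, field, coeffs_true = NULL,
                                coeffs_pred = NULL) {
  structure(list(index = index, field = field,
                 coeffs_true = if (!is.null(coeffs_true))
                   zernike_coefficients(coeffs_true),
                 coeffs_pred = if (!is.null(coeffs_pred))
                   zernike_coefficients(coeffs_pred)),
            class = "illumination_record")
}

#' Compensate the estimated aberration of one recovered field
#'
#' Multiplies the field by exp(-i phi) where phi is the Zernike phase map
#' restricted to orders 3..9. The carrier terms c1, c2 are deliberately not
#' removed here — they place the tile during synthesis — and the piston c0
#' is handled either from ground truth (`remove_piston = TRUE`) or by
#' piston matching during synthesis.
#'
#' @param field a [complex_field()] on the camera grid.
#' @param coeffs 10-element coefficient vector (orders 3..9 are used).
#' @param config an [optical_config()].
#' @param remove_piston also multiply by exp(-i c0).
#' @return the compensated `complex_field`.
#' @export
compensate_field <- function(field, coeffs, config, remove_piston = FALSE) {
  coeffs <- zernike_coefficients(coeffs)
  ab <- c(0, 0, 0, coeffs[4:10])
  vals <- field$values
  if (any(ab != 0)) {
    phase <- zernike_phase_map(ab, config_grid(config))
    attr(phase, "mask") <- NULL
    vals <- vals * exp(-1i * phase)
  }
  if (remove_piston) vals <- vals * exp(-1i * coeffs[1])
  complex_field(vals, field$pixel_pitch, field$wavelength, field$plane_label)
}

# Center (row, col), 0-based, of the spectral tile contributed by a record
# with tilt (c1, c2) after demodulation: the NA disc lands at DC displaced
# by (+sy rows, -sx cols) with (sx, sy) = carrier_fourier_px.
tile_center_px <- function(coeffs, config) {
  s <- carrier_fourier_px(coeffs, config)
  n <- config$n_pixels
  c(row = floor(n / 2) + s[["sy"]], col = floor(n / 2) - s[["sx"]])
}

# Tilt-only phase ramp over the full grid (radians).
carrier_ramp <- function(coeffs, config) {
  p <- grid_polar(config_grid(config))
  (coeffs[3] * p$x + coeffs[2] * p$y) / config$aperture_radius_px
}

# --- streaming Fourier-domain accumulator ----------------------------------

syn_new <- function(config) {
  n <- config$n_pixels
  list(config = config,
       spectrum = matrix(0i, n, n),
       weight = matrix(0L, n, n),
       offsets = numeric(0), indices = integer(0))
}

syn_add <- function(acc, field_values, coeffs, piston_match = FALSE,
                    floor_frac = 0.01, index = NA_integer_) {
  cfg <- acc$config
  s <- carrier_fourier_px(coeffs, cfg)
  if (max(abs(s - round(s))) < 1e-9) {
    # integer-pixel carrier: demodulation is an exact circular shift of the
    # spectrum (cheaper and sample-exact, which keeps overlaps unbiased)
    n <- cfg$n_pixels
    rows <- 1 + (seq_len(n) - 1 - round(s[["sy"]])) %% n
    cols <- 1 + (seq_len(n) - 1 + round(s[["sx"]])) %% n
    Tk <- fft2c(field_values)[rows, cols]
  } else {
    Tk <- fft2c(field_values * exp(-1i * carrier_ramp(coeffs, cfg)))
  }
  ctr <- tile_center_px(coeffs, cfg)
  tile_mask <- na_mask_matrix(cfg$n_pixels, cfg$fourier_mask_diameter_px,
                              center_px = round(ctr))
  Tk <- Tk * tile_mask
  offset <- 0
  if (piston_match && length(acc$indices) > 0) {
    amp <- Mod(Tk)
    over <- acc$weight > 0 & tile_mask > 0 & amp > floor_frac * max(amp)
    if (!any(over))
      stop(sprintf("tile %s has no overlap with the already-matched region",
                   index))
    avg <- acc$spectrum[over] / acc$weight[over]
    offset <- Arg(sum(avg * Conj(Tk[over]) * amp[over]))
    Tk <- Tk * exp(1i * offset)
  }
  acc$spectrum <- acc$spectrum + Tk
  acc$weight <- acc$weight + tile_mask
  acc$offsets <- c(acc$offsets, offset)
  acc$indices <- c(acc$indices, index)
  acc
}

syn_finish <- function(acc) {
  cfg <- acc$config
  avg <- acc$spectrum
  nz <- acc$weight > 0
  avg[nz] <- avg[nz] / acc$weight[nz]
  img <- ifft2c(avg)
  structure(list(spectrum = avg, weight = acc$weight,
                 field = complex_field(img, cfg$pixel_pitch, cfg$wavelength,
                                       "synthesized"),
                 offsets = acc$offsets, indices = acc$indices,
                 config = cfg),
            class = "synthesized_field")
}

#' @export
print.synthesized_field <- function(x, ...) {
  cat(sprintf(paste0("synthesized_field: %d tiles, spectral support %d px",
                     " (%.1f%% of grid), energy %.4g\n"),
              length(x$indices), sum(x$weight > 0),
              100 * mean(x$weight > 0), field_energy(x$field)))
  invisible(x)
}

#' @export
plot.synthesized_field <- function(x, what = c("image", "spectrum"), ...) {
  what <- match.arg(what)
  m <- if (what == "image") Mod(x$field$values)^2 else log1p(Mod(x$spectrum))
  graphics::image(m, col = grDevices::gray.colors(256), asp = 1,
                  axes = FALSE, ...)
  invisible(x)
}

#' Fourier-domain synthetic-aperture synthesis
#'
#' Each record's field is demodulated by its carrier ramp, Fourier
#' transformed, restricted to its NA disc, and accumulated; overlapping
#' tiles are averaged (sum divided by the per-pixel accumulation count), so
#' the effective passband of the synthesized aperture is flat. The
#' synthesized image is the inverse transform of the averaged spectrum.
#'
#' With `piston = "match"`, tiles are processed center-out (carrier radius
#' ascending, ties by index); each tile's constant phase is aligned to the
#' already-accumulated spectrum by an amplitude-weighted mean phase
#' difference over the overlap region (amplitude floor: `floor_frac` of the
#' tile's maximum), the reference (first) tile keeping offset 0. A tile with
#' no overlap with the matched region raises an error naming the tile.
#'
#' @param records list of [illumination_record()]s on congruent grids.
#' @param config an [optical_config()].
#' @param piston `"none"` or `"match"`.
#' @param carrier_source use `"true"` or `"predicted"` coefficients for
#'   demodulation and tile placement.
#' @param floor_frac amplitude floor for the overlap region.
#' @return object of class `synthesized_field`: averaged `spectrum`, integer
#'   `weight` map, reconstructed `field`, per-tile phase `offsets` (in the
#'   processed order; `indices` gives the record order used).
#' @export
synthesize_fields <- function(records, config, piston = c("none", "match"),
                              carrier_source = c("true", "predicted"),
                              floor_frac = 0.01) {
  piston <- match.arg(piston)
  carrier_source <- match.arg(carrier_source)
  if (length(records) == 0) stop("need at least one record")
  get_coeffs <- function(r)
    if (carrier_source == "true") r$coeffs_true else r$coeffs_pred
  ord <- seq_along(records)
  if (piston == "match") {
    rad <- vapply(records, function(r)
      sqrt(sum(carrier_fourier_px(get_coeffs(r), config)^2)), 0)
    ord <- order(rad, vapply(records, function(r) r$index, 0))
  }
  acc <- syn_new(config)
  for (i in ord) {
    r <- records[[i]]
    acc <- syn_add(acc, r$field$values, get_coeffs(r),
                   piston_match = piston == "match",
                   floor_frac = floor_frac, index = r$index)
  }
  syn_finish(acc)
}

#' Hexagonal illumination grid tiling the Fourier domain
#'
#' Carriers on a hexagonal lattice out to the radius needed so the union of
#' NA discs covers spatial frequencies up to `coverage_lpmm`. The default
#' spacing, 0.75 mask diameters, guarantees both gap-free coverage (lattice
#' covering radius spacing/sqrt(3) < mask radius) and tile overlap for
#' piston matching.
#'
#' @param config an [optical_config()].
#' @param coverage_lpmm target synthesized cutoff in lp/mm.
#' @param spacing_px lattice constant in Fourier pixels.
#' @return data.frame with columns index, c1, c2 (tilt radians), sx, sy,
#'   radius_px, sorted by carrier radius (center-out).
#' @export
illumination_grid <- function(config, coverage_lpmm,
                              spacing_px = 0.75 * config$fourier_mask_diameter_px) {
  px_per_lpmm <- config$n_pixels * config$pixel_pitch / 1000
  rmax <- coverage_lpmm * px_per_lpmm - config$fourier_mask_diameter_px / 2
  if (rmax < 0) stop("coverage below a single NA disc")
  imax <- ceiling(rmax / spacing_px) + 1
  pts <- expand.grid(i = -imax:imax, j = -imax:imax)
  # carriers rounded to whole Fourier pixels: demodulation is then an exact
  # circular shift, so overlapping tiles agree sample for sample and piston
  # matching is unbiased
  sx <- round(spacing_px * (pts$i + pts$j / 2))
  sy <- round(spacing_px * pts$j * sqrt(3) / 2)
  keep <- sqrt(sx^2 + sy^2) <= rmax + 1e-9
  sx <- sx[keep]; sy <- sy[keep]
  rad <- sqrt(sx^2 + sy^2)
  ord <- order(rad, atan2(sy, sx))
  tilt_per_px <- 2 * pi * config$aperture_radius_px / config$n_pixels
  data.frame(index = seq_along(ord), c1 = sy[ord] * tilt_per_px,
             c2 = sx[ord] * tilt_per_px, sx = sx[ord], sy = sy[ord],
             radius_px = rad[ord])
}

#' Assemble illumination coefficient vectors for a reconstruction run
#'
#' Carriers come from an [illumination_grid()]; the piston is uniform on
#' \[-pi, pi\] and the image-degrading orders 3..9 are drawn uniform on the
#' high-order range, scaled in proportion to each illumination's carrier
#' magnitude (the aberration of a steered beam grows with its steering
#' angle).
#'
#' @param grid an [illumination_grid()] data.frame.
#' @param ranges a [sampling_ranges()].
#' @param seed integer seed.
#' @param proportional scale orders 3..9 by ||(c1,c2)|| / (tilt sqrt(2)).
#' @return matrix n x 10 of coefficients, one row per illumination.
#' @export
make_illuminations <- function(grid, ranges = sampling_ranges(), seed = 1L,
                               proportional = TRUE) {
  set.seed(seed)
  n <- nrow(grid)
  m <- matrix(0, n, 10L, dimnames = list(NULL, paste0("c", 0:9)))
  m[, 1] <- stats::runif(n, -ranges$z0, ranges$z0)
  m[, 2] <- grid$c1
  m[, 3] <- grid$c2
  hi <- matrix(stats::runif(7 * n, -ranges$high_order, ranges$high_order),
               n, 7L)
  if (proportional)
    hi <- hi * sqrt(grid$c1^2 + grid$c2^2) / (ranges$tilt * sqrt(2))
  m[, 4:10] <- hi
  m
}

#' End-to-end SA-DHM reconstruction of a sample
#'
#' For every illumination: the sample amplitude is illuminated by the
#' (aberrated, tilted) plane wave over the circular aperture, imaged through
#' the 4-f system with the NA mask, recorded as four phase-shifted
#' holograms, recovered, optionally aberration-compensated, and accumulated
#' into the synthesized Fourier spectrum (streaming, so only the
#' accumulator and one tile are ever in memory).
#'
#' Modes: `"ideal"` applies no aberration and no piston (perfect
#' illuminations, ground-truth carriers); `"uncompensated"` applies the full
#' aberration but skips compensation; `"compensated"` compensates orders
#' 3..9 with the ground-truth coefficients; `"predicted"` estimates the
#' coefficients per illumination with a fitted [fit_zernike_estimator()]
#' model from the illumination's own diffraction triplet (no sample) and
#' compensates with those. Carriers for tile placement always come from the
#' ground-truth c1, c2.
#'
#' @param sample real or complex sample transmission on the config grid.
#' @param illuminations matrix n x 10 of ground-truth coefficients
#'   (see [make_illuminations()]).
#' @param config an [optical_config()].
#' @param mode reconstruction mode, see above.
#' @param model a `zernike_estimator` (required for `mode = "predicted"`).
#' @param piston `"ground_truth"` (remove each tile's true c0),
#'   `"match"` (piston matching during synthesis) or `"none"`.
#' @param Ar reference amplitude for the holograms.
#' @param shift_sign phase-step sign for the holograms.
#' @param verbose print progress.
#' @return a `synthesized_field` (see [synthesize_fields()]).
#' @export
sa_reconstruct <- function(sample, illuminations, config,
                           mode = c("ideal", "uncompensated", "compensated",
                                    "predicted"),
                           model = NULL,
                           piston = c("ground_truth", "match", "none"),
                           Ar = 1, shift_sign = -1, verbose = FALSE) {
  mode <- match.arg(mode)
  piston <- match.arg(piston)
  if (mode == "predicted" && is.null(model))
    stop("mode 'predicted' needs a fitted model")
  if (is.null(dim(sample)) || nrow(sample) != config$n_pixels)
    stop("sample must be an n_pixels x n_pixels matrix")
  illuminations <- coeffs_as_matrix(illuminations)
  grid <- config_grid(config)
  apmask <- aperture_mask(grid)

  # center-out order so piston matching always meets an overlapped region
  rad <- apply(illuminations, 1, function(co)
    sqrt(sum(carrier_fourier_px(co, config)^2)))
  ord <- order(rad, seq_len(nrow(illuminations)))

  acc <- syn_new(config)
  for (i in ord) {
    co <- zernike_coefficients(illuminations[i, ])
    phase <- if (mode == "ideal")
      zernike_phase_map(c(0, co[2], co[3], rep(0, 7)), grid)
    else zernike_phase_map(co, grid)
    obj <- complex_field(sample * apmask * exp(1i * phase),
                         config$pixel_pitch, config$wavelength, "object")
    cam <- image_through_4f(obj, config)$camera
    holos <- make_holograms(cam, Ar, shift_sign)
    U <- recover_field(holos)
    U$values <- U$values / (4 * Ar)

    comp_co <- switch(mode,
      ideal = NULL, uncompensated = NULL, compensated = co,
      predicted = {
        trip <- render_triplet(co, config,
                               out_size = model$input_size)
        pred <- predict(model, trip)
        pred
      })
    if (!is.null(comp_co))
      U <- compensate_field(U, comp_co, config, remove_piston = FALSE)
    if (piston == "ground_truth" && mode != "ideal")
      U$values <- U$values * exp(-1i * co[1])

    acc <- syn_add(acc, U$values, co, piston_match = piston == "match",
                   index = i)
    if (verbose) message(sprintf("illumination %d/%d done", which(ord == i),
                                 length(ord)))
  }
  syn_finish(acc)
}
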