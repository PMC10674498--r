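#' Parallel 4-step phase-shifting holograms
#'
#' Forms the four phase-shifted interferograms of the object field with a
#' collimated reference beam:
#' \deqn{I_n = |A_o|^2 + A_r^2 + 2 A_o A_r \cos(\theta_o + s\, n \pi/2),\quad n = 1..4}
#' where s is `shift_sign`. The polarization-camera demosaicing of a real
#' instrument is out of scope; the four maps are produced directly.
#'
#' Sign convention: with s = -1 (the default), the quadrature combination
#' (I1 - I3) + j (I2 - I4) evaluates exactly to -4j Ar Ao exp(j theta_o),
#' so [recover_field()] multiplies by j to return +4 Ar Ao exp(j theta_o).
#' With s = +1 the same combination yields the conjugate instead and
#' recovery conjugates once. Either way the round trip
#' `recover_field(make_holograms(U, Ar)) / (4 * Ar)` reproduces U exactly.
#'
#' @param object_field a [complex_field()] (the object beam on the camera).
#' @param Ar reference amplitude, a scalar >= 0 or a matrix of the field's
#'   size (spatially uniform in simulation by default).
#' @param shift_sign +1 or -1: sign of the reference phase steps.
#' @return object of class `hologram_set`: four intensity maps `I`,
#'   `reference_amplitude`, `shift_sign` and grid metadata.
#' @export
make_holograms <- function(object_field, Ar, shift_sign = -1) {
  if (any(Ar < 0)) stop("Ar must be non-negative")
  if (!shift_sign %in% c(-1, 1)) stop("shift_sign must be +1 or -1")
  v <- object_field$values
  # for quarter-wave steps the cosines reduce to -+Im and -+Re of the field:
  # 2 Ao Ar cos(theta -+ n pi/2) = 2 Ar * {+-Im(v), -Re(v), -+Im(v), +Re(v)}
  dc <- Mod(v)^2 + Ar^2
  I <- if (shift_sign == -1)
    list(dc + 2 * Ar * Im(v), dc - 2 * Ar * Re(v),
         dc - 2 * Ar * Im(v), dc + 2 * Ar * Re(v))
  else
    list(dc - 2 * Ar * Im(v), dc - 2 * Ar * Re(v),
         dc + 2 * Ar * Im(v), dc + 2 * Ar * Re(v))
  structure(list(I = I, reference_amplitude = Ar, shift_sign = shift_sign,
                 pixel_pitch = object_field$pixel_pitch,
                 wavelength = object_field$wavelength),
            class = "hologram_set")
}

#' @export
print.hologram_set <- function(x, ...) {
  cat(sprintf("hologram_set: 4 x %d x %d px, Ar %s, shift_sign %+d\n",
              nrow(x$I[[1]]), ncol(x$I[[1]]),
              if (length(x$reference_amplitude) == 1)
                format(x$reference_amplitude) else "<map>",
              x$shift_sign))
  invisible(x)
}

#' Recover the complex object field from 4-step holograms
#'
#' Computes (I1 - I3) + j (I2 - I4) and applies the fixed complex constant
#' (and, for `shift_sign = +1`, one conjugation) that makes the result equal
#' +4 Ar Ao exp(j theta_o); divide by 4 Ar to obtain the object field
#' itself. DC terms cancel in both differences, so recovery is invariant to
#' adding any constant to all four intensities.
#'
#' @param holos a [make_holograms()] result.
#' @param shift_sign phase-step sign used at recording (default: the one
#'   stored in `holos`).
#' @return a [complex_field()] equal to 4 Ar times the object field.
#' @export
recover_field <- function(holos, shift_sign = holos$shift_sign) {
  dims <- lapply(holos$I, dim)
  if (length(unique(dims)) != 1L) stop("hologram maps must share one grid")
  H <- (holos$I[[1]] - holos$I[[3]]) + 1i * (holos$I[[2]] - holos$I[[4]])
  vals <- if (shift_sign == -1) 1i * H else Conj(1i * H)
  complex_field(vals, holos$pixel_pitch, holos$wavelength, "recovered")
}

#' Save a hologram set as PNGs + JSON sidecar
#'
#' Writes `I1.png` .. `I4.png` (jointly min-max scaled) and a sidecar with
#' the scaling, reference amplitude and shift sign. Quantized export for
#' inspection; not a bit-exact archive.
#'
#' @param holos a [make_holograms()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_holograms <- function(holos, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lo <- min(unlist(lapply(holos$I, min)))
  hi <- max(unlist(lapply(holos$I, max)))
  sc <- if (hi > lo) hi - lo else 1
  for (n in 1:4)
    png::writePNG((holos$I[[n]] - lo) / sc, file.path(dir, sprintf("I%d.png", n)))
  jsonlite::write_json(list(reference_amplitude = holos$reference_amplitude,
                            shift_sign = holos$shift_sign,
                            pixel_pitch = holos$pixel_pitch,
                            wavelength = holos$wavelength,
                            intensity_offset = lo, intensity_scale = sc),
                       file.path(dir, "holograms.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
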