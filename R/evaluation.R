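#' Linear bar-chart specification
#'
#' A binary resolution target made of vertical-bar bands of increasing
#' spatial frequency laid side by side along x, each band
#' `periods_per_band` periods wide, separated by guard gaps of
#' `guard_periods` periods of the coarser neighbor (cross-talk protection).
#' The chart is generated on the reconstruction grid itself so no
#' resampling bias enters the MTF.
#'
#' @param frequencies increasing lp/mm vector; all must be at or below the
#'   grid Nyquist 1000 / (2 pitch).
#' @param config an [optical_config()] (provides grid size and pitch).
#' @param periods_per_band bar periods per band (default 6).
#' @param guard_periods guard width between bands, in periods (default 2).
#' @param height_px band height; default a quarter of the grid side.
#' @param center (row, col) 0-based chart center; default grid center.
#' @return object of class `bar_chart_spec` with the band layout (1-based
#'   pixel ranges) used later by [measure_mtf()].
#' @export
bar_chart_spec <- function(frequencies, config, periods_per_band = 6,
                           guard_periods = 2, height_px = config$n_pixels / 4,
                           center = rep(config$n_pixels / 2, 2)) {
  if (any(diff(frequencies) <= 0)) stop("frequencies must be increasing")
  if (any(frequencies <= 0)) stop("frequencies must be positive")
  nyquist <- 1000 / (2 * config$pixel_pitch)
  if (any(frequencies > nyquist))
    stop(sprintf("frequency above grid Nyquist (%g lp/mm)", nyquist))
  period_px <- 1000 / (frequencies * config$pixel_pitch)
  width_px <- ceiling(periods_per_band * period_px)
  gaps <- c(0, ceiling(guard_periods * period_px[-length(period_px)]))
  total <- sum(width_px) + sum(gaps)
  if (total > config$n_pixels) stop("chart wider than grid")
  x0 <- round(center[2] - total / 2)  # 0-based left edge
  starts <- x0 + cumsum(gaps) + c(0, cumsum(width_px))[seq_along(width_px)]
  y0 <- round(center[1] - height_px / 2)
  bands <- data.frame(frequency_lpmm = frequencies,
                      period_px = period_px,
                      x_start = starts + 1,            # 1-based inclusive
                      x_end = starts + width_px,
                      y_start = y0 + 1, y_end = y0 + height_px)
  if (any(bands$x_start < 1) || any(bands$x_end > config$n_pixels) ||
      any(bands$y_start < 1) || any(bands$y_end > config$n_pixels))
    stop("chart does not fit in grid")
  structure(list(bands = bands, n_pixels = config$n_pixels,
                 pixel_pitch = config$pixel_pitch),
            class = "bar_chart_spec")
}

#' Generate the binary bar chart
#'
#' @param spec a [bar_chart_spec()].
#' @return n x n matrix of 0/1 amplitude with the spec attached as
#'   attribute `"spec"`.
#' @export
make_bar_chart <- function(spec) {
  m <- matrix(0, spec$n_pixels, spec$n_pixels)
  for (i in seq_len(nrow(spec$bands))) {
    b <- spec$bands[i, ]
    x <- b$x_start:b$x_end
    bars <- (floor(2 * (x - b$x_start) / b$period_px) %% 2) == 0
    m[b$y_start:b$y_end, x] <- rep(bars * 1, each = b$y_end - b$y_start + 1)
  }
  attr(m, "spec") <- spec
  m
}

#' Generate a binary spoke (Siemens star) chart
#'
#' Radial bright/dark wedges; the local line-pair frequency at radius r is
#' n_spokes / (2 pi r), so line width grows away from the center. The
#' center pixel is excluded (angular singularity).
#'
#' @param n_spokes number of bright/dark wedge pairs (pattern periods
#'   around the circumference).
#' @param radius_px outer radius in pixels.
#' @param n_pixels grid side.
#' @param center (row, col) 0-based center; default grid center.
#' @return n x n binary matrix.
#' @export
make_spoke_chart <- function(n_spokes, radius_px, n_pixels,
                             center = rep(n_pixels / 2, 2)) {
  if (2 * radius_px > n_pixels) stop("radius does not fit grid")
  g <- unit_disk_grid(n_pixels, radius_px, center)
  p <- grid_polar(g)
  r_px <- p$rho * radius_px
  ((cos(n_spokes * p$phi) >= 0) & (r_px <= radius_px) & (r_px >= 1)) * 1
}

#' Local line-pair frequency of a spoke chart
#'
#' @param n_spokes as in [make_spoke_chart()].
#' @param r_mm radius in mm.
#' @return frequency in lp/mm.
#' @export
spoke_local_frequency <- function(n_spokes, r_mm) n_spokes / (2 * pi * r_mm)

#' Measure the MTF of a reconstruction against a bar chart
#'
#' For each band, the per-row modulation (Imax - Imin) / (Imax + Imin) is
#' computed with robust percentile extremes (95th / 5th) along the
#' bar-normal (x) direction and averaged over the bar-parallel (y) rows.
#' Percentiles rather than raw extremes suppress coherent ringing spikes,
#' and one bar period (at least 3 px) is trimmed from each side of the band
#' so edge ringing from the band boundary does not leak into the estimate.
#' Values are reported as-is (they may exceed 1 slightly from ringing);
#' nothing is silently clipped.
#'
#' @param intensity reconstructed intensity map (|U|^2) on the chart grid.
#' @param spec the [bar_chart_spec()] the chart was generated from.
#' @param probs lower/upper percentile pair (default c(0.05, 0.95)).
#' @param edge_trim_periods bar periods trimmed from each band edge.
#' @return data.frame of class `mtf_curve`: frequency_lpmm, mtf.
#' @export
measure_mtf <- function(intensity, spec, probs = c(0.05, 0.95),
                        edge_trim_periods = 1) {
  if (nrow(intensity) < max(spec$bands$x_end) ||
      ncol(intensity) < max(spec$bands$x_end))
    stop("band outside image")
  mtf <- vapply(seq_len(nrow(spec$bands)), function(i) {
    b <- spec$bands[i, ]
    trim <- max(ceiling(edge_trim_periods * b$period_px), 3)
    x0 <- b$x_start + trim; x1 <- b$x_end - trim
    if (x1 - x0 < b$period_px) { x0 <- b$x_start; x1 <- b$x_end }
    block <- intensity[b$y_start:b$y_end, x0:x1, drop = FALSE]
    mods <- apply(block, 1, function(row) {
      q <- stats::quantile(row, probs, names = FALSE, type = 7)
      s <- q[2] + q[1]
      if (s <= .Machine$double.eps) 0 else (q[2] - q[1]) / s
    })
    mean(mods)
  }, 0)
  structure(data.frame(frequency_lpmm = spec$bands$frequency_lpmm, mtf = mtf),
            class = c("mtf_curve", "data.frame"))
}

#' @export
plot.mtf_curve <- function(x, ...) {
  graphics::plot(x$frequency_lpmm, x$mtf, type = "b", pch = 16,
                 xlab = "spatial frequency (lp/mm)", ylab = "MTF",
                 ylim = c(0, max(1, x$mtf)), ...)
  invisible(x)
}

#' Write an MTF curve as CSV
#'
#' @param curve a [measure_mtf()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_mtf_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Default full-scale bar-chart frequencies
#'
#' Ten bands from 21 to 500 lp/mm (the grid Nyquist at 1 um pitch),
#' including the 38, 167, 250 and 312.5 lp/mm bands that mark the
#' uncompensated cutoff, the high-contrast limit, and the synthesized-
#' coverage rolloff of the default geometry.
#'
#' @return numeric vector of lp/mm.
#' @export
default_chart_frequencies <- function() {
  c(21, 38, 60, 90, 125, 167, 250, 312.5, 400, 500)
}
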