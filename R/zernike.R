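#' Zernike polynomial basis on the circular aperture
#'
#' Evaluates one member of the ten-term Zernike basis used throughout this
#' package, in its *non-normalized* convention (no Noll/OSA radial
#' normalization factors): the printed polynomials are
#'
#' | n | polynomial            | common name        |
#' |---|-----------------------|--------------------|
#' | 0 | 1                     | piston             |
#' | 1 | \eqn{\rho\sin\phi}    | tilt y (carrier)   |
#' | 2 | \eqn{\rho\cos\phi}    | tilt x (carrier)   |
#' | 3 | \eqn{\rho^2\sin 2\phi}| oblique astigmatism|
#' | 4 | \eqn{2\rho^2-1}       | defocus            |
#' | 5 | \eqn{\rho^2\cos 2\phi}| vertical astigmatism|
#' | 6 | \eqn{\rho^3\sin 3\phi}| trefoil            |
#' | 7 | \eqn{(3\rho^3-2\rho)\sin\phi} | coma y     |
#' | 8 | \eqn{(3\rho^3-2\rho)\cos\phi} | coma x     |
#' | 9 | \eqn{\rho^3\cos 3\phi}| trefoil            |
#'
#' Coefficients multiplying these basis functions are phase in radians at the
#' unit-disk boundary (\eqn{\rho = 1} at the circular-aperture rim). The
#' azimuth \eqn{\phi} is measured counter-clockwise from the +x (column)
#' axis with y increasing upward; sin/cos terms swap under axis flips, so
#' this convention is load-bearing.
#'
#' @param n integer index 0..9 selecting the basis member.
#' @param rho radial coordinate(s), \eqn{\rho \ge 0}; callers normally mask
#'   to \eqn{\rho \le 1}.
#' @param phi azimuth(s) in radians.
#' @return numeric vector/matrix of the polynomial evaluated at (rho, phi).
#' @examples
#' zernike_basis(0, 0.3, 1.0)   # 1
#' zernike_basis(4, 0, 0)       # -1
#' @export
zernike_basis <- function(n, rho, phi) {
  if (length(n) != 1L || is.na(n) || n < 0 || n > 9 || n != round(n))
    stop("Zernike index n must be a single integer in 0..9")
  switch(as.character(n),
    "0" = rho * 0 + 1,
    "1" = rho * sin(phi),
    "2" = rho * cos(phi),
    "3" = rho^2 * sin(2 * phi),
    "4" = 2 * rho^2 - 1,
    "5" = rho^2 * cos(2 * phi),
    "6" = rho^3 * sin(3 * phi),
    "7" = (3 * rho^3 - 2 * rho) * sin(phi),
    "8" = (3 * rho^3 - 2 * rho) * cos(phi),
    "9" = rho^3 * cos(3 * phi)
  )
}

#' Validate a 10-element Zernike coefficient vector
#'
#' @param c numeric vector of length 10 (indices n = 0..9), radians of phase
#'   at the unit-disk edge.
#' @return the validated vector (invisibly the same numeric vector).
#' @export
zernike_coefficients <- function(c) {
  c <- as.numeric(c)
  if (length(c) != 10L) stop("Zernike coefficient vector must have length 10")
  if (!all(is.finite(c))) stop("Zernike coefficients must all be finite")
  names(c) <- paste0("c", 0:9)
  c
}

#' Unit-disk sampling grid
#'
#' Defines the pixel grid on which the Zernike domain lives. The grid center
#' sits at (N/2, N/2) in 0-based pixel coordinates (the DC pixel of a
#' centered FFT), and \eqn{\rho} is radial pixel distance divided by
#' `aperture_radius_px`, so \eqn{\rho = 1} exactly at the aperture rim.
#'
#' @param n_pixels grid side length in pixels.
#' @param aperture_radius_px aperture radius in pixels; the aperture must
#'   fit in the grid (2 r <= N).
#' @param center optional (row, col) 0-based center; default (N/2, N/2).
#' @return an object of class `unit_disk_grid`.
#' @export
unit_disk_grid <- function(n_pixels, aperture_radius_px = n_pixels / 4,
                           center = c(n_pixels / 2, n_pixels / 2)) {
  n_pixels <- as.integer(n_pixels)
  if (n_pixels < 2L) stop("n_pixels must be >= 2")
  if (aperture_radius_px <= 0) stop("aperture_radius_px must be positive")
  if (2 * aperture_radius_px > n_pixels)
    stop("aperture does not fit in grid: 2 * aperture_radius_px > n_pixels")
  structure(list(n_pixels = n_pixels,
                 aperture_radius_px = aperture_radius_px,
                 center = as.numeric(center)),
            class = "unit_disk_grid")
}

#' @export
print.unit_disk_grid <- function(x, ...) {
  cat(sprintf("unit_disk_grid: %d x %d px, aperture radius %.1f px, center (%.1f, %.1f)\n",
              x$n_pixels, x$n_pixels, x$aperture_radius_px,
              x$center[1], x$center[2]))
  invisible(x)
}

# Polar coordinates of every pixel of the grid. x runs along columns, y
# increases upward (toward smaller row index); phi = atan2(y, x).
# Memoized per grid geometry (rebuilt for grids above the cache bound).
grid_polar <- function(grid) {
  key <- sprintf("polar_%d_%g_%g_%g", grid$n_pixels, grid$aperture_radius_px,
                 grid$center[1], grid$center[2])
  cache_get(key, cache_if = grid$n_pixels <= 1024, function() {
    n <- grid$n_pixels
    x <- matrix(rep(seq_len(n) - 1 - grid$center[2], each = n), n, n)
    y <- matrix(rep(grid$center[1] - (seq_len(n) - 1), times = n), n, n)
    rho <- sqrt(x^2 + y^2) / grid$aperture_radius_px
    phi <- atan2(y, x)
    list(x = x, y = y, rho = rho, phi = phi)
  })
}

# All ten basis rasters for a grid, as a list; cached for small grids.
zernike_basis_stack <- function(grid) {
  key <- sprintf("basis_%d_%g_%g_%g", grid$n_pixels, grid$aperture_radius_px,
                 grid$center[1], grid$center[2])
  cache_get(key, cache_if = grid$n_pixels <= 1024, function() {
    p <- grid_polar(grid)
    lapply(0:9, function(n) zernike_basis(n, p$rho, p$phi))
  })
}

#' Binary circular aperture mask
#'
#' 1 where \eqn{\rho \le 1}, 0 outside.
#'
#' @param grid a [unit_disk_grid()].
#' @return numeric matrix of 0/1.
#' @export
aperture_mask <- function(grid) {
  p <- grid_polar(grid)
  (p$rho <= 1) * 1
}

#' Compose an aberration phase map from Zernike coefficients
#'
#' Sums \eqn{c_n Z_n(\rho, \phi)} over n = 0..9 at every pixel inside the
#' aperture; pixels outside the disk carry phase 0 (masking is applied to
#' amplitude, not phase, by the imaging code).
#'
#' @param coeffs 10-element coefficient vector (see [zernike_coefficients()]).
#' @param grid a [unit_disk_grid()].
#' @return numeric matrix of phase in radians; attribute `"mask"` holds the
#'   binary disk mask.
#' @export
zernike_phase_map <- function(coeffs, grid) {
  coeffs <- zernike_coefficients(coeffs)
  p <- grid_polar(grid)
  inside <- p$rho <= 1
  phase <- matrix(0, grid$n_pixels, grid$n_pixels)
  if (grid$n_pixels <= 1024) {
    basis <- zernike_basis_stack(grid)
    for (n in 0:9) {
      cn <- coeffs[n + 1]
      if (cn != 0) phase <- phase + cn * basis[[n + 1]]
    }
  } else {
    for (n in 0:9) {
      cn <- coeffs[n + 1]
      if (cn != 0) phase <- phase + cn * zernike_basis(n, p$rho, p$phi)
    }
  }
  phase[!inside] <- 0
  attr(phase, "mask") <- inside * 1
  phase
}

#' Write / read Zernike coefficient records
#'
#' Coefficient vectors are persisted as CSV (`columns id, n, value`, one row
#' per coefficient per illumination) or as JSON (a list of 10-element
#' vectors).
#'
#' @param coeffs a single coefficient vector or a list of them / a 10-column
#'   matrix (one row per illumination).
#' @param path output file; format chosen by extension (.csv or .json).
#' @return `write_coefficients` returns `path` invisibly;
#'   `read_coefficients` returns a matrix with 10 columns c0..c9.
#' @export
write_coefficients <- function(coeffs, path) {
  m <- coeffs_as_matrix(coeffs)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(apply(m, 1, function(r) unname(r), simplify = FALSE),
                         path, digits = NA, auto_unbox = FALSE)
  } else {
    df <- data.frame(id = rep(seq_len(nrow(m)), each = 10L),
                     n = rep(0:9, times = nrow(m)),
                     value = as.vector(t(m)))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    lst <- jsonlite::read_json(path, simplifyVector = TRUE)
    m <- if (is.matrix(lst)) lst
    else if (is.list(lst)) do.call(rbind, lst)
    else matrix(lst, nrow = 1)
  } else {
    df <- utils::read.csv(path)
    ord <- order(df$id, df$n)
    m <- matrix(df$value[ord], ncol = 10L, byrow = TRUE)
  }
  colnames(m) <- paste0("c", 0:9)
  m
}

coeffs_as_matrix <- function(coeffs) {
  if (is.list(coeffs)) coeffs <- do.call(rbind, lapply(coeffs, as.numeric))
  if (is.null(dim(coeffs))) coeffs <- matrix(as.numeric(coeffs), nrow = 1)
  if (ncol(coeffs) != 10L) stop("expected 10 coefficients per record")
  colnames(coeffs) <- paste0("c", 0:9)
  coeffs
}
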