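#' Sampling ranges for random Zernike coefficients
#'
#' The training distribution of the aberration coefficients: piston c0
#' uniform on \[-pi, pi\]; the two carrier/tilt terms c1, c2 uniform on
#' \[-tilt, +tilt\] (the tilt bound exists to prevent aliasing of the carrier
#' in the simulation); the image-degrading orders c3..c9 uniform on
#' \[-high_order, +high_order\], optionally rescaled in proportion to the
#' carrier magnitude (`proportional_to_tilt`). All ranges are symmetric
#' about zero.
#'
#' @param z0 half-range of the piston term, radians (default pi).
#' @param tilt half-range of c1, c2, radians at the aperture rim
#'   (default 1200).
#' @param high_order half-range of c3..c9, radians (default 48).
#' @param proportional_to_tilt if TRUE, draws of c3..c9 are scaled by
#'   ||(c1, c2)|| / (tilt * sqrt(2)).
#' @return object of class `sampling_ranges`.
#' @export
sampling_ranges <- function(z0 = pi, tilt = 1200, high_order = 48,
                            proportional_to_tilt = FALSE) {
  if (any(c(z0, tilt, high_order) <= 0)) stop("ranges must be positive")
  structure(list(z0 = z0, tilt = tilt, high_order = high_order,
                 proportional_to_tilt = proportional_to_tilt),
            class = "sampling_ranges")
}

#' Sampling ranges matched to a scaled-down optical configuration
#'
#' Both bounds scale linearly with the grid side: the tilt bound because it
#' keeps the carrier below the aliasing limit (pi rad/px across the
#' aperture) and fixes the carrier-to-mask-radius geometry, and the
#' high-order bound because the dimensionless quantity that controls how an
#' aberration distorts a spectral tile is its phase *gradient* relative to
#' the NA-mask radius (proportional to c / aperture radius), not the
#' coefficient itself. For the full-scale 2240-px grid this returns the
#' default ranges unchanged.
#'
#' @param config an [optical_config()].
#' @param ... overrides passed to [sampling_ranges()].
#' @return a `sampling_ranges` with `tilt` and `high_order` scaled by
#'   `n_pixels / 2240`.
#' @export
scaled_sampling_ranges <- function(config, ...) {
  s <- config$n_pixels / 2240
  sampling_ranges(tilt = 1200 * s, high_order = 48 * s, ...)
}

#' Validate sampling ranges against a grid's aliasing limit
#'
#' The carrier phase gradient is at most tilt / R radians per pixel; it must
#' stay below pi rad/px.
#'
#' @param ranges a [sampling_ranges()].
#' @param config an [optical_config()].
#' @return `ranges`, invisibly; errors if the tilt bound aliases.
#' @export
validate_ranges <- function(ranges, config) {
  limit <- pi * config$aperture_radius_px
  if (ranges$tilt > limit)
    stop(sprintf("tilt range %g rad aliases on this grid (limit %g rad)",
                 ranges$tilt, limit))
  invisible(ranges)
}

#' Draw one random Zernike coefficient vector
#'
#' Reproducible under a seed; with `seed = NULL` the current RNG stream is
#' used (so batch generators can seed once).
#'
#' @param ranges a [sampling_ranges()].
#' @param seed optional integer seed.
#' @return 10-element named coefficient vector.
#' @export
sample_coefficients <- function(ranges, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  c0 <- stats::runif(1, -ranges$z0, ranges$z0)
  tilt <- stats::runif(2, -ranges$tilt, ranges$tilt)
  hi <- stats::runif(7, -ranges$high_order, ranges$high_order)
  if (ranges$proportional_to_tilt)
    hi <- hi * sqrt(sum(tilt^2)) / (ranges$tilt * sqrt(2))
  zernike_coefficients(c(c0, tilt, hi))
}

#' Render the three-channel diffraction image for one aberration
#'
#' Runs [simulate_observation()] and assembles the network input: channel 1
#' is the masked Fourier-plane intensity cropped to the NA mask's bounding
#' square (so the mask rim lands exactly on the image border) and resampled
#' to `out_size`; channels 2 and 3 are the focal-plane and out-of-focus
#' intensities downsampled to `out_size` (block averaging for integer
#' ratios, bilinear otherwise). Each channel is min-max normalized
#' independently to \[0, 1\] — global intensity scale is deliberately
#' discarded, which is one reason the piston term is unlearnable from these
#' images.
#'
#' @param coeffs 10-element Zernike coefficient vector.
#' @param config an [optical_config()].
#' @param out_size output raster side (default 224).
#' @return object of class `diffraction_triplet`: `image` (out_size x
#'   out_size x 3 array in \[0,1\]), `label` (the coefficients), `dark_field`.
#' @export
render_triplet <- function(coeffs, config, out_size = 224L) {
  coeffs <- zernike_coefficients(coeffs)
  obs <- simulate_observation(coeffs, config)
  n <- config$n_pixels
  d <- config$fourier_mask_diameter_px
  c0 <- floor(n / 2)  # 0-based DC pixel
  ix <- (c0 - floor(d / 2) + 1):(c0 + ceiling(d / 2))  # 1-based crop, d px
  ch1 <- resample_to(obs$fourier_intensity[ix, ix], out_size)
  ch2 <- resample_to(obs$focal_intensity, out_size)
  ch3 <- resample_to(obs$defocus_intensity, out_size)
  img <- array(c(minmax01(ch1), minmax01(ch2), minmax01(ch3)),
               dim = c(out_size, out_size, 3L))
  structure(list(image = img, label = coeffs,
                 dark_field = is_dark_field(coeffs, config)),
            class = "diffraction_triplet")
}

minmax01 <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi > lo) (m - lo) / (hi - lo) else m * 0
}

resample_to <- function(m, out_size) {
  n <- nrow(m)
  if (n == out_size) return(m)
  if (n %% out_size == 0) {
    f <- n %/% out_size  # exact area binning
    m <- matrix(colMeans(matrix(m, nrow = f)), nrow = out_size)
    t(matrix(colMeans(matrix(t(m), nrow = f)), nrow = out_size))
  } else {
    r <- EBImage::resize(m, w = out_size, h = out_size)
    matrix(EBImage::imageData(r), out_size)
  }
}

#' Generate a labeled dataset of diffraction triplets
#'
#' Draws `n_samples` coefficient vectors from `ranges`, renders each
#' triplet, and either keeps them in memory (`out_dir = NULL`) or writes
#' `images/NNNNNN.png` (or `.bmp`), `labels.csv` (columns id, c0..c9,
#' dark_field) and `manifest.json` (seed, ranges, config and a config
#' hash). Deterministic under `seed`; the image filename embeds the label
#' row id so shuffling cannot desynchronize pairs.
#'
#' @param n_samples number of samples (>= 1).
#' @param ranges a [sampling_ranges()].
#' @param config an [optical_config()].
#' @param seed integer seed.
#' @param out_dir output directory, or NULL to return triplets in memory.
#' @param out_size raster side per channel (default 224).
#' @param format "png" (default) or "bmp".
#' @return a manifest list: `labels` (data.frame), `config`, `ranges`,
#'   `seed`, `config_hash`, `out_size`, and `triplets` (list, in-memory
#'   mode) or `dir`.
#' @export
build_dataset <- function(n_samples, ranges, config, seed, out_dir = NULL,
                          out_size = 224L, format = c("png", "bmp")) {
  stopifnot(n_samples >= 1)
  format <- match.arg(format)
  validate_ranges(ranges, config)
  set.seed(seed)
  labels <- matrix(NA_real_, n_samples, 10L,
                   dimnames = list(NULL, paste0("c", 0:9)))
  dark <- logical(n_samples)
  triplets <- if (is.null(out_dir)) vector("list", n_samples)
  if (!is.null(out_dir))
    dir.create(file.path(out_dir, "images"), showWarnings = FALSE,
               recursive = TRUE)
  for (i in seq_len(n_samples)) {
    co <- sample_coefficients(ranges)
    tr <- render_triplet(co, config, out_size)
    labels[i, ] <- co
    dark[i] <- tr$dark_field
    if (is.null(out_dir)) {
      triplets[[i]] <- tr
    } else {
      fn <- file.path(out_dir, "images",
                      sprintf("%06d.%s", i, format))
      if (format == "png") png::writePNG(tr$image, fn)
      else write_bmp(tr$image, fn)
    }
  }
  lab_df <- data.frame(id = seq_len(n_samples), labels, dark_field = dark)
  manifest <- list(seed = seed, n_samples = n_samples, out_size = out_size,
                   ranges = unclass(ranges), config = unclass(config),
                   config_hash = config_hash(config), format = format)
  if (!is.null(out_dir)) {
    utils::write.csv(lab_df, file.path(out_dir, "labels.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  c(manifest, list(labels = lab_df,
                   triplets = if (is.null(out_dir)) triplets,
                   dir = out_dir))
}

#' Load a dataset written by [build_dataset()]
#'
#' @param dir dataset directory.
#' @return manifest list with `labels` and `triplets` re-read from disk.
#' @export
load_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  labels <- utils::read.csv(file.path(dir, "labels.csv"))
  triplets <- lapply(labels$id, function(i) {
    fn <- file.path(dir, "images", sprintf("%06d.%s", i, manifest$format))
    img <- if (manifest$format == "png") png::readPNG(fn) else read_bmp(fn)
    structure(list(image = img,
                   label = zernike_coefficients(unlist(labels[labels$id == i,
                                                              paste0("c", 0:9)])),
                   dark_field = labels$dark_field[labels$id == i]),
              class = "diffraction_triplet")
  })
  c(manifest, list(labels = labels, triplets = triplets, dir = dir))
}

config_hash <- function(config) {
  tf <- tempfile()
  writeLines(paste(names(unclass(config)),
                   vapply(unclass(config), format, ""), sep = "="), tf)
  h <- unname(tools::md5sum(tf))
  unlink(tf)
  h
}

# Minimal uncompressed 24-bit BMP writer/reader (bottom-up row order),
# provided alongside PNG for format fidelity with BMP-based workflows.
write_bmp <- function(img, path) {
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  h <- dim(img)[1]; w <- dim(img)[2]
  rowbytes <- ((3 * w + 3) %/% 4) * 4
  datasize <- rowbytes * h
  u8 <- function(x) as.raw(pmin(pmax(round(x * 255), 0), 255))
  int4 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                               endian = "little")
  int2 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                               endian = "little")
  header <- c(charToRaw("BM"), int4(54 + datasize), int4(0), int4(54),
              int4(40), int4(w), int4(h), int2(1), int2(24), int4(0),
              int4(datasize), int4(2835), int4(2835), int4(0), int4(0))
  pix <- raw(datasize)
  for (r in seq_len(h)) {             # BMP rows bottom-up, BGR order
    row <- img[h - r + 1, , ]
    off <- (r - 1) * rowbytes
    pix[off + seq(1, 3 * w, 3)] <- u8(row[, 3])
    pix[off + seq(2, 3 * w, 3)] <- u8(row[, 2])
    pix[off + seq(3, 3 * w, 3)] <- u8(row[, 1])
  }
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(header, pix), con)
  invisible(path)
}

read_bmp <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  off <- readBin(raw[11:14], "integer", size = 4L, endian = "little")
  w <- readBin(raw[19:22], "integer", size = 4L, endian = "little")
  h <- readBin(raw[23:26], "integer", size = 4L, endian = "little")
  rowbytes <- ((3 * w + 3) %/% 4) * 4
  img <- array(0, c(h, w, 3L))
  for (r in seq_len(h)) {
    start <- off + (r - 1) * rowbytes
    row <- as.integer(raw[start + seq_len(3 * w)])
    img[h - r + 1, , 3] <- row[seq(1, 3 * w, 3)] / 255
    img[h - r + 1, , 2] <- row[seq(2, 3 * w, 3)] / 255
    img[h - r + 1, , 1] <- row[seq(3, 3 * w, 3)] / 255
  }
  img
}
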