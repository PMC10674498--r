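# Shared fixtures: small congruent configs so the suite stays fast.
# All heavy objects are built lazily inside the tests that need them.

cfg_small <- function(n = 120L) scaled_optical_config(n)

random_field <- function(n, seed = 1, pitch = 1, wavelength = 0.532) {
  set.seed(seed)
  complex_field(matrix(complex(real = stats::rnorm(n^2),
                               imaginary = stats::rnorm(n^2)), n),
                pitch, wavelength)
}

# band-limited random field (spectrum confined to a centered disc)
bandlimited_field <- function(n, radius_px, seed = 1) {
  f <- random_field(n, seed)
  Z <- sadhm:::fft2c(f$values) * sadhm:::na_mask_matrix(n, 2 * radius_px)
  complex_field(sadhm:::ifft2c(Z), f$pixel_pitch, f$wavelength)
}

# toy triplets whose images encode the labels through simple deterministic
# patterns: cheap stand-ins for simulator output in estimator plumbing tests
toy_triplets <- function(n, size = 16L, seed = 1) {
  set.seed(seed)
  ranges <- sampling_ranges()
  ax <- seq(-1, 1, length.out = size)
  lapply(seq_len(n), function(i) {
    co <- sample_coefficients(ranges)
    cx <- co[2] / ranges$tilt; cy <- co[3] / ranges$tilt
    blob <- outer(ax, ax, function(y, x) exp(-((x - cx)^2 + (y - cy)^2) / 0.08))
    img <- array(c(blob, blob * abs(co[5]) / ranges$high_order,
                   t(blob)), c(size, size, 3L))
    structure(list(image = img / max(img), label = co, dark_field = TRUE),
              class = "diffraction_triplet")
  })
}
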