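test_that("illumination wavevectors are normalized to 2 pi / lambda", {
  wv <- illumination_wavevector(2, 0, 0, 6.6, 0.532)
  expect_equal(unname(wv), c(0, 0, 2 * pi / 0.532e-3), tolerance = 1e-12)
  wv2 <- illumination_wavevector(1.5, 3.2, -1.1, 6.6, 0.532)
  expect_equal(sqrt(sum(wv2^2)), 2 * pi / 0.532e-3, tolerance = 1e-9)
  expect_gt(wv2[["kz"]], 0)
  expect_error(illumination_wavevector(2, 1, 1, -1, 0.532), "WD")
})

test_that("angular-spectrum propagation is unitary and invertible", {
  cfg <- cfg_small(120L)
  d <- cfg$defocus_d
  flim_px <- floor(120 * 1 / (0.532 * sqrt((2 * d * 1e3 / 120)^2 + 1)))
  u <- bandlimited_field(120L, floor(flim_px * 0.8), seed = 2)
  expect_identical(propagate(u, 0), u)
  up <- propagate(u, d)
  expect_equal(field_energy(up), field_energy(u), tolerance = 1e-10)
  ub <- propagate(up, -d)
  rel_rms <- sqrt(mean(Mod(ub$values - u$values)^2) /
                    mean(Mod(u$values)^2))
  expect_lt(rel_rms, 1e-10)
})

test_that("an on-axis plane wave just advances in phase", {
  pw <- complex_field(matrix(1 + 0i, 32, 32), 1, 0.532)
  d_mm <- 0.004
  out <- propagate(pw, d_mm)
  expect_equal(out$values, matrix(exp(1i * 2 * pi * d_mm * 1e3 / 0.532), 32, 32),
               tolerance = 1e-9)
})

test_that("lens Fourier transform behaves like a lens", {
  g <- unit_disk_grid(64L, 16)
  u <- complex_field(aperture_mask(g) + 0i, 1, 0.532, "aperture")
  F <- lens_fourier(u, 10)
  pk <- which(Mod(F$values) == max(Mod(F$values)), arr.ind = TRUE) - 1
  expect_equal(unname(pk[1, ]), c(32, 32))          # Airy peak at DC
  expect_equal(field_energy(F), field_energy(u), tolerance = 1e-10)
  expect_equal(F$pixel_pitch, 0.532 * 10 * 1e3 / 64)
  # two consecutive transforms invert the image (parity flip)
  set.seed(5)
  asym <- matrix(stats::runif(64^2), 64)
  ua <- complex_field(asym + 0i, 1, 0.532)
  FF <- lens_fourier(lens_fourier(ua, 10), 10)
  flipped <- asym[c(1, 64:2), c(1, 64:2)]  # centered parity flip, even grid
  expect_equal(Mod(FF$values) / max(Mod(FF$values)),
               flipped / max(flipped), tolerance = 1e-8)
})

test_that("a tilted input displaces the Fourier peak", {
  cfg <- cfg_small(120L)
  g <- sadhm:::config_grid(cfg)
  co <- c(0, 0, 18, rep(0, 7))
  u <- complex_field(aperture_mask(g) * exp(1i * zernike_phase_map(co, g)),
                     1, 0.532)
  F <- lens_fourier(u, 10)
  pk <- which(Mod(F$values) == max(Mod(F$values)), arr.ind = TRUE) - 1
  expect_gt(abs(pk[1, 2] - 60), 2)  # displaced from DC column
})

test_that("NA mask arithmetic matches the design geometry", {
  cfg <- optical_config()
  expect_equal(mask_na(cfg), 0.0266)
  expect_equal(mask_na(cfg, cfg$n_pixels), 0.266)
  # scaled preset preserves the NA
  expect_equal(mask_na(scaled_optical_config(560L)), 0.0266)
  f <- random_field(32, seed = 6)
  fm <- apply_na_mask(f, 12)
  expect_lte(field_energy(fm), field_energy(f))
  # full-diameter mask removes at most the rim
  f2 <- apply_na_mask(f, 32)
  changed <- f2$values != f$values
  p <- sadhm:::grid_polar(unit_disk_grid(32L, 16))
  expect_true(all(p$rho[changed] > 0.95))
  expect_error(apply_na_mask(f, 64), "larger")
})

test_that("bright and dark field observations split at the mask radius", {
  cfg <- cfg_small(120L)
  obs0 <- simulate_observation(rep(0, 10), cfg)
  n <- cfg$n_pixels
  m <- sadhm:::na_mask_matrix(n, cfg$fourier_mask_diameter_px)
  # bright field: Fourier energy concentrated at the center, inside the mask
  expect_gt(sum(obs0$fourier_intensity * m) / sum(obs0$fourier_intensity), 0.999)
  expect_false(is_dark_field(rep(0, 10), cfg))
  # strong tilt: carrier peak absent from the masked Fourier intensity
  co <- c(0, 0, 50, rep(0, 7))
  expect_true(is_dark_field(co, cfg))
  obs1 <- simulate_observation(co, cfg)
  s <- carrier_fourier_px(co, cfg)
  pk_val <- obs1$fourier_intensity[round(n / 2 - s[["sy"]]) + 1,
                                   round(n / 2 + s[["sx"]]) + 1]
  expect_equal(pk_val, 0)  # the carrier pixel itself is masked out
  expect_gt(sum(obs1$fourier_intensity), 0)  # only edge diffraction remains
  # the mask only removes energy
  expect_lte(sum(obs1$focal_intensity),
             sum(aperture_mask(sadhm:::config_grid(cfg))) + 1e-6)
})

test_that("imaging is linear and NA-monotone", {
  cfg <- cfg_small(120L)
  u1 <- bandlimited_field(120L, 20, seed = 7)
  u2 <- bandlimited_field(120L, 20, seed = 8)
  i12 <- sadhm:::image_through_4f(
    complex_field(u1$values + u2$values, 1, 0.532), cfg)$camera
  i1 <- sadhm:::image_through_4f(u1, cfg)$camera
  i2 <- sadhm:::image_through_4f(u2, cfg)$camera
  expect_equal(i12$values, i1$values + i2$values, tolerance = 1e-12)
  # enlarging the mask never decreases camera-plane energy
  en <- vapply(c(6L, 12L, 24L, 48L), function(d) {
    cfg2 <- scaled_optical_config(120L)
    cfg2$fourier_mask_diameter_px <- d
    field_energy(sadhm:::image_through_4f(u1, cfg2)$camera)
  }, 0)
  expect_true(all(diff(en) >= -1e-12))
})

test_that("config round-trips through YAML and JSON readers", {
  cfg <- scaled_optical_config(280L)
  fy <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), fy)
  expect_equal(read_optical_config(fy), cfg)
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), fj, auto_unbox = TRUE, digits = NA)
  expect_equal(read_optical_config(fj), cfg)
  unlink(c(fy, fj))
})
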