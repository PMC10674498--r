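test_that("basis polynomials match the printed ten-term table", {
  expect_equal(zernike_basis(0, 0.7, 2.1), 1)
  expect_equal(zernike_basis(4, 0, 0), -1)
  expect_equal(zernike_basis(3, 1, pi / 4), 1)
  expect_equal(zernike_basis(7, 1, pi / 2), 1)
  # spot values against direct formulas at a generic point
  rho <- 0.63; phi <- 1.17
  expect_equal(zernike_basis(1, rho, phi), rho * sin(phi))
  expect_equal(zernike_basis(2, rho, phi), rho * cos(phi))
  expect_equal(zernike_basis(5, rho, phi), rho^2 * cos(2 * phi))
  expect_equal(zernike_basis(6, rho, phi), rho^3 * sin(3 * phi))
  expect_equal(zernike_basis(8, rho, phi), (3 * rho^3 - 2 * rho) * cos(phi))
  expect_equal(zernike_basis(9, rho, phi), rho^3 * cos(3 * phi))
  expect_error(zernike_basis(10, 0.5, 0), "0..9")
  expect_error(zernike_basis(-1, 0.5, 0), "0..9")
})

test_that("defocus term is rotation invariant", {
  rho <- c(0.2, 0.5, 1)
  for (shift in c(0.3, 1.2, 4)) {
    expect_equal(zernike_basis(4, rho, 0.1 + shift), zernike_basis(4, rho, 0.1))
  }
})

test_that("coefficient vectors are validated", {
  expect_error(zernike_coefficients(1:9), "length 10")
  expect_error(zernike_coefficients(c(1:9, NA)), "finite")
  expect_named(zernike_coefficients(rep(0, 10)), paste0("c", 0:9))
})

test_that("aperture mask is a disc of the right area", {
  g <- unit_disk_grid(64L, 16)
  m <- aperture_mask(g)
  expect_equal(m[33, 33], 1)           # center pixel (0-based 32 = N/2)
  expect_equal(m[1, 1], 0)             # far corner, rho ~ 2.8
  g2 <- unit_disk_grid(400L, 150)
  expect_lt(abs(sum(aperture_mask(g2)) - pi * 150^2) / (pi * 150^2), 0.01)
  expect_error(unit_disk_grid(64L, 40), "fit")
})

test_that("phase maps compose linearly and reduce to single terms", {
  g <- unit_disk_grid(64L, 24)
  expect_true(all(zernike_phase_map(rep(0, 10), g) == 0))
  p <- sadhm:::grid_polar(g)
  m4 <- zernike_phase_map(c(0, 0, 0, 0, 1, rep(0, 5)), g)
  inside <- p$rho <= 1
  expect_equal(m4[inside], (2 * p$rho^2 - 1)[inside])
  expect_true(all(m4[!inside] == 0))
  set.seed(4)
  a <- stats::rnorm(10); b <- stats::rnorm(10)
  expect_equal(zernike_phase_map(a + b, g),
               zernike_phase_map(a, g) + zernike_phase_map(b, g),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("a pure tilt shifts the far-field peak proportionally", {
  cfg <- cfg_small(120L)
  g <- sadhm:::config_grid(cfg)
  co <- zernike_coefficients(c(0, 24, -15, rep(0, 7)))
  U <- aperture_mask(g) * exp(1i * zernike_phase_map(co, g))
  F <- sadhm:::fft2c(U)
  pk <- which(Mod(F) == max(Mod(F)), arr.ind = TRUE) - 1  # 0-based
  s <- carrier_fourier_px(co, cfg)
  n <- cfg$n_pixels
  expect_lt(abs(pk[1] - (n / 2 - s[["sy"]])), 1)
  expect_lt(abs(pk[2] - (n / 2 + s[["sx"]])), 1)
})

test_that("basis members are pairwise orthogonal on a dense disc", {
  g <- unit_disk_grid(512L, 256)
  p <- sadhm:::grid_polar(g)
  inside <- p$rho <= 1
  vals <- lapply(1:9, function(n) zernike_basis(n, p$rho, p$phi)[inside])
  for (a in 1:8) for (b in (a + 1):9) {
    expect_lt(abs(mean(vals[[a]] * vals[[b]])), 1e-3)
  }
})

test_that("coefficient records round-trip through CSV and JSON", {
  set.seed(9)
  m <- matrix(stats::rnorm(30), 3, 10)
  for (ext in c("csv", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_coefficients(m, f)
    back <- read_coefficients(f)
    expect_equal(unname(back), unname(m), tolerance = 1e-12)
    unlink(f)
  }
})
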