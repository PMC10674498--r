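test_that("coefficient sampling honors the printed ranges", {
  ranges <- sampling_ranges()
  set.seed(21)
  draws <- t(replicate(10000, sample_coefficients(ranges)))
  expect_gte(min(draws[, 1]), -pi); expect_lte(max(draws[, 1]), pi)
  expect_gte(min(draws[, 2:3]), -1200); expect_lte(max(draws[, 2:3]), 1200)
  expect_true(all(abs(draws[, 4:10]) <= 48))
  # the draws actually fill their ranges
  expect_gt(max(abs(draws[, 1])), 0.99 * pi)
  expect_gt(max(abs(draws[, 2:3])), 0.99 * 1200)
  # determinism under seed
  expect_identical(sample_coefficients(ranges, seed = 7),
                   sample_coefficients(ranges, seed = 7))
})

test_that("proportional mode ties high orders to the carrier magnitude", {
  ranges <- sampling_ranges(proportional_to_tilt = TRUE)
  set.seed(22)
  for (i in 1:200) {
    co <- sample_coefficients(ranges)
    bound <- 48 * sqrt(co[2]^2 + co[3]^2) / (1200 * sqrt(2))
    expect_true(all(abs(co[4:10]) <= bound + 1e-12))
  }
})

test_that("tilt ranges are validated against the aliasing limit", {
  cfg <- cfg_small(120L)
  expect_error(validate_ranges(sampling_ranges(), cfg), "alias")
  expect_silent(validate_ranges(scaled_sampling_ranges(cfg), cfg))
  # full-scale ranges are the printed defaults and pass on the full grid
  r_full <- scaled_sampling_ranges(optical_config())
  expect_equal(r_full$tilt, 1200)
  expect_equal(r_full$high_order, 48)
})

test_that("rendered triplets are normalized, deterministic and flagged", {
  cfg <- cfg_small(120L)
  ranges <- scaled_sampling_ranges(cfg)
  tr0 <- render_triplet(rep(0, 10), cfg, out_size = 32L)
  expect_equal(dim(tr0$image), c(32L, 32L, 3L))
  for (ch in 1:3) {
    expect_equal(min(tr0$image[, , ch]), 0)
    expect_equal(max(tr0$image[, , ch]), 1)
  }
  expect_false(tr0$dark_field)
  # bright field: the Fourier channel peaks in the central region
  pk <- which(tr0$image[, , 1] == 1, arr.ind = TRUE)[1, ]
  expect_true(all(abs(pk - 16.5) < 4))
  expect_lt(mean(tr0$image[c(1:4, 29:32), c(1:4, 29:32), 1]), 0.2)
  co <- sample_coefficients(ranges, seed = 23)
  tr1 <- render_triplet(co, cfg, out_size = 32L)
  tr2 <- render_triplet(co, cfg, out_size = 32L)
  expect_identical(tr1$image, tr2$image)
})

test_that("the dark-field flag matches a brute-force Fourier peak search", {
  cfg <- cfg_small(120L)
  ranges <- scaled_sampling_ranges(cfg)
  g <- sadhm:::config_grid(cfg)
  msk <- aperture_mask(g)
  n <- cfg$n_pixels
  set.seed(24)
  n_dark <- 0
  for (i in 1:25) {
    co <- sample_coefficients(ranges)
    # unmasked far field of the tilted aberrated aperture
    F <- sadhm:::fft2c(msk * exp(1i * zernike_phase_map(
      c(0, co[2], co[3], rep(0, 7)), g)))
    pk <- which(Mod(F) == max(Mod(F)), arr.ind = TRUE)[1, ] - 1
    r_pk <- sqrt(sum((pk - n / 2)^2))
    expect_equal(is_dark_field(co, cfg),
                 r_pk > cfg$fourier_mask_diameter_px / 2)
    n_dark <- n_dark + is_dark_field(co, cfg)
  }
  expect_gt(n_dark, 20)  # almost all samples are dark-field
})

test_that("dark-field draws dominate under the full-scale geometry", {
  # analytic criterion on 1000 draws: carrier radius in Fourier px vs mask
  cfg <- optical_config()
  ranges <- sampling_ranges()
  set.seed(25)
  flags <- replicate(1000, is_dark_field(sample_coefficients(ranges), cfg))
  expect_gt(mean(flags), 0.95)
})

test_that("datasets are written completely and reproducibly", {
  cfg <- cfg_small(120L)
  ranges <- scaled_sampling_ranges(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- build_dataset(6, ranges, cfg, seed = 31, out_dir = d1, out_size = 24L)
  expect_length(list.files(file.path(d1, "images")), 6)
  expect_true(file.exists(file.path(d1, "labels.csv")))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  m2 <- build_dataset(6, ranges, cfg, seed = 31, out_dir = d2, out_size = 24L)
  expect_identical(readBin(file.path(d1, "labels.csv"), "raw", 1e5),
                   readBin(file.path(d2, "labels.csv"), "raw", 1e5))
  # config hash is sensitive to any config field
  cfg2 <- cfg; cfg2$defocus_d <- cfg$defocus_d * 2
  expect_false(sadhm:::config_hash(cfg) == sadhm:::config_hash(cfg2))
  # reload pairs labels with images by embedded id
  back <- load_dataset(d1)
  expect_equal(length(back$triplets), 6)
  expect_equal(unname(back$triplets[[3]]$label),
               unname(unlist(m1$labels[3, paste0("c", 0:9)])),
               tolerance = 1e-12)
})

test_that("in-memory datasets match their labels and the BMP writer is lossless enough", {
  cfg <- cfg_small(120L)
  ranges <- scaled_sampling_ranges(cfg)
  ds <- build_dataset(3, ranges, cfg, seed = 32, out_size = 24L)
  expect_length(ds$triplets, 3)
  expect_equal(unname(ds$triplets[[2]]$label),
               unname(unlist(ds$labels[2, paste0("c", 0:9)])), tolerance = 1e-12)
  img <- ds$triplets[[1]]$image
  f <- tempfile(fileext = ".bmp")
  sadhm:::write_bmp(img, f)
  back <- sadhm:::read_bmp(f)
  expect_lt(max(abs(back - img)), 1 / 255)
  unlink(f)
})
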