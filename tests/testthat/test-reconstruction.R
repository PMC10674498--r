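test_that("aberration compensation inverts the applied phase exactly", {
  cfg <- cfg_small(120L)
  g <- sadhm:::config_grid(cfg)
  u <- bandlimited_field(120L, 20, seed = 51)
  co <- zernike_coefficients(c(0.4, 30, -12, 1.2, -0.8, 0.5, 0.3, -1.1, 0.9, -0.2))
  # apply only the image-degrading orders, then compensate: exact round trip
  ab <- c(0, 0, 0, co[4:10])
  aberrated <- complex_field(u$values * exp(1i * zernike_phase_map(ab, g)),
                             1, 0.532)
  comp <- compensate_field(aberrated, co, cfg)
  msk <- aperture_mask(g) > 0
  resid <- Arg(comp$values[msk] * Conj(u$values[msk]))
  expect_lt(sqrt(mean(resid^2)), 1e-10)
  # zero aberration leaves the field untouched
  expect_equal(compensate_field(u, c(0.3, 5, -2, rep(0, 7)), cfg)$values,
               u$values, tolerance = 1e-15)
  # compensating with c then -c is the identity
  c2 <- compensate_field(compensate_field(u, co, cfg), -co, cfg)
  expect_equal(c2$values, u$values, tolerance = 1e-10)
})

test_that("synthesis of on-axis records is the identity, and averages duplicates", {
  cfg <- cfg_small(120L)
  obs <- simulate_observation(rep(0, 10), cfg)
  rec <- illumination_record(1, obs$camera_field, coeffs_true = rep(0, 10))
  syn1 <- synthesize_fields(list(rec), cfg)
  expect_equal(syn1$field$values, obs$camera_field$values, tolerance = 1e-10)
  rec2 <- illumination_record(2, obs$camera_field, coeffs_true = rep(0, 10))
  syn2 <- synthesize_fields(list(rec, rec2), cfg)
  expect_equal(syn2$field$values, syn1$field$values, tolerance = 1e-12)
  expect_equal(max(syn2$weight), 2)
})

test_that("spectral tiles land where the carrier says and tile the union", {
  cfg <- cfg_small(160L)
  n <- cfg$n_pixels
  tilts <- list(c(0, 0), c(40, 0), c(0, -40), c(28, 28))
  recs <- lapply(seq_along(tilts), function(i) {
    co <- c(0, tilts[[i]][1], tilts[[i]][2], rep(0, 7))
    obs <- simulate_observation(co, cfg)
    illumination_record(i, obs$camera_field, coeffs_true = co)
  })
  syn <- synthesize_fields(recs, cfg)
  union <- matrix(0, n, n)
  for (i in seq_along(tilts)) {
    co <- c(0, tilts[[i]][1], tilts[[i]][2], rep(0, 7))
    ctr <- sadhm:::tile_center_px(co, cfg)
    union <- union + sadhm:::na_mask_matrix(n, cfg$fourier_mask_diameter_px,
                                            center_px = round(ctr))
  }
  expect_equal(syn$weight, union)
  # brute-force check: each tile's energy centroid sits at its center
  for (i in 2:4) {
    co <- c(0, tilts[[i]][1], tilts[[i]][2], rep(0, 7))
    s1 <- synthesize_fields(recs[i], cfg)
    w <- which(s1$weight > 0, arr.ind = TRUE)
    expect_lt(max(abs(colMeans(w) - 1 - sadhm:::tile_center_px(co, cfg))), 1)
  }
})

test_that("piston matching recovers injected offsets to machine precision", {
  cfg <- cfg_small(160L)
  gi <- illumination_grid(cfg, coverage_lpmm = 160)
  expect_gte(nrow(gi), 7)
  # ideal tiles of a structured sample
  set.seed(52)
  g <- sadhm:::config_grid(cfg)
  sample_amp <- matrix(stats::runif(160^2), 160)
  ill <- cbind(0, gi$c1, gi$c2, matrix(0, nrow(gi), 7))
  syn_ref <- sa_reconstruct(sample_amp, ill, cfg, mode = "ideal",
                            piston = "none")
  # corrupt each tile with a known piston and synthesize with matching
  delta <- stats::runif(nrow(gi), -pi, pi)
  apm <- aperture_mask(g)
  recs <- lapply(seq_len(nrow(gi)), function(i) {
    co <- zernike_coefficients(ill[i, ])
    phase <- zernike_phase_map(co, g)
    obj <- complex_field(sample_amp * apm * exp(1i * phase), 1, 0.532)
    cam <- sadhm:::image_through_4f(obj, cfg)$camera
    cam$values <- cam$values * exp(1i * delta[i])
    illumination_record(i, cam, coeffs_true = co)
  })
  syn_m <- synthesize_fields(recs, cfg, piston = "match")
  # recovered offsets cancel the injected pistons up to a global constant
  ord <- syn_m$indices
  err <- (syn_m$offsets + delta[ord]) - (syn_m$offsets[1] + delta[ord[1]])
  err <- Arg(exp(1i * err))
  expect_lt(max(abs(err)), 1e-6)
  # piston-consistent tiles yield all-zero offsets
  recs0 <- lapply(seq_len(nrow(gi)), function(i) {
    co <- zernike_coefficients(ill[i, ])
    obj <- complex_field(sample_amp * apm *
                           exp(1i * zernike_phase_map(co, g)), 1, 0.532)
    illumination_record(i, sadhm:::image_through_4f(obj, cfg)$camera,
                        coeffs_true = co)
  })
  syn0 <- synthesize_fields(recs0, cfg, piston = "match")
  expect_lt(max(abs(Arg(exp(1i * syn0$offsets)))), 1e-6)
  # skipping matching on corrupted tiles is strictly worse
  syn_no <- synthesize_fields(recs, cfg, piston = "none")
  ref_img <- Mod(syn_ref$field$values)
  rms <- function(s) {
    img <- Mod(s$field$values)
    sqrt(mean((img - ref_img)^2))
  }
  expect_lt(rms(syn_m), rms(syn_no))
})

test_that("a disconnected tile raises a topology error naming it", {
  cfg <- cfg_small(160L)
  obs <- simulate_observation(rep(0, 10), cfg)
  co_far <- c(0, 120, 0, rep(0, 7))   # tile far outside any overlap
  obs2 <- simulate_observation(co_far, cfg)
  recs <- list(illumination_record(1, obs$camera_field, rep(0, 10)),
               illumination_record(2, obs2$camera_field, co_far))
  expect_error(synthesize_fields(recs, cfg, piston = "match"), "overlap")
})

test_that("the synthesized PSF narrows as illuminations accumulate", {
  cfg <- cfg_small(160L)
  n <- cfg$n_pixels
  pt <- matrix(0, n, n); pt[n / 2 + 1, n / 2 + 1] <- 1  # point object at DC
  gi <- illumination_grid(cfg, coverage_lpmm = 200)
  counts <- c(1, 7, min(19, nrow(gi)))
  widths <- vapply(counts, function(k) {
    ill <- cbind(0, gi$c1[1:k], gi$c2[1:k], matrix(0, k, 7))
    syn <- sa_reconstruct(pt, ill, cfg, mode = "ideal", piston = "none")
    I <- Mod(syn$field$values)^2
    w <- which(I > 0, arr.ind = TRUE)
    ctr <- c(n / 2 + 1, n / 2 + 1)
    sqrt(sum(I * ((row(I) - ctr[1])^2 + (col(I) - ctr[2])^2)) / sum(I))
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("reconstruction modes order as physics demands on a bar target", {
  cfg <- cfg_small(280L)
  freqs <- c(90, 167)
  spec <- bar_chart_spec(freqs, cfg, height_px = 40)
  chart <- make_bar_chart(spec)
  gi <- illumination_grid(cfg, coverage_lpmm = 220)
  ill <- make_illuminations(gi, scaled_sampling_ranges(cfg), seed = 53,
                            proportional = TRUE)
  syn_id <- sa_reconstruct(chart, ill, cfg, mode = "ideal", piston = "none")
  syn_un <- sa_reconstruct(chart, ill, cfg, mode = "uncompensated",
                           piston = "ground_truth")
  syn_gt <- sa_reconstruct(chart, ill, cfg, mode = "compensated",
                           piston = "ground_truth")
  img <- function(s) Mod(s$field$values)^2
  ref <- img(syn_id)
  err_un <- sqrt(mean((img(syn_un) - ref)^2))
  err_gt <- sqrt(mean((img(syn_gt) - ref)^2))
  expect_lt(err_gt, err_un)   # compensation strictly helps
  m_un <- measure_mtf(img(syn_un), spec)$mtf
  m_gt <- measure_mtf(img(syn_gt), spec)$mtf
  # band estimates carry ~0.01 of coherent-ringing jitter; compensation must
  # never lose more than that anywhere
  expect_true(all(m_gt >= m_un - 0.02))
})
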