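test_that("phantom generation is deterministic from the seed", {
  spec <- phantom_spec(n_stations = 2, slices_per_station = 8,
                       inplane = c(32, 32), organs = list(),
                       lesions = list(list(center_mm = c(64, 64, 48),
                                           semi_axes_mm = c(16, 16, 18),
                                           amplitude = 100, adc = 0.82e-3)),
                       station_gains = c(1, 1.3), station_shifts = c(0L, 1L),
                       seed = 17)
  a <- generate_study(spec)
  b <- generate_study(spec)
  expect_identical(a$stations_low[[1]]$data, b$stations_low[[1]]$data)
  expect_identical(a$stations_high[[2]]$data, b$stations_high[[2]]$data)
  c_ <- generate_study(spec, seed = 18)
  expect_false(identical(a$stations_low[[1]]$data, c_$stations_low[[1]]$data))
})

test_that("a noiseless uncorrupted phantom is an exact fixed point of the ADC model", {
  spec <- tiny_lesion_spec()
  st <- generate_study(spec)
  study <- dwi_study(st$noiseless$low, st$noiseless$high)
  adc <- compute_adc(study)
  lesion <- st$truth$label_map > 0
  rel <- abs(adc$values[lesion] - 0.82e-3) / 0.82e-3
  expect_lt(max(rel), 1e-9)
})

test_that("Rician noise hits the SNR calibration and keeps signal positive", {
  spec <- phantom_spec(seed = 23)   # defaults: SNR 22 / 15
  st <- generate_study(spec)
  low <- fuse_stations(st$stations_low)$data

  # air voxels are pure Rician noise: mean = sigma * sqrt(pi / 2)
  air <- st$noiseless$low$data == 0
  expect_gt(sum(air), 1e4)
  sigma_hat <- mean(low[air]) / sqrt(pi / 2)
  snr_hat <- st$truth$mean_lesion_signal_low / sigma_hat
  expect_lt(abs(snr_hat - spec$snr_low) / spec$snr_low, 0.10)

  high <- fuse_stations(st$stations_high)$data
  expect_true(all(high >= 0))
  expect_gt(mean(high[air]), 0)    # Rician floor: no zero-mean background
})

test_that("response scenarios transform the spec truth exactly", {
  spec <- tiny_lesion_spec(semi_axes_mm = c(20, 16, 18))
  post <- apply_response(spec, response_scenario(volume_scale = 0.5,
                                                 adc_shift = 0.2e-3))
  pre_vol <- 4 / 3 * pi * prod(spec$lesions[[1]]$semi_axes_mm) / 1000
  post_vol <- 4 / 3 * pi * prod(post$lesions[[1]]$semi_axes_mm) / 1000
  expect_equal(post_vol, pre_vol / 2, tolerance = 1e-12)
  expect_equal(post$lesions[[1]]$adc, spec$lesions[[1]]$adc + 0.2e-3)

  ident <- apply_response(spec, response_scenario())
  expect_equal(ident$lesions, spec$lesions)

  expect_error(apply_response(spec, response_scenario(adc_shift = -1e-3)),
               "ADC")
  expect_error(response_scenario(volume_scale = 0), "volume_scale")
})

test_that("lesions outside the grid are rejected", {
  expect_error(
    phantom_spec(n_stations = 1, slices_per_station = 8, inplane = c(16, 16),
                 lesions = list(list(center_mm = c(500, 32, 24),
                                     semi_axes_mm = c(10, 10, 10),
                                     amplitude = 100, adc = 0.8e-3)),
                 organs = list(), station_gains = 1, station_shifts = 0L),
    "outside")
})

test_that("cohort generation is reproducible with planted effect directions", {
  coh1 <- generate_cohort(n_responders = 3, n_nonresponders = 2, seed = 4)
  coh2 <- generate_cohort(n_responders = 3, n_nonresponders = 2, seed = 4)
  expect_identical(coh1$truth, coh2$truth)
  expect_identical(coh1$patients[[2]]$pre_seed, coh2$patients[[2]]$pre_seed)

  resp <- coh1$truth$group == "responder"
  expect_true(median(coh1$truth$volume_scale[resp]) < 1)
  expect_true(median(coh1$truth$volume_scale[!resp]) > 1)
  expect_true(median(coh1$truth$adc_shift[resp]) > 0)
})

test_that("zero effect variability gives identical planted responder changes", {
  eff <- cohort_effects(responder_log_vs_sd = 0, responder_adc_shift_sd = 0,
                        nonresponder_log_vs_sd = 0, nonresponder_adc_shift_sd = 0)
  coh <- generate_cohort(n_responders = 3, n_nonresponders = 2,
                         effects = eff, seed = 6)
  resp <- coh$truth[coh$truth$group == "responder", ]
  expect_equal(resp$volume_scale, rep(0.5, 3))
  expect_equal(resp$adc_shift, rep(0.18e-3, 3))
})
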