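test_that("voxel geometry validates spacing and phase-encode axis", {
  g <- voxel_geometry(c(1.5, 1.5, 5), "column")
  expect_equal(g$spacing_mm, c(1.5, 1.5, 5))
  expect_equal(voxel_volume_ml(g), 1.5 * 1.5 * 5 / 1000)
  expect_error(voxel_geometry(c(0, 1, 1)), "positive")
  expect_error(voxel_geometry(c(1, 1)), "positive|three")
  expect_error(voxel_geometry(c(1, 1, 1), "slice"))
})

test_that("volume types enforce their invariants", {
  g <- voxel_geometry()
  arr <- array(runif(4 * 4 * 3), dim = c(4, 4, 3))
  expect_s3_class(station_volume(arr, g, 50), "station_volume")
  bad <- arr; bad[1] <- -1
  expect_error(station_volume(bad, g, 50), "non-negative")
  nan <- arr; nan[2] <- NaN
  expect_error(station_volume(nan, g, 50), "finite")
  expect_error(station_volume(arr, g, -5), "b_value")
  expect_error(wholebody_volume(arr, g, 50, station_boundaries = c(3, 2)),
               "strictly increasing")
  low <- wholebody_volume(arr, g, 900)
  high <- wholebody_volume(arr, g, 50)
  expect_error(dwi_study(low, high), "b_high > b_low")
})

test_that("NIfTI write/read round trip is lossless with spacing preserved", {
  g <- voxel_geometry(c(1.5, 1.5, 5.0))
  set.seed(42)
  arr <- array(runif(8 * 7 * 5, 0, 100), dim = c(8, 7, 5))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(arr, path, geometry = g)
  back <- read_volume(path)
  expect_identical(dim(back$data), dim(arr))
  expect_equal(back$data, arr, tolerance = 0)
  expect_equal(back$geometry$spacing_mm, c(1.5, 1.5, 5.0), tolerance = 1e-6)

  bad <- arr; bad[3] <- NaN
  expect_error(write_volume(bad, path, geometry = g), "non-finite")
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "no such file")
})

test_that("a phantom study written to disk reads back as declared stations", {
  dir <- withr::local_tempdir()
  spec <- phantom_spec(n_stations = 2, slices_per_station = 6,
                       inplane = c(24, 24), organs = list(),
                       lesions = list(list(center_mm = c(48, 48, 30),
                                           semi_axes_mm = c(14, 14, 14),
                                           amplitude = 100, adc = 0.8e-3)),
                       station_gains = c(1, 1), station_shifts = c(0L, 0L),
                       seed = 3)
  study <- generate_study(spec)
  cfg_path <- write_study(study, dir)
  series <- read_station_series(cfg_path)

  expect_length(series$low, 2)
  expect_length(series$high, 2)
  expect_equal(series$b_low, 50)
  expect_equal(series$b_high, 900)
  expect_equal(vapply(series$low, `[[`, integer(1), "station_index"), 1:2)
  # round trip of the generated intensities is bit-exact
  expect_equal(series$low[[1]]$data, study$stations_low[[1]]$data,
               tolerance = 0)
  expect_equal(series$high[[2]]$data, study$stations_high[[2]]$data,
               tolerance = 0)

  # declared b-values must be a valid pair
  cfg <- read_study_config(cfg_path)
  cfg$b_high <- 10
  bad_cfg <- file.path(dir, "bad.yaml")
  yaml::write_yaml(cfg, bad_cfg)
  expect_error(read_study_config(bad_cfg), "b_high > b_low")

  # a missing station file is fatal
  cfg <- yaml::read_yaml(cfg_path)
  cfg$stations[[2]]$high <- "missing.nii.gz"
  yaml::write_yaml(cfg, file.path(dir, "missing.yaml"))
  expect_error(read_station_series(file.path(dir, "missing.yaml")),
               "no such file")
})

test_that("inconsistent in-plane matrices across stations are fatal with axis report", {
  dir <- withr::local_tempdir()
  g <- voxel_geometry()
  write_volume(array(1, dim = c(8, 8, 4)), file.path(dir, "s1l.nii"), geometry = g)
  write_volume(array(1, dim = c(8, 8, 4)), file.path(dir, "s1h.nii"), geometry = g)
  write_volume(array(1, dim = c(10, 8, 4)), file.path(dir, "s2l.nii"), geometry = g)
  write_volume(array(1, dim = c(10, 8, 4)), file.path(dir, "s2h.nii"), geometry = g)
  cfg <- list(b_low = 50, b_high = 900, phase_encode_axis = "row",
              stations = list(list(low = "s1l.nii", high = "s1h.nii"),
                              list(low = "s2l.nii", high = "s2h.nii")))
  yaml::write_yaml(cfg, file.path(dir, "study.yaml"))
  expect_error(read_station_series(file.path(dir, "study.yaml")),
               "station 2.*10 x 8.*expected 8 x 8")
})
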