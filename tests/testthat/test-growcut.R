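test_that("strict thresholding behaves at the boundaries and on phantoms", {
  vol <- array(c(10, 10, 100, 100), dim = c(2, 2, 1))
  expect_true(all(threshold_volume(vol, 0)))
  expect_false(any(threshold_volume(vol, 100)))       # strict inequality
  expect_equal(sum(threshold_volume(vol, 50)), 2)
  expect_error(threshold_volume(vol, -1), "tau")

  spec <- tiny_lesion_spec()
  st <- generate_study(spec)
  mask <- threshold_volume(st$noiseless$high, 30)
  expect_equal(sum(mask), sum(st$truth$label_map > 0))
})

test_that("GrowCut reproduces the hand-simulated 1-D automaton", {
  feat <- c(0, 0, 0, 100, 100, 100)
  vol <- array(feat, dim = c(6, 1, 1))
  seeds <- seed_map(dim(vol), foreground = matrix(c(1, 1, 1), 1),
                    background = matrix(c(6, 1, 1), 1))
  state <- growcut_3d(vol, seeds)
  expect_true(state$converged)
  expect_equal(as.integer(state$labels), c(1L, 1L, 1L, 2L, 2L, 2L))

  # independent hand simulation of the same update rule
  oracle <- oracle_growcut_1d(feat, labels = c(1L, 0L, 0L, 0L, 0L, 2L),
                              strengths = c(1, 0, 0, 0, 0, 1))
  expect_equal(as.integer(state$labels), oracle$labels)
  expect_equal(as.numeric(state$strengths), oracle$strengths)
})

test_that("a lone foreground seed floods a uniform volume", {
  vol <- array(42, dim = c(5, 4, 3))
  seeds <- seed_map(dim(vol), foreground = matrix(c(3, 2, 2), 1))
  state <- growcut_3d(vol, seeds)
  expect_true(state$converged)
  expect_true(all(state$labels == 1L))
  expect_true(all(state$strengths == 1))
})

test_that("GrowCut reaches a fixed point and strengths stay in [0, 1]", {
  set.seed(9)
  vol <- array(runif(10 * 10 * 6, 0, 100), dim = c(10, 10, 6))
  seeds <- seed_map(dim(vol),
                    foreground = matrix(c(2, 2, 2), 1),
                    background = matrix(c(9, 9, 5), 1))
  state <- growcut_3d(vol, seeds)
  expect_true(state$converged)
  expect_true(all(state$strengths >= 0 & state$strengths <= 1))

  # re-running from the converged state changes nothing, in one sweep
  again <- growcut_3d(vol, structure(list(labels = state$labels,
                                          strengths = state$strengths),
                                     class = "seed_map"))
  expect_identical(again$labels, state$labels)
  expect_identical(again$iterations, 1L)
  expect_true(again$converged)
})

test_that("seed handling rejects empty seed maps", {
  expect_error(seed_map(c(3, 3, 3)), "no seeds")
})

test_that("box-seeded GrowCut removes a bright blob within 5% of its census", {
  fov <- c(64, 64, 32) * c(4, 4, 6)
  blob <- list(center_mm = fov / 2, semi_axes_mm = c(40, 36, 40),
               amplitude = 90, adc = 0.9e-3)
  spec <- phantom_spec(n_stations = 1, slices_per_station = 32,
                       inplane = c(64, 64), lesions = list(), organs = list(blob),
                       station_gains = 1, station_shifts = 0L, seed = 2)
  st <- generate_study(spec)
  study <- fuse_study(st)
  adc <- compute_adc(study)
  cdwi <- compute_cdwi(study, adc, 950)
  mask <- threshold_volume(cdwi, 20)
  blob_truth <- st$noiseless$high$data > 30
  n_blob <- sum(blob_truth)
  expect_gt(n_blob, 0)

  res <- remove_region_growcut(
    mask, cdwi,
    fg_box = list(lo = c(29, 29, 13), hi = c(35, 35, 19)),
    bg_box = list(lo = c(12, 12, 2), hi = c(53, 53, 31)))
  expect_lt(abs(res$n_removed - n_blob) / n_blob, 0.05)
  expect_lt(sum(res$mask), 0.05 * n_blob)

  expect_error(remove_region_growcut(mask, cdwi,
                                     fg_box = list(lo = c(1, 1, 1), hi = c(60, 60, 31)),
                                     bg_box = list(lo = c(12, 12, 2), hi = c(53, 53, 31))),
               "strictly inside")
})

test_that("single-voxel foreground box removes its connected uniform plateau", {
  vol <- array(0, dim = c(12, 12, 5))
  vol[5:8, 5:8, 2:4] <- 100                      # plateau inside the bg box
  mask <- vol > 50
  res <- remove_region_growcut(mask, vol,
                               fg_box = list(lo = c(6, 6, 3), hi = c(6, 6, 3)),
                               bg_box = list(lo = c(2, 2, 1), hi = c(11, 11, 5)))
  expect_equal(res$n_removed, sum(vol > 50))
  expect_false(any(res$mask))
})

test_that("removal in an empty region leaves the disease mask unchanged", {
  vol <- array(0, dim = c(12, 12, 5))
  vol[2:3, 2:3, 1:2] <- 100
  mask <- vol > 50
  res <- remove_region_growcut(mask, vol,
                               fg_box = list(lo = c(7, 7, 3), hi = c(8, 8, 4)),
                               bg_box = list(lo = c(5, 5, 2), hi = c(11, 11, 5)))
  expect_identical(res$mask, mask)
  expect_equal(res$n_removed, 0)
})
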