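#' Specification of a synthetic whole-body DWI phantom
#'
#' Describes a multi-station two-b-value study with known ground truth:
#' an elliptical body cylinder of suppressed background tissue,
#' hyperintense ellipsoidal lesions of known volume and ADC, optional
#' organ blobs of retained signal (spleen-like), an optional
#' fat-suppression-failure band, optional salt (impulse) voxels,
#' per-station gain/shift corruptions applied after noise, and Rician
#' noise calibrated to target SNRs.
#'
#' Noise calibration: the Gaussian channel sigma at each b-value is set so
#' that mean noiseless lesion signal / sigma equals the requested SNR
#' (defaults 22 at the low and 15 at the high b-value, matching the
#' acquisition protocol the pipeline is designed for). Lesion ADC defaults
#' to 0.82e-3 mm^2/s, a typical pre-treatment median gADC for untreated
#' bone metastases.
#'
#' @param n_stations number of stations (default 4).
#' @param slices_per_station axial slices per station (default 24).
#' @param inplane in-plane matrix (rows, columns), default 96 x 96.
#' @param spacing_mm voxel size (row, column, slice) in mm, default
#'   (4, 4, 6).
#' @param phase_encode_axis `"row"` or `"column"`.
#' @param b_low,b_high acquired b-values in s/mm^2 (default 50, 900).
#' @param body list: `semi_axes_mm` (in-plane), `amplitude`, `adc`.
#' @param lesions list of lesions, each `list(center_mm, semi_axes_mm,
#'   amplitude, adc)`; centers in the fused-volume mm frame (voxel (i,j,k)
#'   center sits at ((i-0.5) dr, (j-0.5) dc, (k-0.5) ds)).
#' @param organs like `lesions` but not part of disease truth.
#' @param fat_band `NULL` or `list(row_range, col_range, slice_range,
#'   amplitude, adc, fill_fraction)` (voxel index ranges).
#'   `fill_fraction` (default 1) is the fraction of band voxels that
#'   retain fat signal: incomplete fat suppression leaves speckled, not
#'   solid, residual signal.
#' @param salt `NULL` or `list(fraction, amplitude, adc)`: impulse voxels
#'   placed uniformly at random inside the body.
#' @param station_gains,station_shifts per-station corruption gain
#'   (multiplicative) and phase-encode shift (voxels).
#' @param snr_low,snr_high target SNRs; `Inf` disables noise.
#' @param seed RNG seed used by [generate_study()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_stations = 4, slices_per_station = 24,
                         inplane = c(96, 96), spacing_mm = c(4, 4, 6),
                         phase_encode_axis = "row",
                         b_low = 50, b_high = 900,
                         body = list(semi_axes_mm = NULL, amplitude = 20,
                                     adc = 1.6e-3),
                         lesions = NULL, organs = NULL, fat_band = NULL,
                         salt = NULL,
                         station_gains = rep(1, n_stations),
                         station_shifts = rep(0L, n_stations),
                         snr_low = 22, snr_high = 15, seed = 1L) {
  if (!(b_high > b_low) || b_low < 0) stop("require b_high > b_low >= 0")
  if (snr_low <= 0 || snr_high <= 0) stop("SNRs must be > 0")
  geometry <- voxel_geometry(spacing_mm, phase_encode_axis)
  fov <- c(inplane, n_stations * slices_per_station) * spacing_mm
  if (is.null(body$semi_axes_mm)) body$semi_axes_mm <- 0.42 * fov[1:2]
  if (is.null(lesions)) lesions <- default_lesions(fov)
  if (is.null(organs)) organs <- default_organs(fov)
  for (les in c(lesions, organs)) {
    lo <- les$center_mm - les$semi_axes_mm
    hi <- les$center_mm + les$semi_axes_mm
    if (any(lo < 0) || any(hi > fov)) stop("lesion/organ outside the fused grid")
    if (les$adc <= 0) stop("compartment ADC must be > 0")
  }
  if (length(station_gains) != n_stations || length(station_shifts) != n_stations)
    stop("station_gains/station_shifts must have one entry per station")
  if (any(station_gains <= 0)) stop("station gains must be > 0")
  structure(list(n_stations = as.integer(n_stations),
                 slices_per_station = as.integer(slices_per_station),
                 inplane = as.integer(inplane), geometry = geometry,
                 b_low = b_low, b_high = b_high, body = body,
                 lesions = lesions, organs = organs, fat_band = fat_band,
                 salt = salt, station_gains = as.numeric(station_gains),
                 station_shifts = as.integer(station_shifts),
                 snr_low = snr_low, snr_high = snr_high,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

default_lesions <- function(fov, amplitude = 100, adc = 0.82e-3) {
  centers <- rbind(c(0.45, 0.50, 0.18), c(0.55, 0.46, 0.40),
                   c(0.47, 0.56, 0.60), c(0.53, 0.50, 0.80),
                   c(0.48, 0.44, 0.92))
  lapply(seq_len(nrow(centers)), function(i)
    list(center_mm = centers[i, ] * fov, semi_axes_mm = c(16, 16, 18),
         amplitude = amplitude, adc = adc))
}

default_organs <- function(fov) {
  list(list(center_mm = c(0.34, 0.64, 0.30) * fov,
            semi_axes_mm = c(28, 24, 24), amplitude = 90, adc = 0.9e-3))
}

ellipsoid_mask <- function(dims, spacing, center_mm, semi_axes_mm) {
  r <- ((seq_len(dims[1]) - 0.5) * spacing[1] - center_mm[1]) / semi_axes_mm[1]
  c_ <- ((seq_len(dims[2]) - 0.5) * spacing[2] - center_mm[2]) / semi_axes_mm[2]
  s <- ((seq_len(dims[3]) - 0.5) * spacing[3] - center_mm[3]) / semi_axes_mm[3]
  outer(outer(r^2, c_^2, `+`), s^2, `+`) <= 1
}

#' Generate a synthetic WBDWI study from a phantom spec
#'
#' Builds the noiseless monoexponential signal
#' `S(b) = amplitude * exp(-b * ADC)` per compartment on the fused grid,
#' applies Rician noise per b-value (`observed = sqrt((S + e1)^2 + e2^2)`,
#' `e ~ N(0, sigma_b^2)` with `sigma_b` set from the spec SNR), then
#' splits the volume into stations and applies the per-station gain and
#' shift corruptions (after noise, as acquisition mismatches are).
#' Fully reproducible from the seed.
#'
#' @param spec a [phantom_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return An object of class `phantom_study`: list with `stations_low`,
#'   `stations_high` (lists of [station_volume()]), `noiseless` (the
#'   uncorrupted fused [wholebody_volume()]s, for ground-truth
#'   comparisons), `truth` (lesion `label_map`, per-lesion table with
#'   analytic and census volumes and true ADC, `tdv_ml`, noise sigmas and
#'   mean lesion signals), `spec`.
#' @export
generate_study <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(seed)) seed <- spec$seed
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(seed))

  dims <- c(spec$inplane, spec$n_stations * spec$slices_per_station)
  sp <- spec$geometry$spacing_mm
  amp <- array(0, dim = dims)
  adc <- array(1e-3, dim = dims)

  # body cylinder
  ctr <- c(dims[1:2] * sp[1:2] / 2)
  r <- ((seq_len(dims[1]) - 0.5) * sp[1] - ctr[1]) / spec$body$semi_axes_mm[1]
  c_ <- ((seq_len(dims[2]) - 0.5) * sp[2] - ctr[2]) / spec$body$semi_axes_mm[2]
  body2d <- outer(r^2, c_^2, `+`) <= 1
  body <- array(body2d, dim = dims)
  amp[body] <- spec$body$amplitude
  adc[body] <- spec$body$adc

  fat_idx <- integer(0)
  if (!is.null(spec$fat_band)) {
    fb <- spec$fat_band
    band <- array(FALSE, dim = dims)
    band[fb$row_range[1]:fb$row_range[2], fb$col_range[1]:fb$col_range[2],
         fb$slice_range[1]:fb$slice_range[2]] <- TRUE
    fat_idx <- which(band)
    fill <- if (is.null(fb$fill_fraction)) 1 else fb$fill_fraction
    if (fill < 1) fat_idx <- sample(fat_idx, round(fill * length(fat_idx)))
    amp[fat_idx] <- fb$amplitude
    adc[fat_idx] <- fb$adc
  }
  for (org in spec$organs) {
    m <- ellipsoid_mask(dims, sp, org$center_mm, org$semi_axes_mm)
    amp[m] <- org$amplitude
    adc[m] <- org$adc
  }
  label_map <- array(0L, dim = dims)
  lesion_rows <- list()
  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    m <- ellipsoid_mask(dims, sp, les$center_mm, les$semi_axes_mm)
    amp[m] <- les$amplitude
    adc[m] <- les$adc
    label_map[m] <- i
    lesion_rows[[i]] <- data.frame(
      id = i, adc = les$adc, amplitude = les$amplitude,
      analytic_ml = 4 / 3 * pi * prod(les$semi_axes_mm) / 1000,
      n_voxels = sum(m))
  }
  lesion_table <- do.call(rbind, lesion_rows)

  if (!is.null(spec$salt) && spec$salt$fraction > 0) {
    inside <- which(body)
    n_salt <- round(spec$salt$fraction * length(inside))
    pick <- sample(inside, n_salt)
    pick <- pick[label_map[pick] == 0L]  # never corrupt disease truth
    amp[pick] <- spec$salt$amplitude
    adc[pick] <- spec$salt$adc
  }

  s_low <- amp * exp(-spec$b_low * adc)
  s_high <- amp * exp(-spec$b_high * adc)
  lesion_vox <- label_map > 0L
  ref_vox <- if (any(lesion_vox)) lesion_vox else body
  mean_low <- mean(s_low[ref_vox])
  mean_high <- mean(s_high[ref_vox])
  sigma_low <- if (is.finite(spec$snr_low)) mean_low / spec$snr_low else 0
  sigma_high <- if (is.finite(spec$snr_high)) mean_high / spec$snr_high else 0

  rician <- function(s, sigma) {
    if (sigma <= 0) return(s)
    n <- length(s)
    sqrt((s + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  }
  obs_low <- array(rician(s_low, sigma_low), dim = dims)
  obs_high <- array(rician(s_high, sigma_high), dim = dims)

  axis <- if (spec$geometry$phase_encode_axis == "row") 1L else 2L
  split_corrupt <- function(vol, b) {
    out <- vector("list", spec$n_stations)
    for (st in seq_len(spec$n_stations)) {
      z0 <- (st - 1L) * spec$slices_per_station + 1L
      dat <- vol[, , z0:(z0 + spec$slices_per_station - 1L), drop = FALSE]
      dat <- dat * spec$station_gains[st]
      dat <- shift_inplane(dat, spec$station_shifts[st], axis)
      out[[st]] <- station_volume(dat, spec$geometry, b, st)
    }
    out
  }

  structure(list(
    stations_low = split_corrupt(obs_low, spec$b_low),
    stations_high = split_corrupt(obs_high, spec$b_high),
    noiseless = list(
      low = wholebody_volume(s_low, spec$geometry, spec$b_low),
      high = wholebody_volume(s_high, spec$geometry, spec$b_high)),
    truth = list(label_map = label_map, lesions = lesion_table,
                 tdv_ml = sum(lesion_vox) * voxel_volume_ml(spec$geometry),
                 median_adc = if (any(lesion_vox)) median(adc[lesion_vox]) else NA_real_,
                 sigma_low = sigma_low, sigma_high = sigma_high,
                 mean_lesion_signal_low = mean_low,
                 mean_lesion_signal_high = mean_high),
    spec = spec, seed = as.integer(seed)),
    class = "phantom_study")
}

#' Treatment-response scenario for a phantom
#'
#' @param volume_scale per-lesion volume scale factor(s), > 0 (recycled).
#' @param adc_shift per-lesion additive ADC shift(s) in mm^2/s (recycled).
#' @param new_lesions list of lesions appearing at the post timepoint
#'   (progression), same format as in [phantom_spec()].
#' @return An object of class `response_scenario`.
#' @export
response_scenario <- function(volume_scale = 1, adc_shift = 0,
                              new_lesions = list()) {
  if (any(volume_scale <= 0)) stop("volume_scale must be > 0")
  structure(list(volume_scale = volume_scale, adc_shift = adc_shift,
                 new_lesions = new_lesions),
            class = "response_scenario")
}

#' Apply a response scenario to a phantom spec
#'
#' Scales each lesion's semi-axes by the cube root of its volume scale,
#' shifts its ADC, and appends any progression lesions, returning the
#' post-treatment spec for [generate_study()].
#'
#' @param spec a [phantom_spec()].
#' @param scenario a [response_scenario()].
#' @return The post-treatment `phantom_spec`.
#' @export
apply_response <- function(spec, scenario) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(scenario, "response_scenario"))
  n <- length(spec$lesions)
  vs <- rep_len(scenario$volume_scale, n)
  ds <- rep_len(scenario$adc_shift, n)
  for (i in seq_len(n)) {
    spec$lesions[[i]]$semi_axes_mm <- spec$lesions[[i]]$semi_axes_mm * vs[i]^(1 / 3)
    new_adc <- spec$lesions[[i]]$adc + ds[i]
    if (new_adc <= 0) stop("ADC shift drives lesion ADC <= 0")
    spec$lesions[[i]]$adc <- new_adc
  }
  spec$lesions <- c(spec$lesions, scenario$new_lesions)
  spec
}

#' Default cohort effect-size parameters
#'
#' Between-patient distributions of the simulated treatment effects.
#' Responder medians mirror the effects the pipeline is designed to
#' detect: lesion volumes shrinking to about half (log-normal around
#' log 0.5) with median gADC rising by about +0.18e-3 mm^2/s;
#' non-responders grow by about +26% with essentially unchanged ADC.
#'
#' @param responder_log_vs_mean,responder_log_vs_sd log volume-scale
#'   distribution for responders.
#' @param responder_adc_shift_mean,responder_adc_shift_sd ADC shift
#'   (mm^2/s) distribution for responders.
#' @param nonresponder_log_vs_mean,nonresponder_log_vs_sd log volume-scale
#'   distribution for non-responders.
#' @param nonresponder_adc_shift_mean,nonresponder_adc_shift_sd ADC shift
#'   distribution for non-responders.
#' @return List of effect parameters.
#' @export
cohort_effects <- function(responder_log_vs_mean = log(0.5),
                           responder_log_vs_sd = 0.35,
                           responder_adc_shift_mean = 0.18e-3,
                           responder_adc_shift_sd = 0.08e-3,
                           nonresponder_log_vs_mean = log(1.26),
                           nonresponder_log_vs_sd = 0.25,
                           nonresponder_adc_shift_mean = -0.02e-3,
                           nonresponder_adc_shift_sd = 0.03e-3) {
  as.list(environment())
}

cohort_base_spec <- function(seed = 1L) {
  phantom_spec(n_stations = 3, slices_per_station = 12, inplane = c(64, 64),
               spacing_mm = c(4, 4, 6), lesions = list(), organs = list(),
               seed = seed)
}

random_cohort_lesions <- function(fov, n_lesions) {
  lapply(seq_len(n_lesions), function(i) {
    semi <- c(runif(1, 12, 20), runif(1, 12, 20), runif(1, 14, 22))
    center <- c(runif(1, 0.40, 0.60) * fov[1], runif(1, 0.40, 0.60) * fov[2],
                runif(1, 0.15, 0.85) * fov[3])
    adc <- max(0.5e-3, rnorm(1, 0.82e-3, 0.05e-3))
    list(center_mm = center, semi_axes_mm = semi, amplitude = 100, adc = adc)
  })
}

#' Generate a paired-timepoint response cohort
#'
#' Creates `n_responders + n_nonresponders` synthetic patients, each with
#' randomized lesions and per-station gain/shift corruptions, plus a
#' drawn treatment effect (volume scale and ADC shift from
#' [cohort_effects()]), and pre/post [phantom_spec()]s. Studies are
#' generated lazily by [generate_study()] from the stored specs and
#' per-study seeds, so the cohort object is light.
#'
#' @param n_responders,n_nonresponders group sizes (defaults 7 and 4).
#' @param effects a [cohort_effects()] list.
#' @param seed master seed; all patient geometry, effects and per-study
#'   noise seeds derive from it.
#' @param base_spec template [phantom_spec()]; default is a compact
#'   3-station 64 x 64 x 36 phantom suitable for repeated simulation.
#' @return An object of class `wbdwi_cohort`: list with `patients` (each
#'   with `patient_id`, `group`, `pre_spec`, `post_spec`, `pre_seed`,
#'   `post_seed`, `scenario`) and `truth` (data.frame of planted effects).
#' @export
generate_cohort <- function(n_responders = 7, n_nonresponders = 4,
                            effects = cohort_effects(), seed = 1L,
                            base_spec = NULL) {
  if (n_responders < 1 || n_nonresponders < 1) stop("need >= 1 patient per group")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(seed))
  if (is.null(base_spec)) base_spec <- cohort_base_spec()

  n_pat <- n_responders + n_nonresponders
  groups <- c(rep("responder", n_responders), rep("non-responder", n_nonresponders))
  study_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n_pat),
                        ncol = 2)
  dims <- c(base_spec$inplane, base_spec$n_stations * base_spec$slices_per_station)
  fov <- dims * base_spec$geometry$spacing_mm

  patients <- vector("list", n_pat)
  truth <- vector("list", n_pat)
  for (i in seq_len(n_pat)) {
    spec <- base_spec
    spec$lesions <- random_cohort_lesions(fov, sample(3:5, 1))
    spec$station_gains <- runif(spec$n_stations, 0.8, 1.25)
    spec$station_gains[1] <- 1
    spec$station_shifts <- c(0L, sample(-2:2, spec$n_stations - 1L, replace = TRUE))
    if (groups[i] == "responder") {
      vs <- exp(rnorm(1, effects$responder_log_vs_mean, effects$responder_log_vs_sd))
      shift <- rnorm(1, effects$responder_adc_shift_mean, effects$responder_adc_shift_sd)
    } else {
      vs <- exp(rnorm(1, effects$nonresponder_log_vs_mean, effects$nonresponder_log_vs_sd))
      shift <- rnorm(1, effects$nonresponder_adc_shift_mean, effects$nonresponder_adc_shift_sd)
    }
    # keep post-treatment ADC physical
    mean_adc <- mean(vapply(spec$lesions, `[[`, numeric(1), "adc"))
    shift <- max(shift, -0.8 * mean_adc)
    scen <- response_scenario(volume_scale = vs, adc_shift = shift)
    pid <- sprintf("P%02d", i)
    patients[[i]] <- list(patient_id = pid, group = groups[i],
                          pre_spec = spec, post_spec = apply_response(spec, scen),
                          pre_seed = study_seeds[i, 1], post_seed = study_seeds[i, 2],
                          scenario = scen)
    truth[[i]] <- data.frame(patient_id = pid, group = groups[i],
                             volume_scale = vs, adc_shift = shift,
                             n_lesions = length(spec$lesions))
  }
  structure(list(patients = patients, truth = do.call(rbind, truth),
                 effects = effects, seed = as.integer(seed)),
            class = "wbdwi_cohort")
}

#' Write a phantom study to disk as a NIfTI study directory
#'
#' Writes one NIfTI per station per b-value, a `study.yaml` config
#' consumable by [read_station_series()], the ground-truth lesion label
#' map, and a truth-metrics JSON.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if needed).
#' @return The config path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "phantom_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- study$spec
  stations <- lapply(seq_along(study$stations_low), function(s) {
    lowf <- sprintf("station%02d_b%g.nii.gz", s, spec$b_low)
    highf <- sprintf("station%02d_b%g.nii.gz", s, spec$b_high)
    write_volume(study$stations_low[[s]], file.path(dir, lowf))
    write_volume(study$stations_high[[s]], file.path(dir, highf))
    list(low = lowf, high = highf)
  })
  cfg <- list(b_low = spec$b_low, b_high = spec$b_high,
              phase_encode_axis = spec$geometry$phase_encode_axis,
              stations = stations)
  cfg_path <- file.path(dir, "study.yaml")
  yaml::write_yaml(cfg, cfg_path)
  write_volume(array(as.numeric(study$truth$label_map),
                     dim = dim(study$truth$label_map)),
               file.path(dir, "truth_labels.nii.gz"), geometry = spec$geometry)
  jsonlite::write_json(
    list(tdv_ml = study$truth$tdv_ml, median_adc = study$truth$median_adc,
         lesions = study$truth$lesions, sigma_low = study$truth$sigma_low,
         sigma_high = study$truth$sigma_high, seed = study$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(cfg_path)
}
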