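# Shared phantom configurations for fast tests.

# compact noiseless single-lesion phantom: one station, no corruptions
tiny_lesion_spec <- function(semi_axes_mm = c(20, 15, 10), adc = 0.82e-3,
                             noiseless = TRUE, spacing_mm = c(4, 4, 6)) {
  fov <- c(48, 48, 24) * spacing_mm
  phantom_spec(
    n_stations = 1, slices_per_station = 24, inplane = c(48, 48),
    spacing_mm = spacing_mm,
    lesions = list(list(center_mm = fov / 2, semi_axes_mm = semi_axes_mm,
                        amplitude = 100, adc = adc)),
    organs = list(), station_gains = 1, station_shifts = 0L,
    snr_low = if (noiseless) Inf else 22,
    snr_high = if (noiseless) Inf else 15, seed = 1)
}

# multi-station phantom with configurable planted corruptions; lesions sit
# at station centres so boundary slabs see only body tissue
corrupted_spec <- function(gains, shifts, noiseless = TRUE, seed = 1) {
  n <- length(gains)
  fov <- c(64, 64, 16 * n) * c(4, 4, 6)
  inplane_fr <- list(c(0.45, 0.5), c(0.55, 0.45), c(0.5, 0.55))
  lesions <- lapply(seq_len(min(3, n)), function(s)
    list(center_mm = c(inplane_fr[[s]] * fov[1:2], (s - 0.5) / n * fov[3]),
         semi_axes_mm = c(16, 16, 18), amplitude = 100, adc = 0.82e-3))
  phantom_spec(n_stations = n, slices_per_station = 16, inplane = c(64, 64),
               organs = list(), lesions = lesions,
               station_gains = gains, station_shifts = as.integer(shifts),
               snr_low = if (noiseless) Inf else 20,
               snr_high = if (noiseless) Inf else 20, seed = seed)
}

# the salt + residual-fat phantom used for the MRF-vs-threshold property
salt_fat_spec <- function(seed) {
  phantom_spec(organs = list(),
               fat_band = list(row_range = c(16, 24), col_range = c(25, 72),
                               slice_range = c(30, 60), amplitude = 18,
                               adc = 0.25e-3, fill_fraction = 0.3),
               salt = list(fraction = 0.002, amplitude = 18, adc = 0.25e-3),
               seed = seed)
}

# voxel census of an ellipsoidal compartment on the fused grid
ellipsoid_voxels <- function(spec, comp) {
  dims <- c(spec$inplane, spec$n_stations * spec$slices_per_station)
  sp <- spec$geometry$spacing_mm
  r <- ((seq_len(dims[1]) - 0.5) * sp[1] - comp$center_mm[1]) / comp$semi_axes_mm[1]
  c_ <- ((seq_len(dims[2]) - 0.5) * sp[2] - comp$center_mm[2]) / comp$semi_axes_mm[2]
  s <- ((seq_len(dims[3]) - 0.5) * sp[3] - comp$center_mm[3]) / comp$semi_axes_mm[3]
  sum(outer(outer(r^2, c_^2, `+`), s^2, `+`) <= 1)
}

# seed boxes for removing an ellipsoidal structure: the foreground box sits
# inside the structure, the background box surrounds it with a margin
organ_box <- function(spec, comp, inner) {
  sp <- spec$geometry$spacing_mm
  dims <- c(spec$inplane, spec$n_stations * spec$slices_per_station)
  half <- if (inner) 0.45 * comp$semi_axes_mm else comp$semi_axes_mm + 4 * sp
  lo <- pmax(1, floor((comp$center_mm - half) / sp))
  hi <- pmin(dims, ceiling((comp$center_mm + half) / sp))
  list(lo = as.integer(lo), hi = as.integer(hi))
}

fuse_study <- function(st, search_radius = 5) {
  low <- fuse_stations(st$stations_low, search_radius = search_radius)
  high <- fuse_stations(st$stations_high,
                        corrections = attr(low, "corrections"))
  dwi_study(low, high)
}
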