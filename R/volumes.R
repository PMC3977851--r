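#' Voxel geometry of a DWI volume
#'
#' Bundles voxel spacing and the phase-encode axis. Spacing is given in
#' millimetres as (row, column, slice); the phase-encode axis must be one
#' of the two in-plane axes because inter-station mismatch on echo-planar
#' DWI occurs along phase encoding.
#'
#' @param spacing_mm numeric length-3, positive: voxel size (row, column,
#'   slice) in mm.
#' @param phase_encode_axis `"row"` or `"column"`.
#' @return An object of class `voxel_geometry`.
#' @examples
#' voxel_geometry(c(4, 4, 6), "row")
#' @export
voxel_geometry <- function(spacing_mm = c(4, 4, 6), phase_encode_axis = "row") {
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be three positive finite values (row, column, slice)")
  phase_encode_axis <- match.arg(phase_encode_axis, c("row", "column"))
  structure(list(spacing_mm = spacing_mm, phase_encode_axis = phase_encode_axis),
            class = "voxel_geometry")
}

#' Voxel volume in millilitres
#' @param geometry a [voxel_geometry()].
#' @return Scalar voxel volume in ml (spacing product in mm^3 / 1000).
#' @export
voxel_volume_ml <- function(geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  prod(geometry$spacing_mm) / 1000
}

#' One imaging station of a WBDWI acquisition
#'
#' @param data non-negative finite numeric 3-D array (row, column, slice),
#'   slice 1 most superior.
#' @param geometry a [voxel_geometry()].
#' @param b_value diffusion weighting in s/mm^2, >= 0.
#' @param station_index integer >= 1; 1 is the most superior station.
#' @return An object of class `station_volume`.
#' @export
station_volume <- function(data, geometry, b_value, station_index = 1L) {
  data <- check_volume_array(data)
  if (any(data < 0)) stop("station intensities must be non-negative")
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (!is.finite(b_value) || b_value < 0) stop("b_value must be >= 0")
  station_index <- as.integer(station_index)
  if (station_index < 1L) stop("station_index must be >= 1")
  structure(list(data = data, geometry = geometry, b_value = as.numeric(b_value),
                 station_index = station_index),
            class = "station_volume")
}

#' Fused whole-body volume
#'
#' @param data numeric 3-D array (row, column, slice).
#' @param geometry a [voxel_geometry()].
#' @param b_value diffusion weighting in s/mm^2.
#' @param station_boundaries integer vector of the first slice index of
#'   stations 2..n (strictly increasing, within the slice range); empty for
#'   a single station.
#' @return An object of class `wholebody_volume`.
#' @export
wholebody_volume <- function(data, geometry, b_value,
                             station_boundaries = integer(0)) {
  data <- check_volume_array(data)
  stopifnot(inherits(geometry, "voxel_geometry"))
  sb <- as.integer(station_boundaries)
  if (length(sb)) {
    if (any(diff(sb) <= 0) || any(sb < 2L) || any(sb > dim(data)[3]))
      stop("station_boundaries must be strictly increasing slice indices within range")
  }
  structure(list(data = data, geometry = geometry, b_value = as.numeric(b_value),
                 station_boundaries = sb),
            class = "wholebody_volume")
}

#' Two-b-value whole-body DWI study
#'
#' @param low,high `wholebody_volume` objects at the low and high b-value,
#'   on the same voxel grid.
#' @return An object of class `dwi_study` with elements `low`, `high`,
#'   `b_low`, `b_high`.
#' @export
dwi_study <- function(low, high) {
  stopifnot(inherits(low, "wholebody_volume"), inherits(high, "wholebody_volume"))
  if (!identical(dim(low$data), dim(high$data)))
    stop("low and high b-value volumes must share the same grid shape")
  if (!isTRUE(all.equal(low$geometry$spacing_mm, high$geometry$spacing_mm)))
    stop("low and high b-value volumes must share voxel geometry")
  if (!(high$b_value > low$b_value) || low$b_value < 0)
    stop("require b_high > b_low >= 0")
  structure(list(low = low, high = high,
                 b_low = low$b_value, b_high = high$b_value),
            class = "dwi_study")
}

check_volume_array <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3-D array (row, column, slice)")
  storage.mode(data) <- "double"
  if (any(!is.finite(data))) stop("volume data must be finite (no NA/NaN/Inf)")
  data
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("voxel_geometry: %.3g x %.3g x %.3g mm, phase-encode axis = %s\n",
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              x$phase_encode_axis))
  invisible(x)
}

#' @export
print.station_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("station_volume %d: %d x %d x %d voxels, b = %g s/mm2\n",
              x$station_index, d[1], d[2], d[3], x$b_value))
  invisible(x)
}

#' @export
print.wholebody_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("wholebody_volume: %d x %d x %d voxels, b = %g s/mm2, %d station boundaries\n",
              d[1], d[2], d[3], x$b_value, length(x$station_boundaries)))
  invisible(x)
}

#' @export
print.dwi_study <- function(x, ...) {
  d <- dim(x$low$data)
  cat(sprintf("dwi_study: b = %g / %g s/mm2, grid %d x %d x %d\n",
              x$b_low, x$b_high, d[1], d[2], d[3]))
  invisible(x)
}
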