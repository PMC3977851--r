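#' Write a volume to NIfTI
#'
#' Writes the intensity array with voxel spacing recorded in the header.
#' The default datatype is 64-bit float so that round trips are lossless
#' for any data R holds (and in particular for 32-bit float data).
#'
#' @param volume a `station_volume`, `wholebody_volume`, or plain numeric
#'   3-D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param geometry required when `volume` is a plain array.
#' @param datatype NIfTI datatype, `"double"` (default) or `"float"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, geometry = NULL, datatype = "double") {
  if (inherits(volume, c("station_volume", "wholebody_volume"))) {
    data <- volume$data
    geometry <- volume$geometry
  } else {
    data <- volume
    if (is.null(geometry)) stop("geometry is required for a plain array")
  }
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3-D array")
  if (any(!is.finite(data)))
    stop("volume contains non-finite values; refusing to write")
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- geometry$spacing_mm
  RNifti::writeNifti(img, path, datatype = datatype)
  if (!file.exists(path)) stop("failed to write ", path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file.
#' @param phase_encode_axis phase-encode axis for the returned geometry
#'   (not stored in standard NIfTI headers).
#' @return List with `data` (3-D array) and `geometry`.
#' @export
read_volume <- function(path, phase_encode_axis = "row") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  list(data = data,
       geometry = voxel_geometry(spacing, phase_encode_axis))
}

#' Read a study configuration file
#'
#' The config (YAML or JSON) declares `b_low`, `b_high`,
#' `phase_encode_axis`, and `stations`: a list, ordered superior to
#' inferior, each entry naming the per-b-value NIfTI files as `low` and
#' `high`. Relative paths are resolved against the config file directory.
#'
#' @param path config file.
#' @return Parsed config list with normalised absolute paths.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  for (key in c("b_low", "b_high", "stations"))
    if (is.null(cfg[[key]])) stop("config missing field: ", key)
  if (is.null(cfg$phase_encode_axis)) cfg$phase_encode_axis <- "row"
  cfg$b_low <- as.numeric(cfg$b_low)
  cfg$b_high <- as.numeric(cfg$b_high)
  if (!(cfg$b_high > cfg$b_low) || cfg$b_low < 0)
    stop("config requires b_high > b_low >= 0")
  base <- dirname(normalizePath(path))
  cfg$stations <- lapply(cfg$stations, function(st) {
    for (b in c("low", "high")) {
      if (is.null(st[[b]])) stop("each station needs 'low' and 'high' file paths")
      if (!grepl("^(/|[A-Za-z]:)", st[[b]])) st[[b]] <- file.path(base, st[[b]])
    }
    st
  })
  cfg
}

#' Read the per-station volumes of one study
#'
#' Loads every station at both b-values, ordered superior to inferior as
#' declared in the config, and checks that all stations of the study share
#' one in-plane matrix.
#'
#' @param config a config list from [read_study_config()] or a path to one.
#' @return List with elements `low` and `high`, each a list of
#'   [station_volume()] objects, plus `b_low`, `b_high`.
#' @export
read_station_series <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  out <- list(low = list(), high = list(),
              b_low = config$b_low, b_high = config$b_high)
  shape <- NULL
  for (s in seq_along(config$stations)) {
    st <- config$stations[[s]]
    for (b in c("low", "high")) {
      v <- read_volume(st[[b]], config$phase_encode_axis)
      inplane <- dim(v$data)[1:2]
      if (is.null(shape)) shape <- inplane
      if (!identical(inplane, shape))
        stop(sprintf(
          "inconsistent in-plane matrix at station %d (%s b): %d x %d, expected %d x %d",
          s, b, inplane[1], inplane[2], shape[1], shape[2]))
      bval <- if (b == "low") config$b_low else config$b_high
      out[[b]][[s]] <- station_volume(v$data, v$geometry, bval, s)
    }
  }
  out
}
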