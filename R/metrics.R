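#' Total diffusion volume (tDV)
#'
#' Voxel count of the included VOI components times the voxel volume, in
#' millilitres.
#'
#' @param voiset a `voi_set` (excluded components are not counted).
#' @param geometry a [voxel_geometry()].
#' @return tDV in ml.
#' @export
compute_tdv <- function(voiset, geometry) {
  sum(voi_mask(voiset)) * voxel_volume_ml(geometry)
}

#' Adjusted Fisher-Pearson sample skewness
#' @param x numeric vector, length >= 3, nonzero variance.
#' @return Skewness; `NA` with attribute `undefined = TRUE` when the
#'   distribution is degenerate.
#' @export
sample_skewness <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  if (n < 3 || m2 <= 0) return(structure(NA_real_, undefined = TRUE))
  g1 <- mean((x - mean(x))^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Bias-corrected excess (Fisher) kurtosis
#' @param x numeric vector, length >= 4, nonzero variance.
#' @return Excess kurtosis (0 for a normal distribution); `NA` with
#'   attribute `undefined = TRUE` when degenerate.
#' @export
sample_excess_kurtosis <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  if (n < 4 || m2 <= 0) return(structure(NA_real_, undefined = TRUE))
  g2 <- mean((x - mean(x))^4) / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

#' Global ADC (gADC) histogram statistics
#'
#' Pools the valid ADC values over all included VOI components into one
#' global distribution ("across all lesions") and summarises it: sample
#' median, unbiased sample variance, adjusted Fisher-Pearson skewness and
#' bias-corrected excess kurtosis, plus a fixed-bin histogram for display.
#' Statistics are computed on the raw pooled values, never on binned data.
#' The median is reported (rather than the mean) for robustness to the
#' positive skew typical of whole-body gADC distributions.
#'
#' @param adc_map an [compute_adc()] result.
#' @param voiset a `voi_set` on the same grid.
#' @param geometry a [voxel_geometry()] (for tDV bookkeeping).
#' @param breaks histogram bin edges in mm^2/s (default 100 bins over
#'   0 to 3.0e-3).
#' @return An object of class `tumor_metrics`: list with `tdv_ml`,
#'   `n_voxels`, `gadc_median`, `gadc_variance`, `gadc_skewness`,
#'   `gadc_kurtosis`, `skew_kurt_defined`, `histogram` (list of `breaks`,
#'   `counts`; out-of-range values are counted in the edge bins), and
#'   `per_lesion` (data.frame of per-component medians and counts,
#'   exported for completeness but not used in headline comparisons).
#' @export
gadc_statistics <- function(adc_map, voiset, geometry,
                            breaks = seq(0, 3e-3, length.out = 101)) {
  stopifnot(inherits(adc_map, "adc_map"), inherits(voiset, "voi_set"))
  if (!identical(dim(adc_map$values), dim(voiset$labels)))
    stop("adc_map and voiset grids differ")
  m <- voi_mask(voiset) & adc_map$valid
  vals <- adc_map$values[m]
  if (!length(vals)) stop("empty VOI: no included voxels with valid ADC")

  v <- if (length(vals) > 1) var(vals) else 0
  sk <- sample_skewness(vals)
  ku <- sample_excess_kurtosis(vals)
  clamped <- pmin(pmax(vals, breaks[1]), breaks[length(breaks)])
  counts <- hist(clamped, breaks = breaks, plot = FALSE)$counts

  ids <- as.integer(names(voiset$counts))
  ids <- setdiff(ids, voiset$excluded)
  per <- lapply(ids, function(id) {
    lv <- adc_map$values[voiset$labels == id & adc_map$valid]
    data.frame(id = id, n_voxels = length(lv),
               median_adc = if (length(lv)) median(lv) else NA_real_)
  })
  per <- do.call(rbind, per)

  structure(list(
    tdv_ml = compute_tdv(voiset, geometry),
    n_voxels = length(vals),
    gadc_median = median(vals),
    gadc_variance = v,
    gadc_skewness = as.numeric(sk),
    gadc_kurtosis = as.numeric(ku),
    skew_kurt_defined = !(isTRUE(attr(sk, "undefined")) ||
                          isTRUE(attr(ku, "undefined"))),
    histogram = list(breaks = breaks, counts = counts),
    per_lesion = per
  ), class = "tumor_metrics")
}

#' @export
print.tumor_metrics <- function(x, ...) {
  cat(sprintf("tumor_metrics: tDV = %.1f ml over %d voxels\n", x$tdv_ml,
              x$n_voxels))
  cat(sprintf("  gADC median %.3f, variance %.3f, skewness %.2f, kurtosis %.2f (x1e-3 mm2/s units)\n",
              x$gadc_median * 1e3, x$gadc_variance * 1e6,
              x$gadc_skewness, x$gadc_kurtosis))
  invisible(x)
}

#' Serialize tumor metrics to JSON
#' @param metrics a `tumor_metrics`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  out <- metrics[c("tdv_ml", "n_voxels", "gadc_median", "gadc_variance",
                   "gadc_skewness", "gadc_kurtosis", "skew_kurt_defined")]
  out$histogram <- metrics$histogram
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
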