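#' Voxelwise ADC from a two-b-value study
#'
#' Two-point log-ratio estimator under the monoexponential signal model
#' `S(b) = S(0) exp(-b * ADC)`:
#' `ADC = ln(S(b_low) / S(b_high)) / (b_high - b_low)`, in mm^2/s.
#' Voxels where either measured signal is <= 0 are marked invalid (the
#' estimator is undefined there). Negative ADC values (noise) are retained
#' but counted in `n_negative`; nothing is clamped.
#'
#' @param study a [dwi_study()].
#' @return An object of class `adc_map`: list with `values` (3-D array,
#'   `NA` at invalid voxels), `valid` (logical array), `n_negative`.
#' @examples
#' # S(50) = 100, S(900) = 100 * exp(-0.85) -> ADC = 1e-3 mm^2/s
#' @export
compute_adc <- function(study) {
  stopifnot(inherits(study, "dwi_study"))
  s_low <- study$low$data
  s_high <- study$high$data
  if (!identical(dim(s_low), dim(s_high))) stop("mismatched volume shapes")
  valid <- s_low > 0 & s_high > 0
  values <- array(NA_real_, dim = dim(s_low))
  values[valid] <- log(s_low[valid] / s_high[valid]) / (study$b_high - study$b_low)
  structure(list(values = values, valid = valid,
                 n_negative = sum(values[valid] < 0)),
            class = "adc_map")
}

#' Estimated b = 0 signal
#'
#' `S(0) = S(b_low) * exp(b_low * ADC)` on valid voxels; `NA` where the ADC
#' estimate is invalid.
#'
#' @param study a [dwi_study()].
#' @param adc_map the [compute_adc()] result for the same study.
#' @return 3-D array of S(0) estimates.
#' @export
compute_s0 <- function(study, adc_map) {
  stopifnot(inherits(study, "dwi_study"), inherits(adc_map, "adc_map"))
  if (!identical(dim(study$low$data), dim(adc_map$values)))
    stop("adc_map does not match study grid")
  s0 <- array(NA_real_, dim = dim(adc_map$values))
  v <- adc_map$valid
  s0[v] <- study$low$data[v] * exp(study$b_low * adc_map$values[v])
  s0
}

#' Computed DWI at an arbitrary b-value
#'
#' Extrapolates `S(b_c) = S(0) exp(-b_c * ADC)` voxelwise. Invalid voxels
#' are set to 0 so they cannot survive downstream thresholding.
#'
#' @param study a [dwi_study()].
#' @param adc_map the [compute_adc()] result for the same study.
#' @param computed_b virtual b-value in s/mm^2, >= 0.
#' @return An object of class `computed_dwi`: list with `values` (3-D
#'   array) and `computed_b`.
#' @export
compute_cdwi <- function(study, adc_map, computed_b) {
  if (!is.finite(computed_b) || computed_b < 0)
    stop("computed_b must be >= 0")
  s0 <- compute_s0(study, adc_map)
  values <- array(0, dim = dim(s0))
  v <- adc_map$valid
  values[v] <- s0[v] * exp(-computed_b * adc_map$values[v])
  structure(list(values = values, computed_b = as.numeric(computed_b)),
            class = "computed_dwi")
}

#' @export
print.adc_map <- function(x, ...) {
  cat(sprintf("adc_map: %s voxels, %d invalid, %d negative; median valid ADC %.3g mm2/s\n",
              paste(dim(x$values), collapse = " x "), sum(!x$valid),
              x$n_negative, median(x$values[x$valid])))
  invisible(x)
}
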