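#' Parameters of the two-class Gaussian/Potts MRF
#'
#' The smoothing model assigns each voxel to background (0) or disease (1)
#' by minimising
#' `E(l) = sum_p -log N(I_p; mu_lp, sd_lp) + beta * sum_(p~q) 1[l_p != l_q]`
#' over face (6) or full (26) neighbourhoods. `beta` is in units of
#' log-likelihood; `beta = 0` reduces to per-voxel maximum-likelihood
#' classification.
#'
#' @param mu0,mu1 class mean intensities (background, disease); `NULL` to
#'   estimate from the initial mask.
#' @param sd0,sd1 class standard deviations, > 0; `NULL` to estimate.
#' @param beta smoothness weight, >= 0 (default 1.5).
#' @param neighborhood 6 (faces, default) or 26.
#' @param max_iterations ICM sweep cap.
#' @param sd_floor lower bound substituted (with a warning) when a class is
#'   constant and its estimated sd is 0.
#' @return An object of class `mrf_params`.
#' @export
mrf_params <- function(mu0 = NULL, mu1 = NULL, sd0 = NULL, sd1 = NULL,
                       beta = 1.5, neighborhood = 6, max_iterations = 100,
                       sd_floor = 1e-6) {
  if (!is.finite(beta) || beta < 0) stop("beta must be >= 0")
  if (!neighborhood %in% c(6, 26)) stop("neighborhood must be 6 or 26")
  for (s in list(sd0, sd1)) if (!is.null(s) && s <= 0) stop("class sd must be > 0")
  structure(list(mu0 = mu0, mu1 = mu1, sd0 = sd0, sd1 = sd1, beta = beta,
                 neighborhood = as.integer(neighborhood),
                 max_iterations = as.integer(max_iterations),
                 sd_floor = sd_floor),
            class = "mrf_params")
}

fill_mrf_stats <- function(intensity, initial_mask, params) {
  est <- function(vals, which) {
    m <- mean(vals)
    s <- if (length(vals) > 1) sd(vals) else 0
    if (!is.finite(s) || s <= 0) {
      warning(sprintf("constant %s class: sd floored at %g", which,
                      params$sd_floor))
      s <- params$sd_floor
    }
    c(m, s)
  }
  if (is.null(params$mu0) || is.null(params$sd0)) {
    vals <- intensity[!initial_mask]
    if (!length(vals)) stop("initial mask leaves no background voxels")
    ms <- est(vals, "background")
    if (is.null(params$mu0)) params$mu0 <- ms[1]
    if (is.null(params$sd0)) params$sd0 <- ms[2]
  }
  if (is.null(params$mu1) || is.null(params$sd1)) {
    vals <- intensity[initial_mask]
    if (!length(vals)) stop("initial mask has no foreground voxels")
    ms <- est(vals, "foreground")
    if (is.null(params$mu1)) params$mu1 <- ms[1]
    if (is.null(params$sd1)) params$sd1 <- ms[2]
  }
  if (params$sd0 <= 0) params$sd0 <- params$sd_floor
  if (params$sd1 <= 0) params$sd1 <- params$sd_floor
  params
}

#' MRF smoothing of a segmentation
#'
#' Starts from the per-voxel maximum-likelihood classification under the
#' (estimated or supplied) class Gaussians and runs iterated conditional
#' modes (ICM) in raster order until no label flips or `max_iterations`
#' sweeps. ICM never increases the energy, so the result is a local
#' minimum of the Potts objective; with `beta = 0` it is the exact
#' per-voxel ML labeling. Class statistics default to the mean/sd of
#' voxels inside vs outside `initial_mask`.
#'
#' @param intensity numeric 3-D array (or `computed_dwi`) the model is fit
#'   on.
#' @param initial_mask logical array: the thresholded classification to be
#'   smoothed.
#' @param params an [mrf_params()].
#' @return Logical mask. Attributes: `sweeps`, `converged`, `params`
#'   (with estimated statistics filled in).
#' @export
mrf_smooth <- function(intensity, initial_mask, params = mrf_params()) {
  values <- volume_values(intensity)
  if (!identical(dim(values), dim(initial_mask)))
    stop("initial_mask does not match intensity grid")
  stopifnot(inherits(params, "mrf_params"))
  params <- fill_mrf_stats(values, initial_mask, params)
  # ML initialization, then ICM
  ml <- ml_classify(values, params)
  res <- icm_run_cpp(values, dim(values), ml, params$mu0, params$sd0,
                     params$mu1, params$sd1, params$beta,
                     params$neighborhood, params$max_iterations)
  out <- res$labels == 1L
  attr(out, "sweeps") <- res$sweeps
  attr(out, "converged") <- res$converged
  attr(out, "params") <- params
  out
}

ml_classify <- function(values, params) {
  l1 <- dnorm(values, params$mu1, params$sd1, log = TRUE) >
        dnorm(values, params$mu0, params$sd0, log = TRUE)
  out <- array(0L, dim = dim(values))
  out[l1] <- 1L
  out
}

#' Energy of a labeling under the MRF model
#'
#' @param intensity numeric 3-D array.
#' @param labels logical or 0/1 integer array.
#' @param params an [mrf_params()] with all class statistics set.
#' @return Scalar energy.
#' @export
mrf_energy <- function(intensity, labels, params) {
  values <- volume_values(intensity)
  lab <- array(as.integer(labels), dim = dim(values))
  if (is.null(params$mu0) || is.null(params$mu1) ||
      is.null(params$sd0) || is.null(params$sd1))
    stop("mrf_energy needs fully specified class statistics")
  potts_energy_cpp(values, dim(values), lab, params$mu0, params$sd0,
                   params$mu1, params$sd1, params$beta, params$neighborhood)
}
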