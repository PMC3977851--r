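#' Estimate the inter-station intensity gain
#'
#' Matches the cumulative intensity histograms of the two boundary slabs by
#' a quantile-quantile linear fit through the origin: the returned gain `g`
#' minimises `sum((q_a - g * q_b)^2)` over `n_quantiles` quantiles of the
#' nonzero voxels of each slab, so that scaling slab B by `g` equalises the
#' two cumulative histograms in the least-squares sense.
#'
#' @param slab_a,slab_b numeric arrays: the abutting slice slabs of two
#'   adjacent stations (A superior, B inferior), same in-plane shape.
#' @param n_quantiles number of quantiles for the fit, >= 8.
#' @return Positive scalar gain to apply to slab/station B.
#' @export
estimate_gain <- function(slab_a, slab_b, n_quantiles = 64) {
  if (n_quantiles < 8) stop("n_quantiles must be >= 8")
  a <- as.numeric(slab_a); a <- a[a > 0]
  b <- as.numeric(slab_b); b <- b[b > 0]
  if (!length(a) || !length(b))
    stop("degenerate boundary: all-zero slab")
  probs <- seq(0.5 / n_quantiles, 1 - 0.5 / n_quantiles, length.out = n_quantiles)
  qa <- quantile(a, probs, names = FALSE, type = 7)
  qb <- quantile(b, probs, names = FALSE, type = 7)
  g <- sum(qa * qb) / sum(qb * qb)
  if (!is.finite(g) || g <= 0) stop("degenerate boundary: gain not identifiable")
  g
}

#' Estimate the inter-station phase-encode shift
#'
#' Finds the integer displacement of slab B along the phase-encode axis
#' minimising the mean-square intensity difference to slab A over the
#' overlapping region. Each slab is first averaged over its slices; gain
#' should already have been applied to slab B. Ties are broken toward 0,
#' then toward the negative candidate.
#'
#' @param slab_a,slab_b numeric 3-D arrays (same in-plane shape).
#' @param geometry a [voxel_geometry()] giving the phase-encode axis.
#' @param search_radius maximum |shift| in voxels, >= 1.
#' @return Integer shift (the correction to apply to station B).
#' @export
estimate_shift <- function(slab_a, slab_b, geometry, search_radius = 5) {
  search_radius <- as.integer(search_radius)
  if (search_radius < 1) stop("search_radius must be >= 1")
  ma <- slab_mean(slab_a)
  mb <- slab_mean(slab_b)
  axis <- if (geometry$phase_encode_axis == "row") 1L else 2L
  if (search_radius >= dim(ma)[axis])
    stop("search_radius exceeds slab extent along the phase-encode axis")
  cand <- order(abs(-search_radius:search_radius),
                -(-search_radius:search_radius))  # 0, -1, 1, -2, 2, ...
  cand <- (-search_radius:search_radius)[cand]
  best <- NULL; best_mse <- Inf
  n <- dim(ma)[axis]
  for (s in cand) {
    # overlap of ma with mb shifted by s along the PE axis
    if (s >= 0) { ia <- (1 + s):n; ib <- 1:(n - s) } else { ia <- 1:(n + s); ib <- (1 - s):n }
    if (axis == 1L) {
      d <- ma[ia, , drop = FALSE] - mb[ib, , drop = FALSE]
    } else {
      d <- ma[, ia, drop = FALSE] - mb[, ib, drop = FALSE]
    }
    mse <- mean(d^2)
    if (mse < best_mse - 1e-12) { best_mse <- mse; best <- s }
  }
  as.integer(best)
}

slab_mean <- function(slab) {
  if (is.array(slab) && length(dim(slab)) == 3L) {
    apply(slab, c(1, 2), mean)
  } else if (is.matrix(slab)) {
    slab
  } else stop("slab must be a 2-D or 3-D array")
}

#' Shift a station along the phase-encode axis
#'
#' Integer-voxel translation with zero fill at the vacated edge.
#' @param data 3-D array.
#' @param shift integer shift in voxels (positive = toward higher index).
#' @param axis 1 (row) or 2 (column).
#' @return Shifted array of the same shape.
#' @export
shift_inplane <- function(data, shift, axis) {
  shift <- as.integer(shift)
  if (shift == 0L) return(data)
  out <- array(0, dim = dim(data))
  n <- dim(data)[axis]
  if (abs(shift) >= n) return(out)
  if (shift > 0) { dst <- (1 + shift):n; src <- 1:(n - shift) }
  else { dst <- 1:(n + shift); src <- (1 - shift):n }
  if (axis == 1L) out[dst, , ] <- data[src, , ] else out[, dst, ] <- data[, src, ]
  out
}

#' Fuse imaging stations into one whole-body volume
#'
#' Concatenates stations superior to inferior. Starting from the most
#' superior station as the fixed reference, each subsequent station is
#' scaled by the gain and translated by the phase-encode shift estimated
#' from the boundary slabs against its already-corrected superior
#' neighbour, then appended ("applied in turn"). Corrections estimated on
#' one b-value can be reused for the other b-value of the same study via
#' `corrections`, keeping ADC maps invariant under the joint scaling.
#'
#' @param stations list of [station_volume()] objects, superior first.
#' @param slab_slices boundary slab thickness per side (default 3 slices).
#' @param search_radius shift search radius in voxels.
#' @param corrections optional corrections (as returned in the result's
#'   `corrections` element) to apply instead of estimating.
#' @return A [wholebody_volume()]; its `corrections` attribute-like element
#'   is attached as `attr(x, "corrections")`: a data.frame with columns
#'   `station`, `gain`, `shift`.
#' @export
fuse_stations <- function(stations, slab_slices = 3, search_radius = 5,
                          corrections = NULL) {
  if (!length(stations)) stop("need at least one station")
  lapply(stations, function(s) stopifnot(inherits(s, "station_volume")))
  shapes <- vapply(stations, function(s) dim(s$data)[1:2], integer(2))
  if (length(stations) > 1 && any(shapes[1, ] != shapes[1, 1] | shapes[2, ] != shapes[2, 1]))
    stop("stations must share one in-plane shape")
  geom <- stations[[1]]$geometry
  axis <- if (geom$phase_encode_axis == "row") 1L else 2L
  b <- stations[[1]]$b_value

  n <- length(stations)
  gains <- rep(1, n); shifts <- rep(0L, n)
  corrected <- vector("list", n)
  corrected[[1]] <- stations[[1]]$data
  if (n > 1) {
    for (s in 2:n) {
      dat <- stations[[s]]$data
      if (!is.null(corrections)) {
        gains[s] <- corrections$gain[corrections$station == s]
        shifts[s] <- as.integer(corrections$shift[corrections$station == s])
      } else {
        prev <- corrected[[s - 1]]
        nz <- dim(prev)[3]
        k <- min(slab_slices, nz, dim(dat)[3])
        slab_a <- prev[, , (nz - k + 1):nz, drop = FALSE]
        slab_b <- dat[, , 1:k, drop = FALSE]
        gains[s] <- estimate_gain(slab_a, slab_b)
        shifts[s] <- estimate_shift(slab_a, slab_b * gains[s], geom, search_radius)
      }
      corrected[[s]] <- shift_inplane(dat * gains[s], shifts[s], axis)
    }
  }

  slices <- vapply(corrected, function(d) dim(d)[3], integer(1))
  fused <- array(0, dim = c(dim(corrected[[1]])[1:2], sum(slices)))
  at <- 1L
  for (s in seq_len(n)) {
    fused[, , at:(at + slices[s] - 1L)] <- corrected[[s]]
    at <- at + slices[s]
  }
  boundaries <- if (n > 1) cumsum(slices)[-n] + 1L else integer(0)
  out <- wholebody_volume(fused, geom, b, boundaries)
  attr(out, "corrections") <- data.frame(station = seq_len(n),
                                         gain = gains, shift = shifts)
  out
}
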