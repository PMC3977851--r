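#' Global intensity threshold
#'
#' Strict threshold on a computed-DWI (or any) volume: voxels with
#' intensity strictly greater than `tau` are kept. Mirrors the manual
#' threshold selection step of the segmentation workflow; no automatic
#' threshold estimation is attempted.
#'
#' @param x a `computed_dwi`, `wholebody_volume`, or numeric 3-D array.
#' @param tau threshold, >= 0.
#' @return Logical 3-D mask.
#' @export
threshold_volume <- function(x, tau) {
  if (!is.finite(tau) || tau < 0) stop("tau must be >= 0")
  values <- volume_values(x)
  m <- values > tau
  m[is.na(m)] <- FALSE
  m
}

volume_values <- function(x) {
  if (inherits(x, "computed_dwi")) x$values
  else if (inherits(x, c("wholebody_volume", "station_volume"))) x$data
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected a 3-D volume")
}

#' Build a seed map from labeled voxel sets
#'
#' @param dims volume dimensions (row, column, slice).
#' @param foreground,background integer matrices of (row, column, slice)
#'   voxel coordinates, or linear indices, seeding each class.
#' @return An object of class `seed_map`: integer label array (0
#'   unlabeled, 1 foreground, 2 background) plus initial strengths.
#' @export
seed_map <- function(dims, foreground = NULL, background = NULL) {
  labels <- array(0L, dim = dims)
  strengths <- array(0, dim = dims)
  idx <- function(coords) {
    if (is.matrix(coords)) {
      (coords[, 1] - 1) + dims[1] * ((coords[, 2] - 1) + dims[2] * (coords[, 3] - 1)) + 1
    } else as.integer(coords)
  }
  if (!is.null(foreground) && length(foreground)) {
    labels[idx(foreground)] <- 1L; strengths[idx(foreground)] <- 1
  }
  if (!is.null(background) && length(background)) {
    labels[idx(background)] <- 2L; strengths[idx(background)] <- 1
  }
  if (!any(labels > 0L)) stop("seed map has no seeds")
  structure(list(labels = labels, strengths = strengths), class = "seed_map")
}

#' 3-D GrowCut segmentation
#'
#' Seeded cellular-automaton segmentation: each labeled cell p carries a
#' strength theta_p in \[0, 1\] (seeds start at 1). At every synchronous
#' iteration each neighbour q (26-neighbourhood) attacks p, and p adopts
#' q's label when `g(|C_p - C_q|) * theta_q > theta_p`, where
#' `g(x) = 1 - x / max|C|` is monotonically decreasing with `g(0) = 1` and
#' C is the feature volume (here the computed-DWI intensity). Iteration
#' stops at the first sweep with no label change, or at `max_iters`.
#' Updates within one sweep are computed from the previous sweep's state,
#' and tie-breaks follow a fixed neighbour order, so results are fully
#' deterministic.
#'
#' @param feature numeric 3-D array (or `computed_dwi`) of per-voxel
#'   features.
#' @param seeds a [seed_map()].
#' @param max_iters iteration cap (default 500).
#' @return An object of class `growcut_state`: list with `labels` (0/1/2
#'   array), `strengths`, `iterations`, `converged`.
#' @export
growcut_3d <- function(feature, seeds, max_iters = 500) {
  values <- volume_values(feature)
  if (any(!is.finite(values))) stop("feature volume must be finite")
  stopifnot(inherits(seeds, "seed_map"))
  if (!identical(dim(values), dim(seeds$labels)))
    stop("seed map does not match feature dimensions")
  if (!any(seeds$labels > 0L)) stop("no seeds")
  res <- growcut_run_cpp(values, dim(values), seeds$labels, seeds$strengths,
                         as.integer(max_iters))
  structure(res, class = "growcut_state")
}

as_box <- function(box, dims) {
  # box: list(lo = c(i, j, k), hi = c(i, j, k)), 1-based inclusive
  lo <- as.integer(box$lo); hi <- as.integer(box$hi)
  if (length(lo) != 3L || length(hi) != 3L || any(lo < 1L) || any(hi > dims) ||
      any(lo > hi))
    stop("box must satisfy 1 <= lo <= hi <= dim")
  list(lo = lo, hi = hi)
}

#' Remove a structure from the disease mask with GrowCut
#'
#' Programmatic version of the box-seeded editing workflow used to delete
#' normal structures (e.g. the spleen) that survive thresholding: voxels
#' inside `fg_box` seed the foreground (the structure to remove), voxels on
#' the surface of `bg_box` seed the background, and GrowCut is run on the
#' feature volume restricted to the interior of `bg_box`. Every voxel the
#' automaton labels foreground is then removed from the disease mask.
#'
#' @param mask logical 3-D disease mask.
#' @param feature `computed_dwi` or numeric 3-D array (same grid).
#' @param fg_box,bg_box boxes as `list(lo = c(i, j, k), hi = c(i, j, k))`,
#'   1-based inclusive; `fg_box` must be strictly inside `bg_box`.
#' @param max_iters GrowCut iteration cap.
#' @return List with the edited `mask`, the `removed` logical array, and
#'   `n_removed`.
#' @export
remove_region_growcut <- function(mask, feature, fg_box, bg_box,
                                  max_iters = 500) {
  values <- volume_values(feature)
  dims <- dim(values)
  if (!identical(dim(mask), dims)) stop("mask does not match feature grid")
  fg <- as_box(fg_box, dims); bg <- as_box(bg_box, dims)
  if (!all(fg$lo > bg$lo) || !all(fg$hi < bg$hi))
    stop("fg_box must be strictly inside bg_box")

  sub <- values[bg$lo[1]:bg$hi[1], bg$lo[2]:bg$hi[2], bg$lo[3]:bg$hi[3],
                drop = FALSE]
  sd <- dim(sub)
  labels <- array(0L, dim = sd)
  # background: surface of bg_box
  labels[c(1, sd[1]), , ] <- 2L
  labels[, c(1, sd[2]), ] <- 2L
  labels[, , c(1, sd[3])] <- 2L
  # foreground: interior of fg_box (in sub coordinates)
  flo <- fg$lo - bg$lo + 1L; fhi <- fg$hi - bg$lo + 1L
  labels[flo[1]:fhi[1], flo[2]:fhi[2], flo[3]:fhi[3]] <- 1L
  strengths <- array(0, dim = sd)
  strengths[labels > 0L] <- 1
  seeds <- structure(list(labels = labels, strengths = strengths),
                     class = "seed_map")
  state <- growcut_3d(sub, seeds, max_iters)

  removed <- array(FALSE, dim = dims)
  removed[bg$lo[1]:bg$hi[1], bg$lo[2]:bg$hi[2], bg$lo[3]:bg$hi[3]] <-
    state$labels == 1L
  out <- mask & !removed
  list(mask = out, removed = removed & mask, n_removed = sum(removed & mask),
       growcut = state)
}
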