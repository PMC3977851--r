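#' Connected components of a disease mask
#'
#' 26-connectivity 3-D labeling. Component ids are assigned 1..k ordered
#' by decreasing voxel count, ties broken by first raster encounter
#' (linear array order), so runs are reproducible.
#'
#' @param mask logical 3-D array.
#' @return An object of class `voi_set`: list with `labels` (integer
#'   array, 0 background), `counts` (named integer vector, names = ids),
#'   `excluded` (integer vector of excluded ids).
#' @export
connected_components <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3-D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  mask[is.na(mask)] <- FALSE
  raw <- label_components_cpp(mask, dim(mask))
  k <- max(raw)
  if (k == 0L) {
    return(structure(list(labels = raw, counts = integer(0),
                          excluded = integer(0)), class = "voi_set"))
  }
  counts <- tabulate(raw[raw > 0L], nbins = k)
  # decreasing size; ties keep first-encounter order (raw ids are in
  # first-encounter order and sort() is stable)
  ord <- order(-counts)
  remap <- integer(k)
  remap[ord] <- seq_len(k)
  labels <- array(0L, dim = dim(mask))
  nz <- raw > 0L
  labels[nz] <- remap[raw[nz]]
  counts <- counts[ord]
  names(counts) <- seq_len(k)
  structure(list(labels = labels, counts = counts, excluded = integer(0)),
            class = "voi_set")
}

#' Included-voxel mask of a VOI set
#' @param voiset a `voi_set`.
#' @return Logical array of voxels in non-excluded components.
#' @export
voi_mask <- function(voiset) {
  stopifnot(inherits(voiset, "voi_set"))
  m <- voiset$labels > 0L
  if (length(voiset$excluded))
    m <- m & !(voiset$labels %in% voiset$excluded)
  array(m, dim = dim(voiset$labels))
}

#' Clear everything superior to a cutoff slice
#'
#' Removes all voxels in slices strictly superior to `cutoff_slice`
#' (slice 1 is most superior, so slices with index < `cutoff_slice` are
#' cleared and the cutoff slice itself is retained). Used to exclude the
#' head and neck (e.g. everything above the C4 vertebra) from analysis.
#' For a `voi_set`, component bookkeeping is recomputed.
#'
#' @param x logical mask or `voi_set`.
#' @param cutoff_slice 1-based slice index within range.
#' @return Same type as `x`.
#' @export
apply_superior_cutoff <- function(x, cutoff_slice) {
  is_voi <- inherits(x, "voi_set")
  dims <- if (is_voi) dim(x$labels) else dim(x)
  cutoff_slice <- as.integer(cutoff_slice)
  if (cutoff_slice < 1L || cutoff_slice > dims[3])
    stop("cutoff_slice out of range")
  if (is_voi) {
    m <- voi_mask(x)
    if (cutoff_slice > 1L) m[, , seq_len(cutoff_slice - 1L)] <- FALSE
    connected_components(m)
  } else {
    if (cutoff_slice > 1L) x[, , seq_len(cutoff_slice - 1L)] <- FALSE
    x
  }
}

#' Exclude VOIs from analysis
#'
#' Marks components as excluded (the programmatic analogue of a
#' radiologist deleting erroneous VOIs); excluded voxels are dropped from
#' every downstream metric. Exclusion is reversible via [include_vois()].
#'
#' @param voiset a `voi_set`.
#' @param ids component ids to exclude.
#' @return The updated `voi_set`.
#' @export
exclude_vois <- function(voiset, ids) {
  stopifnot(inherits(voiset, "voi_set"))
  ids <- as.integer(ids)
  valid <- as.integer(names(voiset$counts))
  bad <- setdiff(ids, valid)
  if (length(bad))
    stop(sprintf("unknown VOI id(s) %s; valid ids: %s",
                 paste(bad, collapse = ","), paste(valid, collapse = ",")))
  voiset$excluded <- sort(unique(c(voiset$excluded, ids)))
  voiset
}

#' Re-include previously excluded VOIs
#' @param voiset a `voi_set`.
#' @param ids component ids to re-include.
#' @return The updated `voi_set`.
#' @export
include_vois <- function(voiset, ids) {
  stopifnot(inherits(voiset, "voi_set"))
  voiset$excluded <- setdiff(voiset$excluded, as.integer(ids))
  voiset
}

#' @export
print.voi_set <- function(x, ...) {
  cat(sprintf("voi_set: %d components, %d voxels included, %d excluded ids\n",
              length(x$counts), sum(voi_mask(x)), length(x$excluded)))
  invisible(x)
}
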