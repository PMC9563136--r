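#' Euclidean distance transform of a mask
#'
#' Distance (mm) from every voxel center to the nearest `TRUE` voxel center
#' of `mask`, on an anisotropic regular grid. Exact (separable
#' lower-envelope algorithm), not a chamfer approximation. Voxels inside the
#' mask have distance 0.
#'
#' @param mask logical 3-D array with at least one `TRUE` voxel.
#' @param spacing per-axis voxel size, mm (length 1 or 3, order (z, y, x)).
#' @return numeric array of distances, mm, same shape as `mask`.
#' @export
distance_to_mask <- function(mask, spacing = 2.5) {
  if (!is.logical(mask) || !is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a logical 3-D array")
  if (!any(mask)) stop("`mask` is empty: distances are undefined")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  .edt3d_cpp(mask, dim(mask), spacing)
}

#' Expand a mask by a Euclidean margin
#'
#' Isotropic 3-D expansion: a voxel belongs to the expanded mask iff its
#' center lies within Euclidean distance `margin` (mm) of some original
#' voxel center. `margin = 0` returns the mask unchanged. This is the
#' distance-transform dilation used to build PTV + 5 mm / PTV + 15 mm
#' conformity rings.
#'
#' @param mask logical 3-D array.
#' @param margin expansion margin, mm (>= 0).
#' @param spacing per-axis voxel size, mm.
#' @return logical array, a superset of `mask`, monotone in `margin`.
#' @export
expand_mask <- function(mask, margin, spacing = 2.5) {
  if (!is.numeric(margin) || length(margin) != 1L || is.na(margin) ||
      margin < 0)
    stop("`margin` must be a single non-negative length in mm")
  if (margin == 0) return(mask)
  d <- distance_to_mask(mask, spacing)
  # tolerance absorbs sqrt() round-off for voxels exactly on the ball surface
  out <- d <= margin + 1e-9
  dim(out) <- dim(mask)
  out
}
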