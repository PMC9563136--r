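# Cumulative DVH and dose-volume indices.
#
# Full-voxel convention throughout: no partial volumes, no interpolation.
# Dx is the minimum dose received by the hottest x% of the structure
# (descending sort, element ceil(x/100 * N)); Vx counts voxels with dose >=
# threshold (inclusive). Indices are computed from the raw voxel doses, not
# from a binned curve, so they are exact against a sort/count oracle.

# Accept a dose_grid or a bare array and return in-mask voxel doses.
mask_doses <- function(dose, mask) {
  values <- if (inherits(dose, "dose_grid")) dose$values else dose
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`dose` must be a dose_grid or a 3-D array")
  if (!is.logical(mask) || !identical(dim(mask), dim(values)))
    stop("mask is not congruent with the dose grid")
  if (!any(mask)) stop("structure mask is empty")
  values[mask]
}

#' Cumulative dose-volume histogram
#'
#' Fraction of structure volume receiving at least each dose level, on a
#' regular grid of dose edges from 0 to just above the in-mask maximum.
#'
#' @param dose a [dose_grid()] or 3-D dose array, cGy.
#' @param mask logical mask congruent with `dose`, at least one voxel.
#' @param bin_width dose-edge step, cGy (> 0).
#' @param structure_name label stored on the curve.
#' @return a `dvh_curve`: list with `dose_edges` (cGy), `volume_fraction`
#'   (non-increasing, starts at 1, ends at 0), `structure_name`,
#'   `voxel_count`.
#' @export
cumulative_dvh <- function(dose, mask, bin_width = 10,
                           structure_name = "structure") {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("bin_width must be a single positive dose in cGy")
  doses <- sort(mask_doses(dose, mask))
  n <- length(doses)
  edges <- seq(0, (floor(max(doses) / bin_width) + 1) * bin_width,
               by = bin_width)
  # voxels >= edge = n - (voxels strictly below edge)
  below <- findInterval(edges, doses, left.open = TRUE)
  structure(list(dose_edges = edges,
                 volume_fraction = 1 - below / n,
                 structure_name = structure_name,
                 voxel_count = n),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s: %d voxels, %d edges to %.0f cGy\n",
              x$structure_name, x$voxel_count, length(x$dose_edges),
              max(x$dose_edges)))
  invisible(x)
}

#' Dose to the hottest x% of a structure (Dx)
#'
#' `dose_at_volume(dose, mask, 2)` is D2, `..., 95)` is D95. With voxel
#' doses sorted descending, returns element `ceiling(x/100 * N)`: the
#' minimum dose received by the hottest x% of the structure volume.
#'
#' @inheritParams cumulative_dvh
#' @param x percent of volume, in (0, 100].
#' @return dose, cGy.
#' @export
dose_at_volume <- function(dose, mask, x) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x > 100)
    stop("`x` must be a single percentage in (0, 100]")
  doses <- sort(mask_doses(dose, mask), decreasing = TRUE)
  doses[ceiling(x / 100 * length(doses))]
}

#' Percent of structure volume at or above a dose (Vx)
#'
#' `volume_at_dose(dose, mask, 4500)` is V45Gy in percent. The threshold is
#' inclusive (dose >= threshold counts).
#'
#' @inheritParams cumulative_dvh
#' @param threshold dose threshold, cGy (>= 0).
#' @return percent of structure volume, in \[0, 100\].
#' @export
volume_at_dose <- function(dose, mask, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0)
    stop("`threshold` must be a single non-negative dose in cGy")
  doses <- mask_doses(dose, mask)
  100 * sum(doses >= threshold) / length(doses)
}

#' Mean and maximum structure dose
#'
#' @inheritParams cumulative_dvh
#' @return named numeric vector `c(mean = , max = )`, cGy.
#' @export
mean_max_dose <- function(dose, mask) {
  doses <- mask_doses(dose, mask)
  c(mean = mean(doses), max = max(doses))
}
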