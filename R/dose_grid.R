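#' Absorbed-dose grid
#'
#' A 3-D scalar field of absorbed dose on a regular grid. Axes are ordered
#' (z, y, x); the world position of the voxel with (0-based) index
#' `(i, j, k)` is `origin + c(i, j, k) * spacing` (voxel centers). Doses are
#' carried in cGy throughout; conversion to Gy happens only when reporting.
#'
#' @param values 3-D numeric array of dose, cGy; all values finite and >= 0.
#' @param spacing per-axis voxel size in mm, length 1 (isotropic) or 3.
#' @param origin world coordinate (mm) of voxel (0, 0, 0), length 3.
#' @return A `dose_grid` object (list with `values`, `spacing`, `origin`).
#' @export
dose_grid <- function(values, spacing = 2.5, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array ordered (z, y, x)")
  if (anyNA(values) || any(!is.finite(values)))
    stop("dose values must be finite")
  if (any(values < 0))
    stop("dose values must be >= 0")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s voxels @ %s mm, dose %.1f-%.1f cGy\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Named set of structure masks
#'
#' Boolean masks congruent with a dose grid, one per region of interest.
#' The seven required structures of a pelvis plan must be present:
#' PTV, CTV, bladder, femur_head_L, femur_head_R, small_bowel, body.
#' Extra (derived) structures such as conformity rings are allowed.
#'
#' Enforced invariants: all masks share one shape; CTV is contained in PTV;
#' PTV and every other non-body structure are contained in the body; the PTV
#' is non-empty.
#'
#' @param masks named list of logical 3-D arrays, axes (z, y, x).
#' @param spacing per-axis voxel size, mm.
#' @param origin world coordinate of voxel (0, 0, 0), mm.
#' @return A `structure_set` object.
#' @export
structure_set <- function(masks, spacing = 2.5, origin = c(0, 0, 0)) {
  if (!is.list(masks) || is.null(names(masks)) || any(names(masks) == ""))
    stop("`masks` must be a named list of logical arrays")
  missing <- setdiff(REQUIRED_STRUCTURES, names(masks))
  if (length(missing))
    stop("missing required structures: ", paste(missing, collapse = ", "))
  shp <- dim(masks[[1L]])
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m) || !is.array(m) || length(dim(m)) != 3L)
      stop("mask '", nm, "' must be a logical 3-D array")
    if (!identical(dim(m), shp))
      stop("mask '", nm, "' shape differs from the others")
    if (anyNA(m)) stop("mask '", nm, "' contains NA")
  }
  if (!any(masks$PTV)) stop("PTV mask is empty")
  body <- masks$body
  if (any(masks$PTV & !body)) stop("PTV must be contained in body")
  if (any(masks$CTV & !masks$PTV)) stop("CTV must be contained in PTV")
  for (nm in setdiff(names(masks), "body"))
    if (any(masks[[nm]] & !body))
      stop("structure '", nm, "' must be contained in body")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  structure(list(masks = masks, spacing = spacing,
                 origin = rep_len(as.numeric(origin), 3L)),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  vol <- vapply(x$masks, sum, numeric(1))
  cat(sprintf("<structure_set> %s voxels @ %s mm\n",
              paste(dim(x$masks[[1L]]), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  for (nm in names(vol)) cat(sprintf("  %-14s %d voxels\n", nm, as.integer(vol[nm])))
  invisible(x)
}

#' Treatment plan
#'
#' Binds a dose grid, a structure set, a prescription and the planning
#' strategy that produced the dose.
#'
#' @param dose a [dose_grid()].
#' @param structures a [structure_set()] congruent with `dose`.
#' @param prescription prescription dose, cGy (> 0).
#' @param fractions number of fractions.
#' @param strategy_label one of `"manual"`, `"script_easy"`,
#'   `"script_moderate"`, `"script_hard"`, `"hybrid_easy"`,
#'   `"hybrid_moderate"`, `"hybrid_hard"`.
#' @param patient_id optional patient identifier.
#' @return A `plan` object.
#' @export
plan <- function(dose, structures, prescription = 5000, fractions = 25,
                 strategy_label = "manual", patient_id = NA_character_) {
  stopifnot(inherits(dose, "dose_grid"), inherits(structures, "structure_set"))
  if (!identical(dim(dose$values), dim(structures$masks[[1L]])))
    stop("dose grid and structure masks are not congruent")
  if (!is.numeric(prescription) || length(prescription) != 1L ||
      prescription <= 0)
    stop("prescription must be a single positive dose in cGy")
  if (!strategy_label %in% STRATEGY_LABELS)
    stop("unknown strategy_label '", strategy_label, "'; valid labels: ",
         paste(STRATEGY_LABELS, collapse = ", "))
  structure(list(dose = dose, structures = structures,
                 prescription = prescription, fractions = fractions,
                 strategy_label = strategy_label,
                 patient_id = patient_id),
            class = "plan")
}

#' @export
print.plan <- function(x, ...) {
  cat(sprintf("<plan> %s, Rx %.0f cGy / %d fx, patient %s\n",
              x$strategy_label, x$prescription, x$fractions,
              ifelse(is.na(x$patient_id), "?", x$patient_id)))
  invisible(x)
}
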