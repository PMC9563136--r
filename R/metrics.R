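# Plan-level indices and the evaluation panel.

#' Conformity index (Paddick-style)
#'
#' `CI = (TV_RI / TV) * (TV_RI / V_RI)` where TV is the target volume, V_RI
#' the reference-isodose volume and TV_RI the target volume covered by the
#' reference isodose. CI = 1 means the reference isodose conforms exactly to
#' the target. The reference isodose defaults to 95% of the prescription
#' (4750 cGy at 5000 cGy); whether "the 95% prescription isodose" means that
#' surface or the full prescription surface is a reading choice, so the
#' reference dose is an explicit argument. V_RI is counted inside the body
#' contour when one is supplied (dose outside the patient is non-physical).
#'
#' @param dose a [dose_grid()] or 3-D dose array, cGy.
#' @param ptv_mask logical PTV mask, non-empty.
#' @param reference_dose reference isodose level, cGy (> 0).
#' @param body_mask optional logical body mask restricting V_RI.
#' @return a `conformity_result`: list with voxel counts `tv`, `v_ri`,
#'   `tv_ri`, the index `ci` in \[0, 1\] and a `degenerate` flag (TRUE with
#'   a warning when V_RI is empty, in which case `ci = 0`).
#' @export
conformity_index <- function(dose, ptv_mask, reference_dose,
                             body_mask = NULL) {
  if (!is.numeric(reference_dose) || length(reference_dose) != 1L ||
      reference_dose <= 0)
    stop("reference_dose must be a single positive dose in cGy")
  values <- if (inherits(dose, "dose_grid")) dose$values else dose
  if (!is.logical(ptv_mask) || !identical(dim(ptv_mask), dim(values)))
    stop("PTV mask is not congruent with the dose grid")
  if (!any(ptv_mask)) stop("PTV mask is empty")
  iso <- values >= reference_dose
  if (!is.null(body_mask)) iso <- iso & body_mask
  tv <- sum(ptv_mask)
  v_ri <- sum(iso)
  tv_ri <- sum(iso & ptv_mask)
  degenerate <- v_ri == 0L
  if (degenerate)
    warning("reference isodose volume is empty; CI set to 0", call. = FALSE)
  ci <- if (degenerate) 0 else (tv_ri / tv) * (tv_ri / v_ri)
  structure(list(tv = tv, v_ri = v_ri, tv_ri = tv_ri, ci = ci,
                 degenerate = degenerate),
            class = "conformity_result")
}

#' Homogeneity index
#'
#' `HI = (D2 - D98) / prescription`; 0 means a perfectly uniform target
#' dose, larger values mean a less homogeneous one.
#'
#' @param d2 dose to the hottest 2% of the PTV, cGy.
#' @param d98 dose to the hottest 98% of the PTV, cGy (<= d2).
#' @param prescription prescription dose, cGy (> 0).
#' @return dimensionless index >= 0.
#' @export
homogeneity_index <- function(d2, d98, prescription) {
  if (prescription <= 0) stop("prescription must be > 0")
  if (d2 < d98) stop("D2 must be >= D98")
  (d2 - d98) / prescription
}

# (structure, index) -> metric panel column name; CI and HI are plan-level.
metric_column <- function(roi, index) {
  ifelse(index %in% c("CI", "HI"), index, paste(roi, index, sep = "_"))
}

#' Dose-metric panel of a plan
#'
#' Computes every index used in the cohort comparison: bladder D15, D50,
#' Dmean, Dmax; femoral head D25, D40, V10Gy (each side); small bowel V45Gy,
#' V15Gy; PTV D2, D5, D95, D98, Dmax; CI; HI. Doses in cGy, volumes in
#' percent. A missing structure yields NA for its fields (with a warning),
#' not an abort.
#'
#' @param plan a [plan()].
#' @param reference_fraction the CI reference isodose as a fraction of the
#'   prescription (default 0.95; set 1 for the full prescription surface).
#' @return one-row data.frame keyed by `patient_id` and `strategy_label`.
#' @export
metric_panel <- function(plan, reference_fraction = 0.95) {
  stopifnot(inherits(plan, "plan"))
  dose <- plan$dose
  masks <- plan$structures$masks
  get_mask <- function(nm) {
    m <- masks[[nm]]
    if (is.null(m) || !any(m)) {
      warning("structure '", nm, "' missing or empty; its metrics are NA",
              call. = FALSE)
      return(NULL)
    }
    m
  }
  dx <- function(nm, x) {
    m <- get_mask(nm); if (is.null(m)) NA_real_ else dose_at_volume(dose, m, x)
  }
  vx <- function(nm, thr) {
    m <- get_mask(nm); if (is.null(m)) NA_real_ else volume_at_dose(dose, m, thr)
  }
  mm <- function(nm) {
    m <- get_mask(nm)
    if (is.null(m)) c(mean = NA_real_, max = NA_real_) else mean_max_dose(dose, m)
  }

  ptv <- masks$PTV
  bl <- mm("bladder")
  ptv_mm <- mm("PTV")
  d2 <- dx("PTV", 2); d98 <- dx("PTV", 98)
  ci <- if (is.null(ptv) || !any(ptv)) NA_real_ else
    conformity_index(dose, ptv, reference_fraction * plan$prescription,
                     masks$body)$ci
  hi <- if (is.na(d2) || is.na(d98)) NA_real_ else
    homogeneity_index(d2, d98, plan$prescription)

  data.frame(
    patient_id = plan$patient_id,
    strategy_label = plan$strategy_label,
    prescription = plan$prescription,
    PTV_D2 = d2, PTV_D5 = dx("PTV", 5), PTV_D95 = dx("PTV", 95),
    PTV_D98 = d98, PTV_Dmax = ptv_mm[["max"]],
    bladder_D15 = dx("bladder", 15), bladder_D50 = dx("bladder", 50),
    bladder_Dmean = bl[["mean"]], bladder_Dmax = bl[["max"]],
    femur_head_L_D25 = dx("femur_head_L", 25),
    femur_head_L_D40 = dx("femur_head_L", 40),
    femur_head_L_V10 = vx("femur_head_L", 1000),
    femur_head_R_D25 = dx("femur_head_R", 25),
    femur_head_R_D40 = dx("femur_head_R", 40),
    femur_head_R_V10 = vx("femur_head_R", 1000),
    small_bowel_V45 = vx("small_bowel", 4500),
    small_bowel_V15 = vx("small_bowel", 1500),
    CI = ci, HI = hi,
    stringsAsFactors = FALSE)
}

#' Evaluate a goal set against a plan
#'
#' Per goal: the achieved dose-volume index, the goal limit, and pass/fail.
#' The prescription goal passes when PTV D95 >= limit (inclusive); all other
#' goals are strict upper bounds as printed ("<"), so a tie at the limit
#' fails. Goals on structures absent from the plan are flagged unevaluable.
#'
#' @param plan a [plan()].
#' @param goals a [clinical_goal_set()] or list of [clinical_goal()]s.
#' @return data.frame: structure, kind, x_or_threshold, role, limit,
#'   achieved, pass, evaluable.
#' @export
evaluate_goals <- function(plan, goals) {
  stopifnot(inherits(plan, "plan"))
  gl <- if (inherits(goals, "clinical_goal_set")) goals$goals else goals
  rows <- lapply(gl, function(g) {
    achieved <- achieved_value(g, plan$dose, plan$structures)
    evaluable <- !is.na(achieved)
    pass <- if (!evaluable) NA else if (g$kind == "prescription_D95")
      achieved >= g$limit else achieved < g$limit
    data.frame(structure = g$structure, kind = g$kind,
               x_or_threshold = g$x_or_threshold, role = g$role,
               limit = g$limit, achieved = achieved, pass = pass,
               evaluable = evaluable, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
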