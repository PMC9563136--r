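# Clinical goals: Table-style presets at three difficulty levels, the
# prediction-driven goal update of the hybrid workflow, auxiliary
# conformity-ring goals and the additional organ-at-risk goals.

GOAL_KINDS <- c("prescription_D95", "max_dose", "mean_dose",
                "dose_at_volume", "volume_at_dose")
GOAL_ROLES <- c("target", "oar", "auxiliary")

#' A single clinical goal
#'
#' @param structure structure name the goal applies to.
#' @param kind one of `"prescription_D95"` (PTV D95 >= limit), `"max_dose"`,
#'   `"mean_dose"`, `"dose_at_volume"` (Dx < limit) or `"volume_at_dose"`
#'   (Vx < limit).
#' @param limit goal value: cGy for dose goals, percent for
#'   `volume_at_dose`; must be > 0.
#' @param x_or_threshold percent x for `dose_at_volume`, dose threshold
#'   (cGy) for `volume_at_dose`; NA otherwise.
#' @param role `"target"` (kept fixed by the hybrid update), `"oar"`
#'   (replaced by the predicted value) or `"auxiliary"` (ring goals, kept
#'   fixed).
#' @return a `clinical_goal` object.
#' @export
clinical_goal <- function(structure, kind, limit, x_or_threshold = NA,
                          role = "oar") {
  kind <- match.arg(kind, GOAL_KINDS)
  role <- match.arg(role, GOAL_ROLES)
  if (!is.numeric(limit) || length(limit) != 1L || is.na(limit) || limit <= 0)
    stop("goal limit must be a single positive number")
  needs_x <- kind %in% c("dose_at_volume", "volume_at_dose")
  if (needs_x && (is.na(x_or_threshold) || x_or_threshold < 0))
    stop("kind '", kind, "' requires a non-negative x_or_threshold")
  if (!needs_x) x_or_threshold <- NA_real_
  structure(list(structure = structure, kind = kind,
                 x_or_threshold = as.numeric(x_or_threshold),
                 limit = as.numeric(limit), role = role),
            class = "clinical_goal")
}

#' An ordered set of clinical goals
#'
#' @param goals list of [clinical_goal()] objects containing exactly one
#'   prescription goal and no duplicate (structure, kind, x_or_threshold)
#'   entries.
#' @param level_label `"easy"`, `"moderate"`, `"hard"` or `"custom"`.
#' @return a `clinical_goal_set` object.
#' @export
clinical_goal_set <- function(goals, level_label = "custom") {
  if (!length(goals) || !all(vapply(goals, inherits, logical(1),
                                    "clinical_goal")))
    stop("`goals` must be a non-empty list of clinical_goal objects")
  if (!level_label %in% c("easy", "moderate", "hard", "custom"))
    stop("level_label must be easy, moderate, hard or custom")
  n_rx <- sum(vapply(goals, function(g) g$kind == "prescription_D95",
                     logical(1)))
  if (n_rx != 1L)
    stop("a goal set must contain exactly one prescription goal (found ",
         n_rx, ")")
  keys <- vapply(goals, function(g)
    paste(g$structure, g$kind, g$x_or_threshold, sep = "|"), character(1))
  if (anyDuplicated(keys))
    stop("duplicate goal entries: ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "))
  structure(list(goals = goals, level_label = level_label),
            class = "clinical_goal_set")
}

#' @export
print.clinical_goal_set <- function(x, ...) {
  cat(sprintf("<clinical_goal_set> level '%s', %d goals\n",
              x$level_label, length(x$goals)))
  print(goals_as_data_frame(x))
  invisible(x)
}

#' Goal set as a data frame
#'
#' @param goals a `clinical_goal_set` or list of [clinical_goal()]s.
#' @return data.frame with one row per goal.
#' @export
goals_as_data_frame <- function(goals) {
  gl <- if (inherits(goals, "clinical_goal_set")) goals$goals else goals
  data.frame(structure = vapply(gl, `[[`, character(1), "structure"),
             kind = vapply(gl, `[[`, character(1), "kind"),
             x_or_threshold = vapply(gl, `[[`, numeric(1), "x_or_threshold"),
             limit = vapply(gl, `[[`, numeric(1), "limit"),
             role = vapply(gl, `[[`, character(1), "role"),
             stringsAsFactors = FALSE)
}

#' Append goals to a goal set
#'
#' @param set a [clinical_goal_set()].
#' @param goals list of [clinical_goal()]s to append.
#' @return the extended [clinical_goal_set()].
#' @export
add_goals <- function(set, goals) {
  stopifnot(inherits(set, "clinical_goal_set"))
  clinical_goal_set(c(set$goals, goals), set$level_label)
}

#' Preset clinical goals at three difficulty levels
#'
#' The three goal settings used to probe planning robustness. All levels
#' prescribe D95 = 5000 cGy to the PTV; they differ in the PTV maximum dose
#' (5250 / 5100 / 5500 cGy for moderate / hard / easy) and in the mean-dose
#' goals for the bladder (4000 / 2000 / 4500 cGy) and each femoral head
#' (1800 / 900 / 2700 cGy). The hard setting demands a tighter PTV maximum
#' and stricter organ sparing; the easy setting is the opposite.
#'
#' @param level `"easy"`, `"moderate"` or `"hard"`.
#' @return a [clinical_goal_set()].
#' @export
preset_goals <- function(level = c("moderate", "hard", "easy")) {
  level <- match.arg(level)
  lim <- switch(level,
    moderate = c(ptv_max = 5250, bladder = 4000, femur = 1800),
    hard     = c(ptv_max = 5100, bladder = 2000, femur = 900),
    easy     = c(ptv_max = 5500, bladder = 4500, femur = 2700))
  clinical_goal_set(list(
    clinical_goal("PTV", "prescription_D95", 5000, role = "target"),
    clinical_goal("PTV", "max_dose", lim[["ptv_max"]], role = "target"),
    clinical_goal("bladder", "mean_dose", lim[["bladder"]], role = "oar"),
    clinical_goal("femur_head_L", "mean_dose", lim[["femur"]], role = "oar"),
    clinical_goal("femur_head_R", "mean_dose", lim[["femur"]], role = "oar")
  ), level_label = level)
}

# Evaluate the dose-volume index a goal constrains, on an arbitrary dose.
achieved_value <- function(goal, dose, structures) {
  mask <- structures$masks[[goal$structure]]
  if (is.null(mask) || !any(mask)) return(NA_real_)
  switch(goal$kind,
         prescription_D95 = dose_at_volume(dose, mask, 95),
         max_dose = mean_max_dose(dose, mask)[["max"]],
         mean_dose = mean_max_dose(dose, mask)[["mean"]],
         dose_at_volume = dose_at_volume(dose, mask, goal$x_or_threshold),
         volume_at_dose = volume_at_dose(dose, mask, goal$x_or_threshold))
}

#' Update organ-at-risk goals from a predicted dose
#'
#' The goal-personalisation step of the hybrid workflow: every goal with
#' role `"oar"` has its limit replaced by the same dose-volume index
#' evaluated on the predicted achievable dose; target and auxiliary goals
#' are returned unchanged. Replacement is unconditional by default, so a
#' goal may be loosened when the prediction says the preset is unachievable
#' (e.g. a bladder largely overlapping the PTV); `mode = "tighten_only"`
#' keeps the stricter of preset and prediction instead. The updated set is
#' labelled `"custom"`. Idempotent for a fixed predicted dose. Goal count,
#' order, structures, kinds and roles are never altered.
#'
#' @param goals a [clinical_goal_set()].
#' @param predicted predicted dose, a [dose_grid()] congruent with
#'   `structures` (see [predict_dose()]).
#' @param structures the [structure_set()] the goals refer to.
#' @param mode `"replace"` (unconditional) or `"tighten_only"`.
#' @return a [clinical_goal_set()] with level label `"custom"`.
#' @export
update_goals <- function(goals, predicted, structures,
                         mode = c("replace", "tighten_only")) {
  stopifnot(inherits(goals, "clinical_goal_set"),
            inherits(structures, "structure_set"))
  mode <- match.arg(mode)
  values <- if (inherits(predicted, "dose_grid")) predicted$values else predicted
  if (!identical(dim(values), dim(structures$masks[[1L]])))
    stop("predicted dose is not congruent with the structure set")
  updated <- lapply(goals$goals, function(g) {
    if (g$role != "oar") return(g)
    if (is.null(structures$masks[[g$structure]])) {
      warning("goal on absent structure '", g$structure,
              "' left unchanged", call. = FALSE)
      return(g)
    }
    pred <- achieved_value(g, predicted, structures)
    g$limit <- if (mode == "tighten_only") min(g$limit, pred) else pred
    g
  })
  clinical_goal_set(updated, "custom")
}

#' Auxiliary conformity-ring goals
#'
#' Derives two ring structures -- body minus (PTV + 5 mm) and body minus
#' (PTV + 15 mm), Euclidean expansions -- and returns max-dose goals of
#' 4200 and 3000 cGy on them. These auxiliary goals shape the dose falloff
#' around the target and improve conformity.
#'
#' @param structures a [structure_set()] containing PTV and body.
#' @return list with `goals` (two auxiliary [clinical_goal()]s) and
#'   `structures` (the input set augmented with masks `ring_5mm` and
#'   `ring_15mm`). An expansion that swallows the whole body yields an
#'   empty-ring warning and no goal for that ring.
#' @export
ring_goals <- function(structures) {
  stopifnot(inherits(structures, "structure_set"))
  ptv <- structures$masks$PTV
  body <- structures$masks$body
  rings <- list(ring_5mm = 5, ring_15mm = 15)
  limits <- c(ring_5mm = 4200, ring_15mm = 3000)
  goals <- list()
  for (nm in names(rings)) {
    ring <- body & !expand_mask(ptv, rings[[nm]], structures$spacing)
    if (!any(ring)) {
      # goal still returned; with no mask registered it evaluates as
      # unevaluable downstream
      warning("ring '", nm, "' is empty (expansion swallows the body); ",
              "goal unevaluable", call. = FALSE)
    } else {
      structures$masks[[nm]] <- ring
    }
    goals[[nm]] <- clinical_goal(nm, "max_dose", limits[[nm]],
                                 role = "auxiliary")
  }
  list(goals = unname(goals), structures = structures)
}

#' Additional organ-at-risk clinical goals
#'
#' The five added goals (limits taken from the manual-plan statistics):
#' small bowel V45Gy < 5% and V15Gy < 30%, V10Gy < 75% for each femoral
#' head, and bladder maximum dose < 5250 cGy (52.50 Gy).
#'
#' @return list of five [clinical_goal()]s with role `"oar"`.
#' @export
additional_goals <- function() {
  list(
    clinical_goal("small_bowel", "volume_at_dose", 5, 4500, role = "oar"),
    clinical_goal("small_bowel", "volume_at_dose", 30, 1500, role = "oar"),
    clinical_goal("femur_head_L", "volume_at_dose", 75, 1000, role = "oar"),
    clinical_goal("femur_head_R", "volume_at_dose", 75, 1000, role = "oar"),
    clinical_goal("bladder", "max_dose", 5250, role = "oar")
  )
}

#' Read / write goal sets as JSON
#'
#' Goal sets serialise to an editable JSON document (fields: level_label and
#' a goal table).
#'
#' @param set a [clinical_goal_set()].
#' @param path file path.
#' @return `write_goals` returns `path` invisibly; `read_goals` returns a
#'   [clinical_goal_set()].
#' @export
write_goals <- function(set, path) {
  stopifnot(inherits(set, "clinical_goal_set"))
  jsonlite::write_json(list(level_label = set$level_label,
                            goals = goals_as_data_frame(set)),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_goals
#' @export
read_goals <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- doc$goals
  goals <- lapply(seq_len(nrow(g)), function(i)
    clinical_goal(g$structure[i], g$kind[i], g$limit[i],
                  if (is.null(g$x_or_threshold[i])) NA else g$x_or_threshold[i],
                  g$role[i]))
  clinical_goal_set(goals, doc$level_label)
}
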