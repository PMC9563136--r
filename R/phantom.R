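# Synthetic pelvis phantom and strategy-dependent dose models.
#
# Geometry is sized relative to the physical grid extent so any grid of at
# least 40 voxels per axis at 2.5 mm contains all structures; the default
# 80^3 grid at 2.5 mm gives a ~200 mm pelvis-like cross-section. Axis
# convention: (z, y, x) with +z superior and +y anterior.

# Ellipsoid membership mask from per-axis center and semi-axes (mm).
ellipsoid_mask <- function(shape, spacing, center, semi) {
  ax <- lapply(1:3, function(a) {
    pos <- (seq_len(shape[a]) - 1) * spacing[a]
    ((pos - center[a]) / semi[a])^2
  })
  m <- outer(outer(ax[[1L]], ax[[2L]], "+"), ax[[3L]], "+") <= 1
  dim(m) <- shape
  m
}

# Erode by one voxel shell (6-connected): keep voxels whose face neighbours
# are all inside.
erode_one <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift_and <- function(out, axis, by) {
    idx <- lapply(d, seq_len)
    src <- idx
    idx[[axis]] <- seq_len(d[axis] - 1L) + (if (by > 0) 0L else 1L)
    src[[axis]] <- idx[[axis]] + by
    shifted <- array(FALSE, d)
    shifted[idx[[1]], idx[[2]], idx[[3]]] <-
      mask[src[[1]], src[[2]], src[[3]]]
    out & shifted
  }
  for (axis in 1:3) {
    out <- shift_and(out, axis, 1L)
    out <- shift_and(out, axis, -1L)
  }
  # border voxels have a missing neighbour and are eroded away
  out[c(1L, d[1]), , ] <- FALSE
  out[, c(1L, d[2]), ] <- FALSE
  out[, , c(1L, d[3])] <- FALSE
  out
}

#' Generate a synthetic pelvis phantom
#'
#' Builds the seven structures of a rectal-cancer VMAT plan on a regular
#' grid: an ellipsoidal body; an ellipsoidal PTV centered posteriorly; a CTV
#' obtained by eroding the PTV by one voxel shell; a bladder anterior to the
#' PTV whose overlap fraction with the PTV (overlap voxels / bladder voxels)
#' is drawn uniformly in \[0, 0.3\] per seed, emulating cases where the
#' bladder largely overlaps the target; two lateral spherical femoral heads
#' disjoint from the PTV; and a superior-anterior small bowel. Deterministic
#' for a fixed seed.
#'
#' @param grid_shape voxels per axis (z, y, x); each axis must span at least
#'   100 mm (40 voxels at 2.5 mm).
#' @param spacing voxel size, mm (length 1 or 3).
#' @param seed integer RNG seed controlling anatomical jitter and the
#'   bladder-PTV overlap draw.
#' @return a [structure_set()].
#' @export
generate_phantom <- function(grid_shape = c(80, 80, 80), spacing = 2.5,
                             seed = 1) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  spacing <- rep_len(as.numeric(spacing), 3L)
  ext <- (grid_shape - 1L) * spacing
  if (any(ext < 97.5))
    stop("grid too small to place the body: each axis must span at least ",
         "97.5 mm (40 voxels at 2.5 mm)")
  ctr <- ext / 2

  with_seed(seed, {
    jit <- function(n, frac = 0.1) 1 + runif(n, -frac, frac)

    body <- ellipsoid_mask(grid_shape, spacing, ctr,
                           c(0.46, 0.42, 0.47) * ext)

    ptv_center <- ctr + c(runif(1, -0.02, 0.02) * ext[1],
                          -0.10 * ext[2],
                          runif(1, -0.015, 0.015) * ext[3])
    ptv_semi <- c(0.19, 0.17, 0.17) * ext * jit(3, 0.08)
    ptv <- ellipsoid_mask(grid_shape, spacing, ptv_center, ptv_semi) & body
    if (!any(ptv)) stop("grid too small to place structure 'PTV'")

    ctv <- erode_one(ptv)
    if (!any(ctv)) stop("grid too small to place structure 'CTV'")

    # Bladder: anterior sphere placed by bisection on its center so that
    # the realised overlap fraction |bladder & PTV| / |bladder| matches a
    # uniform draw in [0, 0.3].
    bl_r <- 0.11 * min(ext) * jit(1)
    target_overlap <- runif(1, 0, 0.3)
    bl_zx <- c(ptv_center[1] + runif(1, -0.01, 0.01) * ext[1],
               ptv_center[3] + runif(1, -0.01, 0.01) * ext[3])
    bladder_at <- function(ycen) {
      ellipsoid_mask(grid_shape, spacing,
                     c(bl_zx[1], ycen, bl_zx[2]), rep(bl_r, 3)) & body
    }
    n_ptv <- sum(ptv)
    overlap_at <- function(ycen) {
      b <- bladder_at(ycen)
      if (!any(b)) return(0)
      sum(b & ptv) / sum(b)
    }
    # overlap decreases as the bladder moves anterior (larger y)
    lo <- ptv_center[2]                    # fully engulfed end: max overlap
    hi <- ptv_center[2] + ptv_semi[2] + 2 * bl_r   # detached: zero overlap
    for (i in 1:24) {
      mid <- (lo + hi) / 2
      if (overlap_at(mid) > target_overlap) lo <- mid else hi <- mid
    }
    bladder <- bladder_at(hi)   # hi side guarantees overlap <= target <= 0.3
    if (!any(bladder)) stop("grid too small to place structure 'bladder'")

    fem_r <- 0.10 * min(ext) * jit(1, 0.06)
    fem_y <- ctr[2] + 0.02 * ext[2]
    fem_L <- ellipsoid_mask(grid_shape, spacing,
                            c(ctr[1], fem_y, ctr[3] - 0.31 * ext[3]),
                            rep(fem_r, 3)) & body
    fem_R <- ellipsoid_mask(grid_shape, spacing,
                            c(ctr[1], fem_y, ctr[3] + 0.31 * ext[3]),
                            rep(fem_r, 3)) & body
    if (!any(fem_L)) stop("grid too small to place structure 'femur_head_L'")
    if (!any(fem_R)) stop("grid too small to place structure 'femur_head_R'")
    fem_L <- fem_L & !ptv
    fem_R <- fem_R & !ptv

    bowel <- ellipsoid_mask(grid_shape, spacing,
                            ctr + c(0.24 * ext[1], 0.10 * ext[2], 0),
                            c(0.14, 0.12, 0.16) * ext * jit(3)) & body
    bowel <- bowel & !ptv
    if (!any(bowel)) stop("grid too small to place structure 'small_bowel'")

    structure_set(list(PTV = ptv, CTV = ctv, bladder = bladder,
                       femur_head_L = fem_L, femur_head_R = fem_R,
                       small_bowel = bowel, body = body),
                  spacing = spacing)
  })
}

#' Parameters of the parametric dose model
#'
#' The dose model stands in for the treatment planning system's optimizer
#' output. Inside the PTV the dose is
#' `prescription * coverage_scale * (1 + ptv_hotspot_mean)` plus Gaussian
#' noise of sd `ptv_noise_sd * prescription`; outside, the boundary dose
#' decays as `exp(-d / falloff_length)` with `d` the Euclidean distance to
#' the PTV, multiplied by the sparing factor of any organ at risk containing
#' the voxel (minimum factor if several). `coverage_scale` is auto-calibrated
#' per plan so PTV D95 lands within 1% of the prescription.
#'
#' @param ptv_hotspot_mean relative over-dose inside the PTV, fraction of
#'   prescription (absorbed by the D95 calibration; PTV inhomogeneity across
#'   strategies is carried by `ptv_noise_sd`).
#' @param ptv_noise_sd PTV dose noise sd, fraction of prescription (>= 0).
#' @param falloff_length exponential dose falloff length outside the PTV, mm.
#' @param oar_sparing named numeric vector of multiplicative sparing factors
#'   in (0, 1\], one per organ-at-risk structure name.
#' @param coverage_scale starting value for the D95 calibration.
#' @return a `strategy_params` object.
#' @export
strategy_params <- function(ptv_hotspot_mean = 0.03, ptv_noise_sd = 0.012,
                            falloff_length = 18,
                            oar_sparing = c(bladder = 0.8,
                                            femur_head_L = 0.7,
                                            femur_head_R = 0.7,
                                            small_bowel = 0.85),
                            coverage_scale = 1) {
  if (falloff_length <= 0) stop("falloff_length must be > 0")
  if (ptv_noise_sd < 0) stop("ptv_noise_sd must be >= 0")
  if (length(oar_sparing) && (is.null(names(oar_sparing)) ||
                              any(names(oar_sparing) == "")))
    stop("oar_sparing must be a named vector")
  if (any(oar_sparing <= 0 | oar_sparing > 1))
    stop("sparing factors must lie in (0, 1]")
  structure(list(ptv_hotspot_mean = ptv_hotspot_mean,
                 ptv_noise_sd = ptv_noise_sd,
                 falloff_length = falloff_length,
                 oar_sparing = oar_sparing,
                 coverage_scale = coverage_scale),
            class = "strategy_params")
}

#' Shipped strategy presets
#'
#' One calibrated parameter set per planning strategy. The presets encode
#' the qualitative behaviour of the three planning methods at the three
#' clinical-goal levels: script-based planning tracks its goal setting
#' (weak organ sparing when goals are easy, aggressive sparing at the price
#' of PTV homogeneity and conformity when goals are hard), while hybrid
#' planning replaces organ-at-risk goals with predicted achievable values
#' and therefore varies much less across goal settings.
#'
#' @return named list of [strategy_params()] objects, one per strategy label.
#' @export
strategy_presets <- function() {
  sp <- function(bl, fem, sb) c(bladder = bl, femur_head_L = fem,
                                femur_head_R = fem, small_bowel = sb)
  list(
    manual          = strategy_params(0.030, 0.0130, 38, sp(0.82, 0.62, 0.80)),
    script_easy     = strategy_params(0.050, 0.0250, 34, sp(0.93, 0.80, 0.90)),
    script_moderate = strategy_params(0.030, 0.0130, 40, sp(0.88, 0.70, 0.80)),
    script_hard     = strategy_params(0.020, 0.0260, 48, sp(0.45, 0.42, 0.55)),
    hybrid_easy     = strategy_params(0.045, 0.0190, 40, sp(0.76, 0.66, 0.68)),
    hybrid_moderate = strategy_params(0.030, 0.0120, 42, sp(0.72, 0.62, 0.65)),
    hybrid_hard     = strategy_params(0.020, 0.0135, 43, sp(0.68, 0.58, 0.62))
  )
}

#' Parameters of the achievable-dose predictor surrogate
#'
#' Noise-free parameter set representing the dose-prediction model of the
#' hybrid workflow (in the clinic, a deep-learning model trained on prior
#' plans). Used with [predict_dose()] to obtain the dose-volume indices that
#' replace organ-at-risk goal values.
#'
#' @return a [strategy_params()] object with `ptv_noise_sd = 0`.
#' @export
predictor_params <- function() {
  strategy_params(ptv_hotspot_mean = 0.03, ptv_noise_sd = 0,
                  falloff_length = 42,
                  oar_sparing = c(bladder = 0.72, femur_head_L = 0.62,
                                  femur_head_R = 0.62, small_bowel = 0.65))
}

# Deterministic part of the dose field for a given coverage scale.
dose_field <- function(structures, params, prescription, scale, noise) {
  sh <- dim(structures$masks$PTV)
  ptv <- structures$masks$PTV
  d <- distance_to_mask(ptv, structures$spacing)
  boundary <- prescription * scale * (1 + params$ptv_hotspot_mean)
  dose <- boundary * exp(-d / params$falloff_length)
  spar <- array(1, sh)
  for (nm in names(params$oar_sparing)) {
    m <- structures$masks[[nm]]
    if (!is.null(m)) spar[m] <- pmin(spar[m], params$oar_sparing[[nm]])
  }
  dose <- dose * spar
  dose[ptv] <- boundary + noise      # PTV dose overrides sparing and falloff
  pmax(dose, 0)
}

#' Simulate a strategy-dependent dose distribution
#'
#' Parametric stand-in for an optimized VMAT dose: uniform (noisy) dose in
#' the PTV, exponential falloff with Euclidean distance outside, and
#' per-organ multiplicative sparing. The coverage scale is calibrated so the
#' PTV D95 equals the prescription within 1% (the prescription isodose
#' covers 95% of the PTV). Deterministic for a fixed seed.
#'
#' @param structures a [structure_set()].
#' @param params a [strategy_params()] object.
#' @param prescription prescription dose, cGy.
#' @param seed integer seed for the PTV noise field.
#' @param max_iter calibration iteration bound.
#' @return a [dose_grid()] congruent with `structures`.
#' @export
simulate_dose <- function(structures, params, prescription = 5000, seed = 1,
                          max_iter = 25L) {
  stopifnot(inherits(structures, "structure_set"),
            inherits(params, "strategy_params"))
  if (prescription <= 0) stop("prescription must be > 0")
  ptv <- structures$masks$PTV
  noise <- with_seed(seed,
                     rnorm(sum(ptv), 0, params$ptv_noise_sd * prescription))
  scale <- params$coverage_scale
  for (i in seq_len(max_iter)) {
    dose <- dose_field(structures, params, prescription, scale, noise)
    d95 <- dose_at_volume(dose, ptv, 95)
    if (abs(d95 / prescription - 1) <= 0.01)
      return(dose_grid(dose, structures$spacing, structures$origin))
    scale <- scale * prescription / d95
  }
  stop("coverage calibration failed to bring PTV D95 within 1% of the ",
       "prescription in ", max_iter, " iterations")
}

#' Predict an achievable dose distribution
#'
#' Noise-free evaluation of the parametric dose model: the surrogate for the
#' knowledge-based dose prediction that drives clinical-goal updating.
#' Deterministic (no RNG).
#'
#' @inheritParams simulate_dose
#' @param predictor a [strategy_params()]; its `ptv_noise_sd` is ignored
#'   (treated as 0).
#' @return a [dose_grid()].
#' @export
predict_dose <- function(structures, predictor = predictor_params(),
                         prescription = 5000) {
  noiseless <- strategy_params(predictor$ptv_hotspot_mean, 0,
                               predictor$falloff_length,
                               predictor$oar_sparing,
                               predictor$coverage_scale)
  simulate_dose(structures, noiseless, prescription, seed = 0L)
}

#' Generate a synthetic plan cohort
#'
#' One structure set per patient (shared by all that patient's plans) and
#' one simulated dose per requested strategy. Per-patient and per-plan seeds
#' are derived deterministically from `master_seed`, so cohorts are
#' reproducible and extensible.
#'
#' @param n_patients number of patients (>= 1).
#' @param strategy_labels strategies to simulate per patient.
#' @param master_seed integer master seed.
#' @param grid_shape,spacing grid geometry passed to [generate_phantom()].
#' @param prescription prescription dose, cGy.
#' @return list of [plan()] objects of length
#'   `n_patients * length(strategy_labels)`.
#' @export
generate_cohort <- function(n_patients, strategy_labels = STRATEGY_LABELS,
                            master_seed = 1, grid_shape = c(80, 80, 80),
                            spacing = 2.5, prescription = 5000) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  bad <- setdiff(strategy_labels, STRATEGY_LABELS)
  if (length(bad))
    stop("unknown strategy label(s) ", paste(bad, collapse = ", "),
         "; valid labels: ", paste(STRATEGY_LABELS, collapse = ", "))
  presets <- strategy_presets()
  out <- vector("list", n_patients * length(strategy_labels))
  k <- 0L
  for (p in seq_len(n_patients)) {
    pseed <- mix_seed(master_seed, p)
    structures <- generate_phantom(grid_shape, spacing, seed = pseed)
    for (s in seq_along(strategy_labels)) {
      lab <- strategy_labels[s]
      dose <- simulate_dose(structures, presets[[lab]], prescription,
                            seed = mix_seed(pseed, s))
      k <- k + 1L
      out[[k]] <- plan(dose, structures, prescription,
                       strategy_label = lab,
                       patient_id = sprintf("P%03d", p))
    }
  }
  out
}
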