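test_that("conformity index reproduces the closed-form cases", {
  sh <- c(12, 12, 12)
  ptv <- box_mask(sh, c(4, 4, 4), c(8, 8, 8))   # 125 voxels

  # isodose region exactly equal to the PTV
  dose <- dose_with_values(ptv, rep(5000, sum(ptv)), background = 1000)
  res <- conformity_index(dose, ptv, 4750)
  expect_equal(res$ci, 1.0)
  expect_equal(res$tv_ri, res$tv)
  expect_equal(res$v_ri, res$tv)

  # tv = 100, v_ri = 200, tv_ri = 100 -> ci = 0.5
  ptv100 <- box_mask(sh, c(2, 2, 2), c(6, 5, 6))          # 5*4*5 = 100
  iso <- box_mask(sh, c(2, 2, 2), c(6, 9, 6))             # 5*8*5 = 200
  dose <- dose_with_values(iso, rep(5000, sum(iso)))
  res <- conformity_index(dose, ptv100, 4750)
  expect_equal(c(res$tv, res$v_ri, res$tv_ri), c(100, 200, 100))
  expect_equal(res$ci, 0.5)

  # tv = 100, v_ri = 100, tv_ri = 80 -> ci = 0.64
  iso2 <- box_mask(sh, c(2, 2, 2), c(6, 4, 6))            # 5*3*5 = 75 in PTV
  iso2 <- iso2 | box_mask(sh, c(2, 5, 2), c(6, 5, 2))     # 5 more in PTV (80)
  iso2 <- iso2 | box_mask(sh, c(8, 8, 8), c(11, 8, 12))   # 20 outside
  dose <- dose_with_values(iso2, rep(5000, sum(iso2)))
  res <- conformity_index(dose, ptv100, 4750)
  expect_equal(c(res$tv, res$v_ri, res$tv_ri), c(100, 100, 80))
  expect_equal(res$ci, 0.64)
})

test_that("CI is bounded, body-restricted, and scale-invariant", {
  ph <- small_phantom(seed = 2)
  dose <- simulate_dose(ph, strategy_presets()$script_moderate, 5000, seed = 2)
  res <- conformity_index(dose, ph$masks$PTV, 4750, ph$masks$body)
  expect_gte(res$ci, 0)
  expect_lte(res$ci, 1)
  expect_lte(res$tv_ri, min(res$tv, res$v_ri))
  expect_equal(res$ci, (res$tv_ri / res$tv) * (res$tv_ri / res$v_ri))

  # uniform dose rescaling with an identically rescaled reference level
  scaled <- dose_grid(dose$values * 1.7, dose$spacing, dose$origin)
  res2 <- conformity_index(scaled, ph$masks$PTV, 4750 * 1.7, ph$masks$body)
  expect_identical(res2[c("tv", "v_ri", "tv_ri", "ci")],
                   res[c("tv", "v_ri", "tv_ri", "ci")])

  # empty reference isodose is a flagged zero, not an error
  cold <- dose_grid(array(100, dim(dose$values)))
  expect_warning(res3 <- conformity_index(cold, ph$masks$PTV, 4750), "empty")
  expect_equal(res3$ci, 0)
  expect_true(res3$degenerate)
})

test_that("homogeneity index arithmetic and ordering checks", {
  expect_equal(homogeneity_index(5000, 5000, 5000), 0)
  expect_equal(homogeneity_index(5250, 4750, 5000), 0.10)
  expect_equal(homogeneity_index(5500, 4750, 5000), 0.15)
  expect_error(homogeneity_index(4700, 4750, 5000), "D2 must be >= D98")
  # HI decreases when D2 decreases, D98 and prescription fixed
  expect_lt(homogeneity_index(5100, 4900, 5000),
            homogeneity_index(5300, 4900, 5000))
})

test_that("metric panel equals field-by-field oracle recomputation", {
  ph <- small_phantom(seed = 3)
  dose <- simulate_dose(ph, strategy_presets()$hybrid_moderate, 5000, seed = 3)
  pl <- plan(dose, ph, 5000, strategy_label = "hybrid_moderate",
             patient_id = "P001")
  panel <- metric_panel(pl)
  expect_identical(metric_panel(pl), panel)   # deterministic recomputation

  v <- dose$values
  m <- ph$masks
  expect_equal(panel$PTV_D2, oracle_dx(v[m$PTV], 2))
  expect_equal(panel$PTV_D98, oracle_dx(v[m$PTV], 98))
  expect_equal(panel$bladder_D15, oracle_dx(v[m$bladder], 15))
  expect_equal(panel$bladder_D50, oracle_dx(v[m$bladder], 50))
  expect_equal(panel$bladder_Dmean, mean(v[m$bladder]))
  expect_equal(panel$bladder_Dmax, max(v[m$bladder]))
  expect_equal(panel$femur_head_L_D25, oracle_dx(v[m$femur_head_L], 25))
  expect_equal(panel$femur_head_R_D40, oracle_dx(v[m$femur_head_R], 40))
  expect_equal(panel$femur_head_L_V10, oracle_vx(v[m$femur_head_L], 1000))
  expect_equal(panel$small_bowel_V45, oracle_vx(v[m$small_bowel], 4500))
  expect_equal(panel$small_bowel_V15, oracle_vx(v[m$small_bowel], 1500))
  expect_equal(panel$HI,
               (oracle_dx(v[m$PTV], 2) - oracle_dx(v[m$PTV], 98)) / 5000)
  iso <- (v >= 4750) & m$body
  expect_equal(panel$CI,
               (sum(iso & m$PTV) / sum(m$PTV)) * (sum(iso & m$PTV) / sum(iso)))
})

test_that("uniform prescription dose gives HI 0 and bladder mean = Rx", {
  ph <- small_phantom(seed = 6)
  v <- array(0, dim(ph$masks$body))
  v[ph$masks$body] <- 5000
  pl <- plan(dose_grid(v, ph$spacing), ph, 5000, strategy_label = "manual")
  panel <- metric_panel(pl)
  expect_equal(panel$HI, 0)
  expect_equal(panel$bladder_Dmean, 5000)
})

test_that("goal evaluation applies the printed pass rules", {
  ph <- small_phantom(seed = 6)
  v <- array(0, dim(ph$masks$body))
  v[ph$masks$body] <- 5000
  pl <- plan(dose_grid(v, ph$spacing), ph, 5000, strategy_label = "manual")

  rep <- evaluate_goals(pl, preset_goals("moderate"))
  expect_true(rep$pass[rep$kind == "prescription_D95"])      # D95 = 5000 >= 5000
  expect_false(rep$pass[rep$structure == "bladder"])         # mean 5000 > 4000
  # strict "<": PTV max 5000 < 5250 passes
  expect_true(rep$pass[rep$structure == "PTV" & rep$kind == "max_dose"])

  # zero OAR dose: every OAR goal passes
  v0 <- array(0, dim(ph$masks$body))
  v0[ph$masks$PTV] <- 5000
  pl0 <- plan(dose_grid(v0, ph$spacing), ph, 5000, strategy_label = "manual")
  rep0 <- evaluate_goals(pl0, add_goals(preset_goals("moderate"),
                                        additional_goals()))
  expect_true(all(rep0$pass[rep0$role == "oar"]))

  # a tie at the limit fails a "<" goal
  tie <- clinical_goal("bladder", "mean_dose", 5000)
  expect_false(evaluate_goals(pl, list(tie))$pass)

  # absent structure is unevaluable, not an error
  ghost <- clinical_goal("ring_5mm", "max_dose", 4200, role = "auxiliary")
  repg <- evaluate_goals(pl, list(ghost))
  expect_false(repg$evaluable)
  expect_true(is.na(repg$pass))
})

test_that("goal report matches per-goal oracle on a calibrated plan", {
  ph <- small_phantom(seed = 3)
  dose <- simulate_dose(ph, strategy_presets()$hybrid_moderate, 5000, seed = 3)
  pl <- plan(dose, ph, 5000, strategy_label = "hybrid_moderate")
  goals <- add_goals(preset_goals("moderate"), additional_goals())
  rep <- evaluate_goals(pl, goals)
  v <- dose$values
  for (i in seq_len(nrow(rep))) {
    m <- ph$masks[[rep$structure[i]]]
    expected <- switch(rep$kind[i],
      prescription_D95 = oracle_dx(v[m], 95),
      max_dose = max(v[m]),
      mean_dose = mean(v[m]),
      dose_at_volume = oracle_dx(v[m], rep$x_or_threshold[i]),
      volume_at_dose = oracle_vx(v[m], rep$x_or_threshold[i]))
    expect_equal(rep$achieved[i], expected)
    expected_pass <- if (rep$kind[i] == "prescription_D95")
      expected >= rep$limit[i] else expected < rep$limit[i]
    expect_identical(rep$pass[i], expected_pass)
  }
})
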