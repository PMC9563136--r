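test_that("phantom generation is deterministic and respects placement rules", {
  a <- generate_phantom(c(44, 44, 44), 2.5, seed = 7)
  b <- generate_phantom(c(44, 44, 44), 2.5, seed = 7)
  expect_identical(a$masks, b$masks)

  expect_equal(sum(a$masks$PTV & a$masks$femur_head_L), 0)
  expect_equal(sum(a$masks$PTV & a$masks$femur_head_R), 0)

  expect_error(generate_phantom(c(20, 20, 20), 2.5, seed = 1), "too small")
})

test_that("structure containment invariants hold across many seeds", {
  for (seed in 1:50) {
    ph <- generate_phantom(c(40, 40, 40), 2.5, seed = seed)
    m <- ph$masks
    expect_true(any(m$PTV))
    expect_true(all(!m$PTV | m$body))
    expect_true(all(!m$CTV | m$PTV))
    for (nm in setdiff(names(m), "body"))
      expect_true(all(!m[[nm]] | m$body))
  }
})

test_that("bladder-PTV overlap fraction is seed-varied within [0, 0.3]", {
  ov <- vapply(0:19, function(s) {
    ph <- generate_phantom(c(44, 44, 44), 2.5, seed = s)
    sum(ph$masks$bladder & ph$masks$PTV) / sum(ph$masks$bladder)
  }, numeric(1))
  expect_true(all(ov >= 0 & ov <= 0.3))
  expect_gte(length(unique(round(ov, 3))), 2)
})

test_that("dose simulation is deterministic and calibrated to D95", {
  ph <- small_phantom(seed = 3)
  params <- strategy_presets()$hybrid_moderate
  d1 <- simulate_dose(ph, params, 5000, seed = 11)
  d2 <- simulate_dose(ph, params, 5000, seed = 11)
  expect_identical(d1$values, d2$values)

  d95 <- dose_at_volume(d1, ph$masks$PTV, 95)
  expect_lte(abs(d95 / 5000 - 1), 0.01)
})

test_that("D95 calibration holds for every preset over many seeds", {
  presets <- strategy_presets()
  for (seed in 1:20) {
    ph <- generate_phantom(c(40, 40, 40), 2.5, seed = seed)
    for (lab in names(presets)) {
      dose <- simulate_dose(ph, presets[[lab]], 5000, seed = seed + 100L)
      d95 <- dose_at_volume(dose, ph$masks$PTV, 95)
      expect_lte(abs(d95 / 5000 - 1), 0.01)
    }
  }
})

test_that("degenerate noise gives an exactly uniform PTV dose", {
  ph <- small_phantom(seed = 5)
  params <- strategy_params(ptv_hotspot_mean = 0, ptv_noise_sd = 0,
                            falloff_length = 30)
  dose <- simulate_dose(ph, params, 5000, seed = 1)
  ptv_doses <- dose$values[ph$masks$PTV]
  expect_equal(length(unique(ptv_doses)), 1L)
  # noise-free, hotspot-free: the uniform PTV dose is D95 itself, within
  # the 1% calibration tolerance of the prescription
  expect_lte(abs(ptv_doses[1] / 5000 - 1), 0.01)
})

test_that("dose falls off monotonically with distance outside the PTV", {
  ph <- small_phantom(seed = 9)
  params <- strategy_params(ptv_noise_sd = 0, falloff_length = 25,
                            oar_sparing = c(bladder = 1, femur_head_L = 1,
                                            femur_head_R = 1, small_bowel = 1))
  dose <- simulate_dose(ph, params, 5000, seed = 1)
  d <- distance_to_mask(ph$masks$PTV, ph$spacing)
  outside <- !ph$masks$PTV
  ord <- order(d[outside])
  doses_by_distance <- dose$values[outside][ord]
  expect_true(all(diff(doses_by_distance) <= 1e-9))
})

test_that("hybrid_moderate spares the bladder better than script_easy", {
  ph <- small_phantom(seed = 3)
  presets <- strategy_presets()
  d_hyb <- simulate_dose(ph, presets$hybrid_moderate, 5000, seed = 3)
  d_scr <- simulate_dose(ph, presets$script_easy, 5000, seed = 3)
  bl <- ph$masks$bladder
  # brute-force voxel averages
  expect_lt(sum(d_hyb$values[bl]) / sum(bl), sum(d_scr$values[bl]) / sum(bl))
})

test_that("hard presets spare bladder and femur at least as well as easy, per seed", {
  presets <- strategy_presets()
  for (seed in c(2, 13, 27)) {
    ph <- generate_phantom(c(44, 44, 44), 2.5, seed = seed)
    for (method in c("script", "hybrid")) {
      d_easy <- simulate_dose(ph, presets[[paste0(method, "_easy")]], 5000,
                              seed = seed)
      d_hard <- simulate_dose(ph, presets[[paste0(method, "_hard")]], 5000,
                              seed = seed)
      for (oar in c("bladder", "femur_head_L", "femur_head_R")) {
        m <- ph$masks[[oar]]
        expect_lte(mean(d_hard$values[m]), mean(d_easy$values[m]))
      }
    }
  }
})

test_that("dose prediction is deterministic and sparing is multiplicative", {
  ph <- small_phantom(seed = 4)
  expect_identical(predict_dose(ph)$values, predict_dose(ph)$values)

  base <- strategy_params(ptv_noise_sd = 0, falloff_length = 30,
                          oar_sparing = c(bladder = 1.0))
  half <- strategy_params(ptv_noise_sd = 0, falloff_length = 30,
                          oar_sparing = c(bladder = 0.5))
  p1 <- predict_dose(ph, base)
  p2 <- predict_dose(ph, half)
  bl_out <- ph$masks$bladder & !ph$masks$PTV
  expect_equal(p2$values[bl_out], p1$values[bl_out] / 2)
  # unspared prediction equals the raw falloff field in the bladder
  d <- distance_to_mask(ph$masks$PTV, ph$spacing)
  boundary <- max(p1$values[ph$masks$PTV])
  expect_equal(mean(p1$values[bl_out]),
               mean(boundary * exp(-d[bl_out] / 30)))
})

test_that("cohort generation counts, shares structures, and is reproducible", {
  plans <- generate_cohort(2, master_seed = 11, grid_shape = c(40, 40, 40))
  expect_length(plans, 14L)
  expect_equal(sum(vapply(plans, function(p) p$strategy_label == "manual",
                          logical(1))), 2L)
  p1 <- plans[vapply(plans, function(p) p$patient_id == "P001", logical(1))]
  expect_true(all(vapply(p1, function(p)
    identical(p$structures$masks, p1[[1]]$structures$masks), logical(1))))

  again <- generate_cohort(2, master_seed = 11, grid_shape = c(40, 40, 40))
  expect_identical(lapply(plans, function(p) p$dose$values),
                   lapply(again, function(p) p$dose$values))

  expect_error(generate_cohort(1, c("manual", "nope")), "valid labels")
})

test_that("different patients get different anatomies", {
  plans <- generate_cohort(2, "manual", master_seed = 1,
                           grid_shape = c(40, 40, 40))
  expect_false(identical(plans[[1]]$structures$masks$PTV,
                         plans[[2]]$structures$masks$PTV))
})
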