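test_that("preset goal levels carry the printed limits", {
  mod <- goals_as_data_frame(preset_goals("moderate"))
  expect_equal(mod$limit[mod$kind == "prescription_D95"], 5000)
  expect_equal(mod$limit[mod$structure == "PTV" & mod$kind == "max_dose"], 5250)
  expect_equal(mod$limit[mod$structure == "bladder"], 4000)
  expect_equal(mod$limit[grepl("femur", mod$structure)], c(1800, 1800))

  hard <- goals_as_data_frame(preset_goals("hard"))
  expect_equal(hard$limit[hard$structure == "PTV" & hard$kind == "max_dose"],
               5100)
  expect_equal(hard$limit[hard$structure == "bladder"], 2000)
  expect_equal(hard$limit[grepl("femur", hard$structure)], c(900, 900))

  easy <- goals_as_data_frame(preset_goals("easy"))
  expect_equal(easy$limit[easy$kind == "prescription_D95"], 5000)
  expect_equal(easy$limit[easy$structure == "PTV" & easy$kind == "max_dose"],
               5500)
  expect_equal(easy$limit[easy$structure == "bladder"], 4500)
  expect_equal(easy$limit[grepl("femur", easy$structure)], c(2700, 2700))

  expect_error(preset_goals("impossible"))
})

test_that("goal update replaces OAR limits with predicted indices, keeps targets", {
  ph <- small_phantom(seed = 8)
  pred <- predict_dose(ph)

  easy <- preset_goals("easy")
  up <- update_goals(easy, pred, ph)
  expect_equal(up$level_label, "custom")

  before <- goals_as_data_frame(easy)
  after <- goals_as_data_frame(up)
  # count, order, structures, kinds, roles unchanged
  expect_identical(before[c("structure", "kind", "x_or_threshold", "role")],
                   after[c("structure", "kind", "x_or_threshold", "role")])
  # target goals untouched
  expect_identical(before$limit[before$role == "target"],
                   after$limit[after$role == "target"])
  # every OAR limit equals the index recomputed on the prediction
  for (i in which(after$role == "oar")) {
    m <- ph$masks[[after$structure[i]]]
    expect_identical(after$limit[i], mean(pred$values[m]))
  }
})

test_that("goal update is unconditional by default and idempotent", {
  ph <- small_phantom(seed = 8)
  pred <- predict_dose(ph)
  hard <- preset_goals("hard")   # bladder mean goal 2000 cGy
  pred_bladder_mean <- mean(pred$values[ph$masks$bladder])
  expect_gt(pred_bladder_mean, 2000)   # prediction looser than the hard goal

  up <- update_goals(hard, pred, ph)
  bladder_limit <- function(s) {
    df <- goals_as_data_frame(s)
    df$limit[df$structure == "bladder"]
  }
  expect_equal(bladder_limit(up), pred_bladder_mean)   # loosened

  # tighten_only keeps the stricter preset instead
  up_t <- update_goals(hard, pred, ph, mode = "tighten_only")
  expect_equal(bladder_limit(up_t), 2000)

  # idempotence for an unchanged prediction
  up2 <- update_goals(up, pred, ph)
  expect_identical(goals_as_data_frame(up2), goals_as_data_frame(up))
})

test_that("mask expansion equals the exhaustive Euclidean-ball oracle", {
  # single voxel at 2.5 mm isotropic spacing
  single <- array(FALSE, c(9, 9, 9)); single[5, 5, 5] <- TRUE
  for (margin in c(0, 5, 15)) {
    got <- expand_mask(single, margin, 2.5)
    expect_identical(got, oracle_expand(single, margin, 2.5))
  }
  # margin 5 mm at 2.5 mm spacing: ball of center-distance <= 2 voxels
  exp5 <- expand_mask(single, 5, 2.5)
  expect_equal(sum(exp5), sum(oracle_expand(single, 5, 2.5)))

  set.seed(77)
  for (i in 1:5) {
    m <- array(runif(8 * 7 * 9) < 0.05, c(8, 7, 9))
    if (!any(m)) m[3, 3, 3] <- TRUE
    for (margin in c(0, 5, 15))
      expect_identical(expand_mask(m, margin, 2.5),
                       oracle_expand(m, margin, 2.5))
  }
})

test_that("mask expansion is an identity at margin 0 and monotone in margin", {
  ph <- small_phantom(seed = 12)
  ptv <- ph$masks$PTV
  expect_identical(expand_mask(ptv, 0, 2.5), ptv)
  e5 <- expand_mask(ptv, 5, 2.5)
  e15 <- expand_mask(ptv, 15, 2.5)
  expect_true(all(ptv <= e5))
  expect_true(all(e5 <= e15))
  expect_gt(sum(e15), sum(e5))
  expect_error(expand_mask(ptv, -1, 2.5), "non-negative")
})

test_that("ring goals derive body-minus-expanded-PTV structures", {
  ph <- small_phantom(seed = 12)
  rg <- ring_goals(ph)
  df <- goals_as_data_frame(rg$goals)
  expect_equal(sort(df$limit), c(3000, 4200))
  expect_true(all(df$role == "auxiliary"))
  expect_true(all(df$kind == "max_dose"))

  r5 <- rg$structures$masks$ring_5mm
  r15 <- rg$structures$masks$ring_15mm
  expect_equal(sum(r5 & ph$masks$PTV), 0)
  expect_equal(sum(r15 & ph$masks$PTV), 0)
  # brute-force mask algebra oracle
  expect_identical(r5, ph$masks$body & !oracle_expand(ph$masks$PTV, 5, 2.5))
  expect_identical(r15, ph$masks$body & !oracle_expand(ph$masks$PTV, 15, 2.5))
  expect_true(all(r15 <= r5))  # larger expansion leaves a smaller ring
})

test_that("additional goals are the five printed limits in internal units", {
  g <- additional_goals()
  df <- goals_as_data_frame(g)
  expect_equal(nrow(df), 5)
  expect_equal(df$limit[df$structure == "bladder"], 5250)
  expect_equal(df$kind[df$structure == "bladder"], "max_dose")
  sb <- df[df$structure == "small_bowel", ]
  expect_equal(sb$limit[sb$x_or_threshold == 4500], 5)
  expect_equal(sb$limit[sb$x_or_threshold == 1500], 30)
  fem <- df[grepl("femur", df$structure), ]
  expect_equal(fem$limit, c(75, 75))
  expect_equal(fem$x_or_threshold, c(1000, 1000))
})

test_that("goal sets round-trip through JSON", {
  set <- add_goals(preset_goals("moderate"), additional_goals())
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_goals(set, path)
  back <- read_goals(path)
  expect_equal(goals_as_data_frame(back), goals_as_data_frame(set))
  expect_equal(back$level_label, set$level_label)
})

test_that("goal set validation rejects malformed sets", {
  rx <- clinical_goal("PTV", "prescription_D95", 5000, role = "target")
  oar <- clinical_goal("bladder", "mean_dose", 4000)
  expect_error(clinical_goal_set(list(oar)), "exactly one prescription")
  expect_error(clinical_goal_set(list(rx, rx)), "exactly one prescription")
  expect_error(clinical_goal_set(list(rx, oar, oar)), "duplicate")
  expect_error(clinical_goal("bladder", "mean_dose", -5), "positive")
  expect_error(clinical_goal("bladder", "dose_at_volume", 4000), "x_or_threshold")
})
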