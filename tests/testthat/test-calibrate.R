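test_that("calibration reaches a fixed point on the model's own output", {
  m <- transition_model("female")
  tr <- run_cohort(m)
  sh <- tr$shares
  self_targets <- c(mace = tr$cum_per_1000[["mace"]],
                    strokes = tr$cum_per_1000[["strokes"]],
                    disability = tr$cum_per_1000[["disability"]],
                    cv_deaths = tr$cum_per_1000[["cv_deaths"]])
  fit <- calibrate(m, self_targets)
  expect_true(fit$converged)
  expect_equal(unname(fit$multipliers[c("mace", "disability_entry")]),
               c(1, 1), tolerance = 1e-3)
})

test_that("calibration recovers known multipliers within 1%", {
  m <- transition_model("male")
  truth <- m
  truth$multipliers[["mace"]] <- 1.3
  truth$multipliers[["disability_entry"]] <- 1.3
  truth$multipliers[["stroke_within_mace"]] <- 1.1
  truth$multipliers[["cv_death_share"]] <- 1.2
  tr <- run_cohort(truth)
  targets <- c(mace = tr$cum_per_1000[["mace"]],
               strokes = tr$cum_per_1000[["strokes"]],
               disability = tr$cum_per_1000[["disability"]],
               cv_deaths = tr$cum_per_1000[["cv_deaths"]])
  fit <- calibrate(m, targets)
  rel <- fit$multipliers / truth$multipliers - 1
  expect_true(all(abs(rel[c("mace", "stroke_within_mace",
                            "disability_entry", "cv_death_share")]) < 0.01))
})

test_that("calibration hits the published usual-care column within 0.5 per 1000", {
  tg <- load_lifetime_targets()
  for (popn in c("women", "men")) {
    sex <- if (popn == "women") "female" else "male"
    fit <- calibrate(transition_model(sex), target_vector(tg, popn, "usual_care"))
    expect_true(fit$converged)
    expect_true(all(abs(fit$residuals) <= 0.5), label = popn)
  }
})

test_that("calibration rejects infeasible targets with diagnostics", {
  m <- transition_model("female")
  expect_error(calibrate(m, c(mace = -5, strokes = 10, disability = 5, cv_deaths = 5)),
               "positive")
  err <- tryCatch(
    calibrate(m, c(mace = 999, strokes = 998, disability = 990, cv_deaths = 995)),
    error = function(e) e)
  expect_s3_class(err, "afcea_calibration_error")
  expect_true(!is.null(err$residuals))
})

test_that("an all-unity intervention arm replicates usual care", {
  m <- transition_model("female")
  uc <- run_cohort(m, strategy_arm("usual_care"))
  iv <- run_cohort(m, strategy_arm("mathias"))  # all hazard ratios 1
  expect_equal(iv$cum_per_1000, uc$cum_per_1000)
  expect_equal(iv$occupancy, uc$occupancy)
})

test_that("reduced-form strategy fit reproduces the intervention stroke column", {
  tg <- load_lifetime_targets()
  fit_uc <- calibrate(transition_model("female"),
                      target_vector(tg, "women", "usual_care"))
  arm <- apply_strategy_effect(fit_uc, target_vector(tg, "women", "intervention"))
  tr <- run_cohort(fit_uc$model, arm)
  expect_lt(abs(tr$cum_per_1000[["strokes"]] - 58), 0.5)
  expect_lt(abs(tr$cum_per_1000[["mace"]] - 132), 0.5)
})

test_that("a zero-sensitivity mechanistic cascade collapses to usual care", {
  m <- transition_model("male")
  arm <- strategy_arm("mathias", parameterization = "mechanistic",
                      cascade = list(q4_selection = 1, sensitivity = 0,
                                     specificity = 0.85, uptake = 0.85,
                                     oac_stroke_hr = 0.36))
  uc <- run_cohort(m, strategy_arm("usual_care"))
  iv <- run_cohort(m, arm)
  expect_equal(iv$cum_per_1000, uc$cum_per_1000, tolerance = 1e-12)
})

test_that("the fitted intervention arm dominates usual care clinically in both sexes", {
  bc <- base_case_cached()
  for (popn in c("women", "men")) {
    tr <- bc$populations[[popn]]$traces
    for (ch in c("strokes", "mace", "disability"))
      expect_lt(tr$intervention$cum_per_1000[[ch]],
                tr$usual_care$cum_per_1000[[ch]],
                label = paste(popn, ch))
  }
})
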