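# toy model helpers: start from the fixture-seeded model and override intensities
zeroed_model <- function(sex = "female") {
  m <- transition_model(sex)
  m$rates[] <- 0
  m$structure[["substrate_prevalence"]] <- 0
  m
}

test_that("cycle matrices are row-stochastic with death absorbing", {
  for (sex in c("female", "male")) {
    m <- transition_model(sex)
    for (arm in list(strategy_arm("usual_care"),
                     strategy_arm("mathias", hazard_ratios = c(mace = 0.6)),
                     strategy_arm("mathias", parameterization = "mechanistic"))) {
      p <- build_cycle_matrix(m, arm)
      expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_equal(unname(p[6, ]), c(0, 0, 0, 0, 0, 1))
      expect_true(all(p >= 0))
    }
  }
})

test_that("zero intensities give the identity matrix and a frozen cohort", {
  m <- zeroed_model()
  p <- build_cycle_matrix(m, strategy_arm("usual_care"))
  expect_equal(unname(p), diag(6))
  tr <- run_cohort(m, init = c(0.4, 0.1, 0.2, 0.2, 0.1, 0))
  expect_true(all(abs(sweep(tr$occupancy, 2,
                            tr$occupancy[1, ])) < 1e-14))
  expect_equal(unname(tr$cum_per_1000), rep(0, 6))
})

test_that("an overwhelming death hazard kills the cohort in one cycle", {
  m <- zeroed_model()
  m$rates[["background_death"]] <- 1e7
  tr <- run_cohort(m)
  expect_equal(tr$n_cycles, 1)  # early stop once everyone is dead
  expect_gt(tr$occupancy[2, "DEATH"], 0.9999)
  expect_equal(tr$cum_per_1000[["deaths"]], 1000, tolerance = 1e-3)
})

test_that("competing-risk resolution matches the integrated exponential model", {
  # independent oracle: P(exit to j in [0,h]) = int_0^h lambda_j exp(-Lambda t) dt
  m <- zeroed_model()
  m$rates[["af_onset"]] <- 10   # per 1000 py
  m$rates[["mace"]] <- 25
  m$rates[["background_death"]] <- 30
  p <- build_cycle_matrix(m, strategy_arm("usual_care"))
  lam <- c(af = 0.010, mace = 0.025, death = 0.030)
  total <- sum(lam)
  oracle <- vapply(lam, function(lj)
    stats::integrate(function(t) lj * exp(-total * t), 0, 1,
                     rel.tol = 1e-12)$value, numeric(1))
  expect_equal(p["HIGH_RISK_NO_AF", "DETECTED_AF"], oracle[["af"]], tolerance = 1e-10)
  expect_equal(p["HIGH_RISK_NO_AF", "POST_MACE"], oracle[["mace"]], tolerance = 1e-10)
  expect_equal(p["HIGH_RISK_NO_AF", "DEATH"], oracle[["death"]], tolerance = 1e-10)
  expect_equal(p["HIGH_RISK_NO_AF", "HIGH_RISK_NO_AF"], exp(-total), tolerance = 1e-12)
})

test_that("cohort recursion conserves mass and counters are monotone", {
  m <- transition_model("male")
  tr <- run_cohort(m)
  expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-10))
  expect_true(all(diff(tr$occupancy[, "DEATH"]) >= 0))
  for (ch in c("mace", "strokes", "disability", "cv_deaths", "deaths"))
    expect_true(all(tr$events[[ch]] >= 0), label = ch)
})

test_that("cohort recursion agrees with individual-level microsimulation", {
  m <- transition_model("female")
  arm <- strategy_arm("usual_care")
  n_cycles <- 10
  tr <- run_cohort(m, arm, init = c(1, 0, 0, 0, 0, 0))
  ms <- microsim(m, arm, n = 2e5, n_cycles = n_cycles, init_state = 1)
  exp_mace <- sum(tr$events$mace[seq_len(n_cycles)])
  exp_death <- sum(tr$events$deaths[seq_len(n_cycles)])
  se <- function(p) sqrt(p * (1 - p) * ms$n)
  expect_lt(abs(ms$mace - exp_mace * ms$n), 3 * se(exp_mace))
  expect_lt(abs(ms$deaths - exp_death * ms$n), 3 * se(exp_death))
})

test_that("trace CSVs are tidy and consistent with the trace", {
  tr <- run_cohort(transition_model("female"))
  stem <- file.path(withr::local_tempdir(), "trace")
  paths <- write_trace(tr, stem)
  occ <- read.csv(paths[1])
  expect_equal(nrow(occ), (tr$n_cycles + 1) * 6)
  expect_equal(occ$occupancy[occ$state == "DEATH" & occ$cycle == tr$n_cycles],
               tr$occupancy[tr$n_cycles + 1, "DEATH"], ignore_attr = TRUE)
  ev <- read.csv(paths[2])
  expect_equal(sum(ev$flux_per_1000[ev$channel == "strokes"]),
               tr$cum_per_1000[["strokes"]])
})

test_that("sex pooling is a convex combination with aligned horizons", {
  f <- run_cohort(transition_model("female"))
  m <- run_cohort(transition_model("male"))
  all_f <- pool_sexes(f, m, c(female = 1, male = 0))
  expect_equal(all_f$cum_per_1000, f$cum_per_1000)
  expect_equal(all_f$occupancy, f$occupancy)
  same <- pool_sexes(f, f, c(female = 0.5, male = 0.5))
  expect_equal(same$cum_per_1000, f$cum_per_1000)
  pooled <- pool_sexes(f, m, c(female = 0.52, male = 0.48))
  expect_equal(pooled$cum_per_1000[["mace"]],
               0.52 * f$cum_per_1000[["mace"]] + 0.48 * m$cum_per_1000[["mace"]])
  short <- f; short$n_cycles <- 3
  expect_error(pool_sexes(short, m), "horizons")
})

test_that("published per-sex outcomes pool to the printed overall within 1.5 per 1000", {
  tg <- load_lifetime_targets()
  w <- target_vector(tg, "women", "usual_care")
  m <- target_vector(tg, "men", "usual_care")
  ov <- target_vector(tg, "overall", "usual_care")
  pooled <- 0.52 * w + 0.48 * m
  expect_true(all(abs(pooled - ov) <= 1.5))
})
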