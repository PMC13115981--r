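test_that("cohort generation is deterministic in (profile, seed) and seed-sensitive", {
  prof <- tiny_profile(300)
  a <- generate_cohort(prof, 11)
  b <- generate_cohort(prof, 11)
  c <- generate_cohort(prof, 12)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_equal(nrow(a), 300)
})

test_that("degenerate sex probability yields a single-sex cohort", {
  prof <- tiny_profile(200, p_female = 1)
  coh <- generate_cohort(prof, 1)
  expect_true(all(coh$sex == "female"))
  prof$p_female <- 0
  expect_true(all(generate_cohort(prof, 1)$sex == "male"))
})

test_that("generated marginals recover the profile within 4 binomial SEs", {
  prof <- cohort_profile()
  coh <- generate_cohort(prof, 2024)
  n <- nrow(coh)
  se <- function(p, m) sqrt(p * (1 - p) / m)
  expect_lt(abs(mean(coh$sex == "female") - prof$p_female),
            4 * se(prof$p_female, n))
  for (sex in c("female", "male")) {
    sub <- coh[coh$sex == sex, ]
    for (cond in names(prof$prevalence)) {
      p <- prof$prevalence[[cond]][[sex]]
      expect_lt(abs(mean(sub[[cond]]) - p), 4 * se(p, nrow(sub)),
                label = sprintf("%s prevalence (%s)", cond, sex))
    }
  }
  expect_true(all(coh$age >= 65 & coh$age <= 95))
  expect_lt(abs(mean(coh$age) - prof$age$mean), 0.2)
  expect_true(all(coh$cha2ds2va >= 0 & coh$cha2ds2va <= 9))
})

test_that("summarize_cohort mirrors the profile layout and handles edge cases", {
  prof <- cohort_profile()
  coh <- generate_cohort(prof, 7)
  s <- summarize_cohort(coh)
  expect_true(all(c("variable", "stat", "male", "female", "all") %in% names(s)))
  # pooled score mean close to the published 3.96 at full cohort size
  score_mean <- s$all[s$variable == "cha2ds2va" & s$stat == "mean"]
  expect_lt(abs(score_mean - 3.96), 0.05)
  # diabetes prevalence among men recovered within binomial error
  dm <- s$male[s$variable == "diabetes" & s$stat == "prevalence"]
  n_m <- s$male[s$variable == "n"]
  expect_lt(abs(dm - 0.534), 3 * sqrt(0.534 * 0.466 / n_m))
  # single-individual cohort: sd 0, prevalence in {0, 1}
  one <- summarize_cohort(coh[1, ])
  expect_true(all(one$all[one$stat == "sd"] == 0))
  expect_true(all(one$all[one$stat == "prevalence"] %in% c(0, 1)))
  expect_error(summarize_cohort(coh[0, ]), "empty")
})

test_that("profile validation rejects invalid inputs", {
  prof <- tiny_profile()
  bad <- prof; bad$p_female <- 1.2
  expect_error(generate_cohort(bad, 1), "proportions")
  bad <- prof; bad$n_total <- 0
  expect_error(generate_cohort(bad, 1), "n_total")
})

test_that("population-impact strata partition every cohort", {
  expect_equal(as.character(assign_pip_stratum(5, FALSE, FALSE)), "very_high")
  expect_equal(as.character(assign_pip_stratum(0, FALSE, FALSE)), "moderate_high")
  expect_equal(as.character(assign_pip_stratum(3, FALSE, FALSE)), "high")
  expect_equal(as.character(assign_pip_stratum(1, TRUE, FALSE)), "very_high")
  expect_equal(as.character(assign_pip_stratum(1, FALSE, TRUE)), "very_high")
  expect_error(assign_pip_stratum(NA, FALSE, FALSE), "missing")

  coh <- add_pip_stratum(generate_cohort(tiny_profile(1000), 3))
  expect_equal(sum(table(coh$pip_stratum)), 1000)
  expect_false(any(is.na(coh$pip_stratum)))
  # the secondary threshold is configurable
  coh2 <- add_pip_stratum(generate_cohort(tiny_profile(1000), 3),
                          high_threshold = 2)
  expect_gte(sum(coh2$pip_stratum == "high"), sum(coh$pip_stratum == "high"))
})

test_that("cohort CSV writer round-trips", {
  coh <- generate_cohort(tiny_profile(50), 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$sex, coh$sex)
  expect_equal(back$cha2ds2va, coh$cha2ds2va)
  expect_equal(back$age, coh$age, tolerance = 1e-12)
})
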