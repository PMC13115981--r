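test_that("moment matching recovers textbook parameterisations", {
  b <- fit_distribution("beta", 0.5, sd = 0.1)
  expect_equal(unname(b$pars), c(12, 12))
  g <- fit_distribution("gamma", 100, sd = 20)
  expect_equal(unname(g$pars), c(25, 4))
  expect_equal(fit_distribution("gamma", 100, sd = 0)$sampler(5), rep(100, 5))
  ln <- fit_distribution("lognormal", mean = 1, ci = c(0.5, 2))
  expect_equal(exp(ln$pars[["meanlog"]]), sqrt(0.5 * 2))
  expect_error(fit_distribution("beta", 0.5, sd = 0.6), "variance")
})

test_that("samplers hit their target means within 1% at 1e5 draws", {
  set.seed(99)
  for (d in list(fit_distribution("beta", 0.8, cv = 0.1),
                 fit_distribution("gamma", 1, cv = 0.15),
                 fit_distribution("lognormal", 1, cv = 0.2))) {
    mu <- if (d$family == "beta") 0.8 else 1
    expect_lt(abs(mean(d$sampler(1e5)) - mu) / mu, 0.01, label = d$family)
  }
})

test_that("zero-dispersion PSA collapses to the base case exactly", {
  bc <- base_case_cached()
  draws <- run_psa(bc, psa_config(n_draws = 3, seed = 5, cost_cv = 0,
                                  utility_cv = 0, hr_cv = 0))
  expect_equal(draws$d_cost_payer,
               rep(bc$populations$overall$ce$payer$d_cost, 3))
  expect_equal(draws$d_qaly,
               rep(bc$populations$overall$ce$payer$d_qaly, 3))
})

test_that("the PSA pipeline is reproducible under a fixed seed", {
  bc <- base_case_cached()
  cfg <- psa_config(n_draws = 25, seed = 11)
  a <- run_psa(bc, cfg)
  b <- run_psa(bc, cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- run_psa(bc, psa_config(n_draws = 25, seed = 12))
  expect_false(identical(a$d_cost_payer, c$d_cost_payer))
})

test_that("sampled parameters are centred on the base case", {
  bc <- base_case_cached()
  draws <- run_psa(bc, psa_config(n_draws = 400, seed = 3))
  # gamma cost factors have mean 1, cv 0.15; pooled across components
  cf <- as.matrix(draws[, grep("^cf_", names(draws))])
  mc_se <- 0.15 / sqrt(length(cf))
  expect_lt(abs(mean(cf) - 1), 2 * mc_se)
})

test_that("CEAC properties: definitional identity, bounds, monotonicity", {
  bc <- base_case_cached()
  draws <- run_psa(bc, psa_config(n_draws = 200, seed = 7))
  grid <- seq(0, 60000, by = 5000)
  curve <- ceac(draws, grid)
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  expect_equal(curve$probability[curve$wtp == 0], prob_cost_saving(draws))
  gain <- draws[draws$d_qaly > 0, ]
  curve_gain <- ceac(gain, grid)
  expect_true(all(diff(curve_gain$probability) >= 0))
  expect_error(ceac(draws, numeric(0)), "empty")
  expect_error(ceac(draws[0, ], grid), "empty")
  expect_error(prob_cost_saving(draws[0, ]), "empty")
})

test_that("the dominant quadrant share exceeds one half under default dispersions", {
  bc <- base_case_cached()
  draws <- run_psa(bc, psa_config(n_draws = 200, seed = 21))
  dominant <- mean(draws$d_cost_payer < 0 & draws$d_qaly > 0)
  expect_gt(dominant, 0.5)
})

test_that("all cost-saving, QALY-gaining draws give a CEAC identically 1", {
  bc <- base_case_cached()
  draws <- run_psa(bc, psa_config(n_draws = 100, seed = 13))
  sub <- draws[draws$d_cost_payer < 0 & draws$d_qaly > 0, ]
  expect_gt(nrow(sub), 0)
  expect_true(all(ceac(sub, seq(0, 100000, by = 10000))$probability == 1))
})

test_that("one-way DSA covers the published drivers and behaves at bounds", {
  bc <- base_case_cached()
  drivers <- names(default_dsa_ranges())
  expect_true(all(c("stroke_acute_cost_factor", "substrate_prevalence",
                    "screening_sensitivity", "screening_specificity",
                    "disability_rate_factor") %in% drivers))
  tor <- one_way_dsa(bc)
  expect_s3_class(tor, "tornado_result")
  expect_setequal(unique(tor$parameter), drivers)
  # ordering by descending output range
  expect_true(all(diff(tor$range[seq(1, nrow(tor), by = 2)]) <= 1e-9))
  # raising the acute stroke unit cost deepens the savings
  hi <- tor[tor$parameter == "stroke_acute_cost_factor" & tor$bound == "high", ]
  lo <- tor[tor$parameter == "stroke_acute_cost_factor" & tor$bound == "low", ]
  expect_lt(hi$d_cost_payer, lo$d_cost_payer)
  base_ce <- bc$populations$overall$ce$payer
  # zero-width ranges reproduce the base case at both bounds
  tor0 <- one_way_dsa(bc, ranges = list(
    stroke_acute_cost_factor = c(1, 1),
    substrate_prevalence = rep(bc$profile$pre_af_substrate_prevalence, 2)))
  expect_equal(tor0$d_cost_payer, rep(base_ce$d_cost, 4), tolerance = 1e-9)
  expect_equal(unique(tor0$range), 0, tolerance = 1e-9)
  # ranges must bracket the base value
  expect_error(one_way_dsa(bc, ranges = list(substrate_prevalence = c(0.4, 0.6))),
               "bracket")
})
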