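test_that("discounting follows the closed form", {
  expect_equal(discount(100, 0, 0.03), 100)
  expect_equal(discount(100, 1, 0.03), 100 / 1.03)
  expect_equal(discount(100, 10, 0), 100)
  expect_error(discount(100, -1), "negative")
})

test_that("cost accumulation matches a hand-computed two-cycle toy", {
  # one state occupied throughout, unit cost 100 per state-year, no
  # discounting: the half-cycle correction leaves full occupancy untouched
  # because occupancy is constant, so the total is exactly 200 per person
  m <- transition_model("female")
  m$rates[] <- 0
  m$structure[["substrate_prevalence"]] <- 0
  tr <- run_cohort(m, init = c(0, 0, 0, 0, 1, 0), start_age = 93, max_age = 95)
  expect_equal(tr$n_cycles, 2)
  econ <- econ_inputs(discount_rate = 0)
  res <- accumulate_costs(tr, econ, c(longterm_disability = 100), "payer")
  expect_equal(res$total, 100 * 2 * 1000)  # per 1000 individuals
  # with 3% discounting the second year is divided by 1.03
  econ3 <- econ_inputs(discount_rate = 0.03)
  res3 <- accumulate_costs(tr, econ3, c(longterm_disability = 100), "payer")
  expect_equal(res3$total, (100 + 100 / 1.03) * 1000)
  # zero unit costs give zero totals
  expect_equal(accumulate_costs(tr, econ, c(longterm_disability = 0), "payer")$total, 0)
  # unknown component is a configuration error
  expect_error(accumulate_costs(tr, econ, c(mystery = 5), "payer"),
               "allocation rule")
})

test_that("QALY accumulation matches closed forms and an independent summation", {
  m <- transition_model("female")
  m$rates[] <- 0
  m$structure[["substrate_prevalence"]] <- 0
  tr <- run_cohort(m, init = c(1, 0, 0, 0, 0, 0), start_age = 85, max_age = 95)
  u1 <- default_utilities(); u1[setdiff(names(u1), "DEATH")] <- 1
  econ <- econ_inputs(utilities = u1, discount_rate = 0)
  expect_equal(accumulate_qalys(tr, econ), 10 * 1000)  # 10 years at utility 1
  u0 <- default_utilities(); u0[] <- 0
  expect_equal(accumulate_qalys(tr, econ_inputs(utilities = u0)), 0)
  # independent spreadsheet-style recomputation on a live trace
  tr2 <- run_cohort(transition_model("male"))
  econ2 <- econ_inputs()
  manual <- 0
  for (t in seq_len(tr2$n_cycles)) {
    occ <- (tr2$occupancy[t, ] + tr2$occupancy[t + 1, ]) / 2
    manual <- manual + sum(occ * econ2$utilities) / 1.03^(t - 1)
  }
  expect_equal(accumulate_qalys(tr2, econ2), manual * 1000, tolerance = 1e-9)
})

test_that("fitted unit costs reproduce the published aggregates to the cent", {
  bc <- base_case_cached()
  ov <- bc$populations$overall
  expect_equal(ov$costs$usual_care$payer$total, 4838000)
  expect_equal(ov$costs$intervention$payer$total, 3560000)
  expect_equal(unname(ov$costs$usual_care$payer$components),
               c(48000, 280000, 1755000, 2025000, 730000))
  expect_equal(ov$ce$payer$d_cost, -1278000)
  expect_equal(ov$ce$societal$d_cost, -1135000)
  expect_equal(bc$populations$women$ce$payer$d_cost, -1400000)
  expect_equal(bc$populations$men$ce$payer$d_cost, -1000000)
})

test_that("component additivity and perspective nesting hold exactly", {
  bc <- base_case_cached()
  for (popn in names(bc$populations)) {
    cs <- bc$populations[[popn]]$costs
    for (arm in names(cs)) {
      expect_equal(cs[[arm]]$payer$total, sum(cs[[arm]]$payer$components))
      expect_equal(cs[[arm]]$combined$total,
                   cs[[arm]]$payer$total + cs[[arm]]$societal$total,
                   tolerance = 1e-9)
    }
  }
})

test_that("discounting strictly reduces totals when later flows exist", {
  bc <- base_case_cached()
  tr <- bc$populations$overall$traces$usual_care
  ucosts <- bc$populations$overall$unit_costs$usual_care
  undisc <- accumulate_costs(tr, econ_inputs(discount_rate = 0), ucosts, "payer")
  disc <- bc$populations$overall$costs$usual_care$payer
  expect_gt(undisc$total, disc$total)
})

test_that("incremental results flag dominance and satisfy the NMB identity", {
  grid <- c(0, 30000, 100000)
  dom <- incremental(100, 1378, 80, 6, grid)
  expect_equal(dom$status, "dominant")
  expect_true(all(dom$nmb > 0))
  expect_equal(unname(dom$nmb), grid * dom$d_qaly - dom$d_cost)
  icer <- incremental(1000, 0, 0.1, 0, grid)
  expect_equal(icer$icer, 10000)
  tie <- incremental(5, 5, 3, 3, grid)
  expect_equal(tie$status, "equivalent")
  expect_true(all(tie$nmb == 0))
  undef <- incremental(10, 5, 3, 3, grid)
  expect_equal(undef$status, "undefined")
  expect_true(is.na(undef$icer))
  expect_length(undef$nmb, length(grid))
})

test_that("base-case QALY gains are positive and larger in women than men", {
  bc <- base_case_cached()
  dq_w <- bc$populations$women$ce$payer$d_qaly
  dq_m <- bc$populations$men$ce$payer$d_qaly
  expect_gt(dq_m, 0)
  expect_gt(dq_w, dq_m)
  # ICER dominant in every population, as in the published base case
  for (popn in names(bc$populations))
    expect_equal(bc$populations[[popn]]$ce$payer$status, "dominant")
})

test_that("under-75 share declines over cycles and stays in [0, 1]", {
  prof <- cohort_profile()
  u <- under75_share(prof, 11)
  expect_true(all(u >= 0 & u <= 1))
  expect_true(all(diff(u) <= 0))
  expect_lt(u[1], 0.10)  # cohort mean age ~85: few below 75
})
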