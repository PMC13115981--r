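#' Method-of-moments distribution fitting for PSA parameters
#'
#' Parameterises the PSA sampling distributions from a mean and a dispersion
#' by moment matching: beta for probabilities and utilities, gamma for
#' costs, log-normal for relative risks / hazard ratios. A zero dispersion
#' yields a degenerate point mass at the mean.
#'
#' @param family `"beta"`, `"gamma"` or `"lognormal"`.
#' @param mean Target mean (beta: in (0,1); gamma/lognormal: positive).
#' @param sd Standard deviation; alternatively give `cv` or, for the
#'   log-normal, a 95% `ci` (the mean argument is then ignored for the
#'   location).
#' @param cv Coefficient of variation (sd/mean).
#' @param ci Length-2 vector, 95% CI on the natural scale (lognormal only).
#' @return List of class `psa_dist`: `family`, `pars`, and `sampler`, a
#'   `function(n)` drawing n values.
#' @export
fit_distribution <- function(family = c("beta", "gamma", "lognormal"),
                             mean, sd = NULL, cv = NULL, ci = NULL) {
  family <- match.arg(family)
  if (is.null(sd) && !is.null(cv)) sd <- cv * mean
  if (family == "lognormal" && !is.null(ci)) {
    stopifnot(length(ci) == 2, all(ci > 0), ci[1] < ci[2])
    mu <- (log(ci[1]) + log(ci[2])) / 2
    sigma <- (log(ci[2]) - log(ci[1])) / (2 * stats::qnorm(0.975))
    return(structure(list(family = family, pars = c(meanlog = mu, sdlog = sigma),
                          sampler = function(n) stats::rlnorm(n, mu, sigma)),
                     class = "psa_dist"))
  }
  stopifnot(!is.null(sd), sd >= 0)
  if (sd == 0) {
    return(structure(list(family = family, pars = c(mean = mean, sd = 0),
                          sampler = function(n) rep(mean, n)),
                     class = "psa_dist"))
  }
  pars <- switch(family,
    beta = {
      stopifnot(mean > 0, mean < 1)
      v <- sd^2
      k <- mean * (1 - mean) / v - 1
      if (k <= 0)
        stop("fit_distribution: beta variance must be below mean*(1-mean)",
             call. = FALSE)
      c(shape1 = mean * k, shape2 = (1 - mean) * k)
    },
    gamma = {
      stopifnot(mean > 0)
      c(shape = mean^2 / sd^2, scale = sd^2 / mean)
    },
    lognormal = {
      stopifnot(mean > 0)
      s2 <- log(1 + (sd / mean)^2)
      c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
    })
  sampler <- switch(family,
    beta = function(n) stats::rbeta(n, pars[["shape1"]], pars[["shape2"]]),
    gamma = function(n) stats::rgamma(n, shape = pars[["shape"]],
                                      scale = pars[["scale"]]),
    lognormal = function(n) stats::rlnorm(n, pars[["meanlog"]], pars[["sdlog"]]))
  structure(list(family = family, pars = pars, sampler = sampler),
            class = "psa_dist")
}

#' PSA configuration
#'
#' Draw count, seed, and dispersion magnitudes. The publication states no
#' dispersions; the defaults are conventional magnitudes (costs CV 15%,
#' utilities CV 10%, hazard-ratio-type parameters CV 20%) and the published
#' acceptability probabilities are sensitive to them — they are reported,
#' not asserted.
#'
#' @param n_draws Number of Monte-Carlo draws (default 10000).
#' @param seed Integer seed.
#' @param cost_cv,utility_cv,hr_cv Coefficients of variation by parameter
#'   class.
#' @return List of class `psa_config`.
#' @export
psa_config <- function(n_draws = 10000, seed = 1, cost_cv = 0.15,
                       utility_cv = 0.10, hr_cv = 0.20) {
  stopifnot(n_draws > 0, cost_cv >= 0, utility_cv >= 0, hr_cv >= 0)
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 cost_cv = cost_cv, utility_cv = utility_cv, hr_cv = hr_cv),
            class = "psa_config")
}

#' Re-evaluate the model under parameter overrides
#'
#' Shared evaluation kernel for the PSA and the one-way DSA: rebuilds both
#' arms per sex from the calibrated base case with the given overrides,
#' reruns the cohort recursion, pools sexes, and accumulates costs and QALYs
#' with the (possibly scaled) fitted unit costs and (possibly replaced)
#' utilities.
#'
#' @param bc A [run_base_case()] result.
#' @param overrides Named list; recognised entries: `utilities` (named
#'   replacement vector), `cost_factors` (named multiplicative factors on
#'   unit costs, applied to both arms), `hr_factors` (named factors on the
#'   intervention arm's channel hazard ratios), `mace_baseline_factor` and
#'   `disability_baseline_factor` (factors on the calibrated baseline
#'   multipliers, both arms), `substrate_prevalence`,
#'   `screening_sensitivity`, `screening_specificity` (rebuild the
#'   intervention stroke effect through the mechanistic cascade relative to
#'   the arm's stored cascade, and scale intervention screening costs with
#'   the confirmatory workload).
#' @return List: `d_cost_payer`, `d_cost_societal`, `d_cost_combined`,
#'   `d_qaly`, plus per-arm totals.
#' @export
evaluate_scenario <- function(bc, overrides = list()) {
  ov <- overrides
  econ <- bc$econ
  if (!is.null(ov$utilities)) {
    econ$utilities[names(ov$utilities)] <- ov$utilities
    econ$utilities[["DEATH"]] <- 0
  }

  sex_traces <- lapply(c(women = "women", men = "men"), function(popn) {
    pop <- bc$populations[[popn]]
    model <- pop$fit_uc$model
    arm_i <- pop$arm
    if (!is.null(ov$substrate_prevalence))
      model$structure[["substrate_prevalence"]] <- ov$substrate_prevalence
    if (!is.null(ov$mace_baseline_factor))
      model$multipliers[["mace"]] <- model$multipliers[["mace"]] * ov$mace_baseline_factor
    if (!is.null(ov$disability_baseline_factor))
      model$multipliers[["disability_entry"]] <-
        model$multipliers[["disability_entry"]] * ov$disability_baseline_factor
    if (!is.null(ov$hr_factors)) {
      stopifnot(all(names(ov$hr_factors) %in% names(arm_i$hazard_ratios)))
      arm_i$hazard_ratios[names(ov$hr_factors)] <-
        arm_i$hazard_ratios[names(ov$hr_factors)] * unlist(ov$hr_factors)
    }
    if (!is.null(ov$screening_sensitivity) || !is.null(ov$screening_specificity)) {
      cs <- arm_i$cascade
      sens <- if (is.null(ov$screening_sensitivity)) cs$sensitivity else ov$screening_sensitivity
      p0 <- cs$q4_selection * cs$sensitivity * cs$uptake
      p1 <- cs$q4_selection * sens * cs$uptake
      hr_s0 <- 1 - p0 * (1 - cs$oac_stroke_hr)
      hr_s1 <- 1 - p1 * (1 - cs$oac_stroke_hr)
      s <- bc$populations[[popn]]$traces$usual_care$shares[["stroke_within_mace"]]
      f_mace <- (1 - s + s * hr_s1) / (1 - s + s * hr_s0)
      arm_i$hazard_ratios[["mace"]] <- arm_i$hazard_ratios[["mace"]] * f_mace
      arm_i$hazard_ratios[["stroke_within_mace"]] <-
        arm_i$hazard_ratios[["stroke_within_mace"]] * (hr_s1 / hr_s0) / f_mace
    }
    list(usual_care = run_cohort(model, strategy_arm("usual_care"),
                                 start_age = bc$start_age),
         intervention = run_cohort(model, arm_i, start_age = bc$start_age))
  })

  traces <- list(
    usual_care = pool_sexes(sex_traces$women$usual_care,
                            sex_traces$men$usual_care, bc$sex_weights),
    intervention = pool_sexes(sex_traces$women$intervention,
                              sex_traces$men$intervention, bc$sex_weights))

  unit_costs <- bc$populations$overall$unit_costs
  if (!is.null(ov$cost_factors)) {
    for (arm in names(unit_costs)) {
      stopifnot(all(names(ov$cost_factors) %in% names(unit_costs[[arm]])))
      unit_costs[[arm]][names(ov$cost_factors)] <-
        unit_costs[[arm]][names(ov$cost_factors)] * unlist(ov$cost_factors)
    }
  }
  if (!is.null(ov$screening_specificity) || !is.null(ov$screening_sensitivity)) {
    cs <- bc$populations$women$arm$cascade
    sens <- if (is.null(ov$screening_sensitivity)) cs$sensitivity else ov$screening_sensitivity
    spec <- if (is.null(ov$screening_specificity)) cs$specificity else ov$screening_specificity
    pi_af <- 0.177  # detectable-AF share among screened (incident-AF fraction)
    w0 <- cs$sensitivity * pi_af + (1 - cs$specificity) * (1 - pi_af)
    w1 <- sens * pi_af + (1 - spec) * (1 - pi_af)
    unit_costs$intervention[["screening_diagnostics"]] <-
      unit_costs$intervention[["screening_diagnostics"]] * w1 / w0
  }

  u75 <- under75_share(bc$profile, traces$usual_care$n_cycles)
  res <- lapply(c(usual_care = "usual_care", intervention = "intervention"),
                function(arm) {
    list(payer = accumulate_costs(traces[[arm]], econ, unit_costs[[arm]],
                                  "payer", u75 = u75)$total,
         societal = accumulate_costs(traces[[arm]], econ, unit_costs[[arm]],
                                     "societal", u75 = u75)$total,
         qaly = accumulate_qalys(traces[[arm]], econ))
  })
  list(d_cost_payer = res$intervention$payer - res$usual_care$payer,
       d_cost_societal = res$intervention$societal - res$usual_care$societal,
       d_cost_combined = (res$intervention$payer + res$intervention$societal) -
                         (res$usual_care$payer + res$usual_care$societal),
       d_qaly = res$intervention$qaly - res$usual_care$qaly,
       arms = res)
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty: per draw, samples state
#' utilities (beta), unit-cost factors per component (gamma, mean 1),
#' intervention channel hazard-ratio factors and baseline-risk factors
#' (log-normal, mean 1) and the pre-AF substrate prevalence (beta), rebuilds
#' both arms, reruns the model and records the incremental cost and QALYs.
#' Draws whose rebuilt model is invalid are rejected and logged, not
#' resampled (the effective draw count is reported). Reproducible given the
#' config seed.
#'
#' @param bc A [run_base_case()] result.
#' @param config A [psa_config()].
#' @return Data frame of class `psa_draws` with columns `draw`,
#'   `d_cost_payer`, `d_cost_societal`, `d_qaly` and the sampled parameters;
#'   attributes `seed`, `n_rejected`, `config`.
#' @export
run_psa <- function(bc, config = psa_config()) {
  set.seed(config$seed)
  n <- config$n_draws
  alive <- setdiff(health_states(), "DEATH")
  u0 <- bc$econ$utilities[alive]
  comps <- names(bc$populations$overall$unit_costs$usual_care)
  hr_channels <- c("mace", "stroke_within_mace", "disability_entry", "cv_death_share")
  sp0 <- bc$profile$pre_af_substrate_prevalence

  draw_cols <- list()
  for (s in alive)
    draw_cols[[paste0("u_", s)]] <-
      fit_distribution("beta", u0[[s]], cv = config$utility_cv)$sampler(n)
  for (comp in comps)
    draw_cols[[paste0("cf_", comp)]] <-
      fit_distribution("gamma", 1, cv = config$cost_cv)$sampler(n)
  for (ch in hr_channels)
    draw_cols[[paste0("hrf_", ch)]] <-
      fit_distribution("lognormal", 1, cv = config$hr_cv)$sampler(n)
  draw_cols[["mace_baseline_factor"]] <-
    fit_distribution("lognormal", 1, cv = config$hr_cv)$sampler(n)
  draw_cols[["substrate_prevalence"]] <-
    fit_distribution("beta", sp0, cv = config$hr_cv)$sampler(n)
  par <- as.data.frame(draw_cols)

  out <- matrix(NA_real_, n, 3,
                dimnames = list(NULL, c("d_cost_payer", "d_cost_societal", "d_qaly")))
  n_rejected <- 0L
  for (i in seq_len(n)) {
    ov <- list(
      utilities = stats::setNames(as.numeric(par[i, paste0("u_", alive)]), alive),
      cost_factors = stats::setNames(as.numeric(par[i, paste0("cf_", comps)]), comps),
      hr_factors = stats::setNames(as.numeric(par[i, paste0("hrf_", hr_channels)]),
                                   hr_channels),
      mace_baseline_factor = par$mace_baseline_factor[i],
      substrate_prevalence = par$substrate_prevalence[i])
    res <- tryCatch(evaluate_scenario(bc, ov), error = function(e) NULL)
    if (is.null(res)) { n_rejected <- n_rejected + 1L; next }
    out[i, ] <- c(res$d_cost_payer, res$d_cost_societal, res$d_qaly)
  }
  draws <- cbind(data.frame(draw = seq_len(n)), as.data.frame(out), par)
  draws <- draws[!is.na(draws$d_cost_payer), ]
  structure(draws, class = c("psa_draws", "data.frame"),
            seed = config$seed, n_rejected = n_rejected, config = config)
}

#' Cost-effectiveness acceptability curve
#'
#' Probability of positive net monetary benefit per willingness-to-pay
#' value, `P(lambda * dQALY - dCost > 0)`. At lambda 0 this equals the
#' probability of cost-saving exactly.
#'
#' @param draws A [run_psa()] result.
#' @param wtp_grid Willingness-to-pay grid (euros/QALY).
#' @param perspective Cost column to use (`"payer"` or `"societal"`).
#' @return Data frame `wtp`, `probability`.
#' @export
ceac <- function(draws, wtp_grid = seq(0, 100000, by = 1000),
                 perspective = c("payer", "societal")) {
  perspective <- match.arg(perspective)
  if (length(wtp_grid) == 0) stop("ceac: empty willingness-to-pay grid", call. = FALSE)
  if (nrow(draws) == 0) stop("ceac: empty draw set", call. = FALSE)
  dc <- draws[[paste0("d_cost_", perspective)]]
  dq <- draws$d_qaly
  prob <- vapply(wtp_grid, function(l) mean(l * dq - dc > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Probability that the intervention is cost-saving
#'
#' Fraction of PSA draws with negative incremental cost.
#'
#' @inheritParams ceac
#' @return Probability in `[0, 1]`.
#' @export
prob_cost_saving <- function(draws, perspective = c("payer", "societal")) {
  perspective <- match.arg(perspective)
  if (nrow(draws) == 0) stop("prob_cost_saving: empty draw set", call. = FALSE)
  mean(draws[[paste0("d_cost_", perspective)]] < 0)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Reruns the deterministic model at each bound of each parameter range, one
#' at a time, and reports the net monetary benefit at 30000 euros/QALY and
#' the ICER or dominance status per bound, ordered by descending output
#' range. Default drivers: acute stroke unit cost, pre-AF substrate
#' prevalence, screening sensitivity and specificity, and the disability
#' rate.
#'
#' @param bc A [run_base_case()] result.
#' @param ranges Named list of length-2 numeric ranges bracketing the base
#'   value; see Details for the recognised names.
#' @param wtp Willingness-to-pay for the NMB column (default 30000).
#' @return Data frame of class `tornado_result`: one row per parameter and
#'   bound with `nmb`, `d_cost_payer`, `d_qaly`, `status`, plus the
#'   per-parameter `range` used for ordering.
#' @export
one_way_dsa <- function(bc, ranges = default_dsa_ranges(), wtp = 30000) {
  base_vals <- c(stroke_acute_cost_factor = 1,
                 substrate_prevalence = bc$profile$pre_af_substrate_prevalence,
                 screening_sensitivity = bc$populations$women$arm$cascade$sensitivity,
                 screening_specificity = bc$populations$women$arm$cascade$specificity,
                 disability_rate_factor = 1)
  rows <- list()
  for (pn in names(ranges)) {
    rg <- ranges[[pn]]
    stopifnot(length(rg) == 2, rg[1] <= rg[2])
    if (pn %in% names(base_vals) &&
        (base_vals[[pn]] < rg[1] || base_vals[[pn]] > rg[2]))
      stop("one_way_dsa: range for ", pn, " does not bracket the base value",
           call. = FALSE)
    for (bound in c("low", "high")) {
      v <- if (bound == "low") rg[1] else rg[2]
      ov <- switch(pn,
        stroke_acute_cost_factor = list(cost_factors = c(stroke_acute = v)),
        substrate_prevalence = list(substrate_prevalence = v),
        screening_sensitivity = list(screening_sensitivity = v),
        screening_specificity = list(screening_specificity = v),
        disability_rate_factor = list(disability_baseline_factor = v),
        stop("one_way_dsa: unknown parameter ", pn, call. = FALSE))
      res <- evaluate_scenario(bc, ov)
      ce <- incremental(res$arms$intervention$payer, res$arms$usual_care$payer,
                        res$arms$intervention$qaly, res$arms$usual_care$qaly,
                        wtp)
      rows[[paste(pn, bound)]] <- data.frame(
        parameter = pn, bound = bound, value = v,
        d_cost_payer = res$d_cost_payer, d_qaly = res$d_qaly,
        nmb = ce$nmb[[1]], status = ce$status)
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  spread <- tapply(out$nmb, out$parameter, function(x) diff(range(x)))
  out$range <- as.numeric(spread[out$parameter])
  out <- out[order(-out$range, out$parameter, out$bound), ]
  rownames(out) <- NULL
  class(out) <- c("tornado_result", "data.frame")
  out
}

#' @rdname one_way_dsa
#' @export
default_dsa_ranges <- function() {
  list(stroke_acute_cost_factor = c(0.75, 1.25),
       substrate_prevalence = c(0.05, 0.30),
       screening_sensitivity = c(0.70, 0.95),
       screening_specificity = c(0.70, 0.95),
       disability_rate_factor = c(0.75, 1.25))
}
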