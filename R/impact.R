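#' Population-impact strata shares from a cohort
#'
#' Proportions of a synthetic cohort in each population-impact stratum
#' (see [assign_pip_stratum()]).
#'
#' @param cohort A cohort data frame; a `pip_stratum` column is added if
#'   absent.
#' @param high_threshold Secondary score threshold (see
#'   [assign_pip_stratum()]).
#' @return Named numeric shares summing to 1.
#' @export
pip_shares <- function(cohort, high_threshold = 3) {
  if (is.null(cohort$pip_stratum))
    cohort <- add_pip_stratum(cohort, high_threshold)
  prop.table(table(cohort$pip_stratum))
}

#' Per-stratum population impact of the intervention
#'
#' Runs both arms per risk stratum and sex with the stratum's baseline-risk
#' multiplier applied to the AF-onset and MACE intensities (identical
#' stratification thresholds and model structure across sexes; only baseline
#' risks, costs and utilities differ by sex). The multipliers are normalised
#' so that their share-weighted mean is 1, preserving the pooled
#' calibration. Returns per-capita and total events avoided, QALYs gained
#' and payer savings per stratum, for each sex and pooled.
#'
#' @param bc A [run_base_case()] result.
#' @param shares Named stratum shares (`very_high`, `high`,
#'   `moderate_high`) summing to 1, e.g. from [pip_shares()].
#' @param multipliers Baseline-risk multipliers per stratum before
#'   normalisation (default 1.6 / 1.0 / 0.6).
#' @param cohort_size Reference cohort size for totals (default 1000).
#' @return Data frame of class `pip_result`: one row per (stratum, sex)
#'   including `"pooled"`, with `share`, `risk_multiplier`, per-capita and
#'   total strokes and MACE avoided, `qalys_gained`, `savings`.
#' @export
pip_compute <- function(bc, shares,
                        multipliers = c(very_high = 1.6, high = 1.0,
                                        moderate_high = 0.6),
                        cohort_size = 1000) {
  strata <- c("very_high", "high", "moderate_high")
  shares <- shares[strata]
  stopifnot(!any(is.na(shares)), abs(sum(shares) - 1) < 1e-9,
            all(names(multipliers) == strata))
  mult <- multipliers / sum(shares * multipliers)

  rows <- list()
  for (st in strata) {
    if (shares[[st]] == 0) {
      warning("pip_compute: empty stratum ", st, call. = FALSE)
    }
    per_sex <- lapply(c(women = "women", men = "men"), function(popn) {
      pop <- bc$populations[[popn]]
      model <- pop$fit_uc$model
      model$rates[c("af_onset", "mace")] <-
        model$rates[c("af_onset", "mace")] * mult[[st]]
      tr_uc <- run_cohort(model, strategy_arm("usual_care"), start_age = bc$start_age)
      tr_i <- run_cohort(model, pop$arm, start_age = bc$start_age)
      u75 <- under75_share(bc$profile, tr_uc$n_cycles)
      cost_uc <- accumulate_costs(tr_uc, bc$econ, pop$unit_costs$usual_care,
                                  "payer", u75 = u75)$total
      cost_i <- accumulate_costs(tr_i, bc$econ, pop$unit_costs$intervention,
                                 "payer", u75 = u75)$total
      c(strokes_avoided_per_1000 =
          tr_uc$cum_per_1000[["strokes"]] - tr_i$cum_per_1000[["strokes"]],
        mace_avoided_per_1000 =
          tr_uc$cum_per_1000[["mace"]] - tr_i$cum_per_1000[["mace"]],
        qalys_gained_per_1000 =
          accumulate_qalys(tr_i, bc$econ) - accumulate_qalys(tr_uc, bc$econ),
        savings_per_1000 = cost_uc - cost_i)
    })
    pooled <- bc$sex_weights[["female"]] * per_sex$women +
              bc$sex_weights[["male"]] * per_sex$men
    for (sx in c("women", "men")) {
      v <- per_sex[[sx]]
      rows[[paste(st, sx)]] <- data.frame(
        stratum = st, sex = sx, share = shares[[st]],
        risk_multiplier = mult[[st]], t(v))
    }
    rows[[paste(st, "pooled")]] <- data.frame(
      stratum = st, sex = "pooled", share = shares[[st]],
      risk_multiplier = mult[[st]], t(pooled))
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  n_st <- out$share * cohort_size
  out$strokes_avoided_total <- out$strokes_avoided_per_1000 / 1000 * n_st
  out$mace_avoided_total <- out$mace_avoided_per_1000 / 1000 * n_st
  out$qalys_gained_total <- out$qalys_gained_per_1000 / 1000 * n_st
  out$savings_total <- out$savings_per_1000 / 1000 * n_st
  class(out) <- c("pip_result", "data.frame")
  out
}

#' Short-horizon budget impact
#'
#' Truncates both arms' per-cycle cost streams at a 3-5 year horizon
#' (undiscounted by default, the usual convention for budget impact): the
#' yearly net position is the incremental screening and anticoagulation
#' spend minus the savings from avoided acute strokes, non-stroke MACE
#' hospitalisations and long-term care, scaled by the yearly uptake
#' fraction. The cumulative position is the running sum of yearly nets.
#'
#' @param bc A [run_base_case()] result.
#' @param horizon_years Horizon in years; 3-5 expected (other values are
#'   allowed with a warning).
#' @param uptake Uptake fraction per year, in `[0, 1]`; recycled defaults to
#'   full uptake from year 1.
#' @param discounted Apply the economic discount rate (default FALSE).
#' @param perspective `"payer"`, `"societal"` or `"combined"`.
#' @return Data frame of class `budget_impact`: per year,
#'   `additional_spend` (components with positive increments),
#'   `offsets` (negative increments), `net`, `cumulative`.
#' @export
budget_impact <- function(bc, horizon_years = 5,
                          uptake = rep(1, horizon_years),
                          discounted = FALSE,
                          perspective = c("payer", "societal", "combined")) {
  perspective <- match.arg(perspective)
  if (horizon_years < 3 || horizon_years > 5)
    warning("budget_impact: horizon outside the 3-5 year convention",
            call. = FALSE)
  stopifnot(length(uptake) == horizon_years, all(uptake >= 0 & uptake <= 1))
  costs <- bc$populations$overall$costs
  field <- if (discounted) "by_cycle_discounted" else "by_cycle"
  uc <- costs$usual_care[[perspective]][[field]]
  iv <- costs$intervention[[perspective]][[field]]
  stopifnot(horizon_years <= nrow(uc))
  yrs <- seq_len(horizon_years)
  inc <- (iv[yrs, , drop = FALSE] - uc[yrs, , drop = FALSE]) * uptake
  additional <- rowSums(pmax(inc, 0))
  offsets <- rowSums(pmin(inc, 0))
  net <- additional + offsets
  structure(data.frame(year = yrs, uptake = uptake,
                       additional_spend = additional, offsets = offsets,
                       net = net, cumulative = cumsum(net)),
            class = c("budget_impact", "data.frame"))
}
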