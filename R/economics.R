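#' Economic inputs
#'
#' Bundles the published aggregate cost tables (payer and societal, per 1000
#' individuals per arm), the state utility weights, the annual discount rate
#' and the willingness-to-pay grid. Unit costs per event or state-year are
#' not published; they are fitted per component and arm by
#' [fit_unit_costs()] so that the calibrated traces reproduce the printed
#' aggregates exactly, which makes every accounting step testable against
#' the published cells.
#'
#' The default utility set is not sourced from the publication (which states
#' none); it is a plausible ordering for this population and QALY magnitudes
#' are reported as sensitive to it: high-risk 0.80, pre-AF substrate 0.80,
#' detected AF 0.75, post-MACE 0.65, disability 0.40, death 0.
#'
#' @param payer_path,societal_path CSV fixtures of the aggregate cost
#'   tables.
#' @param utilities Named utility weights for the six states, in `[0, 1]`,
#'   death exactly 0.
#' @param discount_rate Annual discount rate for costs and QALYs
#'   (default 0.03).
#' @param wtp_grid Willingness-to-pay grid in euros per QALY (includes
#'   30000).
#' @return Object of class `econ_inputs`.
#' @export
econ_inputs <- function(payer_path = system.file("extdata", "costs_payer.csv",
                                                 package = "afcea"),
                        societal_path = system.file("extdata", "costs_societal.csv",
                                                    package = "afcea"),
                        utilities = default_utilities(),
                        discount_rate = 0.03,
                        wtp_grid = seq(0, 100000, by = 1000)) {
  stopifnot(discount_rate >= 0, all(utilities >= 0 & utilities <= 1),
            utilities[["DEATH"]] == 0,
            setequal(names(utilities), health_states()))
  payer <- utils::read.csv(payer_path, stringsAsFactors = FALSE)
  societal <- utils::read.csv(societal_path, stringsAsFactors = FALSE)
  stopifnot(all(payer$usual_care >= 0), all(societal$usual_care >= 0))
  structure(list(payer = payer, societal = societal,
                 utilities = utilities[health_states()],
                 discount_rate = discount_rate,
                 wtp_grid = wtp_grid,
                 allocation = component_allocation()),
            class = "econ_inputs")
}

#' @rdname econ_inputs
#' @export
default_utilities <- function() {
  c(HIGH_RISK_NO_AF = 0.80, PRE_AF_SUBSTRATE = 0.80, DETECTED_AF = 0.75,
    POST_MACE = 0.65, DISABILITY = 0.40, DEATH = 0)
}

# component -> driver map; occupancy drivers get the half-cycle correction,
# event (flux) drivers do not
component_allocation <- function() {
  c(screening_diagnostics = "alive_py",
    anticoagulation = "af_py",
    stroke_acute = "stroke_events",
    longterm_disability = "dis_py",
    nonstroke_mace_hosp = "nonstroke_mace_events",
    informal_caregiving = "dis_py",
    longterm_social_care = "dis_py",
    nursing_home = "dis_py",
    productivity_under75 = "under75_py")
}

#' Discount a flow
#'
#' `amount / (1 + rate)^year_index`, the standard annual discounting used
#' for costs and QALYs.
#'
#' @param amount Numeric flow (vectorised).
#' @param year_index Zero-based year (cycle) index.
#' @param rate Annual discount rate.
#' @return Discounted amount.
#' @export
discount <- function(amount, year_index, rate = 0.03) {
  if (any(year_index < 0)) stop("discount: negative year_index", call. = FALSE)
  stopifnot(rate >= 0)
  amount / (1 + rate)^year_index
}

#' Share of survivors younger than 75 by cycle
#'
#' Computed from the cohort's truncated-normal entry-age distribution
#' (differential mortality by age is not tracked within the cohort
#' recursion): the probability that entry age is below `75 - (t - 0.5)` at
#' mid-cycle `t`, under the profile's truncation bounds. Used to allocate
#' productivity losses, which apply only below age 75.
#'
#' @param profile A [cohort_profile()].
#' @param n_cycles Number of cycles.
#' @return Numeric vector of length `n_cycles`, in `[0, 1]`.
#' @export
under75_share <- function(profile, n_cycles) {
  a <- profile$age
  mu <- truncnorm_location(a$mean, a$sd, a$min, a$max)
  z <- function(x) stats::pnorm((x - mu) / a$sd)
  denom <- z(a$max) - z(a$min)
  mids <- 75 - (seq_len(n_cycles) - 0.5)
  pmax((z(pmin(pmax(mids, a$min), a$max)) - z(a$min)) / denom, 0)
}

# per-cycle driver quantities (per person); occupancy drivers half-cycle
# corrected; returns list(by_cycle matrix, discounted totals, undiscounted
# by-cycle matrix)
cost_drivers <- function(trace, discount_rate, u75 = NULL, half_cycle = TRUE) {
  t_n <- trace$n_cycles
  occ0 <- trace$occupancy[seq_len(t_n), , drop = FALSE]
  occ1 <- trace$occupancy[seq_len(t_n) + 1, , drop = FALSE]
  occ <- if (half_cycle) (occ0 + occ1) / 2 else occ0
  if (is.null(u75)) u75 <- rep(0, t_n)
  stopifnot(length(u75) == t_n)
  strokes <- trace$events$strokes
  drivers <- cbind(
    alive_py = rowSums(occ[, 1:5, drop = FALSE]),
    af_py = occ[, 3],
    dis_py = occ[, 5],
    stroke_events = strokes,
    nonstroke_mace_events = trace$events$mace - strokes,
    under75_py = rowSums(occ[, 1:5, drop = FALSE]) * u75)
  df <- 1 / (1 + discount_rate)^(seq_len(t_n) - 1)
  list(by_cycle = drivers, discounted = colSums(drivers * df),
       discount_factors = df)
}

#' Fit unit costs to published aggregate components
#'
#' For each cost component, solves for the unit cost per driver unit (event
#' or state-year) such that the discounted lifetime accumulation over the
#' given trace equals the published per-1000 aggregate: a one-step linear
#' solve per component and arm.
#'
#' @param trace A `markov_trace` for the arm.
#' @param component_totals Named published aggregates per 1000 (euros).
#' @param inputs An [econ_inputs()].
#' @param u75 Optional under-75 share vector (see [under75_share()]).
#' @return Named unit costs (euros per driver unit).
#' @export
fit_unit_costs <- function(trace, component_totals, inputs, u75 = NULL) {
  alloc <- inputs$allocation
  stopifnot(all(names(component_totals) %in% names(alloc)))
  d <- cost_drivers(trace, inputs$discount_rate, u75 = u75)
  q <- d$discounted[alloc[names(component_totals)]] * 1000
  if (any(q <= 0 & component_totals > 0))
    stop("fit_unit_costs: zero driver quantity for a non-zero component",
         call. = FALSE)
  out <- ifelse(q > 0, component_totals / q, 0)
  names(out) <- names(component_totals)
  out
}

#' Accumulate discounted costs from a trace
#'
#' Per-component totals per 1000 individuals: the sum over cycles of
#' allocated driver flows times unit costs times the discount factor, with
#' the half-cycle correction applied to occupancy-allocated components
#' (event-flux components are not corrected). The grand total equals the sum
#' of components exactly.
#'
#' @param trace A `markov_trace`.
#' @param inputs An [econ_inputs()].
#' @param unit_costs Named unit costs from [fit_unit_costs()]; components
#'   without an allocation rule raise an error.
#' @param perspective `"payer"`, `"societal"` or `"combined"` (selects which
#'   components enter the total; all fitted components are reported).
#' @param u75 Optional under-75 share vector.
#' @return List of class `cost_result`: `components` (named totals),
#'   `total`, `by_cycle` (undiscounted per-cycle component matrix, for
#'   budget-impact truncation), `by_cycle_discounted`, `perspective`.
#' @export
accumulate_costs <- function(trace, inputs, unit_costs,
                             perspective = c("payer", "societal", "combined"),
                             u75 = NULL) {
  perspective <- match.arg(perspective)
  alloc <- inputs$allocation
  unknown <- setdiff(names(unit_costs), names(alloc))
  if (length(unknown))
    stop("accumulate_costs: no allocation rule for component(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  payer_set <- c("screening_diagnostics", "anticoagulation", "stroke_acute",
                 "longterm_disability", "nonstroke_mace_hosp")
  keep <- switch(perspective,
                 payer = intersect(names(unit_costs), payer_set),
                 societal = setdiff(names(unit_costs), payer_set),
                 combined = names(unit_costs))
  d <- cost_drivers(trace, inputs$discount_rate, u75 = u75)
  by_cycle <- sapply(keep, function(comp)
    d$by_cycle[, alloc[[comp]]] * unit_costs[[comp]] * 1000)
  by_cycle <- matrix(by_cycle, nrow = trace$n_cycles,
                     dimnames = list(NULL, keep))
  by_cycle_disc <- by_cycle * d$discount_factors
  components <- colSums(by_cycle_disc)
  list(components = components, total = sum(components),
       by_cycle = by_cycle, by_cycle_discounted = by_cycle_disc,
       perspective = perspective)
}

#' Accumulate discounted QALYs from a trace
#'
#' Sum over cycles of occupancy-weighted utility times the discount factor
#' times the cycle length, half-cycle corrected, scaled per 1000
#' individuals.
#'
#' @param trace A `markov_trace`.
#' @param inputs An [econ_inputs()] (supplies utilities and discount rate).
#' @param half_cycle Apply the half-cycle correction (default TRUE).
#' @return Discounted QALYs per 1000.
#' @export
accumulate_qalys <- function(trace, inputs, half_cycle = TRUE) {
  u <- inputs$utilities[colnames(trace$occupancy)]
  if (any(is.na(u))) stop("accumulate_qalys: missing utility", call. = FALSE)
  t_n <- trace$n_cycles
  occ0 <- trace$occupancy[seq_len(t_n), , drop = FALSE]
  occ1 <- trace$occupancy[seq_len(t_n) + 1, , drop = FALSE]
  occ <- if (half_cycle) (occ0 + occ1) / 2 else occ0
  df <- 1 / (1 + inputs$discount_rate)^(seq_len(t_n) - 1)
  sum((occ %*% u) * df) * trace$cycle_length * 1000
}

#' Incremental cost-effectiveness results
#'
#' Incremental cost and QALYs (intervention minus comparator), the ICER when
#' the signs admit one, dominance flags, and net monetary benefit
#' `nmb(lambda) = lambda * dQALY - dCost` over the willingness-to-pay grid.
#'
#' @param cost_i,cost_c Total discounted cost per 1000, intervention and
#'   comparator.
#' @param qaly_i,qaly_c Discounted QALYs per 1000.
#' @param wtp_grid Willingness-to-pay grid (euros/QALY).
#' @return List of class `ce_result`: `d_cost`, `d_qaly`, `icer` (number or
#'   NA), `status` (`"dominant"`, `"dominated"`, `"icer"`, `"equivalent"`,
#'   `"undefined"`), `nmb` (named by lambda).
#' @export
incremental <- function(cost_i, cost_c, qaly_i, qaly_c,
                        wtp_grid = seq(0, 100000, by = 1000)) {
  d_cost <- cost_i - cost_c
  d_qaly <- qaly_i - qaly_c
  nmb <- stats::setNames(wtp_grid * d_qaly - d_cost, wtp_grid)
  status <- if (d_cost < 0 && d_qaly > 0) "dominant"
            else if (d_cost > 0 && d_qaly < 0) "dominated"
            else if (d_qaly == 0 && d_cost == 0) "equivalent"
            else if (d_qaly == 0) "undefined"
            else "icer"
  icer <- if (status == "icer") d_cost / d_qaly else NA_real_
  structure(list(d_cost = d_cost, d_qaly = d_qaly, icer = icer,
                 status = status, nmb = nmb),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("<ce_result> dCost = %.0f, dQALY = %.1f, %s\n",
              x$d_cost, x$d_qaly,
              if (x$status == "icer") sprintf("ICER = %.0f/QALY", x$icer)
              else toupper(x$status)))
  invisible(x)
}
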