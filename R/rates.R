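#' Sex-specific incidence fixture
#'
#' Loads the per-event, per-sex incidence table for the top predicted-AF-risk
#' quartile (Q4) and the incident-AF subgroup: numbers at risk, event counts,
#' crude rates per 1000 person-years with 95% CIs, and the printed
#' men-to-women ratio column. Invariants (counts within denominators, rate
#' inside its CI) are validated on read.
#'
#' @param path CSV path; defaults to the shipped fixture.
#' @return A data frame with columns `event`, `sex`, `subgroup`,
#'   `n_at_risk`, `events`, `rate`, `ci_low`, `ci_high`, `printed_ratio`.
#' @export
load_incidence <- function(path = system.file("extdata", "incidence_q4.csv",
                                              package = "afcea")) {
  inc <- utils::read.csv(path, stringsAsFactors = FALSE)
  with(inc, {
    if (any(!is.na(events) & (events < 0 | events > n_at_risk)))
      stop("incidence fixture: event counts must lie in [0, n_at_risk]", call. = FALSE)
    if (any(rate > 0 & !is.na(events) & events == 0))
      stop("incidence fixture: positive rate with zero events", call. = FALSE)
    if (any(ci_low > rate | rate > ci_high))
      stop("incidence fixture: rate outside its confidence interval", call. = FALSE)
  })
  inc
}

#' Convert an incidence rate to a per-cycle transition probability
#'
#' Standard constant-hazard (exponential) conversion for an annual-cycle
#' Markov model: `p = 1 - exp(-rate/1000 * cycle_length)` for a rate
#' expressed per 1000 person-years.
#'
#' @param rate Non-negative rate per 1000 person-years (vectorised).
#' @param cycle_length Cycle length in years (default 1).
#' @return Probability in `[0, 1)`.
#' @export
rate_to_prob <- function(rate, cycle_length = 1) {
  if (any(rate < 0)) stop("rate_to_prob: negative rate", call. = FALSE)
  stopifnot(cycle_length > 0)
  1 - exp(-rate / 1000 * cycle_length)
}

#' Convert a per-cycle probability back to a rate per 1000 person-years
#'
#' Inverse of [rate_to_prob()] on the shared domain.
#'
#' @param p Probability in `[0, 1)` (vectorised).
#' @inheritParams rate_to_prob
#' @return Rate per 1000 person-years.
#' @export
prob_to_rate <- function(p, cycle_length = 1) {
  if (any(p < 0 | p >= 1)) stop("prob_to_rate: p must lie in [0, 1)", call. = FALSE)
  stopifnot(cycle_length > 0)
  -log(1 - p) / cycle_length * 1000
}

#' Men-to-women cumulative incidence ratio
#'
#' Ratio of cumulative incidence proportions computed from raw counts,
#' `(events_m / n_m) / (events_f / n_f)`. This reproduces the published
#' men/women ratio column when truncated (not rounded) to two decimals; see
#' [incidence_ratio_table()].
#'
#' @param events_m,n_m,events_f,n_f Event counts and denominators.
#' @return The ratio (numeric scalar or vector).
#' @export
cumulative_risk_ratio <- function(events_m, n_m, events_f, n_f) {
  if (any(c(n_m, n_f) <= 0) || any(c(events_m, events_f) < 0))
    stop("cumulative_risk_ratio: counts must be positive", call. = FALSE)
  if (any(events_m > n_m) || any(events_f > n_f))
    stop("cumulative_risk_ratio: events exceed denominator", call. = FALSE)
  if (any(events_f == 0))
    stop("cumulative_risk_ratio: zero events in denominator group, ratio undefined",
         call. = FALSE)
  (events_m / n_m) / (events_f / n_f)
}

# truncate to k decimals (towards zero) -- the rounding convention of the
# published ratio column
trunc_decimals <- function(x, k = 2) trunc(x * 10^k) / 10^k

#' Recompute the published men/women ratio column
#'
#' For each event in a subgroup, recomputes the men-to-women ratio from
#' counts (cumulative incidence ratio) where counts are printed, and from
#' crude rates where they are not (AF), and reports it alongside the printed
#' value both truncated and rounded to two decimals. Truncation reproduces
#' the printed column for every row.
#'
#' @param inc Incidence table from [load_incidence()].
#' @param subgroup Subgroup to tabulate (default `"q4_high_af_risk"`).
#' @return Data frame with columns `event`, `ratio` (full precision),
#'   `ratio_trunc2`, `ratio_round2`, `printed`.
#' @export
incidence_ratio_table <- function(inc = load_incidence(),
                                  subgroup = "q4_high_af_risk") {
  inc <- inc[inc$subgroup == subgroup, ]
  events <- unique(inc$event)
  rows <- lapply(events, function(ev) {
    m <- inc[inc$event == ev & inc$sex == "male", ]
    f <- inc[inc$event == ev & inc$sex == "female", ]
    ratio <- if (is.na(m$events) || is.na(f$events)) m$rate / f$rate
             else cumulative_risk_ratio(m$events, m$n_at_risk, f$events, f$n_at_risk)
    data.frame(event = ev, ratio = ratio,
               ratio_trunc2 = trunc_decimals(ratio, 2),
               ratio_round2 = round(ratio, 2),
               printed = m$printed_ratio)
  })
  do.call(rbind, rows)
}
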