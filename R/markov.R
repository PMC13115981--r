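#' Health states of the cohort model
#'
#' The six mutually exclusive states of the annual-cycle model: high risk
#' without AF, pre-AF substrate (subclinical atrial cardiomyopathy), detected
#' AF, post-MACE, disability and dependency, and death (absorbing).
#'
#' @return Character vector of the six state names, in transition-matrix
#'   order.
#' @export
health_states <- function() {
  c("HIGH_RISK_NO_AF", "PRE_AF_SUBSTRATE", "DETECTED_AF",
    "POST_MACE", "DISABILITY", "DEATH")
}

#' Construct a sex-specific transition model
#'
#' Holds the per-1000-person-year intensities that generate the per-cycle
#' transition matrices, together with calibration multipliers per event
#' channel and the structural parameters of the state diagram. Base AF-onset
#' and all-cause-death intensities are seeded from the observed top-quartile
#' incidence rates; the MACE and disability-entry channels are free
#' parameters whose multipliers are fitted by [calibrate()], and the
#' stroke-within-MACE and cardiovascular-death shares are accounting splits
#' fitted alongside them.
#'
#' @param sex `"female"` or `"male"`; selects the incidence rows.
#' @param incidence Incidence table from [load_incidence()].
#' @param substrate_prevalence Fraction of the cohort starting in the pre-AF
#'   substrate state (default 0.15; not an observed quantity, swept in DSA).
#' @param substrate_entry_rate Intensity (per 1000 py) of progression from
#'   high-risk to the substrate state.
#' @param substrate_hr Multiplier on AF-onset and MACE intensities while in
#'   the substrate state (default 2).
#' @param af_mace_hr Multiplier on the MACE intensity while in detected AF.
#' @param base_mace_rate Base MACE intensity per 1000 py before calibration;
#'   defaults to the sum of the observed stroke/TIA and ischaemic heart
#'   disease rates for the sex.
#' @param base_disability_rate Base post-MACE to disability intensity per
#'   1000 py before calibration.
#' @param stroke_share Base fraction of MACE events that are ischaemic
#'   strokes (refined by calibration).
#' @param cv_death_share Base fraction of deaths from the post-MACE and
#'   disability states attributed to cardiovascular causes (refined by
#'   calibration).
#' @param post_mace_death_hr,disability_death_hr Multipliers on background
#'   mortality in the post-MACE and disability states.
#' @param gompertz_b Optional per-cycle log-linear aging slope on background
#'   mortality (default 0: flat observed rates; lifetime calibration absorbs
#'   age effects).
#' @param multipliers Named calibration multipliers per channel; all 1 before
#'   calibration.
#' @param cycle_length Cycle length in years (fixed at 1 in the analyses).
#' @return An object of class `transition_model`.
#' @export
transition_model <- function(sex = c("female", "male"),
                             incidence = load_incidence(),
                             substrate_prevalence = 0.15,
                             substrate_entry_rate = 20,
                             substrate_hr = 2,
                             af_mace_hr = 2,
                             base_mace_rate = NULL,
                             base_disability_rate = 100,
                             stroke_share = 0.40,
                             cv_death_share = 0.50,
                             post_mace_death_hr = 3,
                             disability_death_hr = 5,
                             gompertz_b = 0,
                             multipliers = NULL,
                             cycle_length = 1) {
  sex <- match.arg(sex)
  q4 <- incidence[incidence$subgroup == "q4_high_af_risk" & incidence$sex == sex, ]
  pick <- function(ev) q4$rate[q4$event == ev]
  af_rate <- pick("af")
  death_rate <- pick("death_all_cause")
  if (is.null(base_mace_rate))
    base_mace_rate <- pick("stroke_tia") + pick("ihd")
  if (is.null(multipliers))
    multipliers <- c(af_onset = 1, mace = 1, stroke_within_mace = 1,
                     disability_entry = 1, cv_death_share = 1,
                     background_death = 1)
  stopifnot(all(multipliers > 0),
            substrate_prevalence >= 0, substrate_prevalence <= 1,
            af_rate >= 0, death_rate >= 0, base_mace_rate >= 0,
            base_disability_rate >= 0,
            stroke_share > 0, stroke_share < 1,
            cv_death_share > 0, cv_death_share <= 1)
  structure(list(
    sex = sex,
    rates = c(af_onset = af_rate, mace = base_mace_rate,
              disability_entry = base_disability_rate,
              background_death = death_rate,
              substrate_entry = substrate_entry_rate),
    shares = c(stroke_within_mace = stroke_share,
               cv_death_share = cv_death_share),
    structure = c(substrate_prevalence = substrate_prevalence,
                  substrate_hr = substrate_hr,
                  af_mace_hr = af_mace_hr,
                  post_mace_death_hr = post_mace_death_hr,
                  disability_death_hr = disability_death_hr,
                  gompertz_b = gompertz_b),
    multipliers = multipliers,
    cycle_length = cycle_length
  ), class = "transition_model")
}

#' Define a strategy arm
#'
#' Usual care is the comparator (all hazard ratios 1: opportunistic AF
#' detection and score-guided anticoagulation). The intervention arm applies
#' hazard ratios per event channel — fitted in reduced form against the
#' published lifetime outcome column by [apply_strategy_effect()], or
#' composed mechanistically from the detection cascade (top-quartile
#' selection, device screening sensitivity/specificity, anticoagulation
#' uptake and the anticoagulant stroke hazard ratio). Effects are constant
#' over cycles.
#'
#' @param name `"usual_care"` or `"mathias"` (the AI-guided arm).
#' @param parameterization `"reduced_form"` or `"mechanistic"`.
#' @param hazard_ratios Named positive hazard ratios per channel
#'   (`af_onset`, `mace`, `stroke_within_mace`, `disability_entry`,
#'   `cv_death_share`, `background_death`); missing entries default to 1.
#' @param cascade Mechanistic cascade parameters: `q4_selection`,
#'   `sensitivity`, `specificity`, `uptake` (probabilities) and
#'   `oac_stroke_hr` (stroke hazard ratio on anticoagulation).
#' @return Object of class `strategy_arm`.
#' @export
strategy_arm <- function(name = c("usual_care", "mathias"),
                         parameterization = c("reduced_form", "mechanistic"),
                         hazard_ratios = NULL,
                         cascade = list(q4_selection = 1, sensitivity = 0.90,
                                        specificity = 0.85, uptake = 0.85,
                                        oac_stroke_hr = 0.36)) {
  name <- match.arg(name)
  parameterization <- match.arg(parameterization)
  hr <- c(af_onset = 1, mace = 1, stroke_within_mace = 1,
          disability_entry = 1, cv_death_share = 1, background_death = 1)
  if (!is.null(hazard_ratios)) {
    stopifnot(all(names(hazard_ratios) %in% names(hr)), all(hazard_ratios > 0))
    hr[names(hazard_ratios)] <- hazard_ratios
  }
  if (name == "usual_care" && any(hr != 1))
    stop("strategy_arm: usual care must have all hazard ratios equal to 1",
         call. = FALSE)
  probs <- unlist(cascade[c("q4_selection", "sensitivity", "specificity", "uptake")])
  stopifnot(all(probs >= 0 & probs <= 1), cascade$oac_stroke_hr > 0)
  structure(list(name = name, parameterization = parameterization,
                 hazard_ratios = hr, cascade = cascade),
            class = "strategy_arm")
}

# Effective per-channel hazard ratios for an arm given a model.  In
# mechanistic mode the cascade protects a fraction p = q4 x sensitivity x
# uptake of the cohort, whose stroke hazard is multiplied by the
# anticoagulant hazard ratio; composed onto the MACE channel through the
# current stroke share s:
#   hr_stroke = 1 - p (1 - oac_hr)
#   hr_mace   = 1 - s + s hr_stroke
#   hr_share  = hr_stroke / hr_mace
effective_hazard_ratios <- function(model, arm) {
  hr <- arm$hazard_ratios
  if (arm$name == "mathias" && arm$parameterization == "mechanistic") {
    cs <- arm$cascade
    p <- cs$q4_selection * cs$sensitivity * cs$uptake
    hr_stroke <- 1 - p * (1 - cs$oac_stroke_hr)
    s <- effective_share(model, hr_share = 1)["stroke_within_mace"]
    hr["mace"] <- hr["mace"] * (1 - s + s * hr_stroke)
    hr["stroke_within_mace"] <- hr_stroke / (1 - s + s * hr_stroke)
  }
  hr
}

# effective accounting shares after multipliers and arm hazard ratios (capped)
effective_share <- function(model, hr_share = 1, hr_cv = 1) {
  c(stroke_within_mace = min(unname(
      model$shares["stroke_within_mace"] *
      model$multipliers["stroke_within_mace"] * hr_share), 0.999),
    cv_death_share = min(unname(
      model$shares["cv_death_share"] *
      model$multipliers["cv_death_share"] * hr_cv), 1))
}

#' Build the per-cycle transition matrix
#'
#' Converts the model's outgoing intensities into a 6x6 row-stochastic
#' matrix: per row, the total exit intensity is converted to an exit
#' probability through the exponential formula and allocated across
#' destinations in proportion to their intensities (standard competing-risk
#' resolution); the diagonal holds the stay probability and the death row is
#' the unit vector on death.
#'
#' @param model A [transition_model()].
#' @param arm A [strategy_arm()].
#' @param cycle_index Zero-based cycle index (only used when the aging slope
#'   is active).
#' @return A 6x6 row-stochastic matrix with dimnames [health_states()].
#' @export
build_cycle_matrix <- function(model, arm = strategy_arm("usual_care"),
                               cycle_index = 0) {
  hr <- effective_hazard_ratios(model, arm)
  m <- model$multipliers
  r <- model$rates
  s <- model$structure
  aging <- exp(s[["gompertz_b"]] * cycle_index)

  af  <- r[["af_onset"]] * m[["af_onset"]] * hr[["af_onset"]]
  mc  <- r[["mace"]] * m[["mace"]] * hr[["mace"]]
  dis <- r[["disability_entry"]] * m[["disability_entry"]] * hr[["disability_entry"]]
  dth <- r[["background_death"]] * m[["background_death"]] * hr[["background_death"]] * aging
  sub <- r[["substrate_entry"]]

  k <- matrix(0, 6, 6, dimnames = list(health_states(), health_states()))
  k[1, ] <- c(0, sub, af, mc, 0, dth)
  k[2, ] <- c(0, 0, af * s[["substrate_hr"]], mc * s[["substrate_hr"]], 0, dth)
  k[3, ] <- c(0, 0, 0, mc * s[["af_mace_hr"]], 0, dth)
  k[4, ] <- c(0, 0, 0, 0, dis, dth * s[["post_mace_death_hr"]])
  k[5, ] <- c(0, 0, 0, 0, 0, dth * s[["disability_death_hr"]])

  if (any(k < 0))
    stop("build_cycle_matrix: negative intensity", call. = FALSE)

  p <- diag(6)
  dimnames(p) <- dimnames(k)
  for (i in 1:5) {
    lam <- sum(k[i, ]) / 1000 * model$cycle_length
    if (lam > 0) {
      exit <- 1 - exp(-lam)
      p[i, ] <- exit * k[i, ] / sum(k[i, ])
      p[i, i] <- exp(-lam)
    }
  }
  p
}

#' Run the cohort model over the lifetime horizon
#'
#' Deterministic cohort recursion with annual cycles from the starting age
#' until age 95 (or until the death state holds more than `stop_death` of
#' the cohort). Event flows are computed from transition fluxes, not from
#' occupancy differences: incident MACE is the flux into the post-MACE
#' state, ischaemic strokes are the stroke share of that flux, disability
#' entries are the post-MACE to disability flux, and cardiovascular deaths
#' are the CV share of deaths occurring from the post-MACE and disability
#' states.
#'
#' @param model A [transition_model()].
#' @param arm A [strategy_arm()].
#' @param init Initial occupancy over the six states; defaults to everyone
#'   alive and AF-free, split between the high-risk and substrate states by
#'   the model's substrate prevalence.
#' @param start_age Cohort mean age at entry (years, default 84.66).
#' @param max_age Horizon cap (years, default 95).
#' @param stop_death Early-stop threshold on death occupancy.
#' @return Object of class `markov_trace`: occupancy matrix (cycles + 1 rows,
#'   six columns), per-cycle event flows, cumulative event counts per 1000
#'   (`mace`, `strokes`, `disability`, `cv_deaths`, `deaths`,
#'   `af_detected`), the effective accounting shares, horizon metadata.
#' @export
run_cohort <- function(model, arm = strategy_arm("usual_care"),
                       init = NULL, start_age = 84.66, max_age = 95,
                       stop_death = 0.999) {
  stopifnot(start_age <= max_age)
  if (is.null(init)) {
    sp <- model$structure[["substrate_prevalence"]]
    init <- c(1 - sp, sp, 0, 0, 0, 0)
  }
  stopifnot(length(init) == 6, abs(sum(init) - 1) < 1e-9, all(init >= -1e-12))

  n_cycles <- max(ceiling((max_age - start_age) / model$cycle_length), 1L)
  hr <- effective_hazard_ratios(model, arm)
  sh <- effective_share(model, hr_share = hr[["stroke_within_mace"]],
                        hr_cv = hr[["cv_death_share"]])
  time_invariant <- model$structure[["gompertz_b"]] == 0
  if (time_invariant) p_const <- build_cycle_matrix(model, arm, 0)

  occ <- matrix(NA_real_, n_cycles + 1, 6,
                dimnames = list(NULL, health_states()))
  occ[1, ] <- init
  ev <- matrix(0, n_cycles, 6,
               dimnames = list(NULL, c("mace", "strokes", "disability",
                                       "cv_deaths", "deaths", "af_detected")))
  t_used <- 0L
  for (t in seq_len(n_cycles)) {
    p <- if (time_invariant) p_const else build_cycle_matrix(model, arm, t - 1L)
    if (any(abs(rowSums(p) - 1) > 1e-9))
      stop("run_cohort: non-stochastic transition matrix at cycle ", t, call. = FALSE)
    o <- occ[t, ]
    occ[t + 1, ] <- o %*% p
    mace_flux <- sum(o[1:3] * p[1:3, 4])
    deaths_post <- o[4] * p[4, 6] + o[5] * p[5, 6]
    ev[t, ] <- c(
      mace = mace_flux,
      strokes = sh[["stroke_within_mace"]] * mace_flux,
      disability = o[4] * p[4, 5],
      cv_deaths = sh[["cv_death_share"]] * deaths_post,
      deaths = sum(o[1:5] * p[1:5, 6]),
      af_detected = o[1] * p[1, 3] + o[2] * p[2, 3])
    t_used <- t
    if (occ[t + 1, 6] > stop_death) break
  }
  occ <- occ[seq_len(t_used + 1), , drop = FALSE]
  ev <- ev[seq_len(t_used), , drop = FALSE]

  structure(list(
    occupancy = occ,
    events = data.frame(cycle = seq_len(t_used), ev),
    cum_per_1000 = colSums(ev) * 1000,
    shares = sh,
    n_cycles = t_used,
    start_age = start_age,
    cycle_length = model$cycle_length,
    sex = model$sex
  ), class = "markov_trace")
}

#' Pool two sex-specific traces
#'
#' Convex combination of occupancy, event flows and cumulative counts using
#' the modelled cohort composition (default 52% women, 48% men).
#'
#' @param trace_f,trace_m Traces from [run_cohort()] on identical horizons.
#' @param weights Named weights (`female`, `male`) summing to 1.
#' @return A pooled `markov_trace`.
#' @export
pool_sexes <- function(trace_f, trace_m,
                       weights = c(female = 0.52, male = 0.48)) {
  stopifnot(abs(sum(weights) - 1) < 1e-9)
  if (trace_f$n_cycles != trace_m$n_cycles)
    stop("pool_sexes: traces have mismatched horizons", call. = FALSE)
  wf <- weights[["female"]]; wm <- weights[["male"]]
  ev <- trace_f$events
  ev[, -1] <- wf * trace_f$events[, -1] + wm * trace_m$events[, -1]
  structure(list(
    occupancy = wf * trace_f$occupancy + wm * trace_m$occupancy,
    events = ev,
    cum_per_1000 = wf * trace_f$cum_per_1000 + wm * trace_m$cum_per_1000,
    shares = c(wf * trace_f$shares + wm * trace_m$shares),
    n_cycles = trace_f$n_cycles,
    start_age = trace_f$start_age,
    cycle_length = trace_f$cycle_length,
    sex = "pooled"
  ), class = "markov_trace")
}

#' Write a trace as tidy CSVs
#'
#' Writes two plain CSVs: `<stem>_occupancy.csv` (cycle, state, occupancy)
#' and `<stem>_events.csv` (cycle, channel, flux per 1000).
#'
#' @param trace A `markov_trace`.
#' @param stem Output path stem (without extension).
#' @return The two paths, invisibly.
#' @export
write_trace <- function(trace, stem) {
  occ <- trace$occupancy
  tidy_occ <- data.frame(
    cycle = rep(seq_len(nrow(occ)) - 1L, each = ncol(occ)),
    state = rep(colnames(occ), nrow(occ)),
    occupancy = as.vector(t(occ)))
  ev <- trace$events
  channels <- setdiff(names(ev), "cycle")
  tidy_ev <- data.frame(
    cycle = rep(ev$cycle, each = length(channels)),
    channel = rep(channels, nrow(ev)),
    flux_per_1000 = as.vector(t(as.matrix(ev[channels]))) * 1000)
  paths <- paste0(stem, c("_occupancy.csv", "_events.csv"))
  utils::write.csv(tidy_occ, paths[1], row.names = FALSE)
  utils::write.csv(tidy_ev, paths[2], row.names = FALSE)
  invisible(paths)
}

#' @export
print.markov_trace <- function(x, ...) {
  cat(sprintf("<markov_trace> %s, %d annual cycles from age %.1f\n",
              x$sex, x$n_cycles, x$start_age))
  cat("cumulative events per 1000:\n")
  print(round(x$cum_per_1000, 1))
  invisible(x)
}
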