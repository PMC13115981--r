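#' Lifetime outcome targets fixture
#'
#' Published lifetime clinical outcomes per 1000 high-risk individuals, by
#' population (overall, women, men), arm, with absolute differences and
#' relative reductions.
#'
#' @param path CSV path; defaults to the shipped fixture.
#' @return Data frame with columns `population`, `outcome`, `usual_care`,
#'   `intervention`, `abs_difference`, `rel_reduction`.
#' @export
load_lifetime_targets <- function(path = system.file("extdata", "lifetime_targets.csv",
                                                     package = "afcea")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Extract a calibration target vector
#'
#' @param targets Table from [load_lifetime_targets()].
#' @param population `"overall"`, `"women"` or `"men"`.
#' @param arm_col `"usual_care"` or `"intervention"`.
#' @return Named numeric: lifetime `mace`, `strokes`, `disability` and
#'   `cv_deaths` per 1000.
#' @export
target_vector <- function(targets, population = "overall",
                          arm_col = c("usual_care", "intervention")) {
  arm_col <- match.arg(arm_col)
  sub <- targets[targets$population == population &
                 targets$outcome %in% c("mace", "strokes", "disability", "cv_deaths"), ]
  stats::setNames(sub[[arm_col]], sub$outcome)
}

# run the model and return the four channel totals per 1000 plus the
# post-event death flux needed to profile the CV-death share
channel_totals <- function(model, arm, ...) {
  tr <- run_cohort(model, arm, ...)
  p <- tr$occupancy[-nrow(tr$occupancy), , drop = FALSE]
  # undo the accounting shares to expose the raw fluxes
  sh <- tr$shares
  list(mace = tr$cum_per_1000[["mace"]],
       strokes_raw = tr$cum_per_1000[["mace"]],           # share applied later
       disability = tr$cum_per_1000[["disability"]],
       deaths_post = tr$cum_per_1000[["cv_deaths"]] / sh[["cv_death_share"]],
       trace = tr)
}

#' Calibrate channel multipliers to lifetime event targets
#'
#' Fits the model's calibration multipliers so that the simulated lifetime
#' event counts per 1000 reproduce the targets: MACE events, ischaemic
#' strokes, severe-disability entries and cardiovascular deaths. The MACE and
#' disability-entry multipliers are found by a derivative-free Nelder-Mead
#' search on the log scale from three fixed starting points (deterministic;
#' ties broken by lowest objective, then by lexicographic multiplier order);
#' the stroke-within-MACE share and the cardiovascular-death share have no
#' effect on the state dynamics and are therefore profiled out exactly at
#' each evaluation (the share equals target/flux, capped at its upper bound).
#' The objective is the sum of squared relative deviations.
#'
#' @param model A [transition_model()].
#' @param targets Named lifetime targets per 1000 (`mace`, `strokes`,
#'   `disability`, `cv_deaths`), each positive and at most 1000.
#' @param arm The [strategy_arm()] under which to calibrate (hazard ratios
#'   held fixed).
#' @param tol_events Convergence requirement: every residual at most this
#'   many events per 1000 (default 0.5).
#' @param maxit Nelder-Mead iteration budget per start.
#' @param ... Passed to [run_cohort()] (e.g. `start_age`).
#' @return List of class `afcea_calibration`: `model` (with fitted
#'   multipliers), `multipliers`, `achieved`, `targets`, `residuals`,
#'   `converged`, `objective`, and the converged `trace`.
#' @export
calibrate <- function(model, targets, arm = strategy_arm("usual_care"),
                      tol_events = 0.5, maxit = 400, ...) {
  need <- c("mace", "strokes", "disability", "cv_deaths")
  stopifnot(all(need %in% names(targets)))
  targets <- targets[need]
  if (any(targets <= 0) || any(targets > 1000))
    stop("calibrate: targets must be positive and at most 1000 per 1000",
         call. = FALSE)

  eval_at <- function(x) {
    m <- model
    m$multipliers[["mace"]] <- exp(x[1])
    m$multipliers[["disability_entry"]] <- exp(x[2])
    ct <- channel_totals(m, arm, ...)
    hr <- effective_hazard_ratios(m, arm)
    # profile the accounting shares exactly (capped at their bounds)
    share_s <- min(targets[["strokes"]] / ct$mace, 0.999)
    share_c <- min(targets[["cv_deaths"]] / ct$deaths_post, 1)
    m$multipliers[["stroke_within_mace"]] <-
      share_s / (model$shares[["stroke_within_mace"]] * hr[["stroke_within_mace"]])
    m$multipliers[["cv_death_share"]] <-
      share_c / (model$shares[["cv_death_share"]] * hr[["cv_death_share"]])
    achieved <- c(mace = ct$mace,
                  strokes = share_s * ct$mace,
                  disability = ct$disability,
                  cv_deaths = share_c * ct$deaths_post)
    list(model = m, achieved = achieved,
         value = sum(((achieved - targets) / targets)^2))
  }

  objective <- function(x) eval_at(x)$value
  starts <- list(c(0, 0), c(log(2), log(2)), c(log(0.5), log(0.5)))
  fits <- lapply(starts, function(x0)
    stats::optim(x0, objective, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-12)))
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  # polish from the best point
  best <- stats::optim(best$par, objective, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-14))

  sol <- eval_at(best$par)
  residuals <- sol$achieved - targets
  converged <- all(abs(residuals) <= tol_events)
  if (!converged)
    stop(structure(class = c("afcea_calibration_error", "error", "condition"),
                   list(message = paste0(
                     "calibrate: not converged; residuals per 1000: ",
                     paste(sprintf("%s=%.2f", names(residuals), residuals),
                           collapse = ", ")),
                        call = sys.call(-1),
                        residuals = residuals,
                        multipliers = sol$model$multipliers)))
  structure(list(model = sol$model,
                 multipliers = sol$model$multipliers,
                 achieved = sol$achieved,
                 targets = targets,
                 residuals = residuals,
                 converged = converged,
                 objective = best$value,
                 trace = run_cohort(sol$model, arm, ...)),
            class = "afcea_calibration")
}

#' @export
print.afcea_calibration <- function(x, ...) {
  cat("<afcea_calibration>", if (x$converged) "converged" else "NOT converged", "\n")
  print(data.frame(channel = names(x$targets), target = x$targets,
                   achieved = round(x$achieved, 3),
                   residual = round(x$residuals, 3), row.names = NULL))
  invisible(x)
}

#' Fit the intervention strategy effect in reduced form
#'
#' Given a usual-care-calibrated model, calibrates the same base model under
#' the intervention arm's structural settings (e.g. its AF-detection hazard
#' ratio) to the intervention lifetime outcome column, and expresses the
#' result as constant per-channel hazard ratios relative to usual care:
#' `HR(channel) = multiplier(intervention) / multiplier(usual care)`. Running
#' the usual-care model under the returned arm reproduces the intervention
#' targets.
#'
#' @param calibration Usual-care [calibrate()] result.
#' @param targets_intervention Named intervention lifetime targets per 1000.
#' @param af_detection_hr Hazard ratio on AF detection under the
#'   intervention (earlier detection through targeted screening; default
#'   1.5).
#' @param ... Passed to [run_cohort()] / [calibrate()].
#' @return A `strategy_arm` named `"mathias"` with fitted hazard ratios;
#'   attribute `"calibration"` holds the intervention-side calibration.
#' @export
apply_strategy_effect <- function(calibration, targets_intervention,
                                  af_detection_hr = 1.5, ...) {
  stopifnot(inherits(calibration, "afcea_calibration"), af_detection_hr > 0)
  base_model <- calibration$model
  arm0 <- strategy_arm("mathias",
                       hazard_ratios = c(af_onset = af_detection_hr))
  fit_i <- calibrate(base_model, targets_intervention, arm = arm0, ...)
  ratio <- fit_i$multipliers / calibration$multipliers
  hr <- c(af_onset = af_detection_hr,
          mace = unname(ratio[["mace"]]),
          stroke_within_mace = unname(ratio[["stroke_within_mace"]]),
          disability_entry = unname(ratio[["disability_entry"]]),
          cv_death_share = unname(ratio[["cv_death_share"]]),
          background_death = 1)
  arm <- strategy_arm("mathias", hazard_ratios = hr)
  attr(arm, "calibration") <- fit_i
  arm
}
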