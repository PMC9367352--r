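#' Simulated growth inhibition of a protocol
#'
#' Runs the paired simulation behind every calibration step: a drug-free
#' control and a treated arm that share all parameters except the drug
#' terms (`mu_AC`, its linked clearance `mu_CA = 10 * mu_AC`, and the
#' drug's own `mu_C`), then reads [inhibition_percent()] at the protocol's
#' evaluation day.
#'
#' @param protocol An `ld_protocol` (or `ld_combination`).
#' @param mu_AC Cytotoxicity rate \[1/h\]; defaults to the protocol's
#'   calibrated value.
#' @param params Base parameter set; drug-specific entries are overridden
#'   per arm.
#' @param initial Initial state (treatment start).
#' @param t_eval Readout time \[h\]; defaults to
#'   `24 * protocol$evaluation_day`.
#' @param control Optional pre-computed control trajectory covering
#'   `t_eval` (reused across sweep/fit iterations).
#' @param ... Passed to [simulate_model()] (tolerances, output grid).
#' @return Percent inhibition (scalar).
#' @examples
#' protocol_inhibition(bundled_protocol("cyt_high"))
#' @export
protocol_inhibition <- function(protocol, mu_AC = protocol$mu_AC,
                                params = model_parameters(),
                                initial = system_state(),
                                t_eval = 24 * protocol$evaluation_day,
                                control = NULL, ...) {
  if (is.na(mu_AC))
    stop("protocol has no default mu_AC; supply one", call. = FALSE)
  if (inherits(protocol, "ld_combination")) {
    schedule <- protocol$schedule
    mu_C <- protocol$mu_C
  } else {
    schedule <- build_schedule(protocol)
    mu_C <- protocol$drug$mu_C
  }
  treated_params <- do.call(model_parameters,
                            utils::modifyList(unclass(params),
                                              list(mu_AC = mu_AC,
                                                   mu_CA = 10 * mu_AC,
                                                   mu_C = mu_C)))
  if (is.null(control)) {
    control_params <- do.call(model_parameters,
                              utils::modifyList(unclass(params),
                                                list(mu_AC = 0, mu_CA = 0)))
    control <- simulate_model(control_params, dose_schedule(),
                              initial = initial, t_end = t_eval, ...)
  }
  treated <- simulate_model(treated_params, schedule, initial = initial,
                            t_end = t_eval, ...)
  inhibition_percent(control, treated, t_eval = t_eval)
}

#' Sensitivity sweep over the cytotoxicity rate
#'
#' Integrates the control and treated trajectories for each candidate
#' `mu_AC` (with the tenfold clearance linkage applied) and records the
#' inhibition at the protocol's evaluation day. Inhibition is monotone
#' non-decreasing in `mu_AC`; the sweep asserts this and fails loudly if
#' the property is violated.
#'
#' @param protocol An `ld_protocol`.
#' @param muAC_values Positive candidate rates \[1/h\].
#' @inheritParams protocol_inhibition
#' @return A data frame of class `ld_sweep` with columns `mu_AC` and
#'   `inhibition_pct`, carrying the protocol name as an attribute.
#' @examples
#' sweep_muAC(bundled_protocol("cyt_low"), c(1e-4, 1e-3, 3e-3))
#' @export
sweep_muAC <- function(protocol, muAC_values,
                       params = model_parameters(),
                       initial = system_state(),
                       t_eval = 24 * protocol$evaluation_day, ...) {
  if (any(muAC_values <= 0))
    stop("muAC_values must be positive", call. = FALSE)
  control_params <- do.call(model_parameters,
                            utils::modifyList(unclass(params),
                                              list(mu_AC = 0, mu_CA = 0)))
  control <- simulate_model(control_params, dose_schedule(),
                            initial = initial, t_end = t_eval, ...)
  inh <- vapply(muAC_values, function(m)
    protocol_inhibition(protocol, mu_AC = m, params = params,
                        initial = initial, t_eval = t_eval,
                        control = control, ...),
    numeric(1))
  ord <- order(muAC_values)
  if (is.unsorted(inh[ord]))
    stop("inhibition is not monotone in mu_AC for protocol '",
         protocol$name, "'; integration problem", call. = FALSE)
  structure(data.frame(mu_AC = muAC_values, inhibition_pct = inh),
            class = c("ld_sweep", "data.frame"),
            protocol = protocol$name, t_eval = t_eval)
}

#' Calibrate the cytotoxicity rate to a target inhibition
#'
#' Bisection on `mu_AC`, exploiting the monotone dose-response of the kill
#' rate, until the simulated inhibition is within `tol_pp` percentage
#' points of the target and the bracket has shrunk below 0.5% relative
#' width. This is the tool that regenerates the per-protocol calibrated
#' rates from measured (or synthetic-cohort) inhibition values.
#'
#' @param protocol An `ld_protocol`.
#' @param target_inhibition Target percent inhibition in `[0, 100)`.
#' @param bracket Lower/upper bracket on `mu_AC` \[1/h\]; the target must
#'   lie between the inhibitions attained at the two ends.
#' @param tol_pp Inhibition tolerance \[percentage points\].
#' @inheritParams protocol_inhibition
#' @return Fitted `mu_AC` \[1/h\].
#' @examples
#' \donttest{
#' fit_muAC(bundled_protocol("cyt_high"), target_inhibition = 58)
#' }
#' @export
fit_muAC <- function(protocol, target_inhibition,
                     bracket = c(1e-5, 0.05), tol_pp = 0.1,
                     params = model_parameters(),
                     initial = system_state(),
                     t_eval = 24 * protocol$evaluation_day, ...) {
  if (target_inhibition < 0 || target_inhibition >= 100)
    stop("target inhibition must be in [0, 100)", call. = FALSE)
  control_params <- do.call(model_parameters,
                            utils::modifyList(unclass(params),
                                              list(mu_AC = 0, mu_CA = 0)))
  control <- simulate_model(control_params, dose_schedule(),
                            initial = initial, t_end = t_eval, ...)
  f <- function(m) protocol_inhibition(protocol, mu_AC = m, params = params,
                                       initial = initial, t_eval = t_eval,
                                       control = control, ...)
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- f(lo); f_hi <- f(hi)
  if (target_inhibition < f_lo || target_inhibition > f_hi)
    stop(sprintf(paste0("target %.3g%% outside the bracket's inhibition ",
                        "range [%.3g%%, %.3g%%]; widen the bracket"),
                 target_inhibition, f_lo, f_hi), call. = FALSE)
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    if (f_mid < target_inhibition) lo <- mid else hi <- mid
    if (abs(f_mid - target_inhibition) < tol_pp &&
        (hi - lo) / hi < 5e-3) return(mid)
  }
  (lo + hi) / 2
}

#' Predict the effect of a combined regimen
#'
#' Integrates the combined-parameter model (from [combine_drugs()]) over
#' the merged schedule and reports control and treated trajectories plus
#' the inhibition at the evaluation time.
#'
#' @param combination An `ld_combination` from [combine_drugs()].
#' @param params Base parameters; the combination's `mu_C`, `mu_AC`,
#'   `mu_CA` override the drug entries.
#' @param initial Initial state.
#' @param t_eval Readout time \[h\].
#' @param ... Passed to [simulate_model()].
#' @return List with `control`, `treated` (trajectories) and
#'   `inhibition_pct`.
#' @examples
#' \donttest{
#' cmb <- combine_drugs(bundled_protocol("cyt_high"), bundled_protocol("ibr_low"))
#' predict_combination(cmb)$inhibition_pct
#' }
#' @export
predict_combination <- function(combination,
                                params = model_parameters(),
                                initial = system_state(),
                                t_eval = 24 * combination$evaluation_day,
                                ...) {
  stopifnot(inherits(combination, "ld_combination"))
  control_params <- do.call(model_parameters,
                            utils::modifyList(unclass(params),
                                              list(mu_AC = 0, mu_CA = 0)))
  treated_params <- do.call(model_parameters,
                            utils::modifyList(unclass(params),
                                              list(mu_AC = combination$mu_AC,
                                                   mu_CA = combination$mu_CA,
                                                   mu_C = combination$mu_C)))
  control <- simulate_model(control_params, dose_schedule(),
                            initial = initial, t_end = t_eval, ...)
  treated <- simulate_model(treated_params, combination$schedule,
                            initial = initial, t_end = t_eval, ...)
  list(control = control, treated = treated,
       inhibition_pct = inhibition_percent(control, treated, t_eval = t_eval))
}
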