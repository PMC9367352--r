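#' Impulsive dose schedule
#'
#' Drug administration is modelled as a Dirac comb: at each dosing time the
#' drug pool `C` jumps upward by exactly `dose_amount` molecules while `A`
#' and `E` stay continuous. An empty schedule reduces the drug equation to
#' pure decay.
#'
#' @param dose_amount Molecules added per administration.
#' @param dose_times Strictly increasing administration times \[h\], all
#'   non-negative.
#' @return An object of class `ld_schedule` with fields `dose_amount`,
#'   `dose_times` and `n_doses`.
#' @examples
#' dose_schedule(3e15, c(0, 24, 48))   # daily for three days
#' dose_schedule()                     # drug-free
#' @export
dose_schedule <- function(dose_amount = 0, dose_times = numeric(0)) {
  if (length(dose_times)) {
    if (any(!is.finite(dose_times)) || any(dose_times < 0))
      stop("dose_times must be finite and non-negative", call. = FALSE)
    if (any(diff(dose_times) <= 0))
      stop("dose_times must be strictly increasing", call. = FALSE)
    if (!is.finite(dose_amount) || dose_amount < 0)
      stop("dose_amount must be a non-negative number", call. = FALSE)
  }
  structure(list(dose_amount = dose_amount,
                 dose_times = as.numeric(dose_times),
                 n_doses = length(dose_times)),
            class = "ld_schedule")
}

#' @export
print.ld_schedule <- function(x, ...) {
  if (x$n_doses == 0) {
    cat("Empty dose schedule (drug-free)\n")
  } else {
    cat(sprintf("Dose schedule: %g molecules x %d administrations at t = %s h\n",
                x$dose_amount, x$n_doses,
                paste(x$dose_times, collapse = ", ")))
  }
  invisible(x)
}

# Smooth part of the vector field; impulses are handled by the integrator.
.ld_rhs <- function(A, E, C, p) {
  c(dA_dt = p$r * A * (1 - A / p$K) - p$mu_A * A * E -
      p$mu_AC * A * C / (p$a + C),
    dE_dt = -p$mu_E * E + p$p * A * E / (p$c + A) - p$mu_EA * A * E -
      p$mu_EC * E * C / (p$b + C),
    dC_dt = -p$mu_C * C - p$mu_CA * C * A / (p$a + A))
}

#' Evaluate the smooth right-hand side of the model
#'
#' Time derivatives of tumor cells, effector cells and drug amount between
#' doses:
#' \deqn{dA/dt = r A (1 - A/K) - \mu_A A E - \mu_{AC} A C/(a + C)}
#' \deqn{dE/dt = -\mu_E E + p A E/(c + A) - \mu_{EA} A E - \mu_{EC} E C/(b + C)}
#' \deqn{dC/dt = -\mu_C C - \mu_{CA} C A/(a + A)}
#' The impulsive dosing source is *not* included here; [simulate_model()]
#' applies doses as exact jumps in `C`.
#'
#' @param state An [system_state()] object or a numeric vector `c(A, E, C)`.
#' @param params An [model_parameters()] object.
#' @return Named numeric vector `c(dA_dt, dE_dt, dC_dt)`.
#' @examples
#' evaluate_rhs(system_state(), model_parameters())
#' evaluate_rhs(c(A = 0, E = 0, C = 0), model_parameters())  # fixed point
#' @export
evaluate_rhs <- function(state, params) {
  stopifnot(inherits(params, "ld_params"))
  if (inherits(state, "ld_state")) {
    vals <- c(A = state$A, E = state$E, C = state$C)
  } else {
    if (length(state) != 3L)
      stop("state must have components (A, E, C)", call. = FALSE)
    vals <- c(A = state[[1]], E = state[[2]], C = state[[3]])
  }
  for (nm in names(vals)) {
    if (!is.finite(vals[[nm]]))
      stop("state component '", nm, "' must be finite", call. = FALSE)
    if (vals[[nm]] < 0)
      stop("state component '", nm, "' is negative", call. = FALSE)
  }
  .ld_rhs(vals[["A"]], vals[["E"]], vals[["C"]], params)
}

#' Closed-form logistic growth
#'
#' Analytic solution of the drug-free, immune-negligible limit of the tumor
#' equation, `A' = r A (1 - A/K)`:
#' \deqn{A(t) = K A_0 e^{rt} / (K + A_0 (e^{rt} - 1))}
#' Used as the independent oracle for the integrator and as the control-arm
#' endpoint in dose-response calculations.
#'
#' @param A0 Initial cell count (> 0).
#' @param r Growth rate \[1/h\] (>= 0).
#' @param K Carrying capacity (> 0).
#' @param t Time \[h\]; may be a vector.
#' @return Cell count(s) at `t`.
#' @examples
#' logistic_closed_form(5e4, 0.01, 4e6, 288)
#' @export
logistic_closed_form <- function(A0, r, K, t) {
  if (!is.finite(A0) || A0 <= 0) stop("A0 must be positive", call. = FALSE)
  if (!is.finite(K) || K <= 0) stop("K must be positive", call. = FALSE)
  if (!is.finite(r) || r < 0) stop("r must be non-negative", call. = FALSE)
  ert <- exp(r * t)
  K * A0 * ert / (K + A0 * (ert - 1))
}

#' Integrate the model with impulsive dosing
#'
#' Piecewise-smooth integration: between consecutive dose times the smooth
#' system is solved with `deSolve::lsoda` under adaptive error control; at
#' each dose time the drug amount `C` jumps by exactly
#' `schedule$dose_amount` while `A` and `E` remain continuous. Every dose
#' time appears twice in the output (pre-impulse and post-impulse row) so
#' the jump is explicit.
#'
#' The drug-on-effector mortality rate is orders of magnitude faster than
#' every other rate, which makes the flow stiff while drug is on board; the
#' default solver switches automatically between stiff and non-stiff
#' methods. States may ring slightly negative while sitting below the
#' error-control floor (the stiff effector collapse drives `E` to
#' essentially zero within minutes of a dose); excursions smaller than
#' `clamp_tol` — one cell for `A` and `E`, a sub-ppm fraction of any
#' bundled dose for `C` — are physically meaningless round-off and are
#' clamped to zero, while larger excursions raise an error.
#'
#' @param params [model_parameters()].
#' @param schedule [dose_schedule()]; empty for a drug-free run.
#' @param initial [system_state()] at the start of the run.
#' @param t_end End time \[h\]; must exceed `initial$t` and cover all doses.
#' @param dt_out Spacing of the regular output grid \[h\] (default hourly).
#' @param rtol,atol Relative tolerance and per-state absolute tolerances
#'   `c(A, E, C)`. The drug pool must stay accurate down to the kill-term
#'   half-max scale (`a` ~ 2e3 molecules) even though it starts ~1e15,
#'   so its absolute tolerance is 1 molecule.
#' @param clamp_tol Per-state thresholds below which negative excursions
#'   are treated as round-off and clamped to zero.
#' @param method deSolve integration method.
#' @return An `ld_trajectory`: a data frame with columns
#'   `time_h`, `A_cells`, `E_cells`, `C_molecules`, carrying the parameters
#'   and schedule as attributes.
#' @examples
#' tr <- simulate_model(model_parameters(mu_AC = 0), t_end = 48)
#' tail(tr, 3)
#' @export
simulate_model <- function(params,
                           schedule = dose_schedule(),
                           initial = system_state(),
                           t_end = 288,
                           dt_out = 1,
                           rtol = 1e-10,
                           atol = c(1e-2, 1e-2, 1),
                           clamp_tol = c(1, 1, 1e6),
                           method = "lsoda") {
  stopifnot(inherits(params, "ld_params"), inherits(schedule, "ld_schedule"),
            inherits(initial, "ld_state"))
  t0 <- initial$t
  if (t_end <= t0) stop("t_end must exceed the initial time", call. = FALSE)
  if (schedule$n_doses > 0 &&
      (min(schedule$dose_times) < t0 || max(schedule$dose_times) > t_end))
    stop("all dose times must lie within [initial$t, t_end]", call. = FALSE)

  deriv <- function(t, y, p) list(.ld_rhs(y[[1]], y[[2]], y[[3]], p))

  clamp <- function(y) {
    for (i in 1:3) {
      if (y[i] < 0) {
        if (y[i] < -clamp_tol[i])
          stop("state '", c("A", "E", "C")[i], "' went negative (",
               y[i], ") beyond the absolute tolerance; ",
               "model misuse or integration failure", call. = FALSE)
        y[i] <- 0
      }
    }
    y
  }

  grid <- seq(t0, t_end, by = dt_out)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  bounds <- sort(unique(c(schedule$dose_times, t_end)))
  bounds <- bounds[bounds > t0 | bounds == t0]

  y <- c(A = initial$A, E = initial$E, C = initial$C)
  t_cur <- t0
  rows <- list(c(time_h = t0, y))
  segment_starts <- t0

  apply_dose <- function(y) { y["C"] <- y["C"] + schedule$dose_amount; y }

  if (t0 %in% schedule$dose_times) {
    y <- apply_dose(y)
    rows[[length(rows) + 1L]] <- c(time_h = t0, y)
  }

  for (tb in bounds[bounds > t0]) {
    times <- unique(c(t_cur, grid[grid > t_cur & grid < tb], tb))
    sol <- deSolve::ode(y = y, times = times, func = deriv, parms = params,
                        method = method, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("integration failed near t = ", utils::tail(sol[, 1], 1), " h",
           call. = FALSE)
    for (i in seq_len(nrow(sol))[-1]) {
      yi <- clamp(sol[i, c("A", "E", "C")])
      rows[[length(rows) + 1L]] <- c(time_h = sol[i, 1], yi)
    }
    y <- clamp(sol[nrow(sol), c("A", "E", "C")])
    t_cur <- tb
    if (tb %in% schedule$dose_times) {
      y <- apply_dose(y)
      rows[[length(rows) + 1L]] <- c(time_h = tb, y)
    }
  }

  m <- do.call(rbind, rows)
  out <- data.frame(time_h = m[, "time_h"],
                    A_cells = m[, "A"],
                    E_cells = m[, "E"],
                    C_molecules = m[, "C"],
                    row.names = NULL)
  structure(out,
            class = c("ld_trajectory", "data.frame"),
            params = params, schedule = schedule,
            rtol = rtol, atol = atol, method = method)
}

#' Interpolate a trajectory at a time point
#'
#' Linear interpolation of `A`, `E`, `C` at time `t`. At a dose time (where
#' the output holds a pre- and a post-impulse row) the post-impulse value is
#' returned, i.e. the trajectory is treated as right-continuous in `C`.
#'
#' @param trajectory An `ld_trajectory` from [simulate_model()].
#' @param t Time \[h\] inside the trajectory's span.
#' @return Named numeric vector `c(A, E, C)`.
#' @export
trajectory_state <- function(trajectory, t) {
  stopifnot(inherits(trajectory, "ld_trajectory"))
  tt <- trajectory$time_h
  if (t < tt[1] || t > tt[length(tt)])
    stop("t = ", t, " outside trajectory span [", tt[1], ", ",
         tt[length(tt)], "]", call. = FALSE)
  hit <- which(tt == t)
  cols <- c("A_cells", "E_cells", "C_molecules")
  if (length(hit)) {
    v <- unlist(trajectory[max(hit), cols])
  } else {
    i <- max(which(tt < t))
    w <- (t - tt[i]) / (tt[i + 1] - tt[i])
    v <- (1 - w) * unlist(trajectory[i, cols]) +
      w * unlist(trajectory[i + 1, cols])
  }
  stats::setNames(as.numeric(v), c("A", "E", "C"))
}

#' Percent growth inhibition at an evaluation time
#'
#' The validation statistic of the model: at the readout time,
#' `100 * (A_control - A_treated) / A_control`. Values lie in
#' (-Inf, 100]; 0 means no effect, 100 means complete kill, negative values
#' mean the "treated" arm outgrew the control.
#'
#' @param control,treated `ld_trajectory` objects covering `t_eval`,
#'   differing only in drug terms.
#' @param t_eval Readout time \[h\]; default 288 h (= study Day 12).
#' @return Percent inhibition (scalar).
#' @examples
#' p <- model_parameters()
#' ctl <- simulate_model(p, t_end = 72)
#' trt <- simulate_model(p, dose_schedule(3e15, c(0, 24, 48)), t_end = 72)
#' inhibition_percent(ctl, trt, t_eval = 72)
#' @export
inhibition_percent <- function(control, treated, t_eval = 288) {
  a_c <- trajectory_state(control, t_eval)[["A"]]
  a_t <- trajectory_state(treated, t_eval)[["A"]]
  if (a_c == 0)
    stop("control tumor burden is zero at t_eval; inhibition undefined",
         call. = FALSE)
  100 * (a_c - a_t) / a_c
}

#' @export
print.ld_trajectory <- function(x, ...) {
  sc <- attr(x, "schedule")
  cat(sprintf("Model trajectory: %d samples over [%g, %g] h, %d dose(s)\n",
              nrow(x), x$time_h[1], x$time_h[nrow(x)], sc$n_doses))
  NextMethod()
}

#' Write / read a trajectory as CSV with a JSON sidecar
#'
#' The CSV carries the four columns `time_h,A_cells,E_cells,C_molecules`;
#' the sidecar `<path>.json` records the parameters and dose schedule used
#' so a stored run is self-describing.
#'
#' @param trajectory An `ld_trajectory`.
#' @param path CSV file path.
#' @return `read_trajectory()` returns the `ld_trajectory` (with parameters
#'   and schedule restored from the sidecar when present).
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "ld_trajectory"))
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  side <- list(params = unclass(attr(trajectory, "params")),
               schedule = unclass(attr(trajectory, "schedule")))
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_h", "A_cells", "E_cells", "C_molecules") %in%
                  names(df)))
  params <- NULL
  schedule <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    params <- do.call(model_parameters, as.list(side$params))
    schedule <- dose_schedule(side$schedule$dose_amount,
                              side$schedule$dose_times)
  }
  structure(df, class = c("ld_trajectory", "data.frame"),
            params = params, schedule = schedule)
}
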