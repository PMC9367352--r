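#' Jacobian of the smooth flow
#'
#' Exact partial derivatives of the smooth right-hand side (the impulse
#' term has no Jacobian contribution) at a state, as a 3x3 matrix ordered
#' (A, E, C). At the origin the matrix is diagonal with entries
#' `(r, -mu_E, -mu_C)`.
#'
#' @param state [system_state()] or numeric `c(A, E, C)`.
#' @param params [model_parameters()].
#' @return 3x3 numeric matrix with dimnames `A`, `E`, `C`.
#' @examples
#' model_jacobian(c(0, 0, 0), model_parameters())
#' @export
model_jacobian <- function(state, params) {
  stopifnot(inherits(params, "ld_params"))
  if (inherits(state, "ld_state")) state <- c(state$A, state$E, state$C)
  A <- state[[1]]; E <- state[[2]]; C <- state[[3]]
  p <- params
  J <- matrix(0, 3, 3, dimnames = list(c("A", "E", "C"), c("A", "E", "C")))
  J["A", "A"] <- p$r * (1 - 2 * A / p$K) - p$mu_A * E - p$mu_AC * C / (p$a + C)
  J["A", "E"] <- -p$mu_A * A
  J["A", "C"] <- -p$mu_AC * A * p$a / (p$a + C)^2
  J["E", "A"] <- p$p * E * p$c / (p$c + A)^2 - p$mu_EA * E
  J["E", "E"] <- -p$mu_E + p$p * A / (p$c + A) - p$mu_EA * A -
    p$mu_EC * C / (p$b + C)
  J["E", "C"] <- -p$mu_EC * E * p$b / (p$b + C)^2
  J["C", "A"] <- -p$mu_CA * C * p$a / (p$a + A)^2
  J["C", "C"] <- -p$mu_C - p$mu_CA * A / (p$a + A)
  J
}

.ld_classify <- function(re_parts, eps) {
  if (all(re_parts < -eps)) "stable"
  else if (any(re_parts > eps)) "unstable"
  else "non-hyperbolic"
}

.ld_equilibrium_report <- function(point, params, label, C_const = 0) {
  J <- model_jacobian(point, params)
  ev <- eigen(J, only.values = TRUE)$values
  rates <- unlist(params)
  eps <- 1e-12 * max(abs(rates))
  rhs <- .ld_rhs(point[1], point[2], point[3], params)
  if (C_const > 0) rhs["dC_dt"] <- 0  # C held constant in the frozen-drug case
  scaled <- abs(rhs) / pmax(1, abs(point) * max(abs(rates)))
  structure(list(point = stats::setNames(point, c("A", "E", "C")),
                 eigenvalues = ev,
                 classification = .ld_classify(Re(ev), eps),
                 label = label,
                 residual = max(scaled)),
            class = "ld_equilibrium")
}

#' @export
print.ld_equilibrium <- function(x, ...) {
  cat(sprintf("%s equilibrium at (A=%.6g, E=%.6g, C=%.6g): %s\n",
              x$label, x$point["A"], x$point["E"], x$point["C"],
              x$classification))
  cat("  eigenvalues:",
      paste(sprintf("%.6g%+.2gi", Re(x$eigenvalues), Im(x$eigenvalues)),
            collapse = ", "), "\n")
  invisible(x)
}

# dE/dt = 0 with E != 0 reduces to a 1-D condition in A at fixed C.
.ld_effector_balance <- function(A, p, C) {
  -p$mu_E + p$p * A / (p$c + A) - p$mu_EA * A - p$mu_EC * C / (p$b + C)
}

# Scan for sign changes of f over a log-spaced grid on (lo, hi), refine
# each bracket with uniroot.
.ld_root_scan <- function(f, lo, hi, n = 400) {
  xs <- exp(seq(log(lo), log(hi), length.out = n))
  fs <- vapply(xs, f, numeric(1))
  roots <- numeric(0)
  for (i in seq_len(n - 1)) {
    if (is.finite(fs[i]) && is.finite(fs[i + 1]) &&
        sign(fs[i]) * sign(fs[i + 1]) < 0) {
      rt <- stats::uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-12 * xs[i + 1])
      roots <- c(roots, rt$root)
    }
  }
  roots
}

#' Fixed points and their linear stability
#'
#' Computes equilibria of the smooth flow and classifies each by the real
#' parts of its Jacobian eigenvalues (`stable` if all < -eps, `unstable`
#' if any > +eps, else `non-hyperbolic`, with `eps = 1e-12 * max rate`).
#'
#' Drug-free case (`C_const = 0`): the extinction state `(0, 0, 0)`
#' (labelled `Eqm0`) and the tumor-at-capacity state `(K, 0, 0)` (`Eqm1`)
#' are returned analytically; interior equilibria with a surviving effector
#' population are searched by reducing `dE/dt = 0` (with `E != 0`) to a
#' one-dimensional root problem in `A` over a log-spaced scan, with `E`
#' recovered from `dA/dt = 0`. Under the default parameter magnitudes the
#' effector balance is negative for all `A`, so no interior equilibrium
#' exists; the scan verifies rather than assumes this.
#'
#' Dosed case (`C_const > 0`): the drug amount is held constant
#' (frozen-drug approximation of the periodically forced system) and the
#' same branch reduction is applied to the (A, E) subsystem; the
#' tumor-suppressed state on the `E = 0` branch solves
#' `r (1 - A/K) = mu_AC * C / (a + C)` in closed form and is labelled
#' `Eqm2`. Eigenvalues are those of the full Jacobian evaluated with
#' `C = C_const`. True periodic orbits of the impulsive system are out of
#' scope.
#'
#' @param params [model_parameters()].
#' @param C_const Constant drug amount \[molecules\]; 0 for the drug-free
#'   system.
#' @return List of `ld_equilibrium` reports (point, eigenvalues,
#'   classification, label, scaled residual).
#' @examples
#' eq <- find_equilibria(model_parameters())
#' sapply(eq, function(e) e$classification)
#' @export
find_equilibria <- function(params, C_const = 0) {
  stopifnot(inherits(params, "ld_params"))
  p <- params
  out <- list()

  if (C_const == 0) {
    out[[length(out) + 1L]] <-
      .ld_equilibrium_report(c(0, 0, 0), p, "Eqm0")
    out[[length(out) + 1L]] <-
      .ld_equilibrium_report(c(p$K, 0, 0), p, "Eqm1")
    if (p$mu_A > 0) {
      roots <- .ld_root_scan(function(A) .ld_effector_balance(A, p, 0),
                             lo = 1e-3, hi = 10 * p$K)
      for (A_star in roots) {
        E_star <- p$r * (1 - A_star / p$K) / p$mu_A
        if (E_star > 0)
          out[[length(out) + 1L]] <-
            .ld_equilibrium_report(c(A_star, E_star, 0), p, "other")
      }
    }
    return(out)
  }

  # Frozen-drug system: C held at C_const.
  kill <- p$mu_AC * C_const / (p$a + C_const)
  # E = 0 branch: r (1 - A/K) = kill.
  A_star <- p$K * (1 - kill / p$r)
  if (A_star > 0)
    out[[length(out) + 1L]] <-
      .ld_equilibrium_report(c(A_star, 0, C_const), p, "Eqm2",
                             C_const = C_const)
  # Tumor-free branch.
  out[[length(out) + 1L]] <-
    .ld_equilibrium_report(c(0, 0, C_const), p, "other", C_const = C_const)
  # Interior branch (E != 0).
  if (p$mu_A > 0) {
    roots <- .ld_root_scan(function(A) .ld_effector_balance(A, p, C_const),
                           lo = 1e-3, hi = 10 * p$K)
    for (A_r in roots) {
      E_r <- (p$r * (1 - A_r / p$K) - kill) / p$mu_A
      if (E_r > 0)
        out[[length(out) + 1L]] <-
          .ld_equilibrium_report(c(A_r, E_r, C_const), p, "other",
                                 C_const = C_const)
    }
  }
  out
}

#' Export equilibrium reports as JSON
#'
#' @param reports List of `ld_equilibrium` objects from [find_equilibria()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_equilibria <- function(reports, path) {
  js <- lapply(reports, function(e) {
    list(label = e$label,
         point = as.list(e$point),
         eigenvalues = lapply(e$eigenvalues,
                              function(z) list(re = Re(z), im = Im(z))),
         classification = e$classification)
  })
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
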