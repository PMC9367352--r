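#' Model parameters for the tumor-immune-drug system
#'
#' Constructs the full rate-constant set of the three-compartment model
#' (tumor cells A, effector cells E, drug molecules C). Defaults reproduce
#' the reference parameter table for the murine A20 model: logistic growth
#' `r = 0.01` per hour towards a carrying capacity `K = 4e6` cells/mouse,
#' a drug kill term with Michaelis-Menten saturation `C/(a + C)`, and a
#' drug pool cleared both chemically (`mu_C`) and through engagement with
#' tumor cells (`mu_CA`, tied to `mu_AC` by the tenfold linkage
#' `mu_CA = 10 * mu_AC` unless overridden).
#'
#' The cytotoxicity rate `mu_AC` is protocol specific; the default `0.012`
#' is the high-dose cytarabine value, and `mu_C = 0.231` is cytarabine's
#' chemical deactivation rate (ln 2 / 3 h). Use [sweep_muAC()] / [fit_muAC()]
#' to explore or re-derive `mu_AC` for other regimens.
#'
#' All parameters must be non-negative; only `mu_A`, `mu_AC` and `mu_CA`
#' may be exactly zero (immune-free / drug-free reductions of the model).
#'
#' @param r Tumor growth rate \[1/h\].
#' @param K Maximal tumor cell population \[cells/mouse\].
#' @param mu_A Effector-on-tumor kill coefficient \[1/h\].
#' @param mu_AC Drug cytotoxicity rate on tumor cells \[1/h\].
#' @param a Drug amount giving half-maximal drug effect on tumor cells
#'   \[molecules\].
#' @param mu_E Natural death rate of effector cells \[1/h\].
#' @param p Effector production rate stimulated by tumor cells \[1/h\].
#' @param c Tumor cell number at half-maximal immune stimulation \[cells\].
#' @param mu_EA Tumor-on-effector interaction coefficient \[1/h\].
#' @param mu_EC Drug mortality rate on effector cells \[1/h\].
#' @param b Drug amount giving half-maximal drug effect on effector cells
#'   \[molecules\].
#' @param mu_C Chemical deactivation rate of the drug \[1/h\]; see
#'   [decay_rate_from_half_life()].
#' @param mu_CA Drug deactivation rate due to killing tumor cells \[1/h\];
#'   defaults to `10 * mu_AC`.
#' @return An object of class `ld_params`: a named list of the thirteen
#'   rate and saturation constants.
#' @examples
#' params <- model_parameters()
#' params$mu_CA == 10 * params$mu_AC
#' drugfree <- model_parameters(mu_AC = 0, mu_A = 0)
#' @export
model_parameters <- function(r = 0.01,
                             K = 4e6,
                             mu_A = 2e-12,
                             mu_AC = 0.012,
                             a = 2e3,
                             mu_E = 4e-5,
                             p = 4e-14,
                             c = 1e2,
                             mu_EA = 4e-15,
                             mu_EC = 417,
                             b = 5e6,
                             mu_C = 0.231,
                             mu_CA = 10 * mu_AC) {
  prm <- list(r = r, K = K, mu_A = mu_A, mu_AC = mu_AC, a = a,
              mu_E = mu_E, p = p, c = c, mu_EA = mu_EA, mu_EC = mu_EC,
              b = b, mu_C = mu_C, mu_CA = mu_CA)
  may_be_zero <- c("mu_A", "mu_AC", "mu_CA")
  for (nm in names(prm)) {
    v <- prm[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("parameter '", nm, "' must be non-negative (got ", v, ")",
           call. = FALSE)
    if (v == 0 && !(nm %in% may_be_zero))
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
    prm[[nm]] <- as.numeric(v)
  }
  structure(prm, class = "ld_params")
}

#' @export
print.ld_params <- function(x, ...) {
  cat("Tumor-immune-drug model parameters [1/h unless noted]:\n")
  df <- data.frame(value = unlist(x))
  print(format(df, digits = 6))
  invisible(x)
}

#' System state (tumor, effector, drug)
#'
#' A point in state space: tumor cell count `A`, effector cell count `E`,
#' drug amount `C` (molecules), at time `t` (hours). The defaults are the
#' canonical treatment-start conditions: `A = 5e4` engrafted leukemic cells,
#' `E = 2500` effector cells, no drug on board.
#'
#' @param A Tumor cells per mouse.
#' @param E Effector cells per mouse.
#' @param C Drug molecules per mouse.
#' @param t Time \[h\].
#' @return An object of class `ld_state`.
#' @examples
#' system_state()          # treatment-start default
#' system_state(A = 1e6)   # late-stage tumor burden
#' @export
system_state <- function(A = 5e4, E = 2500, C = 0, t = 0) {
  vals <- c(A = A, E = E, C = C)
  for (nm in names(vals)) {
    if (!is.finite(vals[[nm]]))
      stop("state component '", nm, "' must be finite", call. = FALSE)
    if (vals[[nm]] < 0)
      stop("state component '", nm, "' is negative (", vals[[nm]], ")",
           call. = FALSE)
  }
  if (!is.finite(t)) stop("time 't' must be finite", call. = FALSE)
  structure(list(A = A, E = E, C = C, t = t), class = "ld_state")
}

#' Read / write parameter sets as flat YAML
#'
#' Parameter files are flat key-value YAML using the field names of
#' [model_parameters()]. The bundled file `table1_defaults.yaml` (under
#' `inst/extdata`) carries the reference defaults.
#'
#' @param path File path.
#' @return `read_parameters()` returns an `ld_params` object.
#' @examples
#' f <- system.file("extdata", "table1_defaults.yaml", package = "leukodyn")
#' read_parameters(f)
#' @export
read_parameters <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(model_parameters, vals)
}

#' @rdname read_parameters
#' @param params An `ld_params` object.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "ld_params"))
  yaml::write_yaml(lapply(unclass(params), identity), path)
  invisible(path)
}
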