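#' Drug specifications
#'
#' A drug is described by its molar mass, elimination half-life, the rounded
#' molecules-per-mg conversion constant used for dose schedules, and the
#' resulting chemical deactivation rate `mu_C = ln(2) / t_half`. Two drugs
#' are bundled: cytarabine (`"Cyt"`, M = 243.217 g/mol, 2.4e15 molecules/mg,
#' mu_C = 0.231 / h) and ibrutinib (`"Ibr"`, M = 440.5 g/mol, 1.4e15
#' molecules/mg, mu_C = 0.116 / h).
#'
#' @param name Drug identifier.
#' @param molar_mass Molar mass \[g/mol\].
#' @param t_half Elimination half-life \[h\].
#' @param molecules_per_mg Rounded molecules-per-mg constant used in dose
#'   schedules (see [dose_molecules()]).
#' @param mu_C Chemical deactivation rate \[1/h\]; defaults to
#'   `ln(2) / t_half` but the bundled specs pin the published rounded values.
#' @return An object of class `ld_drug`.
#' @examples
#' bundled_drug("Cyt")
#' drug_spec("X", molar_mass = 300, t_half = 2, molecules_per_mg = 2e15)
#' @export
drug_spec <- function(name, molar_mass, t_half, molecules_per_mg,
                      mu_C = decay_rate_from_half_life(t_half)) {
  stopifnot(is.character(name), length(name) == 1L)
  if (molar_mass <= 0) stop("molar_mass must be positive", call. = FALSE)
  if (t_half <= 0) stop("t_half must be positive", call. = FALSE)
  if (molecules_per_mg <= 0)
    stop("molecules_per_mg must be positive", call. = FALSE)
  structure(list(name = name, molar_mass = molar_mass, t_half = t_half,
                 molecules_per_mg = molecules_per_mg, mu_C = mu_C),
            class = "ld_drug")
}

#' @rdname drug_spec
#' @export
bundled_drug <- function(name = c("Cyt", "Ibr")) {
  name <- match.arg(name)
  switch(name,
         Cyt = drug_spec("Cyt", molar_mass = 243.217, t_half = 3,
                         molecules_per_mg = 2.4e15, mu_C = 0.231),
         Ibr = drug_spec("Ibr", molar_mass = 440.5, t_half = 6,
                         molecules_per_mg = 1.4e15, mu_C = 0.116))
}

#' Exact molecule count from drug mass
#'
#' Avogadro arithmetic, `mass_kg * 6.022e23 / molar_mass`, with the mass
#' entered in kilograms against the molar mass in g/mol — reproducing the
#' published worked conversions digit for digit (1.25 mg cytarabine ->
#' ~3e15 molecules; 0.36 mg ibrutinib -> ~5e14). Dose schedules use the
#' rounded per-mg constants instead (see [dose_molecules()]); this function
#' is the exact-audit counterpart.
#'
#' @param mass_kg Drug mass \[kg\] (>= 0).
#' @param molar_mass Molar mass \[g/mol\] (> 0).
#' @return Number of molecules.
#' @examples
#' molecules_from_mass(1.25e-6, 243.217)  # ~3e15
#' molecules_from_mass(3.6e-7, 440.5)     # ~5e14
#' @export
molecules_from_mass <- function(mass_kg, molar_mass) {
  if (any(mass_kg < 0)) stop("mass must be non-negative", call. = FALSE)
  if (any(molar_mass <= 0)) stop("molar_mass must be positive", call. = FALSE)
  mass_kg * 6.022e23 / molar_mass
}

#' Decay rate from elimination half-life
#'
#' First-order elimination: `mu_C = ln(2) / t_half`.
#'
#' @param t_half Elimination half-life \[h\] (> 0).
#' @return Decay rate \[1/h\].
#' @examples
#' decay_rate_from_half_life(3)  # 0.231 (cytarabine)
#' decay_rate_from_half_life(6)  # 0.116 (ibrutinib)
#' @export
decay_rate_from_half_life <- function(t_half) {
  if (any(!is.finite(t_half)) || any(t_half <= 0))
    stop("t_half must be positive", call. = FALSE)
  log(2) / t_half
}

#' Treatment protocols
#'
#' A clinical-style description of a regimen: drug, dose in mg/kg, the
#' 1-based treatment-day pattern (one administration at the start of each
#' listed day), the evaluation day for the inhibition readout, and the
#' mouse mass. The bundled protocols reproduce the in vivo study arms:
#'
#' * `cyt_low`: 0.12 mg/kg cytarabine, days 1-5
#' * `cyt_high`: 62.5 mg/kg cytarabine, days 1-3
#' * `ibr_low`: 9 mg/kg ibrutinib, days 1-5 and 8-10
#' * `ibr_high`: 18 mg/kg ibrutinib, days 1-5 and 8-10
#'
#' all evaluated on Day 12 with a 20 g mouse, and each carrying its
#' calibrated default cytotoxicity rate `mu_AC`.
#'
#' @param name Protocol identifier.
#' @param drug An `ld_drug` (see [bundled_drug()]).
#' @param dose_mg_per_kg Dose per administration \[mg/kg\].
#' @param dosing_days Sorted vector of distinct 1-based day indices.
#' @param evaluation_day Day of the inhibition readout (default 12).
#' @param mouse_mass_kg Mouse mass \[kg\] (default 0.020).
#' @param mu_AC Default drug cytotoxicity rate for this regimen \[1/h\].
#' @return An object of class `ld_protocol`.
#' @examples
#' bundled_protocol("cyt_high")
#' @export
treatment_protocol <- function(name, drug, dose_mg_per_kg, dosing_days,
                               evaluation_day = 12, mouse_mass_kg = 0.020,
                               mu_AC = NA_real_) {
  stopifnot(inherits(drug, "ld_drug"))
  if (length(dosing_days)) {
    if (any(duplicated(dosing_days)))
      stop("duplicate dosing days", call. = FALSE)
    if (is.unsorted(dosing_days))
      stop("dosing_days must be sorted", call. = FALSE)
    if (any(dosing_days < 1))
      stop("dosing_days are 1-based day indices", call. = FALSE)
  }
  if (dose_mg_per_kg < 0) stop("dose must be non-negative", call. = FALSE)
  if (mouse_mass_kg <= 0) stop("mouse mass must be positive", call. = FALSE)
  structure(list(name = name, drug = drug,
                 dose_mg_per_kg = dose_mg_per_kg,
                 dosing_days = as.integer(dosing_days),
                 evaluation_day = evaluation_day,
                 mouse_mass_kg = mouse_mass_kg,
                 mu_AC = mu_AC),
            class = "ld_protocol")
}

#' @rdname treatment_protocol
#' @export
bundled_protocol <- function(name = c("cyt_low", "cyt_high",
                                      "ibr_low", "ibr_high")) {
  name <- match.arg(name)
  switch(name,
    cyt_low = treatment_protocol("cyt_low", bundled_drug("Cyt"),
                                 0.12, 1:5, mu_AC = 0.001),
    cyt_high = treatment_protocol("cyt_high", bundled_drug("Cyt"),
                                  62.5, 1:3, mu_AC = 0.012),
    ibr_low = treatment_protocol("ibr_low", bundled_drug("Ibr"),
                                 9, c(1:5, 8:10), mu_AC = 0.0041),
    ibr_high = treatment_protocol("ibr_high", bundled_drug("Ibr"),
                                  18, c(1:5, 8:10), mu_AC = 0.0042))
}

#' @export
print.ld_protocol <- function(x, ...) {
  cat(sprintf("Protocol '%s': %g mg/kg %s on days %s; readout day %d\n",
              x$name, x$dose_mg_per_kg, x$drug$name,
              paste(x$dosing_days, collapse = ","), x$evaluation_day))
  invisible(x)
}

#' Per-administration molecule count for a protocol
#'
#' Converts mg/kg to mg per mouse (`dose_mg_per_kg * mouse_mass_kg`) and
#' multiplies by the drug's rounded molecules-per-mg constant, so that
#' 62.5 mg/kg cytarabine in a 20 g mouse gives exactly 3.0e15 molecules.
#' For the exact Avogadro arithmetic use [molecules_from_mass()].
#'
#' @param protocol An `ld_protocol`.
#' @param drug Drug spec; defaults to the protocol's own drug.
#' @return Molecules per administration.
#' @examples
#' dose_molecules(bundled_protocol("cyt_high"))  # 3e15
#' dose_molecules(bundled_protocol("ibr_high"))  # 5.04e14
#' @export
dose_molecules <- function(protocol, drug = protocol$drug) {
  stopifnot(inherits(protocol, "ld_protocol"), inherits(drug, "ld_drug"))
  if (!identical(drug$name, protocol$drug$name))
    stop("drug '", drug$name, "' is not the protocol's drug", call. = FALSE)
  mg_per_mouse <- protocol$dose_mg_per_kg * protocol$mouse_mass_kg
  mg_per_mouse * drug$molecules_per_mg
}

#' Build the impulsive dose schedule of a protocol
#'
#' One administration per treatment day, at `24 * (day - 1)` hours, with
#' the per-dose molecule count from [dose_molecules()]. An empty dosing-day
#' pattern yields an empty (drug-free) schedule.
#'
#' @param protocol An `ld_protocol`.
#' @return An [dose_schedule()] object.
#' @examples
#' build_schedule(bundled_protocol("ibr_low"))$dose_times
#' @export
build_schedule <- function(protocol) {
  stopifnot(inherits(protocol, "ld_protocol"))
  if (!length(protocol$dosing_days)) return(dose_schedule())
  dose_schedule(dose_molecules(protocol), 24 * (protocol$dosing_days - 1))
}

#' Combine two single-drug regimens into one mixed regimen
#'
#' The combined per-dose amount is the sum of the two per-dose molecule
#' counts; the combined chemical deactivation rate is the molecule-fraction
#' weighted average of the two single-drug rates; the combined cytotoxicity
#' rate is the *sum* of the two single-drug rates (no interaction term);
#' and the tumor-driven drug clearance keeps the tenfold linkage
#' `mu_CA = 10 * mu_AC`.
#'
#' By default molecule fractions are rounded to two decimals before the
#' weighted average, matching the published arithmetic for the
#' cytarabine-plus-ibrutinib regimen (fractions 0.92/0.08, combined
#' `mu_C = 0.2218`). Pass `round_fractions = NULL` for exact fractions.
#'
#' @param protocol_a,protocol_b Two `ld_protocol` objects.
#' @param muAC_a,muAC_b Single-drug cytotoxicity rates \[1/h\]; default to
#'   the protocols' own `mu_AC`.
#' @param dosing_days Day pattern of the merged course (default days 1-5
#'   and 8-10: five days on, two off, three on).
#' @param round_fractions Decimal places for the molecule fractions, or
#'   `NULL` for no rounding.
#' @return A list of class `ld_combination` with elements `dose_amount`,
#'   `fractions`, `mu_C`, `mu_AC`, `mu_CA`, `schedule`, `evaluation_day`
#'   and the component doses.
#' @examples
#' cmb <- combine_drugs(bundled_protocol("cyt_high"), bundled_protocol("ibr_low"))
#' cmb$dose_amount  # 3.252e15
#' cmb$mu_C         # 0.2218
#' @export
combine_drugs <- function(protocol_a, protocol_b,
                          muAC_a = protocol_a$mu_AC,
                          muAC_b = protocol_b$mu_AC,
                          dosing_days = c(1:5, 8:10),
                          round_fractions = 2) {
  stopifnot(inherits(protocol_a, "ld_protocol"),
            inherits(protocol_b, "ld_protocol"))
  d_a <- dose_molecules(protocol_a)
  d_b <- dose_molecules(protocol_b)
  d <- d_a + d_b
  if (d <= 0) stop("combined dose is zero", call. = FALSE)
  f <- c(d_a, d_b) / d
  if (!is.null(round_fractions)) f <- round(f, round_fractions)
  mu_C <- f[1] * protocol_a$drug$mu_C + f[2] * protocol_b$drug$mu_C
  mu_AC <- muAC_a + muAC_b
  structure(list(name = paste0(protocol_a$name, "+", protocol_b$name),
                 dose_amount = d,
                 dose_components = c(a = d_a, b = d_b),
                 fractions = stats::setNames(f, c(protocol_a$drug$name,
                                                  protocol_b$drug$name)),
                 mu_C = mu_C, mu_AC = mu_AC, mu_CA = 10 * mu_AC,
                 dosing_days = as.integer(dosing_days),
                 evaluation_day = max(protocol_a$evaluation_day,
                                      protocol_b$evaluation_day),
                 schedule = dose_schedule(d, 24 * (sort(dosing_days) - 1))),
            class = "ld_combination")
}

#' Read a protocol from a YAML config
#'
#' Keys: `name`, `drug` ("Cyt" or "Ibr", or a mapping with the
#' [drug_spec()] fields), `dose_mg_per_kg`, `days` (list of day indices or
#' a range string such as `"1-5,8-10"`), `evaluation_day`,
#' `mouse_mass_kg`, optional `mu_AC`. Bundled configs for the study arms
#' live under `system.file("extdata", "protocols", package = "leukodyn")`.
#'
#' @param path YAML file path.
#' @return An `ld_protocol`.
#' @examples
#' f <- system.file("extdata", "protocols", "cyt_high.yaml", package = "leukodyn")
#' read_protocol(f)
#' @export
read_protocol <- function(path) {
  cfg <- yaml::read_yaml(path)
  drug <- if (is.character(cfg$drug)) bundled_drug(cfg$drug) else
    do.call(drug_spec, cfg$drug)
  days <- parse_day_pattern(cfg$days)
  treatment_protocol(name = cfg$name %||% tools::file_path_sans_ext(basename(path)),
                     drug = drug,
                     dose_mg_per_kg = cfg$dose_mg_per_kg,
                     dosing_days = days,
                     evaluation_day = cfg$evaluation_day %||% 12,
                     mouse_mass_kg = cfg$mouse_mass_kg %||% 0.020,
                     mu_AC = cfg$mu_AC %||% NA_real_)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Parse a day-pattern string
#'
#' Accepts a numeric vector of day indices or a compact range string such
#' as `"1-5,8-10"`.
#'
#' @param x Numeric vector or range string.
#' @return Sorted integer vector of day indices.
#' @examples
#' parse_day_pattern("1-5,8-10")
#' @export
parse_day_pattern <- function(x) {
  if (is.numeric(x)) return(sort(as.integer(x)))
  if (is.list(x)) return(sort(as.integer(unlist(x))))
  stopifnot(is.character(x), length(x) == 1L)
  parts <- strsplit(gsub(" ", "", x), ",", fixed = TRUE)[[1]]
  days <- unlist(lapply(parts, function(p) {
    if (grepl("-", p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      seq(ab[1], ab[2])
    } else as.integer(p)
  }))
  sort(days)
}
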