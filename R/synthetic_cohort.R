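#' Configuration of the synthetic mouse-cohort generator
#'
#' Describes a simulated animal experiment: which groups to enrol, the
#' model parameters driving each group's whole-body tumor trajectory, and
#' the blood-readout noise model. Each mouse is bled twice (`pre` at
#' treatment day 0, `post` at the evaluation day) and its leukemic-cell
#' count among `readout_depth` analyzed blood cells is recorded, mimicking
#' a fixed-event flow-cytometry acquisition.
#'
#' The readout model has two noise layers:
#' * a per-mouse multiplicative log-normal factor (sd `mouse_effect_sd` on
#'   the log scale, median 1) on the blood-sampling fraction, constant
#'   across that mouse's two bleeds — so frequency *changes* cancel it;
#' * binomial count sampling at `readout_depth` events.
#'
#' `sampling_fraction` converts whole-body tumor burden to expected blood
#' frequency; it is a nuisance constant (the downstream estimator is
#' invariant to it) chosen so that frequencies stay in a realistic
#' flow-cytometry range over the study window.
#'
#' @param params Base [model_parameters()] (drug-free entries are used for
#'   the control group).
#' @param groups Character vector of group names; `"control"` plus any of
#'   the bundled protocol names and `"combo"`.
#' @param protocols Named list mapping treated group names to
#'   `ld_protocol` / `ld_combination` objects; defaults to the bundled
#'   arms.
#' @param n_mice Mice per group.
#' @param sampling_fraction Expected blood-readout frequency per whole-body
#'   tumor cell.
#' @param mouse_effect_sd Log-scale sd of the per-mouse factor; 0 disables
#'   inter-mouse variability.
#' @param readout_depth Analyzed blood cells per bleed (default 2e5).
#' @param pre_day,post_day Study days of the two bleeds.
#' @param count_noise `"binomial"` (default) or `"none"` (counts set to
#'   their expectation; useful for exactness checks).
#' @return A list of class `ld_cohort_config`.
#' @examples
#' cohort_config(groups = c("control", "cyt_high"), n_mice = 4)
#' @export
cohort_config <- function(params = model_parameters(),
                          groups = c("control", "cyt_low", "cyt_high",
                                     "ibr_low", "ibr_high"),
                          protocols = NULL,
                          n_mice = 4,
                          sampling_fraction = 5e-7,
                          mouse_effect_sd = 0.2,
                          readout_depth = 2e5,
                          pre_day = 0,
                          post_day = 12,
                          count_noise = c("binomial", "none")) {
  count_noise <- match.arg(count_noise)
  if (sampling_fraction <= 0)
    stop("sampling_fraction must be positive", call. = FALSE)
  if (n_mice < 1) stop("need at least one mouse per group", call. = FALSE)
  if (mouse_effect_sd < 0)
    stop("mouse_effect_sd must be non-negative", call. = FALSE)
  if (is.null(protocols)) {
    protocols <- list()
    for (g in setdiff(groups, c("control", "combo")))
      protocols[[g]] <- bundled_protocol(g)
    if ("combo" %in% groups)
      protocols$combo <- combine_drugs(bundled_protocol("cyt_high"),
                                       bundled_protocol("ibr_low"))
  }
  missing <- setdiff(setdiff(groups, "control"), names(protocols))
  if (length(missing))
    stop("no protocol supplied for group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(params = params, groups = groups, protocols = protocols,
                 n_mice = n_mice, sampling_fraction = sampling_fraction,
                 mouse_effect_sd = mouse_effect_sd,
                 readout_depth = readout_depth,
                 pre_day = pre_day, post_day = post_day,
                 count_noise = count_noise),
            class = "ld_cohort_config")
}

#' Generate a synthetic mouse cohort
#'
#' For each group, integrates the group's whole-body trajectory (control:
#' drug-free; treated: the group's protocol with its calibrated `mu_AC`),
#' then draws each mouse's pre- and post-bleed counts under the noise model
#' of [cohort_config()]. Deterministic under a fixed seed.
#'
#' @param config An `ld_cohort_config`.
#' @param seed Integer seed; the run is reproducible bit-for-bit.
#' @return A data frame of class `ld_cohort` with columns
#'   `mouse_id, group, timepoint, day, a20_count, readout_depth`, two rows
#'   (pre/post) per mouse.
#' @examples
#' coh <- generate_cohort(cohort_config(groups = "control", n_mice = 4),
#'                        seed = 42)
#' head(coh)
#' @export
generate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "ld_cohort_config"))
  set.seed(seed)
  t_pre <- 24 * config$pre_day
  t_post <- 24 * config$post_day
  t_end <- max(t_pre, t_post)
  rows <- list()
  for (g in config$groups) {
    if (g == "control") {
      prm <- do.call(model_parameters,
                     utils::modifyList(unclass(config$params),
                                       list(mu_AC = 0, mu_CA = 0)))
      traj <- simulate_model(prm, dose_schedule(), t_end = t_end)
    } else {
      proto <- config$protocols[[g]]
      if (inherits(proto, "ld_combination")) {
        prm <- do.call(model_parameters,
                       utils::modifyList(unclass(config$params),
                                         list(mu_AC = proto$mu_AC,
                                              mu_CA = proto$mu_CA,
                                              mu_C = proto$mu_C)))
        sched <- proto$schedule
      } else {
        prm <- do.call(model_parameters,
                       utils::modifyList(unclass(config$params),
                                         list(mu_AC = proto$mu_AC,
                                              mu_CA = 10 * proto$mu_AC,
                                              mu_C = proto$drug$mu_C)))
        sched <- build_schedule(proto)
      }
      traj <- simulate_model(prm, sched, t_end = t_end)
    }
    a_pre <- trajectory_state(traj, t_pre)[["A"]]
    a_post <- trajectory_state(traj, t_post)[["A"]]
    for (i in seq_len(config$n_mice)) {
      mouse_factor <- if (config$mouse_effect_sd > 0)
        stats::rlnorm(1, meanlog = 0, sdlog = config$mouse_effect_sd) else 1
      for (tp in c("pre", "post")) {
        a <- if (tp == "pre") a_pre else a_post
        day <- if (tp == "pre") config$pre_day else config$post_day
        freq <- a * config$sampling_fraction * mouse_factor
        if (freq > 1)
          stop("expected blood frequency ", signif(freq, 3),
               " exceeds 1 for group '", g,
               "'; use a smaller sampling_fraction", call. = FALSE)
        count <- switch(config$count_noise,
                        binomial = stats::rbinom(1, config$readout_depth, freq),
                        none = freq * config$readout_depth)
        rows[[length(rows) + 1L]] <-
          data.frame(mouse_id = sprintf("%s_m%02d", g, i),
                     group = g, timepoint = tp, day = day,
                     a20_count = count,
                     readout_depth = config$readout_depth)
      }
    }
  }
  structure(do.call(rbind, rows),
            class = c("ld_cohort", "data.frame"),
            config = config, seed = seed)
}

#' Estimate percent growth inhibition from a cohort table
#'
#' Implements the frequency-based readout of the animal experiment: at each
#' timepoint, every mouse's leukemic-cell frequency is normalized to the
#' control group's average frequency at that timepoint; each mouse's
#' percent change between bleeds is computed from the normalized
#' frequencies (so per-mouse sampling factors cancel); the group-average
#' change of the treated arm is then differenced against the control arm's
#' own average change. For noise-free data this reduces exactly to
#' `100 * (1 - A_treated / A_control)` at the post bleed, i.e. to
#' [inhibition_percent()].
#'
#' @param cohort An `ld_cohort` data frame (or one read by [read_cohort()]).
#' @param group Treated group name.
#' @return Percent inhibition (scalar).
#' @examples
#' cfg <- cohort_config(groups = c("control", "cyt_high"))
#' coh <- generate_cohort(cfg, seed = 7)
#' estimate_inhibition(coh, "cyt_high")
#' @export
estimate_inhibition <- function(cohort, group) {
  stopifnot(is.data.frame(cohort))
  if (!"control" %in% cohort$group)
    stop("cohort has no control group", call. = FALSE)
  if (!group %in% cohort$group)
    stop("group '", group, "' not present in cohort", call. = FALSE)
  freq <- cohort$a20_count / cohort$readout_depth
  ctl_pre <- mean(freq[cohort$group == "control" & cohort$timepoint == "pre"])
  ctl_post <- mean(freq[cohort$group == "control" & cohort$timepoint == "post"])
  if (ctl_pre == 0 || ctl_post == 0)
    stop("control-group average frequency is zero; inhibition undefined",
         call. = FALSE)

  pct_change <- function(g) {
    pre <- cohort[cohort$group == g & cohort$timepoint == "pre", ]
    post <- cohort[cohort$group == g & cohort$timepoint == "post", ]
    m <- merge(pre[, c("mouse_id", "a20_count", "readout_depth")],
               post[, c("mouse_id", "a20_count", "readout_depth")],
               by = "mouse_id", suffixes = c("_pre", "_post"))
    x_pre <- (m$a20_count_pre / m$readout_depth_pre) / ctl_pre
    x_post <- (m$a20_count_post / m$readout_depth_post) / ctl_post
    if (any(x_pre == 0))
      stop("zero pre-treatment count for mouse ",
           paste(m$mouse_id[x_pre == 0], collapse = ", "),
           "; per-mouse change undefined", call. = FALSE)
    mean(100 * (x_post / x_pre - 1))
  }
  pct_change("control") - pct_change(group)
}

#' Write / read a cohort table as CSV
#'
#' Columns: `mouse_id,group,timepoint,day,a20_count,readout_depth`.
#'
#' @param cohort An `ld_cohort` data frame.
#' @param path CSV file path.
#' @return `read_cohort()` returns the cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mouse_id", "group", "timepoint", "day", "a20_count",
            "readout_depth")
  if (!all(need %in% names(df)))
    stop("cohort CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  structure(df, class = c("ld_cohort", "data.frame"))
}
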