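#' Trial simulation specification
#'
#' Defines a two-arm trial whose Kaplan-Meier curves stand in for
#' digitized published curves. Per-patient progression times are drawn
#' from a Weibull (shape 1 = exponential by default) with the stated
#' control median; death times are the progression time plus an
#' exponential post-progression survival draw, so OS >= PFS holds for
#' every simulated patient by construction. The treated arm applies the
#' PFS hazard ratio to the progression hazard and the OS hazard ratio to
#' the post-progression hazard (proportional hazards). Follow-up is
#' administratively censored at `max_follow_up`.
#'
#' @param n_patients patients per arm (>= 2).
#' @param control_median_pfs control-arm median progression-free
#'   survival, years.
#' @param control_median_os control-arm median overall survival, years
#'   (> median PFS; the post-progression survival draw has median
#'   `control_median_os - control_median_pfs`, floored at one month).
#' @param hr_pfs treated-vs-control hazard ratio for progression
#'   ([hazard_ratio()] or number).
#' @param hr_os hazard ratio applied to post-progression survival
#'   (default 1: no post-progression benefit).
#' @param weibull_shape shape of the progression-time distribution
#'   (default 1, exponential).
#' @param max_follow_up administrative censoring time, years.
#' @param seed integer seed making the simulation reproducible.
#' @return a `trial_sim_spec` object.
#' @export
trial_sim_spec <- function(n_patients = 500,
                           control_median_pfs,
                           control_median_os,
                           hr_pfs = hazard_ratio(1),
                           hr_os = hazard_ratio(1),
                           weibull_shape = 1,
                           max_follow_up = 5,
                           seed = 1L) {
  stopifnot(n_patients >= 2, control_median_pfs > 0,
            control_median_os > 0, weibull_shape > 0, max_follow_up > 0)
  structure(list(n_patients = as.integer(n_patients),
                 control_median_pfs = control_median_pfs,
                 control_median_os = control_median_os,
                 hr_pfs = .hr_value(hr_pfs), hr_os = .hr_value(hr_os),
                 weibull_shape = weibull_shape,
                 max_follow_up = max_follow_up, seed = as.integer(seed)),
            class = "trial_sim_spec")
}

# Kaplan-Meier step curve from event/censor data via survival::survfit
.km_curve <- function(time, event, label) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  survival_curve("step", times = c(0, fit$time), probs = c(1, fit$surv),
                 label = label)
}

#' Simulate trial-like PFS and OS Kaplan-Meier curves
#'
#' @param spec a [trial_sim_spec()].
#' @return a list with elements `control` and `treated`, each a list of
#'   step `survival_curve`s `pfs` and `os`, plus `data`, the per-patient
#'   data frame (`arm`, `prog_time`, `death_time`, censored analogues).
#' @export
#' @examples
#' sim <- simulate_trial_curves(trial_sim_spec(
#'   n_patients = 200, control_median_pfs = 0.6, control_median_os = 2,
#'   hr_pfs = 0.3, seed = 7))
#' curve_median(sim$control$pfs)
simulate_trial_curves <- function(spec) {
  stopifnot(inherits(spec, "trial_sim_spec"))
  n <- spec$n_patients
  k <- spec$weibull_shape
  # scale such that S(median) = 0.5 for the control arm
  scale_c <- spec$control_median_pfs / log(2)^(1 / k)
  pp_median <- max(spec$control_median_os - spec$control_median_pfs, 1 / 12)
  pp_rate <- log(2) / pp_median
  draw_arm <- function(arm, hr_pfs, hr_os) {
    # proportional hazards: scale shrinks by hr^(1/k)
    prog <- stats::rweibull(n, shape = k,
                            scale = scale_c * hr_pfs^(-1 / k))
    post <- stats::rexp(n, rate = pp_rate * hr_os)
    death <- prog + post
    data.frame(arm = arm, prog_time = prog, death_time = death)
  }
  d <- withr::with_seed(spec$seed, {
    rbind(draw_arm("control", 1, 1),
          draw_arm("treated", spec$hr_pfs, spec$hr_os))
  })
  tau <- spec$max_follow_up
  d$pfs_time <- pmin(d$prog_time, tau)
  d$pfs_event <- as.integer(d$prog_time <= tau)
  d$os_time <- pmin(d$death_time, tau)
  d$os_event <- as.integer(d$death_time <= tau)
  arm_curves <- function(a) {
    da <- d[d$arm == a, ]
    list(pfs = .km_curve(da$pfs_time, da$pfs_event, paste0(a, " PFS")),
         os = .km_curve(da$os_time, da$os_event, paste0(a, " OS")))
  }
  list(control = arm_curves("control"), treated = arm_curves("treated"),
       data = d)
}
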