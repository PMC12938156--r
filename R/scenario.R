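#' Build a bundled scenario
#'
#' A scenario bundles strategies (regimen + arm-specific PFS/OS curves),
#' utilities, horizon, discount rate and WTP threshold into one runnable
#' configuration. Three presets ship with the package:
#'
#' * `"dmmr"` — mismatch-repair-deficient subgroup: strategies TC,
#'   PEM-TC, DOS-TC (2- and 3-year maintenance) and DUO-TC (2- and
#'   3-year maintenance), with PFS hazard ratios 0.30 / 0.29 / 0.42
#'   versus chemotherapy and a control median PFS of 7.6 months.
#' * `"pmmr"` — mismatch-repair-proficient subgroup: TC, PEM-TC and
#'   DOS-TC (2y/3y), PFS hazard ratios 0.54 / 0.76, control median PFS
#'   8.7 months.
#' * `"toy"` — two exponential strategies with no toxicity, built so
#'   every model output has a closed form (for analytic tests).
#'
#' Curves are exponential by default (`curves = "parametric"`,
#' deterministic, derived from the control medians and hazard ratios);
#' `curves = "km"` replaces them with Kaplan-Meier step curves from
#' [simulate_trial_curves()] at the stated trial sizes. The OS curve is
#' shared across arms (crossover confounds the published OS effect; the
#' base case takes no post-progression survival benefit).
#'
#' @param preset `"dmmr"`, `"pmmr"` or `"toy"`.
#' @param curves `"parametric"` (default) or `"km"`.
#' @param seed integer seed used when `curves = "km"`.
#' @return a `cea_scenario` object.
#' @export
#' @examples
#' sc <- build_scenario("toy")
#' run_cea(sc)
build_scenario <- function(preset = c("dmmr", "pmmr", "toy"),
                           curves = c("parametric", "km"), seed = 1L) {
  preset <- match.arg(preset)
  curves <- match.arg(curves)
  if (preset == "toy") return(.toy_scenario())
  horizon <- 5
  median_os <- 3.0
  if (preset == "dmmr") {
    median_pfs <- 7.6 / 12
    arms <- list("PEM-TC" = 0.30, "DOS-TC-2y" = 0.29, "DOS-TC-3y" = 0.29,
                 "DUO-TC-2y" = 0.42, "DUO-TC-3y" = 0.42)
  } else {
    median_pfs <- 8.7 / 12
    arms <- list("PEM-TC" = 0.54, "DOS-TC-2y" = 0.76, "DOS-TC-3y" = 0.76)
  }
  os <- exp_curve(median = median_os, label = "OS")
  pfs_control <- exp_curve(median = median_pfs, label = "control PFS")
  if (curves == "km") {
    # one simulated trial per distinct drug; the control arm is shared
    hrs <- unlist(arms)
    sims <- lapply(seq_along(hrs), function(i)
      simulate_trial_curves(trial_sim_spec(
        n_patients = 400, control_median_pfs = median_pfs,
        control_median_os = median_os, hr_pfs = hrs[i],
        max_follow_up = horizon, seed = seed + i)))
    names(sims) <- names(arms)
    ctrl <- simulate_trial_curves(trial_sim_spec(
      n_patients = 400, control_median_pfs = median_pfs,
      control_median_os = median_os, hr_pfs = 1,
      max_follow_up = horizon, seed = seed))
    strategies <- c(
      list(strategy(regimen_preset("TC"), ctrl$control$pfs,
                    ctrl$control$os, name = "TC")),
      lapply(names(arms), function(nm)
        strategy(regimen_preset(nm), sims[[nm]]$treated$pfs,
                 sims[[nm]]$treated$os, name = nm)))
  } else {
    strategies <- c(
      list(strategy(regimen_preset("TC"), pfs_control, os, name = "TC")),
      lapply(names(arms), function(nm)
        strategy(regimen_preset(nm),
                 apply_hazard_ratio(pfs_control, arms[[nm]]), os,
                 name = nm)))
  }
  names(strategies) <- vapply(strategies, `[[`, "", "name")
  cea_scenario(
    name = paste0(preset, " advanced/recurrent endometrial cancer"),
    strategies = strategies, utilities = utility_set(0.84, 0.50),
    horizon = horizon, discount_rate = 0, wtp = 1e5, comparator = "TC",
    mmr_split = c(dmmr = 0.33, pmmr = 0.67), seed = seed)
}

.toy_scenario <- function() {
  no_tox <- toxicity_profile(0, 0)
  reg_active <- regimen(
    "active",
    induction = dose_phase(weeks(3), max_doses = 6, fixed_cost = 1000),
    guaranteed_doses = 0, toxicity = no_tox)
  reg_control <- regimen(
    "control",
    induction = dose_phase(weeks(3), max_doses = 6, fixed_cost = 100),
    guaranteed_doses = 0, toxicity = no_tox)
  strategies <- list(
    control = strategy(reg_control, exp_curve(rate = 0.9),
                       exp_curve(rate = 0.3), name = "control"),
    active = strategy(reg_active, exp_curve(rate = 0.3),
                      exp_curve(rate = 0.1), name = "active"))
  cea_scenario(name = "toy exponential scenario", strategies = strategies,
               utilities = utility_set(0.84, 0.50), horizon = 5,
               discount_rate = 0, wtp = 1e5, comparator = "control",
               mmr_split = NULL, seed = 1L)
}

#' Construct a scenario
#'
#' @param name scenario name.
#' @param strategies named list of [strategy()] objects.
#' @param utilities a [utility_set()].
#' @param horizon model horizon in years, > 0.
#' @param discount_rate continuous discount rate per year, >= 0.
#' @param wtp willingness-to-pay threshold, USD per effectiveness unit.
#' @param comparator name of the comparator strategy.
#' @param mmr_split optional named vector recording the assumed
#'   dMMR/pMMR prevalence split (metadata only; results are reported per
#'   subgroup, never prevalence-weighted).
#' @param seed integer seed attached to the scenario.
#' @return a `cea_scenario` object.
#' @export
cea_scenario <- function(name, strategies, utilities, horizon = 5,
                         discount_rate = 0, wtp = 1e5, comparator,
                         mmr_split = NULL, seed = 1L) {
  stopifnot(length(strategies) >= 1,
            all(vapply(strategies, inherits, TRUE, "strategy")),
            inherits(utilities, "utility_set"))
  if (!is.numeric(horizon) || horizon <= 0)
    stop("invalid `horizon`: must be > 0", call. = FALSE)
  if (!is.numeric(discount_rate) || discount_rate < 0)
    stop("invalid `discount_rate`: must be >= 0", call. = FALSE)
  if (!is.numeric(wtp) || wtp < 0)
    stop("invalid `wtp`: must be >= 0", call. = FALSE)
  if (is.null(names(strategies)) || any(names(strategies) == ""))
    names(strategies) <- vapply(strategies, `[[`, "", "name")
  if (!comparator %in% names(strategies))
    stop("invalid `comparator`: no strategy named `", comparator, "`",
         call. = FALSE)
  structure(list(name = name, strategies = strategies,
                 utilities = utilities, horizon = horizon,
                 discount_rate = discount_rate, wtp = wtp,
                 comparator = comparator, mmr_split = mmr_split,
                 seed = as.integer(seed)),
            class = "cea_scenario")
}

#' @export
print.cea_scenario <- function(x, ...) {
  cat(sprintf(
    "<cea_scenario: %s>\n  strategies: %s (comparator %s)\n  horizon %g y, discount %g/y, WTP $%s\n",
    x$name, paste(names(x$strategies), collapse = ", "), x$comparator,
    x$horizon, x$discount_rate, format(x$wtp, big.mark = ",")))
  invisible(x)
}

#' Run the deterministic cost-effectiveness analysis of a scenario
#'
#' Evaluates every strategy (expected cost, PFLY, QA-PFLYS, QALY) and
#' performs the incremental analysis against the scenario's comparator.
#'
#' @param scenario a `cea_scenario`.
#' @param effect effectiveness measure for the incremental analysis,
#'   `"qa_pflys"` (default) or `"qalys"`.
#' @return a `cea_result` data frame (see [incremental_analysis()]).
#' @export
run_cea <- function(scenario, effect = c("qa_pflys", "qalys")) {
  stopifnot(inherits(scenario, "cea_scenario"))
  effect <- match.arg(effect)
  rows <- do.call(rbind, lapply(scenario$strategies, evaluate_strategy,
                                utilities = scenario$utilities,
                                horizon = scenario$horizon,
                                discount_rate = scenario$discount_rate))
  rownames(rows) <- NULL
  out <- incremental_analysis(rows, scenario$comparator, effect = effect)
  structure(out, class = c("cea_result", "data.frame"),
            scenario = scenario$name, wtp = scenario$wtp, effect = effect)
}

# ---- named model parameters (for OWSA / tornado / PSA) ----------------

#' List the tunable parameters of a scenario
#'
#' Returns the registry of named parameters the sensitivity analyses
#' can vary: health-state utilities, per-strategy drug price, toxicity
#' probability/cost/utility, maintenance duration (where capped), and —
#' for parametric curves — the PFS rate standing in for the response
#' rate. One-way bounds default to +/-20% of base, except probabilities
#' and utilities which move +/-10% (capped at 1), in step with the
#' probabilistic distributions: gamma for costs (SE 20% of base), beta
#' for probabilities and utilities (SE 10% of base) and fixed for
#' structural settings and survival-curve parameters (which have no
#' joint uncertainty model preserving PFS <= OS).
#'
#' @param scenario a `cea_scenario`.
#' @param strategies strategies whose parameters to list (default: all
#'   non-comparator strategies plus the comparator's toxicity).
#' @return a data frame: `name`, `base`, `low`, `high`, `distribution`.
#' @export
scenario_parameters <- function(scenario,
                                strategies = names(scenario$strategies)) {
  stopifnot(inherits(scenario, "cea_scenario"))
  rows <- list(
    data.frame(name = "utility.on_treatment",
               base = scenario$utilities$on_treatment,
               distribution = "beta"),
    data.frame(name = "utility.progressive",
               base = scenario$utilities$progressive,
               distribution = "beta"))
  for (s in strategies) {
    st <- scenario$strategies[[s]]
    reg <- st$regimen
    if (reg$drug_price > 0)
      rows <- c(rows, list(data.frame(
        name = paste0("drug_price.", s), base = reg$drug_price,
        distribution = "gamma")))
    if (reg$toxicity$cost > 0) {
      rows <- c(rows, list(
        data.frame(name = paste0("toxicity_probability.", s),
                   base = reg$toxicity$probability, distribution = "beta"),
        data.frame(name = paste0("toxicity_cost.", s),
                   base = reg$toxicity$cost, distribution = "gamma"),
        data.frame(name = paste0("toxicity_utility.", s),
                   base = reg$toxicity$utility, distribution = "beta")))
    }
    if (is.finite(reg$max_treatment_years) && !is.null(reg$maintenance))
      rows <- c(rows, list(data.frame(
        name = paste0("maintenance_years.", s),
        base = reg$max_treatment_years, distribution = "fixed")))
    # response-rate surrogate: varied one-way, but held fixed in the
    # PSA — drawing PFS hazards independently of the shared OS curve
    # can violate PFS <= OS, and no joint uncertainty model is defined
    if (st$pfs$kind != "step")
      rows <- c(rows, list(data.frame(
        name = paste0("pfs_rate.", s), base = st$pfs$rate,
        distribution = "fixed")))
  }
  out <- do.call(rbind, rows)
  # one-way bounds: +/-20% of base, except bounded (beta) parameters --
  # probabilities and utilities -- which move +/-10%, mirroring the
  # half-sized standard error the probabilistic analysis assigns them
  bounded <- out$distribution == "beta"
  spread <- ifelse(bounded, 0.1, 0.2)
  out$low <- out$base * (1 - spread)
  out$high <- out$base * (1 + spread)
  out$high[bounded] <- pmin(out$high[bounded], 1)
  rownames(out) <- NULL
  out[, c("name", "base", "low", "high", "distribution")]
}

#' Set a named scenario parameter
#'
#' @param scenario a `cea_scenario`.
#' @param name a parameter name as listed by [scenario_parameters()]
#'   (`"utility.on_treatment"`, `"drug_price.<strategy>"`, ...).
#' @param value new value.
#' @return the modified scenario.
#' @export
set_scenario_parameter <- function(scenario, name, value) {
  stopifnot(inherits(scenario, "cea_scenario"), is.numeric(value),
            length(value) == 1)
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  field <- parts[1]
  strat <- if (length(parts) > 1) paste(parts[-1], collapse = ".") else NULL
  if (field != "utility" && !is.null(strat) &&
      !strat %in% names(scenario$strategies))
    stop("unknown strategy in parameter name: ", name, call. = FALSE)
  switch(
    field,
    "utility" = {
      if (!strat %in% c("on_treatment", "progressive"))
        stop("unknown parameter: ", name, call. = FALSE)
      scenario$utilities[[strat]] <- value
    },
    "drug_price" =
      scenario$strategies[[strat]]$regimen$drug_price <- value,
    "toxicity_probability" =
      scenario$strategies[[strat]]$regimen$toxicity$probability <- value,
    "toxicity_cost" =
      scenario$strategies[[strat]]$regimen$toxicity$cost <- value,
    "toxicity_utility" =
      scenario$strategies[[strat]]$regimen$toxicity$utility <- value,
    "maintenance_years" =
      scenario$strategies[[strat]]$regimen$max_treatment_years <- value,
    "pfs_rate" = {
      if (scenario$strategies[[strat]]$pfs$kind == "step")
        stop("pfs_rate only applies to parametric curves: ", name,
             call. = FALSE)
      scenario$strategies[[strat]]$pfs$rate <- value
    },
    stop("unknown parameter: ", name, call. = FALSE)
  )
  scenario
}
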