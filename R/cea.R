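#' Health-state utilities
#'
#' @param on_treatment utility for progression-free patients on active
#'   treatment, in `[0, 1]` (bundled default 0.84; an alternative
#'   scenario uses 0.80).
#' @param progressive utility in the post-progression state, in `[0, 1]`
#'   (default 0.50).
#' @return a `utility_set` object.
#' @export
utility_set <- function(on_treatment = 0.84, progressive = 0.50) {
  stopifnot(on_treatment >= 0, on_treatment <= 1,
            progressive >= 0, progressive <= 1)
  structure(list(on_treatment = on_treatment, progressive = progressive),
            class = "utility_set")
}

#' Treatment strategy
#'
#' A strategy binds a regimen to its arm-specific PFS and OS curves and
#' a flat cost rate while in the post-progression state.
#'
#' @param name strategy name (defaults to the regimen name).
#' @param regimen a [regimen()].
#' @param pfs,os `survival_curve`s for this arm, defined on the model
#'   horizon.
#' @param post_progression_cost_rate USD per year spent in the
#'   post-progression state (default 0).
#' @return a `strategy` object.
#' @export
strategy <- function(regimen, pfs, os, name = regimen$name,
                     post_progression_cost_rate = 0) {
  stopifnot(inherits(regimen, "regimen"),
            inherits(pfs, "survival_curve"), inherits(os, "survival_curve"),
            post_progression_cost_rate >= 0)
  structure(list(name = name, regimen = regimen, pfs = pfs, os = os,
                 post_progression_cost_rate = post_progression_cost_rate),
            class = "strategy")
}

# effective on-treatment utility integral over [0, horizon]:
# u * [m * A(0, d) + A(d, H)] with m the expected toxicity multiplier
# over the toxicity window d
.pf_utility_area <- function(pfs, utilities, toxicity, horizon,
                             discount_rate) {
  u <- utilities$on_treatment
  if (is.null(toxicity) || toxicity$probability == 0 ||
      toxicity$duration == 0 || toxicity$utility == 1)
    return(u * curve_area(pfs, 0, horizon, discount_rate))
  m <- 1 - toxicity$probability * (1 - toxicity$utility)
  d <- min(toxicity$duration, horizon)
  u * (m * curve_area(pfs, 0, d, discount_rate) +
         curve_area(pfs, d, horizon, discount_rate))
}

#' Quality-adjusted progression-free life-years (QA-PFLYS)
#'
#' The discounted integral of progression-free occupancy weighted by the
#' on-treatment utility, with the utility reduced by the toxicity
#' multiplier (weighted by the toxicity probability) during the toxicity
#' window:
#' \eqn{\int_0^{H} u_{eff}(t)\, PF(t)\, e^{-rt}\, dt}.
#'
#' @param occupancy a `state_occupancy` from [partition()].
#' @param utilities a [utility_set()].
#' @param toxicity a [toxicity_profile()] or `NULL` for none.
#' @param horizon model horizon in years.
#' @param discount_rate continuous discount rate per year (default 0).
#' @return QA-PFLYS (years).
#' @export
qa_pflys <- function(occupancy, utilities, toxicity = NULL, horizon,
                     discount_rate = 0) {
  pfs <- occ_pfs_curve(occupancy)
  stopifnot(!is.null(pfs), inherits(utilities, "utility_set"))
  .pf_utility_area(pfs, utilities, toxicity, horizon, discount_rate)
}

#' Quality-adjusted life-years (QALYs)
#'
#' Adds the post-progression term
#' \eqn{\int_0^{H} u_{pp}\, PP(t)\, e^{-rt}\, dt} to [qa_pflys()],
#' where PP(t) = OS(t) - PFS(t).
#'
#' @inheritParams qa_pflys
#' @return QALYs (years).
#' @export
qalys <- function(occupancy, utilities, toxicity = NULL, horizon,
                  discount_rate = 0) {
  os <- occ_os_curve(occupancy)
  pfs <- occ_pfs_curve(occupancy)
  stopifnot(!is.null(os), !is.null(pfs))
  pp_area <- curve_area(os, 0, horizon, discount_rate) -
    curve_area(pfs, 0, horizon, discount_rate)
  qa_pflys(occupancy, utilities, toxicity, horizon, discount_rate) +
    utilities$progressive * max(pp_area, 0)
}

#' Total expected cost of a strategy
#'
#' Drug cost + expected toxicity cost + post-progression cost rate times
#' discounted post-progression person-years.
#'
#' @param strategy a [strategy()].
#' @param horizon model horizon in years.
#' @param discount_rate continuous discount rate per year.
#' @return expected cost in 2024 USD.
#' @export
total_cost <- function(strategy, horizon, discount_rate = 0) {
  stopifnot(inherits(strategy, "strategy"))
  pp_area <- curve_area(strategy$os, 0, horizon, discount_rate) -
    curve_area(strategy$pfs, 0, horizon, discount_rate)
  drug_cost(strategy$regimen, strategy$pfs, horizon, discount_rate) +
    toxicity_cost(strategy$regimen$toxicity) +
    strategy$post_progression_cost_rate * max(pp_area, 0)
}

#' Evaluate one strategy: cost and effectiveness
#'
#' @inheritParams total_cost
#' @param utilities a [utility_set()].
#' @return a one-row data frame: `strategy`, `total_cost`, `pfly`
#'   (unadjusted progression-free life-years), `qa_pflys`, `qalys`.
#' @export
evaluate_strategy <- function(strategy, utilities, horizon,
                              discount_rate = 0) {
  occ <- partition(strategy$os, strategy$pfs, horizon = horizon)
  data.frame(
    strategy = strategy$name,
    total_cost = total_cost(strategy, horizon, discount_rate),
    pfly = curve_area(strategy$pfs, 0, horizon, discount_rate),
    qa_pflys = qa_pflys(occ, utilities, strategy$regimen$toxicity,
                        horizon, discount_rate),
    qalys = qalys(occ, utilities, strategy$regimen$toxicity,
                  horizon, discount_rate))
}

#' Incremental cost-effectiveness analysis
#'
#' For each strategy against the named comparator, computes incremental
#' cost, incremental effectiveness and their ratio (the ICER =
#' incremental cost / incremental effectiveness). Dominance is flagged
#' instead of reporting a negative ICER: a strategy that is cheaper and
#' more effective than the comparator is `dominant`, one that is costlier
#' and less effective is `dominated`, and a zero incremental effect
#' leaves the ICER `undefined`.
#'
#' @param results a data frame with columns `strategy`, `total_cost` and
#'   the effectiveness column named by `effect` (as produced by
#'   [evaluate_strategy()] / [run_cea()]), one row per strategy.
#' @param comparator name of the comparator strategy (present in
#'   `results`).
#' @param effect which effectiveness column to use (default
#'   `"qa_pflys"`).
#' @return `results` with added columns `incremental_cost`,
#'   `incremental_effect`, `icer` (`NA` where not reportable) and
#'   `status` (`"comparator"`, `"icer"`, `"dominant"`, `"dominated"`,
#'   `"undefined"`).
#' @export
#' @examples
#' res <- data.frame(strategy = c("TC", "PEM-TC"),
#'                   total_cost = c(19259, 320696),
#'                   qa_pflys = c(1, 2.385))
#' incremental_analysis(res, "TC")
incremental_analysis <- function(results, comparator, effect = "qa_pflys") {
  stopifnot(is.data.frame(results),
            all(c("strategy", "total_cost", effect) %in% names(results)))
  if (!comparator %in% results$strategy)
    stop("comparator `", comparator, "` not among the strategies",
         call. = FALSE)
  base <- results[results$strategy == comparator, , drop = FALSE][1, ]
  dc <- results$total_cost - base$total_cost
  de <- results[[effect]] - base[[effect]]
  icer <- rep(NA_real_, nrow(results))
  status <- rep("icer", nrow(results))
  status[results$strategy == comparator] <- "comparator"
  status[de == 0 & status == "icer"] <- "undefined"
  status[dc < 0 & de > 0] <- "dominant"
  status[dc > 0 & de < 0] <- "dominated"
  ok <- status == "icer"
  icer[ok] <- dc[ok] / de[ok]
  out <- results
  out$incremental_cost <- dc
  out$incremental_effect <- de
  out$icer <- icer
  out$status <- status
  out
}

#' Net monetary benefit
#'
#' NMB = WTP x effect - cost. At a given willingness-to-pay threshold
#' the strategy with the highest NMB is the cost-effective choice; for a
#' pairwise comparison with positive incremental effect, a non-negative
#' incremental NMB is equivalent to ICER <= WTP.
#'
#' @param cost expected cost (USD).
#' @param effect expected effectiveness (e.g. QA-PFLYS).
#' @param wtp willingness-to-pay threshold, USD per effectiveness unit.
#' @return net monetary benefit in USD (vectorized).
#' @export
net_monetary_benefit <- function(cost, effect, wtp) {
  wtp * effect - cost
}
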