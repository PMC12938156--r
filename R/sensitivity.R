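# pairwise ICER of one strategy vs a comparator under a scenario
.pair_eval <- function(scenario, strategy, comparator,
                       effect = "qa_pflys") {
  ev <- function(nm) evaluate_strategy(scenario$strategies[[nm]],
                                       scenario$utilities,
                                       scenario$horizon,
                                       scenario$discount_rate)
  a <- ev(strategy); b <- ev(comparator)
  list(dc = a$total_cost - b$total_cost,
       de = a[[effect]] - b[[effect]],
       cost = a$total_cost, effect = a[[effect]])
}

#' Pairwise ICER under a scenario
#'
#' @param scenario a `cea_scenario`.
#' @param strategy strategy name.
#' @param comparator comparator name (default: the scenario's).
#' @param effect effectiveness measure.
#' @return the ICER in USD per effectiveness unit (`NA` if the
#'   incremental effect is zero).
#' @export
scenario_icer <- function(scenario, strategy,
                          comparator = scenario$comparator,
                          effect = "qa_pflys") {
  p <- .pair_eval(scenario, strategy, comparator, effect)
  if (p$de == 0) return(NA_real_)
  p$dc / p$de
}

#' Break-even (threshold) drug price
#'
#' Finds the per-administration price of the strategy's priced drug
#' component at which its ICER versus the comparator equals the
#' willingness-to-pay threshold. Because drug cost is exactly linear in
#' the price, the root has a closed form:
#' p* = p0 - (dC(p0) - WTP x dE) / N, where N is the expected
#' discounted number of priced units delivered. The returned price is
#' per induction administration (price unit 1); maintenance
#' administrations scale by their dose-ratio price units.
#'
#' @param scenario a `cea_scenario`.
#' @param strategy name of the strategy whose drug price is varied.
#' @param comparator comparator name (default: the scenario's).
#' @param wtp willingness-to-pay threshold (default: the scenario's).
#' @param effect effectiveness measure.
#' @return a one-row data frame: `strategy`, `wtp`, `current_price`,
#'   `break_even_price`, `required_decrease`, `delta_effect`, `status`
#'   (`"ok"`, or `"no_finite_price"` when the incremental effect is not
#'   positive, in which case the price columns are `NA`).
#' @export
#' @examples
#' break_even_price(build_scenario("dmmr"), "PEM-TC")
break_even_price <- function(scenario, strategy,
                             comparator = scenario$comparator,
                             wtp = scenario$wtp, effect = "qa_pflys") {
  stopifnot(inherits(scenario, "cea_scenario"))
  st <- scenario$strategies[[strategy]]
  if (is.null(st)) stop("unknown strategy: ", strategy, call. = FALSE)
  p0 <- st$regimen$drug_price
  pe <- .pair_eval(scenario, strategy, comparator, effect)
  if (pe$de <= 0)
    return(data.frame(strategy = strategy, wtp = wtp, current_price = p0,
                      break_even_price = NA_real_,
                      required_decrease = NA_real_,
                      delta_effect = pe$de, status = "no_finite_price"))
  n_units <- expected_price_units(st$regimen, st$pfs, scenario$horizon,
                                  scenario$discount_rate)
  if (n_units <= 0)
    stop("strategy `", strategy, "` has no priced administrations",
         call. = FALSE)
  p_star <- p0 - (pe$dc - wtp * pe$de) / n_units
  data.frame(strategy = strategy, wtp = wtp, current_price = p0,
             break_even_price = p_star,
             required_decrease = p0 - p_star,
             delta_effect = pe$de, status = "ok")
}

#' One-way sensitivity analysis of a single parameter
#'
#' Re-runs the deterministic engine with the parameter at its low and
#' high bound (all other parameters at base) and reports the pairwise
#' ICER at each.
#'
#' @param scenario a `cea_scenario`.
#' @param parameter parameter name (see [scenario_parameters()]).
#' @param strategy,comparator the strategy pair whose ICER is tracked
#'   (comparator defaults to the scenario's).
#' @param low,high parameter bounds; default +/-20% of base (bounded
#'   parameters capped at 1).
#' @param effect effectiveness measure.
#' @return a one-row data frame: `parameter`, `base`, `low`, `high`,
#'   `icer_base`, `icer_low`, `icer_high`, `width`.
#' @export
one_way <- function(scenario, parameter, strategy,
                    comparator = scenario$comparator,
                    low = NULL, high = NULL, effect = "qa_pflys") {
  pars <- scenario_parameters(scenario)
  row <- pars[pars$name == parameter, , drop = FALSE]
  if (nrow(row) == 0)
    stop("unknown parameter: ", parameter, call. = FALSE)
  if (is.null(low)) low <- row$low
  if (is.null(high)) high <- row$high
  icer_at <- function(v)
    scenario_icer(set_scenario_parameter(scenario, parameter, v),
                  strategy, comparator, effect)
  data.frame(parameter = parameter, base = row$base, low = low,
             high = high,
             icer_base = scenario_icer(scenario, strategy, comparator,
                                       effect),
             icer_low = icer_at(low), icer_high = icer_at(high))
}

#' Tornado diagram data
#'
#' Runs [one_way()] for each parameter and sorts the resulting ICER
#' ranges by width, widest first (the order the bars are drawn in a
#' tornado diagram).
#'
#' @inheritParams one_way
#' @param parameters character vector of parameter names (default: all
#'   parameters of the strategy pair plus the shared utilities).
#' @return a data frame of [one_way()] rows plus `width`
#'   (`|icer_high - icer_low|`), sorted by decreasing width, with the
#'   base-case ICER attached as attribute `icer_base`.
#' @export
#' @examples
#' tor <- tornado(build_scenario("dmmr"), strategy = "PEM-TC")
#' head(tor[, c("parameter", "width")])
tornado <- function(scenario, strategy,
                    comparator = scenario$comparator,
                    parameters = NULL, effect = "qa_pflys") {
  if (is.null(parameters)) {
    pars <- scenario_parameters(scenario,
                                strategies = c(strategy, comparator))
    parameters <- pars$name
  }
  rows <- do.call(rbind, lapply(parameters, function(p)
    one_way(scenario, p, strategy, comparator, effect = effect)))
  rows$width <- abs(rows$icer_high - rows$icer_low)
  rows <- rows[order(-rows$width), , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows, icer_base = rows$icer_base[1])
}
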