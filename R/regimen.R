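#' Dosing phase
#'
#' One phase of a regimen schedule: doses every `interval` years, up to
#' `max_doses` administrations. The cost of each administration is
#' `fixed_cost + price_units * drug_price`, where `drug_price` lives on
#' the [regimen()]: `fixed_cost` covers the chemotherapy backbone and
#' `price_units` expresses how many price units of the (priced)
#' immunotherapy the administration contains — e.g. a maintenance dose
#' at double the induction dose carries 2 price units. This split keeps
#' drug cost exactly linear in the drug price, which the threshold
#' (break-even price) analysis exploits.
#'
#' @param interval time between doses in years, > 0 (see [weeks()]).
#' @param max_doses cap on the number of administrations in this phase
#'   (`Inf` for uncapped).
#' @param fixed_cost per-administration cost component in 2024 USD that
#'   does not scale with the drug price.
#' @param price_units price units of the priced drug per administration.
#' @param stop_on_progression if `TRUE` (default) doses beyond the
#'   regimen's guaranteed minimum are only delivered to patients still
#'   progression-free at the dose time.
#' @return a `dose_phase` object.
#' @export
#' @examples
#' dose_phase(weeks(3), max_doses = 6, fixed_cost = 1126, price_units = 1)
dose_phase <- function(interval, max_doses = Inf, fixed_cost = 0,
                       price_units = 0, stop_on_progression = TRUE) {
  stopifnot(interval > 0, max_doses >= 0, fixed_cost >= 0, price_units >= 0)
  structure(list(interval = interval, max_doses = max_doses,
                 fixed_cost = fixed_cost, price_units = price_units,
                 stop_on_progression = stop_on_progression),
            class = "dose_phase")
}

#' Grade >= 3 toxicity profile
#'
#' Toxicity is modeled as a one-time expected cost at model start
#' (`probability * cost`, undiscounted) plus a utility multiplier
#' applied to progression-free utility over the first `duration` years,
#' weighted by the toxicity probability.
#'
#' @param probability probability of a grade >= 3 event, in `[0, 1]`.
#' @param cost one-time event cost, 2024 USD.
#' @param utility utility multiplier in `[0, 1]` applied while the
#'   toxicity window is open.
#' @param duration window length in years over which the multiplier
#'   applies (default 18 weeks, the induction length).
#' @return a `toxicity_profile` object.
#' @export
#' @examples
#' toxicity_profile(0.63, 9784, utility = 0.70)
toxicity_profile <- function(probability, cost, utility = 1,
                             duration = weeks(18)) {
  stopifnot(probability >= 0, probability <= 1, cost >= 0,
            utility >= 0, utility <= 1, duration >= 0)
  structure(list(probability = probability, cost = cost,
                 utility = utility, duration = duration),
            class = "toxicity_profile")
}

#' Treatment regimen
#'
#' A regimen is an induction phase followed by an optional maintenance
#' phase, a guaranteed minimum number of induction doses delivered
#' regardless of progression (standard practice delivers the first 3
#' cycles before any progression call), a grade >= 3 toxicity profile,
#' and a per-unit drug price for the priced (immunotherapy) component.
#' `max_treatment_years` caps total treatment duration measured from
#' treatment start (so a "2 years total" rule includes induction);
#' a phase's own `max_doses` caps that phase's count (so "42 additional
#' cycles" caps maintenance only). Both encodings are explicit so each
#' regimen can use the wording of its trial.
#'
#' @param name regimen name.
#' @param induction a [dose_phase()].
#' @param maintenance a [dose_phase()] or `NULL`.
#' @param guaranteed_doses number of initial induction doses always
#'   delivered and costed (default 3); must not exceed the induction
#'   dose cap.
#' @param toxicity a [toxicity_profile()].
#' @param drug_price price per price unit of the priced drug component,
#'   2024 USD (0 for chemotherapy-only regimens).
#' @param max_treatment_years cap on treatment duration from start,
#'   years (`Inf` for treat-until-progression).
#' @return a `regimen` object.
#' @export
regimen <- function(name, induction, maintenance = NULL,
                    guaranteed_doses = 3, toxicity = toxicity_profile(0, 0),
                    drug_price = 0, max_treatment_years = Inf) {
  stopifnot(inherits(induction, "dose_phase"),
            is.null(maintenance) || inherits(maintenance, "dose_phase"),
            inherits(toxicity, "toxicity_profile"),
            guaranteed_doses >= 0, drug_price >= 0, max_treatment_years > 0)
  if (guaranteed_doses > induction$max_doses)
    stop("guaranteed_doses cannot exceed the induction dose cap", call. = FALSE)
  structure(list(name = name, induction = induction,
                 maintenance = maintenance,
                 guaranteed_doses = as.integer(guaranteed_doses),
                 toxicity = toxicity, drug_price = drug_price,
                 max_treatment_years = max_treatment_years),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("<regimen %s: induction q%.1fw x %s, %s, price $%s/unit>\n",
              x$name, x$induction$interval * DAYS_PER_YEAR / 7,
              format(x$induction$max_doses),
              if (is.null(x$maintenance)) "no maintenance" else
                sprintf("maintenance q%.1fw (cap %s y)",
                        x$maintenance$interval * DAYS_PER_YEAR / 7,
                        format(x$max_treatment_years)),
              format(x$drug_price, big.mark = ",")))
  invisible(x)
}

#' Scheduled dose times of a regimen
#'
#' Induction doses fall at 0, i, 2i, ...; maintenance doses continue at
#' the maintenance interval from the end of induction (last scheduled
#' induction dose + induction interval), truncated by the maintenance
#' dose cap, the regimen's total-treatment-time cap, and the model
#' horizon. Deterministic.
#'
#' @param regimen a [regimen()].
#' @param horizon model horizon in years.
#' @return a data frame with one row per scheduled administration:
#'   `time` (years), `phase` (`"induction"`/`"maintenance"`),
#'   `fixed_cost`, `price_units`, `cost` (fixed + units x price),
#'   `guaranteed` (delivered regardless of progression),
#'   `stop_on_progression`.
#' @export
#' @examples
#' dose_times(regimen_preset("PEM-TC"), horizon = 5)
dose_times <- function(regimen, horizon) {
  stopifnot(inherits(regimen, "regimen"), horizon > 0)
  cap <- min(horizon, regimen$max_treatment_years)
  ind <- regimen$induction
  n_ind <- if (is.finite(ind$max_doses)) ind$max_doses else
    ceiling(cap / ind$interval) + 1
  t_ind <- (seq_len(n_ind) - 1) * ind$interval
  t_ind <- t_ind[t_ind < cap - 1e-12]
  n_i <- length(t_ind)
  rows <- data.frame(
    time = t_ind, phase = rep("induction", n_i),
    fixed_cost = rep(ind$fixed_cost, n_i),
    price_units = rep(ind$price_units, n_i),
    stop_on_progression = rep(ind$stop_on_progression, n_i))
  mnt <- regimen$maintenance
  if (!is.null(mnt) && mnt$max_doses > 0) {
    start <- (if (is.finite(ind$max_doses)) ind$max_doses else length(t_ind)) *
      ind$interval
    n_max <- if (is.finite(mnt$max_doses)) mnt$max_doses else
      ceiling((cap - start) / mnt$interval) + 1
    t_m <- start + (seq_len(max(n_max, 0)) - 1) * mnt$interval
    t_m <- t_m[t_m < cap - 1e-12]
    if (length(t_m))
      rows <- rbind(rows, data.frame(
        time = t_m, phase = "maintenance",
        fixed_cost = mnt$fixed_cost, price_units = mnt$price_units,
        stop_on_progression = mnt$stop_on_progression))
  }
  rows <- rows[order(rows$time), , drop = FALSE]
  rownames(rows) <- NULL
  rows$cost <- rows$fixed_cost + rows$price_units * regimen$drug_price
  rows$guaranteed <- seq_len(nrow(rows)) <= regimen$guaranteed_doses
  rows
}

# survival weight of each scheduled dose: guaranteed doses count with
# probability 1; later doses with stop_on_progression require being
# progression-free at the dose time
.dose_weights <- function(doses, pfs) {
  w <- rep(1, nrow(doses))
  cond <- !doses$guaranteed & doses$stop_on_progression
  if (any(cond)) w[cond] <- evaluate(pfs, doses$time[cond])
  w
}

#' Expected number of administrations under a PFS curve
#'
#' The first `guaranteed_doses` administrations are always delivered;
#' each later dose at time t contributes PFS(t) when the phase stops on
#' progression (and 1 otherwise). The result is the sum of these
#' per-dose delivery probabilities.
#'
#' @inheritParams dose_times
#' @param pfs progression-free-survival `survival_curve`.
#' @return a list with expected counts `induction`, `maintenance`,
#'   `total`.
#' @export
expected_doses <- function(regimen, pfs, horizon) {
  doses <- dose_times(regimen, horizon)
  w <- .dose_weights(doses, pfs)
  list(induction = sum(w[doses$phase == "induction"]),
       maintenance = sum(w[doses$phase == "maintenance"]),
       total = sum(w))
}

#' Expected discounted drug cost of a regimen
#'
#' Sum over scheduled administrations of
#' cost x delivery probability x discount factor at the dose time.
#'
#' @inheritParams expected_doses
#' @param discount_rate continuous discount rate per year.
#' @return expected cost in 2024 USD.
#' @export
drug_cost <- function(regimen, pfs, horizon, discount_rate = 0) {
  doses <- dose_times(regimen, horizon)
  w <- .dose_weights(doses, pfs)
  sum(doses$cost * w * exp(-discount_rate * doses$time))
}

# expected discounted number of price units actually delivered; the
# derivative of drug_cost with respect to drug_price (exact, by linearity)
expected_price_units <- function(regimen, pfs, horizon, discount_rate = 0) {
  doses <- dose_times(regimen, horizon)
  w <- .dose_weights(doses, pfs)
  sum(doses$price_units * w * exp(-discount_rate * doses$time))
}

#' Expected toxicity cost
#'
#' Event probability times one-time event cost, applied undiscounted at
#' model start.
#'
#' @param profile a [toxicity_profile()].
#' @return expected cost in 2024 USD.
#' @export
toxicity_cost <- function(profile) {
  stopifnot(inherits(profile, "toxicity_profile"))
  profile$probability * profile$cost
}
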