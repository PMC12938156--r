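#' Survival curves
#'
#' A `survival_curve` represents a non-increasing survival function S(t),
#' t in years, either as a digitized Kaplan-Meier step function
#' (right-continuous, `times`/`probs` pairs starting at (0, 1)) or in
#' parametric form (exponential or Weibull). Parametric curves use
#' S(t) = exp(-(rate * t)^shape), so `rate` is the hazard per year for
#' the exponential (shape = 1) and the median is log(2)^(1/shape)/rate.
#'
#' @param kind one of `"step"`, `"exponential"`, `"weibull"`.
#' @param times for step curves, strictly increasing times (years)
#'   starting at 0.
#' @param probs for step curves, survival probabilities at `times`;
#'   non-increasing, in `[0, 1]`, with `probs[1] == 1`.
#' @param rate for parametric curves, positive rate parameter per year.
#' @param shape Weibull shape (1 for exponential).
#' @param label free-text label.
#' @param extrapolation what S(t) does past the last step time:
#'   `"hold"` keeps the last value (default), `"exp_tail"` continues
#'   with an exponential fitted to the final quarter of the curve.
#'   Ignored for parametric curves.
#' @return an object of class `survival_curve`.
#' @export
#' @examples
#' survival_curve("exponential", rate = log(2)) # median 1 year
#' survival_curve("step", times = c(0, 1, 2), probs = c(1, 0.8, 0.6))
survival_curve <- function(kind = c("step", "exponential", "weibull"),
                           times = NULL, probs = NULL,
                           rate = NULL, shape = 1, label = "",
                           extrapolation = c("hold", "exp_tail")) {
  kind <- match.arg(kind)
  extrapolation <- match.arg(extrapolation)
  if (kind == "step") {
    if (is.null(times) || is.null(probs))
      stop("step curves require `times` and `probs`", call. = FALSE)
    times <- as.numeric(times)
    probs <- as.numeric(probs)
    if (length(times) != length(probs))
      stop("`times` and `probs` must have equal length", call. = FALSE)
    if (length(times) < 1L || times[1] != 0)
      stop("step curve `times` must start at 0", call. = FALSE)
    if (any(diff(times) <= 0))
      stop("step curve `times` must be strictly increasing", call. = FALSE)
    if (abs(probs[1] - 1) > 1e-9)
      stop("step curve must start at S(0) = 1", call. = FALSE)
    if (any(probs < -1e-12 | probs > 1 + 1e-12))
      stop("survival probabilities must lie in [0, 1]", call. = FALSE)
    if (any(diff(probs) > 1e-9))
      stop("survival probabilities must be non-increasing", call. = FALSE)
    probs <- pmin(pmax(probs, 0), 1)
    obj <- list(kind = kind, times = times, probs = probs,
                label = label, extrapolation = extrapolation)
  } else {
    if (is.null(rate) || !is.finite(rate) || rate <= 0)
      stop("parametric curves require `rate` > 0", call. = FALSE)
    if (!is.finite(shape) || shape <= 0)
      stop("Weibull `shape` must be > 0", call. = FALSE)
    if (kind == "exponential") shape <- 1
    obj <- list(kind = kind, rate = rate, shape = shape, label = label)
  }
  structure(obj, class = "survival_curve")
}

#' Exponential survival curve from a rate or a median
#'
#' @param rate hazard per year; exactly one of `rate`/`median` is given.
#' @param median median survival in years.
#' @param label curve label.
#' @return a `survival_curve`.
#' @export
#' @examples
#' exp_curve(median = 1) # rate log(2)
exp_curve <- function(rate = NULL, median = NULL, label = "") {
  if (is.null(rate) == is.null(median))
    stop("give exactly one of `rate` or `median`", call. = FALSE)
  if (is.null(rate)) rate <- log(2) / median
  survival_curve("exponential", rate = rate, label = label)
}

#' Weibull survival curve from rate/shape or median/shape
#'
#' @inheritParams exp_curve
#' @param shape Weibull shape parameter.
#' @return a `survival_curve`.
#' @export
weibull_curve <- function(rate = NULL, median = NULL, shape = 1, label = "") {
  if (is.null(rate) == is.null(median))
    stop("give exactly one of `rate` or `median`", call. = FALSE)
  if (is.null(rate)) rate <- log(2)^(1 / shape) / median
  survival_curve("weibull", rate = rate, shape = shape, label = label)
}

#' @export
print.survival_curve <- function(x, ...) {
  if (x$kind == "step") {
    cat(sprintf("<survival_curve: step, %d points over [0, %.3g] y%s>\n",
                length(x$times), max(x$times),
                if (nzchar(x$label)) paste0(", ", x$label) else ""))
  } else {
    cat(sprintf("<survival_curve: %s, rate %.4g/y, shape %.3g%s>\n",
                x$kind, x$rate, x$shape,
                if (nzchar(x$label)) paste0(", ", x$label) else ""))
  }
  invisible(x)
}

#' Median survival of a curve
#'
#' For step curves this is the first time at which S(t) drops to 0.5 or
#' below (`NA` if the curve never does within its support).
#'
#' @param curve a `survival_curve`.
#' @return median survival time in years.
#' @export
curve_median <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  if (curve$kind == "step") {
    i <- which(curve$probs <= 0.5)
    if (length(i) == 0L) return(NA_real_)
    curve$times[min(i)]
  } else {
    log(2)^(1 / curve$shape) / curve$rate
  }
}

# exponential tail rate fitted to the last quarter of a step curve
.tail_rate <- function(curve) {
  tmax <- max(curve$times)
  keep <- curve$times >= 0.75 * tmax & curve$probs > 0
  if (sum(keep) < 2L) return(0)
  t <- curve$times[keep]
  s <- log(curve$probs[keep])
  max(0, -stats::coef(stats::lm(s ~ t))[["t"]])
}

#' Evaluate a survival curve
#'
#' Step curves are evaluated by right-continuous step interpolation (the
#' value at the last step time <= t); parametric curves use the closed
#' form. Beyond the last step time the curve's extrapolation policy
#' applies (hold-last-value by default).
#'
#' @param curve a `survival_curve`.
#' @param t vector of times in years, all >= 0.
#' @return survival probabilities S(t), same length as `t`.
#' @export
#' @examples
#' s <- survival_curve("step", times = c(0, 1, 2), probs = c(1, 0.8, 0.6))
#' evaluate(s, c(0, 0.5, 1.5, 3))
evaluate <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("negative evaluation time", call. = FALSE)
  if (curve$kind != "step")
    return(exp(-(curve$rate * t)^curve$shape))
  idx <- findInterval(t, curve$times)
  out <- curve$probs[pmax(idx, 1L)]
  tmax <- max(curve$times)
  beyond <- t > tmax
  if (any(beyond) && identical(curve$extrapolation, "exp_tail")) {
    lam <- .tail_rate(curve)
    out[beyond] <- curve$probs[length(curve$probs)] * exp(-lam * (t[beyond] - tmax))
  }
  out
}

#' Hazard ratio
#'
#' @param value positive hazard ratio.
#' @param ci_low,ci_high optional confidence bounds, `ci_low <= value <=
#'   ci_high`.
#' @return an object of class `hazard_ratio`.
#' @export
#' @examples
#' hazard_ratio(0.30, 0.19, 0.48)
hazard_ratio <- function(value, ci_low = NA_real_, ci_high = NA_real_) {
  if (!is.finite(value) || value <= 0)
    stop("hazard ratio must be > 0", call. = FALSE)
  if (!is.na(ci_low) && !is.na(ci_high) &&
      !(ci_low <= value && value <= ci_high))
    stop("hazard ratio CI must bracket the point estimate", call. = FALSE)
  structure(list(value = value, ci_low = ci_low, ci_high = ci_high),
            class = "hazard_ratio")
}

.hr_value <- function(hr) {
  if (inherits(hr, "hazard_ratio")) hr <- hr$value
  if (!is.numeric(hr) || !is.finite(hr) || hr <= 0)
    stop("hazard ratio must be > 0", call. = FALSE)
  hr
}

#' Apply a proportional-hazards transform to a curve
#'
#' Under proportional hazards the transformed curve is
#' S_new(t) = S(t)^hr: pointwise powers for step curves, rate scaling
#' for parametric curves (rate * hr for the exponential,
#' rate * hr^(1/shape) for the Weibull).
#'
#' @param curve a `survival_curve`.
#' @param hr a `hazard_ratio` or a positive number.
#' @return a transformed `survival_curve` of the same kind.
#' @export
#' @examples
#' apply_hazard_ratio(exp_curve(median = 1), 0.30) # median ~ 3.33 y
apply_hazard_ratio <- function(curve, hr) {
  stopifnot(inherits(curve, "survival_curve"))
  h <- .hr_value(hr)
  if (curve$kind == "step") {
    out <- curve
    out$probs <- curve$probs^h
    out
  } else {
    out <- curve
    out$rate <- curve$rate * h^(1 / curve$shape)
    out
  }
}

# Integral of S(t) e^(-r t) over [from, to].
# Step curves integrate exactly, piece by piece (including the
# extrapolated tail); parametric curves use adaptive quadrature.
.disc_seg <- function(s, a, b, r) {
  if (b <= a) return(0)
  if (r == 0) s * (b - a) else s * (exp(-r * a) - exp(-r * b)) / r
}

curve_area <- function(curve, from = 0, to, discount_rate = 0) {
  stopifnot(inherits(curve, "survival_curve"), to >= from, from >= 0,
            discount_rate >= 0)
  r <- discount_rate
  if (curve$kind != "step") {
    f <- function(t) evaluate(curve, t) * exp(-r * t)
    return(stats::integrate(f, from, to, rel.tol = 1e-12,
                            subdivisions = 1000L)$value)
  }
  brk <- c(curve$times, Inf)
  total <- 0
  for (i in seq_along(curve$times)) {
    a <- max(from, curve$times[i])
    b <- min(to, brk[i + 1])
    if (i == length(curve$times) &&
        identical(curve$extrapolation, "exp_tail") && to > curve$times[i]) {
      lam <- .tail_rate(curve)
      s0 <- curve$probs[i]
      t0 <- curve$times[i]
      # s0 * exp(-lam (t - t0)) * exp(-r t) integrated over [a, to]
      total <- total + if (lam + r == 0) s0 * (to - a) else
        s0 * exp(lam * t0) * (exp(-(lam + r) * a) - exp(-(lam + r) * to)) / (lam + r)
    } else if (b > a) {
      total <- total + .disc_seg(curve$probs[i], a, b, r)
    }
  }
  total
}

#' Discounted restricted area under a survival curve
#'
#' Computes the restricted (discounted) mean survival time
#' \eqn{\int_0^{H} S(t) e^{-rt} dt}: undiscounted life-years spent alive
#' (or progression-free) over the horizon when `discount_rate = 0`.
#' Step curves integrate exactly as rectangle sums; parametric curves
#' use adaptive quadrature.
#'
#' @param curve a `survival_curve`.
#' @param horizon integration horizon in years, > 0.
#' @param discount_rate continuous discount rate per year, >= 0.
#' @return life-years (a scalar).
#' @export
#' @examples
#' restricted_area(exp_curve(rate = 0.2), horizon = 5) # (1 - e^-1)/0.2
restricted_area <- function(curve, horizon, discount_rate = 0) {
  stopifnot(horizon > 0)
  curve_area(curve, 0, horizon, discount_rate)
}

#' Read a digitized survival curve from CSV
#'
#' The file dialect is a two-column CSV, header `time_years,survival`,
#' '.' decimal separator, one curve per file.
#'
#' @param path file path.
#' @param label curve label (defaults to the file name).
#' @param extrapolation see [survival_curve()].
#' @return a step `survival_curve`.
#' @export
read_km_csv <- function(path, label = basename(path),
                        extrapolation = c("hold", "exp_tail")) {
  d <- utils::read.csv(path, colClasses = "numeric")
  if (!all(c("time_years", "survival") %in% names(d)))
    stop("expected columns `time_years,survival` in ", path, call. = FALSE)
  survival_curve("step", times = d$time_years, probs = d$survival,
                 label = label, extrapolation = match.arg(extrapolation))
}

#' Write a digitized survival curve to CSV
#'
#' @param curve a step `survival_curve`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_km_csv <- function(curve, path) {
  stopifnot(inherits(curve, "survival_curve"))
  if (curve$kind != "step")
    stop("only step curves can be written as digitized CSV", call. = FALSE)
  d <- data.frame(time_years = sprintf("%.6f", curve$times),
                  survival = sprintf("%.6f", curve$probs))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
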