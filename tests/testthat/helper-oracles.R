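# Independent oracles used across the suite.

# closed-form discounted restricted area for an exponential curve:
# int_a^b e^(-lambda t) e^(-r t) dt
exp_area <- function(lambda, a = 0, b, r = 0) {
  k <- lambda + r
  if (k == 0) return(b - a)
  (exp(-k * a) - exp(-k * b)) / k
}

# Patient-level Monte-Carlo oracle for a strategy with exponential
# PFS/OS: simulates progression/death times, delivers doses per the
# guaranteed-minimum / stop-on-progression rules, and averages cost and
# QA-PFLYS. Returns means and standard errors.
mc_strategy_oracle <- function(strategy, utilities, horizon, n = 2e5,
                               discount_rate = 0, seed = 99L) {
  stopifnot(strategy$pfs$kind == "exponential",
            strategy$os$kind == "exponential")
  reg <- strategy$regimen
  tox <- reg$toxicity
  doses <- dose_times(reg, horizon)
  r <- discount_rate
  disc_int <- function(t) if (r == 0) t else (1 - exp(-r * t)) / r
  withr::with_seed(seed, {
    prog <- stats::rexp(n, rate = strategy$pfs$rate)
    tox_event <- stats::runif(n) < tox$probability
    # doses: delivered[i, k] = guaranteed or still progression-free
    delivered <- outer(prog, doses$time, `>`)
    delivered[, doses$guaranteed | !doses$stop_on_progression] <- TRUE
    disc_cost <- doses$cost * exp(-r * doses$time)
    cost <- as.vector(delivered %*% disc_cost) + tox_event * tox$cost
    # QA-PFLYS: utility u, toxicity multiplier during [0, duration)
    u <- utilities$on_treatment
    t_pf <- pmin(prog, horizon)
    d <- min(tox$duration, horizon)
    a_win <- disc_int(pmin(t_pf, d))
    a_all <- disc_int(t_pf)
    mult <- ifelse(tox_event, tox$utility, 1)
    qaplf <- u * (mult * a_win + (a_all - a_win))
    list(cost = mean(cost), cost_se = stats::sd(cost) / sqrt(n),
         qa_pflys = mean(qaplf), qa_pflys_se = stats::sd(qaplf) / sqrt(n),
         doses = mean(rowSums(delivered)),
         doses_se = stats::sd(rowSums(delivered)) / sqrt(n))
  })
}

# step curve fixture used by several files
step_fixture <- function() {
  survival_curve("step", times = c(0, 1, 2), probs = c(1, 0.8, 0.6))
}
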