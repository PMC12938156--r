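test_that("break-even price closed form agrees with bisection on the engine", {
  sc <- build_scenario("dmmr")
  for (nm in c("PEM-TC", "DOS-TC-3y", "DUO-TC-2y")) {
    be <- break_even_price(sc, nm)
    expect_identical(be$status, "ok")
    # root-finding oracle on the full engine
    f <- function(p) scenario_icer(
      set_scenario_parameter(sc, paste0("drug_price.", nm), p), nm) -
      sc$wtp
    root <- stats::uniroot(f, c(1, 30000), tol = 1e-6)$root
    expect_lt(abs(be$break_even_price - root), 0.01)
    # engine ICER evaluated at p* equals the WTP within 1e-6 relative
    icer_at_star <- scenario_icer(
      set_scenario_parameter(sc, paste0("drug_price.", nm),
                             be$break_even_price), nm)
    expect_lt(abs(icer_at_star - sc$wtp) / sc$wtp, 1e-6)
  }
})

test_that("break-even price is a fixed point at ICER == WTP and fails gracefully", {
  sc <- build_scenario("dmmr")
  # move the price so the ICER is exactly the WTP; the break-even price
  # must then be the current price
  be <- break_even_price(sc, "PEM-TC")
  sc2 <- set_scenario_parameter(sc, "drug_price.PEM-TC",
                                be$break_even_price)
  be2 <- break_even_price(sc2, "PEM-TC")
  expect_equal(be2$break_even_price, be2$current_price, tolerance = 1e-9)
  expect_equal(be2$required_decrease, 0, tolerance = 1e-6)
  # dE <= 0 has no finite break-even price
  sc_flip <- sc
  sc_flip$comparator <- "PEM-TC"
  be3 <- break_even_price(sc_flip, "TC", comparator = "PEM-TC")
  expect_identical(be3$status, "no_finite_price")
  expect_true(is.na(be3$break_even_price))
})

test_that("break-even arithmetic is linear: known decrease for synthetic inputs", {
  # one strategy with exactly 10 undiscounted priced administrations,
  # dC = 200,000, dE = 1, wtp = 100,000 -> price drops by 10,000
  ones <- survival_curve("step", times = 0, probs = 1)
  price0 <- 20000
  reg_a <- regimen("a", dose_phase(weeks(3), max_doses = 10,
                                   price_units = 1),
                   guaranteed_doses = 10, drug_price = price0)
  reg_b <- regimen("b", dose_phase(weeks(3), max_doses = 1,
                                   fixed_cost = 0), guaranteed_doses = 1)
  # effects: a has pf area exactly 1 more than b over the horizon
  h <- 5
  pfs_a <- ones                       # area 5
  pfs_b <- survival_curve("step", times = c(0, 4), probs = c(1, 0)) # area 4
  sc <- cea_scenario(
    "synthetic", strategies = list(
      a = strategy(reg_a, pfs_a, ones, name = "a"),
      b = strategy(reg_b, pfs_b, ones, name = "b")),
    utilities = utility_set(1, 0.5), horizon = h, wtp = 1e5,
    comparator = "b")
  pair <- scenario_icer(sc, "a")
  expect_equal(pair, (10 * price0) / 1, tolerance = 1e-12) # dC/dE sanity
  be <- break_even_price(sc, "a")
  expect_equal(be$required_decrease, (10 * price0 - 1e5) / 10,
               tolerance = 1e-9)
  # with dC = 200,000 (price0 = 20,000): decrease of exactly 10,000
  expect_equal(be$break_even_price, price0 - 10000, tolerance = 1e-9)
})

test_that("one-way analysis hits bounds, degenerates and is monotone", {
  sc <- build_scenario("dmmr")
  # low = high = base returns the base-case ICER exactly
  base_icer <- scenario_icer(sc, "PEM-TC")
  ow0 <- one_way(sc, "drug_price.PEM-TC", "PEM-TC",
                 low = 12338, high = 12338)
  expect_equal(ow0$icer_low, base_icer)
  expect_equal(ow0$icer_high, base_icer)
  # a parameter the pair's ICER does not depend on gives a zero-width bar
  ow_indep <- one_way(sc, "toxicity_cost.DOS-TC-3y", "PEM-TC")
  expect_equal(ow_indep$icer_low, ow_indep$icer_high)
  # price endpoints follow the exact linear relation
  st <- sc$strategies[["PEM-TC"]]
  n_units <- expected_price_units(st$regimen, st$pfs, sc$horizon)
  pair <- psmcea:::.pair_eval(sc, "PEM-TC", "TC")
  ow <- one_way(sc, "drug_price.PEM-TC", "PEM-TC")
  p0 <- 12338
  icer_lin <- function(p) (pair$dc + n_units * (p - p0)) / pair$de
  expect_equal(ow$icer_low, icer_lin(0.8 * p0), tolerance = 1e-9)
  expect_equal(ow$icer_high, icer_lin(1.2 * p0), tolerance = 1e-9)
  # raising the on-treatment utility raises dE, hence lowers the ICER
  ow_u <- one_way(sc, "utility.on_treatment", "PEM-TC")
  expect_gt(ow_u$icer_low, ow_u$icer_base)
  expect_lt(ow_u$icer_high, ow_u$icer_base)
  expect_error(one_way(sc, "no_such_parameter", "PEM-TC"), "unknown")
})

test_that("tornado sorts bars by width and the immunotherapy price leads", {
  sc <- build_scenario("dmmr")
  tor <- tornado(sc, strategy = "PEM-TC")
  expect_true(all(diff(tor$width) <= 1e-9))
  expect_equal(tor$width, abs(tor$icer_high - tor$icer_low))
  # the widest bar is the immunotherapy cost (or maintenance-duration)
  # parameter of the strategy under study
  expect_true(tor$parameter[1] %in%
                c("drug_price.PEM-TC", "maintenance_years.PEM-TC"))
  # single parameter -> single bar
  tor1 <- tornado(sc, strategy = "PEM-TC",
                  parameters = "utility.progressive")
  expect_equal(nrow(tor1), 1)
})

test_that("PSA is reproducible, degenerate when fixed, and sums to one", {
  sc <- build_scenario("toy")
  pars <- scenario_parameters(sc)
  # all-fixed distributions: every iteration identical, CEAC in {0, 1}
  pars_fixed <- pars; pars_fixed$distribution <- "fixed"
  psa0 <- run_psa(sc, n_sims = 20, seed = 5, parameters = pars_fixed,
                  wtp_grid = c(0, 1e4, 1e5))
  expect_equal(length(unique(psa0$samples$cost[
    psa0$samples$strategy == "active"])), 1)
  expect_true(all(psa0$ceac$probability %in% c(0, 1)))
  # deterministic result recovered: the zero-variance winner at the
  # scenario WTP is the strategy with the best deterministic NMB
  res <- run_cea(sc)
  det_best <- res$strategy[which.max(
    net_monetary_benefit(res$total_cost, res$qa_pflys, 1e5))]
  win0 <- psa0$ceac[psa0$ceac$wtp == 1e5 & psa0$ceac$probability == 1,
                    "strategy"]
  expect_identical(win0, det_best)
  # same seed twice: identical results; different seed: different draws
  psa1 <- run_psa(sc, n_sims = 30, seed = 42, wtp_grid = c(0, 1e5))
  psa2 <- run_psa(sc, n_sims = 30, seed = 42, wtp_grid = c(0, 1e5))
  expect_identical(psa1$samples, psa2$samples)
  expect_identical(psa1$ceac, psa2$ceac)
  psa3 <- run_psa(sc, n_sims = 30, seed = 43, wtp_grid = c(0, 1e5))
  expect_false(identical(psa1$samples, psa3$samples))
  # CEAC probabilities sum to one across strategies at every WTP
  sums <- tapply(psa1$ceac$probability, psa1$ceac$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("PSA with a Gaussian cost shock matches the analytic CEAC", {
  # two strategies with fixed effects and one normally distributed cost
  # parameter: P(cost-effective) = Phi((wtp*dE - dC)/sigma)
  ones <- survival_curve("step", times = 0, probs = 1)
  tox_a <- toxicity_profile(1, 60000, utility = 1, duration = 0)
  reg_a <- regimen("a", dose_phase(weeks(3), max_doses = 0),
                   guaranteed_doses = 0, toxicity = tox_a)
  reg_b <- regimen("b", dose_phase(weeks(3), max_doses = 0),
                   guaranteed_doses = 0)
  sc <- cea_scenario(
    "gauss", strategies = list(
      a = strategy(reg_a, exp_curve(rate = 0.2), ones, name = "a"),
      b = strategy(reg_b, exp_curve(rate = 0.4), ones, name = "b")),
    utilities = utility_set(0.84, 0.5), horizon = 5, wtp = 1e5,
    comparator = "b")
  de <- 0.84 * (exp_area(0.2, b = 5) - exp_area(0.4, b = 5))
  mu <- 1e5 * de - 60000
  sigma <- 0.2 * 60000
  pars <- data.frame(name = "toxicity_cost.a", base = 60000,
                     distribution = "normal", cv = 0.2)
  psa <- run_psa(sc, n_sims = 10000, seed = 9, parameters = pars,
                 wtp_grid = 1e5)
  p_hat <- psa$ceac$probability[psa$ceac$strategy == "a"]
  p_true <- stats::pnorm(mu / sigma)
  mc_se <- sqrt(p_true * (1 - p_true) / 10000)
  expect_lt(abs(p_hat - p_true), 4 * mc_se)
})

test_that("shrinking PSA variances concentrates on the deterministic result", {
  sc <- build_scenario("toy")
  pars <- scenario_parameters(sc)
  pars$cv <- rep(1e-6, nrow(pars))
  psa <- run_psa(sc, n_sims = 40, seed = 3, parameters = pars,
                 wtp_grid = c(5e3, 1e5))
  res <- run_cea(sc)
  for (w in c(5e3, 1e5)) {
    det_best <- res$strategy[which.max(
      net_monetary_benefit(res$total_cost, res$qa_pflys, w))]
    top <- psa$ceac[psa$ceac$wtp == w, ]
    expect_identical(top$strategy[which.max(top$probability)], det_best)
    expect_gte(max(top$probability), 1 - 1e-9)
  }
})
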