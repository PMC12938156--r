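test_that("evaluate handles step interpolation, closed forms and domain errors", {
  s <- step_fixture()
  e <- exp_curve(rate = log(2)) # median 1 year
  # survival at the origin is 1 for any curve
  expect_equal(evaluate(s, 0), 1.0)
  expect_equal(evaluate(e, 0), 1.0)
  # median definition for the exponential
  expect_equal(evaluate(e, 1), 0.5)
  # right-continuous step interpolation
  expect_equal(evaluate(s, 1.5), 0.8)
  expect_equal(evaluate(s, 1), 0.8)
  expect_equal(evaluate(s, c(0.2, 2.7)), c(1, 0.6)) # hold past last point
  expect_error(evaluate(s, -0.1), "negative")
  # exp-tail extrapolation decays past the last digitized point
  s2 <- survival_curve("step", times = c(0, 1, 2, 3, 4),
                       probs = c(1, 0.8, 0.6, 0.45, 0.34),
                       extrapolation = "exp_tail")
  expect_lt(evaluate(s2, 6), 0.34)
  expect_gt(evaluate(s2, 6), 0)
})

test_that("curve constructors enforce the invariants", {
  expect_error(survival_curve("step", times = c(0, 1), probs = c(0.9, 0.8)),
               "S\\(0\\) = 1")
  expect_error(survival_curve("step", times = c(0.5, 1), probs = c(1, 0.8)),
               "start at 0")
  expect_error(survival_curve("step", times = c(0, 1, 1), probs = c(1, 1, 1)),
               "strictly increasing")
  expect_error(survival_curve("step", times = c(0, 1, 2),
                              probs = c(1, 0.5, 0.7)), "non-increasing")
  expect_error(survival_curve("exponential", rate = -1), "rate")
  expect_error(weibull_curve(rate = 1, shape = 0), "shape")
  expect_error(survival_curve("weibull", rate = 1, shape = -2), "shape")
  expect_error(hazard_ratio(0), "> 0")
  expect_error(hazard_ratio(0.5, 0.6, 0.9), "bracket")
})

test_that("proportional-hazards transform matches S^hr and scales medians", {
  # hr = 1 leaves any curve unchanged
  s <- step_fixture()
  expect_equal(apply_hazard_ratio(s, 1)$probs, s$probs)
  e <- exp_curve(median = 1)
  expect_equal(apply_hazard_ratio(e, hazard_ratio(1))$rate, e$rate)
  # median 12 months with hr 0.30 -> median 40 months (closed form),
  # and the transformed curve equals S(t)^hr on a fine grid
  e12 <- exp_curve(median = 1)
  e40 <- apply_hazard_ratio(e12, 0.30)
  expect_equal(curve_median(e40), 1 / 0.30, tolerance = 1e-12)
  grid <- seq(0, 10, by = 0.01)
  expect_equal(evaluate(e40, grid), evaluate(e12, grid)^0.30,
               tolerance = 1e-12)
  # Weibull rate scaling also agrees with the pointwise power
  w <- weibull_curve(median = 1, shape = 1.7)
  w2 <- apply_hazard_ratio(w, 0.4)
  expect_equal(evaluate(w2, grid), evaluate(w, grid)^0.4, tolerance = 1e-12)
  # step curve: survival 0.64 at hr 0.5 becomes 0.8
  s3 <- survival_curve("step", times = c(0, 1), probs = c(1, 0.64))
  expect_equal(evaluate(apply_hazard_ratio(s3, 0.5), 1), 0.8)
  # monotonicity: hr < 1 raises survival pointwise, hr > 1 lowers it
  for (hr in c(0.3, 0.8, 1.3, 2.5)) {
    shifted <- evaluate(apply_hazard_ratio(e12, hr), grid[-1])
    base <- evaluate(e12, grid[-1])
    if (hr < 1) expect_true(all(shifted >= base))
    else expect_true(all(shifted <= base))
  }
})

test_that("partition applies the state formulas and guards curve crossing", {
  os <- survival_curve("step", times = c(0, 1), probs = c(1, 0.8))
  pfs <- survival_curve("step", times = c(0, 1), probs = c(1, 0.5))
  occ <- partition(os, pfs, grid = c(0, 1, 2))
  expect_equal(occ$pp[2], 0.3)
  expect_equal(occ$dead[2], 0.2)
  # OS == PFS leaves no post-progression occupancy
  occ2 <- partition(os, os, grid = seq(0, 3, 0.5))
  expect_equal(occ2$pp, rep(0, 7))
  # PFS above OS beyond the clamping tolerance is an error naming the time
  bad_pfs <- survival_curve("step", times = c(0, 1), probs = c(1, 0.9))
  expect_error(partition(os, bad_pfs, grid = c(0, 1, 2)),
               "curves cross")
  expect_error(partition(os, bad_pfs, grid = c(0, 1, 2)), "1\\.0000")
  # a sub-tolerance excess is clamped with a warning and stays consistent
  close_pfs <- survival_curve("step", times = c(0, 1), probs = c(1, 0.803))
  expect_warning(occ3 <- partition(os, close_pfs, grid = c(0, 1, 2)),
                 "clamped")
  expect_equal(occ3$pf[2], 0.8)
  expect_true(all(abs(occ3$pf + occ3$pp + occ3$dead - 1) < 1e-9))
})

test_that("state occupancy conserves probability for random curve pairs", {
  withr::with_seed(11, {
    for (i in 1:25) {
      lam_os <- runif(1, 0.05, 0.5)
      lam_pfs <- lam_os + runif(1, 0, 1.5)
      occ <- partition(exp_curve(rate = lam_os), exp_curve(rate = lam_pfs),
                       horizon = runif(1, 1, 10))
      expect_true(all(abs(occ$pf + occ$pp + occ$dead - 1) < 1e-9))
      expect_true(all(occ$pf >= 0 & occ$pf <= 1))
      expect_true(all(occ$pp >= -1e-12 & occ$pp <= 1))
      expect_true(all(diff(occ$dead) >= -1e-12))
      expect_true(all(diff(occ$pf) <= 1e-12))
    }
  })
})

test_that("restricted areas match closed forms and exact rectangle sums", {
  # unit survival accrues the full horizon
  ones <- survival_curve("step", times = 0, probs = 1)
  expect_equal(restricted_area(ones, horizon = 5), 5.0)
  # exponential closed forms, undiscounted and discounted
  e <- exp_curve(rate = 0.2)
  expect_equal(restricted_area(e, 5), exp_area(0.2, b = 5),
               tolerance = 1e-9)
  expect_equal(restricted_area(e, 5), (1 - exp(-1)) / 0.2,
               tolerance = 1e-9)
  expect_equal(restricted_area(e, 5, discount_rate = 0.03),
               exp_area(0.2, b = 5, r = 0.03), tolerance = 1e-9)
  # step curves integrate exactly as rectangle areas
  s <- step_fixture()
  expect_equal(restricted_area(s, 2), 1 * 1 + 0.8 * 1, tolerance = 1e-12)
  expect_equal(restricted_area(s, 3.5), 1 + 0.8 + 0.6 * 1.5,
               tolerance = 1e-12)
  # discounted step curve: sum of per-piece exponential segments
  r <- 0.05
  manual <- (1 - exp(-r)) / r + 0.8 * (exp(-r) - exp(-2 * r)) / r +
    0.6 * (exp(-2 * r) - exp(-3.5 * r)) / r
  expect_equal(restricted_area(s, 3.5, discount_rate = r), manual,
               tolerance = 1e-12)
})

test_that("restricted_area is monotone in horizon and discount rate", {
  withr::with_seed(21, {
    for (i in 1:10) {
      crv <- if (i %% 2) exp_curve(rate = runif(1, 0.1, 1)) else
        survival_curve("step", times = c(0, sort(runif(4, 0.1, 4))),
                       probs = c(1, sort(runif(4, 0.2, 0.99),
                                         decreasing = TRUE)))
      h <- sort(runif(2, 1, 8))
      expect_lte(restricted_area(crv, h[1]), restricted_area(crv, h[2]))
      rr <- sort(runif(2, 0, 0.1))
      expect_gte(restricted_area(crv, 5, rr[1]),
                 restricted_area(crv, 5, rr[2]))
    }
  })
})

test_that("digitized-curve CSV round-trips through the documented dialect", {
  s <- survival_curve("step", times = c(0, 0.25, 1.5),
                      probs = c(1, 0.84321, 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_km_csv(s, path)
  head <- readLines(path, n = 2)
  expect_identical(head[1], "time_years,survival")
  expect_match(head[2], "^0\\.000000,1\\.000000$")
  s2 <- read_km_csv(path)
  expect_equal(s2$times, s$times, tolerance = 1e-6)
  expect_equal(s2$probs, s$probs, tolerance = 1e-6)
  expect_error(write_km_csv(exp_curve(rate = 1), path), "step")
})
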