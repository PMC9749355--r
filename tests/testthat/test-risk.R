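test_that("the linear predictor is zero at centering values and additive in terms", {
  cfg <- load_config()
  ind <- centered_individual()
  expect_equal(linear_predictor(ind, cfg$risk_first_ever), 0, tolerance = 1e-12)

  one_term <- list(name = "toy", horizon_years = 5, baseline_survival = 0.98,
                   predictors = list(list(name = "sbp", beta = 0.2, center = 0,
                                          transform = "identity")))
  expect_equal(linear_predictor(list(age = 40, sbp = 5), one_term), 1.0, tolerance = 1e-12)
})

test_that("the full coefficient vector matches a term-by-term recomputation", {
  cfg <- load_config()
  ind <- data.frame(id = 1L, age = 47, ses_quintile = 4L, smoking = "current",
                    diabetes = TRUE, sbp = 143.5, tc = 6.1, hdl = 1.1)
  # independent spreadsheet-style oracle: each term written out explicitly
  m <- cfg$risk_first_ever
  nm <- vapply(m$predictors, `[[`, "", "name")
  beta <- setNames(vapply(m$predictors, `[[`, 0, "beta"), nm)
  ctr <- setNames(vapply(m$predictors, `[[`, 0, "center"), nm)
  oracle <- beta[["age"]] * (min(47, m$lp_age_cap) - ctr[["age"]]) +
    beta[["ses_quintile"]] * (4 - ctr[["ses_quintile"]]) +
    beta[["smoking_ex"]] * (0 - ctr[["smoking_ex"]]) +
    beta[["smoking_current"]] * (1 - ctr[["smoking_current"]]) +
    beta[["diabetes"]] * (1 - ctr[["diabetes"]]) +
    beta[["sbp"]] * (143.5 / 10 - ctr[["sbp"]]) +
    beta[["tc_hdl_ratio"]] * (6.1 / 1.1 - ctr[["tc_hdl_ratio"]])
  expect_equal(linear_predictor(ind, m), unname(oracle), tolerance = 1e-12)

  # missing optional predictors resolve to centering values (zero contribution)
  sparse <- list(age = 47, sbp = 143.5)
  expect_equal(linear_predictor(sparse, m),
               unname(beta[["age"]] * (47 - ctr[["age"]]) +
                        beta[["sbp"]] * (14.35 - ctr[["sbp"]])), tolerance = 1e-12)
})

test_that("horizon risk follows the Cox closed form", {
  m <- list(baseline_survival = 0.95, horizon_years = 5)
  expect_equal(horizon_risk(0, m), 1 - 0.95, tolerance = 1e-12)
  expect_equal(horizon_risk(0.5, m), 1 - 0.95^exp(0.5), tolerance = 1e-12)
  expect_lt(horizon_risk(-30, m), 1e-12)
  m1 <- list(baseline_survival = 1)
  expect_equal(horizon_risk(2, m1), 0)
})

test_that("horizon-to-annual conversion is the constant-hazard closed form and inverts exactly", {
  expect_equal(horizon_to_annual(0, 5), 0)
  expect_equal(horizon_to_annual(0.05, 5), 1 - 0.95^(1 / 5), tolerance = 1e-12)
  expect_equal(horizon_to_annual(0.05, 5), 0.010206, tolerance = 5e-5)
  grid <- seq(0, 0.999, by = 0.0271)
  for (h in c(1, 5, 10)) {
    expect_equal(annual_to_horizon(horizon_to_annual(grid, h), h), grid, tolerance = 1e-12)
  }
  expect_warning(p1 <- horizon_to_annual(1, 5))
  expect_equal(p1, 1)
})

test_that("the intervention shifts risk-relevant SBP only while adherent and CVD-free", {
  cfg <- load_config()
  run <- cfg$run
  uc <- list(arm = "usual_care", sbp = 130)
  expect_equal(apply_intervention(uc, 0, run)$sbp_effective, 130)
  expect_false(apply_intervention(uc, 0, run)$on_intervention)

  iv <- list(arm = "intervention", sbp = 130)
  a0 <- apply_intervention(iv, 0, run)
  expect_equal(a0$sbp_effective, 130 - 3.16, tolerance = 1e-12)
  expect_true(a0$on_intervention)
  a5 <- apply_intervention(iv, 5, run)          # zero-based cycle 5 = sixth year
  expect_equal(a5$sbp_effective, 130)
  expect_false(a5$on_intervention)
  post <- apply_intervention(list(arm = "intervention", sbp = 130, n_events = 1), 2, run)
  expect_equal(post$sbp_effective, 130)          # stops at the de novo event
  expect_false(post$on_intervention)
})

test_that("lowering SBP strictly lowers first-ever risk (positive coefficient)", {
  cfg <- load_config()
  ind <- centered_individual()
  lo <- ind; lo$sbp <- ind$sbp - 3.16
  p_hi <- horizon_risk(linear_predictor(ind, cfg$risk_first_ever), cfg$risk_first_ever)
  p_lo <- horizon_risk(linear_predictor(lo, cfg$risk_first_ever), cfg$risk_first_ever)
  expect_lt(p_lo, p_hi)
})

test_that("recurrent risk is non-increasing in time since the first event", {
  cfg <- load_config()
  m <- cfg$risk_recurrent
  beta_t <- vapply(m$predictors, function(p) if (p$name == "years_since_first") p$beta else NA_real_, 0)
  expect_lt(beta_t[!is.na(beta_t)], 0)   # sign taken from the coefficient set
  base <- list(age = 60, smoking = "never", diabetes = FALSE, sbp = 140, tc = 5.2, hdl = 1.3)
  risks <- vapply(c(1, 2, 5, 10, 20), function(ys) {
    b <- base; b$years_since_first <- ys
    horizon_risk(linear_predictor(b, m), m)
  }, 0)
  expect_true(all(diff(risks) <= 0))
  # floored at one year: values below 1 give the same risk as 1
  b0 <- base; b0$years_since_first <- 0.2
  b1 <- base; b1$years_since_first <- 1
  expect_equal(linear_predictor(b0, m), linear_predictor(b1, m), tolerance = 1e-12)
})

test_that("subtype draws have the configured composition", {
  cfg <- load_config()
  split <- cfg$subtypes$first_ever
  expect_true(all(draw_first_event_subtype(split, runif(50)) %in% names(split)))
  expect_true(all(draw_first_event_subtype(list(MI = 1), rep(c(0.01, 0.5, 0.99), 5)) == "MI"))

  set.seed(1234)
  u <- runif(1e5)
  draws <- draw_first_event_subtype(split, u)
  freq <- table(factor(draws, levels = names(split))) / 1e5
  p <- unlist(split)
  se <- sqrt(p * (1 - p) / 1e5)
  expect_true(all(abs(as.numeric(freq) - p) <= 3 * se))

  half <- list(a = 0.5, b = 0.5)
  set.seed(99)
  d2 <- draw_recurrent_event_type(half, runif(2e4))
  expect_equal(mean(d2 == "a"), 0.5, tolerance = 0.02)
})

test_that("non-CVD mortality lookup is an exact step function", {
  zero <- data.frame(age_lo = 30, age_hi = 100, p = 0)
  expect_equal(noncvd_death_prob(c(30, 65, 100), zero), c(0, 0, 0))

  tab <- data.frame(age_lo = c(30, 40, 50), age_hi = c(39, 49, 60), p = c(0.001, 0.002, 0.004))
  expect_equal(noncvd_death_prob(35, tab), 0.001)
  expect_equal(noncvd_death_prob(40, tab), 0.002)
  expect_equal(noncvd_death_prob(49, tab), 0.002)
  expect_error(noncvd_death_prob(61, tab), class = "cvd_config_error")
  expect_error(noncvd_death_prob(29, tab), class = "cvd_config_error")

  # monotone tables give monotone lookups (property over random tables)
  set.seed(5)
  for (k in 1:20) {
    edges <- sort(sample(31:99, 5))
    lo <- c(30, edges); hi <- c(edges - 1, 100)
    ps <- sort(runif(length(lo), 0, 0.5))
    rt <- data.frame(age_lo = lo, age_hi = hi, p = ps)
    ages <- 30:100
    expect_true(all(diff(noncvd_death_prob(ages, rt)) >= 0))
  }
})

test_that("computed probabilities always lie in [0, 1] across a random cohort", {
  cfg <- load_config()
  co <- sample_cohort(cfg$population, 500, seed = 21)
  lp <- linear_predictor(co, cfg$risk_first_ever)
  p5 <- horizon_risk(lp, cfg$risk_first_ever)
  p1 <- horizon_to_annual(p5, 5)
  expect_true(all(p5 >= 0 & p5 < 1))
  expect_true(all(p1 >= 0 & p1 < 1))
  expect_true(all(p1 <= p5))
})
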