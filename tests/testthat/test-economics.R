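test_that("cycle utilities follow the age curve with the minimum post-event rule", {
  econ <- load_config()$economics
  expect_equal(cycle_utility(list(age = 35, n_events = 0), econ), 0.84)
  expect_equal(cycle_utility(list(age = 45, n_events = 1, last_subtype = "MI"), econ), 0.81)
  expect_equal(cycle_utility(list(age = 45, n_events = 1, last_subtype = "haemorrhagic_stroke"), econ), 0.30)
  # unstable angina carries no published decrement: age-band value applies
  expect_equal(cycle_utility(list(age = 52, n_events = 1, last_subtype = "UA"), econ), 0.80)
  # two or more events: flat post-CVD utility through the minimum rule
  expect_equal(cycle_utility(list(age = 45, n_events = 2, last_subtype = "MI"), econ), 0.626)
  # ages beyond the oldest band clamp to it
  expect_equal(cycle_utility(list(age = 93, n_events = 0), econ), 0.68)

  # ischaemic stroke: mRS-weighted composite, against an explicit oracle
  w <- c(0.25, 0.25, 0.2, 0.15, 0.1, 0.05)
  u <- c(0.63, 0.63, 0.40, 0.18, 0.06, 0.02)
  expect_equal(mrs_stroke_utility(econ), sum(w * u), tolerance = 1e-12)
  expect_equal(sum(w * u), 0.429, tolerance = 1e-12)
  expect_equal(cycle_utility(list(age = 45, n_events = 1, last_subtype = "ischaemic_stroke"), econ),
               0.429, tolerance = 1e-12)
})

test_that("cycle costs place program, acute and management charges correctly", {
  econ <- load_config()$economics
  expect_equal(cycle_cost(list(on_intervention = TRUE, n_events = 0), econ), 335.63)
  expect_equal(cycle_cost(list(on_intervention = FALSE, event_subtype = "MI", n_events = 0), econ), 8944)
  expect_equal(cycle_cost(list(n_events = 1, last_subtype = "ischaemic_stroke"), econ), 6410)
  expect_equal(cycle_cost(list(n_events = 1, last_subtype = "TIA"), econ), 1431)
  expect_error(cycle_cost(list(event_subtype = "gout"), econ), "unknown event subtype")
  # optional flat post-CVD management after a recurrence
  econ2 <- econ; econ2$mgmt_post_recurrent <- "postCVD"
  expect_equal(cycle_cost(list(n_events = 2, last_subtype = "nonfatal_MI"), econ2), 4667)
  expect_equal(cycle_cost(list(n_events = 2, last_subtype = "nonfatal_MI"), econ), 4302)
})

test_that("discounting applies the mid-cycle factor and is exact at r = 0", {
  led <- data.frame(cycle = 0:3,
                    cost_intervention = c(335.63, 335.63, 0, 0),
                    cost_acute = c(0, 0, 8944, 0),
                    cost_mgmt = c(0, 0, 0, 4302),
                    utility = c(0.84, 0.84, 0.87, 0.87),
                    ly = c(1, 1, 1, 0.5))
  t0 <- discounted_totals(led, 0)
  expect_equal(t0$cost, 335.63 * 2 + 8944 + 4302)
  expect_equal(t0$ly, 3.5)
  expect_equal(t0$qaly, sum(led$utility * led$ly))

  one <- data.frame(cycle = 0, cost_intervention = 100, cost_acute = 0, cost_mgmt = 0,
                    utility = 1, ly = 1)
  t1 <- discounted_totals(one, 0.03)
  expect_equal(t1$cost, 100 * 1.03^-0.5, tolerance = 1e-12)
  expect_equal(t1$cost, 98.533, tolerance = 1e-3)

  # constant utility stream vs the annuity closed form
  k <- 12; u <- 0.8
  led2 <- data.frame(cycle = 0:(k - 1), cost_intervention = 0, cost_acute = 0,
                     cost_mgmt = 0, utility = u, ly = 1)
  t2 <- discounted_totals(led2, 0.03)
  expect_equal(t2$qaly, u * sum(1.03^-((0:(k - 1)) + 0.5)), tolerance = 1e-12)
})

test_that("ICERs are quadrant-labelled and match the worked example", {
  mk <- function(cost, qaly, ly) data.frame(
    id = 1L, cost = cost, cost_intervention = cost, cost_acute = 0, cost_mgmt = 0,
    qaly = qaly, ly = ly, cost_undisc = cost, qaly_undisc = qaly, ly_undisc = ly)
  # printed base-case increments: $1389 / 0.012766 QALY -> ~ $108.8k per QALY
  ic <- compute_icer(mk(8133, 18.070, 23.084), mk(8133 - 1389, 18.070 - 0.012766, 23.084 - 0.0094))
  expect_equal(ic$icer_qaly, 1389 / 0.012766, tolerance = 1e-9)
  expect_equal(ic$icer_qaly, 108800, tolerance = 1e-3)
  expect_equal(ic$dominance, "trade-off")
  expect_false(ic$cost_effective)

  dom <- compute_icer(mk(90, 10.01, 12), mk(100, 10.0, 12))
  expect_equal(dom$dominance, "dominant")
  expect_true(is.na(dom$icer_qaly))
  expect_true(dom$cost_effective)

  dominated <- compute_icer(mk(100, 9.99, 12), mk(50, 10.0, 12))
  expect_equal(dominated$dominance, "dominated")
  expect_true(is.na(dominated$icer_qaly))

  # dyadic-exact increments: delta cost 12,500, delta QALY 0.25 -> exactly at WTP
  at <- compute_icer(mk(12600, 10.25, 12), mk(100, 10.0, 12), wtp = 50000)
  expect_equal(at$icer_qaly, 50000, tolerance = 1e-12)
  expect_true(at$cost_effective)  # NMB = 0 counts as acceptable
})

test_that("simulated totals satisfy the accounting identities", {
  cfg <- base_cfg(list(run = list(n_individuals = 500)))
  co <- sample_cohort(cfg$population, 500, seed = 14)
  res <- simulate_arm(co, "intervention", cfg, master_seed = 3)
  t <- res$totals
  expect_equal(t$cost, t$cost_intervention + t$cost_acute + t$cost_mgmt, tolerance = 1e-9)
  expect_true(all(t$qaly <= t$ly + 1e-12))
  expect_true(all(t$qaly_undisc <= t$ly_undisc + 1e-12))
  expect_true(all(t$cost >= 0))
  # discounting with r = 0 reproduces undiscounted sums exactly
  cfg0 <- base_cfg(list(run = list(n_individuals = 500, discount_rate = 0)))
  res0 <- simulate_arm(co, "intervention", cfg0, master_seed = 3)
  expect_equal(res0$totals$cost, res0$totals$cost_undisc, tolerance = 1e-9)
  expect_equal(res0$totals$qaly, res0$totals$qaly_undisc, tolerance = 1e-9)
  expect_equal(res0$totals$ly, res0$totals$ly_undisc, tolerance = 1e-9)
  # the per-individual ledger reproduces the engine's discounted totals
  res1 <- simulate_individual(co[7, ], "intervention", cfg, master_seed = 3)
  dt <- discounted_totals(res1$ledger, cfg$run$discount_rate)
  expect_equal(dt$cost, res1$totals$cost, tolerance = 1e-9)
  expect_equal(dt$qaly, res1$totals$qaly, tolerance = 1e-9)
  expect_equal(dt$ly, res1$totals$ly, tolerance = 1e-9)
})

test_that("raising the healthy-age utility weight lowers the ICER at fixed event logs", {
  cfg <- base_cfg(strong_effect(3000))
  res <- run_base_case(cfg)
  up <- param_set(cfg, "u_norm_40_49", 0.90)
  res_up <- run_base_case(up)
  # same seed, same events; only the utility weighting moved
  expect_equal(res_up$first_ever_per_10000, res$first_ever_per_10000)
  if (!is.na(res$icer_qaly) && !is.na(res_up$icer_qaly) && res$increments$qaly > 0) {
    expect_lte(res_up$icer_qaly, res$icer_qaly)
  }
})
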