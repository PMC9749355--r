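# Shared fixtures: all built in code from the bundled defaults.

base_cfg <- function(overrides = NULL) load_config(overrides = overrides)

# No CVD risk, no background mortality: everyone reaches the age cap.
immortal_overrides <- list(
  risk_first_ever = list(baseline_survival = 1),
  risk_recurrent = list(baseline_survival = 1),
  mortality = list(rows = list(list(age_lo = 30, age_hi = 100, p = 0)))
)

# Flat background mortality, no CVD risk (geometric-lifetime oracle).
flat_mortality_overrides <- function(p) list(
  risk_first_ever = list(baseline_survival = 1),
  risk_recurrent = list(baseline_survival = 1),
  mortality = list(rows = list(list(age_lo = 30, age_hi = 100, p = p)))
)

# Degenerate marginals: identical women aged `age`, SBP 125, TC 5, HDL 1.5.
degenerate_population <- function(age = 40) list(
  age_bands = list(list(age_lo = age, age_hi = age, mass = 1)),
  smoking_by_age = list(list(age_lo = 30, age_hi = 54, current = 0, ex = 0, never = 1)),
  diabetes_by_age = list(list(age_lo = 30, age_hi = 54, prevalence = 0)),
  sbp_band_masses_by_age = list(list(age_lo = 30, age_hi = 54,
                                     masses = c(0, 0, 0, 1, 0, 0, 0, 0, 0))),
  tc_by_age = list(list(age_lo = 30, age_hi = 54, mean = 5.0, sd = 0)),
  hdl_by_age = list(list(age_lo = 30, age_hi = 54, mean = 1.5, sd = 0))
)

# Null intervention effect (the DSA range is widened so it still brackets 0).
zero_effect_overrides <- function(...) list(
  run = c(list(intervention_effect_sbp = 0), list(...)),
  economics = list(dsa_ranges = list(intervention_effect_sbp = c(-6.32, 0)))
)

# A deliberately strong SBP effect for property tests whose assertions hold
# for any effect size: the signal then dominates Monte-Carlo noise.
strong_effect <- function(n, ...) list(
  run = c(list(n_individuals = n, intervention_effect_sbp = -15), list(...)),
  economics = list(dsa_ranges = list(intervention_effect_sbp = c(-20, -0.01)))
)

# Overlay degenerate marginals onto the default population section.
merge_pop <- function(pop, overlay) cvdmicrosim:::merge_lists(pop, overlay)

# A woman fixed at every centering value of the first-ever equation.
centered_individual <- function() {
  data.frame(id = 1L, age = 56, ses_quintile = 3L, smoking = "never",
             diabetes = FALSE, sbp = 129, tc = 3.7 * 1.5, hdl = 1.5)
}
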