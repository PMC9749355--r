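#' @keywords internal
#' @importFrom stats runif rnorm rbeta rgamma
#' @importFrom graphics plot abline
#' @importFrom utils read.csv write.csv
"_PACKAGE"

cfg_error <- function(...) stop(errorCondition(paste0(...), class = c("cvd_config_error", "cvd_error")))
val_error <- function(...) stop(errorCondition(paste0(...), class = c("cvd_validation_error", "cvd_error")))

#' Path to the bundled default configuration
#'
#' @return File path of the YAML document holding all default model parameters.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "cvdmicrosim", mustWork = TRUE)
}

merge_lists <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) && !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_lists(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load and validate the full model parameter set
#'
#' Reads a YAML configuration (defaults bundled with the package), applies any
#' overrides layered on top, and validates every structural invariant: mass
#' vectors summing to one, probabilities in \[0,1\], non-negative costs,
#' utilities in \[0,1\], contiguous mortality coverage from age 30 to the age
#' cap, and sensitivity ranges bracketing their base values. Validation
#' failures are raised at load time, never during simulation.
#'
#' @param path Path to a YAML configuration; `NULL` uses the bundled defaults.
#' @param overrides Optional named list merged over the loaded document
#'   (nested lists merge recursively).
#' @return A validated configuration object of class `cvd_config` with
#'   sections `run`, `risk_first_ever`, `risk_recurrent`, `subtypes`,
#'   `mortality`, `economics`, `population` and `budget`.
#' @examples
#' cfg <- load_config()
#' cfg$economics$acute_costs$MI
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  if (is.null(path)) path <- default_config_path()
  if (!file.exists(path)) cfg_error("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg <- merge_lists(cfg, overrides)
  validate_config(cfg)
}

#' Persist a configuration to YAML
#'
#' Round-trips losslessly through [load_config()] (numeric values written at
#' 12 significant digits).
#'
#' @param cfg A `cvd_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cvd_config"))
  out <- unclass(cfg)
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

required_sections <- c("run", "risk_first_ever", "risk_recurrent", "subtypes",
                       "mortality", "economics", "population", "budget")

check_mass <- function(x, what, tol = 1e-9) {
  x <- as.numeric(x)
  if (any(x < 0 | x > 1)) val_error(what, ": masses must lie in [0, 1]")
  s <- sum(x)
  if (abs(s - 1) > tol) val_error(what, ": masses sum to ", format(s, digits = 12), ", expected 1")
  invisible(x)
}

validate_config <- function(cfg) {
  miss <- setdiff(required_sections, names(cfg))
  if (length(miss)) cfg_error("missing required table(s): ", paste(miss, collapse = ", "))

  run <- cfg$run
  if (is.null(run$effect_years)) run$effect_years <- run$adherence_years
  if (is.null(run$adherence_years)) run$adherence_years <- run$intervention_years
  if (is.null(run$sbp_jitter)) run$sbp_jitter <- TRUE
  if (!is.numeric(run$n_individuals) || run$n_individuals <= 0)
    val_error("run: n_individuals must be > 0")
  if (run$discount_rate < 0 || run$discount_rate >= 1)
    val_error("run: discount_rate must satisfy 0 <= r < 1")
  if (run$cycle_length != 1) val_error("run: cycle_length is fixed at 1 year")
  if (!(run$intervention_years >= run$adherence_years && run$adherence_years >= 0))
    val_error("run: need intervention_years >= adherence_years >= 0")
  if (run$effect_years < 0) val_error("run: effect_years must be >= 0")
  cfg$run <- run

  for (rm_name in c("risk_first_ever", "risk_recurrent")) {
    rm <- cfg[[rm_name]]
    if (is.null(rm$predictors) || !length(rm$predictors))
      cfg_error("missing required table: ", rm_name, " predictors")
    if (!(rm$baseline_survival > 0 && rm$baseline_survival <= 1))
      val_error(rm_name, ": baseline_survival must be in (0, 1]")
    if (!(rm$horizon_years %in% c(5, 10)))
      val_error(rm_name, ": horizon_years must be 5 or 10")
    for (p in rm$predictors) {
      if (is.null(p$name) || is.null(p$beta) || is.null(p$center))
        val_error(rm_name, ": every predictor needs name, beta and center")
      if (is.null(p$transform)) p$transform <- "identity"
      if (!p$transform %in% c("identity", "per10", "log_floor1"))
        val_error(rm_name, ": unknown transform '", p$transform, "'")
    }
  }

  check_mass(unlist(cfg$subtypes$first_ever), "subtypes$first_ever")
  check_mass(unlist(cfg$subtypes$recurrent), "subtypes$recurrent")

  mt <- mortality_table(cfg)
  if (any(mt$p < 0 | mt$p > 1)) val_error("mortality: probabilities must be in [0, 1]")
  if (min(mt$age_lo) > 30 || max(mt$age_hi) < cfg$run$age_cap)
    val_error("mortality: table must cover ages 30 to ", cfg$run$age_cap)
  o <- order(mt$age_lo)
  if (any(mt$age_lo[o][-1] != mt$age_hi[o][-nrow(mt)] + 1))
    val_error("mortality: age bands must be contiguous (no gaps)")

  ec <- cfg$economics
  costs <- c(unlist(ec$acute_costs), unlist(ec$mgmt_costs_annual), ec$intervention_cost_annual)
  if (any(costs < 0)) val_error("economics: all costs must be >= 0")
  ub <- utility_table(cfg)
  if (any(ub$utility < 0 | ub$utility > 1)) val_error("economics: utilities must be in [0, 1]")
  pu <- unlist(ec$post_event_utilities)
  if (any(pu < 0 | pu > 1)) val_error("economics: post-event utilities must be in [0, 1]")
  check_mass(ec$mrs_weights, "economics$mrs_weights")
  if (length(ec$mrs_utilities) != length(ec$mrs_weights))
    val_error("economics: mrs_utilities and mrs_weights must have equal length")
  for (nm in names(ec$dsa_ranges)) {
    rng <- as.numeric(ec$dsa_ranges[[nm]])
    base <- param_get(cfg, nm)
    if (!(rng[1] <= base && base <= rng[2]))
      val_error("economics$dsa_ranges: ", nm, " base value ", base,
                " outside range [", rng[1], ", ", rng[2], "]")
  }
  for (nm in names(ec$psa_sd)) {
    if (ec$psa_sd[[nm]] < 0) val_error("economics$psa_sd: ", nm, " SD must be >= 0")
    param_get(cfg, nm)  # errors if no base value exists
  }

  pop <- cfg$population
  check_mass(vapply(pop$age_bands, function(b) b$mass, 0), "population$age_bands")
  check_mass(pop$ses_quintile, "population$ses_quintile")
  for (b in pop$smoking_by_age)
    check_mass(c(b$current, b$ex, b$never),
               sprintf("population$smoking_by_age[%d-%d]", b$age_lo, b$age_hi))
  for (b in pop$sbp_band_masses_by_age)
    check_mass(b$masses, sprintf("population$sbp_band_masses_by_age[%d-%d]", b$age_lo, b$age_hi))
  for (b in pop$diabetes_by_age)
    if (b$prevalence < 0 || b$prevalence > 1) val_error("population$diabetes_by_age: prevalence in [0,1]")
  for (tbl in c("tc_by_age", "hdl_by_age"))
    for (b in pop[[tbl]])
      if (b$sd < 0) val_error("population$", tbl, ": SDs must be >= 0")

  if (cfg$budget$eligible_n <= 0) val_error("budget: eligible_n must be > 0")

  structure(cfg, class = "cvd_config")
}

# ---- flat accessors used throughout the engine --------------------------------

mortality_table <- function(cfg) {
  r <- cfg$mortality$rows
  data.frame(age_lo = vapply(r, `[[`, 0, "age_lo"),
             age_hi = vapply(r, `[[`, 0, "age_hi"),
             p = vapply(r, `[[`, 0, "p"))
}

utility_table <- function(cfg) {
  r <- cfg$economics$utilities_by_age
  data.frame(age_lo = vapply(r, `[[`, 0, "age_lo"),
             age_hi = vapply(r, `[[`, 0, "age_hi"),
             utility = vapply(r, `[[`, 0, "utility"))
}

#' mRS-weighted post-ischaemic-stroke utility
#'
#' The post-ischaemic-stroke health-state utility is the modified Rankin Scale
#' (mRS 0-5) utility vector weighted by the configured mRS distribution.
#'
#' @param econ The `economics` section of a `cvd_config`.
#' @return A single utility weight.
#' @export
mrs_stroke_utility <- function(econ) {
  sum(as.numeric(econ$mrs_utilities) * as.numeric(econ$mrs_weights))
}

# ---- named-parameter registry (DSA / PSA) -------------------------------------

# Table-style labels -> location in the config tree.
param_map <- list(
  c_MI          = c("acute", "MI"),
  c_UA          = c("acute", "UA"),
  c_stroke_IS   = c("acute", "ischaemic_stroke"),
  c_stroke_HA   = c("acute", "haemorrhagic_stroke"),
  c_TIA         = c("acute", "TIA"),
  c_PVD         = c("acute", "PVD"),
  c_CHF         = c("acute", "CHF"),
  c_otherCVD    = c("acute", "other_CHD"),
  c_CVD_death_other = c("acute", "other_CVD_death"),
  c_mgmt_MI     = c("mgmt", "MI"),
  c_mgmt_UA     = c("mgmt", "UA"),
  c_mgmt_stroke = c("mgmt", "ischaemic_stroke"),
  c_mgmt_TIA    = c("mgmt", "TIA"),
  c_mgmt_PVD    = c("mgmt", "PVD"),
  c_mgmt_CHD    = c("mgmt", "CHF"),
  c_mgmt_otherCVD = c("mgmt", "other_CHD"),
  c_mgmt_postCVD  = c("mgmt", "postCVD"),
  u_MI          = c("post_utility", "MI"),
  u_stroke_HE   = c("post_utility", "haemorrhagic_stroke"),
  u_TIA         = c("post_utility", "TIA"),
  u_CHF         = c("post_utility", "CHF"),
  u_PVD         = c("post_utility", "PVD"),
  u_otherCHD    = c("post_utility", "other_CHD"),
  u_postCVD     = c("post_utility", "postCVD"),
  c_intervention = c("run_scalar", "intervention_cost_annual"),
  discount_rate = c("run", "discount_rate"),
  intervention_effect_sbp = c("run", "intervention_effect_sbp"),
  effect_years  = c("run", "effect_years"),
  age_cap       = c("run", "age_cap")
)

# Acute costs that shadow a recurrent-event alias as well.
acute_alias <- list(MI = "nonfatal_MI", ischaemic_stroke = "nonfatal_stroke",
                    other_CVD_death = "cvd_death")
mgmt_alias <- list(MI = "nonfatal_MI", ischaemic_stroke = c("haemorrhagic_stroke", "nonfatal_stroke"))

parse_unorm <- function(name) {
  m <- regmatches(name, regexec("^u_norm_([0-9]+)_([0-9]+)$", name))[[1]]
  if (!length(m)) return(NULL)
  as.numeric(m[2:3])
}

#' Look up a named scalar parameter
#'
#' Resolves the Table-style parameter labels used by the sensitivity analyses
#' (`c_MI`, `u_stroke_HE`, `u_norm_40_49`, `discount_rate`, ...) to their
#' current value in the configuration.
#'
#' @param cfg A `cvd_config`.
#' @param name Parameter label.
#' @return The scalar base value.
#' @export
param_get <- function(cfg, name) {
  band <- parse_unorm(name)
  if (!is.null(band)) {
    for (b in cfg$economics$utilities_by_age)
      if (b$age_lo == band[1] && b$age_hi == band[2]) return(b$utility)
    cfg_error("no utility age band matches parameter ", name)
  }
  loc <- param_map[[name]]
  if (is.null(loc)) cfg_error("unknown parameter name: ", name)
  switch(loc[1],
    acute = cfg$economics$acute_costs[[loc[2]]],
    mgmt = cfg$economics$mgmt_costs_annual[[loc[2]]],
    post_utility = cfg$economics$post_event_utilities[[loc[2]]],
    run_scalar = cfg$economics[[loc[2]]],
    run = cfg$run[[loc[2]]]
  )
}

#' Set a named scalar parameter
#'
#' Counterpart of [param_get()]; returns a modified copy of the configuration.
#' Acute/management costs keyed by a first-ever subtype propagate to their
#' recurrent-event aliases (e.g. `c_MI` also updates the nonfatal recurrent MI
#' cost) so a one-way sensitivity run moves the parameter everywhere it is used.
#'
#' @param cfg A `cvd_config`.
#' @param name Parameter label.
#' @param value New scalar value.
#' @return The updated `cvd_config`.
#' @export
param_set <- function(cfg, name, value) {
  band <- parse_unorm(name)
  if (!is.null(band)) {
    for (i in seq_along(cfg$economics$utilities_by_age)) {
      b <- cfg$economics$utilities_by_age[[i]]
      if (b$age_lo == band[1] && b$age_hi == band[2]) {
        cfg$economics$utilities_by_age[[i]]$utility <- value
        return(cfg)
      }
    }
    cfg_error("no utility age band matches parameter ", name)
  }
  loc <- param_map[[name]]
  if (is.null(loc)) cfg_error("unknown parameter name: ", name)
  if (loc[1] == "acute") {
    cfg$economics$acute_costs[[loc[2]]] <- value
    for (al in acute_alias[[loc[2]]]) cfg$economics$acute_costs[[al]] <- value
  } else if (loc[1] == "mgmt") {
    cfg$economics$mgmt_costs_annual[[loc[2]]] <- value
    for (al in mgmt_alias[[loc[2]]]) cfg$economics$mgmt_costs_annual[[al]] <- value
  } else if (loc[1] == "post_utility") {
    cfg$economics$post_event_utilities[[loc[2]]] <- value
  } else if (loc[1] == "run_scalar") {
    cfg$economics[[loc[2]]] <- value
  } else {
    cfg$run[[loc[2]]] <- value
  }
  cfg
}

#' @export
print.cvd_config <- function(x, ...) {
  cat("<cvd_config>\n")
  cat(sprintf("  cohort: n = %d women aged 30-54, lifetime horizon to age %d\n",
              as.integer(x$run$n_individuals), as.integer(x$run$age_cap)))
  cat(sprintf("  intervention: %+.2f mmHg SBP for %d year(s), $%.2f/yr, adherence %d yr\n",
              x$run$intervention_effect_sbp, as.integer(x$run$effect_years),
              x$economics$intervention_cost_annual, as.integer(x$run$adherence_years)))
  cat(sprintf("  discounting: %.1f%%/yr, WTP $%s/QALY\n",
              100 * x$run$discount_rate, format(x$run$wtp_threshold, big.mark = ",")))
  invisible(x)
}
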