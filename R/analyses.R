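# Analysis orchestration: base case, subgroups, one-way deterministic
# sensitivity (tornado), probabilistic sensitivity (CE plane + CEAC),
# threshold search, extreme-value adherence and budget impact.

assemble_cea <- function(cfg, cohort, paired, label = "base case") {
  n <- nrow(cohort)
  ic <- compute_icer(paired$intervention$totals, paired$usual_care$totals,
                     wtp = cfg$run$wtp_threshold)
  ev <- lapply(paired, function(a) count_events(a$events, n))
  structure(list(
    label = label,
    n_individuals = n,
    master_seed = cfg$run$master_seed,
    arms = ic$arms,
    increments = ic$increments,
    icer_qaly = ic$icer_qaly, icer_ly = ic$icer_ly,
    dominance = ic$dominance, wtp = ic$wtp, nmb = ic$nmb,
    cost_effective = ic$cost_effective,
    events_per_10000 = ev,
    first_ever_per_10000 = vapply(ev, function(e) sum(e$per_10000[e$first_ever]), 0),
    recurrent_per_10000 = vapply(ev, function(e) sum(e$per_10000[!e$first_ever]), 0),
    mean_age_first_event = vapply(paired, function(a) mean_age_first_event(a$events), 0)
  ), class = "cea_result")
}

#' Run the base-case cost-effectiveness analysis
#'
#' Samples the baseline cohort, simulates both arms under common random
#' numbers, and summarises discounted costs, QALYs, LYs, their increments,
#' ICERs and event counts per 10,000 women.
#'
#' @param config A `cvd_config` (see [load_config()]).
#' @param n Cohort size; defaults to `config$run$n_individuals`.
#' @param seed Master seed; defaults to `config$run$master_seed`.
#' @return A `cea_result` object.
#' @examples
#' \donttest{
#' cfg <- load_config()
#' res <- run_base_case(cfg, n = 1000)
#' print(res)
#' }
#' @export
run_base_case <- function(config, n = NULL, seed = NULL) {
  if (!is.null(n)) config$run$n_individuals <- n
  if (!is.null(seed)) config$run$master_seed <- seed
  pop <- config$population
  if (!is.null(config$run$subgroup_age_range)) {
    rg <- as.numeric(config$run$subgroup_age_range)
    pop <- restrict_to_age_band(pop, rg[1], rg[2])
  }
  cohort <- sample_cohort(pop, config$run$n_individuals,
                          seed = mix_seed(config$run$master_seed, 999983),
                          sbp_jitter = isTRUE(config$run$sbp_jitter))
  paired <- run_paired(cohort, config, config$run$master_seed)
  assemble_cea(config, cohort, paired)
}

#' Subgroup analysis on a baseline age band
#'
#' Re-runs the base case with the baseline age distribution restricted to
#' `[lo, hi)` and renormalised; everything else unchanged.
#'
#' @param config A `cvd_config`.
#' @param lo,hi Age band bounds in years.
#' @param n,seed Optional overrides as in [run_base_case()].
#' @return A `cea_result`.
#' @export
run_subgroup <- function(config, lo, hi, n = NULL, seed = NULL) {
  config$run$subgroup_age_range <- c(lo, hi)
  out <- run_base_case(config, n = n, seed = seed)
  out$label <- sprintf("subgroup age %g-%g", lo, hi)
  out
}

dsa_default_params <- function(config) names(config$economics$dsa_ranges)

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Each parameter is pushed to the low and high end of its configured
#' plausible range while everything else — including the master seed, hence
#' the random streams — is held at base, so the ICER span isolates that
#' parameter. The starting-age parameter is handled structurally by
#' restricting the baseline age distribution to its two endpoint bands.
#'
#' @param config A `cvd_config`.
#' @param params Parameter labels to vary; default is every entry of
#'   `economics$dsa_ranges` plus the starting-age bands.
#' @param n,seed Optional overrides as in [run_base_case()].
#' @return A `cvd_dsa` data frame (parameter, low, high, icer_low, icer_high,
#'   icer_base, span) sorted by decreasing span; plot it for a tornado
#'   diagram.
#' @export
run_dsa <- function(config, params = NULL, n = NULL, seed = NULL) {
  if (is.null(params)) params <- c(dsa_default_params(config), "start_age")
  base <- run_base_case(config, n = n, seed = seed)
  icer_of <- function(cfg) run_base_case(cfg, n = n, seed = seed)$icer_qaly
  rows <- lapply(params, function(pm) {
    if (pm == "start_age") {
      lo_band <- as.numeric(config$economics$dsa_start_age_bands$low)
      hi_band <- as.numeric(config$economics$dsa_start_age_bands$high)
      cfg_lo <- config; cfg_lo$run$subgroup_age_range <- lo_band
      cfg_hi <- config; cfg_hi$run$subgroup_age_range <- hi_band
      lo <- lo_band[1]; hi <- hi_band[1]
    } else {
      rng <- as.numeric(config$economics$dsa_ranges[[pm]])
      lo <- rng[1]; hi <- rng[2]
      cfg_lo <- param_set(config, pm, lo)
      cfg_hi <- param_set(config, pm, hi)
    }
    data.frame(parameter = pm, low = lo, high = hi,
               icer_low = icer_of(cfg_lo), icer_high = icer_of(cfg_hi),
               icer_base = base$icer_qaly)
  })
  out <- do.call(rbind, rows)
  out$span <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  class(out) <- c("cvd_dsa", "data.frame")
  out
}

sample_psa_params <- function(config, draw_seed) {
  set.seed(draw_seed)
  cfg <- config
  for (nm in names(config$economics$psa_sd)) {
    sd <- config$economics$psa_sd[[nm]]
    if (sd == 0) next
    base <- param_get(config, nm)
    if (startsWith(nm, "u_")) {
      if (sd^2 >= base * (1 - base))
        val_error("infeasible beta moments for ", nm, ": sd^2 >= mean*(1-mean)")
      nu <- base * (1 - base) / sd^2 - 1
      val <- stats::rbeta(1, base * nu, (1 - base) * nu)
    } else {
      val <- stats::rgamma(1, shape = base^2 / sd^2, scale = sd^2 / base)
    }
    cfg <- param_set(cfg, nm, val)
  }
  cfg
}

#' Probabilistic sensitivity analysis
#'
#' Cost parameters are drawn from gamma and utility parameters from beta
#' distributions, matched to their base value and configured SD by the method
#' of moments (exactly the parameters carrying a `psa_sd`; risk coefficients
#' stay fixed). Every draw re-runs the paired simulation on a reduced inner
#' cohort with the base-case event seed, so draws differ only through the
#' sampled parameters.
#'
#' @param config A `cvd_config`.
#' @param n_draws Number of parameter draws (default `run$psa_draws`).
#' @param seed Seed for the parameter draws (default derived from the master
#'   seed).
#' @param inner_n Inner cohort size per draw (default `run$psa_inner_n`).
#' @param wtp_grid WTP grid for the acceptability curve, AUD/QALY.
#' @return A `cvd_psa` object: `draws` (delta cost, delta QALY, cost-effective
#'   flag per draw), `ceac` (probability cost-effective over the WTP grid) and
#'   `prob_ce_at_wtp`.
#' @export
run_psa <- function(config, n_draws = NULL, seed = NULL, inner_n = NULL,
                    wtp_grid = seq(0, 200000, by = 5000)) {
  if (is.null(n_draws)) n_draws <- config$run$psa_draws
  if (is.null(seed)) seed <- mix_seed(config$run$master_seed, 424243)
  if (is.null(inner_n)) inner_n <- config$run$psa_inner_n
  cohort <- sample_cohort(config$population, inner_n,
                          seed = mix_seed(config$run$master_seed, 999983),
                          sbp_jitter = isTRUE(config$run$sbp_jitter))
  K <- as.integer(config$run$age_cap - min(cohort$age))
  U <- rng_streams(config$run$master_seed, cohort$id, K)
  wtp <- config$run$wtp_threshold
  draws <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    cfg_d <- sample_psa_params(config, mix_seed(seed, d))
    ti <- simulate_core(cohort, "intervention", cfg_d, config$run$master_seed, U)$totals
    tu <- simulate_core(cohort, "usual_care", cfg_d, config$run$master_seed, U)$totals
    draws[[d]] <- data.frame(draw = d,
                             d_cost = mean(ti$cost) - mean(tu$cost),
                             d_qaly = mean(ti$qaly) - mean(tu$qaly))
  }
  draws <- do.call(rbind, draws)
  draws$cost_effective <- wtp * draws$d_qaly - draws$d_cost >= 0
  ceac <- data.frame(wtp = wtp_grid,
                     prob_ce = vapply(wtp_grid, function(w)
                       mean(w * draws$d_qaly - draws$d_cost >= 0), 0))
  structure(list(draws = draws, ceac = ceac, wtp = wtp,
                 prob_ce_at_wtp = mean(draws$cost_effective),
                 inner_n = inner_n), class = "cvd_psa")
}

#' Threshold analysis on a single parameter
#'
#' Finds the smallest parameter value at which the ICER crosses the
#' willingness-to-pay threshold, assuming the ICER is monotone over the search
#' range. Integer-year parameters (effect duration) are swept by bisection on
#' whole years; continuous parameters by bisection to a relative tolerance.
#'
#' @param config A `cvd_config`.
#' @param parameter Parameter label (default `"effect_years"`, the duration
#'   of the sustained SBP effect).
#' @param range Search range `c(lo, hi)`; default 1 to 40 years for
#'   `effect_years`.
#' @param target Willingness-to-pay target (default `run$wtp_threshold`).
#' @param integer_steps Treat the parameter as integer-valued.
#' @param tol Relative tolerance for continuous parameters.
#' @param n,seed Optional overrides as in [run_base_case()].
#' @return A list with `parameter`, `threshold` (or `NA` if the target is not
#'   reached in range), `target` and the ICERs at the range ends.
#' @export
run_threshold <- function(config, parameter = "effect_years", range = NULL,
                          target = NULL, integer_steps = parameter == "effect_years",
                          tol = 1e-4, n = NULL, seed = NULL) {
  if (is.null(target)) target <- config$run$wtp_threshold
  if (is.null(range)) range <- if (parameter == "effect_years") c(1, 40) else
    as.numeric(config$economics$dsa_ranges[[parameter]])
  icer_at <- function(v) run_base_case(param_set(config, parameter, v), n = n, seed = seed)$icer_qaly
  crosses <- function(v) { ic <- icer_at(v); !is.na(ic) && ic <= target }
  lo <- range[1]; hi <- range[2]
  f_lo <- icer_at(lo); f_hi <- icer_at(hi)
  if (!is.na(f_lo) && f_lo <= target)
    return(list(parameter = parameter, threshold = lo, target = target,
                icer_lo = f_lo, icer_hi = f_hi, found = TRUE))
  if (is.na(f_hi) || f_hi > target)
    return(list(parameter = parameter, threshold = NA_real_, target = target,
                icer_lo = f_lo, icer_hi = f_hi, found = FALSE))
  # f(lo) > target >= f(hi): bisect for the smallest crossing value
  a <- lo; b <- hi
  while (if (integer_steps) (b - a) > 1 else (b - a) > tol * max(1, abs(b))) {
    m <- if (integer_steps) floor((a + b) / 2) else (a + b) / 2
    if (crosses(m)) b <- m else a <- m
  }
  list(parameter = parameter, threshold = b, target = target,
       icer_lo = f_lo, icer_hi = f_hi, found = TRUE)
}

#' Extreme-value analysis: 0% adherence after one year
#'
#' The program is delivered (and its SBP effect lasts) for the first cycle
#' only; lower benefit, lower incremental cost.
#'
#' @param config A `cvd_config`.
#' @param n,seed Optional overrides as in [run_base_case()].
#' @return A `cea_result`.
#' @export
run_extreme_adherence <- function(config, n = NULL, seed = NULL) {
  config$run$adherence_years <- 1
  config$run$effect_years <- 1
  out <- run_base_case(config, n = n, seed = seed)
  out$label <- "extreme value: 0% adherence after one year"
  out
}

#' Budget impact of a national roll-out
#'
#' The total intervention budget is the eligible population times the annual
#' per-capita cost times a `years`-payment annuity discounted at `r` (first
#' payment undiscounted). The lifetime cost offset scales the per-person
#' discounted hospitalisation and management savings to the eligible
#' population.
#'
#' @param config A `cvd_config` (supplies defaults for every argument).
#' @param eligible_n Eligible population size.
#' @param per_capita_annual Annual per-person program cost, AUD.
#' @param years Number of annual deliveries.
#' @param r Discount rate for the payment stream.
#' @param offsets Named per-person savings `c(hospitalisation=, management=)`;
#'   defaults to the configured (printed base-case) values. Pass the
#'   increments of a [run_base_case()] result to use model-derived offsets.
#' @return A `budget_result` list with `total_intervention_cost` and
#'   `total_cost_offset` (AUD).
#' @export
run_budget_impact <- function(config, eligible_n = NULL, per_capita_annual = NULL,
                              years = NULL, r = NULL, offsets = NULL) {
  if (is.null(eligible_n)) eligible_n <- config$budget$eligible_n
  if (is.null(per_capita_annual)) per_capita_annual <- config$economics$intervention_cost_annual
  if (is.null(years)) years <- config$budget$years
  if (is.null(r)) r <- config$run$discount_rate
  if (is.null(offsets)) offsets <- unlist(config$budget$per_person_offsets)
  stopifnot(eligible_n > 0, years >= 1)
  annuity <- sum((1 + r)^(-(seq_len(years) - 1)))
  structure(list(
    eligible_n = eligible_n, per_capita_annual_cost = per_capita_annual,
    years = years, discount_rate = r,
    total_intervention_cost = eligible_n * per_capita_annual * annuity,
    per_person_offset = sum(offsets),
    total_cost_offset = eligible_n * sum(offsets)
  ), class = "budget_result")
}

#' @export
print.budget_result <- function(x, ...) {
  cat("Budget impact of national roll-out\n")
  cat(sprintf("  eligible women: %s; $%.2f/person/yr over %d year(s) at %.1f%%\n",
              format(x$eligible_n, big.mark = ","), x$per_capita_annual_cost,
              as.integer(x$years), 100 * x$discount_rate))
  cat(sprintf("  total intervention cost: $%.1f million\n", x$total_intervention_cost / 1e6))
  cat(sprintf("  lifetime cost offset:    $%.1f million\n", x$total_cost_offset / 1e6))
  invisible(x)
}
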