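# Risk engine: Cox-form linear predictors for first-ever (5-year horizon) and
# recurrent (10-year horizon) CVD, horizon-to-annual probability conversion,
# categorical subtype draws and the background non-CVD mortality lookup.

# Resolve a predictor's raw value from a state list of (equal-length) vectors.
# Missing or NA values fall back to the centering value, contributing zero.
resolve_predictor <- function(name, state, model, n) {
  v <- switch(name,
    age = {
      a <- state$age
      if (!is.null(model$lp_age_cap)) a <- pmin(a, model$lp_age_cap)
      a
    },
    ses_quintile = state$ses_quintile,
    smoking_current = as.numeric(state$smoking == "current"),
    smoking_ex = as.numeric(state$smoking == "ex"),
    diabetes = as.numeric(state$diabetes),
    sbp = state$sbp,
    tc = state$tc,
    hdl = state$hdl,
    tc_hdl_ratio = state$tc / state$hdl,
    years_since_first = state$years_since_first,
    stop(errorCondition(paste0("predictor not resolvable: ", name),
                        class = c("cvd_predictor_error", "cvd_error")))
  )
  if (is.null(v)) v <- rep(NA_real_, n)
  v
}

apply_transform <- function(x, transform) {
  switch(transform,
    identity = x,
    per10 = x / 10,
    log_floor1 = log(pmax(1, x)),
    stop("unknown transform: ", transform))
}

lp_vec <- function(state, model) {
  n <- length(state$age)
  lp <- numeric(n)
  for (p in model$predictors) {
    tr <- if (is.null(p$transform)) "identity" else p$transform
    x <- apply_transform(resolve_predictor(p$name, state, model, n), tr)
    x[is.na(x)] <- p$center
    lp <- lp + p$beta * (x - p$center)
  }
  lp
}

#' Centred Cox linear predictor for one individual
#'
#' Computes `sum_j beta_j (x_j - center_j)` with the declared transforms
#' (per-10 mmHg scaling, TC/HDL ratio, floored-log time since first event)
#' applied first. Predictors missing from the individual resolve to their
#' centering value and contribute zero.
#'
#' @param individual A one-row cohort data frame or named list; recognised
#'   fields: `age`, `ses_quintile`, `smoking`, `diabetes`, `sbp`, `tc`, `hdl`,
#'   `years_since_first`.
#' @param model A risk-model specification (`risk_first_ever` or
#'   `risk_recurrent` section of a `cvd_config`).
#' @return The linear predictor (a real number).
#' @export
linear_predictor <- function(individual, model) {
  state <- list(
    age = as.numeric(individual$age),
    ses_quintile = if (is.null(individual$ses_quintile)) NA_real_ else as.numeric(individual$ses_quintile),
    smoking = if (is.null(individual$smoking)) NA_character_ else individual$smoking,
    diabetes = if (is.null(individual$diabetes)) NA else individual$diabetes,
    sbp = if (is.null(individual$sbp)) NA_real_ else as.numeric(individual$sbp),
    tc = if (is.null(individual$tc)) NA_real_ else as.numeric(individual$tc),
    hdl = if (is.null(individual$hdl)) NA_real_ else as.numeric(individual$hdl),
    years_since_first = if (is.null(individual$years_since_first)) NA_real_
                        else as.numeric(individual$years_since_first)
  )
  lp_vec(state, model)
}

#' Event probability over the model's horizon
#'
#' Cox form: `1 - S0^exp(lp)` where `S0` is the baseline survival at the
#' equation's horizon (5 years for first-ever, 10 for recurrent CVD).
#'
#' @param lp Linear predictor (vectorised).
#' @param model Risk-model specification with `baseline_survival`.
#' @return Probability in `[0, 1)`.
#' @export
horizon_risk <- function(lp, model) {
  s0 <- model$baseline_survival
  stopifnot(s0 > 0, s0 <= 1)
  1 - s0^exp(lp)
}

#' Convert a horizon probability to an annual probability
#'
#' Constant-hazard conversion `p1 = 1 - (1 - ph)^(1/h)` (the `probtoprob`
#' rule): the complement of surviving one year at the hazard implied by the
#' h-year probability.
#'
#' @param p_h Probability over `horizon` years (vectorised).
#' @param horizon Horizon length in years (>= 1).
#' @return Annual probability. `p_h = 1` returns 1 with a warning.
#' @export
horizon_to_annual <- function(p_h, horizon) {
  stopifnot(all(p_h >= 0 & p_h <= 1), horizon >= 1)
  if (any(p_h == 1)) warning("horizon probability of 1 converts to an annual probability of 1")
  1 - (1 - p_h)^(1 / horizon)
}

#' Inverse of [horizon_to_annual()]
#' @param p_1 Annual probability.
#' @param horizon Horizon length in years.
#' @return Probability over `horizon` years.
#' @export
annual_to_horizon <- function(p_1, horizon) 1 - (1 - p_1)^horizon

# Engine fast path: identical arithmetic to horizon_risk() + horizon_to_annual()
# without their argument guards (inputs are validated at config load).
annual_event_prob <- function(state, model) {
  p_h <- 1 - model$baseline_survival^exp(lp_vec(state, model))
  1 - (1 - p_h)^(1 / model$horizon_years)
}

#' Intervention effect on an individual's risk-relevant state
#'
#' While the individual is in the intervention arm, CVD-free, and within the
#' adherence window, the SBP entering the risk equations is shifted by the
#' configured (negative) effect and the annual program cost applies. The
#' stored SBP trajectory is never permanently altered. Usual-care individuals
#' pass through unchanged.
#'
#' @param individual A one-row cohort data frame or list with fields `arm`
#'   (`"intervention"` or `"usual_care"`), `sbp`, and optionally `n_events`
#'   (prior CVD events, default 0).
#' @param cycle Zero-based cycle index.
#' @param run The `run` section of a `cvd_config`.
#' @return The individual with `sbp_effective` and `on_intervention` fields set.
#' @export
apply_intervention <- function(individual, cycle, run) {
  n_events <- if (is.null(individual$n_events)) 0 else individual$n_events
  effect_years <- if (is.null(run$effect_years)) run$adherence_years else run$effect_years
  on <- identical(individual$arm, "intervention") && n_events == 0 && cycle < effect_years
  individual$on_intervention <- on && cycle < run$adherence_years
  individual$sbp_effective <- individual$sbp + if (on) run$intervention_effect_sbp else 0
  individual
}

draw_categorical <- function(u, probs) {
  cum <- cumsum(as.numeric(probs))
  cum[length(cum)] <- 1  # guard rounding
  names(probs)[findInterval(u, cum, left.open = TRUE) + 1L]
}

#' Draw the subtype of a first-ever CVD event
#'
#' Categorical draw over MI, unstable angina, ischaemic/haemorrhagic stroke,
#' TIA, PVD, CHF, other CHD and other CVD-related death (the fatal category).
#'
#' @param split Named conditional probabilities (the `subtypes$first_ever`
#'   table), summing to one.
#' @param u Uniform(0,1) draws (vectorised).
#' @return Character vector of subtype names.
#' @export
draw_first_event_subtype <- function(split, u) draw_categorical(u, unlist(split))

#' Draw the type of a recurrent CVD event
#'
#' Categorical draw over nonfatal stroke, nonfatal MI and CVD death (fatal).
#'
#' @param split Named probabilities (the `subtypes$recurrent` table).
#' @param u Uniform(0,1) draws (vectorised).
#' @return Character vector of event types.
#' @export
draw_recurrent_event_type <- function(split, u) draw_categorical(u, unlist(split))

#' Annual non-CVD death probability at a given age
#'
#' Exact step-function lookup in the background mortality table (all-cause
#' female mortality net of CVD deaths).
#'
#' @param age Age(s) in years.
#' @param table Mortality table: data frame with `age_lo`, `age_hi`, `p`
#'   (from the config via the internal accessor, or built by hand).
#' @return Annual probability of non-CVD death.
#' @export
noncvd_death_prob <- function(age, table) {
  o <- order(table$age_lo)
  table <- table[o, ]
  idx <- findInterval(age, table$age_lo)
  if (any(idx < 1) || any(age > table$age_hi[pmax(idx, 1)]))
    cfg_error("age ", age[which(idx < 1 | age > table$age_hi[pmax(idx, 1)])[1]],
              " outside mortality table coverage")
  table$p[idx]
}
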