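# Annual-cycle individual-level simulation over the lifetime horizon.
# Both arms share per-individual random-number streams (common random numbers)
# keyed by (master seed, individual id); within a cycle three uniforms are
# consumed in a fixed order: non-CVD death, CVD event, subtype.

# Exact 31-bit Lehmer-style mixer: deterministic, portable, < 2^31.
mix_seed <- function(seed, id) {
  a <- as.double(seed) %% 2147483647
  if (a <= 0) a <- a + 2147483646
  a <- (a * 48271) %% 2147483647
  a <- (a + as.double(id)) %% 2147483647
  a <- (a * 48271) %% 2147483647
  if (a == 0) a <- 1
  as.integer(a)
}

# Per-individual uniform streams: U[i, k, t] is draw k (1 death, 2 event,
# 3 subtype) of cycle t for individual ids[i]. Draw order within a stream is
# fixed so results are independent of cohort composition.
rng_streams <- function(master_seed, ids, n_cycles) {
  n <- length(ids)
  U <- array(NA_real_, dim = c(n, 3L, n_cycles))
  for (i in seq_len(n)) {
    set.seed(mix_seed(master_seed, ids[i]))
    U[i, , ] <- matrix(stats::runif(3L * n_cycles), nrow = 3L)
  }
  U
}

fatal_first <- "other_CVD_death"
fatal_recurrent <- "cvd_death"

# Precompute flat economics lookups used every cycle.
econ_precompute <- function(cfg) {
  ec <- cfg$economics
  post_ut <- unlist(ec$post_event_utilities)
  mrs <- mrs_stroke_utility(ec)
  post_ut[["ischaemic_stroke"]] <- mrs
  post_ut[["nonfatal_stroke"]] <- mrs
  list(
    acute = unlist(ec$acute_costs),
    mgmt = unlist(ec$mgmt_costs_annual),
    c_int = ec$intervention_cost_annual,
    post_ut = post_ut,
    u_postCVD = ec$post_event_utilities$postCVD,
    mgmt_post_recurrent = if (is.null(ec$mgmt_post_recurrent)) "subtype" else ec$mgmt_post_recurrent,
    ut = utility_table(cfg),
    mort = if (!is.null(cfg$mortality)) mortality_table(cfg) else NULL
  )
}

age_band_utility <- function(age, ut) {
  idx <- pmin(pmax(findInterval(age, ut$age_lo), 1L), nrow(ut))  # clamp to oldest band
  ut$utility[idx]
}

# Vectorised health-state utility: CVD-free -> age-band value; one prior event
# -> min(age-band, post-event utility of that subtype; subtypes without a
# listed utility keep the age-band value); two or more events -> min(age-band,
# post-CVD utility).
state_utility_vec <- function(age, n_events, last_sub, ep) {
  u <- age_band_utility(age, ep$ut)
  one <- which(n_events == 1)
  if (length(one)) {
    pu <- ep$post_ut[last_sub[one]]
    pu[is.na(pu)] <- Inf
    u[one] <- pmin(u[one], pu)
  }
  multi <- which(n_events >= 2)
  if (length(multi)) u[multi] <- pmin(u[multi], ep$u_postCVD)
  u
}

simulate_core <- function(cohort, arm, cfg, master_seed, U = NULL, keep_ledger = FALSE) {
  n <- nrow(cohort)
  run <- cfg$run
  empty_events <- data.frame(id = integer(), cycle = integer(), age_at_event = numeric(),
                             subtype = character(), fatal = logical(), first_ever = logical())
  if (n == 0) {
    return(list(totals = data.frame(id = integer(), cost = numeric(), cost_intervention = numeric(),
                                    cost_acute = numeric(), cost_mgmt = numeric(), qaly = numeric(),
                                    ly = numeric(), cost_undisc = numeric(), qaly_undisc = numeric(),
                                    ly_undisc = numeric()),
                events = empty_events, ledger = NULL))
  }
  intervention <- identical(arm, "intervention")
  effect_years <- if (is.null(run$effect_years)) run$adherence_years else run$effect_years
  adherence <- min(run$adherence_years, run$intervention_years)
  r <- run$discount_rate
  ep <- econ_precompute(cfg)
  pop <- cfg$population
  m_first <- cfg$risk_first_ever
  m_rec <- cfg$risk_recurrent
  split_first <- unlist(cfg$subtypes$first_ever)
  split_rec <- unlist(cfg$subtypes$recurrent)

  age <- as.numeric(cohort$age); sbp <- cohort$sbp; tc <- cohort$tc; hdl <- cohort$hdl
  ses <- cohort$ses_quintile; smoking <- cohort$smoking; diabetes <- cohort$diabetes
  ids <- cohort$id
  K <- as.integer(run$age_cap - min(age))
  if (is.null(U)) U <- rng_streams(master_seed, ids, K)

  # Age-indexed lookups (ages are integral inside the engine; step functions
  # are evaluated at floor(age), matching the banded tables exactly).
  ages_all <- 30:run$age_cap
  mort_vec <- noncvd_death_prob(ages_all, ep$mort)
  ut_vec <- age_band_utility(ages_all, ep$ut)
  sbp_inc_vec <- increment_at(pop$sbp_annual_increment_by_age, ages_all)
  tc_inc_vec <- increment_at(pop$tc_annual_increment_by_age, ages_all)
  hdl_inc_vec <- increment_at(pop$hdl_annual_increment_by_age, ages_all)
  aidx <- function(a) as.integer(a) - 29L  # engine ages are integral and in [30, cap]
  fast_util <- function(age, nev, last_sub) {
    u <- ut_vec[aidx(age)]
    one <- which(nev == 1L)
    if (length(one)) {
      pu <- ep$post_ut[last_sub[one]]
      pu[is.na(pu)] <- Inf
      u[one] <- pmin(u[one], pu)
    }
    multi <- which(nev >= 2L)
    if (length(multi)) u[multi] <- pmin(u[multi], ep$u_postCVD)
    u
  }

  alive <- rep(TRUE, n)
  nev <- integer(n)
  last_sub <- rep(NA_character_, n)
  first_cyc <- rep(NA_integer_, n)
  cost_int <- cost_ac <- cost_mg <- qaly <- ly <- numeric(n)
  cost_int_u <- cost_ac_u <- cost_mg_u <- qaly_u <- ly_u <- numeric(n)
  ev_id <- list(); ev_cyc <- list(); ev_age <- list(); ev_sub <- list()
  ev_fatal <- list(); ev_first <- list()
  ledger <- if (keep_ledger) vector("list", K) else NULL

  for (t in seq_len(K) - 1L) {
    act <- alive & age < run$age_cap
    if (!any(act)) break
    ai <- which(act)

    on_eff <- intervention & act & nev == 0L & t < effect_years
    on_cost <- intervention & act & nev == 0L & t < adherence
    sbp_eff <- sbp
    if (any(on_eff)) sbp_eff[on_eff] <- sbp_eff[on_eff] + run$intervention_effect_sbp

    p_ev <- numeric(n)
    fi <- which(act & nev == 0L)
    if (length(fi)) {
      st <- list(age = age[fi], ses_quintile = ses[fi], smoking = smoking[fi],
                 diabetes = diabetes[fi], sbp = sbp_eff[fi], tc = tc[fi], hdl = hdl[fi],
                 years_since_first = rep(NA_real_, length(fi)))
      p_ev[fi] <- annual_event_prob(st, m_first)
    }
    ri <- which(act & nev > 0L)
    if (length(ri)) {
      st <- list(age = age[ri], ses_quintile = ses[ri], smoking = smoking[ri],
                 diabetes = diabetes[ri], sbp = sbp_eff[ri], tc = tc[ri], hdl = hdl[ri],
                 years_since_first = pmax(1, t - first_cyc[ri]))
      p_ev[ri] <- annual_event_prob(st, m_rec)
    }
    p_d <- numeric(n)
    p_d[ai] <- mort_vec[aidx(age[ai])]

    u1 <- U[, 1L, t + 1L]; u2 <- U[, 2L, t + 1L]; u3 <- U[, 3L, t + 1L]
    die_nc <- act & u1 < p_d
    ev <- act & !die_nc & u2 < p_ev

    sub <- rep(NA_character_, n)
    efi <- which(ev & nev == 0L)
    if (length(efi)) sub[efi] <- draw_categorical(u3[efi], split_first)
    eri <- which(ev & nev > 0L)
    if (length(eri)) sub[eri] <- draw_categorical(u3[eri], split_rec)
    fatal_ev <- ev & (sub %in% c(fatal_first, fatal_recurrent))
    dies <- die_nc | fatal_ev

    u_pre <- fast_util(age, nev, last_sub)
    nev2 <- nev + as.integer(ev)
    last2 <- last_sub; last2[ev] <- sub[ev]
    first2 <- first_cyc; newly_first <- ev & nev == 0L
    first2[newly_first] <- t
    u_post <- fast_util(age, nev2, last2)

    ly_t <- numeric(n); ly_t[act] <- 1; ly_t[dies] <- 0.5
    util_t <- numeric(n)
    util_t[act] <- u_pre[act]
    nf_ev <- act & ev & !dies
    util_t[nf_ev] <- u_post[nf_ev]           # post-event utility from the event cycle
    qaly_t <- util_t * ly_t

    c_int_t <- numeric(n)
    c_int_t[on_cost & !ev] <- ep$c_int       # program stops at the de novo event
    c_ac_t <- numeric(n)
    evi <- which(ev)
    if (length(evi)) {
      ac <- ep$acute[sub[evi]]
      if (anyNA(ac)) stop("unknown event subtype: ", sub[evi][which(is.na(ac))[1]])
      c_ac_t[evi] <- ac
    }
    c_mg_t <- numeric(n)
    mgi <- which(act & nev > 0L & !ev)       # post-event, non-event cycles
    if (length(mgi)) {
      key <- last_sub[mgi]
      if (ep$mgmt_post_recurrent == "postCVD") key[nev[mgi] >= 2L] <- "postCVD"
      mg <- ep$mgmt[key]
      if (anyNA(mg)) stop("unknown management subtype: ", key[which(is.na(mg))[1]])
      c_mg_t[mgi] <- mg
    }

    df <- (1 + r)^(-(t + 0.5))               # half-cycle correction
    cost_int <- cost_int + df * c_int_t;  cost_int_u <- cost_int_u + c_int_t
    cost_ac <- cost_ac + df * c_ac_t;     cost_ac_u <- cost_ac_u + c_ac_t
    cost_mg <- cost_mg + df * c_mg_t;     cost_mg_u <- cost_mg_u + c_mg_t
    qaly <- qaly + df * qaly_t;           qaly_u <- qaly_u + qaly_t
    ly <- ly + df * ly_t;                 ly_u <- ly_u + ly_t

    if (length(evi)) {
      ev_id[[length(ev_id) + 1L]] <- ids[evi]
      ev_cyc[[length(ev_cyc) + 1L]] <- rep(t, length(evi))
      ev_age[[length(ev_age) + 1L]] <- age[evi]
      ev_sub[[length(ev_sub) + 1L]] <- sub[evi]
      ev_fatal[[length(ev_fatal) + 1L]] <- fatal_ev[evi]
      ev_first[[length(ev_first) + 1L]] <- newly_first[evi]
    }
    if (keep_ledger) {
      ledger[[t + 1L]] <- data.frame(
        id = ids[ai], cycle = t, cost_intervention = c_int_t[ai], cost_acute = c_ac_t[ai],
        cost_mgmt = c_mg_t[ai], utility = util_t[ai], ly = ly_t[ai], discount_factor = df)
    }

    alive[dies] <- FALSE
    nev <- nev2; last_sub <- last2; first_cyc <- first2
    surv <- act & !dies
    age[act] <- age[act] + 1
    si <- which(surv)
    if (length(si)) {
      k <- aidx(age[si])
      sbp[si] <- sbp[si] + sbp_inc_vec[k]
      tc[si] <- tc[si] + tc_inc_vec[k]
      hdl[si] <- hdl[si] + hdl_inc_vec[k]
    }
  }

  events <- if (length(ev_id)) {
    data.frame(id = unlist(ev_id), cycle = unlist(ev_cyc), age_at_event = unlist(ev_age),
               subtype = unlist(ev_sub), fatal = unlist(ev_fatal), first_ever = unlist(ev_first))
  } else empty_events
  totals <- data.frame(
    id = ids,
    cost = cost_int + cost_ac + cost_mg,
    cost_intervention = cost_int, cost_acute = cost_ac, cost_mgmt = cost_mg,
    qaly = qaly, ly = ly,
    cost_undisc = cost_int_u + cost_ac_u + cost_mg_u,
    qaly_undisc = qaly_u, ly_undisc = ly_u)
  list(totals = totals, events = events,
       ledger = if (keep_ledger) do.call(rbind, ledger[!vapply(ledger, is.null, TRUE)]) else NULL)
}

#' Simulate one arm of the trial for a whole cohort
#'
#' Runs the annual-cycle microsimulation for every individual until death or
#' the age cap. Within each cycle the competing risks are resolved
#' sequentially: non-CVD death, then a CVD event given survival, then the
#' subtype draw. Costs (intervention, acute, management) and utility-weighted
#' life years accrue with mid-cycle discounting `(1+r)^-(t+0.5)` and a half
#' life-year credit in the death cycle. Per-individual random-number streams
#' depend only on `(master_seed, id)`, so the two arms are coupled (common
#' random numbers) and results are independent of cohort ordering or
#' splitting.
#'
#' @param cohort Cohort data frame from [sample_cohort()].
#' @param arm `"intervention"` or `"usual_care"`.
#' @param params A `cvd_config`.
#' @param master_seed Integer master seed (shared by both arms).
#' @param keep_ledger Also return the full per-cycle ledger (memory-heavy for
#'   large cohorts).
#' @return A list with `totals` (one row per individual: discounted and
#'   undiscounted cost components, QALYs, LYs), `events` (one row per CVD
#'   event: id, cycle, age, subtype, fatal, first_ever), and optionally
#'   `ledger`.
#' @export
simulate_arm <- function(cohort, arm, params, master_seed, keep_ledger = FALSE) {
  arm <- match.arg(arm, c("intervention", "usual_care"))
  simulate_core(cohort, arm, params, master_seed, keep_ledger = keep_ledger)
}

#' Simulate a single individual
#'
#' Convenience wrapper around the engine for one woman; returns her full
#' cycle ledger and event log.
#'
#' @param individual A one-row cohort data frame (fields as in
#'   [sample_cohort()]; an `id` column is required for the random stream).
#' @param arm `"intervention"` or `"usual_care"`.
#' @param params A `cvd_config`.
#' @param master_seed Integer master seed.
#' @return A list with `ledger`, `events` and `totals` (one row).
#' @export
simulate_individual <- function(individual, arm, params, master_seed) {
  stopifnot(nrow(individual) == 1)
  res <- simulate_arm(individual, arm, params, master_seed, keep_ledger = TRUE)
  list(ledger = res$ledger, events = res$events, totals = res$totals)
}

# One paired run: generate the uniform streams once, reuse for both arms.
run_paired <- function(cohort, cfg, master_seed, keep_ledger = FALSE) {
  K <- as.integer(cfg$run$age_cap - min(cohort$age))
  U <- rng_streams(master_seed, cohort$id, K)
  list(intervention = simulate_core(cohort, "intervention", cfg, master_seed, U, keep_ledger),
       usual_care = simulate_core(cohort, "usual_care", cfg, master_seed, U, keep_ledger))
}

subtype_levels <- c("MI", "UA", "ischaemic_stroke", "haemorrhagic_stroke", "TIA",
                    "PVD", "CHF", "other_CHD", "other_CVD_death",
                    "nonfatal_stroke", "nonfatal_MI", "cvd_death")

#' Tabulate event counts by subtype, scaled per 10,000 women
#'
#' @param events Event log from [simulate_arm()].
#' @param n_individuals Cohort size the log came from.
#' @return Data frame with `subtype`, `first_ever`, `count`, `per_10000`;
#'   totals over subtypes equal the sums of the rows (conservation).
#' @export
count_events <- function(events, n_individuals) {
  stopifnot(n_individuals > 0)
  grid <- expand.grid(subtype = subtype_levels, first_ever = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  cnt <- integer(nrow(grid))
  if (nrow(events)) {
    key <- paste(events$subtype, events$first_ever)
    tab <- table(key)
    m <- match(paste(grid$subtype, grid$first_ever), names(tab))
    cnt <- ifelse(is.na(m), 0L, as.integer(tab[m]))
  }
  out <- data.frame(grid, count = cnt, per_10000 = 10000 * cnt / n_individuals)
  out[out$count > 0 | (out$first_ever & out$subtype %in% subtype_levels[1:9]) |
        (!out$first_ever & out$subtype %in% subtype_levels[10:12]), ]
}

#' Mean age at the first-ever CVD event
#'
#' @param events Event log from [simulate_arm()].
#' @return Arithmetic mean of the age at first-ever events, or `NA` when the
#'   log contains none.
#' @export
mean_age_first_event <- function(events) {
  f <- events$age_at_event[events$first_ever]
  if (!length(f)) return(NA_real_)
  mean(f)
}
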