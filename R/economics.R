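# Health-economic rules: per-cycle utilities and costs, discounted totals,
# incremental cost-effectiveness ratios.

#' Health-state utility weight for one cycle
#'
#' CVD-free individuals carry the general female population age-band utility.
#' After one event the weight is the minimum of the age-band value and the
#' post-event utility of that subtype (post-ischaemic-stroke is the
#' mRS-weighted composite; unstable angina has no listed decrement and keeps
#' the age-band value). After two or more events the flat post-CVD utility
#' applies, again through the minimum rule. Ages beyond the oldest band clamp
#' to it.
#'
#' @param state List or one-row data frame with `age`, `n_events` (prior CVD
#'   events) and `last_subtype` (most recent event subtype, `NA` if none).
#' @param econ The `economics` section of a `cvd_config`.
#' @return Utility weight in `[0, 1]`.
#' @export
cycle_utility <- function(state, econ) {
  ep <- econ_precompute(list(economics = econ))
  n_events <- if (is.null(state$n_events)) 0L else as.integer(state$n_events)
  last <- if (is.null(state$last_subtype)) NA_character_ else as.character(state$last_subtype)
  state_utility_vec(as.numeric(state$age), n_events, last, ep)
}

#' Cost accrued in one cycle
#'
#' Adherent, CVD-free intervention cycles carry the annual program cost; the
#' cycle of an event carries the subtype's acute hospitalisation cost (and no
#' program cost: delivery stops at the de novo event); every later
#' non-event cycle carries the annual management cost of the most recent
#' subtype.
#'
#' @param state List with `on_intervention` (flag), `event_subtype` (subtype
#'   of an event occurring this cycle, or `NA`), `n_events` (events before
#'   this cycle) and `last_subtype` (most recent prior subtype).
#' @param econ The `economics` section of a `cvd_config`.
#' @return Total cost for the cycle, AUD.
#' @export
cycle_cost <- function(state, econ) {
  ep <- econ_precompute(list(economics = econ))
  ev_sub <- if (is.null(state$event_subtype)) NA_character_ else state$event_subtype
  n_events <- if (is.null(state$n_events)) 0L else as.integer(state$n_events)
  cost <- 0
  if (!is.na(ev_sub)) {
    ac <- unname(ep$acute[ev_sub])
    if (is.na(ac)) stop("unknown event subtype: ", ev_sub)
    cost <- cost + ac
  } else {
    if (isTRUE(state$on_intervention)) cost <- cost + ep$c_int
    if (n_events > 0) {
      key <- if (ep$mgmt_post_recurrent == "postCVD" && n_events >= 2) "postCVD" else state$last_subtype
      mg <- unname(ep$mgmt[key])
      if (is.na(mg)) stop("unknown management subtype: ", key)
      cost <- cost + mg
    }
  }
  cost
}

#' Discounted totals from a cycle ledger
#'
#' Applies mid-cycle discounting `(1+r)^-(cycle+0.5)` to every cost and
#' utility-weighted life-year increment. With `r = 0` this reproduces the
#' plain sums exactly.
#'
#' @param ledger Cycle ledger (from [simulate_individual()] or built by
#'   hand) with columns `cycle`, `cost_intervention`, `cost_acute`,
#'   `cost_mgmt`, `utility`, `ly`.
#' @param r Annual discount rate.
#' @return A list with `cost`, `qaly`, `ly`.
#' @export
discounted_totals <- function(ledger, r) {
  stopifnot(r >= 0, r < 1)
  df <- (1 + r)^(-(ledger$cycle + 0.5))
  cost <- sum((ledger$cost_intervention + ledger$cost_acute + ledger$cost_mgmt) * df)
  list(cost = cost, qaly = sum(ledger$utility * ledger$ly * df), ly = sum(ledger$ly * df))
}

icer_quadrant <- function(d_cost, d_eff) {
  if (d_eff > 0 && d_cost > 0) "trade-off"
  else if (d_eff > 0 && d_cost <= 0) "dominant"
  else if (d_eff <= 0 && d_cost >= 0) "dominated"
  else "trade-off (southwest)"
}

#' Incremental cost-effectiveness of intervention vs usual care
#'
#' Per-person totals are averaged over each (paired) cohort before
#' differencing. The ICER is reported only in the trade-off quadrant
#' (both increments strictly positive); otherwise it is `NA` and the
#' dominance label carries the interpretation.
#'
#' @param totals_int,totals_uc Per-individual totals from [simulate_arm()]
#'   for the intervention and usual-care arms (same cohort size).
#' @param wtp Willingness-to-pay threshold, AUD per QALY.
#' @return A list of class `icer_summary`: per-arm means, increments,
#'   `icer_qaly`, `icer_ly`, dominance label, and the net monetary benefit at
#'   `wtp`.
#' @export
compute_icer <- function(totals_int, totals_uc, wtp = 50000) {
  stopifnot(nrow(totals_int) == nrow(totals_uc))
  arm_mean <- function(x) list(
    cost = mean(x$cost), qaly = mean(x$qaly), ly = mean(x$ly),
    cost_intervention = mean(x$cost_intervention),
    cost_acute = mean(x$cost_acute), cost_mgmt = mean(x$cost_mgmt))
  a <- arm_mean(totals_int); b <- arm_mean(totals_uc)
  d_cost <- a$cost - b$cost
  d_qaly <- a$qaly - b$qaly
  d_ly <- a$ly - b$ly
  quad <- icer_quadrant(d_cost, d_qaly)
  icer_q <- if (d_cost > 0 && d_qaly > 0) d_cost / d_qaly else NA_real_
  icer_l <- if (d_cost > 0 && d_ly > 0) d_cost / d_ly else NA_real_
  structure(list(
    arms = list(intervention = a, usual_care = b),
    increments = list(cost = d_cost, qaly = d_qaly, ly = d_ly,
                      cost_intervention = a$cost_intervention - b$cost_intervention,
                      cost_acute = a$cost_acute - b$cost_acute,
                      cost_mgmt = a$cost_mgmt - b$cost_mgmt),
    icer_qaly = icer_q, icer_ly = icer_l, dominance = quad,
    wtp = wtp, nmb = wtp * d_qaly - d_cost,
    cost_effective = (wtp * d_qaly - d_cost) >= 0
  ), class = "icer_summary")
}

#' @export
print.icer_summary <- function(x, ...) {
  cat("Incremental cost-effectiveness (intervention vs usual care)\n")
  cat(sprintf("  incremental cost:  $%.2f\n", x$increments$cost))
  cat(sprintf("  incremental QALY:  %.5f    incremental LY: %.5f\n",
              x$increments$qaly, x$increments$ly))
  if (!is.na(x$icer_qaly))
    cat(sprintf("  ICER: $%s/QALY, $%s/LY\n",
                format(round(x$icer_qaly), big.mark = ","),
                format(round(x$icer_ly), big.mark = ",")))
  cat(sprintf("  quadrant: %s; %scost-effective at WTP $%s/QALY\n", x$dominance,
              if (x$cost_effective) "" else "NOT ", format(x$wtp, big.mark = ",")))
  invisible(x)
}
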