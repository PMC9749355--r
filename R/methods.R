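# S3 methods for result objects, plus tabular/JSON writers.

fmt_money <- function(x, digits = 0) paste0("$", format(round(x, digits), big.mark = ",", trim = TRUE))

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Cost-effectiveness analysis (%s), n = %s women per arm\n",
              x$label, format(x$n_individuals, big.mark = ",")))
  a <- x$arms$intervention; b <- x$arms$usual_care
  row <- function(lab, va, vb, f = function(z) sprintf("%.3f", z))
    cat(sprintf("  %-28s %12s %12s %12s\n", lab, f(va), f(vb), f(va - vb)))
  cat(sprintf("  %-28s %12s %12s %12s\n", "", "lifestyle", "usual care", "difference"))
  row("Total cost", a$cost, b$cost, fmt_money)
  row("QALY", a$qaly, b$qaly)
  row("LY", a$ly, b$ly)
  row("Cost of intervention", a$cost_intervention, b$cost_intervention, fmt_money)
  row("Cost of hospitalisation", a$cost_acute, b$cost_acute, fmt_money)
  row("Cost of CVD management", a$cost_mgmt, b$cost_mgmt, fmt_money)
  row("First-ever CVD /10,000", x$first_ever_per_10000[["intervention"]],
      x$first_ever_per_10000[["usual_care"]], function(z) sprintf("%.0f", z))
  row("Recurrent CVD /10,000", x$recurrent_per_10000[["intervention"]],
      x$recurrent_per_10000[["usual_care"]], function(z) sprintf("%.0f", z))
  if (!is.na(x$icer_qaly))
    cat(sprintf("  ICER: %s/QALY, %s/LY\n", fmt_money(x$icer_qaly), fmt_money(x$icer_ly)))
  cat(sprintf("  %s; %scost-effective at WTP %s/QALY\n", x$dominance,
              if (x$cost_effective) "" else "NOT ", fmt_money(x$wtp)))
  invisible(x)
}

#' @export
summary.cea_result <- function(object, ...) {
  out <- data.frame(
    quantity = c("total_cost", "qaly", "ly", "cost_intervention", "cost_acute",
                 "cost_mgmt", "first_ever_per_10000", "recurrent_per_10000",
                 "mean_age_first_event"),
    intervention = c(object$arms$intervention$cost, object$arms$intervention$qaly,
                     object$arms$intervention$ly, object$arms$intervention$cost_intervention,
                     object$arms$intervention$cost_acute, object$arms$intervention$cost_mgmt,
                     object$first_ever_per_10000[["intervention"]],
                     object$recurrent_per_10000[["intervention"]],
                     object$mean_age_first_event[["intervention"]]),
    usual_care = c(object$arms$usual_care$cost, object$arms$usual_care$qaly,
                   object$arms$usual_care$ly, object$arms$usual_care$cost_intervention,
                   object$arms$usual_care$cost_acute, object$arms$usual_care$cost_mgmt,
                   object$first_ever_per_10000[["usual_care"]],
                   object$recurrent_per_10000[["usual_care"]],
                   object$mean_age_first_event[["usual_care"]]))
  out$difference <- out$intervention - out$usual_care
  attr(out, "icer_qaly") <- object$icer_qaly
  attr(out, "icer_ly") <- object$icer_ly
  out
}

#' Write an analysis result to disk
#'
#' `cea_result` objects go to JSON (full machine-readable structure) or CSV
#' (a presentation table mirroring the base-case layout: totals, QALYs, LYs,
#' cost components and per-10,000 event counts, at full precision with a
#' rounded display column). Data frames (tornado tables, PSA draws, CEAC) go
#' to CSV with a deterministic column order; `budget_result` and `cvd_psa`
#' objects go to JSON.
#'
#' @param result A `cea_result`, `cvd_dsa`, `cvd_psa`, `budget_result` or
#'   plain data frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (inherits(result, "cea_result")) {
    if (format == "json") {
      jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
    } else {
      s <- summary(result)
      s$display <- ifelse(s$quantity %in% c("qaly", "ly", "mean_age_first_event"),
                          sprintf("%.3f", s$difference), sprintf("%.0f", s$difference))
      utils::write.csv(s[, c("quantity", "intervention", "usual_care", "difference", "display")],
                       path, row.names = FALSE)
    }
  } else if (inherits(result, "cvd_psa")) {
    if (format == "json") {
      jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else {
      utils::write.csv(result$draws, path, row.names = FALSE)
    }
  } else if (inherits(result, "budget_result")) {
    jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (is.data.frame(result)) {
    if (format == "json") {
      jsonlite::write_json(result, path, digits = NA, pretty = TRUE)
    } else {
      utils::write.csv(as.data.frame(result), path, row.names = FALSE)
    }
  } else {
    jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @export
print.cvd_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d draws, inner cohort %d\n",
              nrow(x$draws), x$inner_n))
  cat(sprintf("  mean incremental cost $%.0f, mean incremental QALY %.5f\n",
              mean(x$draws$d_cost), mean(x$draws$d_qaly)))
  cat(sprintf("  probability cost-effective at WTP %s/QALY: %.1f%%\n",
              fmt_money(x$wtp), 100 * x$prob_ce_at_wtp))
  invisible(x)
}

#' Plot a PSA result: cost-effectiveness plane or acceptability curve
#'
#' @param x A `cvd_psa` object.
#' @param type `"plane"` (incremental QALY vs incremental cost scatter with
#'   the WTP ray) or `"ceac"`.
#' @param ... Passed to the base plotting call.
#' @export
plot.cvd_psa <- function(x, type = c("plane", "ceac"), ...) {
  type <- match.arg(type)
  if (type == "plane") {
    plot(x$draws$d_qaly, x$draws$d_cost, pch = 16, cex = 0.5,
         col = ifelse(x$draws$cost_effective, "forestgreen", "grey40"),
         xlab = "Incremental QALYs", ylab = "Incremental cost (AUD)",
         main = "Cost-effectiveness plane", ...)
    abline(h = 0, v = 0, col = "grey70")
    abline(a = 0, b = x$wtp, lty = 2, col = "firebrick")
  } else {
    plot(x$ceac$wtp, x$ceac$prob_ce, type = "l", lwd = 2, ylim = c(0, 1),
         xlab = "Willingness to pay (AUD/QALY)", ylab = "Probability cost-effective",
         main = "Cost-effectiveness acceptability curve", ...)
    abline(v = x$wtp, lty = 2, col = "grey60")
  }
  invisible(x)
}

#' Tornado diagram for a one-way sensitivity analysis
#'
#' @param x A `cvd_dsa` object from [run_dsa()].
#' @param ... Passed to `barplot`.
#' @export
plot.cvd_dsa <- function(x, ...) {
  x <- x[order(x$span), ]
  lo <- x$icer_low - x$icer_base
  hi <- x$icer_high - x$icer_base
  rng <- range(c(lo, hi), na.rm = TRUE)
  old <- graphics::par(mar = c(5, 11, 3, 2)); on.exit(graphics::par(old))
  graphics::plot(NULL, xlim = rng, ylim = c(0.5, nrow(x) + 0.5), yaxt = "n",
                 xlab = "Change in ICER vs base (AUD/QALY)", ylab = "",
                 main = "One-way sensitivity (tornado)", ...)
  for (i in seq_len(nrow(x))) {
    graphics::rect(min(lo[i], 0), i - 0.35, max(lo[i], 0), i + 0.35, col = "steelblue")
    graphics::rect(min(hi[i], 0), i - 0.35, max(hi[i], 0), i + 0.35, col = "indianred")
  }
  graphics::axis(2, at = seq_len(nrow(x)), labels = x$parameter, las = 1, cex.axis = 0.8)
  graphics::abline(v = 0)
  invisible(x)
}

#' Export an event log to CSV
#' @param events Event log from [simulate_arm()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  utils::write.csv(events[, c("id", "cycle", "age_at_event", "subtype", "fatal", "first_ever")],
                   path, row.names = FALSE)
  invisible(path)
}
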