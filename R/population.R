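# Synthetic baseline cohort: women aged 30-54 drawn from survey-style marginal
# distributions conditioned on age band, plus the deterministic risk-factor
# drift applied at each annual cycle.

band_lookup <- function(bands, age, field) {
  lo <- vapply(bands, `[[`, 0, "age_lo")
  hi <- vapply(bands, `[[`, 0, "age_hi")
  idx <- findInterval(age, lo)
  if (any(idx < 1) || any(age > hi[idx]))
    cfg_error("age ", paste(age[idx < 1 | age > hi[pmax(idx, 1)]][1]),
              " outside configured band coverage")
  vapply(bands, `[[`, 0, field)[idx]
}

band_index <- function(bands, age) {
  lo <- vapply(bands, `[[`, 0, "age_lo")
  hi <- vapply(bands, `[[`, 0, "age_hi")
  idx <- findInterval(age, lo)
  if (any(idx < 1) || any(age > hi[idx]))
    cfg_error("marginals missing an age band covering age ", age[which(idx < 1 | age > hi[pmax(idx, 1)])[1]])
  idx
}

#' Draw the baseline cohort from configured marginal distributions
#'
#' Each woman is sampled independently: an integer age from the configured age
#' bands; IRSD quintile, smoking status, diabetes, survey SBP band, and
#' normally distributed total and HDL cholesterol (truncated at physiologic
#' floors) conditional on her age band. SBP is the band midpoint, with uniform
#' within-band jitter when `run$sbp_jitter` is on.
#'
#' @param population The `population` section of a `cvd_config`.
#' @param n Number of individuals (`n = 0` gives an empty cohort).
#' @param seed Integer seed; draws are fully reproducible.
#' @param sbp_jitter Jitter SBP uniformly within its survey band (default) or
#'   use the band midpoint.
#' @return A data frame with one row per individual: `id`, `age`,
#'   `ses_quintile`, `smoking` (never/ex/current), `diabetes`, `sbp`, `tc`,
#'   `hdl`.
#' @examples
#' cfg <- load_config()
#' head(sample_cohort(cfg$population, 5, seed = 1))
#' @export
sample_cohort <- function(population, n, seed, sbp_jitter = TRUE) {
  stopifnot(n >= 0)
  n <- as.integer(n)
  if (n == 0) {
    return(data.frame(id = integer(), age = numeric(), ses_quintile = integer(),
                      smoking = character(), diabetes = logical(),
                      sbp = numeric(), tc = numeric(), hdl = numeric()))
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  ab <- population$age_bands
  mass <- vapply(ab, `[[`, 0, "mass")
  keep <- which(mass > 0)   # sample.int avoids the scalar-`sample()` pitfall
  bi <- keep[sample.int(length(keep), n, replace = TRUE, prob = mass[keep])]
  lo <- vapply(ab, `[[`, 0, "age_lo")[bi]
  hi <- vapply(ab, `[[`, 0, "age_hi")[bi]
  age <- lo + floor(runif(n) * (hi - lo + 1))

  ses <- sample.int(5L, n, replace = TRUE, prob = as.numeric(population$ses_quintile))

  smk_i <- band_index(population$smoking_by_age, age)
  smoking <- character(n)
  for (j in unique(smk_i)) {
    b <- population$smoking_by_age[[j]]
    sel <- smk_i == j
    smoking[sel] <- sample(c("current", "ex", "never"), sum(sel), replace = TRUE,
                           prob = c(b$current, b$ex, b$never))
  }

  dia_p <- band_lookup(population$diabetes_by_age, age, "prevalence")
  diabetes <- runif(n) < dia_p

  sbp_lo <- vapply(population$sbp_bands, `[[`, 0, "lo")
  sbp_hi <- vapply(population$sbp_bands, `[[`, 0, "hi")
  sbp_i <- band_index(population$sbp_band_masses_by_age, age)
  sbp <- numeric(n)
  for (j in unique(sbp_i)) {
    m <- as.numeric(population$sbp_band_masses_by_age[[j]]$masses)
    sel <- which(sbp_i == j)
    pos <- which(m > 0)
    bk <- pos[sample.int(length(pos), length(sel), replace = TRUE, prob = m[pos])]
    sbp[sel] <- if (sbp_jitter) runif(length(sel), sbp_lo[bk], sbp_hi[bk])
                else (sbp_lo[bk] + sbp_hi[bk]) / 2
  }

  rnorm_floor <- function(mean, sd, floor) {
    x <- rnorm(length(mean), mean, sd)
    while (any(bad <- x < floor)) x[bad] <- rnorm(sum(bad), mean[bad], sd[bad])
    x
  }
  tc <- rnorm_floor(band_lookup(population$tc_by_age, age, "mean"),
                    band_lookup(population$tc_by_age, age, "sd"), population$tc_floor)
  hdl <- rnorm_floor(band_lookup(population$hdl_by_age, age, "mean"),
                     band_lookup(population$hdl_by_age, age, "sd"), population$hdl_floor)

  data.frame(id = seq_len(n), age = as.numeric(age), ses_quintile = as.integer(ses),
             smoking = smoking, diabetes = diabetes, sbp = sbp, tc = tc, hdl = hdl)
}

increment_at <- function(bands, age) {
  lo <- vapply(bands, `[[`, 0, "age_lo")
  hi <- vapply(bands, `[[`, 0, "age_hi")
  inc <- vapply(bands, `[[`, 0, "increment")
  idx <- findInterval(age, lo)
  out <- numeric(length(age))
  ok <- idx >= 1 & age <= hi[pmax(idx, 1)]
  out[ok] <- inc[idx[ok]]
  out  # zero drift outside configured coverage
}

#' Advance one individual by one model cycle
#'
#' Ages the individual by one year and applies the configured annual
#' systolic-blood-pressure and lipid drifts for the new age. Deterministic.
#'
#' @param individual A one-row cohort data frame (or list) with fields `age`,
#'   `sbp`, `tc`, `hdl`.
#' @param population The `population` section of a `cvd_config` (holds the
#'   age-banded annual increments).
#' @return The updated individual.
#' @export
age_update <- function(individual, population) {
  individual$age <- individual$age + 1
  individual$sbp <- individual$sbp + increment_at(population$sbp_annual_increment_by_age, individual$age)
  individual$tc  <- individual$tc  + increment_at(population$tc_annual_increment_by_age, individual$age)
  individual$hdl <- individual$hdl + increment_at(population$hdl_annual_increment_by_age, individual$age)
  individual
}

#' Restrict the baseline age distribution to a band
#'
#' Used by the subgroup analyses: masses outside `[lo, hi)` are zeroed (bands
#' straddling an edge are clipped, their mass scaled by the retained fraction
#' of years) and the remainder renormalised. Conditional tables are untouched.
#'
#' @param population The `population` section of a `cvd_config`.
#' @param lo,hi Age bounds in years; `[lo, hi)` must overlap `[30, 55)`.
#' @return A modified `population` list.
#' @export
restrict_to_age_band <- function(population, lo, hi) {
  if (hi <= lo) cfg_error("empty age range [", lo, ", ", hi, ")")
  bands <- population$age_bands
  new <- list()
  for (b in bands) {
    keep_lo <- max(b$age_lo, lo)
    keep_hi <- min(b$age_hi, hi - 1)          # bands are inclusive in years
    if (keep_lo > keep_hi) next
    frac <- (keep_hi - keep_lo + 1) / (b$age_hi - b$age_lo + 1)
    new[[length(new) + 1]] <- list(age_lo = keep_lo, age_hi = keep_hi, mass = b$mass * frac)
  }
  if (!length(new)) cfg_error("age range [", lo, ", ", hi, ") does not overlap the configured bands")
  tot <- sum(vapply(new, `[[`, 0, "mass"))
  if (tot <= 0) cfg_error("age range [", lo, ", ", hi, ") carries zero mass")
  for (i in seq_along(new)) new[[i]]$mass <- new[[i]]$mass / tot
  population$age_bands <- new
  population
}

#' Write a cohort to CSV for fixture reuse
#'
#' @param cohort A cohort data frame from [sample_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#' @param path CSV file path.
#' @return A cohort data frame.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$diabetes <- as.logical(x$diabetes)
  x
}
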