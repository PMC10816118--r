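AGE_BANDS <- paste(seq(40, 85, 5), seq(44, 89, 5), sep = "-")
BAND_START <- seq(40L, 85L, 5L)

#' European standard population weights, 40-89
#'
#' The 1976 and 2013 European Standard Population age weights truncated to
#' the ten 5-year bands 40-44 ... 85-89 and renormalized to sum to 1
#' (the 1976 table's open-ended 85+ weight stands in for 85-89). For
#' age-sex standardization each sex gets half the age weight.
#'
#' @param which `"esp2013"` (default) or `"esp1976"`.
#' @return data frame: `age_band`, `weight` (normalized).
#' @export
std_population <- function(which = c("esp2013", "esp1976")) {
  which <- match.arg(which)
  w <- switch(which,
    esp2013 = c(7000, 7000, 7000, 6500, 6000, 5500, 5000, 4000, 2500, 1500),
    esp1976 = c(7000, 7000, 7000, 6000, 5000, 4000, 3000, 2000, 1000, 1000))
  data.frame(age_band = AGE_BANDS, weight = w / sum(w),
             stringsAsFactors = FALSE)
}

#' Split follow-up into person-time by age band and sex
#'
#' Each patient's eligibility window is cut exactly at their 5-year-band
#' birthdays (completed age at each day of follow-up), so total person-time
#' is conserved to the day. Optionally also split by calendar year.
#'
#' @param windows eligibility windows (`patient_id`, `entry_date`,
#'   `exit_date`, `sex`, `birth_date`).
#' @param by_year also split at 1 January boundaries.
#' @return data frame: `age_band`, `sex`, (`year`,) `person_years`
#'   (days / 365.25).
#' @export
person_time <- function(windows, by_year = FALSE) {
  segs <- list()
  for (b in seq_along(BAND_START)) {
    lo_age <- BAND_START[b]
    band_lo <- add_years(windows$birth_date, lo_age)
    band_hi <- add_years(windows$birth_date, lo_age + 5L)  # exclusive
    s <- pmax(windows$entry_date, band_lo)
    e <- pmin(windows$exit_date + 1L, band_hi)             # half-open [s, e)
    keep <- which(as.numeric(e - s) > 0)
    if (!length(keep)) next
    segs[[b]] <- data.frame(patient_id = windows$patient_id[keep],
                            sex = windows$sex[keep],
                            age_band = AGE_BANDS[b],
                            start = s[keep], end = e[keep],
                            stringsAsFactors = FALSE)
  }
  seg <- do.call(rbind, segs)
  if (is.null(seg))
    return(data.frame(age_band = character(), sex = character(),
                      person_years = numeric()))
  if (by_year) {
    pieces <- lapply(seq_len(nrow(seg)), function(i) {
      y0 <- as.integer(format(seg$start[i], "%Y"))
      y1 <- as.integer(format(seg$end[i] - 1L, "%Y"))
      yrs <- y0:y1
      s <- pmax(seg$start[i], as.Date(paste0(yrs, "-01-01")))
      e <- pmin(seg$end[i], as.Date(paste0(yrs + 1L, "-01-01")))
      data.frame(age_band = seg$age_band[i], sex = seg$sex[i], year = yrs,
                 days = as.numeric(e - s), stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, pieces)
    out <- stats::aggregate(days ~ age_band + sex + year, df, sum)
  } else {
    seg$days <- as.numeric(seg$end - seg$start)
    out <- stats::aggregate(days ~ age_band + sex, seg, sum)
  }
  out$person_years <- out$days / 365.25
  out$days <- NULL
  out
}

# completed age in years at a given date (exact birthday arithmetic)
completed_age <- function(date, birth_date) {
  age <- as.integer(format(date, "%Y")) - as.integer(format(birth_date, "%Y"))
  not_yet <- add_years(birth_date, age) > date
  age - as.integer(not_yet)
}

# age band of each case at its index date
case_age_band <- function(index_date, birth_date) {
  age <- completed_age(index_date, birth_date)
  band <- findInterval(age, c(BAND_START, 90L))
  ifelse(band >= 1 & band <= length(AGE_BANDS), AGE_BANDS[band],
         NA_character_)
}

#' Count incident events by age band and sex
#'
#' @param cases case table with `patient_id`, `index_date`; joined against
#'   `windows` for sex and birth date. Age is completed years at the index
#'   date.
#' @param windows eligibility windows.
#' @return data frame `age_band`, `sex`, `events`.
#' @export
events_by_band <- function(cases, windows) {
  m <- merge(cases, windows[c("patient_id", "sex", "birth_date")],
             by = "patient_id")
  empty <- data.frame(age_band = character(), sex = character(),
                      events = integer(), stringsAsFactors = FALSE)
  if (!nrow(m)) return(empty)
  m$age_band <- case_age_band(m$index_date, m$birth_date)
  m <- m[!is.na(m$age_band), , drop = FALSE]
  if (!nrow(m)) return(empty)
  stats::aggregate(list(events = rep(1L, nrow(m))),
                   m[c("age_band", "sex")], sum)
}

#' Crude and direct age-sex standardized incidence rate
#'
#' Crude rate = total events / total person-time. The standardized rate is
#' `SIR = sum_b w_b * (events_b / pt_b)` per `per` person-years, with the
#' standard-population age weights applied within each sex and the sexes
#' weighted `sex_weights` (default 0.5/0.5). The default CI uses the
#' normal approximation with `var = sum(w_b^2 * events_b / pt_b^2)`
#' (Poisson event counts); `ci_method = "gamma"` gives the exact-Poisson
#' (Fay-Feuer) alternative. Bands with weight but no person-time are
#' dropped and the weights renormalized, with a warning.
#'
#' @param events data frame `age_band`, `sex`, `events` (see
#'   [events_by_band()]).
#' @param pt person-time table from [person_time()].
#' @param std_pop standard population from [std_population()].
#' @param per rate denominator (default 100000 person-years).
#' @param sex_weights named weights for `male`, `female`; use e.g.
#'   `c(male = 1)` for a single-sex rate.
#' @param ci_method `"normal"` or `"gamma"`.
#' @param conf confidence level.
#' @return one-row data frame: `events`, `person_years`, `crude_rate`,
#'   `sir`, `ci_low`, `ci_high` (rates per `per`).
#' @export
standardized_rate <- function(events, pt, std_pop = std_population(),
                              per = 1e5,
                              sex_weights = c(male = 0.5, female = 0.5),
                              ci_method = c("normal", "gamma"),
                              conf = 0.95) {
  ci_method <- match.arg(ci_method)
  grid <- expand.grid(age_band = std_pop$age_band,
                      sex = names(sex_weights),
                      stringsAsFactors = FALSE)
  grid <- merge(grid, std_pop, by = "age_band")
  grid$weight <- grid$weight * sex_weights[grid$sex]
  grid <- merge(grid, pt, by = c("age_band", "sex"), all.x = TRUE)
  grid <- merge(grid, events, by = c("age_band", "sex"), all.x = TRUE)
  grid$person_years[is.na(grid$person_years)] <- 0
  grid$events[is.na(grid$events)] <- 0
  empty <- grid$person_years <= 0 & grid$weight > 0
  if (any(empty)) {
    warn_digephen("%d standard-population cell(s) have no person-time; %s",
                  sum(empty), "weights renormalized over the rest")
    grid <- grid[!empty, , drop = FALSE]
  }
  grid$weight <- grid$weight / sum(grid$weight)
  rate_b <- ifelse(grid$person_years > 0,
                   grid$events / grid$person_years, 0)
  sir <- sum(grid$weight * rate_b) * per
  var_sir <- sum(grid$weight^2 * grid$events /
                   pmax(grid$person_years, .Machine$double.eps)^2) * per^2
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (ci_method == "normal") {
    ci <- c(max(sir - z * sqrt(var_sir), 0), sir + z * sqrt(var_sir))
  } else {
    # Fay-Feuer gamma interval for directly standardized rates
    x <- sum(grid$events)
    wm <- max(grid$weight / pmax(grid$person_years,
                                 .Machine$double.eps)) * per
    mu <- sir
    v <- var_sir
    lo <- if (mu <= 0) 0 else
      v / (2 * mu) * stats::qchisq((1 - conf) / 2, 2 * mu^2 / v)
    hi <- (v + wm^2) / (2 * (mu + wm)) *
      stats::qchisq(1 - (1 - conf) / 2, 2 * (mu + wm)^2 / (v + wm^2))
    ci <- c(lo, hi)
  }
  tot_ev <- sum(grid$events)
  tot_pt <- sum(grid$person_years)
  data.frame(events = tot_ev, person_years = tot_pt,
             crude_rate = tot_ev / tot_pt * per, sir = sir,
             ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
}

#' Per-cancer rate table
#'
#' Convenience wrapper: one [standardized_rate()] row per cancer type
#' (plus an `all_digestive` row) from a case table and eligibility windows.
#'
#' @param cases case table from [find_cases()].
#' @param windows eligibility windows.
#' @inheritParams standardized_rate
#' @return RateTable data frame with a `cancer_type` column.
#' @export
rate_table <- function(cases, windows, std_pop = std_population(),
                       per = 1e5, ci_method = "normal") {
  pt <- person_time(windows)
  types <- c(as.list(intersect(CANCER_TYPES, unique(cases$cancer_type))),
             list("all_digestive"))
  rows <- lapply(types, function(ct) {
    sub <- if (identical(ct, "all_digestive")) cases
    else cases[cases$cancer_type == ct, , drop = FALSE]
    ev <- events_by_band(sub, windows)
    r <- standardized_rate(ev, pt, std_pop, per, ci_method = ci_method)
    cbind(cancer_type = ct, r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
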