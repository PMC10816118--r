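one_window <- function(entry, exit, birth, sex = "male") {
  data.frame(patient_id = "P1", entry_date = as.Date(entry),
             exit_date = as.Date(exit), sex = sex,
             birth_date = as.Date(birth), stringsAsFactors = FALSE)
}

test_that("person-time lands wholly in one band when no boundary is crossed", {
  # followed 2011-06-15..2012-06-14 inclusive, aged 61-62: all in 60-64
  w <- one_window("2011-06-15", "2012-06-13", "1950-01-01")
  pt <- person_time(w)
  expect_equal(nrow(pt), 1)
  expect_equal(pt$age_band, "60-64")
  expect_equal(pt$person_years, 365 / 365.25)
})

test_that("band-crossing windows split exactly and conserve total time", {
  # crosses the 65th birthday (2015-01-01) mid-window
  w <- one_window("2014-07-01", "2015-06-30", "1950-01-01")
  pt <- person_time(w)
  expect_setequal(pt$age_band, c("60-64", "65-69"))
  total <- as.numeric(as.Date("2015-06-30") - as.Date("2014-07-01")) + 1
  expect_equal(sum(pt$person_years) * 365.25, total)
  expect_equal(pt$person_years[pt$age_band == "60-64"] * 365.25,
               as.numeric(as.Date("2015-01-01") - as.Date("2014-07-01")))
})

test_that("person-time equals a day-by-day accumulator on a synthetic cohort", {
  gen <- generate_cohort(synth_config(n_patients = 40, seed = 8))
  w <- build_eligibility(gen$cohort)$windows
  # the day-level oracle builds birthdays by string substitution, which has
  # no 29 Feb in common years; skip those few patients on both sides
  w <- w[format(w$birth_date, "%m-%d") != "02-29", , drop = FALSE]
  pt <- person_time(w)
  # brute force: iterate days, classify by completed age and sex
  acc <- new.env()
  for (i in seq_len(nrow(w))) {
    days <- seq(w$entry_date[i], w$exit_date[i], by = "day")
    yrs <- as.integer(format(days, "%Y")) -
      as.integer(format(w$birth_date[i], "%Y"))
    bd <- as.Date(paste0(as.integer(format(days, "%Y")),
                         format(w$birth_date[i], "-%m-%d")))
    age <- yrs - as.integer(bd > days)
    band <- cut(age, c(seq(40, 90, 5)), right = FALSE,
                labels = paste(seq(40, 85, 5), seq(44, 89, 5), sep = "-"))
    tab <- table(band[!is.na(band)])
    for (b in names(tab)) {
      key <- paste(b, w$sex[i])
      acc[[key]] <- (acc[[key]] %||% 0) + as.numeric(tab[[b]])
    }
  }
  for (j in seq_len(nrow(pt))) {
    key <- paste(pt$age_band[j], pt$sex[j])
    expect_equal(pt$person_years[j] * 365.25, acc[[key]] %||% 0,
                 tolerance = 1e-8, info = key)
  }
})

test_that("total person-time is conserved across the band split", {
  gen <- generate_cohort(synth_config(n_patients = 300, seed = 31))
  w <- build_eligibility(gen$cohort)$windows
  pt <- person_time(w)
  # windows clipped to the 40-89 age range they were built with
  expect_equal(sum(pt$person_years) * 365.25,
               sum(as.numeric(w$exit_date - w$entry_date) + 1),
               tolerance = 1e-8)
})

test_that("SIR equals the crude rate under uniform band rates", {
  pt <- expand.grid(age_band = std_population()$age_band,
                    sex = c("male", "female"), stringsAsFactors = FALSE)
  pt$person_years <- 1000
  ev <- pt; ev$events <- 5; ev$person_years <- NULL
  r <- standardized_rate(ev, pt)
  expect_equal(r$sir, r$crude_rate)
  expect_equal(r$sir, 5 / 1000 * 1e5)
})

test_that("two-band worked example and single-band identity", {
  sp <- data.frame(age_band = c("60-64", "65-69"), weight = c(0.25, 0.75))
  pt <- data.frame(age_band = c("60-64", "65-69"), sex = "male",
                   person_years = c(1e5, 1e5))
  ev <- data.frame(age_band = c("60-64", "65-69"), sex = "male",
                   events = c(10, 30))
  r <- standardized_rate(ev, pt, sp, sex_weights = c(male = 1))
  expect_equal(r$sir, 0.25 * 10 + 0.75 * 30)

  r1 <- standardized_rate(ev[1, ], pt[1, ], sp[1, ],
                          sex_weights = c(male = 1))
  expect_equal(r1$sir, 10)
})

test_that("SIR is invariant to proportional rescaling of the weights", {
  sp <- data.frame(age_band = c("60-64", "65-69"), weight = c(1, 3))
  sp2 <- data.frame(age_band = c("60-64", "65-69"), weight = c(10, 30))
  pt <- data.frame(age_band = c("60-64", "65-69"), sex = "male",
                   person_years = c(500, 2000))
  ev <- data.frame(age_band = c("60-64", "65-69"), sex = "male",
                   events = c(4, 9))
  r1 <- standardized_rate(ev, pt, sp, sex_weights = c(male = 1))
  r2 <- standardized_rate(ev, pt, sp2, sex_weights = c(male = 1))
  expect_equal(r1$sir, r2$sir)
  expect_equal(r1$ci_low, r2$ci_low)
})

test_that("empty weighted bands are dropped with renormalization warning", {
  sp <- data.frame(age_band = c("60-64", "65-69"), weight = c(0.5, 0.5))
  pt <- data.frame(age_band = "60-64", sex = "male", person_years = 1000)
  ev <- data.frame(age_band = "60-64", sex = "male", events = 10)
  expect_warning(r <- standardized_rate(ev, pt, sp,
                                        sex_weights = c(male = 1)),
                 "renormalized")
  expect_equal(r$sir, 10 / 1000 * 1e5)
})

test_that("gamma (exact-Poisson) intervals bracket the SIR and stay positive", {
  pt <- data.frame(age_band = c("60-64", "65-69"), sex = "male",
                   person_years = c(5000, 8000))
  ev <- data.frame(age_band = c("60-64", "65-69"), sex = "male",
                   events = c(3, 7))
  sp <- data.frame(age_band = c("60-64", "65-69"), weight = c(0.4, 0.6))
  r <- standardized_rate(ev, pt, sp, sex_weights = c(male = 1),
                         ci_method = "gamma")
  expect_true(r$ci_low > 0 && r$ci_low < r$sir && r$sir < r$ci_high)
})

test_that("standard populations are normalized and band-complete", {
  for (v in c("esp2013", "esp1976")) {
    sp <- std_population(v)
    expect_equal(sum(sp$weight), 1)
    expect_equal(nrow(sp), 10)
  }
  # 2013 revision is flatter in old age than the 1976 table
  expect_gt(std_population("esp2013")$weight[10],
            std_population("esp1976")$weight[10])
})

test_that("rate_table covers every observed cancer type plus the total", {
  gen <- generate_cohort(synth_config(n_patients = 3000, seed = 12))
  el <- build_eligibility(gen$cohort)
  cs <- find_cases(gen$cohort, el$windows)
  rt <- suppressWarnings(rate_table(cs, el$windows))
  expect_true("all_digestive" %in% rt$cancer_type)
  tot <- rt[rt$cancer_type == "all_digestive", ]
  expect_equal(tot$events, nrow(cs[!is.na(
    digephen:::case_age_band(cs$index_date,
      el$windows$birth_date[match(cs$patient_id, el$windows$patient_id)])), ]))
  expect_true(all(rt$sir >= 0))
})
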