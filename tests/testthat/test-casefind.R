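test_that("eligibility entry is the latest of study start, registry+1y, 40th birthday", {
  cb <- tiny_cohort()
  el <- build_eligibility(cb)
  w <- el$windows
  # P1 registered 1999-06-01, born 1950 -> study start binds
  expect_equal(w$entry_date[w$patient_id == "P1"], as.Date("2001-01-01"))
  # P2 registered 2005-03-10 -> one-year-registry rule binds
  expect_equal(w$entry_date[w$patient_id == "P2"], as.Date("2006-03-10"))
  # P3 born 1962-02-28 -> 40th birthday binds
  expect_equal(w$entry_date[w$patient_id == "P3"], as.Date("2002-02-28"))
  # exits: registry_end / study end
  expect_equal(w$exit_date[w$patient_id == "P2"], as.Date("2018-06-30"))
  expect_equal(w$exit_date[w$patient_id == "P1"], as.Date("2019-12-31"))
})

test_that("the 90th birthday censors follow-up", {
  p <- data.frame(patient_id = "P1", sex = "male",
                  birth_date = as.Date("1920-05-10"),
                  registry_start = as.Date("1995-01-01"),
                  registry_end = as.Date("2019-12-31"),
                  stringsAsFactors = FALSE)
  cb <- new_cohort(p, empty_episodes(), empty_notes())
  w <- build_eligibility(cb)$windows
  expect_equal(w$exit_date, as.Date("2010-05-09"))
})

test_that("pre-entry cancer history excludes the patient (skin cancer exempt)", {
  ep <- episode_row("P1", "2000-05-01", field = "PH", code = "151.2")
  cb <- tiny_cohort(episodes = ep)
  el <- build_eligibility(cb)
  expect_false("P1" %in% el$windows$patient_id)
  expect_equal(unname(el$exclusions["prior_cancer"]), 1)

  # non-digestive malignancy also excludes
  ep2 <- episode_row("P1", "2000-05-01", field = "PH", code = "174.9")
  el2 <- build_eligibility(tiny_cohort(episodes = ep2))
  expect_false("P1" %in% el2$windows$patient_id)

  # non-melanoma skin cancer does not
  ep3 <- episode_row("P1", "2000-05-01", field = "PH", code = "173.3")
  el3 <- build_eligibility(tiny_cohort(episodes = ep3))
  expect_true("P1" %in% el3$windows$patient_id)
})

test_that("find_cases builds one stratified case from code + notes + support", {
  cb <- tiny_cohort(
    episodes = episode_row("P1", "2010-06-01", field = "ID", code = "153.4",
                           descriptor = "neoplasia de colon"),
    notes = note_row("P1", "2010-06-10", "adenocarcinoma de colon confirmado"),
    evidence = evidence_row("P1", "2010-07-01", "histopathology"))
  cs <- find_cases(cb, build_eligibility(cb)$windows)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$cancer_type, "colorectal")
  expect_equal(cs$index_date, as.Date("2010-06-01"))
  expect_equal(cs$detection_route, "diagnostic_code")
  expect_equal(cs$stratum, "S1_code_notes_support")
})

test_that("descriptor-only evidence yields a text_only case", {
  ep <- episode_row("P1", "2012-03-05", field = "ID", system = "ICPC_BIFAP",
                    code = "D02", descriptor = "neoplasia de esófago")
  cb <- tiny_cohort(episodes = ep)
  cs <- find_cases(cb, build_eligibility(cb)$windows)
  expect_equal(cs$detection_route, "text_only")
  expect_equal(cs$cancer_type, "esophageal")
  expect_equal(cs$stratum, "S3_code_only")
})

test_that("prevalent PH/CPL-only patterns never create a case", {
  # in-window PH record, no incident signal
  ep <- episode_row("P1", "2010-06-01", field = "PH", code = "153.4")
  cb <- tiny_cohort(episodes = ep)
  cs <- find_cases(cb, build_eligibility(cb)$windows)
  expect_equal(nrow(cs), 0)

  # CPL alone is also prevalent
  ep2 <- episode_row("P1", "2010-06-01", field = "CPL", code = "153.4")
  cs2 <- find_cases(tiny_cohort(episodes = ep2),
                    build_eligibility(tiny_cohort(episodes = ep2))$windows)
  expect_equal(nrow(cs2), 0)

  # but a hospital-discharge code is an incident signal
  ep3 <- episode_row("P1", "2010-06-01", field = "CPL",
                     system = "ICD9_HOSPITAL", code = "153.4")
  cb3 <- tiny_cohort(episodes = ep3)
  cs3 <- find_cases(cb3, build_eligibility(cb3)$windows)
  expect_equal(nrow(cs3), 1)
})

test_that("hierarchy resolves co-occurring cancers deterministically", {
  expect_equal(resolve_hierarchy(c("colorectal", "hepatobiliary"),
                                 "cáncer de recto con metástasis hepáticas"),
               "colorectal")
  expect_equal(resolve_hierarchy("gastric"), "gastric")
  # no metastasis wording: fixed rank breaks the tie
  expect_equal(resolve_hierarchy(c("pancreatic", "gastric"), ""), "gastric")
  expect_equal(resolve_hierarchy(c("hepatobiliary", "colorectal"), ""),
               "colorectal")

  # end to end: dual-coded patient with metastasis note -> one colorectal case
  cb <- tiny_cohort(
    episodes = rbind(
      episode_row("P1", "2010-06-01", code = "154.1"),
      episode_row("P1", "2010-06-05", code = "155.0")),
    notes = note_row("P1", "2010-06-03",
                     "cáncer de recto con metástasis hepáticas"))
  cs <- find_cases(cb, build_eligibility(cb)$windows)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$cancer_type, "colorectal")
})

test_that("one case per patient at the brute-force minimal date; strata partition", {
  gen <- generate_cohort(synth_config(n_patients = 3000, seed = 99))
  el <- build_eligibility(gen$cohort)
  cs <- find_cases(gen$cohort, el$windows)
  expect_false(any(duplicated(cs$patient_id)))
  expect_true(all(cs$stratum %in% c("S1_code_notes_support", "S2_code_notes",
                                    "S3_code_only")))
  expect_equal(sum(table(cs$stratum)), nrow(cs))
  # index dates inside windows
  m <- merge(cs, el$windows, by = "patient_id")
  expect_true(all(m$index_date >= m$entry_date & m$index_date <= m$exit_date))
  # brute-force minimum: no qualifying ID/hospital code evidence earlier
  ep <- merge(gen$cohort$episodes, cs[c("patient_id", "cancer_type",
                                        "index_date")], by = "patient_id")
  ep <- ep[ep$field == "ID" | ep$coding_system == "ICD9_HOSPITAL", ]
  ct <- match_codes(ep$code, ep$coding_system)
  w <- el$windows[match(ep$patient_id, el$windows$patient_id), ]
  early <- !is.na(ct) & ct == ep$cancer_type &
    ep$event_date >= w$entry_date & ep$event_date < ep$index_date
  expect_false(any(early))
})

test_that("sensitivity to planted truth and monotone response to miscoding noise", {
  base <- synth_config(n_patients = 4000, seed = 17,
                       p_false_positive_code = 0)
  noisy <- synth_config(n_patients = 4000, seed = 17,
                        p_false_positive_code = 0.02)
  ppv_of <- function(cfg) {
    gen <- generate_cohort(cfg)
    el <- build_eligibility(gen$cohort)
    cs <- find_cases(gen$cohort, el$windows)
    tr <- gen$truth[match(cs$patient_id, gen$truth$patient_id), ]
    mean(tr$true_type != "none" & !tr$is_prevalent)
  }
  p0 <- ppv_of(base); p1 <- ppv_of(noisy)
  expect_equal(p0, 1)          # no miscoding -> every case is real
  expect_lt(p1, p0)            # more miscoding noise -> lower PPV
})
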