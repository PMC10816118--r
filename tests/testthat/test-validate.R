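# small adjudication-table constructor
adj_table <- function(valid = 0, non_valid = 0, inconclusive = 0,
                      unsupported = 0) {
  n <- valid + non_valid + inconclusive + unsupported
  data.frame(case_id = if (n) paste0("c", seq_len(n)) else character(0),
             category = rep(c("valid", "non_valid", "inconclusive",
                              "unsupported"),
                            c(valid, non_valid, inconclusive, unsupported)),
             stringsAsFactors = FALSE)
}

test_that("sampling is reproducible, clipped with a warning, and phased", {
  cases <- data.frame(
    patient_id = sprintf("P%03d", 1:50), cancer_type = "gastric",
    stratum = rep(c("S1_code_notes_support", "S2_code_notes",
                    "S3_code_only"), c(40, 6, 4)),
    stringsAsFactors = FALSE)
  expect_warning(s1 <- draw_sample(cases, sampling_plan(per_group = 100),
                                   seed = 3),
                 "only 50 cases")
  expect_equal(nrow(s1$sample), 50)  # clipped to the pool
  s2 <- suppressWarnings(draw_sample(cases, sampling_plan(per_group = 100),
                                     seed = 3))
  expect_identical(s1$sample, s2$sample)
  expect_setequal(unique(s1$sample$review_phase),
                  c("consensus", "joint", "independent"))
  # pool weights recorded from the full pool, not the sample
  w <- s1$pool_weights
  expect_equal(w$pool_share[w$stratum == "S1_code_notes_support"], 0.8)
  expect_equal(sum(w$pool_share), 1)
})

test_that("sampling without replacement is uniform over the stratum", {
  cases <- data.frame(patient_id = sprintf("P%02d", 1:20),
                      cancer_type = "gastric",
                      stratum = "S1_code_notes_support",
                      stringsAsFactors = FALSE)
  plan <- sampling_plan(per_group = 10, supplemental = 0)
  counts <- integer(20)
  reps <- 400
  for (r in seq_len(reps)) {
    s <- suppressWarnings(draw_sample(cases, plan, seed = r))
    expect_false(any(duplicated(s$sample$patient_id)))
    counts[match(s$sample$patient_id, cases$patient_id)] <-
      counts[match(s$sample$patient_id, cases$patient_id)] + 1L
  }
  gof <- chisq.test(counts, p = rep(1 / 20, 20))
  expect_gt(gof$p.value, 1e-4)
})

test_that("linear weighted kappa: agreement, chance, and hand-built table", {
  cats <- c("valid", "inconclusive", "non_valid", "unsupported")
  x <- rep(cats, times = c(10, 5, 3, 2))
  expect_equal(cohen_kappa_linear(x, x, cats), 1)

  # independence with identical marginals: kappa 0 by construction
  a <- rep(cats, each = 4)
  b <- rep(cats, times = 4)
  expect_equal(cohen_kappa_linear(a, b, cats), 0)

  # frozen hand computation for a 4x4 contingency table:
  # ratings giving table t[i,j] = count of (a=i, b=j)
  tab <- matrix(c(20, 3, 1, 0,
                  2, 10, 2, 1,
                  0, 3, 8, 1,
                  1, 0, 2, 6), 4, 4, byrow = TRUE)
  a2 <- rep(rep(cats, each = 4), times = as.vector(t(tab)))
  b2 <- rep(rep(cats, times = 4), times = as.vector(t(tab)))
  # direct formula evaluation (independent arithmetic path)
  p <- tab / sum(tab)
  w <- 1 - abs(outer(1:4, 1:4, "-")) / 3
  po <- sum(w * p)
  pe <- sum(w * outer(rowSums(p), colSums(p)))
  expect_equal(cohen_kappa_linear(a2, b2, cats), (po - pe) / (1 - pe))

  expect_error(cohen_kappa_linear("valid", "valid", cats), "at least 2")
})

test_that("kappa with only two adjacent-free categories equals unweighted kappa", {
  # all disagreement concentrated in the extreme categories
  a <- rep(c("valid", "non_valid"), c(30, 20))
  b <- c(rep("valid", 25), rep("non_valid", 25))
  lin <- cohen_kappa_linear(a, b, c("valid", "non_valid"))
  # unweighted kappa by direct computation
  po <- mean(a == b)
  pe <- mean(a == "valid") * mean(b == "valid") +
    mean(a == "non_valid") * mean(b == "non_valid")
  expect_equal(lin, (po - pe) / (1 - pe))
})

test_that("ppv counts and sensitivity scenarios reproduce the count oracle", {
  expect_equal(ppv(adj_table(valid = 5, non_valid = 5))$ppv, 0.5)

  adj <- adj_table(valid = 9, inconclusive = 1, unsupported = 2)
  expect_equal(ppv(adj, unsupported_handling = "excluded")$ppv, 0.9)
  expect_equal(ppv(adj, unsupported_handling = "as_valid")$ppv, 11 / 12)
  expect_equal(ppv(adj, unsupported_handling = "as_nonvalid")$ppv, 9 / 12)

  expect_true(is.na(ppv(adj_table())$ppv))
  expect_error(ppv(data.frame(category = "weird")), "unknown adjudication")
})

test_that("scenario ordering holds on random adjudication sets", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    adj <- data.frame(case_id = seq_len(n),
                      category = sample(c("valid", "non_valid",
                                          "inconclusive", "unsupported"),
                                        n, replace = TRUE,
                                        prob = c(.6, .2, .1, .1)))
    p_ex <- ppv(adj, unsupported_handling = "excluded")$ppv
    p_av <- ppv(adj, unsupported_handling = "as_valid")$ppv
    p_an <- ppv(adj, unsupported_handling = "as_nonvalid")$ppv
    if (is.na(p_ex)) next
    expect_gte(p_av, p_ex)
    expect_gte(p_ex, p_an)
  }
})

test_that("proportion CIs: Wald reproduces printed pairs; exact handles bounds", {
  expect_equal(round(100 * proportion_ci(0.924, 760), 1), c(90.5, 94.3))
  expect_equal(round(100 * proportion_ci(0.876, 124), 1), c(81.8, 93.4))
  wald_boundary <- proportion_ci(1, 30, "wald")
  expect_equal(wald_boundary, c(1, 1))
  cp <- proportion_ci(1, 30, "clopper_pearson")
  expect_lt(cp[1], 1)
  expect_equal(cp[2], 1)
  wil <- proportion_ci(0.9, 50, "wilson")
  expect_true(wil[1] > 0.75 && wil[2] < 1)
  expect_error(proportion_ci(0.5, 10, "jeffreys"))
})

test_that("weighted mean PPV: arithmetic, invariance, and bounds", {
  st <- rbind(
    ppv(adj_table(valid = 93, non_valid = 7)),
    ppv(adj_table(valid = 34, non_valid = 4)),
    ppv(adj_table(valid = 22, non_valid = 2)))
  st$ppv <- c(0.930, 0.895, 0.917)  # point estimates under test
  wm <- weighted_mean_ppv(st, c(0.84, 0.10, 0.06))
  expect_equal(wm$ppv, 0.84 * 0.930 + 0.10 * 0.895 + 0.06 * 0.917)
  expect_equal(round(wm$ppv, 3), 0.926)
  # weighted mean stays inside the stratum range
  expect_true(wm$ppv >= min(st$ppv) && wm$ppv <= max(st$ppv))
  # single stratum: identity
  expect_equal(weighted_mean_ppv(st[1, ], 1)$ppv, st$ppv[1])
  # equal PPVs: invariant to weights
  st2 <- st; st2$ppv <- 0.9
  expect_equal(weighted_mean_ppv(st2, c(0.2, 0.3, 0.5))$ppv, 0.9)
  expect_error(weighted_mean_ppv(st, c(0.5, 0.2, 0.2)), "sum to 1")
  # delta-method alternative is finite and ordered
  wm2 <- weighted_mean_ppv(st, c(0.84, 0.10, 0.06), ci_method = "weighted")
  expect_true(wm2$ci_low <= wm2$ppv && wm2$ppv <= wm2$ci_high)
})

test_that("sex-stratified PPVs: undefined flag and pooling identity", {
  adj <- adj_table(valid = 8, non_valid = 2)
  sexes <- stats::setNames(rep("male", 10), adj$case_id)
  bysex <- ppv_by_sex(adj, sexes)
  expect_true(is.na(bysex$ppv[bysex$scope == "female"]))
  expect_equal(bysex$ppv[bysex$scope == "male"], 0.8)

  # pooled PPV is the case-count weighted average of the sex-specific PPVs
  sexes2 <- stats::setNames(rep(c("male", "female"), c(6, 4)), adj$case_id)
  bysex2 <- ppv_by_sex(adj, sexes2)
  pooled <- ppv(adj)$ppv
  n <- bysex2$n_evaluated
  expect_equal(sum(bysex2$ppv * n) / sum(n), pooled)
})

test_that("validation_report produces coherent stratum, group and global rows", {
  gen <- generate_cohort(synth_config(n_patients = 6000, seed = 23))
  el <- build_eligibility(gen$cohort)
  cases <- find_cases(gen$cohort, el$windows)
  cases$case_id <- cases$patient_id
  s <- suppressWarnings(draw_sample(cases, sampling_plan(), seed = 23))
  s$sample$case_id <- s$sample$patient_id
  adj <- simulate_adjudication(s$sample, gen$truth, reviewer_error = 0,
                               p_unsupported = 0, p_inconclusive = 0,
                               seed = 23)
  rep_main <- validation_report(adj$final, s$sample, s$pool_weights)
  glob <- rep_main[rep_main$scope == "overall/weighted_mean", ]
  expect_equal(nrow(glob), 1)
  expect_true(glob$ppv > 0.8 && glob$ppv <= 1)
  expect_true(all(rep_main$ci_low <= rep_main$ppv + 1e-12, na.rm = TRUE))
  expect_true(all(rep_main$ppv <= rep_main$ci_high + 1e-12, na.rm = TRUE))
})
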