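#' Synthetic-cohort generator configuration
#'
#' Defaults emulate the observed shape of a Spanish primary-care
#' digestive-cancer case pool: information-completeness strata at roughly
#' 84/10/6 percent, about a third of cases detectable only through
#' descriptor text mining, colorectal the most common site, and realistic
#' per-site incidence (per 100,000 person-years, rising with age). The
#' `hazard_scale` multiplier (default 5) thickens the case pool so that
#' validation-sized experiments are feasible on cohorts of tens of
#' thousands rather than millions of patients; set it to 1 for
#' population-realistic incidence.
#'
#' @param n_patients cohort size.
#' @param seed mandatory integer seed; every stream derives from it.
#' @param study_start,study_end study period.
#' @param p_female probability a patient is female.
#' @param base_rates per-site incidence per 100,000 person-years at age 65.
#' @param age_log_slope log-linear age effect on rates per year of age.
#' @param hazard_scale global multiplier on all rates.
#' @param p_text_only share of true cases recorded only as descriptor text
#'   attached to a non-cancer code.
#' @param stratum_shares probabilities of strata S1/S2/S3 for a case.
#' @param p_false_positive_code chance a cancer-free patient still gets an
#'   incident cancer-list code (miscoding noise).
#' @param p_missing_trace chance a true case leaves no detectable trace.
#' @param p_prevalent_record chance of a history-only (PH) cancer code.
#' @param p_suspicion_note chance of a rule-out note on a cancer-free
#'   patient.
#' @param p_cooccurrence share of colorectal cases also coded at the
#'   metastatic liver site with matching metastasis wording.
#' @param p_hepatic_angle,p_gej,p_ampulloma shares of colorectal /
#'   esophageal / hepato-biliary cases using the phrasings the
#'   fine-tuning rules exist for.
#' @param p_neuroendocrine,p_genetic chances of neuroendocrine /
#'   hereditary-syndrome mentions (excluded biology).
#' @param p_unsupported,p_inconclusive chances a true record reviews as
#'   unsupported / inconclusive.
#' @param reviewer_error per-reviewer adjacent-category flip probability in
#'   simulated adjudication.
#' @return a `digephen_synth_config` list.
#' @export
synth_config <- function(n_patients = 2000L, seed = 20010101L,
                         study_start = as.Date("2001-01-01"),
                         study_end = as.Date("2019-12-31"),
                         p_female = 0.5,
                         base_rates = c(colorectal = 48, gastric = 13.5,
                                        hepatobiliary = 7.2, pancreatic = 6.3,
                                        esophageal = 2.8),
                         age_log_slope = 0.05,
                         hazard_scale = 5,
                         p_text_only = 0.333,
                         stratum_shares = c(S1 = 0.84, S2 = 0.10, S3 = 0.06),
                         p_false_positive_code = 0.003,
                         p_missing_trace = 0,
                         p_prevalent_record = 0.01,
                         p_suspicion_note = 0.01,
                         p_cooccurrence = 0.05,
                         p_hepatic_angle = 0.03,
                         p_gej = 0.05,
                         p_ampulloma = 0.04,
                         p_neuroendocrine = 0.003,
                         p_genetic = 0.003,
                         p_unsupported = 0.07,
                         p_inconclusive = 0.03,
                         reviewer_error = 0.05) {
  cfg <- as.list(environment())
  probs <- unlist(cfg[grepl("^p_", names(cfg))])
  stopifnot(all(probs >= 0 & probs <= 1), all(base_rates >= 0),
            abs(sum(stratum_shares) - 1) < 1e-9, !is.null(seed))
  structure(cfg, class = "digephen_synth_config")
}

CASE_PHRASES <- list(
  esophageal = c("neoplasia de esofago", "carcinoma de esofago",
                 "adenocarcinoma esofagico"),
  gastric = c("cancer gastrico", "adenocarcinoma de estomago",
              "neoplasia de estomago"),
  pancreatic = c("adenocarcinoma de pancreas",
                 "neoplasia de cabeza de pancreas", "cancer de pancreas"),
  hepatobiliary = c("hepatocarcinoma", "colangiocarcinoma",
                    "neoplasia de via biliar"),
  colorectal = c("adenocarcinoma de colon", "neoplasia de recto",
                 "cancer de sigma"))

BENIGN_CODES <- data.frame(
  coding_system = c("ICPC_BIFAP", "ICPC_BIFAP", "ICD9", "ICD9"),
  code = c("K86", "D02", "401.9", "250.0"),
  descriptor = c("hipertension arterial", "dolor de estomago",
                 "hipertension esencial", "diabetes mellitus"),
  stringsAsFactors = FALSE)

# representative exact codes per cancer type, drawn from the shipped lists
sample_cancer_code <- function(ct, n, codelists) {
  cl <- codelists[[ct]]
  pool_icpc <- expanded_icpc(cl)
  pool_icd <- unlist(lapply(cl$icd9[!grepl("^230", cl$icd9)], function(p) {
    r <- parse_icd9_range(p)
    sprintf("%.1f", round(seq(r[1], r[2], by = 0.1), 1))
  }))
  sys <- sample(c("ICPC_BIFAP", "ICD9"), n, replace = TRUE)
  code <- character(n)
  code[sys == "ICPC_BIFAP"] <- sample(pool_icpc, sum(sys == "ICPC_BIFAP"),
                                      replace = TRUE)
  code[sys == "ICD9"] <- sample(pool_icd, sum(sys == "ICD9"), replace = TRUE)
  data.frame(coding_system = sys, code = code, stringsAsFactors = FALSE)
}

#' Generate a synthetic primary-care cohort with planted ground truth
#'
#' Deterministic given `config$seed`. Emits a validated cohort bundle
#' (patients, coded episodes with descriptors, free-text notes, supporting
#' evidence) plus a ground-truth table that the case-finding path never
#' reads. True cases are planted from age-dependent per-site hazards over
#' each patient's eligibility window; coding noise, prevalent history
#' records, rule-out notes, co-occurrence phrasings and excluded-biology
#' mentions are injected per the configuration so every disambiguation rule
#' is exercised.
#'
#' @param config a [synth_config()].
#' @return list: `cohort` (a `digephen_cohort`) and `truth` (data frame:
#'   `patient_id`, `true_type`, `true_date`, `is_prevalent`,
#'   `is_neuroendocrine_or_genetic`).
#' @export
generate_cohort <- function(config = synth_config()) {
  cfg <- config
  n <- cfg$n_patients
  set.seed(derive_seed(cfg$seed, "patients"))
  pid <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(runif(n) < cfg$p_female, "female", "male")
  # age 30-88 at study start so entries spread over the 40-89 range
  birth <- cfg$study_start - round(runif(n, 30, 88) * 365.25)
  reg_start <- as.Date("1994-01-01") + round(runif(n, 0, 18 * 365.25))
  fup_years <- pmin(rexp(n, 1 / 12) + 0.5, 30)
  reg_end <- pmin(reg_start + round(fup_years * 365.25), cfg$study_end)
  reg_end <- pmax(reg_end, reg_start + 60)
  patients <- data.frame(patient_id = pid, sex = sex, birth_date = birth,
                         registry_start = reg_start, registry_end = reg_end,
                         stringsAsFactors = FALSE)

  entry <- pmax(cfg$study_start, add_years(reg_start, 1L),
                add_years(birth, 40L))
  exit <- pmin(cfg$study_end, reg_end, add_years(birth, 90L) - 1L)
  yrs <- pmax(as.numeric(exit - entry) / 365.25, 0)
  age_entry <- completed_age(pmax(entry, birth), birth)

  # planted incidence: site-specific rates at the patient's mid-window age
  set.seed(derive_seed(cfg$seed, "truth"))
  age_mid <- age_entry + yrs / 2
  rate_mult <- exp(cfg$age_log_slope * (age_mid - 65))
  rates <- sapply(cfg$base_rates, function(r)
    r / 1e5 * cfg$hazard_scale * rate_mult)  # n x site matrix
  total_rate <- rowSums(rates)
  # Poisson expectation over the whole cohort; an expectation beyond the
  # cohort size means the hazards cannot be interpreted as incidence
  expected <- sum(total_rate * yrs)
  if (expected > n)
    stop_digephen("infeasible config: expected cases (%.0f) exceed patients",
                  expected)
  p_case <- (1 - exp(-total_rate * yrs)) * (yrs > 0)
  is_case <- runif(n) < p_case
  type_draw <- rep(NA_character_, n)
  ci <- which(is_case)
  if (length(ci)) {
    u <- runif(length(ci))
    cum <- t(apply(rates[ci, , drop = FALSE], 1, cumsum)) /
      total_rate[ci]
    type_draw[ci] <- names(cfg$base_rates)[
      max.col(u <= cum, ties.method = "first")]
    type_draw[ci][is.na(type_draw[ci])] <- names(cfg$base_rates)[1]
  }
  case_date <- as.Date(rep(NA, n))
  case_date[ci] <- entry[ci] + round(runif(length(ci)) *
                                       as.numeric(exit[ci] - entry[ci]))

  episodes <- list(); notes <- list(); evidence <- list()
  codelists <- default_codelists()

  set.seed(derive_seed(cfg$seed, "records"))
  # background noise records for everyone
  bg <- sample.int(nrow(BENIGN_CODES), n, replace = TRUE)
  bg_date <- reg_start + round(runif(n) *
                                 pmax(as.numeric(reg_end - reg_start), 1))
  episodes$background <- data.frame(
    patient_id = pid, event_date = bg_date, field = "ID",
    coding_system = BENIGN_CODES$coding_system[bg],
    code = BENIGN_CODES$code[bg],
    descriptor = BENIGN_CODES$descriptor[bg], stringsAsFactors = FALSE)
  bg_note <- runif(n) < 0.5
  notes$background <- data.frame(
    patient_id = pid[bg_note], note_date = bg_date[bg_note],
    text = "control rutinario, sin hallazgos relevantes",
    stringsAsFactors = FALSE)

  # true cases --------------------------------------------------------
  if (length(ci)) {
    m <- length(ci)
    cpid <- pid[ci]; ctype <- type_draw[ci]; cdate <- case_date[ci]
    detectable <- runif(m) >= cfg$p_missing_trace
    stratum <- sample(c("S1", "S2", "S3"), m, replace = TRUE,
                      prob = cfg$stratum_shares)
    text_only <- runif(m) < cfg$p_text_only
    special <- rep("", m)
    special[ctype == "colorectal" &
              runif(m) < cfg$p_hepatic_angle] <- "hepatic_angle"
    special[ctype == "esophageal" & runif(m) < cfg$p_gej] <- "gej"
    special[ctype == "hepatobiliary" &
              runif(m) < cfg$p_ampulloma] <- "ampulloma"
    phrase <- vapply(seq_len(m), function(i) {
      switch(special[i],
             hepatic_angle = "neoplasia en angulo hepatico del colon",
             gej = "adenocarcinoma de la union gastroesofagica",
             ampulloma = "ampuloma",
             sample(CASE_PHRASES[[ctype[i]]], 1))
    }, character(1))

    det <- which(detectable)
    # coded route: incident-diagnosis episode with a cancer-list code
    coded <- det[!text_only[det] & special[det] == ""]
    if (length(coded)) {
      cc <- sample_cancer_code_by_type(ctype[coded], codelists)
      episodes$case_code <- data.frame(
        patient_id = cpid[coded], event_date = cdate[coded], field = "ID",
        coding_system = cc$coding_system, code = cc$code,
        descriptor = phrase[coded], stringsAsFactors = FALSE)
    }
    # text route (and all special phrasings): descriptor on a benign code
    texty <- det[text_only[det] | special[det] != ""]
    if (length(texty)) {
      bi <- sample.int(nrow(BENIGN_CODES), length(texty), replace = TRUE)
      episodes$case_text <- data.frame(
        patient_id = cpid[texty], event_date = cdate[texty], field = "ID",
        coding_system = BENIGN_CODES$coding_system[bi],
        code = BENIGN_CODES$code[bi], descriptor = phrase[texty],
        stringsAsFactors = FALSE)
    }
    # co-occurrence: liver-metastasis wording plus a liver-site code
    cooc <- det[ctype[det] == "colorectal" & special[det] == "" &
                  runif(length(det)) < cfg$p_cooccurrence]
    if (length(cooc)) {
      lc <- sample_cancer_code("hepatobiliary", length(cooc), codelists)
      episodes$cooc <- data.frame(
        patient_id = cpid[cooc], event_date = cdate[cooc], field = "ID",
        coding_system = lc$coding_system, code = lc$code,
        descriptor = "metastasis hepaticas", stringsAsFactors = FALSE)
      notes$cooc <- data.frame(
        patient_id = cpid[cooc], note_date = cdate[cooc] + 3,
        text = "cancer de recto con metastasis hepaticas",
        stringsAsFactors = FALSE)
    }
    # stratum dressing: notes for S1/S2, supporting evidence for S1
    noted <- det[stratum[det] %in% c("S1", "S2")]
    if (length(noted)) {
      notes$case <- data.frame(
        patient_id = cpid[noted], note_date = cdate[noted] + 7,
        text = paste("paciente diagnosticado de", phrase[noted],
                     "en seguimiento oncologico"),
        stringsAsFactors = FALSE)
    }
    supported <- det[stratum[det] == "S1"]
    if (length(supported)) {
      evidence$case <- data.frame(
        patient_id = cpid[supported], evidence_date = cdate[supported] + 14,
        kind = sample(EVIDENCE_KINDS, length(supported), replace = TRUE),
        stringsAsFactors = FALSE)
      # hospital-discharge codes for a share of well-documented cases
      hosp <- supported[runif(length(supported)) < 0.3]
      if (length(hosp)) {
        hc <- sample_cancer_code_by_type(ctype[hosp], codelists)
        icd <- hc$coding_system == "ICD9"
        if (any(icd)) {
          episodes$discharge <- data.frame(
            patient_id = cpid[hosp][icd], event_date = cdate[hosp][icd] + 10,
            field = "ID", coding_system = "ICD9_HOSPITAL",
            code = hc$code[icd], descriptor = "diagnostico al alta",
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  # noise on cancer-free patients -------------------------------------
  free <- which(!is_case)
  set.seed(derive_seed(cfg$seed, "noise"))
  fp <- free[runif(length(free)) < cfg$p_false_positive_code & yrs[free] > 0]
  if (length(fp)) {
    fc <- sample_cancer_code_by_type(
      sample(names(cfg$base_rates), length(fp), replace = TRUE,
             prob = cfg$base_rates), codelists)
    fpd <- entry[fp] + round(runif(length(fp)) *
                               pmax(as.numeric(exit[fp] - entry[fp]), 1))
    episodes$false_positive <- data.frame(
      patient_id = pid[fp], event_date = fpd, field = "ID",
      coding_system = fc$coding_system, code = fc$code,
      descriptor = "codificacion erronea", stringsAsFactors = FALSE)
  }
  prev <- setdiff(free[runif(length(free)) < cfg$p_prevalent_record], fp)
  is_prevalent <- logical(n)
  if (length(prev)) {
    is_prevalent[prev] <- TRUE
    pc <- sample_cancer_code_by_type(
      sample(names(cfg$base_rates), length(prev), replace = TRUE),
      codelists)
    pre_entry <- runif(length(prev)) < 0.5
    pdate <- ifelse(pre_entry,
                    reg_start[prev] + 30,
                    pmin(entry[prev] + 200, exit[prev]))
    episodes$prevalent <- data.frame(
      patient_id = pid[prev], event_date = as.Date(pdate, origin = "1970-01-01"),
      field = "PH", coding_system = pc$coding_system, code = pc$code,
      descriptor = "antecedente de neoplasia", stringsAsFactors = FALSE)
  }
  susp <- free[runif(length(free)) < cfg$p_suspicion_note & yrs[free] > 0]
  if (length(susp)) {
    sd_ <- entry[susp] + round(runif(length(susp)) *
                                 pmax(as.numeric(exit[susp] - entry[susp]), 1))
    notes$suspicion <- data.frame(
      patient_id = pid[susp], note_date = sd_,
      text = "descartar cancer de colon, se solicita colonoscopia",
      stringsAsFactors = FALSE)
  }
  is_excl_bio <- logical(n)
  neur <- free[runif(length(free)) < cfg$p_neuroendocrine & yrs[free] > 0]
  if (length(neur)) {
    is_excl_bio[neur] <- TRUE
    nd <- entry[neur] + round(runif(length(neur)) *
                                pmax(as.numeric(exit[neur] - entry[neur]), 1))
    notes$neuro <- data.frame(
      patient_id = pid[neur], note_date = nd,
      text = "tumor neuroendocrino de pancreas en seguimiento",
      stringsAsFactors = FALSE)
  }
  gen <- free[runif(length(free)) < cfg$p_genetic & yrs[free] > 0]
  gen <- setdiff(gen, neur)
  if (length(gen)) {
    is_excl_bio[gen] <- TRUE
    gd <- entry[gen] + round(runif(length(gen)) *
                               pmax(as.numeric(exit[gen] - entry[gen]), 1))
    notes$genetic <- data.frame(
      patient_id = pid[gen], note_date = gd,
      text = "sindrome de lynch, cancer de colon hereditario en la familia",
      stringsAsFactors = FALSE)
  }

  ep <- do.call(rbind, episodes); rownames(ep) <- NULL
  nt <- do.call(rbind, notes); rownames(nt) <- NULL
  ev <- if (length(evidence)) do.call(rbind, evidence) else NULL
  # clamp record dates inside the registry interval
  clamp <- function(df, col) {
    i <- match(df$patient_id, pid)
    df[[col]] <- pmin(pmax(df[[col]], reg_start[i]), reg_end[i])
    df
  }
  ep <- clamp(ep, "event_date"); nt <- clamp(nt, "note_date")
  if (!is.null(ev)) ev <- clamp(ev, "evidence_date")

  truth <- data.frame(
    patient_id = pid,
    true_type = ifelse(is_case, type_draw, "none"),
    true_date = case_date,
    is_prevalent = is_prevalent,
    is_neuroendocrine_or_genetic = is_excl_bio,
    stringsAsFactors = FALSE)

  list(cohort = new_cohort(patients, ep, nt, ev), truth = truth)
}

# vectorised per-type code sampler
sample_cancer_code_by_type <- function(types, codelists) {
  out <- data.frame(coding_system = character(length(types)),
                    code = character(length(types)),
                    stringsAsFactors = FALSE)
  for (ct in unique(types)) {
    i <- which(types == ct)
    out[i, ] <- sample_cancer_code(ct, length(i), codelists)
  }
  out
}

#' Simulate two-reviewer adjudication of a case sample
#'
#' Each sampled case gets a truth-derived category (valid for a planted
#' incident digestive cancer; non-valid for miscoding, prevalent or
#' excluded-biology records; a configurable share review as unsupported or
#' inconclusive), then two simulated reviewers independently flip to an
#' adjacent category with probability `reviewer_error`, and a committee
#' decision restores the truth category wherever the reviewers disagree.
#'
#' @param cases sampled case rows (needs `patient_id`).
#' @param truth ground-truth table from [generate_cohort()].
#' @param reviewer_error per-reviewer adjacent-category flip probability.
#' @param p_unsupported,p_inconclusive truth-level shares of poorly
#'   documented records.
#' @param seed integer seed.
#' @return list: `ratings` (long: `case_id`, `reviewer_id`, `category`),
#'   `final` (`case_id`, `category` after committee arbitration).
#' @export
simulate_adjudication <- function(cases, truth, reviewer_error = 0.05,
                                  p_unsupported = 0.07,
                                  p_inconclusive = 0.03, seed = 1L) {
  set.seed(derive_seed(seed, "adjudication"))
  tr <- truth[match(cases$patient_id, truth$patient_id), ]
  n <- nrow(cases)
  base <- ifelse(tr$true_type != "none" & !tr$is_prevalent &
                   !tr$is_neuroendocrine_or_genetic, "valid", "non_valid")
  u <- runif(n)
  base[u < p_unsupported] <- "unsupported"
  base[u >= p_unsupported & u < p_unsupported + p_inconclusive] <-
    "inconclusive"
  flip_adjacent <- function(cat) {
    i <- match(cat, ADJ_CATEGORIES)
    do_flip <- runif(length(cat)) < reviewer_error
    dir <- ifelse(i == 1, 1L,
                  ifelse(i == length(ADJ_CATEGORIES), -1L,
                         sample(c(-1L, 1L), length(cat), replace = TRUE)))
    ifelse(do_flip, ADJ_CATEGORIES[i + dir], cat)
  }
  r1 <- flip_adjacent(base)
  r2 <- flip_adjacent(base)
  final <- ifelse(r1 == r2, r1, base)  # committee arbitration
  list(
    ratings = data.frame(
      case_id = rep(cases$patient_id, 2),
      reviewer_id = rep(c("R1", "R2"), each = n),
      category = c(r1, r2), stringsAsFactors = FALSE),
    final = data.frame(case_id = cases$patient_id, category = final,
                       stringsAsFactors = FALSE))
}

#' Plant Bernoulli validity over a case sample
#'
#' Replicate-level helper for parameter-recovery experiments: every case in
#' the sample independently reviews valid with probability `q`. Used to
#' check that PPV interval estimates cover a planted precision at nominal
#' rate.
#'
#' @param case_ids character vector of case ids.
#' @param q planted precision.
#' @param seed integer seed.
#' @return final-adjudication data frame (`case_id`, `category`).
#' @export
plant_validity <- function(case_ids, q, seed = 1L) {
  set.seed(derive_seed(seed, "plant_validity"))
  data.frame(case_id = case_ids,
             category = ifelse(runif(length(case_ids)) < q,
                               "valid", "non_valid"),
             stringsAsFactors = FALSE)
}
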