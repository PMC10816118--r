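#' Build eligibility windows for a cohort
#'
#' A patient enters follow-up at the latest of: the study start, one year
#' after first registration with their primary-care physician, and their
#' 40th birthday. They exit at the earliest of: the study end, the registry
#' end (transfer-out or death), and their 90th birthday. Patients whose
#' window is empty, or who have any cancer episode (any malignancy, not just
#' digestive; non-melanoma skin cancer exempt) dated before their entry,
#' are excluded.
#'
#' @param cohort a validated `digephen_cohort`.
#' @param study_start,study_end study period bounds (`Date`).
#' @param age_min,age_max entry is not before the `age_min`-th birthday and
#'   exit not after the `age_max + 1`-th.
#' @param prior_cancer_patterns "any malignancy" pattern set; see
#'   [any_cancer_patterns()].
#' @return list with `windows` (data frame: `patient_id`, `entry_date`,
#'   `exit_date`, `sex`, `birth_date`) and `exclusions` (named counts by
#'   reason: `empty_window`, `prior_cancer`).
#' @export
build_eligibility <- function(cohort,
                              study_start = as.Date("2001-01-01"),
                              study_end = as.Date("2019-12-31"),
                              age_min = 40L, age_max = 89L,
                              prior_cancer_patterns = any_cancer_patterns()) {
  p <- cohort$patients
  entry <- pmax(study_start, add_years(p$registry_start, 1L),
                add_years(p$birth_date, age_min))
  exit <- pmin(study_end, p$registry_end,
               add_years(p$birth_date, age_max + 1L) - 1L)
  ok <- entry < exit
  w <- data.frame(patient_id = p$patient_id, entry_date = entry,
                  exit_date = exit, sex = p$sex, birth_date = p$birth_date,
                  stringsAsFactors = FALSE)[ok, , drop = FALSE]

  # prior cancer history: any malignancy episode dated before entry
  ep <- cohort$episodes
  cancerous <- matches_any_cancer(ep$code, ep$coding_system,
                                  prior_cancer_patterns)
  pre <- ep[cancerous, c("patient_id", "event_date")]
  pre <- merge(pre, w[c("patient_id", "entry_date")], by = "patient_id")
  prior_ids <- unique(pre$patient_id[pre$event_date < pre$entry_date])
  excl <- c(empty_window = sum(!ok), prior_cancer = length(prior_ids))
  w <- w[!w$patient_id %in% prior_ids, , drop = FALSE]
  rownames(w) <- NULL
  list(windows = w, exclusions = excl)
}

empty_cases <- function() {
  data.frame(patient_id = character(), cancer_type = character(),
             index_date = as.Date(character()), detection_route = character(),
             stratum = character(), n_code_evidence = integer(),
             n_text_evidence = integer(), stringsAsFactors = FALSE)
}

#' Resolve co-occurring cancer candidates for one patient
#'
#' Deterministic replacement for the random classification that plagues
#' naive code searches when two cancers co-occur in one record (the classic
#' case: "rectal cancer with liver metastasis" hits both the colorectal and
#' hepato-biliary lists). Metastasis phrasings in the patient's text
#' suppress the metastatic-site candidate; any remaining tie is broken by
#' the fixed hierarchy rank of the code lists (default: colorectal >
#' esophageal > gastric > pancreatic > hepato-biliary).
#'
#' @param candidates character vector of candidate cancer types (>= 1).
#' @param context the patient's pooled descriptor/note text (may be `""`).
#' @param codelists a `digephen_codelists` supplying `hierarchy_rank`.
#' @param lexicon a `digephen_lexicon` supplying metastasis phrasings.
#' @return a single cancer type.
#' @export
#' @examples
#' resolve_hierarchy(c("colorectal", "hepatobiliary"),
#'                   "cáncer de recto con metástasis hepáticas")
resolve_hierarchy <- function(candidates, context = "",
                              codelists = default_codelists(),
                              lexicon = default_lexicon()) {
  candidates <- unique(candidates)
  if (!length(candidates)) stop_digephen("no candidate cancer types")
  if (length(candidates) > 1L && nzchar(context))
    candidates <- suppress_metastatic(candidates, context, lexicon)
  if (length(candidates) == 1L) return(candidates)
  ranks <- vapply(candidates, function(ct)
    codelists[[ct]]$hierarchy_rank, integer(1))
  candidates[which.min(ranks)]
}

#' Assign the information-completeness stratum of a case
#'
#' Strata describe how much corroborating information the record holds:
#' `S1_code_notes_support` — diagnosis plus free-text notes plus supporting
#' information (stage, surgery, chemo/radiotherapy, discharge or specialist
#' codes, histopathology, imaging/colonoscopy); `S2_code_notes` — diagnosis
#' plus notes; `S3_code_only` — diagnosis only. Notes and supporting
#' evidence count when dated within `link_months` of the index date.
#'
#' @param case one row of a case table (needs `patient_id`, `index_date`).
#' @param cohort the `digephen_cohort`.
#' @param link_months half-width of the temporal linkage window (months).
#' @return one of the three stratum labels.
#' @export
assign_stratum <- function(case, cohort, link_months = 6) {
  lo <- case$index_date - round(link_months * 30.44)
  hi <- case$index_date + round(link_months * 30.44)
  ev <- cohort$evidence
  has_support <- any(ev$patient_id == case$patient_id &
                       ev$evidence_date >= lo & ev$evidence_date <= hi)
  if (has_support) return("S1_code_notes_support")
  nt <- cohort$notes
  has_notes <- any(nt$patient_id == case$patient_id &
                     nt$note_date >= lo & nt$note_date <= hi &
                     nzchar(nt$text))
  if (has_notes) return("S2_code_notes")
  "S3_code_only"
}

#' Find potential incident digestive-cancer cases
#'
#' Runs the full case-finding algorithm over a cohort:
#'
#' 1. qualifying evidence inside each patient's eligibility window is
#'    collected — incident-diagnosis (`ID`) episodes and hospital-discharge
#'    episodes whose code matches a cancer list, plus non-excluded text hits
#'    from descriptor/note mining;
#' 2. personal-history/problem-list codes alone never create a case (they
#'    are the prevalent pattern), though they still contribute to the
#'    candidate type set of a patient who has incident evidence;
#' 3. each patient yields at most one case at the earliest qualifying date;
#'    co-occurring candidate types are resolved by [resolve_hierarchy()];
#' 4. each case gets an information-completeness stratum
#'    ([assign_stratum()]) and a detection route: `diagnostic_code` if any
#'    in-window code evidence supports the assigned type, else `text_only`.
#'
#' @param cohort a validated `digephen_cohort`.
#' @param windows eligibility windows from [build_eligibility()] (its
#'   `$windows` component).
#' @param codelists a `digephen_codelists`.
#' @param lexicon a `digephen_lexicon`.
#' @param link_months stratum/evidence linkage half-window, months.
#' @return PotentialCase table: `patient_id`, `cancer_type`, `index_date`,
#'   `detection_route`, `stratum`, evidence counts.
#' @export
find_cases <- function(cohort, windows, codelists = default_codelists(),
                       lexicon = default_lexicon(), link_months = 6) {
  if (!nrow(windows)) return(empty_cases())
  ep <- merge(cohort$episodes,
              windows[c("patient_id", "entry_date", "exit_date")],
              by = "patient_id")
  ep$cancer_type <- match_codes(ep$code, ep$coding_system, codelists)
  ep <- ep[!is.na(ep$cancer_type), , drop = FALSE]
  in_win <- ep$event_date >= ep$entry_date & ep$event_date <= ep$exit_date
  ep <- ep[in_win, , drop = FALSE]
  # incident signal: ID field or hospital-discharge code; PH/CPL codes are
  # the prevalent pattern and only widen the candidate set
  ep$incident <- ep$field == "ID" | ep$coding_system == "ICD9_HOSPITAL"

  th <- mine_cohort(cohort, lexicon, codelists)
  th <- th[!th$excluded, , drop = FALSE]
  th <- merge(th, windows[c("patient_id", "entry_date", "exit_date")],
              by = "patient_id")
  th <- th[th$hit_date >= th$entry_date & th$hit_date <= th$exit_date, ,
           drop = FALSE]

  code_ev <- ep[ep$incident,
                c("patient_id", "cancer_type", "event_date")]
  names(code_ev)[3] <- "ev_date"
  text_ev <- th[c("patient_id", "assigned_cancer_type", "hit_date")]
  names(text_ev) <- c("patient_id", "cancer_type", "ev_date")
  code_ev$route <- rep("diagnostic_code", nrow(code_ev))
  text_ev$route <- rep("text_only", nrow(text_ev))
  qual <- rbind(code_ev, text_ev)
  if (!nrow(qual)) return(empty_cases())

  # pooled text context per patient for metastasis disambiguation
  ctx_tab <- c(split(cohort$notes$text, cohort$notes$patient_id),
               split(cohort$episodes$descriptor, cohort$episodes$patient_id))
  pool_ctx <- function(pid) {
    paste(unlist(ctx_tab[names(ctx_tab) == pid], use.names = FALSE),
          collapse = ". ")
  }

  # candidate types per patient include PH/CPL code matches
  all_cand <- rbind(qual[c("patient_id", "cancer_type")],
                    ep[c("patient_id", "cancer_type")])

  out <- lapply(split(qual, qual$patient_id), function(q) {
    pid <- q$patient_id[1]
    cands <- unique(all_cand$cancer_type[all_cand$patient_id == pid])
    ct <- if (length(cands) > 1L)
      resolve_hierarchy(cands, pool_ctx(pid), codelists, lexicon)
    else cands
    # index date: earliest qualifying evidence for the assigned type;
    # if the assigned type only ever co-occurred (suppressed metastatic
    # reading), fall back to the earliest evidence of any type
    q_ct <- q[q$cancer_type == ct, , drop = FALSE]
    if (!nrow(q_ct)) q_ct <- q
    i <- which.min(q_ct$ev_date)
    data.frame(patient_id = pid, cancer_type = ct,
               index_date = q_ct$ev_date[i],
               detection_route = if (any(q_ct$route == "diagnostic_code"))
                 "diagnostic_code" else "text_only",
               n_code_evidence = sum(q$route == "diagnostic_code"),
               n_text_evidence = sum(q$route == "text_only"),
               stringsAsFactors = FALSE)
  })
  cases <- do.call(rbind, out)
  rownames(cases) <- NULL
  cases$stratum <- vapply(seq_len(nrow(cases)), function(i)
    assign_stratum(cases[i, ], cohort, link_months), character(1))
  cases[c("patient_id", "cancer_type", "index_date", "detection_route",
          "stratum", "n_code_evidence", "n_text_evidence")]
}

#' Attrition and composition summary of a case-finding run
#'
#' @param cohort the cohort the cases came from.
#' @param elig result of [build_eligibility()].
#' @param cases result of [find_cases()].
#' @return named list of counts (total patients, exclusions by reason,
#'   eligible patients, potential cases, per-type and per-stratum counts,
#'   text-only share).
#' @export
casefind_summary <- function(cohort, elig, cases) {
  list(
    n_patients = nrow(cohort$patients),
    excluded = as.list(elig$exclusions),
    n_eligible = nrow(elig$windows),
    n_potential_cases = nrow(cases),
    by_type = as.list(table(factor(cases$cancer_type, CANCER_TYPES))),
    by_stratum = as.list(table(factor(cases$stratum, STRATA))),
    pct_text_only = if (nrow(cases))
      100 * mean(cases$detection_route == "text_only") else NA_real_)
}
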