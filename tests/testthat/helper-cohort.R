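# shared fixture builders; everything is constructed in code

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_patients <- function() {
  data.frame(
    patient_id = c("P1", "P2", "P3"),
    sex = c("female", "male", "male"),
    birth_date = as.Date(c("1950-04-01", "1945-10-20", "1962-02-28")),
    registry_start = as.Date(c("1999-06-01", "2005-03-10", "1998-01-01")),
    registry_end = as.Date(c("2019-12-31", "2018-06-30", "2019-12-31")),
    stringsAsFactors = FALSE)
}

empty_episodes <- function() {
  data.frame(patient_id = character(), event_date = as.Date(character()),
             field = character(), coding_system = character(),
             code = character(), descriptor = character(),
             stringsAsFactors = FALSE)
}

empty_notes <- function() {
  data.frame(patient_id = character(), note_date = as.Date(character()),
             text = character(), stringsAsFactors = FALSE)
}

empty_evidence <- function() {
  data.frame(patient_id = character(), evidence_date = as.Date(character()),
             kind = character(), stringsAsFactors = FALSE)
}

episode_row <- function(pid, date, field = "ID", system = "ICD9",
                        code = "153.4", descriptor = "") {
  data.frame(patient_id = pid, event_date = as.Date(date), field = field,
             coding_system = system, code = code, descriptor = descriptor,
             stringsAsFactors = FALSE)
}

note_row <- function(pid, date, text) {
  data.frame(patient_id = pid, note_date = as.Date(date), text = text,
             stringsAsFactors = FALSE)
}

evidence_row <- function(pid, date, kind = "histopathology") {
  data.frame(patient_id = pid, evidence_date = as.Date(date), kind = kind,
             stringsAsFactors = FALSE)
}

tiny_cohort <- function(episodes = empty_episodes(), notes = empty_notes(),
                        evidence = NULL, patients = tiny_patients()) {
  new_cohort(patients, episodes, notes, evidence)
}

# resolved non-excluded prediction of the text miner for one snippet
mined_prediction <- function(text, lexicon = default_lexicon()) {
  hits <- mine_text(text, lexicon)
  kept <- hits[!hits$excluded, , drop = FALSE]
  if (!nrow(kept)) return("none")
  types <- unique(kept$assigned_cancer_type)
  if (length(types) == 1) return(types)
  resolve_hierarchy(types, text, lexicon = lexicon)
}
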