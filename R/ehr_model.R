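#' EHR cohort bundle
#'
#' A `digephen_cohort` is a validated set of up to four tables mirroring the
#' structure of a Spanish primary-care research database extract:
#'
#' * `patients`: `patient_id`, `sex` (`"male"`/`"female"`), `birth_date`,
#'   `registry_start` (first registration with the primary-care physician),
#'   `registry_end` (transfer-out, death, or study end).
#' * `episodes`: coded diagnostic episodes — `patient_id`, `event_date`,
#'   `field` (`ID` incident diagnosis, `PH` personal history, `CPL` clinical
#'   problem list), `coding_system` (`ICPC_BIFAP`, `ICD9`, `ICD9_HOSPITAL`
#'   for hospital-discharge codes), `code`, and the physician-editable
#'   free-text `descriptor` attached to the code.
#' * `notes`: free-text clinical notes — `patient_id`, `note_date`, `text`.
#' * `evidence`: supporting-information records — `patient_id`,
#'   `evidence_date`, `kind` (stage, location, surgery, chemo/radiotherapy,
#'   hospital discharge code, specialist report, histopathology,
#'   imaging/colonoscopy).
#'
#' All dates are day-resolution `Date`s (ISO-8601 on disk). Validation
#' enforces per-row invariants (`registry_start < registry_end`,
#' `birth_date < registry_start`, non-empty codes, closed enums) and
#' referential integrity of `patient_id`.
#'
#' @param patients,episodes,notes,evidence data frames with the columns above
#'   (`evidence` may be `NULL`).
#' @return an object of class `digephen_cohort`.
#' @export
#' @examples
#' cb <- new_cohort(
#'   patients = data.frame(patient_id = "P1", sex = "female",
#'                         birth_date = as.Date("1950-04-01"),
#'                         registry_start = as.Date("1999-01-01"),
#'                         registry_end = as.Date("2019-12-31")),
#'   episodes = data.frame(patient_id = "P1",
#'                         event_date = as.Date("2010-06-01"),
#'                         field = "ID", coding_system = "ICD9",
#'                         code = "153.4", descriptor = "neoplasia de colon"),
#'   notes = data.frame(patient_id = character(), note_date = as.Date(character()),
#'                      text = character()))
new_cohort <- function(patients, episodes, notes, evidence = NULL) {
  if (is.null(evidence)) {
    evidence <- data.frame(patient_id = character(),
                           evidence_date = as.Date(character()),
                           kind = character(), stringsAsFactors = FALSE)
  }
  bundle <- structure(list(patients = patients, episodes = episodes,
                           notes = notes, evidence = evidence),
                      class = "digephen_cohort")
  validate_cohort(bundle)
}

PATIENT_COLS <- c("patient_id", "sex", "birth_date", "registry_start",
                  "registry_end")
EPISODE_COLS <- c("patient_id", "event_date", "field", "coding_system",
                  "code", "descriptor")
NOTE_COLS <- c("patient_id", "note_date", "text")
EVIDENCE_COLS <- c("patient_id", "evidence_date", "kind")

check_cols <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_digephen("%s table is missing required column(s): %s",
                  table, paste(missing, collapse = ", "))
  df[cols]
}

as_date_col <- function(x, table, col) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(out) & !is.na(x) & nzchar(as.character(x)))
  if (length(bad))
    stop_digephen("%s: %d unparseable date(s) in '%s' (first at row %d: '%s')",
                  table, length(bad), col, bad[1], as.character(x)[bad[1]])
  out
}

row_fail <- function(ok, table, what) {
  bad <- which(!ok)
  if (length(bad))
    stop_digephen("%s: %d row(s) violate %s (rows: %s)", table, length(bad),
                  what, paste(head(bad, 5), collapse = ", "))
}

#' Validate a cohort bundle
#'
#' Checks column presence, types, enum membership, date ordering invariants
#' and referential integrity. Errors name the offending table, rows and rule.
#'
#' @param bundle a `digephen_cohort` or plain list with the four tables.
#' @return the validated `digephen_cohort`, with dates coerced to `Date`.
#' @export
validate_cohort <- function(bundle) {
  p <- check_cols(as.data.frame(bundle$patients), PATIENT_COLS, "patients")
  e <- check_cols(as.data.frame(bundle$episodes), EPISODE_COLS, "episodes")
  n <- check_cols(as.data.frame(bundle$notes), NOTE_COLS, "notes")
  v <- check_cols(as.data.frame(bundle$evidence), EVIDENCE_COLS, "evidence")

  p$patient_id <- as.character(p$patient_id)
  p$sex <- as.character(p$sex)
  for (col in c("birth_date", "registry_start", "registry_end"))
    p[[col]] <- as_date_col(p[[col]], "patients", col)
  row_fail(p$sex %in% c("male", "female"), "patients", "sex in {male, female}")
  row_fail(!duplicated(p$patient_id), "patients", "unique patient_id")
  row_fail(p$registry_start < p$registry_end, "patients",
           "registry_start < registry_end")
  row_fail(p$birth_date < p$registry_start, "patients",
           "birth_date < registry_start")

  e$patient_id <- as.character(e$patient_id)
  e$event_date <- as_date_col(e$event_date, "episodes", "event_date")
  e$field <- as.character(e$field); e$coding_system <- as.character(e$coding_system)
  e$code <- as.character(e$code)
  e$descriptor <- ifelse(is.na(e$descriptor), "", as.character(e$descriptor))
  row_fail(e$field %in% FIELD_LEVELS, "episodes", "field in {ID, PH, CPL}")
  row_fail(e$coding_system %in% CODING_SYSTEMS, "episodes",
           "known coding_system")
  row_fail(nzchar(e$code), "episodes", "non-empty code")

  n$patient_id <- as.character(n$patient_id)
  n$note_date <- as_date_col(n$note_date, "notes", "note_date")
  n$text <- ifelse(is.na(n$text), "", as.character(n$text))

  v$patient_id <- as.character(v$patient_id)
  v$evidence_date <- as_date_col(v$evidence_date, "evidence", "evidence_date")
  v$kind <- as.character(v$kind)
  row_fail(v$kind %in% EVIDENCE_KINDS, "evidence", "known evidence kind")

  for (tab in list(episodes = e, notes = n, evidence = v)) NULL
  orphan <- function(df, table) {
    row_fail(df$patient_id %in% p$patient_id, table,
             "patient_id present in patients table")
  }
  orphan(e, "episodes"); orphan(n, "notes"); orphan(v, "evidence")

  structure(list(patients = p, episodes = e, notes = n, evidence = v),
            class = "digephen_cohort")
}

#' @export
print.digephen_cohort <- function(x, ...) {
  cat("<digephen_cohort>\n")
  cat(sprintf("  patients: %d   episodes: %d   notes: %d   evidence: %d\n",
              nrow(x$patients), nrow(x$episodes), nrow(x$notes),
              nrow(x$evidence)))
  invisible(x)
}

cohort_files <- function(dir, format) {
  ext <- if (format == "jsonl") "jsonl" else "csv"
  file.path(dir, paste0(c("patients", "episodes", "notes", "evidence"),
                        ".", ext))
}

read_table_file <- function(path, format, date_cols) {
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
      df <- data.frame()
    } else {
      df <- do.call(rbind, lapply(lines, function(l)
        as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
    }
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  }
  df
}

#' Read a cohort bundle from a directory
#'
#' Expects `patients.csv`, `episodes.csv`, `notes.csv` and (optionally)
#' `evidence.csv` — or the `.jsonl` JSON-lines equivalents — with the schema
#' documented in [new_cohort()]. UTF-8, comma-delimited with a header row,
#' ISO-8601 dates.
#'
#' @param dir directory containing the table files.
#' @param format `"csv"` (default) or `"jsonl"`.
#' @return a validated `digephen_cohort`.
#' @export
read_cohort <- function(dir, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  paths <- cohort_files(dir, format)
  names(paths) <- c("patients", "episodes", "notes", "evidence")
  for (nm in c("patients", "episodes", "notes"))
    if (!file.exists(paths[[nm]]))
      stop_digephen("missing required table file: %s", paths[[nm]])
  tabs <- lapply(paths[1:3], read_table_file, format = format)
  ev <- if (file.exists(paths[["evidence"]]))
    read_table_file(paths[["evidence"]], format) else NULL
  if (!is.null(ev) && !nrow(ev))
    ev <- NULL
  new_cohort(tabs$patients, tabs$episodes, tabs$notes, ev)
}

write_table_file <- function(df, path, fmt) {
  format <- fmt
  date_cols <- vapply(df, inherits, logical(1), what = "Date")
  df[date_cols] <- lapply(df[date_cols], base::format, "%Y-%m-%d")
  if (format == "jsonl") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    if (nrow(df))
      writeLines(vapply(seq_len(nrow(df)), function(i)
        as.character(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                      auto_unbox = TRUE)), character(1)), con)
  } else {
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                     quote = TRUE)
  }
  invisible(path)
}

#' Write a cohort bundle to a directory
#'
#' Emits the same delimited schema [read_cohort()] accepts; the write/read
#' round trip is lossless on validated bundles.
#'
#' @param bundle a validated `digephen_cohort`.
#' @param dir output directory (created if absent).
#' @inheritParams read_cohort
#' @return the directory, invisibly.
#' @export
write_cohort <- function(bundle, dir, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  bundle <- validate_cohort(bundle)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- cohort_files(dir, format)
  write_table_file(bundle$patients, paths[1], format)
  write_table_file(bundle$episodes, paths[2], format)
  write_table_file(bundle$notes, paths[3], format)
  write_table_file(bundle$evidence, paths[4], format)
  invisible(dir)
}
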