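#' Per-cancer diagnostic code lists
#'
#' The shipped default encodes the dual-dictionary case-finding lists for the
#' five digestive cancers. Pattern notations:
#'
#' * exact ICPC-BIFAP codes (`"D74.1"`), including the database-private
#'   4-digit extensions (`"D75.1003"`);
#' * slash shorthand expanding one stem over several suffixes
#'   (`"D77.2/8"` = `D77.2`, `D77.8`);
#' * closed ICD-9 numeric ranges (`"150-150.9"`), endpoint-inclusive, with
#'   sub-codes of the range stems included;
#' * ICD-O morphology codes matched as opaque strings (`"M8170/3"`).
#'
#' Carcinoma-in-situ rubrics (230.x) are part of the default lists; whether
#' they count as cases can be switched off per call via `include_in_situ`.
#'
#' @return a `digephen_codelists`: named list (one element per cancer type)
#'   with components `icpc`, `icd9`, `morphology` (character pattern vectors)
#'   and `hierarchy_rank` (integer tie-break priority, 1 = wins).
#' @export
default_codelists <- function() {
  raw <- list(
    esophageal = list(
      icpc = c("D77.2/8"),
      icd9 = c("150-150.9", "230.1"),
      morphology = character()),
    gastric = list(
      icpc = c("D74.1", "D75.1003"),
      icd9 = c("151-151.9", "230.2"),
      morphology = character()),
    pancreatic = list(
      icpc = c("D76.1/4/5"),
      icd9 = c("157-157.9"),
      morphology = c("M8154/3")),
    hepatobiliary = list(
      icpc = c("D77.4/5"),
      icd9 = c("155-155.2", "156-156.9", "230.8"),
      morphology = c("M8160/3", "M8161/3", "M8170/3", "M8180/3",
                     "M8970/3", "M8970/6")),
    colorectal = list(
      icpc = c("D75.1/4/5/6/999/1004/1005"),
      icd9 = c("153.0-153.9", "154-154.8", "230.3-230.4"),
      morphology = character())
  )
  as_codelists(raw)
}

as_codelists <- function(raw) {
  unknown <- setdiff(names(raw), CANCER_TYPES)
  if (length(unknown))
    stop_digephen("unknown cancer type(s) in code lists: %s",
                  paste(unknown, collapse = ", "))
  out <- lapply(names(raw), function(ct) {
    x <- raw[[ct]]
    list(cancer_type = ct,
         icpc = as.character(x$icpc %||% character()),
         icd9 = as.character(x$icd9 %||% character()),
         morphology = as.character(x$morphology %||% character()),
         hierarchy_rank = as.integer(x$hierarchy_rank %||%
                                       match(ct, CANCER_TYPES)))
  })
  names(out) <- names(raw)
  structure(out, class = "digephen_codelists")
}

#' Load code lists from a YAML file
#'
#' File layout: `{cancer_type: {icpc: [...], icd9: [...], morphology: [...],
#' hierarchy_rank: int}}`. The shipped default file
#' (`system.file("extdata", "codelists_digestive_es.yaml", package =
#' "digephen")`) loads to the same sets as [default_codelists()].
#'
#' @param path YAML file path.
#' @return a `digephen_codelists`.
#' @export
load_codelists <- function(path) {
  as_codelists(yaml::read_yaml(path))
}

#' Expand slash shorthand into exact codes
#'
#' `"D77.2/8"` denotes the codes sharing the stem before the first dot with
#' each listed suffix: `D77.2` and `D77.8`. A pattern without a slash is
#' returned unchanged (as a length-1 set).
#'
#' @param pattern a single shorthand pattern.
#' @return character vector of exact codes.
#' @export
#' @examples
#' expand_shorthand("D76.1/4/5")   # D76.1 D76.4 D76.5
#' expand_shorthand("D74.1")       # D74.1
expand_shorthand <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  if (!grepl("/", pattern, fixed = TRUE)) return(pattern)
  if (!grepl("^[A-Za-z0-9]+\\.[0-9]+(/[0-9]+)+$", pattern))
    stop_digephen("malformed slash shorthand: '%s'", pattern)
  stem <- sub("\\..*$", "", pattern)
  suffixes <- strsplit(sub("^[A-Za-z0-9]+\\.", "", pattern), "/",
                       fixed = TRUE)[[1]]
  paste0(stem, ".", suffixes)
}

# parse an ICD-9 range pattern "a-b" (or a single code) into numeric bounds
parse_icd9_range <- function(pattern) {
  parts <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  if (!length(parts) %in% 1:2 || anyNA(suppressWarnings(as.numeric(parts))))
    stop_digephen("malformed ICD-9 pattern: '%s'", pattern)
  lo <- as.numeric(parts[1])
  hi <- as.numeric(parts[length(parts)])
  if (lo > hi) stop_digephen("inverted ICD-9 range: '%s'", pattern)
  c(lo, hi)
}

icd9_value <- function(code) suppressWarnings(as.numeric(code))

# numeric value truncated to one decimal digit, so deep sub-codes
# (e.g. 150.91) fall with their one-decimal parent inside printed ranges
icd9_trunc1 <- function(code) {
  v <- icd9_value(code)
  trunc(v * 10) / 10
}

match_icd9_patterns <- function(code, patterns) {
  v <- icd9_value(code)
  if (is.na(v)) return(FALSE)
  t1 <- icd9_trunc1(code)
  for (p in patterns) {
    r <- parse_icd9_range(p)
    if ((v >= r[1] && v <= r[2]) || (t1 >= r[1] && t1 <= r[2])) return(TRUE)
  }
  FALSE
}

expanded_icpc <- function(cl) {
  unlist(lapply(cl$icpc, expand_shorthand), use.names = FALSE)
}

#' Test whether a code matches a cancer's code list
#'
#' @param code the recorded code string.
#' @param coding_system one of `"ICPC_BIFAP"`, `"ICD9"`, `"ICD9_HOSPITAL"`
#'   (hospital-discharge codes use the ICD-9 patterns).
#' @param cancer_type one of the five digestive cancer types.
#' @param codelists a `digephen_codelists` (default: shipped lists).
#' @param include_in_situ if `FALSE`, carcinoma-in-situ rubrics
#'   (ICD-9 230.x) do not match.
#' @return `TRUE`/`FALSE`.
#' @export
#' @examples
#' code_matches("150.3", "ICD9", "esophageal")     # TRUE (in 150-150.9)
#' code_matches("151.0", "ICD9", "esophageal")     # FALSE
#' code_matches("M8170/3", "ICD9", "hepatobiliary") # TRUE (morphology)
code_matches <- function(code, coding_system, cancer_type,
                         codelists = default_codelists(),
                         include_in_situ = TRUE) {
  cl <- codelists[[cancer_type]]
  if (is.null(cl)) stop_digephen("unknown cancer_type: '%s'", cancer_type)
  if (coding_system == "ICPC_BIFAP")
    return(code %in% expanded_icpc(cl))
  if (!coding_system %in% c("ICD9", "ICD9_HOSPITAL"))
    stop_digephen("unknown coding_system: '%s'", coding_system)
  if (code %in% cl$morphology) return(TRUE)
  icd9 <- cl$icd9
  if (!include_in_situ)
    icd9 <- icd9[!grepl("^230", icd9)]
  match_icd9_patterns(code, icd9)
}

#' Match a vector of episodes against all code lists at once
#'
#' Vectorised form used by the case-finding pipeline.
#'
#' @param code,coding_system parallel character vectors.
#' @inheritParams code_matches
#' @return character vector: matched cancer type per element, `NA` if none.
#' @export
match_codes <- function(code, coding_system,
                        codelists = default_codelists(),
                        include_in_situ = TRUE) {
  out <- rep(NA_character_, length(code))
  # hierarchy order so an (impossible for the defaults) double match is
  # resolved by rank, never by list position
  ranks <- vapply(codelists, `[[`, integer(1), "hierarchy_rank")
  for (ct in names(codelists)[order(ranks, decreasing = TRUE)]) {
    cl <- codelists[[ct]]
    is_icpc <- coding_system == "ICPC_BIFAP"
    hit <- logical(length(code))
    hit[is_icpc] <- code[is_icpc] %in% expanded_icpc(cl)
    idx <- which(!is_icpc)
    if (length(idx)) {
      icd9 <- cl$icd9
      if (!include_in_situ) icd9 <- icd9[!grepl("^230", icd9)]
      m <- code[idx] %in% cl$morphology
      if (length(icd9)) {
        v <- icd9_value(code[idx]); t1 <- icd9_trunc1(code[idx])
        for (p in icd9) {
          r <- parse_icd9_range(p)
          m <- m | (!is.na(v) & ((v >= r[1] & v <= r[2]) |
                                   (t1 >= r[1] & t1 <= r[2])))
        }
      }
      hit[idx] <- m
    }
    out[hit] <- ct
  }
  out
}

#' Enumerate all exact codes a code list can match
#'
#' ICD-9 ranges are expanded at one-decimal granularity; used by the
#' disjointness check.
#' @keywords internal
expanded_codes <- function(cl) {
  icd <- unlist(lapply(cl$icd9, function(p) {
    r <- parse_icd9_range(p)
    v <- seq(r[1], r[2], by = 0.1)
    sprintf("%.1f", round(v, 1))
  }), use.names = FALSE)
  c(expanded_icpc(cl), icd, cl$morphology)
}

#' Check code lists for syntax and cross-list disjointness
#'
#' Brute-force enumerates every expandable code of every list and errors if
#' any exact code is claimed by two cancer types.
#'
#' @inheritParams code_matches
#' @return invisibly `TRUE`; errors otherwise.
#' @export
check_codelists <- function(codelists = default_codelists()) {
  all_codes <- lapply(codelists, expanded_codes)
  flat <- unlist(all_codes, use.names = FALSE)
  dup <- unique(flat[duplicated(flat)])
  if (length(dup))
    stop_digephen("code(s) claimed by two cancer types: %s",
                  paste(head(dup, 10), collapse = ", "))
  invisible(TRUE)
}

#' Default "any malignancy" exclusion patterns
#'
#' Used by eligibility building to exclude patients with a pre-entry history
#' of any cancer. Non-melanoma skin cancer (ICD-9 173.x) is exempt, per the
#' usual cohort convention. ICD-9: malignant neoplasms 140–208.9 and in-situ
#' 230–234.9 (minus 173.x). ICPC-2: the malignancy rubrics across chapters.
#' Both sets are configurable by passing a like-shaped list to
#' [build_eligibility()].
#'
#' @return list with `icd9_ranges`, `icd9_exempt_ranges`, `icpc_codes`.
#' @export
any_cancer_patterns <- function() {
  list(
    icd9_ranges = c("140-172.9", "174-208.9", "230-234.9"),
    icd9_exempt_ranges = c("173-173.9"),
    icpc_codes = c("A79", "B72", "B73", "B74", "D74", "D75", "D76", "D77",
                   "L71", "N74", "R84", "R85", "S77", "T71", "U75", "U76",
                   "U77", "W72", "X75", "X76", "X77", "Y77", "Y78")
  )
}

# does the episode code indicate any malignancy (vectorised)?
matches_any_cancer <- function(code, coding_system,
                               patterns = any_cancer_patterns()) {
  out <- logical(length(code))
  is_icpc <- coding_system == "ICPC_BIFAP"
  stem <- sub("\\..*$", "", code)
  out[is_icpc] <- stem[is_icpc] %in% patterns$icpc_codes
  idx <- which(!is_icpc)
  if (length(idx)) {
    v <- icd9_value(code[idx]); t1 <- icd9_trunc1(code[idx])
    m <- logical(length(idx)); ex <- logical(length(idx))
    for (p in patterns$icd9_ranges) {
      r <- parse_icd9_range(p)
      m <- m | (!is.na(v) & ((v >= r[1] & v <= r[2]) | (t1 >= r[1] & t1 <= r[2])))
    }
    for (p in patterns$icd9_exempt_ranges) {
      r <- parse_icd9_range(p)
      ex <- ex | (!is.na(v) & ((v >= r[1] & v <= r[2]) | (t1 >= r[1] & t1 <= r[2])))
    }
    out[idx] <- m & !ex
  }
  out
}
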