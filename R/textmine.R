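#' Default Spanish text-mining lexicon
#'
#' Lexicon-based mining is how the case-finding algorithms pick up cancers
#' recorded only in physician-edited descriptors or free-text notes, and how
#' suspicions, screening activity and excluded tumour biology are told apart
#' from actual diagnoses. The default is a Spanish clinical lexicon:
#'
#' * `cancer_words`: generic malignancy words (`cancer`, `neoplasia`, ...)
#'   that must co-occur with an organ term in the same clause;
#' * `organs`: per-cancer organ/site terms;
#' * `standalone`: single terms that name a malignancy on their own
#'   (`hepatocarcinoma`, `colangiocarcinoma`, `ampuloma`);
#' * `exclude`: clause-scoped suspicion/negation/screening/family-history
#'   markers that cancel a hit (reason recorded);
#' * `reassign`: ordered context rules resolving known misrouting — hepatic
#'   angle to colorectal, gastroesophageal junction to esophageal, ampulloma
#'   to hepato-biliary;
#' * `global_exclude`: neuroendocrine and hereditary-syndrome patterns,
#'   applied after reassignment;
#' * `metastasis`: per-site metastasis phrasings used by the co-occurrence
#'   hierarchy to suppress metastatic-site candidates.
#'
#' Matching is case- and accent-insensitive; patterns are stored unaccented.
#' The same lexicon ships as YAML in
#' `system.file("extdata", "lexicon_es.yaml", package = "digephen")`.
#'
#' @return a `digephen_lexicon` list.
#' @export
default_lexicon <- function() {
  lex <- list(
    cancer_words = c("cancer", "carcinoma", "adenocarcinoma", "neoplasia",
                     "neoplasia maligna", "tumor maligno", "neo"),
    organs = list(
      esophageal = c("esofago", "esofagico", "esofagica",
                     "union gastroesofagica"),
      gastric = c("estomago", "gastrico", "gastrica", "antro gastrico"),
      pancreatic = c("pancreas", "pancreatico", "pancreatica",
                     "cabeza de pancreas", "cola de pancreas"),
      hepatobiliary = c("higado", "hepatico", "hepatica", "hepaticas",
                        "via biliar", "vias biliares", "vesicula biliar",
                        "hepatocelular"),
      colorectal = c("colon", "recto", "rectal", "colorrectal", "sigma",
                     "ciego", "colon ascendente", "colon descendente",
                     "colon transverso")),
    standalone = list(
      esophageal = character(),
      gastric = c("linitis plastica"),
      pancreatic = character(),
      hepatobiliary = c("hepatocarcinoma", "colangiocarcinoma", "hepatoma",
                        "ampuloma", "ampulloma"),
      colorectal = character()),
    exclude = list(
      suspicion = c("descartar", "sospecha", "dudoso", "posible", "probable",
                    "pendiente de confirmar", "a estudio"),
      screening = c("cribado", "screening", "sangre oculta en heces"),
      family_history = c("antecedente familiar", "antecedentes familiares",
                         "madre con", "padre con", "hermano con",
                         "hermana con"),
      negation = c("no evidencia de", "sin evidencia de", "se descarta",
                   "negativo para", "no se observa", "sin signos de")),
    reassign = list(
      list(pattern = "angulo hepatico", to = "colorectal"),
      list(pattern = "union gastroesofagica|gastroesofagic", to = "esophageal"),
      list(pattern = "ampuloma|ampulloma|ampular", to = "hepatobiliary")),
    global_exclude = list(
      neuroendocrine = c("neuroendocrino", "neuroendocrina", "carcinoide"),
      genetic_syndrome = c("sindrome de lynch", "lynch",
                           "poliposis adenomatosa familiar",
                           "cancer colorrectal hereditario")),
    metastasis = list(
      hepatobiliary = c("metastasis hepatica", "metastasis hepaticas",
                        "metastasis en higado", "metastasis en el higado"),
      pancreatic = c("metastasis pancreatica", "metastasis pancreaticas"),
      gastric = c("metastasis gastrica", "metastasis gastricas"),
      esophageal = c("metastasis esofagica"),
      colorectal = c("metastasis colonica", "metastasis colonicas"))
  )
  structure(lex, class = "digephen_lexicon")
}

#' Load a lexicon from YAML
#' @param path YAML file with the layout of [default_lexicon()].
#' @return a `digephen_lexicon`.
#' @export
load_lexicon <- function(path) {
  lex <- yaml::read_yaml(path)
  lex$cancer_words <- as.character(lex$cancer_words)
  for (part in c("organs", "standalone", "exclude", "global_exclude",
                 "metastasis"))
    lex[[part]] <- lapply(lex[[part]], as.character)
  lex$reassign <- lapply(lex$reassign, function(r)
    list(pattern = r$pattern, to = r$to))
  structure(lex, class = "digephen_lexicon")
}

#' Fold clinical text: lower-case and strip Spanish accents
#' @param x character vector.
#' @return folded character vector.
#' @export
fold_text <- function(x) {
  x <- tolower(x)
  chartr("\u00e1\u00e9\u00ed\u00f3\u00fa\u00fc\u00f1", "aeiouun", x)
}

# clause = sentence-level unit; exclusion markers only act within a clause
split_clauses <- function(text) {
  cl <- strsplit(text, "[.;:!?\u00b7\n]+")[[1]]
  cl <- trimws(cl)
  cl[nzchar(cl)]
}

term_regex <- function(term) paste0("\\b", term, "\\b")

clause_has <- function(clause, terms) {
  if (!length(terms)) return(rep(FALSE, length(clause)))
  pat <- paste(vapply(terms, term_regex, character(1)), collapse = "|")
  grepl(pat, clause, perl = TRUE)
}

first_matching_term <- function(clause, terms) {
  for (t in terms) if (grepl(term_regex(t), clause, perl = TRUE)) return(t)
  NA_character_
}

empty_hits <- function() {
  data.frame(clause_index = integer(), clause = character(),
             matched_term = character(), assigned_cancer_type = character(),
             excluded = logical(), reason = character(),
             stringsAsFactors = FALSE)
}

#' Scan one text for cancer mentions
#'
#' Splits `text` into clauses at sentence punctuation and reports, per
#' clause, every cancer type for which either (a) a generic malignancy word
#' and an organ term co-occur, or (b) a standalone malignancy term appears.
#' A clause-level suspicion/negation/screening marker cancels the clause's
#' hits (they are returned with `excluded = TRUE` and the marker class as
#' `reason`). Matching is case- and accent-insensitive.
#'
#' Reassignment ([apply_reassignment()]) and neuroendocrine/hereditary
#' exclusions ([apply_global_exclusions()]) are separate passes;
#' [mine_text()] chains all three.
#'
#' @param text a single character string (may be empty).
#' @param lexicon a `digephen_lexicon`.
#' @return data frame of hit fragments: `clause_index`, `clause`,
#'   `matched_term`, `assigned_cancer_type`, `excluded`, `reason`.
#' @export
#' @examples
#' scan_text("neoplasia de esófago", default_lexicon())
#' scan_text("descartar cáncer de colon", default_lexicon())
scan_text <- function(text, lexicon = default_lexicon()) {
  if (is.na(text) || !nzchar(trimws(text))) return(empty_hits())
  clauses <- split_clauses(fold_text(text))
  if (!length(clauses)) return(empty_hits())
  out <- empty_hits()
  has_cancer_word <- clause_has(clauses, lexicon$cancer_words)
  excl_reason <- rep(NA_character_, length(clauses))
  for (rs in names(lexicon$exclude)) {
    m <- clause_has(clauses, lexicon$exclude[[rs]])
    excl_reason[is.na(excl_reason) & m] <- rs
  }
  for (ct in names(lexicon$organs)) {
    organ_hit <- clause_has(clauses, lexicon$organs[[ct]]) & has_cancer_word
    stand_hit <- clause_has(clauses, lexicon$standalone[[ct]] %||% character())
    idx <- which(organ_hit | stand_hit)
    for (i in idx) {
      term <- if (stand_hit[i] && !organ_hit[i])
        first_matching_term(clauses[i], lexicon$standalone[[ct]])
      else first_matching_term(clauses[i], lexicon$organs[[ct]])
      out <- rbind(out, data.frame(
        clause_index = i, clause = clauses[i], matched_term = term,
        assigned_cancer_type = ct,
        excluded = !is.na(excl_reason[i]),
        reason = ifelse(is.na(excl_reason[i]), "", excl_reason[i]),
        stringsAsFactors = FALSE))
    }
  }
  out[order(out$clause_index, out$assigned_cancer_type), , drop = FALSE]
}

#' Apply ordered reassignment rules to a hit
#'
#' The first rule whose pattern matches the (folded) context wins:
#' hepatic-angle context forces colorectal, gastroesophageal-junction
#' context forces esophageal, ampulloma forces hepato-biliary. Applying the
#' rule set twice equals applying it once.
#'
#' @param hit one row of a [scan_text()] result.
#' @param context the clause or full text the hit came from.
#' @param lexicon a `digephen_lexicon`.
#' @return the hit with `assigned_cancer_type` possibly overridden.
#' @export
apply_reassignment <- function(hit, context, lexicon = default_lexicon()) {
  ctx <- fold_text(context)
  for (rule in lexicon$reassign) {
    if (grepl(rule$pattern, ctx, perl = TRUE)) {
      hit$assigned_cancer_type <- rule$to
      return(hit)
    }
  }
  hit
}

#' Mark hits in neuroendocrine / hereditary-syndrome contexts as excluded
#'
#' Neuroendocrine and genetically based digestive cancers are outside the
#' phenotype, so hits whose context carries those markers are excluded with
#' the matching reason (`"neuroendocrine"` or `"genetic_syndrome"`).
#'
#' @inheritParams apply_reassignment
#' @return the hit, possibly with `excluded = TRUE` and a reason.
#' @export
apply_global_exclusions <- function(hit, context,
                                    lexicon = default_lexicon()) {
  ctx <- fold_text(context)
  for (rs in names(lexicon$global_exclude)) {
    if (clause_has(ctx, lexicon$global_exclude[[rs]])) {
      hit$excluded <- TRUE
      hit$reason <- rs
      return(hit)
    }
  }
  hit
}

#' Full text-mining pass over one text
#'
#' [scan_text()], then per-hit clause-context reassignment, then global
#' exclusions (in that order, so an "ampuloma neuroendocrino" ends up
#' excluded rather than reassigned and kept).
#'
#' @inheritParams scan_text
#' @return hit data frame as in [scan_text()].
#' @export
mine_text <- function(text, lexicon = default_lexicon()) {
  hits <- scan_text(text, lexicon)
  if (!nrow(hits)) return(hits)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, , drop = FALSE]
    h <- apply_reassignment(h, h$clause, lexicon)
    h <- apply_global_exclusions(h, h$clause, lexicon)
    hits[i, ] <- h
  }
  hits
}

# vectorised clause-level miner used by mine_cohort(); doc_id keys back to
# the source rows
mine_many <- function(texts, lexicon) {
  folded <- fold_text(texts)
  pieces <- strsplit(folded, "[.;:!?\u00b7\n]+")
  n_cl <- lengths(pieces)
  doc <- rep(seq_along(texts), n_cl)
  clause <- trimws(unlist(pieces, use.names = FALSE))
  keep <- nzchar(clause)
  doc <- doc[keep]; clause <- clause[keep]
  if (!length(clause)) return(cbind(empty_hits(), doc_id = integer()))

  has_cw <- clause_has(clause, lexicon$cancer_words)
  excl_reason <- rep(NA_character_, length(clause))
  for (rs in names(lexicon$exclude)) {
    m <- clause_has(clause, lexicon$exclude[[rs]])
    excl_reason[is.na(excl_reason) & m] <- rs
  }
  res <- list()
  for (ct in names(lexicon$organs)) {
    organ_hit <- clause_has(clause, lexicon$organs[[ct]]) & has_cw
    stand_hit <- clause_has(clause, lexicon$standalone[[ct]] %||% character())
    idx <- which(organ_hit | stand_hit)
    if (!length(idx)) next
    res[[ct]] <- data.frame(
      doc_id = doc[idx], clause = clause[idx],
      matched_term = NA_character_, assigned_cancer_type = ct,
      excluded = !is.na(excl_reason[idx]),
      reason = ifelse(is.na(excl_reason[idx]), "", excl_reason[idx]),
      stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(doc_id = integer(), clause = character(),
                      matched_term = character(),
                      assigned_cancer_type = character(),
                      excluded = logical(), reason = character()))
  hits <- do.call(rbind, res)
  rownames(hits) <- NULL
  # reassignment: first matching ordered rule per clause
  for (rule in rev(lexicon$reassign)) {
    m <- grepl(rule$pattern, hits$clause, perl = TRUE)
    hits$assigned_cancer_type[m] <- rule$to
  }
  # global exclusions after reassignment
  for (rs in names(lexicon$global_exclude)) {
    m <- clause_has(hits$clause, lexicon$global_exclude[[rs]])
    hits$excluded[m] <- TRUE
    hits$reason[m] <- rs
  }
  hits[order(hits$doc_id, hits$assigned_cancer_type), , drop = FALSE]
}

#' Mine a whole cohort's descriptors and notes
#'
#' Descriptors are only mined on episodes whose own code does not already
#' match a digestive-cancer list (those are the descriptor-detected cases
#' "not associated with a diagnostic code"); notes are always mined.
#'
#' @param cohort a validated `digephen_cohort`.
#' @param lexicon a `digephen_lexicon`.
#' @param codelists a `digephen_codelists` used to decide which descriptors
#'   to mine.
#' @return TextHit table: `patient_id`, `source` (`descriptor`/`note`),
#'   `hit_date`, `matched_term`, `assigned_cancer_type`, `excluded`,
#'   `reason`.
#' @export
mine_cohort <- function(cohort, lexicon = default_lexicon(),
                        codelists = default_codelists()) {
  ep <- cohort$episodes
  code_ct <- match_codes(ep$code, ep$coding_system, codelists)
  desc_rows <- which(is.na(code_ct) & nzchar(ep$descriptor))
  docs <- data.frame(
    patient_id = c(ep$patient_id[desc_rows], cohort$notes$patient_id),
    source = rep(c("descriptor", "note"),
                 c(length(desc_rows), nrow(cohort$notes))),
    hit_date = c(ep$event_date[desc_rows], cohort$notes$note_date),
    text = c(ep$descriptor[desc_rows], cohort$notes$text),
    stringsAsFactors = FALSE)
  if (!nrow(docs))
    return(data.frame(patient_id = character(), source = character(),
                      hit_date = as.Date(character()),
                      matched_term = character(),
                      assigned_cancer_type = character(),
                      excluded = logical(), reason = character()))
  hits <- mine_many(docs$text, lexicon)
  data.frame(patient_id = docs$patient_id[hits$doc_id],
             source = docs$source[hits$doc_id],
             hit_date = docs$hit_date[hits$doc_id],
             matched_term = hits$clause,
             assigned_cancer_type = hits$assigned_cancer_type,
             excluded = hits$excluded, reason = hits$reason,
             stringsAsFactors = FALSE)
}

#' Metastasis-context candidate suppression
#'
#' Given the candidate cancer types seen for one patient and the patient's
#' pooled (folded) text, drops candidates that only appear as a metastatic
#' site ("cáncer de recto con metástasis hepáticas" keeps colorectal,
#' drops hepato-biliary) as long as at least one candidate survives.
#' @keywords internal
suppress_metastatic <- function(candidates, context,
                                lexicon = default_lexicon()) {
  ctx <- fold_text(context)
  drop <- vapply(candidates, function(ct) {
    pats <- lexicon$metastasis[[ct]] %||% character()
    length(pats) && clause_has(ctx, pats)
  }, logical(1))
  if (all(drop)) return(candidates)
  candidates[!drop]
}
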