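#' Construct a concept lexicon
#'
#' A lexicon maps query phrases (synonyms) to concepts of two kinds:
#' `"target"` concepts identify the substance of interest (e.g. the terms
#' "cannabis" and "marijuana" plus slang synonyms), and `"adr"` concepts are
#' layperson descriptions of adverse reactions (symptom vocabulary). Matching
#' is whole-token phrase containment after [normalize_text()], so `"pot"`
#' never matches `"potato"`.
#'
#' @param df data.frame with columns `concept_id`, `kind` (one of `"target"`,
#'   `"adr"`) and `synonym` (one synonym per row).
#' @return An object of class `lexicon`: a `data.table` with columns
#'   `concept_id`, `kind`, `synonym` (normalized), one row per unique
#'   concept/synonym pair.
#' @details Duplicate synonyms within one concept are collapsed. A synonym
#'   appearing under two different concepts of the same kind is an error,
#'   because the dictionary would be ambiguous; the same phrase may however
#'   appear under both a target and an adr concept.
#' @seealso [load_lexicon()], [match_query()]
#' @export
lexicon <- function(df) {
  need <- c("concept_id", "kind", "synonym")
  if (!all(need %in% names(df))) {
    stopf("lexicon needs columns %s", paste(need, collapse = ", "))
  }
  lx <- data.table::as.data.table(df)[, .(
    concept_id = as.character(concept_id),
    kind = as.character(kind),
    synonym = normalize_text(as.character(synonym))
  )]
  if (any(!lx$kind %in% c("target", "adr"))) {
    stopf("lexicon kind must be 'target' or 'adr', got: %s",
          paste(unique(setdiff(lx$kind, c("target", "adr"))), collapse = ", "))
  }
  if (any(lx$concept_id == "") || any(is.na(lx$concept_id))) {
    stopf("empty concept_id in lexicon")
  }
  if (any(lx$synonym == "")) {
    bad <- unique(lx$concept_id[lx$synonym == ""])
    stopf("concept(s) with empty synonym after normalization: %s",
          paste(bad, collapse = ", "))
  }
  kinds <- unique(lx[, .(concept_id, kind)])
  dup_kind <- kinds$concept_id[duplicated(kinds$concept_id)]
  if (length(dup_kind)) {
    stopf("concept(s) declared with more than one kind: %s",
          paste(unique(dup_kind), collapse = ", "))
  }
  lx <- unique(lx)
  amb <- lx[, .(n = .N), by = .(kind, synonym)][n > 1L]
  if (nrow(amb)) {
    stopf("synonym(s) shared by multiple concepts of the same kind: %s",
          paste(unique(amb$synonym), collapse = ", "))
  }
  data.table::setkeyv(lx, c("kind", "concept_id", "synonym"))
  structure(lx, class = c("lexicon", class(lx)))
}

#' Load a lexicon from target and ADR dictionary files
#'
#' Each file is a CSV with header `concept_id,kind,synonym`, one synonym per
#' row. The `kind` column of the target file must be `target` throughout, and
#' `adr` in the ADR file.
#'
#' @param target_path path to the target-substance synonym CSV.
#' @param adr_path path to the ADR concept dictionary CSV.
#' @return A validated [lexicon] object.
#' @export
load_lexicon <- function(target_path, adr_path) {
  read_one <- function(path, expected_kind) {
    if (!file.exists(path)) stopf("lexicon file not found: %s", path)
    df <- utils::read.csv(path, colClasses = "character")
    need <- c("concept_id", "kind", "synonym")
    if (!all(need %in% names(df))) {
      stopf("malformed lexicon file %s: expected columns %s", path,
            paste(need, collapse = ","))
    }
    if (nrow(df) && any(df$kind != expected_kind)) {
      stopf("file %s must contain only kind '%s'", path, expected_kind)
    }
    df
  }
  lexicon(rbind(read_one(target_path, "target"), read_one(adr_path, "adr")))
}

#' @export
print.lexicon <- function(x, ...) {
  tab <- table(unique(data.table::as.data.table(x)[, .(concept_id, kind)])$kind)
  cat(sprintf("<lexicon> %d concepts (%d target, %d adr), %d synonyms\n",
              length(unique(x$concept_id)),
              if ("target" %in% names(tab)) tab[["target"]] else 0L,
              if ("adr" %in% names(tab)) tab[["adr"]] else 0L,
              nrow(x)))
  invisible(x)
}

target_concepts <- function(lx) unique(lx$concept_id[lx$kind == "target"])
adr_concepts <- function(lx) unique(lx$concept_id[lx$kind == "adr"])

# Vectorized matcher over a character vector of (raw) texts. Returns a
# data.table(idx, concept_id, kind) with one row per (text, concept) match.
# Matching is containment of the synonym as a contiguous whole-token phrase
# in the normalized text; implemented as fixed-string search of " syn " in
# the space-padded normalized text, one pass per synonym over unique texts.
match_texts <- function(texts, lx) {
  norm <- normalize_text(texts)
  uniq <- unique(norm)
  padded <- paste0(" ", uniq, " ")
  hits <- vector("list", nrow(lx))
  for (i in seq_len(nrow(lx))) {
    j <- grep(paste0(" ", lx$synonym[i], " "), padded, fixed = TRUE)
    if (length(j)) {
      hits[[i]] <- data.table::data.table(
        uidx = j, concept_id = lx$concept_id[i], kind = lx$kind[i])
    }
  }
  hits <- data.table::rbindlist(hits)
  if (!nrow(hits)) {
    return(data.table::data.table(idx = integer(), concept_id = character(),
                                  kind = character()))
  }
  hits <- unique(hits) # two synonyms of one concept in one text
  map <- data.table::data.table(idx = seq_along(norm),
                                uidx = match(norm, uniq))
  out <- merge(map, hits, by = "uidx", allow.cartesian = TRUE)
  data.table::setorder(out, idx, kind, concept_id)
  out[, .(idx, concept_id, kind)]
}

#' Match a single query against a lexicon
#'
#' Returns the concepts whose any synonym occurs in the query as a contiguous
#' whole-token phrase, case-insensitively and ignoring punctuation. Several
#' concepts can match one query; an unmatched query yields an empty set.
#'
#' @param text a single query string.
#' @param lexicon a [lexicon] object.
#' @return character vector of matched `concept_id`s (possibly empty).
#' @export
#' @examples
#' lx <- lexicon(data.frame(
#'   concept_id = c("cannabis", "cannabis", "cough"),
#'   kind = c("target", "target", "adr"),
#'   synonym = c("cannabis", "marijuana", "cough")))
#' match_query("cough after marijuana", lx)
match_query <- function(text, lexicon) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  match_texts(text, lexicon)$concept_id
}
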