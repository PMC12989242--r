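# Rule-based extraction of performance-status mentions from clinical text.
#
# Grammar: a score keyword (ECOG family: ECOG, PS, OMS, WHO, Zubrod,
# "performance status"; Karnofsky family: Karnofsky, IK, "indice de
# Karnofsky"), an optional connector run (":", "=", "à", "de", copulas and
# negation words such as "est"/"is not"/"pas", or bare whitespace), then a
# numeric value. ECOG-family values are 0-4 (optionally "/4", optionally a
# range "1-2"); Karnofsky values are 10-100 in steps of 10 (optionally "%"
# or "/100"). A bare ECOG keyword with a Karnofsky-range value ("PS 80")
# is read as Karnofsky: clinicians mix conventions and the value range is
# the safest arbiter. Keywords match case-insensitively and must not be
# followed by a letter, so "PSA" and "IPS" never fire.

ps_pattern <- paste0(
  "(?i)\\b",
  "(?:(indice\\s+de\\s+karnofsky|karnofsky|ik)",                      # 1
  "|(performance\\s+status|ecog|zubrod|oms|who|ps))",                 # 2
  "(?!\\p{L})",
  "((?:\\s*(?:[:=]|(?:est|is|was|had|de|à|a|cotée?|côté|",
  "évaluée?|estimée?|not|non|pas)(?!\\p{L})))*)",      # 3
  "\\s*",
  "(\\d{1,3})(?!\\d)(?![.,]\\d)",                                     # 4
  "(?:\\s*[-–]\\s*(\\d{1,3})(?!\\d)(?![.,]\\d))?",               # 5
  "(?:\\s*(%)|\\s*/\\s*(\\d{1,3})(?!\\d))?"                           # 6, 7
)

karnofsky_values <- seq(10L, 100L, by = 10L)

#' Find performance-status score mentions in free text
#'
#' Scans text left to right for non-overlapping matches of a score keyword
#' followed by a valid value and returns one row per candidate mention,
#' unqualified (negation and family scoping are applied downstream by
#' [qualify_negation()] / [qualify_family()], or in one pass by
#' [extract_ps_mentions()]). Offsets are 0-based, half-open character
#' positions.
#'
#' @param text character vector of document texts (may be empty strings)
#' @param doc_id identifiers aligned with `text` (default positional)
#' @return tibble with columns doc_id, start, end, matched_text, scale
#'   (`"ECOG_FAMILY"` or `"KARNOFSKY"`), value, value_upper, negated,
#'   family (the last two all `FALSE` here)
#' @examples
#' find_ps_mentions("Etat général : OMS 1. PSA 4.5 ng/mL.")
#' @export
find_ps_mentions <- function(text, doc_id = as.character(seq_along(text))) {
  stopifnot(length(text) == length(doc_id))
  empty <- tibble::tibble(
    doc_id = character(), start = integer(), end = integer(),
    matched_text = character(), scale = character(), value = integer(),
    value_upper = integer(), negated = logical(), family = logical()
  )
  if (length(text) == 0) return(empty)
  loc <- stringr::str_locate_all(text, ps_pattern)
  grp <- stringr::str_match_all(text, ps_pattern)
  out <- purrr::map2(seq_along(text), doc_id, function(i, id) {
    m <- grp[[i]]
    if (nrow(m) == 0) return(NULL)
    parsed <- parse_ps_match(m)
    keep <- !is.na(parsed$scale)
    if (!any(keep)) return(NULL)
    tibble::tibble(
      doc_id = as.character(id),
      start = loc[[i]][keep, 1] - 1L,
      end = loc[[i]][keep, 2],
      matched_text = m[keep, 1],
      scale = parsed$scale[keep],
      value = parsed$value[keep],
      value_upper = parsed$value_upper[keep],
      negated = FALSE,
      family = FALSE
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty else res
}

# Validate raw regex matches and resolve the scale. A row whose value (or
# range/denominator) is inconsistent with any scale is rejected.
parse_ps_match <- function(m) {
  karn_kw <- !is.na(m[, 2])
  v <- as.integer(m[, 5])
  upper <- suppressWarnings(as.integer(m[, 6]))
  pct <- !is.na(m[, 7])
  denom <- suppressWarnings(as.integer(m[, 8]))

  scale <- rep(NA_character_, nrow(m))
  is_k_val <- v %in% karnofsky_values
  is_e_val <- !is.na(v) & v >= 0 & v <= 4

  scale[karn_kw & is_k_val] <- "KARNOFSKY"
  ecog_kw <- !karn_kw
  scale[ecog_kw & !is.na(denom) & denom == 4 & is_e_val] <- "ECOG_FAMILY"
  scale[ecog_kw & ((!is.na(denom) & denom == 100) | pct) & is_k_val] <- "KARNOFSKY"
  plain <- ecog_kw & is.na(denom) & !pct
  scale[plain & is_e_val] <- "ECOG_FAMILY"
  scale[plain & !is_e_val & is_k_val] <- "KARNOFSKY"

  # denominators other than the scale's own invalidate the match
  bad_denom <- !is.na(denom) &
    !(denom == 4 & scale %in% "ECOG_FAMILY") &
    !(denom == 100 & scale %in% "KARNOFSKY")
  scale[bad_denom] <- NA_character_
  has_up <- !is.na(upper)
  bad_up_e <- has_up & scale %in% "ECOG_FAMILY" & !(upper >= 0 & upper <= 4 & upper >= v)
  bad_up_k <- has_up & scale %in% "KARNOFSKY" &
    !(upper %in% karnofsky_values & upper >= v)
  scale[bad_up_e | bad_up_k] <- NA_character_

  list(scale = scale, value = v, value_upper = upper)
}

# Locate the sentence (period/newline delimited) containing position `pos`
# (0-based). Returns 0-based half-open sentence bounds.
sentence_bounds <- function(text, pos) {
  brks <- stringr::str_locate_all(text, "[.\\n]")[[1]][, 1]
  lo <- brks[brks <= pos]  # 1-based positions of breaks at/before pos
  start <- if (length(lo)) max(lo) else 0L
  hi <- brks[brks > pos + 1]
  end <- if (length(hi)) min(hi) - 1L else nchar(text, type = "chars")
  c(start = as.integer(start), end = as.integer(end))
}

# Tokens of a sentence with 0-based half-open offsets (whitespace split,
# surrounding punctuation stripped for cue matching).
sentence_tokens <- function(text, bounds) {
  sent <- stringr::str_sub(text, bounds[["start"]] + 1, bounds[["end"]])
  loc <- stringr::str_locate_all(sent, "\\S+")[[1]]
  if (nrow(loc) == 0) {
    return(tibble::tibble(token = character(), start = integer(),
                          end = integer()))
  }
  tok <- stringr::str_sub(sent, loc[, 1], loc[, 2])
  tibble::tibble(
    token = stringr::str_to_lower(
      stringr::str_remove_all(tok, "^[[:punct:]]+|[[:punct:]]+$")
    ),
    start = bounds[["start"]] + loc[, 1] - 1L,
    end = bounds[["start"]] + loc[, 2]
  )
}

default_negation_lexicon <- c("not", "no", "pas", "non", "sans", "aucun",
                              "aucune")
default_family_lexicon <- c("mother", "father", "mère", "père",
                            "frère", "sœur", "soeur", "fils",
                            "fille", "famille", "familiaux", "familiale")

#' Qualify mentions as negated
#'
#' A mention is negated when a negation cue occurs in the same sentence
#' (periods/newlines delimit sentences) within `window` tokens preceding
#' the mention, or inside the mention span itself ("PS is not 0").
#'
#' @param text the single document text the mentions came from
#' @param mentions mention tibble from [find_ps_mentions()] for that text
#' @param lexicon negation cue words, matched on punctuation-stripped
#'   lowercased tokens
#' @param window number of preceding tokens searched (default 5)
#' @return `mentions` with the `negated` column updated
#' @examples
#' txt <- "PS is not 0."
#' qualify_negation(txt, find_ps_mentions(txt))
#' @export
qualify_negation <- function(text, mentions,
                             lexicon = default_negation_lexicon,
                             window = 5) {
  if (nrow(mentions) == 0) return(mentions)
  mentions$negated <- vapply(seq_len(nrow(mentions)), function(i) {
    b <- sentence_bounds(text, mentions$start[i])
    toks <- sentence_tokens(text, b)
    before <- toks[toks$end <= mentions$start[i], , drop = FALSE]
    before <- utils::tail(before, window)
    inside <- toks[toks$start < mentions$end[i] &
                     toks$end > mentions$start[i], , drop = FALSE]
    any(c(before$token, inside$token) %in% lexicon)
  }, logical(1))
  mentions
}

#' Qualify mentions as family-attributed
#'
#' A mention refers to a relative when a kinship cue occurs earlier in the
#' same sentence ("mother had PS = 3"). Cues after the mention do not
#' count ("PS 2; family informed" stays a patient mention).
#'
#' @inheritParams qualify_negation
#' @param lexicon kinship cue words
#' @return `mentions` with the `family` column updated
#' @examples
#' txt <- "Mother had PS = 3."
#' qualify_family(txt, find_ps_mentions(txt))
#' @export
qualify_family <- function(text, mentions,
                           lexicon = default_family_lexicon) {
  if (nrow(mentions) == 0) return(mentions)
  mentions$family <- vapply(seq_len(nrow(mentions)), function(i) {
    b <- sentence_bounds(text, mentions$start[i])
    toks <- sentence_tokens(text, b)
    before <- toks[toks$end <= mentions$start[i], , drop = FALSE]
    any(before$token %in% lexicon)
  }, logical(1))
  mentions
}

#' Extract and qualify mentions for a table of documents
#'
#' One-pass convenience wrapper: runs [find_ps_mentions()] then the
#' negation and family qualifiers on each document of a document table.
#'
#' @param documents tibble with at least `doc_id` and `text` columns
#' @param negation_lexicon,family_lexicon cue overrides
#' @param negation_window token window for negation scoping
#' @return qualified mention tibble (possibly zero rows)
#' @export
extract_ps_mentions <- function(documents,
                                negation_lexicon = default_negation_lexicon,
                                family_lexicon = default_family_lexicon,
                                negation_window = 5) {
  stopifnot(all(c("doc_id", "text") %in% names(documents)))
  raw <- find_ps_mentions(documents$text, documents$doc_id)
  if (nrow(raw) == 0) return(raw)
  txt <- stats::setNames(documents$text, documents$doc_id)
  raw |>
    dplyr::group_split(.data$doc_id) |>
    purrr::map(function(m) {
      t <- txt[[m$doc_id[1]]]
      m <- qualify_negation(t, m, negation_lexicon, negation_window)
      qualify_family(t, m, family_lexicon)
    }) |>
    dplyr::bind_rows()
}

#' Convert a Karnofsky score to the ECOG scale
#'
#' Standard correspondence: 100-90 -> 0, 80-70 -> 1, 60-50 -> 2,
#' 40-30 -> 3, 20-10 -> 4. Monotone non-increasing in the Karnofsky value.
#'
#' @param k integer vector of Karnofsky scores (10-100, step 10)
#' @return integer ECOG scores in 0-4
#' @examples
#' karnofsky_to_ecog(c(100, 70, 10))
#' @export
karnofsky_to_ecog <- function(k) {
  if (any(!k %in% karnofsky_values)) {
    abort("Karnofsky scores must be in 10, 20, ..., 100.")
  }
  as.integer(5 - ceiling(k / 20))
}

#' Document- and patient-level documentation labels
#'
#' A document contains a performance status when it has at least one
#' mention that is neither negated nor family-attributed. A patient has a
#' documented status when any of their (already window-filtered) documents
#' does.
#'
#' @param mentions qualified mention tibble for a single document
#' @return logical scalar
#' @examples
#' document_has_ps(extract_ps_mentions(
#'   tibble::tibble(doc_id = "d1", text = "OMS 2 ce jour.")))
#' @export
document_has_ps <- function(mentions) {
  nrow(mentions) > 0 && any(!mentions$negated & !mentions$family)
}

#' @rdname document_has_ps
#' @param documents document tibble with `doc_id` (and optionally
#'   `patient_id`) columns
#' @param mentions_all qualified mentions for all documents, as returned by
#'   [extract_ps_mentions()]
#' @return `label_documents()`: the document tibble with a logical
#'   `has_ps` column
#' @export
label_documents <- function(documents, mentions_all) {
  lab <- mentions_all |>
    dplyr::filter(!.data$negated, !.data$family) |>
    dplyr::distinct(.data$doc_id) |>
    dplyr::mutate(has_ps = TRUE)
  documents |>
    dplyr::left_join(lab, by = "doc_id") |>
    dplyr::mutate(has_ps = dplyr::coalesce(.data$has_ps, FALSE))
}

#' @rdname document_has_ps
#' @param labelled_documents in-window documents with `patient_id` and
#'   `has_ps` columns
#' @return `patient_has_ps()`: tibble with one row per patient and a
#'   logical `has_ps`
#' @export
patient_has_ps <- function(labelled_documents) {
  labelled_documents |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(has_ps = any(.data$has_ps), .groups = "drop")
}
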