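# Incident-cancer cohort construction from ICD-10 claims events.

#' Identify incident cancer diagnoses with a 24-month washout
#'
#' A patient is incident when their earliest cancer code inside the study
#' window has no cancer code in the preceding 730 days (open interval: a
#' code exactly 730 days earlier does not block incidence). The index date
#' is that earliest in-window code date.
#'
#' @param events claims tibble: patient_id, code, date, hospital_id
#' @param study_start,study_end study window for index dates (inclusive)
#' @param washout_days look-back length, default 730
#' @param include_d_codes also count in-situ (D00-D09) and
#'   uncertain-behaviour (D37-D48) codes as cancer codes
#' @return tibble patient_id, index_date for incident patients only
#' @examples
#' ev <- tibble::tibble(patient_id = "p1", code = "C50.9",
#'                      date = as.Date("2019-06-01"), hospital_id = "H01")
#' find_incident_cases(ev)
#' @export
find_incident_cases <- function(events,
                                study_start = as.Date("2019-01-01"),
                                study_end = as.Date("2021-06-01"),
                                washout_days = 730,
                                include_d_codes = FALSE) {
  ca <- events |>
    dplyr::filter(is_cancer_code(.data$code, include_d_codes)) |>
    dplyr::arrange(.data$patient_id, .data$date)
  if (nrow(ca) == 0) {
    return(tibble::tibble(patient_id = character(),
                          index_date = as.Date(character())))
  }
  first_in <- ca |>
    dplyr::filter(.data$date >= study_start, .data$date <= study_end) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(index_date = min(.data$date), .groups = "drop")
  prior <- ca |>
    dplyr::inner_join(first_in, by = "patient_id") |>
    dplyr::filter(.data$date > .data$index_date - washout_days,
                  .data$date < .data$index_date) |>
    dplyr::distinct(.data$patient_id)
  dplyr::anti_join(first_in, prior, by = "patient_id")
}

#' Assign cancer group and diagnosing hospital from the first code
#'
#' Uses the event(s) on the index date; ties on the same date are broken
#' by lexicographic code, then input order. Later cancer codes are never
#' re-checked: the group is fixed at the first code.
#'
#' @param events claims tibble
#' @param incident tibble from [find_incident_cases()]
#' @inheritParams find_incident_cases
#' @return `incident` with cancer_group, first_code and hospital_id added
#' @export
assign_group_hospital <- function(events, incident, include_d_codes = FALSE) {
  events |>
    dplyr::filter(is_cancer_code(.data$code, include_d_codes)) |>
    dplyr::inner_join(incident, by = "patient_id") |>
    dplyr::filter(.data$date == .data$index_date) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(.data$code, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      index_date = .data$index_date,
      first_code = .data$code,
      cancer_group = cancer_group_from_code(.data$code),
      hospital_id = .data$hospital_id
    )
}

#' Restrict documents to the analysis window around the index date
#'
#' Keeps MDT, consultation and hospitalization reports dated between 90
#' days before and 365 days after the index date, both bounds inclusive.
#'
#' @param documents document tibble with patient_id, doc_type, date
#' @param index tibble patient_id, index_date
#' @param days_before,days_after window half-widths (positive numbers)
#' @return the in-window subset, with index_date joined on
#' @export
window_documents <- function(documents, index,
                             days_before = 90, days_after = 365) {
  documents |>
    dplyr::inner_join(index[, c("patient_id", "index_date")],
                      by = "patient_id") |>
    dplyr::filter(
      .data$doc_type %in% c("MDT", "CONSULTATION", "HOSPITALIZATION"),
      .data$date >= .data$index_date - days_before,
      .data$date <= .data$index_date + days_after
    )
}

#' Apply the cohort exclusion cascade
#'
#' Ordered, logged exclusions: (1) age under 18 at index; (2) first code
#' recorded in a hospital holding less than `hospital_min_share` of all
#' incident diagnoses (share computed once, before any exclusion) or in a
#' hospital flagged paediatric; (3) sex-cancer inconsistency (male
#' gynaecological, female prostate; male breast cancer is retained);
#' (4) no in-window document of the three report types.
#'
#' @param candidates tibble from [assign_group_hospital()]
#' @param patients patient tibble with patient_id, sex, birth_date
#' @param documents document tibble
#' @param hospital_min_share minimum share of incident diagnoses, default 0.01
#' @param paediatric_hospitals hospital ids excluded outright
#' @param days_before,days_after document window bounds
#' @return list: `cohort` (retained candidates with age_at_dx and document
#'   counts) and `log`, a tibble (step, n_removed, n_remaining)
#' @export
apply_exclusions <- function(candidates, patients, documents,
                             hospital_min_share = 0.01,
                             paediatric_hospitals = character(),
                             days_before = 90, days_after = 365) {
  share <- candidates |>
    dplyr::count(.data$hospital_id) |>
    dplyr::mutate(share = .data$n / sum(.data$n))
  small_hosp <- share$hospital_id[share$share < hospital_min_share]

  cur <- candidates |>
    dplyr::inner_join(
      dplyr::select(patients, "patient_id", "sex", "birth_date"),
      by = "patient_id"
    ) |>
    dplyr::mutate(
      age_at_dx = floor(as.numeric(.data$index_date - .data$birth_date) / 365.25)
    )
  log <- list()
  note <- function(step, before, after) {
    tibble::tibble(step = step, n_removed = before - after, n_remaining = after)
  }

  n0 <- nrow(cur)
  cur <- dplyr::filter(cur, .data$age_at_dx >= 18)
  log <- c(log, list(note("age_under_18", n0, nrow(cur))))

  n1 <- nrow(cur)
  cur <- dplyr::filter(
    cur, !.data$hospital_id %in% c(small_hosp, paediatric_hospitals)
  )
  log <- c(log, list(note("small_or_paediatric_hospital", n1, nrow(cur))))

  n2 <- nrow(cur)
  cur <- dplyr::filter(
    cur,
    !(.data$sex == "M" & .data$cancer_group == "Gynaecological"),
    !(.data$sex == "F" & .data$cancer_group == "Prostate")
  )
  log <- c(log, list(note("sex_cancer_mismatch", n2, nrow(cur))))

  n3 <- nrow(cur)
  counts <- window_documents(documents, cur, days_before, days_after) |>
    dplyr::count(.data$patient_id, .data$doc_type) |>
    tidyr::pivot_wider(names_from = "doc_type", values_from = "n",
                       values_fill = 0L)
  for (col in c("MDT", "CONSULTATION", "HOSPITALIZATION")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  cur <- cur |>
    dplyr::left_join(counts, by = "patient_id") |>
    dplyr::mutate(dplyr::across(c("MDT", "CONSULTATION", "HOSPITALIZATION"),
                                ~ tidyr::replace_na(.x, 0L))) |>
    dplyr::rename(n_mdt = "MDT", n_consult = "CONSULTATION",
                  n_hosp = "HOSPITALIZATION") |>
    dplyr::filter(.data$n_mdt + .data$n_consult + .data$n_hosp >= 1)
  log <- c(log, list(note("no_document", n3, nrow(cur))))

  list(cohort = cur, log = dplyr::bind_rows(log))
}

#' Derive metastatic status and one-year mortality
#'
#' Metastatic at diagnosis means a secondary-neoplasm code (C77-C79 by
#' default) dated within 0 to +90 days of index, inclusive. Death within
#' one year means a death date at or before index + 365 days. A death
#' date before the index date is inconsistent data; it raises a warning
#' and counts as a one-year death.
#'
#' @param cohort tibble with patient_id, index_date
#' @param events claims tibble
#' @param patients patient tibble with death_date
#' @param metastasis_prefixes 3-character code prefixes counted as
#'   metastasis
#' @param metastasis_window_days upper bound of the metastasis window
#' @return `cohort` with logical metastatic_at_dx and died_within_1y
#' @export
derive_outcomes <- function(cohort, events, patients,
                            metastasis_prefixes = c("C77", "C78", "C79"),
                            metastasis_window_days = 90) {
  met <- events |>
    dplyr::filter(is_metastasis_code(.data$code, metastasis_prefixes)) |>
    dplyr::inner_join(cohort[, c("patient_id", "index_date")],
                      by = "patient_id") |>
    dplyr::filter(.data$date >= .data$index_date,
                  .data$date <= .data$index_date + metastasis_window_days) |>
    dplyr::distinct(.data$patient_id) |>
    dplyr::mutate(metastatic_at_dx = TRUE)
  out <- cohort |>
    dplyr::left_join(met, by = "patient_id") |>
    dplyr::mutate(metastatic_at_dx = dplyr::coalesce(.data$metastatic_at_dx,
                                                     FALSE)) |>
    dplyr::left_join(dplyr::select(patients, "patient_id", "death_date"),
                     by = "patient_id") |>
    dplyr::mutate(
      died_within_1y = !is.na(.data$death_date) &
        .data$death_date <= .data$index_date + 365
    )
  bad <- !is.na(out$death_date) & out$death_date < out$index_date
  if (any(bad)) {
    warn(sprintf(
      "%d patient(s) have a death date before the index date; counted as 1-year deaths.",
      sum(bad)
    ))
  }
  dplyr::select(out, -"death_date")
}

#' Build the full analysis cohort
#'
#' End-to-end wrapper: incidence with washout, group and hospital
#' assignment, exclusion cascade, document windowing and counting,
#' outcome derivation, and the per-patient documentation label taken from
#' document-level extraction results.
#'
#' @param patients,events,documents input tibbles (documents must carry a
#'   logical `has_ps` column, e.g. from [label_documents()])
#' @inheritParams find_incident_cases
#' @inheritParams apply_exclusions
#' @inheritParams derive_outcomes
#' @return list: `cohort` tibble (one analysis row per patient) and
#'   `log`, the exclusion cascade
#' @export
build_cohort <- function(patients, events, documents,
                         study_start = as.Date("2019-01-01"),
                         study_end = as.Date("2021-06-01"),
                         washout_days = 730,
                         include_d_codes = FALSE,
                         hospital_min_share = 0.01,
                         paediatric_hospitals = character(),
                         days_before = 90, days_after = 365,
                         metastasis_prefixes = c("C77", "C78", "C79"),
                         metastasis_window_days = 90) {
  stopifnot("has_ps" %in% names(documents))
  incident <- find_incident_cases(events, study_start, study_end,
                                  washout_days, include_d_codes)
  candidates <- assign_group_hospital(events, incident, include_d_codes)
  excl <- apply_exclusions(candidates, patients, documents,
                           hospital_min_share, paediatric_hospitals,
                           days_before, days_after)
  cohort <- excl$cohort
  inwin <- window_documents(documents, cohort, days_before, days_after)
  labels <- patient_has_ps(inwin)
  cohort <- cohort |>
    dplyr::left_join(labels, by = "patient_id") |>
    dplyr::mutate(has_ps = dplyr::coalesce(.data$has_ps, FALSE))
  cohort <- derive_outcomes(cohort, events, patients,
                            metastasis_prefixes, metastasis_window_days)
  cohort <- dplyr::select(
    cohort, "patient_id", "index_date", "sex", "age_at_dx", "cancer_group",
    "first_code", "hospital_id", "n_mdt", "n_consult", "n_hosp",
    "metastatic_at_dx", "has_ps", "died_within_1y"
  )
  list(cohort = cohort, log = excl$log)
}
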