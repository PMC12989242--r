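# File-based pipeline orchestration. Stages communicate only through files
# with documented schemas (CSV for tables, JSONL for documents/mentions,
# JSON for metrics), so each stage is independently testable and the run
# directory is a complete record.

#' Write a simulated EHR extract to disk
#'
#' Writes `patients.csv`, `events.csv`, `documents.jsonl` (one JSON object
#' per document, gold annotations under a `"gold"` key) and a
#' `manifest.json` recording the seed and a hash of the full
#' configuration. All dates are ISO-8601; files are UTF-8 with headers.
#'
#' @param ehr result of [simulate_ehr()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_synthetic_data <- function(ehr, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(ehr$patients, file.path(dir, "patients.csv"))
  readr::write_csv(ehr$events, file.path(dir, "events.csv"))
  write_documents_jsonl(ehr$documents, file.path(dir, "documents.jsonl"))
  manifest <- list(
    seed = ehr$config$seed,
    n_patients = ehr$config$n_patients,
    config_hash = rlang::hash(ehr$config),
    n_documents = nrow(ehr$documents)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

write_documents_jsonl <- function(documents, path) {
  lines <- purrr::pmap_chr(documents, function(...) {
    d <- list(...)
    rec <- list(
      doc_id = d$doc_id, patient_id = d$patient_id, doc_type = d$doc_type,
      date = format(d$date), cancer_coded_stay = d$cancer_coded_stay,
      text = d$text
    )
    if (!is.null(d$gold_has_ps)) {
      rec$gold <- list(has_ps = d$gold_has_ps, spans = d$gold_spans)
    }
    jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null", dataframe = "rows")
  })
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
}

#' Read a documents.jsonl file back into a tibble
#'
#' @param path path to a documents JSONL file written by
#'   [write_synthetic_data()]
#' @return document tibble; gold annotations, when present, are restored
#'   as `gold_has_ps` and the `gold_spans` list column
#' @export
read_documents_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  empty_spans <- tibble::tibble(
    start = integer(), end = integer(), scale = character(),
    value = integer(), value_upper = integer(), negated = logical(),
    family = logical()
  )
  recs <- purrr::map(lines, function(l) {
    r <- jsonlite::fromJSON(l, simplifyDataFrame = TRUE)
    tibble::tibble(
      doc_id = r$doc_id, patient_id = r$patient_id, doc_type = r$doc_type,
      date = as.Date(r$date),
      cancer_coded_stay = r$cancer_coded_stay %||% NA,
      text = r$text,
      gold_has_ps = if (is.null(r$gold)) NA else r$gold$has_ps,
      gold_spans = list(
        if (is.null(r$gold) || length(r$gold$spans) == 0) empty_spans
        else tibble::as_tibble(r$gold$spans)
      )
    )
  })
  dplyr::bind_rows(recs)
}

#' Simulate and persist a synthetic dataset
#'
#' @param config a [generator_config()]
#' @param out_dir output directory
#' @return the output directory, invisibly
#' @export
run_simulate <- function(config, out_dir) {
  ehr <- simulate_ehr(config)
  write_synthetic_data(ehr, out_dir)
}

#' Run the full analysis pipeline on an input directory
#'
#' Reads `patients.csv`, `events.csv` and `documents.jsonl` from
#' `input_dir`, then: extracts and qualifies score mentions
#' (`mentions.csv`), labels documents, builds the incident cohort
#' (`cohort.csv`, `exclusions.log`), tabulates prevalence
#' (`prevalence_*.csv`), computes the hospital volume-documentation rank
#' correlation (`spearman.csv`), evaluates the extractor against gold
#' annotations when they are present (`extraction_metrics.json`), fits
#' the two documentation-propensity models (`coefficients.csv`), and
#' writes a plain-text `summary.txt` of the headline statistics. Any
#' stage failure aborts with the stage name.
#'
#' @param input_dir directory with the three input files
#' @param out_dir directory for results (created if needed)
#' @param ... cohort-construction options passed to [build_cohort()]
#' @return tibble of written files, invisibly
#' @export
run_full <- function(input_dir, out_dir, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  inputs <- stage("read_inputs", {
    list(
      patients = readr::read_csv(file.path(input_dir, "patients.csv"),
                                 show_col_types = FALSE),
      events = readr::read_csv(file.path(input_dir, "events.csv"),
                               show_col_types = FALSE),
      documents = read_documents_jsonl(file.path(input_dir, "documents.jsonl"))
    )
  })

  mentions <- stage("extract", extract_ps_mentions(inputs$documents))
  readr::write_csv(mentions, file.path(out_dir, "mentions.csv"))
  docs <- stage("label", label_documents(inputs$documents, mentions))

  built <- stage("cohort", build_cohort(inputs$patients, inputs$events,
                                        docs, ...))
  cohort <- built$cohort
  readr::write_csv(cohort, file.path(out_dir, "cohort.csv"))
  readr::write_tsv(built$log, file.path(out_dir, "exclusions.log"))

  stage("prevalence", {
    readr::write_csv(patient_prevalence(cohort, "hospital_id"),
                     file.path(out_dir, "prevalence_by_hospital.csv"))
    readr::write_csv(patient_prevalence(cohort, "cancer_group"),
                     file.path(out_dir, "prevalence_by_cancer_group.csv"))
    inwin <- window_documents(docs, cohort)
    readr::write_csv(document_prevalence(inwin, "doc_type"),
                     file.path(out_dir, "prevalence_by_doc_type.csv"))
  })

  sp <- stage("spearman", {
    inwin <- window_documents(docs, cohort) |>
      dplyr::inner_join(
        dplyr::select(cohort, "patient_id", "hospital_id"),
        by = "patient_id"
      )
    by_type <- inwin |>
      dplyr::group_by(.data$doc_type, .data$hospital_id) |>
      dplyr::summarise(n_docs = dplyr::n(), prop = mean(.data$has_ps),
                       .groups = "drop")
    res <- by_type |>
      dplyr::group_by(.data$doc_type) |>
      dplyr::group_modify(function(d, g) {
        if (nrow(d) < 3) {
          return(tibble::tibble(rho = NA_real_, p_value = NA_real_,
                                n = nrow(d), method = "insufficient data"))
        }
        spearman_volume_correlation(d$n_docs, d$prop)
      }) |>
      dplyr::ungroup()
    readr::write_csv(res, file.path(out_dir, "spearman.csv"))
    res
  })

  metrics <- NULL
  if ("gold_has_ps" %in% names(inputs$documents) &&
      !anyNA(inputs$documents$gold_has_ps)) {
    metrics <- stage("evaluate", evaluate_extraction(
      dplyr::select(docs, "doc_id", "has_ps"),
      dplyr::select(inputs$documents, "doc_id", "doc_type", "gold_has_ps")
    ))
    jsonlite::write_json(metrics, file.path(out_dir, "extraction_metrics.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  fits <- stage("fit", tryCatch({
    cmp <- compare_ps_models(cohort)
    coefs <- dplyr::bind_rows(
      dplyr::mutate(cmp$without$coefficients, model_variant = "without_metastatic"),
      dplyr::mutate(cmp$with$coefficients, model_variant = "with_metastatic")
    )
    readr::write_csv(coefs, file.path(out_dir, "coefficients.csv"))
    cmp
  }, error = function(e) {
    writeLines(paste("model fitting skipped:", conditionMessage(e)),
               file.path(out_dir, "coefficients.SKIPPED"))
    NULL
  }))

  stage("summary", {
    overall <- patient_prevalence(cohort)
    mort <- mortality_by_documentation(cohort)
    lines <- c(
      sprintf("patients in cohort: %d", nrow(cohort)),
      sprintf("patient-level PS documentation: %.1f%%",
              100 * overall$proportion),
      sprintf("1-year mortality, documented PS: %.1f%%",
              100 * mort$proportion[mort$has_ps]),
      sprintf("1-year mortality, no documented PS: %.1f%%",
              100 * mort$proportion[!mort$has_ps]),
      sprintf("extraction macro-F1 (overall): %s",
              if (is.null(metrics)) "n/a" else
                sprintf("%.3f", metrics$macro_f1[metrics$doc_type == "overall"])),
      sprintf("metastatic OR: %s",
              if (is.null(fits)) "n/a" else {
                met <- dplyr::filter(fits$with$coefficients,
                                     .data$term == "metastatic_at_dxTRUE")
                sprintf("%.2f [%.2f; %.2f]",
                        met$odds_ratio, met$ci_low, met$ci_high)
              })
    )
    writeLines(lines, file.path(out_dir, "summary.txt"))
  })

  invisible(tibble::tibble(file = list.files(out_dir, full.names = TRUE)))
}
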