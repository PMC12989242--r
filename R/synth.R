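#' Simulate patients and ICD-10 claims events
#'
#' Draws a synthetic patient table and claims-event table with the joint
#' structure the downstream analysis assumes: every patient has a primary
#' cancer code on their intended index date, a configurable fraction are
#' "washout violators" with an additional cancer code 1-24 months earlier
#' (so the incident-diagnosis filter has true positives), metastatic
#' patients receive a secondary-neoplasm code (C77-C79) within 90 days of
#' index, and death dates follow the latent performance-status model.
#' Ground-truth columns are prefixed `gold_` and never consulted by the
#' analysis modules.
#'
#' @param config a [generator_config()]
#' @return list with tibbles `patients` (patient_id, sex, birth_date,
#'   death_date, gold_* truth columns) and `events` (patient_id, code,
#'   date, hospital_id)
#' @examples
#' sim <- simulate_cohort(generator_config(n_patients = 20, seed = 1))
#' sim$patients
#' @export
simulate_cohort <- function(config) {
  config <- validate_generator_config(config)
  n <- config$n_patients
  empty <- list(
    patients = tibble::tibble(
      patient_id = character(), sex = character(),
      birth_date = as.Date(character()), death_date = as.Date(character()),
      gold_index_date = as.Date(character()), gold_age = integer(),
      gold_cancer_group = character(),
      gold_hospital_id = character(), gold_metastatic = logical(),
      gold_latent_ps = integer(), gold_washout_violator = logical()
    ),
    events = tibble::tibble(
      patient_id = character(), code = character(),
      date = as.Date(character()), hospital_id = character()
    )
  )
  if (n == 0) return(empty)

  withr::with_seed(derive_seed(config$seed, "cohort"), {
    pat <- draw_patient_covariates(n, config)
    # Washout violators get a cancer code 1-24 months before index that
    # predates the study window, so the incident filter must drop them.
    # Their index dates are kept within 698 days of study start so such a
    # prior code always exists.
    violator <- rbinom(n, 1, config$washout_violator_frac) == 1
    early_span <- min(698L, as.integer(config$study_end - config$study_start))
    pat$gold_index_date[violator] <- config$study_start +
      sample.int(early_span + 1L, sum(violator), replace = TRUE) - 1L
    pp <- config$mortality_params
    p_die <- plogis(qlogis(pp$baseline_p) +
                      pp$poor_ps_log_or * (pat$gold_latent_ps >= 2))
    died_1y <- rbinom(n, 1, p_die) == 1
    death_offset <- ifelse(
      died_1y, sample.int(366, n, replace = TRUE) - 1L,
      ifelse(runif(n) < 0.05, sample(366:540, n, replace = TRUE), NA_integer_)
    )
    death_date <- pat$gold_index_date + death_offset

    # birth date such that completed age at index equals the drawn age
    day_offset <- sample(5:360, n, replace = TRUE)
    birth_date <- pat$gold_index_date - round(pat$gold_age * 365.25) - day_offset

    patients <- tibble::tibble(
      patient_id = pat$patient_id,
      sex = pat$sex,
      birth_date = birth_date,
      death_date = death_date,
      gold_index_date = pat$gold_index_date,
      gold_age = pat$gold_age,
      gold_cancer_group = pat$gold_cancer_group,
      gold_hospital_id = pat$gold_hospital_id,
      gold_metastatic = pat$gold_metastatic,
      gold_latent_ps = pat$gold_latent_ps,
      gold_washout_violator = violator
    )

    primary_code <- purrr::map_chr(
      patients$gold_cancer_group,
      function(g) sample(group_code_pool[[g]], 1)
    )
    events <- tibble::tibble(
      patient_id = patients$patient_id,
      code = primary_code,
      date = patients$gold_index_date,
      hospital_id = patients$gold_hospital_id
    )
    # follow-up coding of the same primary after index
    has_fu <- runif(n) < 0.5
    if (any(has_fu)) {
      events <- dplyr::bind_rows(events, tibble::tibble(
        patient_id = patients$patient_id[has_fu],
        code = primary_code[has_fu],
        date = patients$gold_index_date[has_fu] +
          sample(30:300, sum(has_fu), replace = TRUE),
        hospital_id = patients$gold_hospital_id[has_fu]
      ))
    }
    viol <- patients$gold_washout_violator
    if (any(viol)) {
      since_start <- as.integer(patients$gold_index_date[viol] -
                                  config$study_start)
      back <- vapply(since_start, function(d) {
        sample(seq(max(31L, d + 1L), 729L), 1)
      }, numeric(1))
      events <- dplyr::bind_rows(events, tibble::tibble(
        patient_id = patients$patient_id[viol],
        code = purrr::map_chr(patients$gold_cancer_group[viol],
                              function(g) sample(group_code_pool[[g]], 1)),
        date = patients$gold_index_date[viol] - back,
        hospital_id = patients$gold_hospital_id[viol]
      ))
    }
    met <- patients$gold_metastatic
    if (any(met)) {
      events <- dplyr::bind_rows(events, tibble::tibble(
        patient_id = patients$patient_id[met],
        code = sample(c("C77.9", "C78.0", "C78.7", "C79.5"),
                      sum(met), replace = TRUE),
        date = patients$gold_index_date[met] +
          sample.int(90, sum(met), replace = TRUE),
        hospital_id = patients$gold_hospital_id[met]
      ))
    }
    events <- dplyr::arrange(events, .data$patient_id, .data$date, .data$code)
    list(patients = patients, events = events)
  })
}

# Shared covariate draw for the full and fast simulation paths.
draw_patient_covariates <- function(n, config) {
  group <- sample(names(config$cancer_group_weights), n, replace = TRUE,
                  prob = config$cancer_group_weights)
  hospital <- sample(names(config$hospital_weights), n, replace = TRUE,
                     prob = config$hospital_weights)
  sex <- ifelse(runif(n) < 0.53, "M", "F")
  sex[group == "Gynaecological"] <- "F"
  sex[group == "Prostate"] <- "M"
  nb <- sum(group == "Breast")
  sex[group == "Breast"] <- ifelse(runif(nb) < 0.99, "F", "M")
  age <- pmin(pmax(round(rnorm(n, 65, 14)), 18), 95)
  metastatic <- rbinom(n, 1, config$p_metastatic_by_group[group]) == 1
  # latent true ECOG score; worse when metastatic (informative presence)
  ps_probs_nm <- c(0.35, 0.35, 0.18, 0.09, 0.03)
  ps_probs_m <- c(0.10, 0.25, 0.30, 0.22, 0.13)
  latent_ps <- vapply(metastatic, function(m) {
    sample(0:4, 1, prob = if (m) ps_probs_m else ps_probs_nm)
  }, integer(1))
  span <- as.integer(config$study_end - config$study_start)
  index_date <- config$study_start + sample.int(span + 1L, n, replace = TRUE) - 1L
  tibble::tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    sex = sex,
    gold_age = age,
    gold_cancer_group = group,
    gold_hospital_id = hospital,
    gold_metastatic = metastatic,
    gold_latent_ps = latent_ps,
    gold_index_date = index_date
  )
}

# Documentation-propensity linear predictor (additive log-odds model).
ps_linear_predictor <- function(pp, sex, age, group, hospital, metastatic,
                                n_mdt, n_consult, n_hosp) {
  pp$baseline +
    pp$sex_male * (sex == "M") +
    pp$age_per_decade * (age - 65) / 10 +
    unname(pp$cancer_group[group]) +
    unname(pp$hospital[hospital]) +
    pp$metastatic * metastatic +
    pp$per_doc[["mdt"]] * n_mdt +
    pp$per_doc[["consultation"]] * n_consult +
    pp$per_doc[["hospitalization"]] * n_hosp
}

#' Simulate gold-annotated clinical documents
#'
#' Assembles MDT, consultation and hospitalization reports for a simulated
#' cohort. Whether a patient has any documented performance status is drawn
#' from the additive log-odds propensity model in the configuration
#' (covariates: sex, age, cancer group, hospital, metastatic status, and
#' in-window document counts); positive patients then get clean score
#' mentions spread over their in-window documents (at least one), while
#' negated, family-attributed and decoy sentences are mixed in everywhere
#' according to `mention_mix`. Document dates fall inside and outside the
#' -90/+365-day analysis window. Gold labels and character spans come from
#' the templates themselves, never from the extractor.
#'
#' @param patients,events tibbles from [simulate_cohort()]
#' @param config the same [generator_config()]
#' @return tibble of documents: doc_id, patient_id, doc_type, date,
#'   cancer_coded_stay, text, gold_has_ps, and gold_spans (list column of
#'   tibbles with 0-based half-open `start`/`end`, `scale`, `value`,
#'   `value_upper`, `negated`, `family`)
#' @export
simulate_documents <- function(patients, events, config) {
  config <- validate_generator_config(config)
  empty <- tibble::tibble(
    doc_id = character(), patient_id = character(), doc_type = character(),
    date = as.Date(character()), cancer_coded_stay = logical(),
    text = character(), gold_has_ps = logical(), gold_spans = list()
  )
  if (nrow(patients) == 0) return(empty)

  withr::with_seed(derive_seed(config$seed, "documents"), {
    templates <- ps_templates(config$language)
    mix <- config$mention_mix
    pos_weight <- mix[["ecog_style"]] + mix[["karnofsky_style"]]

    skel <- tidyr::expand_grid(
      i = seq_len(nrow(patients)),
      doc_type = c("MDT", "CONSULTATION", "HOSPITALIZATION")
    )
    means <- c(MDT = config$doc_rate_params[["mdt"]],
               CONSULTATION = config$doc_rate_params[["consultation"]],
               HOSPITALIZATION = config$doc_rate_params[["hospitalization"]])
    skel$n <- rpois(nrow(skel), means[skel$doc_type])
    docs <- skel[rep(seq_len(nrow(skel)), skel$n), c("i", "doc_type")]
    if (nrow(docs) == 0) return(empty)

    nd <- nrow(docs)
    docs$in_window <- runif(nd) >= config$out_of_window_frac
    off_in <- sample(-90:365, nd, replace = TRUE)
    off_out <- sample(c(-180:-91, 366:540), nd, replace = TRUE)
    docs$date <- patients$gold_index_date[docs$i] +
      ifelse(docs$in_window, off_in, off_out)
    docs$cancer_coded_stay <- ifelse(
      docs$doc_type == "HOSPITALIZATION",
      runif(nd) < config$p_cancer_coded_stay, NA
    )

    # patient-level truth from the propensity model on in-window counts
    cnt <- docs |>
      dplyr::filter(.data$in_window) |>
      dplyr::count(.data$i, .data$doc_type) |>
      tidyr::pivot_wider(names_from = "doc_type", values_from = "n",
                         values_fill = 0L)
    for (col in c("MDT", "CONSULTATION", "HOSPITALIZATION")) {
      if (!col %in% names(cnt)) cnt[[col]] <- 0L
    }
    n_in <- tibble::tibble(i = seq_len(nrow(patients))) |>
      dplyr::left_join(cnt, by = "i") |>
      dplyr::mutate(dplyr::across(c("MDT", "CONSULTATION", "HOSPITALIZATION"),
                                  ~ tidyr::replace_na(.x, 0L)))
    eta <- ps_linear_predictor(
      config$ps_propensity, patients$sex, patients$gold_age,
      patients$gold_cancer_group, patients$gold_hospital_id,
      patients$gold_metastatic,
      n_in$MDT, n_in$CONSULTATION, n_in$HOSPITALIZATION
    )
    any_in <- (n_in$MDT + n_in$CONSULTATION + n_in$HOSPITALIZATION) > 0
    patient_pos <- (rbinom(nrow(patients), 1, plogis(eta)) == 1) &
      any_in & pos_weight > 0

    # document-level clean-mention flags
    docs$clean <- FALSE
    pos_in <- patient_pos[docs$i] & docs$in_window
    docs$clean[pos_in] <- runif(sum(pos_in)) < config$p_mention_given_pos
    cand <- which(patient_pos[docs$i] & docs$in_window)
    for (pid in unique(docs$i[cand])) {
      rows <- cand[docs$i[cand] == pid]
      if (!any(docs$clean[rows])) {
        docs$clean[rows[sample.int(length(rows), 1)]] <- TRUE
      }
    }
    out_clean <- !docs$in_window & pos_weight > 0
    docs$clean[out_clean] <- runif(sum(out_clean)) < config$p_out_window_mention

    # distractor category per document; gold-negative documents may only
    # receive non-asserting families so labels stay template-determined
    neg_mass <- mix[["negated"]] + mix[["family_attributed"]] + mix[["decoy_only"]]
    distractor <- rep(NA_character_, nd)
    take <- runif(nd) < 0.6
    cats <- names(mix)
    full_draw <- sample(cats, nd, replace = TRUE, prob = mix)
    if (neg_mass > 0) {
      neg_cats <- c("negated", "family_attributed", "decoy_only")
      neg_draw <- sample(neg_cats, nd, replace = TRUE, prob = mix[neg_cats])
    } else {
      neg_draw <- rep(NA_character_, nd)
    }
    distractor[take & docs$clean] <- full_draw[take & docs$clean]
    distractor[take & !docs$clean] <- neg_draw[take & !docs$clean]

    latent <- patients$gold_latent_ps[docs$i]
    assembled <- purrr::pmap(
      list(docs$clean, distractor, latent),
      function(clean, dis, v) assemble_document(clean, dis, v, templates, mix)
    )
    tibble::tibble(
      doc_id = sprintf("D%07d", seq_len(nd)),
      patient_id = patients$patient_id[docs$i],
      doc_type = docs$doc_type,
      date = docs$date,
      cancer_coded_stay = docs$cancer_coded_stay,
      text = purrr::map_chr(assembled, "text"),
      gold_has_ps = purrr::map_lgl(assembled, "has_ps"),
      gold_spans = purrr::map(assembled, "spans")
    )
  })
}

# Build one document's text from template sentences, tracking gold spans.
assemble_document <- function(clean, distractor, v_ecog, templates, mix) {
  sentences <- list(list(text = sample(templates$filler, 1), span = NULL))
  if (clean) {
    fam <- if (runif(1) * (mix[["ecog_style"]] + mix[["karnofsky_style"]]) <
               mix[["ecog_style"]]) "ecog_style" else "karnofsky_style"
    t <- templates[[fam]][[sample.int(length(templates[[fam]]), 1)]]
    sentences <- c(sentences, list(render_template(t, v_ecog)))
  }
  if (!is.na(distractor) && distractor != "decoy_only" &&
      length(templates[[distractor]]) > 0) {
    t <- templates[[distractor]][[sample.int(length(templates[[distractor]]), 1)]]
    sentences <- c(sentences, list(render_template(t, sample(0:4, 1))))
  } else if (!is.na(distractor) && distractor == "decoy_only") {
    sentences <- c(sentences,
                   list(list(text = sample(templates$decoy_only, 1),
                             span = NULL)))
  }
  if (runif(1) < 0.5) {
    sentences <- c(sentences,
                   list(list(text = sample(templates$filler, 1), span = NULL)))
  }
  offset <- 0L
  spans <- list()
  texts <- character(length(sentences))
  for (s in seq_along(sentences)) {
    texts[s] <- sentences[[s]]$text
    if (!is.null(sentences[[s]]$span)) {
      sp <- sentences[[s]]$span
      sp$start <- sp$start + offset
      sp$end <- sp$end + offset
      spans <- c(spans, list(sp))
    }
    offset <- offset + nchar(texts[s], type = "chars") + 1L  # +1 for " "
  }
  spans <- if (length(spans)) dplyr::bind_rows(spans) else
    tibble::tibble(start = integer(), end = integer(), scale = character(),
                   value = integer(), value_upper = integer(),
                   negated = logical(), family = logical())
  list(
    text = paste(texts, collapse = " "),
    has_ps = any(!spans$negated & !spans$family),
    spans = spans
  )
}

#' Simulate a full synthetic EHR extract
#'
#' Convenience wrapper around [simulate_cohort()] and
#' [simulate_documents()]. Adds to the patient table the ground-truth
#' documentation label `gold_has_ps` (any clean-mention document within
#' -90/+365 days of the gold index date).
#'
#' @param config a [generator_config()]
#' @return list of tibbles: `patients`, `events`, `documents`, plus the
#'   `config` used
#' @examples
#' ehr <- simulate_ehr(generator_config(n_patients = 10, seed = 7))
#' names(ehr)
#' @export
simulate_ehr <- function(config) {
  config <- validate_generator_config(config)
  sim <- simulate_cohort(config)
  documents <- simulate_documents(sim$patients, sim$events, config)
  lab <- documents |>
    dplyr::inner_join(
      dplyr::select(sim$patients, "patient_id", "gold_index_date"),
      by = "patient_id"
    ) |>
    dplyr::filter(.data$date >= .data$gold_index_date - 90,
                  .data$date <= .data$gold_index_date + 365) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(gold_has_ps = any(.data$gold_has_ps), .groups = "drop")
  patients <- sim$patients |>
    dplyr::left_join(lab, by = "patient_id") |>
    dplyr::mutate(gold_has_ps = dplyr::coalesce(.data$gold_has_ps, FALSE))
  list(patients = patients, events = sim$events, documents = documents,
       config = config)
}

#' Simulate an analysis-ready cohort table directly
#'
#' Fast path for statistical experiments: draws per-patient covariates and
#' the documentation outcome straight from the propensity model, skipping
#' claims and text assembly. Because the outcome is generated by exactly
#' the additive logistic model the regression module fits, this is the
#' testbed for parameter recovery at large n. Patients with zero documents
#' are dropped, mirroring the cohort exclusion cascade (selection on
#' covariates only, which leaves the conditional model intact).
#'
#' @param config a [generator_config()]
#' @return cohort tibble: patient_id, sex, age_at_dx, cancer_group,
#'   hospital_id, n_mdt, n_consult, n_hosp, metastatic_at_dx, has_ps,
#'   died_within_1y
#' @examples
#' head(simulate_cohort_table(generator_config(n_patients = 100, seed = 3)))
#' @export
simulate_cohort_table <- function(config) {
  config <- validate_generator_config(config)
  n <- config$n_patients
  withr::with_seed(derive_seed(config$seed, "cohort_table"), {
    pat <- draw_patient_covariates(max(n, 1L), config)[seq_len(n), ]
    n_mdt <- rpois(n, config$doc_rate_params[["mdt"]])
    n_consult <- rpois(n, config$doc_rate_params[["consultation"]])
    n_hosp <- rpois(n, config$doc_rate_params[["hospitalization"]])
    eta <- ps_linear_predictor(
      config$ps_propensity, pat$sex, pat$gold_age, pat$gold_cancer_group,
      pat$gold_hospital_id, pat$gold_metastatic, n_mdt, n_consult, n_hosp
    )
    has_ps <- rbinom(n, 1, plogis(eta)) == 1
    mp <- config$mortality_params
    died <- rbinom(n, 1, plogis(qlogis(mp$baseline_p) +
                                  mp$poor_ps_log_or *
                                    (pat$gold_latent_ps >= 2))) == 1
    tibble::tibble(
      patient_id = pat$patient_id,
      sex = pat$sex,
      age_at_dx = as.numeric(pat$gold_age),
      cancer_group = pat$gold_cancer_group,
      hospital_id = pat$gold_hospital_id,
      n_mdt = n_mdt, n_consult = n_consult, n_hosp = n_hosp,
      metastatic_at_dx = pat$gold_metastatic,
      has_ps = has_ps,
      died_within_1y = died
    ) |>
      dplyr::filter(.data$n_mdt + .data$n_consult + .data$n_hosp >= 1)
  })
}
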