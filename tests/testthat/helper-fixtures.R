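# Hand-labelled fixture corpora and independent oracles used across tests.
# Labels were assigned by hand against the documented scoping rules
# (negation: cue in the same sentence within 5 tokens before, or inside,
# the mention; family: kinship cue earlier in the same sentence).

negation_fixture <- tibble::tibble(
  text = c(
    "PS is not 0.",
    "Pas de PS à 2 ce jour.",
    "Le patient n'est pas OMS 1.",
    "Sans certitude, ECOG 2 rapporté.",
    "Aucun score fiable, PS 2 incertain.",
    "Etat non compatible, PS 4 annoncé.",
    "pas d'OMS 2 retenu.",
    "Karnofsky pas évalué à 50.",
    "OMS non 2.",
    "Performance status is not 2 today.",
    "No PS 3 documented.",
    "ECOG 1, bon état général.",
    "OMS 2 ce jour.",
    "Karnofsky 80% stable.",
    "Pas d'anomalie. PS 1 ce jour.",
    "Aucune douleur. OMS 1.",
    "Score stable depuis la dernière consultation, PS 1.",
    "Zubrod 0, pleinement actif.",
    "PS 2 mais pas de traitement.",
    "Pas de douleur thoracique ni de dyspnée rapportée ce jour, OMS 1.",
    "Sans aide à domicile depuis plusieurs semaines maintenant, PS 2.",
    "ECOG 3 despite treatment."
  ),
  negated = c(rep(TRUE, 11), rep(FALSE, 11))
)

family_fixture <- tibble::tibble(
  text = c(
    "mother had PS = 3.",
    "Sa mère : OMS 2.",
    "Père : IK 70 avant son décès.",
    "Antécédents familiaux : frère avec PS 4.",
    "Famille : père OMS 4 en fin de vie.",
    "Family history: father with ECOG 2.",
    "PS = 3.",
    "OMS 1 ; famille informée.",
    "PS 2; family informed.",
    "Mère en bonne santé. PS 1 pour le patient.",
    "ECOG 2, vit avec sa fille.",
    "Karnofsky 60% ce jour."
  ),
  family = c(rep(TRUE, 6), rep(FALSE, 6))
)

# Decoy sentences that must never yield a mention.
decoy_fixture <- c(
  "PSA 4.5 ng/mL, bilan normal.",
  "PSA 11 en augmentation.",
  "IPS 0.9 aux membres inférieurs.",
  "Contact : 01 42 34 56 78.",
  "TA 12/8, FC 72/min.",
  "Glycémie à 1.2 g/L.",
  "EVA 3/10 ce jour.",
  "Le patient pèse 80 kg.",
  "Hémoglobine 10 g/dL.",
  "Saturation 95% en air ambiant.",
  "Chambre 204, lit 2.",
  "CA 19-9 à 37."
)

# Small unambiguous document corpus with hand-assigned gold labels.
unambiguous_corpus <- tibble::tibble(
  doc_id = sprintf("U%02d", 1:18),
  doc_type = rep(c("MDT", "CONSULTATION", "HOSPITALIZATION"), each = 6),
  text = c(
    "Dossier présenté en RCP. Etat général : OMS 1. Décision de chimiothérapie.",
    "Patient de 62 ans. PS = 2. Traitement palliatif discuté.",
    "Karnofsky 80% ce jour. Indication opératoire retenue.",
    "Dossier discuté. PSA 8.2 en augmentation. Surveillance.",
    "Pas de PS coté dans le dossier. Décision reportée.",
    "Antécédents familiaux : mère avec PS 3. Patient asymptomatique.",
    "Consultation de suivi. ECOG : 0. Poursuite du traitement.",
    "Vu ce jour. IK 70. Adaptation des doses.",
    "Zubrod 2 à l'examen. Asthénie marquée.",
    "Bilan biologique sans anomalie. Revoir dans 3 mois.",
    "PS non évaluable ce jour, patient non examiné.",
    "Le patient n'est pas OMS 0. Surveillance rapprochée.",
    "Hospitalisation pour cure. performance status 1 à l'entrée.",
    "Entrée par les urgences. PS 3-4 selon les jours.",
    "Sortie à domicile. WHO 2 à la sortie.",
    "Séjour sans complication. IPS 0.9 noté.",
    "Sa fille signale une dégradation. Pas de score coté.",
    "Père : OMS 4 avant son décès. Patient lui-même très autonome."
  ),
  gold_has_ps = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                  TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                  TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
)

# ---- independent oracles -------------------------------------------------

# Spearman via explicit average ranks and the raw Pearson sum formula;
# shares no code with the package implementation.
naive_spearman <- function(x, y) {
  avg_rank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(rx)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt(n * sum(rx^2) - sum(rx)^2) * sqrt(n * sum(ry^2) - sum(ry)^2)
  num / den
}

# Brute-force cohort re-derivation: plain loops, no dplyr, independent
# group mapping. Documents must already carry a has_ps column.
brute_cohort <- function(patients, events, documents,
                         study_start = as.Date("2019-01-01"),
                         study_end = as.Date("2021-06-01")) {
  grp_of <- function(code) {
    num <- suppressWarnings(as.integer(substr(code, 2, 3)))
    if (substr(code, 1, 1) != "C" || is.na(num)) return("Other")
    if (num == 50) "Breast"
    else if (num %in% 18:21) "Colorectal"
    else if (num %in% 33:34) "Lung"
    else if (num == 61) "Prostate"
    else if (num %in% 51:58) "Gynaecological"
    else if (num %in% c(60, 62:68)) "Genitourinary"
    else if (num %in% 43:44) "Skin"
    else if (num %in% 81:96) "Haematological"
    else if (num %in% c(15:17, 22:26)) "OtherGI"
    else "Other"
  }
  is_ca <- function(code) {
    substr(code, 1, 1) == "C" &
      !is.na(suppressWarnings(as.integer(substr(code, 2, 3)))) &
      suppressWarnings(as.integer(substr(code, 2, 3))) <= 97
  }
  rows <- list()
  for (pid in patients$patient_id) {
    ev <- events[events$patient_id == pid & is_ca(events$code), ]
    inw <- ev[ev$date >= study_start & ev$date <= study_end, ]
    if (nrow(inw) == 0) next
    idx <- min(inw$date)
    if (any(ev$date > idx - 730 & ev$date < idx)) next
    first <- ev[ev$date == idx, ]
    first <- first[order(first$code), ][1, ]
    p <- patients[patients$patient_id == pid, ]
    rows[[pid]] <- data.frame(
      patient_id = pid, index_date = idx,
      sex = p$sex,
      age_at_dx = floor(as.numeric(idx - p$birth_date) / 365.25),
      cancer_group = grp_of(first$code),
      hospital_id = first$hospital_id,
      death_date = p$death_date
    )
  }
  cand <- do.call(rbind, rows)
  if (is.null(cand)) return(list(cohort = NULL, log = NULL))
  log <- data.frame(step = character(), n_removed = integer(),
                    n_remaining = integer())
  push <- function(log, step, before, after) {
    rbind(log, data.frame(step = step, n_removed = before - after,
                          n_remaining = after))
  }
  hosp_share <- table(cand$hospital_id) / nrow(cand)

  n0 <- nrow(cand)
  cand <- cand[cand$age_at_dx >= 18, ]
  log <- push(log, "age_under_18", n0, nrow(cand))
  n1 <- nrow(cand)
  cand <- cand[hosp_share[cand$hospital_id] >= 0.01, ]
  log <- push(log, "small_or_paediatric_hospital", n1, nrow(cand))
  n2 <- nrow(cand)
  cand <- cand[!(cand$sex == "M" & cand$cancer_group == "Gynaecological") &
                 !(cand$sex == "F" & cand$cancer_group == "Prostate"), ]
  log <- push(log, "sex_cancer_mismatch", n2, nrow(cand))

  n3 <- nrow(cand)
  out <- list()
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, ]
    d <- documents[documents$patient_id == r$patient_id &
                     documents$doc_type %in%
                       c("MDT", "CONSULTATION", "HOSPITALIZATION") &
                     documents$date >= r$index_date - 90 &
                     documents$date <= r$index_date + 365, ]
    if (nrow(d) == 0) next
    ev <- events[events$patient_id == r$patient_id, ]
    met <- any(substr(ev$code, 1, 3) %in% c("C77", "C78", "C79") &
                 ev$date >= r$index_date & ev$date <= r$index_date + 90)
    out[[r$patient_id]] <- data.frame(
      patient_id = r$patient_id, index_date = r$index_date, sex = r$sex,
      age_at_dx = r$age_at_dx, cancer_group = r$cancer_group,
      hospital_id = r$hospital_id,
      n_mdt = sum(d$doc_type == "MDT"),
      n_consult = sum(d$doc_type == "CONSULTATION"),
      n_hosp = sum(d$doc_type == "HOSPITALIZATION"),
      metastatic_at_dx = met,
      has_ps = any(d$has_ps),
      died_within_1y = !is.na(r$death_date) &
        r$death_date <= r$index_date + 365
    )
  }
  cohort <- do.call(rbind, out)
  log <- push(log, "no_document", n3,
              if (is.null(cohort)) 0L else nrow(cohort))
  rownames(cohort) <- NULL
  list(cohort = cohort, log = log)
}

# Expand aggregate counts into a row-per-patient tibble for the
# prevalence operations.
expand_counts <- function(n_pos, n_neg, col = "has_ps") {
  tibble::tibble(!!col := rep(c(TRUE, FALSE), c(n_pos, n_neg)))
}
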