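# Default 15-hospital patient-volume profile for a large multisite system.
# Shares are heavily skewed: the largest site sees ~13x the smallest.
default_hospital_weights <- local({
  n <- c(11195, 3358, 3221, 3387, 3515, 2991, 9537, 6734, 834, 1412,
         1743, 1074, 3819, 10086, 5573)
  w <- n / sum(n)
  names(w) <- sprintf("H%02d", seq_along(w))
  w
})

default_cancer_group_weights <- local({
  n <- c(Breast = 5429, Colorectal = 5863, Genitourinary = 5359,
         Gynaecological = 2732, Haematological = 10883, Lung = 5940,
         Other = 11341, OtherGI = 10167, Prostate = 3821, Skin = 6944)
  n / sum(n)
})

# Metastatic-at-diagnosis probability by primary site; weighted average ~0.22.
default_p_metastatic <- c(
  Breast = 0.15, Colorectal = 0.25, Genitourinary = 0.20,
  Gynaecological = 0.20, Haematological = 0.05, Lung = 0.45,
  Other = 0.25, OtherGI = 0.35, Prostate = 0.20, Skin = 0.10
)

# Additive log-odds effects on the probability that a performance status is
# documented for a patient. Hospital effects span roughly the range implied
# by between-site documentation rates of ~20% to ~63%.
default_ps_propensity <- list(
  baseline = -1.65,
  sex_male = 0.08,
  age_per_decade = 0.15,
  metastatic = log(3.3),
  per_doc = c(mdt = 0.25, consultation = 0.12, hospitalization = 0.18),
  cancer_group = c(
    Breast = 0.65, Colorectal = -0.10, Genitourinary = -0.75,
    Gynaecological = 0.05, Haematological = 0.30, Lung = 1.19,
    Other = -0.45, OtherGI = 0.35, Prostate = -0.45, Skin = -1.05
  ),
  hospital = c(
    H01 = 0, H02 = -1.0, H03 = 0, H04 = -0.05, H05 = -1.1, H06 = -0.1,
    H07 = -0.5, H08 = 0.35, H09 = -0.4, H10 = -0.2, H11 = 0.4,
    H12 = -1.05, H13 = 0.05, H14 = 0.9, H15 = 0.15
  )
)

#' Configuration for the synthetic EHR generator
#'
#' Bundles and validates every knob of the synthetic-data module: cohort
#' composition, claims structure, document counts, the additive log-odds
#' model for documentation propensity, the mix of surface forms used in
#' generated text, and mortality. Defaults emulate a large multisite
#' university hospital system: 15 hospitals of very unequal volume, ten
#' primary-site cancer groups, ~22% metastatic at diagnosis, a median of
#' about six reports per patient, and an overall documentation prevalence
#' near 40%.
#'
#' @param n_patients number of patients to simulate (non-negative integer)
#' @param seed integer seed; all generator randomness derives from it
#' @param hospital_weights named probabilities over hospital ids (sum to 1)
#' @param cancer_group_weights named probabilities over cancer groups
#' @param p_metastatic_by_group named per-group metastatic probabilities
#' @param doc_rate_params named non-negative Poisson means for in-window
#'   document counts, names `mdt`, `consultation`, `hospitalization`
#' @param ps_propensity list with elements `baseline`, `sex_male`,
#'   `age_per_decade` (log-odds per decade of age above 65), `metastatic`,
#'   `per_doc` (named increments per document of each type), `cancer_group`
#'   and `hospital` (named additive log-odds offsets)
#' @param mention_mix named probabilities over surface-form families
#'   `ecog_style`, `karnofsky_style`, `negated`, `family_attributed`,
#'   `decoy_only` (sum to 1)
#' @param mortality_params list: `baseline_p`, the 1-year death probability
#'   for patients with preserved performance status, and `poor_ps_log_or`,
#'   the log-odds shift when the latent score is 2 or worse
#' @param washout_violator_frac fraction of patients given an extra cancer
#'   code 1-24 months before their intended index date, so that the
#'   incident-diagnosis filter has true positives to remove
#' @param out_of_window_frac fraction of documents dated outside the
#'   analysis window around the index date
#' @param p_mention_given_pos probability that each in-window document of a
#'   documented patient carries a clean performance-status mention (at least
#'   one is always forced)
#' @param p_out_window_mention probability that an out-of-window document
#'   carries a clean mention (exercises window filtering)
#' @param p_cancer_coded_stay probability that a hospitalization report is
#'   linked to a cancer-coded stay
#' @param language `"fr"` (default) or `"en"` template set
#' @param study_start,study_end bounds for index dates (ISO dates)
#' @return a validated `ps_generator_config` list
#' @examples
#' cfg <- generator_config(n_patients = 100, seed = 1)
#' @export
generator_config <- function(n_patients,
                             seed,
                             hospital_weights = default_hospital_weights,
                             cancer_group_weights = default_cancer_group_weights,
                             p_metastatic_by_group = default_p_metastatic,
                             doc_rate_params = c(mdt = 1.5, consultation = 2.5,
                                                 hospitalization = 2.0),
                             ps_propensity = default_ps_propensity,
                             mention_mix = c(ecog_style = 0.35,
                                             karnofsky_style = 0.15,
                                             negated = 0.20,
                                             family_attributed = 0.10,
                                             decoy_only = 0.20),
                             mortality_params = list(baseline_p = 0.10,
                                                     poor_ps_log_or = log(3)),
                             washout_violator_frac = 0.05,
                             out_of_window_frac = 0.15,
                             p_mention_given_pos = 0.45,
                             p_out_window_mention = 0.15,
                             p_cancer_coded_stay = 0.6,
                             language = c("fr", "en"),
                             study_start = as.Date("2019-01-01"),
                             study_end = as.Date("2021-06-01")) {
  cfg <- list(
    n_patients = n_patients, seed = seed,
    hospital_weights = hospital_weights,
    cancer_group_weights = cancer_group_weights,
    p_metastatic_by_group = p_metastatic_by_group,
    doc_rate_params = doc_rate_params,
    ps_propensity = ps_propensity,
    mention_mix = mention_mix,
    mortality_params = mortality_params,
    washout_violator_frac = washout_violator_frac,
    out_of_window_frac = out_of_window_frac,
    p_mention_given_pos = p_mention_given_pos,
    p_out_window_mention = p_out_window_mention,
    p_cancer_coded_stay = p_cancer_coded_stay,
    language = match.arg(language),
    study_start = as.Date(study_start), study_end = as.Date(study_end)
  )
  validate_generator_config(cfg)
}

#' @rdname generator_config
#' @param cfg a generator configuration list
#' @export
validate_generator_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      is.na(cfg$n_patients) || cfg$n_patients < 0 ||
      cfg$n_patients != floor(cfg$n_patients)) {
    abort("`n_patients` must be a single non-negative integer.")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    abort("`seed` must be a single integer.")
  }
  check_simplex(cfg$hospital_weights, "hospital_weights")
  check_simplex(cfg$cancer_group_weights, "cancer_group_weights")
  check_simplex(cfg$mention_mix, "mention_mix")
  if (!setequal(names(cfg$mention_mix),
                c("ecog_style", "karnofsky_style", "negated",
                  "family_attributed", "decoy_only"))) {
    abort("`mention_mix` must name exactly the five surface-form families.")
  }
  check_probs(cfg$p_metastatic_by_group, "p_metastatic_by_group")
  if (!all(names(cfg$cancer_group_weights) %in%
           names(cfg$p_metastatic_by_group))) {
    abort("`p_metastatic_by_group` must cover every sampled cancer group.")
  }
  check_nonneg(cfg$doc_rate_params, "doc_rate_params")
  if (!setequal(names(cfg$doc_rate_params),
                c("mdt", "consultation", "hospitalization"))) {
    abort("`doc_rate_params` must name mdt, consultation, hospitalization.")
  }
  pp <- cfg$ps_propensity
  needed <- c("baseline", "sex_male", "age_per_decade", "metastatic",
              "per_doc", "cancer_group", "hospital")
  if (!all(needed %in% names(pp))) {
    abort(sprintf("`ps_propensity` is missing: %s.",
                  paste(setdiff(needed, names(pp)), collapse = ", ")))
  }
  if (!all(names(cfg$cancer_group_weights) %in% names(pp$cancer_group))) {
    abort("`ps_propensity$cancer_group` must cover every sampled group.")
  }
  if (!all(names(cfg$hospital_weights) %in% names(pp$hospital))) {
    abort("`ps_propensity$hospital` must cover every sampled hospital.")
  }
  check_probs(cfg$mortality_params$baseline_p, "mortality_params$baseline_p")
  check_probs(c(cfg$washout_violator_frac, cfg$out_of_window_frac,
                cfg$p_mention_given_pos, cfg$p_out_window_mention,
                cfg$p_cancer_coded_stay),
              "generator fractions")
  if (cfg$study_end <= cfg$study_start) {
    abort("`study_end` must be after `study_start`.")
  }
  structure(cfg, class = "ps_generator_config")
}
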