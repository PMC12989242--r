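# Sentence templates for synthetic clinical text. Each mention template is a
# (prefix, mention, suffix) triple; the mention part carries the score and is
# the gold span. Placeholders: {v} ECOG value, {u} ECOG upper bound of a
# range, {k} Karnofsky value. Gold labels derive from template identity
# alone — the extractor is never consulted at generation time.

tpl <- function(prefix, mention, suffix, scale = NA_character_,
                negated = FALSE, family = FALSE, range = FALSE) {
  list(prefix = prefix, mention = mention, suffix = suffix, scale = scale,
       negated = negated, family = family, range = range,
       has_span = !is.na(scale))
}

ps_templates <- function(language = "fr") {
  if (language == "fr") {
    list(
      filler = c(
        "Patient vu ce jour en consultation.",
        "Poursuite de la prise en charge oncologique.",
        "Bilan biologique sans anomalie notable.",
        "Le traitement est bien toléré.",
        "Examen clinique sans particularité.",
        "Dossier discuté en réunion."
      ),
      ecog_style = list(
        tpl("Etat général : ", "OMS {v}", ".", "ECOG_FAMILY"),
        tpl("Sur le plan fonctionnel, ", "PS = {v}", ".", "ECOG_FAMILY"),
        tpl("", "ECOG : {v}", " à l'examen.", "ECOG_FAMILY"),
        tpl("Score ", "OMS à {v}", " ce jour.", "ECOG_FAMILY"),
        tpl("", "Zubrod {v}", ".", "ECOG_FAMILY"),
        tpl("Autonomie : ", "PS {v}/4", ".", "ECOG_FAMILY"),
        tpl("", "PS {v}-{u}", " selon les jours.", "ECOG_FAMILY", range = TRUE),
        tpl("Statut ", "WHO {v}", ".", "ECOG_FAMILY")
      ),
      karnofsky_style = list(
        tpl("", "Karnofsky {k}%", " ce jour.", "KARNOFSKY"),
        tpl("Echelle ", "IK {k}", ".", "KARNOFSKY"),
        tpl("Autonomie conservée, ", "indice de Karnofsky {k}", ".", "KARNOFSKY"),
        tpl("", "Karnofsky {k}/100", ".", "KARNOFSKY")
      ),
      negated = list(
        tpl("PS non évaluable ce jour.", NA, NA),
        tpl("Pas de PS coté dans le dossier.", NA, NA),
        tpl("Score OMS non renseigné.", NA, NA),
        tpl("Pas de ", "PS à {v}", " retenu.", "ECOG_FAMILY", negated = TRUE),
        tpl("Le patient n'est pas ", "OMS {v}", ".", "ECOG_FAMILY", negated = TRUE)
      ),
      family_attributed = list(
        tpl("Antécédents familiaux : mère avec ", "PS {v}", ".",
            "ECOG_FAMILY", family = TRUE),
        tpl("Sa mère : ", "OMS {v}", " avant son décès.",
            "ECOG_FAMILY", family = TRUE),
        tpl("Père : ", "IK {k}", " en fin de vie.", "KARNOFSKY", family = TRUE)
      ),
      decoy_only = c(
        "PSA 4.5 ng/mL, bilan normal.",
        "IPS 0.9 aux membres inférieurs.",
        "Contact : 01 42 34 56 78.",
        "TA 12/8, FC 72/min.",
        "Glycémie à 1.2 g/L.",
        "EVA 3/10 ce jour."
      )
    )
  } else {
    list(
      filler = c(
        "Patient seen today in clinic.",
        "Treatment ongoing without complication.",
        "Laboratory results unremarkable.",
        "Physical examination without abnormality."
      ),
      ecog_style = list(
        tpl("General condition: ", "ECOG {v}", ".", "ECOG_FAMILY"),
        tpl("", "performance status {v}", " on examination.", "ECOG_FAMILY"),
        tpl("Patient remains active, ", "PS = {v}", ".", "ECOG_FAMILY"),
        tpl("", "PS {v}-{u}", " depending on the day.", "ECOG_FAMILY",
            range = TRUE)
      ),
      karnofsky_style = list(
        tpl("", "Karnofsky {k}%", " today.", "KARNOFSKY"),
        tpl("Functional scale ", "IK {k}", ".", "KARNOFSKY")
      ),
      negated = list(
        tpl("No PS recorded in the chart.", NA, NA),
        tpl("", "PS is not {v}", ".", "ECOG_FAMILY", negated = TRUE)
      ),
      family_attributed = list(
        tpl("Mother had ", "PS = {v}", ".", "ECOG_FAMILY", family = TRUE),
        tpl("Family history: father with ", "ECOG {v}", ".", "ECOG_FAMILY",
            family = TRUE)
      ),
      decoy_only = c(
        "PSA 4.5 ng/mL, otherwise unremarkable.",
        "IPS 0.9 in the lower limbs.",
        "Contact number 01 42 34 56 78."
      )
    )
  }
}

# Karnofsky values compatible with a latent ECOG score.
karnofsky_for_ecog <- c("0" = 100, "0b" = 90, "1" = 80, "1b" = 70,
                        "2" = 60, "2b" = 50, "3" = 40, "3b" = 30,
                        "4" = 20, "4b" = 10)

# Instantiate a mention template with concrete values. Returns the sentence
# and the gold span (0-based, half-open) relative to the sentence start.
render_template <- function(t, v_ecog) {
  if (!t$has_span) {
    return(list(text = t$prefix, span = NULL))
  }
  if (t$scale == "KARNOFSKY") {
    value <- unname(karnofsky_for_ecog[paste0(v_ecog,
                                              sample(c("", "b"), 1))])
    value_upper <- NA_integer_
    mention <- gsub("{k}", value, t$mention, fixed = TRUE)
  } else {
    value <- v_ecog
    value_upper <- if (t$range) min(v_ecog + 1L, 4L) else NA_integer_
    mention <- gsub("{v}", value, t$mention, fixed = TRUE)
    if (t$range) mention <- gsub("{u}", value_upper, mention, fixed = TRUE)
  }
  start <- nchar(t$prefix, type = "chars")
  list(
    text = paste0(t$prefix, mention, t$suffix),
    span = tibble::tibble(
      start = start,
      end = start + nchar(mention, type = "chars"),
      scale = t$scale,
      value = as.integer(value),
      value_upper = as.integer(value_upper),
      negated = t$negated,
      family = t$family
    )
  )
}
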