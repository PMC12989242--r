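test_that("mention finding handles the canonical surface forms", {
  cases <- tibble::tribble(
    ~text,                ~scale,         ~value, ~upper,
    "OMS 1",              "ECOG_FAMILY",  1L,     NA_integer_,
    "PS = 2",             "ECOG_FAMILY",  2L,     NA_integer_,
    "ECOG : 3",           "ECOG_FAMILY",  3L,     NA_integer_,
    "Karnofsky 80%",      "KARNOFSKY",    80L,    NA_integer_,
    "IK 70",              "KARNOFSKY",    70L,    NA_integer_,
    "Zubrod 0",           "ECOG_FAMILY",  0L,     NA_integer_,
    "WHO 2",              "ECOG_FAMILY",  2L,     NA_integer_,
    "performance status 4", "ECOG_FAMILY", 4L,    NA_integer_,
    "indice de Karnofsky 90", "KARNOFSKY", 90L,   NA_integer_,
    "PS 1-2",             "ECOG_FAMILY",  1L,     2L,
    "PS 2/4",             "ECOG_FAMILY",  2L,     NA_integer_,
    "Karnofsky 80/100",   "KARNOFSKY",    80L,    NA_integer_,
    "PS 80",              "KARNOFSKY",    80L,    NA_integer_,
    "OMS à 2",            "ECOG_FAMILY",  2L,     NA_integer_
  )
  for (i in seq_len(nrow(cases))) {
    m <- find_ps_mentions(cases$text[i])
    expect_equal(nrow(m), 1, info = cases$text[i])
    expect_equal(m$scale, cases$scale[i], info = cases$text[i])
    expect_equal(m$value, cases$value[i], info = cases$text[i])
    expect_equal(m$value_upper, cases$upper[i], info = cases$text[i])
  }
})

test_that("invalid values, decoys and empty text yield no mentions", {
  expect_equal(nrow(find_ps_mentions("")), 0)
  expect_equal(nrow(find_ps_mentions(character(0))), 0)
  for (txt in c("PS 7", "PS 85", "Karnofsky 75", "IK 5", "PS 2-1",
                "PS 1/2", "Karnofsky 80/10", decoy_fixture)) {
    expect_equal(nrow(find_ps_mentions(txt)), 0, info = txt)
  }
})

test_that("negated statements still surface as mentions, flagged downstream", {
  m <- find_ps_mentions("PS is not 0")
  expect_equal(nrow(m), 1)
  expect_equal(m$scale, "ECOG_FAMILY")
  expect_equal(m$value, 0L)
  expect_false(m$negated)
  q <- qualify_negation("PS is not 0", m)
  expect_true(q$negated)
})

test_that("mention offsets are 0-based half-open and reproduce matched_text", {
  texts <- c(unambiguous_corpus$text, negation_fixture$text,
             family_fixture$text)
  m <- find_ps_mentions(texts, doc_id = seq_along(texts))
  expect_gt(nrow(m), 10)
  for (i in seq_len(nrow(m))) {
    txt <- texts[as.integer(m$doc_id[i])]
    expect_identical(
      stringr::str_sub(txt, m$start[i] + 1, m$end[i]),
      m$matched_text[i]
    )
  }
  expect_true(all(m$start >= 0 & m$start < m$end))
})

test_that("extraction is deterministic", {
  txt <- paste(unambiguous_corpus$text, collapse = " ")
  expect_identical(find_ps_mentions(txt), find_ps_mentions(txt))
})

test_that("negation qualification matches the hand-labelled manifest", {
  for (i in seq_len(nrow(negation_fixture))) {
    txt <- negation_fixture$text[i]
    m <- find_ps_mentions(txt)
    expect_equal(nrow(m), 1, info = txt)
    q <- qualify_negation(txt, m)
    expect_equal(q$negated, negation_fixture$negated[i], info = txt)
  }
})

test_that("family qualification matches the hand-labelled manifest", {
  for (i in seq_len(nrow(family_fixture))) {
    txt <- family_fixture$text[i]
    m <- find_ps_mentions(txt)
    expect_equal(nrow(m), 1, info = txt)
    q <- qualify_family(txt, m)
    expect_equal(q$family, family_fixture$family[i], info = txt)
  }
})

test_that("family cues after the mention do not qualify it", {
  txt <- "PS 2; family informed."
  q <- qualify_family(txt, find_ps_mentions(txt))
  expect_false(q$family)
})

test_that("karnofsky_to_ecog follows the standard correspondence", {
  expect_equal(karnofsky_to_ecog(100), 0L)
  expect_equal(karnofsky_to_ecog(10), 4L)
  expect_equal(karnofsky_to_ecog(70), 1L)
  full <- karnofsky_to_ecog(seq(10, 100, 10))
  expect_equal(full, c(4L, 4L, 3L, 3L, 2L, 2L, 1L, 1L, 0L, 0L))
  expect_true(all(diff(full) <= 0))
  expect_error(karnofsky_to_ecog(75), "Karnofsky")
  expect_error(karnofsky_to_ecog(0), "Karnofsky")
})

test_that("document-level label is existential over clean mentions", {
  none <- find_ps_mentions("")
  expect_false(document_has_ps(none))
  txt <- "Le patient n'est pas OMS 0."
  negd <- qualify_negation(txt, find_ps_mentions(txt))
  expect_false(document_has_ps(negd))
  txt2 <- "Sa mère : OMS 2. Patient lui-même PS 1."
  both <- extract_ps_mentions(tibble::tibble(doc_id = "d", text = txt2))
  expect_equal(nrow(both), 2)
  expect_true(document_has_ps(both))
})

test_that("document and patient labels agree with gold on the fixture corpus", {
  m <- extract_ps_mentions(unambiguous_corpus)
  lab <- label_documents(unambiguous_corpus, m)
  expect_equal(lab$has_ps, unambiguous_corpus$gold_has_ps)
})

test_that("patient-level label equals a brute-force scan of gold spans", {
  ehr <- simulate_ehr(generator_config(n_patients = 60, seed = 11))
  m <- extract_ps_mentions(ehr$documents)
  lab <- label_documents(ehr$documents, m)
  inwin <- window_documents(
    lab,
    tibble::tibble(patient_id = ehr$patients$patient_id,
                   index_date = ehr$patients$gold_index_date)
  )
  got <- patient_has_ps(inwin)
  # oracle: scan gold spans of in-window documents directly
  for (pid in got$patient_id) {
    docs <- ehr$documents[ehr$documents$patient_id == pid, ]
    idx <- ehr$patients$gold_index_date[ehr$patients$patient_id == pid]
    docs <- docs[docs$date >= idx - 90 & docs$date <= idx + 365, ]
    oracle <- any(vapply(docs$gold_spans, function(sp) {
      any(!sp$negated & !sp$family)
    }, logical(1)))
    expect_equal(got$has_ps[got$patient_id == pid], oracle, info = pid)
  }
})

test_that("classification metrics match closed-form confusion arithmetic", {
  gold <- tibble::tibble(
    doc_id = as.character(1:100), doc_type = "MDT",
    gold_has_ps = rep(c(TRUE, FALSE), 50)
  )
  perfect <- tibble::tibble(doc_id = gold$doc_id, has_ps = gold$gold_has_ps)
  ev <- evaluate_extraction(perfect, gold)
  expect_equal(ev$accuracy, rep(1, 2))
  expect_equal(ev$macro_f1, rep(1, 2))

  allneg <- tibble::tibble(doc_id = gold$doc_id, has_ps = FALSE)
  ev2 <- evaluate_extraction(allneg, gold)
  ov <- ev2[ev2$doc_type == "overall", ]
  expect_equal(ov$accuracy, 0.5)
  expect_equal(ov$f1_pos, 0)
  expect_equal(ov$f1_neg, 2 / 3)
  expect_equal(ov$macro_f1, 1 / 3)

  # TP=45 FP=5 FN=5 TN=45
  gold3 <- tibble::tibble(doc_id = as.character(1:100), doc_type = "C",
                          gold_has_ps = rep(c(TRUE, FALSE), c(50, 50)))
  pred3 <- tibble::tibble(
    doc_id = gold3$doc_id,
    has_ps = c(rep(TRUE, 45), rep(FALSE, 5), rep(TRUE, 5), rep(FALSE, 45))
  )
  ev3 <- evaluate_extraction(pred3, gold3)
  expect_equal(ev3$accuracy[ev3$doc_type == "overall"], 0.9)

  expect_error(
    evaluate_extraction(perfect[1:10, ], gold),
    "align"
  )
})

test_that("macro and weighted F1 satisfy their defining identities", {
  ehr <- simulate_ehr(generator_config(n_patients = 40, seed = 5))
  m <- extract_ps_mentions(ehr$documents)
  lab <- label_documents(ehr$documents, m)
  # perturb some predictions so the confusion matrix is non-trivial
  lab$has_ps[seq(1, nrow(lab), by = 7)] <- !lab$has_ps[seq(1, nrow(lab), by = 7)]
  ev <- evaluate_extraction(
    dplyr::select(lab, doc_id, has_ps),
    dplyr::select(ehr$documents, doc_id, doc_type, gold_has_ps)
  )
  expect_equal(ev$macro_f1, (ev$f1_pos + ev$f1_neg) / 2)
  ov <- ev[ev$doc_type == "overall", ]
  n_pos <- sum(ehr$documents$gold_has_ps)
  n_neg <- sum(!ehr$documents$gold_has_ps)
  expect_equal(ov$weighted_f1,
               (n_pos * ov$f1_pos + n_neg * ov$f1_neg) / (n_pos + n_neg))
})
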