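mk_events <- function(...) {
  rows <- list(...)
  tibble::tibble(
    patient_id = vapply(rows, `[[`, "", 1),
    code = vapply(rows, `[[`, "", 2),
    date = as.Date(vapply(rows, `[[`, "", 3)),
    hospital_id = vapply(rows, function(r) r[4] %||% "H01", "")
  )
}
`%||%` <- function(x, y) if (is.na(x)) y else x

test_that("washout logic: the look-back interval is open at 730 days", {
  ev <- mk_events(c("p1", "C50.9", "2019-06-01", "H01"))
  inc <- find_incident_cases(ev)
  expect_equal(inc$patient_id, "p1")
  expect_equal(inc$index_date, as.Date("2019-06-01"))

  # prior code 273 days before: blocked
  ev2 <- mk_events(c("p1", "C50.9", "2018-09-01", "H01"),
                   c("p1", "C50.9", "2019-06-01", "H01"))
  expect_equal(nrow(find_incident_cases(ev2)), 0)

  # a code exactly 730 days earlier (pre-study) does not block incidence
  idx <- as.Date("2020-06-01")
  ev3 <- mk_events(c("p1", "C18.9", format(idx - 730), "H01"),
                   c("p1", "C18.9", format(idx), "H01"))
  inc3 <- find_incident_cases(ev3)
  expect_equal(inc3$index_date, idx)
  # one day closer and the washout bites
  ev4 <- mk_events(c("p1", "C18.9", format(idx - 729), "H01"),
                   c("p1", "C18.9", format(idx), "H01"))
  expect_equal(nrow(find_incident_cases(ev4)), 0)
})

test_that("only cancer codes trigger incidence; D codes are opt-in", {
  ev <- mk_events(c("p1", "Z51.1", "2019-06-01", "H01"))
  expect_equal(nrow(find_incident_cases(ev)), 0)
  ev2 <- mk_events(c("p1", "D05.1", "2019-06-01", "H01"))
  expect_equal(nrow(find_incident_cases(ev2)), 0)
  expect_equal(nrow(find_incident_cases(ev2, include_d_codes = TRUE)), 1)
})

test_that("ICD-10 codes map to the ten analysis groups", {
  expect_equal(cancer_group_from_code("C50.9"), "Breast")
  expect_equal(cancer_group_from_code("C34.1"), "Lung")
  expect_equal(cancer_group_from_code("C16.0"), "OtherGI")
  # audit the full mapping against its defining ranges
  codes <- sprintf("C%02d", 0:97)
  grp <- cancer_group_from_code(codes)
  nums <- 0:97
  expect_true(all(grp[nums == 50] == "Breast"))
  expect_true(all(grp[nums %in% 18:21] == "Colorectal"))
  expect_true(all(grp[nums %in% 33:34] == "Lung"))
  expect_true(all(grp[nums == 61] == "Prostate"))
  expect_true(all(grp[nums %in% 51:58] == "Gynaecological"))
  expect_true(all(grp[nums %in% c(60, 62:68)] == "Genitourinary"))
  expect_true(all(grp[nums %in% 43:44] == "Skin"))
  expect_true(all(grp[nums %in% 81:96] == "Haematological"))
  expect_true(all(grp[nums %in% c(15:17, 22:26)] == "OtherGI"))
  expect_true(all(grp[nums %in% 77:79] == "Other"))
  expect_equal(cancer_group_from_code("D05"), "Other")
  expect_equal(cancer_group_from_code("garbage"), "Other")
})

test_that("same-date ties resolve by lexicographic code", {
  ev <- mk_events(c("p1", "C50.9", "2019-06-01", "H02"),
                  c("p1", "C34.1", "2019-06-01", "H01"))
  inc <- find_incident_cases(ev)
  a <- assign_group_hospital(ev, inc)
  expect_equal(a$cancer_group, "Lung")
  expect_equal(a$hospital_id, "H01")
})

test_that("document windowing keeps inclusive bounds and report types only", {
  idx <- tibble::tibble(patient_id = "p1",
                        index_date = as.Date("2020-01-01"))
  docs <- tibble::tibble(
    patient_id = "p1",
    doc_id = as.character(1:6),
    doc_type = c("MDT", "MDT", "MDT", "MDT", "OTHER", "CONSULTATION"),
    date = as.Date("2020-01-01") + c(-90, -91, 365, 366, 0, 10)
  )
  kept <- window_documents(docs, idx)
  expect_setequal(kept$doc_id, c("1", "3", "6"))
})

test_that("the exclusion cascade removes, in order, and logs each step", {
  patients <- tibble::tibble(
    patient_id = c("kid", "mgyn", "mbreast", "fprost", "nodoc", "ok"),
    sex = c("F", "M", "M", "F", "M", "F"),
    birth_date = as.Date(c("2003-06-01", "1960-01-01", "1960-01-01",
                           "1960-01-01", "1960-01-01", "1960-01-01")),
    death_date = as.Date(NA)
  )
  ev <- mk_events(
    c("kid", "C50.9", "2020-01-01", "H01"),
    c("mgyn", "C53.9", "2020-01-01", "H01"),
    c("mbreast", "C50.1", "2020-01-01", "H01"),
    c("fprost", "C61", "2020-01-01", "H01"),
    c("nodoc", "C18.0", "2020-01-01", "H01"),
    c("ok", "C34.9", "2020-01-01", "H01")
  )
  docs <- tibble::tibble(
    patient_id = c("kid", "mgyn", "mbreast", "fprost", "ok"),
    doc_id = as.character(1:5), doc_type = "CONSULTATION",
    date = as.Date("2020-01-10"), has_ps = TRUE
  )
  built <- build_cohort(patients, ev, docs)
  expect_setequal(built$cohort$patient_id, c("mbreast", "ok"))
  log <- built$log
  expect_equal(log$step, c("age_under_18", "small_or_paediatric_hospital",
                           "sex_cancer_mismatch", "no_document"))
  expect_equal(log$n_removed, c(1L, 0L, 2L, 1L))
  expect_equal(log$n_remaining, c(5L, 5L, 3L, 2L))
  expect_true(all(diff(log$n_remaining) <= 0))
})

test_that("hospital share is computed before any exclusion", {
  # 99 patients in H01 and 1 in H02 -> H02 holds exactly 1%, retained;
  # a paediatric flag still removes explicitly listed hospitals
  patients <- tibble::tibble(
    patient_id = sprintf("p%03d", 1:100), sex = "F",
    birth_date = as.Date("1960-01-01"), death_date = as.Date(NA)
  )
  ev <- tibble::tibble(
    patient_id = patients$patient_id, code = "C50.9",
    date = as.Date("2020-01-01"),
    hospital_id = c(rep("H01", 99), "H02")
  )
  docs <- tibble::tibble(
    patient_id = patients$patient_id,
    doc_id = as.character(1:100), doc_type = "MDT",
    date = as.Date("2020-02-01"), has_ps = FALSE
  )
  built <- build_cohort(patients, ev, docs)
  expect_equal(nrow(built$cohort), 100)
  built2 <- build_cohort(patients, ev, docs, paediatric_hospitals = "H02")
  expect_equal(nrow(built2$cohort), 99)
  # 1-in-101 falls below 1%
  patients3 <- dplyr::bind_rows(
    patients,
    tibble::tibble(patient_id = "p101", sex = "F",
                   birth_date = as.Date("1960-01-01"),
                   death_date = as.Date(NA))
  )
  ev3 <- dplyr::bind_rows(ev, tibble::tibble(
    patient_id = "p101", code = "C50.9", date = as.Date("2020-01-01"),
    hospital_id = "H01"
  ))
  docs3 <- dplyr::bind_rows(docs, tibble::tibble(
    patient_id = "p101", doc_id = "101", doc_type = "MDT",
    date = as.Date("2020-02-01"), has_ps = FALSE
  ))
  built3 <- build_cohort(patients3, ev3, docs3)
  expect_false("p100" %in% built3$cohort$patient_id)
  expect_equal(nrow(built3$cohort), 100)
})

test_that("outcome windows: metastasis [0, 90], death through day 365", {
  cohort <- tibble::tibble(patient_id = c("a", "b", "c", "d"),
                           index_date = as.Date("2020-01-01"))
  ev <- mk_events(
    c("a", "C78.0", format(as.Date("2020-01-01") + 30), "H01"),
    c("b", "C78.0", format(as.Date("2020-01-01") + 91), "H01"),
    c("c", "C78.0", format(as.Date("2020-01-01") + 0), "H01"),
    c("d", "C78.0", format(as.Date("2019-12-31")), "H01")
  )
  patients <- tibble::tibble(
    patient_id = c("a", "b", "c", "d"),
    death_date = as.Date("2020-01-01") + c(365, 366, NA, 100)
  )
  out <- derive_outcomes(cohort, ev, patients)
  expect_equal(out$metastatic_at_dx, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$died_within_1y, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("a death date before index warns and counts as a 1-year death", {
  cohort <- tibble::tibble(patient_id = "a",
                           index_date = as.Date("2020-06-01"))
  patients <- tibble::tibble(patient_id = "a",
                             death_date = as.Date("2020-01-01"))
  ev <- mk_events(c("a", "C50.9", "2020-06-01", "H01"))
  expect_warning(out <- derive_outcomes(cohort, ev, patients),
                 "death date before")
  expect_true(out$died_within_1y)
})

test_that("the whole builder matches a brute-force oracle on synthetic data", {
  ehr <- simulate_ehr(generator_config(n_patients = 50, seed = 7))
  m <- extract_ps_mentions(ehr$documents)
  docs <- label_documents(ehr$documents, m)
  built <- build_cohort(ehr$patients, ehr$events, docs,
                        hospital_min_share = 0)
  oracle <- brute_cohort(ehr$patients, ehr$events, docs)
  got <- dplyr::arrange(built$cohort, patient_id)
  want <- dplyr::arrange(tibble::as_tibble(oracle$cohort), patient_id)
  expect_equal(got$patient_id, want$patient_id)
  for (col in c("index_date", "sex", "age_at_dx", "cancer_group",
                "hospital_id", "n_mdt", "n_consult", "n_hosp",
                "metastatic_at_dx", "has_ps", "died_within_1y")) {
    expect_equal(got[[col]], want[[col]], info = col,
                 ignore_attr = TRUE)
  }
  # washout ground truth: every violator is absent, everyone else with
  # documents and valid demographics is present or accounted for
  expect_false(any(
    ehr$patients$patient_id[ehr$patients$gold_washout_violator] %in%
      got$patient_id
  ))
  # washout property on the result
  for (pid in got$patient_id) {
    idx <- got$index_date[got$patient_id == pid]
    ca <- ehr$events[ehr$events$patient_id == pid &
                       grepl("^C", ehr$events$code), ]
    expect_false(any(ca$date > idx - 730 & ca$date < idx), info = pid)
  }
})

test_that("cohort rows satisfy their structural invariants", {
  ehr <- simulate_ehr(generator_config(n_patients = 120, seed = 31))
  m <- extract_ps_mentions(ehr$documents)
  docs <- label_documents(ehr$documents, m)
  built <- build_cohort(ehr$patients, ehr$events, docs)
  co <- built$cohort
  expect_true(all(co$age_at_dx >= 18))
  expect_true(all(co$n_mdt + co$n_consult + co$n_hosp >= 1))
  expect_false(any(co$sex == "M" & co$cancer_group == "Gynaecological"))
  expect_false(any(co$sex == "F" & co$cancer_group == "Prostate"))
  # rerunning gives identical results (cascade is deterministic)
  built2 <- build_cohort(ehr$patients, ehr$events, docs)
  expect_identical(built, built2)
})
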