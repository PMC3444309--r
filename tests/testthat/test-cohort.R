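onto <- ctx_ontology()

test_that("cohort CSV reading preserves polarity and treats blanks as unknown", {
  csv <- paste(
    "patient_id,family_id,variant_ids,term_id,polarity,property_group,onset_age_years,duration_weeks",
    "P1,F1,p.R395C,Epilepsy,present,neurological,,",
    "P2,F2,p.Q230X,Epilepsy,absent,neurological,,",
    "P3,F3,p.Q525X,,,,,",
    sep = "\n")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(csv, path)
  co <- read_cohort(path)
  expect_equal(nrow(co$patients), 3)
  st <- phenotype_status(co, "Epilepsy", onto)
  expect_equal(st$status, c("present", "absent", "unknown"))
  # no diarrhea information anywhere: everyone unknown, not absent
  std <- phenotype_status(co, "Diarrhea", onto)
  expect_true(all(std$status == "unknown"))
})

test_that("read errors name the offending row or patient", {
  bad_pol <- paste(
    "patient_id,family_id,variant_ids,term_id,polarity",
    "P1,F1,v1,Epilepsy,maybe", sep = "\n")
  p1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(bad_pol, p1)
  expect_error(read_cohort(p1), "polarity")

  dup <- paste(
    "patient_id,family_id,variant_ids,term_id,polarity",
    "P1,F1,v1,Epilepsy,present",
    "P1,F2,v1,Ataxia,present", sep = "\n")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(dup, p2)
  expect_error(read_cohort(p2), "P1")
})

test_that("cohort round-trips through CSV and JSON", {
  fx <- build_canonical_fixture(verify = FALSE)
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    attrs <- withr::local_tempfile(fileext = ".csv")
    write_cohort(fx$cohort, path, format = fmt, attributes_path = attrs)
    back <- if (fmt == "csv") read_cohort(path, attributes_path = attrs)
            else read_cohort(path, format = "json")
    expect_equal(back$patients, fx$cohort$patients)
    expect_setequal(
      paste(back$variants$patient_id, back$variants$variant_id),
      paste(fx$cohort$variants$patient_id, fx$cohort$variants$variant_id))
    key <- function(co) {
      aa <- co$assertions[order(co$assertions$patient_id, co$assertions$term_id,
                                co$assertions$polarity), ]
      rownames(aa) <- NULL
      tibble::as_tibble(aa)
    }
    expect_equal(key(back), key(fx$cohort))
    at <- function(co) {
      a <- co$attributes[order(co$attributes$patient_id, co$attributes$attribute), ]
      rownames(a) <- NULL
      tibble::as_tibble(a)
    }
    expect_equal(at(back), at(fx$cohort))
  }
})

test_that("validate_cohort reports contradictions, unknown terms and ages", {
  co <- cohort(
    patients = tibble::tibble(patient_id = c("P1", "P2", "P3")),
    variants = tibble::tibble(patient_id = rep("P3", 3),
                              variant_id = c("v1", "v2", "v3")),
    assertions = tibble::tibble(
      patient_id = c("P1", "P1", "P2", "P3"),
      term_id = c("Epilepsy", "Epilepsy", "MadeUpTerm", "Ataxia"),
      polarity = c("present", "absent", "present", "present"),
      onset_age_years = c(NA, NA, NA, -1)))
  issues <- validate_cohort(co, onto)
  expect_setequal(unique(issues$type),
                  c("contradiction", "unknown-term", "negative-age",
                    "variant-count"))
  expect_true(all(issues$level[issues$type == "variant-count"] == "warning"))
  expect_true(all(issues$level[issues$type == "contradiction"] == "error"))
})

test_that("the canonical fixture validates cleanly", {
  fx <- build_canonical_fixture(verify = FALSE)
  issues <- validate_cohort(fx$cohort, fx$ontology)
  expect_equal(sum(issues$level == "error"), 0)
})

test_that("status is three-valued, propagates presence upward but never absence", {
  co <- cohort(
    patients = tibble::tibble(patient_id = c("P1", "P2", "P3")),
    assertions = tibble::tibble(
      patient_id = c("P1", "P2"),
      term_id = c("Ataxia", "AbnormalityOfTheCerebellum"),
      polarity = c("present", "absent")))
  # presence lifts to every ancestor
  for (a in c("AbnormalityOfTheCerebellum",
              "AbnormalityOfTheCentralNervousSystem", "Phenotype")) {
    st <- phenotype_status(co, a, onto)
    expect_equal(st$status[st$patient_id == "P1"], "present")
  }
  # absence stays literal: neither ancestors nor descendants inherit it
  st_up <- phenotype_status(co, "AbnormalityOfTheCentralNervousSystem", onto)
  expect_equal(st_up$status[st_up$patient_id == "P2"], "unknown")
  st_down <- phenotype_status(co, "Ataxia", onto)
  expect_equal(st_down$status[st_down$patient_id == "P2"], "unknown")
  # no assertions at all: unknown everywhere
  st3 <- phenotype_status(co, "Epilepsy", onto)
  expect_equal(st3$status[st3$patient_id == "P3"], "unknown")
  # hierarchy off: only literal assertions on the term count
  st_flat <- phenotype_status(co, "AbnormalityOfTheCerebellum", onto,
                              hierarchy = FALSE)
  expect_equal(st_flat$status, c("unknown", "absent", "unknown"))
})

test_that("status matches the loop oracle on random cohorts", {
  for (seed in 1:5) {
    ront <- random_dag_ontology(12, seed)
    co <- random_small_cohort(seed, ront)
    R <- oracle_reach(ront)
    for (t in sample(ront$terms$term_id, 4)) {
      for (cw in c(FALSE, TRUE)) {
        got <- phenotype_status(co, t, ront, closed_world = cw)
        want <- oracle_statuses(co, t, R, closed_world = cw)
        expect_equal(got$status, unname(want[got$patient_id]))
      }
    }
  }
})

test_that("tidy and glance summarize cohorts", {
  fx <- build_canonical_fixture(verify = FALSE)
  g <- glance(fx$cohort)
  expect_equal(g$n_patients, 25)
  expect_equal(g$n_families, 19)
  expect_equal(g$n_variants, 14)
  td <- tidy(fx$cohort)
  expect_true(all(c("patient_id", "family_id", "term_id", "polarity") %in%
                    names(td)))
})
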