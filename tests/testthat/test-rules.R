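onto <- ctx_ontology()
rules <- ctx_ruleset()

mini_cohort <- function(assertions, attributes = NULL, patients = NULL) {
  if (is.null(patients)) patients <- unique(assertions$patient_id)
  cohort(patients = tibble::tibble(patient_id = patients),
         assertions = assertions, attributes = attributes)
}

test_that("a single-rule file parses into its atoms", {
  txt <- "
parameters:
  childhood_onset_max_age: 16.0
  chronic_min_duration: 4.0
rules:
  - id: cocd-presence
    when:
      - {status: Diarrhea, polarity: present}
      - {attribute: diarrhea_onset_age, op: \"<\", value: childhood_onset_max_age}
      - {attribute: diarrhea_duration_weeks, op: \">=\", value: chronic_min_duration}
    then: {term: ChildhoodOnsetChronicDiarrhea, polarity: present, group: extra-neurological}
"
  rs <- parse_rules(txt, text = TRUE)
  expect_length(rs$rules, 1)
  kinds <- vapply(rs$rules[[1]]$antecedent, function(a) a$kind, character(1))
  expect_equal(sort(kinds),
               sort(c("status-check", "attribute-comparison",
                      "attribute-comparison")))
  expect_equal(rs$rules[[1]]$antecedent[[2]]$threshold, 16.0)
})

test_that("rule parse errors are informative", {
  expect_error(parse_rules("
rules:
  - id: r1
    when:
      - {attribute: x, op: \"<\", value: no_such_param}
    then: {term: Epilepsy, polarity: present}
", text = TRUE), "unresolved parameter")
  expect_error(parse_rules("
rules:
  - id: r2
    when:
      - {status: Epilepsy, polarity: present}
    then: {term: Epilepsy}
", text = TRUE), "polarity")
  expect_error(parse_rules("
rules:
  - id: r3
    when: []
    then: {term: Epilepsy, polarity: present}
", text = TRUE), "empty antecedent")
})

test_that("the shipped ruleset references only ontology terms", {
  all_terms <- onto$terms$term_id
  for (r in rules$rules) {
    expect_true(r$consequent$term_id %in% all_terms)
    for (a in r$antecedent) {
      if (a$kind != "attribute-comparison") {
        expect_true(a$subject %in% all_terms)
      }
    }
  }
})

test_that("childhood-onset chronic diarrhea is derived from raw fields", {
  co <- mini_cohort(
    tibble::tibble(patient_id = "P1", term_id = "Diarrhea",
                   polarity = "present", onset_age_years = 2, duration_weeks = 8),
    tibble::tibble(patient_id = c("P1", "P1"),
                   attribute = c("diarrhea_onset_age", "diarrhea_duration_weeks"),
                   value = c(2, 8)))
  enr <- apply_rules(co, rules, onto)
  st <- phenotype_status(enr, "ChildhoodOnsetChronicDiarrhea", onto)
  expect_equal(st$status, "present")
  derived <- enr$assertions[enr$assertions$derived, ]
  expect_true("ChildhoodOnsetChronicDiarrhea" %in% derived$term_id)
  expect_equal(
    derived$rule_id[derived$term_id == "ChildhoodOnsetChronicDiarrhea"],
    "cocd-presence")
})

test_that("adult-onset or short-lived diarrhea does not abstract", {
  make <- function(onset, dur) {
    mini_cohort(
      tibble::tibble(patient_id = "P1", term_id = "Diarrhea",
                     polarity = "present", onset_age_years = onset,
                     duration_weeks = dur),
      tibble::tibble(patient_id = c("P1", "P1"),
                     attribute = c("diarrhea_onset_age",
                                   "diarrhea_duration_weeks"),
                     value = c(onset, dur)))
  }
  for (case in list(c(20, 8), c(16, 8), c(2, 3.9))) {
    enr <- apply_rules(make(case[1], case[2]), rules, onto)
    st <- phenotype_status(enr, "ChildhoodOnsetChronicDiarrhea", onto)
    expect_equal(st$status, "unknown")
  }
  # boundary: duration exactly at the chronic threshold qualifies
  enr <- apply_rules(make(2, 4), rules, onto)
  expect_equal(phenotype_status(enr, "ChildhoodOnsetChronicDiarrhea",
                                onto)$status, "present")
})

test_that("asserted absence of diarrhea derives absence of the abstraction", {
  co <- mini_cohort(tibble::tibble(patient_id = "P1", term_id = "Diarrhea",
                                   polarity = "absent"))
  enr <- apply_rules(co, rules, onto)
  st <- phenotype_status(enr, "ChildhoodOnsetChronicDiarrhea", onto)
  expect_equal(st$status, "absent")
})

test_that("group link rules attach manifestation markers", {
  co <- mini_cohort(tibble::tibble(
    patient_id = c("P1", "P1"), term_id = c("Ataxia", "TendonXanthomas"),
    polarity = "present"))
  enr <- apply_rules(co, rules, onto)
  derived <- enr$assertions[enr$assertions$derived, ]
  expect_setequal(derived$term_id,
                  c("AbnormalityOfTheNervousSystem",
                    "ExtraNeurologicalAbnormality"))
  expect_equal(
    derived$property_group[derived$term_id == "AbnormalityOfTheNervousSystem"],
    "neurological")
})

test_that("a consequent term outside the ontology aborts before deriving", {
  bad <- parse_rules("
rules:
  - id: r-bad
    when:
      - {status: Epilepsy, polarity: present}
    then: {term: NotInOntology, polarity: present, group: other}
", text = TRUE)
  co <- mini_cohort(tibble::tibble(patient_id = "P1", term_id = "Epilepsy",
                                   polarity = "present"))
  expect_error(apply_rules(co, bad, onto), "NotInOntology")
})

test_that("forward chaining is idempotent and monotone", {
  for (seed in 1:5) {
    rc <- random_ctx_cohort(seed)
    once <- apply_rules(rc$cohort, rules, rc$ontology)
    twice <- apply_rules(once, rules, rc$ontology)
    expect_equal(assertion_key(twice), assertion_key(once))
    expect_true(nrow(once$assertions) >= nrow(rc$cohort$assertions))
    # raw assertions all survive
    expect_true(all(
      paste(rc$cohort$assertions$patient_id, rc$cohort$assertions$term_id,
            rc$cohort$assertions$polarity) %in%
        paste(once$assertions$patient_id, once$assertions$term_id,
              once$assertions$polarity)))
  }
})

test_that("the fixpoint does not depend on rule order", {
  for (seed in 1:5) {
    rc <- random_ctx_cohort(seed + 100)
    base <- apply_rules(rc$cohort, rules, rc$ontology)
    shuf <- apply_rules(rc$cohort, shuffle_ruleset(rules, seed), rc$ontology)
    expect_equal(assertion_key(shuf), assertion_key(base))
  }
})

test_that("explain returns one chain per deriving rule and none for asserted facts", {
  co <- mini_cohort(
    tibble::tibble(patient_id = "P1", term_id = "Diarrhea",
                   polarity = "present", onset_age_years = 2,
                   duration_weeks = 8),
    tibble::tibble(patient_id = c("P1", "P1"),
                   attribute = c("diarrhea_onset_age", "diarrhea_duration_weeks"),
                   value = c(2, 8)))
  enr <- apply_rules(co, rules, onto)
  chains <- explain_derivations(enr, "P1", "ChildhoodOnsetChronicDiarrhea")
  expect_length(chains, 1)
  expect_equal(chains[[1]]$rule_id[nrow(chains[[1]])], "cocd-presence")
  # asserted, not derived: empty explanation
  expect_length(explain_derivations(enr, "P1", "Diarrhea"), 0)

  # two distinct rules concluding the same assertion give two chains
  two <- parse_rules("
rules:
  - id: via-ataxia
    when:
      - {status: Ataxia, polarity: present}
    then: {term: CerebellarAtrophy, polarity: present, group: neurological}
  - id: via-epilepsy
    when:
      - {status: Epilepsy, polarity: present}
    then: {term: CerebellarAtrophy, polarity: present, group: neurological}
", text = TRUE)
  co2 <- mini_cohort(tibble::tibble(
    patient_id = c("P1", "P1"), term_id = c("Ataxia", "Epilepsy"),
    polarity = "present"))
  enr2 <- apply_rules(co2, two, onto)
  expect_length(explain_derivations(enr2, "P1", "CerebellarAtrophy"), 2)
})
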