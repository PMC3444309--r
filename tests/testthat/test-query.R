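onto <- ctx_ontology()

enriched_fixture <- local({
  fx <- build_canonical_fixture(verify = FALSE)
  fx$cohort <- apply_rules(fx$cohort, fx$ruleset, fx$ontology)
  fx
})

test_that("every query pattern matches the brute-force evaluator on random cohorts", {
  n_cohorts <- 200
  for (i in seq_len(n_cohorts)) {
    ront <- random_dag_ontology(sample(6:15, 1), seed = i)
    co <- random_small_cohort(i, ront,
                              n_patients = sample(3:10, 1),
                              n_variants = sample(2:6, 1))
    R <- oracle_reach(ront)
    terms <- sample(ront$terms$term_id, 2)
    t1 <- terms[1]
    v1 <- sample(unique(co$variants$variant_id), 1)

    expect_equal(variants_with_trait(co, t1, ront)$variant_id,
                 oracle_variants_with_trait(co, t1, R))
    expect_equal(variants_with_trait(co, t1, ront, polarity = "absent")$variant_id,
                 oracle_variants_with_trait(co, t1, R, polarity = "absent"))
    expect_equal(variants_with_all_traits(co, terms, ront)$variant_id,
                 oracle_variants_with_all(co, terms, R))

    assoc <- oracle_associations(co, t1, R)
    expect_equal(variants_always_associated(co, t1, ront)$variant_id,
                 sort(names(assoc)[unlist(assoc) == "always"]))
    nv <- variants_never_associated(co, t1, ront)
    expect_equal(nv$variant_id, sort(names(assoc)[unlist(assoc) == "never"]))
    expect_equal(sort(attr(nv, "do_not_know")),
                 sort(names(assoc)[unlist(assoc) == "do-not-know"]))

    expect_equal(traits_for_variant(co, v1, t1, ront)$term_id,
                 oracle_traits_for_variant(co, v1, t1, R))
    expect_equal(trait_frequency(co, v1, t1, ront)$value,
                 oracle_trait_frequency(co, v1, t1, R))
    expect_equal(cohort_frequency(co, t1, ront)$value,
                 oracle_cohort_frequency(co, t1, R))

    st <- oracle_statuses(co, t1, R)
    qualifying <- names(st)[st == "present"]
    got <- mean_attribute(co, "onset_a", list(filter_term(t1, "present")), ront)
    expect_equal(got$value, oracle_mean_attribute(co, "onset_a", qualifying))
  }
})

test_that("mean_interval averages pairwise differences over doubly-observed patients", {
  co <- cohort(
    patients = tibble::tibble(patient_id = c("P1", "P2", "P3")),
    attributes = tibble::tibble(
      patient_id = c("P1", "P1", "P2", "P2", "P3"),
      attribute = c("a", "b", "a", "b", "a"),
      value = c(3, 10, 10, 8, 99)))
  out <- mean_interval(co, "a", "b", list(), onto)
  # P1: +7, P2: -2 (negative allowed); P3 lacks b and is excluded
  expect_equal(out$value, 2.5)
  expect_equal(out$denominator, 2)
  # single patient degenerate case
  out1 <- mean_interval(co, "a", "b",
                        list(filter_term("Epilepsy", "present")), onto)
  expect_equal(out1$note, "empty-denominator")
  expect_true(is.na(out1$value))
})

test_that("percentage aggregates use floor, means round half up at 0.1", {
  co <- cohort(
    patients = tibble::tibble(patient_id = paste0("P", 1:7)),
    variants = tibble::tibble(patient_id = paste0("P", 1:7), variant_id = "v"),
    assertions = tibble::tibble(patient_id = paste0("P", 1:4),
                                term_id = "Ataxia", polarity = "present"))
  expect_equal(trait_frequency(co, "v", "Ataxia", onto)$value, 57) # floor(57.14)
  expect_equal(cohort_frequency(co, "Ataxia", onto)$value, 57)
  co2 <- cohort(
    patients = tibble::tibble(patient_id = c("P1", "P2")),
    attributes = tibble::tibble(patient_id = c("P1", "P2"),
                                attribute = "age", value = c(1.0, 1.05)))
  expect_equal(mean_attribute(co2, "age", list(), onto)$value, 1.0) # 1.025 -> 1.0
  co3 <- cohort(
    patients = tibble::tibble(patient_id = c("P1", "P2")),
    attributes = tibble::tibble(patient_id = c("P1", "P2"),
                                attribute = "age", value = c(1.0, 1.1)))
  expect_equal(mean_attribute(co3, "age", list(), onto)$value, 1.1) # 1.05 rounds up
})

test_that("empty denominators are reported, never zero or an error", {
  empty <- cohort(patients = tibble::tibble(patient_id = character(0)))
  out <- cohort_frequency(empty, "Epilepsy", onto)
  expect_equal(out$note, "empty-denominator")
  expect_true(is.na(out$value))
  expect_equal(nrow(variants_with_trait(empty, "Epilepsy", onto)), 0)
  out2 <- trait_frequency(enriched_fixture$cohort, "p.NOSUCH", "Ataxia", onto)
  expect_equal(out2$note, "empty-denominator")
})

test_that("hierarchy superset: a parent query covers every child query", {
  for (seed in 1:20) {
    ront <- random_dag_ontology(12, seed + 300)
    co <- random_small_cohort(seed + 300, ront)
    for (t in sample(ront$terms$term_id, 3)) {
      parent_set <- variants_with_trait(co, t, ront)$variant_id
      kids <- ront$terms$term_id[vapply(ront$terms$parents,
                                        function(p) t %in% p, logical(1))]
      for (k in kids) {
        expect_true(all(variants_with_trait(co, k, ront)$variant_id %in%
                          parent_set))
      }
    }
  }
})

test_that("adding an assertion-free patient never changes a variant-set answer", {
  for (seed in 1:10) {
    ront <- random_dag_ontology(10, seed + 500)
    co <- random_small_cohort(seed + 500, ront)
    bigger <- co
    bigger$patients <- dplyr::bind_rows(
      bigger$patients, tibble::tibble(patient_id = "GHOST", family_id = "GHOST"))
    t1 <- sample(ront$terms$term_id, 1)
    expect_equal(variants_with_trait(bigger, t1, ront),
                 variants_with_trait(co, t1, ront))
    expect_equal(variants_never_associated(bigger, t1, ront)$variant_id,
                 variants_never_associated(co, t1, ront)$variant_id)
    expect_equal(variants_always_associated(bigger, t1, ront),
                 variants_always_associated(co, t1, ront))
    # denominators of cohort frequencies do move
    expect_equal(cohort_frequency(bigger, t1, ront)$denominator,
                 cohort_frequency(co, t1, ront)$denominator + 1)
  }
})

test_that("association classes partition the carried variants", {
  for (seed in 1:20) {
    ront <- random_dag_ontology(10, seed + 700)
    co <- random_small_cohort(seed + 700, ront)
    t1 <- sample(ront$terms$term_id, 1)
    va <- variant_associations(co, t1, ront)
    expect_setequal(va$variant_id, unique(co$variants$variant_id))
    expect_true(all(va$association %in%
                      c("always", "never", "mixed", "do-not-know")))
    always <- variants_always_associated(co, t1, ront)$variant_id
    never <- variants_never_associated(co, t1, ront)$variant_id
    expect_length(intersect(always, never), 0)
  }
})

test_that("closed-world mode empties do-not-know and widens never-associated", {
  fx <- enriched_fixture
  ow <- variants_never_associated(fx$cohort, "ChildhoodOnsetChronicDiarrhea",
                                  onto)
  cw <- variants_never_associated(fx$cohort, "ChildhoodOnsetChronicDiarrhea",
                                  onto, closed_world = TRUE)
  expect_length(attr(cw, "do_not_know"), 0)
  expect_true(all(ow$variant_id %in% cw$variant_id))
  expect_true(all(attr(ow, "do_not_know") %in% cw$variant_id))
})

test_that("evaluate_query dispatches, orders rows and validates arity", {
  fx <- build_canonical_fixture(verify = FALSE)
  spec <- query_spec("variants_with_all_traits",
                     term_ids = c("Epilepsy", "Dementia"))
  res <- evaluate_query(spec, fx$cohort, fx$ontology, fx$ruleset)
  expect_equal(res$variant_id, sort(res$variant_id))
  expect_equal(result_note(res), "ok")

  expect_error(query_spec("trait_frequency", term_ids = "Ataxia"), "variant")
  expect_error(query_spec("no_such_pattern"), "available")
  expect_error(query_spec("mean_attribute"), "attribute")

  # every pattern runs ok on the canonical fixture
  specs <- list(
    query_spec("variants_with_trait", "ChildhoodOnsetChronicDiarrhea"),
    query_spec("variants_with_all_traits", c("Epilepsy", "Dementia")),
    query_spec("variants_always_associated", "ChildhoodOnsetChronicDiarrhea"),
    query_spec("variants_never_associated", "ChildhoodOnsetChronicDiarrhea"),
    query_spec("traits_for_variant", variant_id = "p.R395C",
               scope_class = "AbnormalityOfTheCerebellum"),
    query_spec("trait_frequency", "Ataxia", variant_id = "p.R395C"),
    query_spec("cohort_frequency", "Epilepsy"),
    query_spec("mean_attribute", attribute = "neurological_symptom_onset_age",
               filters = list(filter_term("Xanthoma", "present"))),
    query_spec("mean_interval", start_attribute = "diarrhea_onset_age",
               end_attribute = "neurological_symptom_onset_age",
               filters = list(filter_variant("p.R395C"))))
  for (s in specs) {
    res <- evaluate_query(s, fx$cohort, fx$ontology, fx$ruleset)
    expect_equal(result_note(res), "ok")
  }
})
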