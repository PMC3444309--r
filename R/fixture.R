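#' Canonical synthetic CTX cohort
#'
#' Builds the deterministic synthetic cohort that stands in for the
#' original (undeposited) CTX study dataset: 25 patients from 19 families
#' carrying 14 CYP27A1 variants — eight published labels plus six
#' unmistakably synthetic placeholders (`p.SYN001`..`p.SYN006`). The cohort
#' is *raw*: childhood-onset chronic diarrhea appears only as asserted
#' absences; presences are derivable exclusively through the abstraction
#' rules. Patient-level layout (who carries what, onset ages) is a fixed,
#' hand-curated choice; only the aggregate structure is meaningful, and it
#' is verified against the full constraint set on every build.
#'
#' @param verify Run [verify_constraints()] and abort naming the first
#'   failed constraint (default `TRUE`).
#' @return A list with elements `cohort` (raw `pheno_cohort`), `ontology`
#'   (the CTX ontology) and `ruleset` (the CTX ruleset).
#' @examples
#' fx <- build_canonical_fixture()
#' glance(fx$cohort)
#' @export
build_canonical_fixture <- function(verify = TRUE) {
  ontology <- ctx_ontology()
  ruleset <- ctx_ruleset()

  patients <- tibble::tribble(
    ~patient_id, ~family_id,
    "CTX-01", "F01", "CTX-02", "F02", "CTX-03", "F03",
    "564385-1", "F04", "CTX-05", "F04",
    "CTX-06", "F05", "CTX-07", "F05",
    "CTX-08", "F06", "CTX-09", "F07", "CTX-10", "F08",
    "CTX-11", "F09", "CTX-12", "F10", "CTX-13", "F11", "CTX-14", "F12",
    "CTX-15", "F09", "CTX-16", "F13", "CTX-17", "F14", "CTX-18", "F15",
    "CTX-19", "F16", "CTX-20", "F17", "CTX-21", "F18",
    "CTX-22", "F13", "CTX-23", "F02", "CTX-24", "F10", "CTX-25", "F19"
  )

  carriage <- tibble::tribble(
    ~patient_id, ~variant_id,
    "CTX-01", "c.844+1G>T",
    "CTX-02", "p.Q230X",
    "CTX-03", "p.Q525X",
    "564385-1", "p.R395C",
    "CTX-05", "p.R395C", "CTX-06", "p.R395C", "CTX-07", "p.R395C",
    "CTX-08", "p.R395C", "CTX-09", "p.R395C", "CTX-10", "p.R395C",
    "CTX-11", "p.R405W",
    "CTX-12", "p.T343R",
    "CTX-13", "p.N403K",
    "CTX-14", "p.T339M",
    "CTX-15", "p.R405W",
    "CTX-16", "p.SYN001",
    "CTX-17", "p.SYN002",
    "CTX-18", "p.SYN003",
    "CTX-19", "p.SYN004",
    "CTX-20", "p.SYN005",
    "CTX-21", "p.SYN006",
    "CTX-22", "p.SYN001", "CTX-22", "p.SYN002",
    "CTX-23", "p.Q230X",
    "CTX-24", "p.T343R",
    "CTX-25", "c.844+1G>T"
  )
  carriage$gene <- "CYP27A1"

  pres <- function(ids, term, group, onset = NA_real_, dur = NA_real_) {
    tibble::tibble(patient_id = ids, term_id = term, polarity = "present",
                   property_group = group, onset_age_years = onset,
                   duration_weeks = dur)
  }
  abs_ <- function(ids, term, group) {
    tibble::tibble(patient_id = ids, term_id = term, polarity = "absent",
                   property_group = group, onset_age_years = NA_real_,
                   duration_weeks = NA_real_)
  }

  diarrhea <- tibble::tribble(
    ~patient_id, ~onset, ~dur,
    "CTX-01", 3.0, 12, "CTX-02", 5.0, 8,
    "CTX-05", 8.0, 6, "CTX-06", 8.0, 10, "CTX-07", 8.0, 26,
    "CTX-08", 6.0, 52, "CTX-09", 7.4, 8,
    "CTX-11", 2.0, 8, "CTX-12", 4.5, 6, "CTX-13", 1.0, 20, "CTX-14", 10.0, 5
  )

  assertions <- dplyr::bind_rows(
    pres(diarrhea$patient_id, "Diarrhea", "extra-neurological",
         diarrhea$onset, diarrhea$dur),
    abs_(c("CTX-03", "564385-1"), "Diarrhea", "extra-neurological"),
    pres(c("CTX-01", "CTX-05", "CTX-06", "CTX-11", "CTX-12", "CTX-13",
           "CTX-14", "CTX-17"), "Epilepsy", "neurological"),
    abs_(c("CTX-02", "CTX-03", "564385-1"), "Epilepsy", "neurological"),
    pres(c("CTX-01", "CTX-02", "CTX-03", "CTX-05", "CTX-07", "CTX-08",
           "CTX-11", "CTX-12", "CTX-13", "CTX-14", "CTX-16", "CTX-18",
           "CTX-19"), "Dementia", "neurological"),
    abs_(c("CTX-06", "CTX-17"), "Dementia", "neurological"),
    pres(c("CTX-01", "CTX-05", "CTX-06", "CTX-07", "CTX-08", "CTX-12"),
         "Ataxia", "neurological"),
    pres("CTX-09", "ArnoldChiariTypeI", "neurological"),
    pres("CTX-10", "PeripheralNeuropathy", "neurological"),
    pres(c("CTX-01", "CTX-02", "564385-1", "CTX-05", "CTX-06", "CTX-07",
           "CTX-10", "CTX-11", "CTX-13", "CTX-15"),
         "TendonXanthomas", "extra-neurological"),
    abs_(c("CTX-03", "CTX-08", "CTX-09", "CTX-12", "CTX-14"),
         "Xanthoma", "extra-neurological"),
    pres(c("CTX-01", "CTX-05", "CTX-12", "CTX-19"), "Cataract",
         "extra-neurological"),
    pres(c("CTX-01", "564385-1", "CTX-05", "CTX-11", "CTX-16"),
         "ElevatedCholestanol", "diagnostic-study")
  )

  attr_rows <- function(ids, name, values) {
    tibble::tibble(patient_id = ids, attribute = name, value = values)
  }
  nso <- tibble::tribble(
    ~patient_id, ~value,
    "CTX-01", 12.0, "CTX-02", 19.0, "CTX-03", 20.0, "564385-1", 30.0,
    "CTX-05", 15.0, "CTX-06", 16.0, "CTX-07", 16.0, "CTX-08", 12.0,
    "CTX-09", 13.4, "CTX-10", 40.0, "CTX-11", 30.0, "CTX-12", 16.6,
    "CTX-13", 20.0, "CTX-14", 18.0, "CTX-15", 32.0, "CTX-16", 22.0,
    "CTX-19", 35.5
  )
  xage <- tibble::tribble(
    ~patient_id, ~value,
    "CTX-01", 10.0, "CTX-02", 25.0, "564385-1", 28.0, "CTX-05", 14.0,
    "CTX-06", 15.0, "CTX-07", 20.0, "CTX-10", 35.0, "CTX-11", 24.0,
    "CTX-13", 18.0, "CTX-15", 30.0
  )
  diag_age <- tibble::tibble(
    patient_id = patients$patient_id,
    value = c(25, 30, 35, 42, 24, 26, 28, 20, 22, 48, 38, 27, 31,
              29, 40, 33, 36, 41, 44, 30, 34, 37, 28, 32, 39)
  )

  attributes <- dplyr::bind_rows(
    attr_rows(nso$patient_id, "neurological_symptom_onset_age", nso$value),
    attr_rows(diarrhea$patient_id, "diarrhea_onset_age", diarrhea$onset),
    attr_rows(diarrhea$patient_id, "diarrhea_duration_weeks", diarrhea$dur),
    attr_rows(xage$patient_id, "xanthoma_onset_age", xage$value),
    attr_rows(diag_age$patient_id, "age_at_diagnosis", diag_age$value)
  )

  co <- cohort(patients, carriage, assertions, attributes,
               provenance = "synthetic canonical CTX fixture (phenoquery)")

  if (verify) {
    report <- verify_constraints(co, ontology, ruleset)
    if (!all(report$pass)) {
      bad <- report$name[!report$pass][1]
      stop("canonical fixture violates constraint '", bad, "': expected ",
           report$expected[report$name == bad], ", computed ",
           report$computed[report$name == bad], call. = FALSE)
    }
  }
  list(cohort = co, ontology = ontology, ruleset = ruleset)
}

#' The worked mini-scenario of variants with and without a trait
#'
#' A seven-patient scenario illustrating open-world querying of
#' childhood-onset chronic diarrhea: four patients with childhood-onset
#' chronic diarrhea (derivable), carrying p.Q230X, p.R395C, p.R405W and
#' p.T343R; one patient (564385-1, p.R395C) with asserted absence of
#' diarrhea; and two carriers of c.844+1G>T and p.Q525X with no diarrhea
#' information at all — the "Do not know" answers.
#'
#' @return A list with `cohort`, `ontology`, `ruleset`.
#' @export
build_mini_scenario <- function() {
  ontology <- ctx_ontology()
  ruleset <- ctx_ruleset()
  patients <- tibble::tibble(
    patient_id = c("564385-1", "MINI-P2", "MINI-P3", "MINI-P4", "MINI-P5",
                   "MINI-P6", "MINI-P7"),
    family_id = paste0("MINI-F", 1:7))
  carriage <- tibble::tibble(
    patient_id = patients$patient_id,
    variant_id = c("p.R395C", "p.Q230X", "p.R395C", "p.R405W", "p.T343R",
                   "c.844+1G>T", "p.Q525X"),
    gene = "CYP27A1")
  dd <- tibble::tibble(
    patient_id = c("MINI-P2", "MINI-P3", "MINI-P4", "MINI-P5"),
    onset = c(3.0, 5.0, 2.0, 6.5), dur = c(10, 8, 12, 6))
  assertions <- dplyr::bind_rows(
    tibble::tibble(patient_id = dd$patient_id, term_id = "Diarrhea",
                   polarity = "present", property_group = "extra-neurological",
                   onset_age_years = dd$onset, duration_weeks = dd$dur),
    tibble::tibble(patient_id = "564385-1", term_id = "Diarrhea",
                   polarity = "absent", property_group = "extra-neurological",
                   onset_age_years = NA_real_, duration_weeks = NA_real_))
  attributes <- dplyr::bind_rows(
    tibble::tibble(patient_id = dd$patient_id,
                   attribute = "diarrhea_onset_age", value = dd$onset),
    tibble::tibble(patient_id = dd$patient_id,
                   attribute = "diarrhea_duration_weeks", value = dd$dur))
  list(cohort = cohort(patients, carriage, assertions, attributes,
                       provenance = "worked open-world mini-scenario"),
       ontology = ontology, ruleset = ruleset)
}

#' The constraint set the canonical fixture must satisfy
#'
#' Every printed aggregate the synthetic cohort is required to reproduce,
#' as machine-checkable constraints: each row carries a description, the
#' expected value, and a check function computing the value from the raw
#' and rule-enriched cohorts through the query engine.
#'
#' @return A tibble: `name`, `description`, `expected` (character),
#'   `check` (list of functions `(raw, enriched, ontology)` returning the
#'   computed value).
#' @export
ctx_constraints <- function() {
  cc <- function(name, description, expected, check) {
    tibble::tibble(name = name, description = description,
                   expected = as.character(expected), check = list(check))
  }
  setchr <- function(x) paste(sort(x), collapse = ";")
  dplyr::bind_rows(
    cc("n-patients", "cohort size", 25,
       function(raw, enr, on) nrow(raw$patients)),
    cc("n-families", "distinct families", 19,
       function(raw, enr, on) dplyr::n_distinct(raw$patients$family_id)),
    cc("n-variants", "distinct CYP27A1 variants", 14,
       function(raw, enr, on) dplyr::n_distinct(raw$variants$variant_id)),
    cc("raw-cocd-presences",
       "raw cohort holds no asserted presence of childhood-onset chronic diarrhea (derivable only)",
       0,
       function(raw, enr, on) {
         sum(raw$assertions$term_id == "ChildhoodOnsetChronicDiarrhea" &
               raw$assertions$polarity == "present")
       }),
    cc("index-absence-patient",
       "patient 564385-1 carries p.R395C with derived absence of childhood-onset chronic diarrhea",
       "yes",
       function(raw, enr, on) {
         carries <- any(raw$variants$patient_id == "564385-1" &
                          raw$variants$variant_id == "p.R395C")
         st <- phenotype_status(enr, "ChildhoodOnsetChronicDiarrhea", on)
         absent <- st$status[st$patient_id == "564385-1"] == "absent"
         if (carries && length(absent) == 1 && absent) "yes" else "no"
       }),
    cc("cocd-frequency",
       "presence of childhood-onset chronic diarrhea in 44% of patients",
       44,
       function(raw, enr, on) {
         cohort_frequency(enr, "ChildhoodOnsetChronicDiarrhea", on)$value
       }),
    cc("cocd-present-patients",
       "11 of 25 patients with derived presence", 11,
       function(raw, enr, on) {
         cohort_frequency(enr, "ChildhoodOnsetChronicDiarrhea", on)$numerator
       }),
    cc("cocd-variants-with",
       "7 of 14 variants associated with presence", 7,
       function(raw, enr, on) {
         nrow(variants_with_trait(enr, "ChildhoodOnsetChronicDiarrhea", on))
       }),
    cc("cocd-worked-example-variants",
       "the four worked-example variants are among the presence-associated set",
       "yes",
       function(raw, enr, on) {
         got <- variants_with_trait(enr, "ChildhoodOnsetChronicDiarrhea", on)$variant_id
         need <- c("p.Q230X", "p.R395C", "p.R405W", "p.T343R")
         if (all(need %in% got)) "yes" else "no"
       }),
    cc("cocd-mixed-variant",
       "exactly one variant (p.R395C) seen with both presence and absence",
       "p.R395C",
       function(raw, enr, on) {
         va <- variant_associations(enr, "ChildhoodOnsetChronicDiarrhea", on)
         setchr(va$variant_id[va$association == "mixed"])
       }),
    cc("cocd-never-variant",
       "only p.Q525X never associated", "p.Q525X",
       function(raw, enr, on) {
         setchr(variants_never_associated(
           enr, "ChildhoodOnsetChronicDiarrhea", on)$variant_id)
       }),
    cc("epilepsy-frequency", "presence of epilepsy in 32% of patients", 32,
       function(raw, enr, on) cohort_frequency(enr, "Epilepsy", on)$value),
    cc("dementia-frequency", "presence of dementia in 52% of patients", 52,
       function(raw, enr, on) cohort_frequency(enr, "Dementia", on)$value),
    cc("epilepsy-dementia-variants",
       "exactly the six listed variants co-associated with epilepsy and dementia",
       setchr(c("c.844+1G>T", "p.N403K", "p.R395C", "p.R405W", "p.T339M",
                "p.T343R")),
       function(raw, enr, on) {
         setchr(variants_with_all_traits(enr, c("Epilepsy", "Dementia"),
                                         on)$variant_id)
       }),
    cc("r395c-carriers", "p.R395C carried by 7 patients", 7,
       function(raw, enr, on) {
         dplyr::n_distinct(raw$variants$patient_id[
           raw$variants$variant_id == "p.R395C"])
       }),
    cc("r395c-ataxia-frequency",
       "p.R395C associated with ataxia in 57% of its carriers (4 of 7)", 57,
       function(raw, enr, on) {
         trait_frequency(enr, "p.R395C", "Ataxia", on)$value
       }),
    cc("r395c-cerebellar-traits",
       "cerebellar-scope traits of p.R395C carriers are ataxia and Arnold-Chiari type I",
       setchr(c("ArnoldChiariTypeI", "Ataxia")),
       function(raw, enr, on) {
         setchr(traits_for_variant(enr, "p.R395C",
                                   "AbnormalityOfTheCerebellum", on)$term_id)
       }),
    cc("nso-xanthoma-present",
       "mean neurological onset age 23 years with xanthomas", 23,
       function(raw, enr, on) {
         mean_attribute(enr, "neurological_symptom_onset_age",
                        list(filter_term("Xanthoma", "present")), on)$value
       }),
    cc("nso-xanthoma-absent",
       "mean neurological onset age 16 years without xanthomas", 16,
       function(raw, enr, on) {
         mean_attribute(enr, "neurological_symptom_onset_age",
                        list(filter_term("Xanthoma", "absent")), on)$value
       }),
    cc("nso-xp-r405w",
       "mean neurological onset age 31 years with xanthomas and p.R405W", 31,
       function(raw, enr, on) {
         mean_attribute(enr, "neurological_symptom_onset_age",
                        list(filter_term("Xanthoma", "present"),
                             filter_variant("p.R405W")), on)$value
       }),
    cc("nso-xp-r395c",
       "mean neurological onset age 23.4 years with xanthomas and p.R395C",
       23.4,
       function(raw, enr, on) {
         mean_attribute(enr, "neurological_symptom_onset_age",
                        list(filter_term("Xanthoma", "present"),
                             filter_variant("p.R395C")), on)$value
       }),
    cc("nso-xa-r395c",
       "mean neurological onset age 12.7 years without xanthomas and with p.R395C",
       12.7,
       function(raw, enr, on) {
         mean_attribute(enr, "neurological_symptom_onset_age",
                        list(filter_term("Xanthoma", "absent"),
                             filter_variant("p.R395C")), on)$value
       }),
    cc("diarrhea-to-neuro-interval-r395c",
       "mean 7 years from diarrhea onset to first neurological symptom in p.R395C carriers",
       7,
       function(raw, enr, on) {
         mean_interval(enr, "diarrhea_onset_age",
                       "neurological_symptom_onset_age",
                       list(filter_variant("p.R395C")), on)$value
       })
  )
}

#' Verify a cohort against a constraint set
#'
#' Applies the ruleset (if the cohort is not already enriched) and
#' evaluates every constraint, reporting computed versus expected values.
#' An empty constraint set passes vacuously.
#'
#' @param cohort A raw or enriched `pheno_cohort`.
#' @param ontology A `pheno_ontology`.
#' @param ruleset A `pheno_ruleset`.
#' @param constraints A constraint tibble as from [ctx_constraints()].
#' @return A `constraint_report` tibble: `name`, `description`, `expected`,
#'   `computed`, `pass`; attribute `overall_pass`.
#' @export
verify_constraints <- function(cohort, ontology, ruleset,
                               constraints = ctx_constraints()) {
  enriched <- if (isTRUE(cohort$enriched)) cohort
              else apply_rules(cohort, ruleset, ontology)
  if (nrow(constraints) == 0) {
    out <- tibble::tibble(name = character(0), description = character(0),
                          expected = character(0), computed = character(0),
                          pass = logical(0))
  } else {
    computed <- purrr::map_chr(constraints$check, function(f) {
      as.character(f(cohort, enriched, ontology))
    })
    out <- tibble::tibble(name = constraints$name,
                          description = constraints$description,
                          expected = constraints$expected,
                          computed = computed,
                          pass = computed == constraints$expected)
  }
  attr(out, "overall_pass") <- all(out$pass)
  class(out) <- c("constraint_report", class(out))
  out
}

#' @export
print.constraint_report <- function(x, ...) {
  ok <- sum(x$pass)
  cat("<constraint_report> ", ok, "/", nrow(x), " constraints satisfied\n",
      sep = "")
  NextMethod()
}
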