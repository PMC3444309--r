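# Programmatic fixtures: random DAG ontologies (via the tabular parser, so
# generation shares nothing with the package's graph code) and small random
# cohorts with attributes.

random_dag_ontology <- function(n_terms, seed) {
  set.seed(seed)
  ids <- paste0("T", seq_len(n_terms))
  parent_ids <- character(n_terms)
  for (i in seq_len(n_terms)) {
    if (i == 1) {
      parent_ids[i] <- ""
    } else {
      k <- sample(1:min(2, i - 1), 1)
      parent_ids[i] <- paste(sample(ids[seq_len(i - 1)], k), collapse = ";")
    }
  }
  tsv <- paste(
    c("term_id\tlabel\tparent_ids\tsynonyms",
      paste(ids, ids, parent_ids, "", sep = "\t")),
    collapse = "\n")
  parse_ontology(tsv, format = "tabular", text = TRUE)
}

# Small cohort with random assertions over a given ontology plus random
# clinical attributes; suited to oracle comparisons.
random_small_cohort <- function(seed, ontology, n_patients = 8,
                                n_variants = 5) {
  cfg <- generator_config(seed = seed, n_patients = n_patients,
                          n_variants = n_variants,
                          prevalence = stats::setNames(
                            rep(0.35, nrow(ontology$terms)),
                            ontology$terms$term_id),
                          absence_rate = 0.3)
  co <- generate_random_cohort(cfg, ontology)
  set.seed(seed + 10000L)
  pids <- co$patients$patient_id
  co$attributes <- dplyr::bind_rows(
    tibble::tibble(
      patient_id = sample(pids, max(1, length(pids) %/% 2)),
      attribute = "onset_a", value = round(runif(max(1, length(pids) %/% 2), 0.5, 50), 1)),
    tibble::tibble(
      patient_id = sample(pids, max(1, length(pids) %/% 2)),
      attribute = "onset_b", value = round(runif(max(1, length(pids) %/% 2), 0.5, 50), 1))
  )
  co
}

# Random cohort over the CTX ontology with diarrhea attributes aligned to
# the diarrhea assertions, so the abstraction rules have something to chew.
random_ctx_cohort <- function(seed, n_patients = 8) {
  onto <- ctx_ontology()
  prevalence <- c(Epilepsy = 0.35, Dementia = 0.35, Ataxia = 0.25,
                  Diarrhea = 0.45, TendonXanthomas = 0.3, Cataract = 0.2,
                  ElevatedCholestanol = 0.3)
  cfg <- generator_config(seed = seed, n_patients = n_patients,
                          n_variants = 5, prevalence = prevalence,
                          absence_rate = 0.25)
  co <- generate_random_cohort(cfg, onto)
  dd <- co$assertions[co$assertions$term_id == "Diarrhea" &
                        co$assertions$polarity == "present", ]
  if (nrow(dd) > 0) {
    co$attributes <- dplyr::bind_rows(
      co$attributes,
      tibble::tibble(patient_id = dd$patient_id,
                     attribute = "diarrhea_onset_age",
                     value = dd$onset_age_years),
      tibble::tibble(patient_id = dd$patient_id,
                     attribute = "diarrhea_duration_weeks",
                     value = dd$duration_weeks))
  }
  list(cohort = co, ontology = onto)
}

shuffle_ruleset <- function(ruleset, seed) {
  set.seed(seed)
  ruleset$rules <- sample(ruleset$rules)
  ruleset
}

# Canonical sorted view of a cohort's assertions, for fixpoint comparisons.
assertion_key <- function(cohort) {
  aa <- cohort$assertions[, c("patient_id", "term_id", "polarity")]
  aa <- dplyr::distinct(aa)
  aa <- aa[order(aa$patient_id, aa$term_id, aa$polarity), ]
  rownames(aa) <- NULL
  aa
}
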