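#' Configuration for the random cohort generator
#'
#' @param seed Integer seed; the same configuration always yields the same
#'   cohort.
#' @param n_patients,n_variants Cohort dimensions.
#' @param prevalence Named numeric vector mapping term ids to presence
#'   probabilities; defaults to 0.3 for every leaf under the ontology's
#'   first root at generation time.
#' @param missingness Probability that a generated assertion is dropped
#'   (becomes unknown information).
#' @param absence_rate Probability that a non-case receives an explicit
#'   absence assertion (rather than staying unknown).
#' @return A `generator_config` object.
#' @export
generator_config <- function(seed, n_patients = 25, n_variants = 14,
                             prevalence = NULL, missingness = 0,
                             absence_rate = 0.2) {
  probs <- c(prevalence, missingness = missingness,
             absence_rate = absence_rate)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_patients < 1 || n_variants < 1) {
    stop("n_patients and n_variants must be positive", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 n_variants = as.integer(n_variants), prevalence = prevalence,
                 missingness = missingness, absence_rate = absence_rate),
            class = "generator_config")
}

local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Leaf terms of an ontology
#'
#' Terms with no children — the most specific phenotype descriptions, the
#' level at which the random generator asserts traits.
#'
#' @param ontology A `pheno_ontology`.
#' @param under Optional term id; restrict to leaves subsumed by it.
#' @return Character vector of term ids.
#' @export
ontology_leaves <- function(ontology, under = NULL) {
  ids <- ontology$terms$term_id
  has_child <- unique(unlist(ontology$terms$parents))
  leaves <- setdiff(ids, has_child)
  if (!is.null(under)) {
    check_term(ontology, under)
    scope <- c(under, descendants(ontology, under))
    leaves <- intersect(leaves, scope)
  }
  leaves
}

#' Generate a seeded random cohort
#'
#' Draws a reproducible cohort emulating the statistical structure of a
#' small rare-disease study: each patient carries one or two variants drawn
#' uniformly from the variant pool; each leaf phenotype in the prevalence
#' map is asserted present with its prevalence, otherwise asserted absent
#' with probability `absence_rate`, otherwise left unknown; assertions are
#' then dropped with probability `missingness`. Onset ages are uniform on
#' 0.5-60.0 years at 0.1 resolution, durations uniform on 1-104 weeks.
#' Traits are drawn independently per term — no comorbidity correlation.
#'
#' @param config A [generator_config()].
#' @param ontology A `pheno_ontology`; prevalence defaults to 0.3 on every
#'   leaf under its first root.
#' @return A `pheno_cohort`.
#' @examples
#' onto <- ctx_ontology()
#' cfg <- generator_config(seed = 1, n_patients = 6, n_variants = 3,
#'                         prevalence = c(Epilepsy = 0.5, Ataxia = 0.3))
#' generate_random_cohort(cfg, onto)
#' @export
generate_random_cohort <- function(config, ontology) {
  stopifnot(inherits(config, "generator_config"),
            inherits(ontology, "pheno_ontology"))
  prevalence <- config$prevalence
  if (is.null(prevalence)) {
    leaves <- ontology_leaves(ontology, under = ontology$roots[1])
    prevalence <- stats::setNames(rep(0.3, length(leaves)), leaves)
  }
  unknown_terms <- setdiff(names(prevalence), ontology$terms$term_id)
  if (length(unknown_terms) > 0) {
    stop("prevalence names not in ontology: ",
         paste(unknown_terms, collapse = ", "), call. = FALSE)
  }

  local_seed(config$seed, {
    pids <- sprintf("PT-%04d", seq_len(config$n_patients))
    vlabs <- sprintf("VAR-%03d", seq_len(config$n_variants))
    variants <- dplyr::bind_rows(purrr::map(pids, function(p) {
      k <- sample(1:2, 1)
      tibble::tibble(patient_id = p,
                     variant_id = sample(vlabs, min(k, length(vlabs))),
                     gene = "GENE1")
    }))
    pid_v <- term_v <- pol_v <- character(0)
    onset_v <- dur_v <- numeric(0)
    for (p in pids) {
      for (t in names(prevalence)) {
        u <- stats::runif(1)
        if (u < prevalence[[t]]) {
          pid_v <- c(pid_v, p); term_v <- c(term_v, t)
          pol_v <- c(pol_v, "present")
          onset_v <- c(onset_v, round(stats::runif(1, 0.5, 60.0), 1))
          dur_v <- c(dur_v, round(stats::runif(1, 1, 104), 1))
        } else if (stats::runif(1) < config$absence_rate) {
          pid_v <- c(pid_v, p); term_v <- c(term_v, t)
          pol_v <- c(pol_v, "absent")
          onset_v <- c(onset_v, NA_real_); dur_v <- c(dur_v, NA_real_)
        }
      }
    }
    assertions <- if (length(pid_v) > 0) {
      tibble::tibble(patient_id = pid_v, term_id = term_v, polarity = pol_v,
                     property_group = "other", onset_age_years = onset_v,
                     duration_weeks = dur_v)
    } else NULL
    if (!is.null(assertions) && config$missingness > 0) {
      keep <- stats::runif(nrow(assertions)) >= config$missingness
      assertions <- assertions[keep, , drop = FALSE]
    }
    cohort(
      patients = tibble::tibble(patient_id = pids, family_id = pids),
      variants = variants, assertions = assertions,
      provenance = paste0("random cohort, seed ", config$seed)
    )
  })
}
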