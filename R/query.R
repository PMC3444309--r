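#' Bidirectional phenotype-genotype query patterns
#'
#' The query layer answers the competency-question patterns over an
#' enriched cohort: genotype to phenotype (which traits accompany a
#' variant) and phenotype to genotype (which variants accompany a trait),
#' with is-a hierarchy expansion, open-world handling of unknowns, and
#' set or aggregate answers. Percentages use floor (truncation) to an
#' integer; means are reported at 0.1-year precision, rounded half up.
#'
#' @name query-patterns
NULL

round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

aggregate_outcome <- function(value, numerator, denominator, unit,
                              note = "ok") {
  tibble::tibble(value = value, numerator = numerator,
                 denominator = denominator, unit = unit, note = note)
}

variant_universe <- function(cohort) sort(unique(cohort$variants$variant_id))

status_by_variant <- function(cohort, term_id, ontology, hierarchy,
                              closed_world = FALSE) {
  st <- phenotype_status(cohort, term_id, ontology, hierarchy = hierarchy,
                         closed_world = closed_world)
  dplyr::inner_join(cohort$variants, st, by = "patient_id")
}

#' Variants observed with (or without) a trait
#'
#' The distinct genetic variants carried by at least one patient whose
#' three-valued status for `term_id` equals `polarity`. For
#' `polarity = "present"` the term is hierarchy-expanded by default; for
#' `"absent"` only literal absence assertions count (open world), unless
#' `closed_world = TRUE` reads blanks as absence.
#'
#' @param cohort An enriched `pheno_cohort`.
#' @param term_id Ontology term id.
#' @param ontology A `pheno_ontology`.
#' @param polarity `"present"` or `"absent"`.
#' @param hierarchy Expand to descendants for presence (default `TRUE`).
#' @param closed_world Treat unknown as absent (default `FALSE`).
#' @return A tibble with a sorted `variant_id` column.
#' @export
variants_with_trait <- function(cohort, term_id, ontology,
                                polarity = c("present", "absent"),
                                hierarchy = TRUE, closed_world = FALSE) {
  polarity <- match.arg(polarity)
  sv <- status_by_variant(cohort, term_id, ontology, hierarchy, closed_world)
  tibble::tibble(variant_id = sort(unique(sv$variant_id[sv$status == polarity])))
}

#' Variants observed with a combination of traits
#'
#' Variants carried by at least one patient who is `present` for *every*
#' listed term — co-occurrence in the same patient, not across carriers.
#'
#' @inheritParams variants_with_trait
#' @param term_ids Character vector of one or more term ids.
#' @return A tibble with a sorted `variant_id` column.
#' @export
variants_with_all_traits <- function(cohort, term_ids, ontology,
                                     hierarchy = TRUE) {
  stopifnot(length(term_ids) >= 1)
  ok <- cohort$patients$patient_id
  for (t in term_ids) {
    st <- phenotype_status(cohort, t, ontology, hierarchy = hierarchy)
    ok <- intersect(ok, st$patient_id[st$status == "present"])
  }
  vv <- cohort$variants
  tibble::tibble(variant_id = sort(unique(vv$variant_id[vv$patient_id %in% ok])))
}

#' Per-variant association breakdown for a trait
#'
#' Classifies every variant with at least one carrier into `always`
#' (some present carrier, no absent carrier), `never` (some absent carrier,
#' no present carrier), `mixed` (both) or `do-not-know` (only
#' unknown-status carriers). The four classes partition the variants.
#'
#' @inheritParams variants_with_trait
#' @return A tibble: `variant_id`, `n_carriers`, `n_present`, `n_absent`,
#'   `n_unknown`, `association`.
#' @export
variant_associations <- function(cohort, term_id, ontology, hierarchy = TRUE,
                                 closed_world = FALSE) {
  sv <- status_by_variant(cohort, term_id, ontology, hierarchy, closed_world)
  sv |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(
      n_carriers = dplyr::n_distinct(.data$patient_id),
      n_present = dplyr::n_distinct(.data$patient_id[.data$status == "present"]),
      n_absent = dplyr::n_distinct(.data$patient_id[.data$status == "absent"]),
      n_unknown = dplyr::n_distinct(.data$patient_id[.data$status == "unknown"]),
      .groups = "drop") |>
    dplyr::mutate(association = dplyr::case_when(
      n_present > 0 & n_absent > 0 ~ "mixed",
      n_present > 0 ~ "always",
      n_absent > 0 ~ "never",
      TRUE ~ "do-not-know")) |>
    dplyr::arrange(.data$variant_id)
}

#' Variants always associated with a trait
#'
#' Variants with at least one present-status carrier and no absent-status
#' carrier.
#'
#' @inheritParams variants_with_trait
#' @return A tibble with a sorted `variant_id` column.
#' @export
variants_always_associated <- function(cohort, term_id, ontology,
                                       hierarchy = TRUE) {
  va <- variant_associations(cohort, term_id, ontology, hierarchy)
  tibble::tibble(variant_id = va$variant_id[va$association == "always"])
}

#' Variants never associated with a trait
#'
#' Variants with at least one absent-status carrier and no present-status
#' carrier. Variants whose carriers are all of unknown status are reported
#' separately in the `"do_not_know"` attribute of the result ("Do not
#' know", not "never") — unless `closed_world = TRUE`, in which case
#' unknown carriers count as absent and the do-not-know list is empty.
#'
#' @inheritParams variants_with_trait
#' @return A tibble with a sorted `variant_id` column; attribute
#'   `do_not_know` holds the unknown-only variants.
#' @export
variants_never_associated <- function(cohort, term_id, ontology,
                                      hierarchy = TRUE, closed_world = FALSE) {
  va <- variant_associations(cohort, term_id, ontology, hierarchy, closed_world)
  out <- tibble::tibble(variant_id = va$variant_id[va$association == "never"])
  attr(out, "do_not_know") <- va$variant_id[va$association == "do-not-know"]
  out
}

#' Traits associated with a variant
#'
#' The union, across every carrier of `variant_id` and across all property
#' groups, of presence assertions whose term is subsumed by `scope_class`
#' (the scope itself included). Derived assertions participate like
#' asserted ones.
#'
#' @inheritParams variants_with_trait
#' @param variant_id A variant label.
#' @param scope_class Term id restricting the answer (use an ontology root
#'   for no restriction).
#' @return A tibble `term_id`, `polarity` (always `"present"`), sorted by
#'   term; an unknown variant yields zero rows with attribute
#'   `note = "do-not-know"`.
#' @export
traits_for_variant <- function(cohort, variant_id, scope_class, ontology) {
  check_term(ontology, scope_class)
  vv <- cohort$variants
  if (!variant_id %in% vv$variant_id) {
    out <- tibble::tibble(term_id = character(0), polarity = character(0))
    attr(out, "note") <- "do-not-know"
    return(out)
  }
  pids <- unique(vv$patient_id[vv$variant_id == variant_id])
  scope <- c(scope_class, descendants(ontology, scope_class))
  aa <- cohort$assertions
  hits <- unique(aa$term_id[aa$patient_id %in% pids &
                              aa$polarity == "present" &
                              aa$term_id %in% scope])
  out <- tibble::tibble(term_id = sort(hits),
                        polarity = rep("present", length(hits)))
  attr(out, "note") <- "ok"
  out
}

#' How often a variant co-occurs with a trait
#'
#' Percentage (floor to integer) of carriers of `variant_id` whose status
#' for `term_id` is present. The denominator is *all* carriers, including
#' those of unknown status.
#'
#' @inheritParams traits_for_variant
#' @return A one-row aggregate tibble: `value`, `numerator`, `denominator`,
#'   `unit = "percent"`, `note` (`"empty-denominator"` when the variant has
#'   no carrier, in which case `value` is `NA`).
#' @export
trait_frequency <- function(cohort, variant_id, term_id, ontology,
                            hierarchy = TRUE) {
  sv <- status_by_variant(cohort, term_id, ontology, hierarchy)
  sv <- sv[sv$variant_id == variant_id, , drop = FALSE]
  denom <- dplyr::n_distinct(sv$patient_id)
  if (denom == 0) {
    return(aggregate_outcome(NA_real_, 0L, 0L, "percent", "empty-denominator"))
  }
  num <- dplyr::n_distinct(sv$patient_id[sv$status == "present"])
  aggregate_outcome(floor(100 * num / denom), num, denom, "percent")
}

#' Cohort-wide frequency of a trait status
#'
#' Percentage (floor to integer) of all patients whose status for `term_id`
#' equals `polarity`. Patients are counted individually, never per family.
#'
#' @inheritParams variants_with_trait
#' @return A one-row aggregate tibble (`unit = "percent"`).
#' @export
cohort_frequency <- function(cohort, term_id, ontology,
                             polarity = c("present", "absent"),
                             hierarchy = TRUE, closed_world = FALSE) {
  polarity <- match.arg(polarity)
  denom <- nrow(cohort$patients)
  if (denom == 0) {
    return(aggregate_outcome(NA_real_, 0L, 0L, "percent", "empty-denominator"))
  }
  st <- phenotype_status(cohort, term_id, ontology, hierarchy = hierarchy,
                         closed_world = closed_world)
  num <- sum(st$status == polarity)
  aggregate_outcome(floor(100 * num / denom), num, denom, "percent")
}

check_filters <- function(filters) {
  purrr::walk(filters, function(f) {
    if (!is.list(f) || is.null(f$type) ||
          !f$type %in% c("term", "variant")) {
      stop("filters must be built with filter_term() / filter_variant()",
           call. = FALSE)
    }
  })
  invisible(filters)
}

#' Query filters on patients
#'
#' Conditions restricting the patients an aggregate query averages over:
#' `filter_term()` requires a three-valued status on an ontology term,
#' `filter_variant()` requires carriage of a variant.
#'
#' @param term_id Ontology term id.
#' @param polarity `"present"` or `"absent"`.
#' @param variant_id Variant label.
#' @return A filter condition object.
#' @export
filter_term <- function(term_id, polarity = c("present", "absent")) {
  polarity <- match.arg(polarity)
  list(type = "term", term_id = term_id, polarity = polarity)
}

#' @rdname filter_term
#' @export
filter_variant <- function(variant_id) {
  list(type = "variant", variant_id = variant_id)
}

qualifying_patients <- function(cohort, filters, ontology, hierarchy = TRUE) {
  check_filters(filters)
  ids <- cohort$patients$patient_id
  for (f in filters) {
    if (f$type == "term") {
      st <- phenotype_status(cohort, f$term_id, ontology, hierarchy = hierarchy)
      ids <- intersect(ids, st$patient_id[st$status == f$polarity])
    } else {
      vv <- cohort$variants
      ids <- intersect(ids, vv$patient_id[vv$variant_id == f$variant_id])
    }
  }
  ids
}

attribute_values <- function(cohort, attribute, ids) {
  at <- cohort$attributes
  at <- at[at$patient_id %in% ids & at$attribute == attribute &
             !is.na(at$value), , drop = FALSE]
  stats::setNames(at$value, at$patient_id)
}

#' Mean of a clinical attribute over filtered patients
#'
#' Arithmetic mean of a named clinical attribute (e.g.
#' `neurological_symptom_onset_age`) over patients satisfying every filter.
#' Patients lacking the attribute are excluded from numerator and
#' denominator. Reported at 0.1 precision, rounded half up.
#'
#' @inheritParams variants_with_trait
#' @param attribute Attribute name as stored in the cohort attribute table.
#' @param filters List of conditions from [filter_term()] /
#'   [filter_variant()].
#' @return A one-row aggregate tibble (`unit = "years"`); `numerator` and
#'   `denominator` both report the number of contributing patients.
#' @export
mean_attribute <- function(cohort, attribute, filters = list(), ontology,
                           hierarchy = TRUE) {
  ids <- qualifying_patients(cohort, filters, ontology, hierarchy)
  vals <- attribute_values(cohort, attribute, ids)
  n <- length(vals)
  if (n == 0) {
    return(aggregate_outcome(NA_real_, 0L, 0L, "years", "empty-denominator"))
  }
  aggregate_outcome(round_half_up(mean(vals)), n, n, "years")
}

#' Mean interval between two onset attributes
#'
#' Mean of (`end_attribute` - `start_attribute`) over filtered patients
#' having *both* attributes; individual differences may be negative, and
#' every qualifying patient counts in the denominator. Reported at 0.1
#' precision, rounded half up.
#'
#' @inheritParams mean_attribute
#' @param start_attribute,end_attribute Attribute names.
#' @return A one-row aggregate tibble (`unit = "years"`).
#' @export
mean_interval <- function(cohort, start_attribute, end_attribute,
                          filters = list(), ontology, hierarchy = TRUE) {
  ids <- qualifying_patients(cohort, filters, ontology, hierarchy)
  a <- attribute_values(cohort, start_attribute, ids)
  b <- attribute_values(cohort, end_attribute, ids)
  both <- intersect(names(a), names(b))
  n <- length(both)
  if (n == 0) {
    return(aggregate_outcome(NA_real_, 0L, 0L, "years", "empty-denominator"))
  }
  aggregate_outcome(round_half_up(mean(b[both] - a[both])), n, n, "years")
}

QUERY_PATTERNS <- c("variants_with_trait", "variants_with_all_traits",
                    "variants_always_associated", "variants_never_associated",
                    "traits_for_variant", "trait_frequency",
                    "cohort_frequency", "mean_attribute", "mean_interval")

#' Build a query specification
#'
#' A `query_spec` names one of the supported query patterns together with
#' its parameters; [evaluate_query()] dispatches it. Parameter consistency
#' with the pattern's arity is checked here.
#'
#' @param pattern One of `variants_with_trait`, `variants_with_all_traits`,
#'   `variants_always_associated`, `variants_never_associated`,
#'   `traits_for_variant`, `trait_frequency`, `cohort_frequency`,
#'   `mean_attribute`, `mean_interval`.
#' @param term_ids Character vector of term ids (patterns needing terms).
#' @param polarity `"present"` or `"absent"`.
#' @param variant_id Variant label (variant-scoped patterns).
#' @param scope_class Scope term for `traits_for_variant`.
#' @param attribute,start_attribute,end_attribute Attribute names for the
#'   mean patterns.
#' @param filters List from [filter_term()] / [filter_variant()].
#' @param hierarchy Expand terms to descendants (default `TRUE`).
#' @param closed_world Read blanks as absence (default `FALSE`).
#' @return A `query_spec` object.
#' @export
query_spec <- function(pattern, term_ids = character(0),
                       polarity = "present", variant_id = NULL,
                       scope_class = NULL, attribute = NULL,
                       start_attribute = NULL, end_attribute = NULL,
                       filters = list(), hierarchy = TRUE,
                       closed_world = FALSE) {
  if (!pattern %in% QUERY_PATTERNS) {
    stop("unknown query pattern '", pattern, "'; available: ",
         paste(QUERY_PATTERNS, collapse = ", "), call. = FALSE)
  }
  need_term <- c("variants_with_trait", "variants_with_all_traits",
                 "variants_always_associated", "variants_never_associated",
                 "trait_frequency", "cohort_frequency")
  if (pattern %in% need_term && length(term_ids) < 1) {
    stop("pattern '", pattern, "' needs at least one term", call. = FALSE)
  }
  if (pattern %in% c("traits_for_variant", "trait_frequency") &&
        is.null(variant_id)) {
    stop("pattern '", pattern, "' needs a variant", call. = FALSE)
  }
  if (pattern == "traits_for_variant" && is.null(scope_class)) {
    stop("pattern 'traits_for_variant' needs a scope class", call. = FALSE)
  }
  if (pattern == "mean_attribute" && is.null(attribute)) {
    stop("pattern 'mean_attribute' needs an attribute", call. = FALSE)
  }
  if (pattern == "mean_interval" &&
        (is.null(start_attribute) || is.null(end_attribute))) {
    stop("pattern 'mean_interval' needs start and end attributes", call. = FALSE)
  }
  check_filters(filters)
  structure(list(pattern = pattern, term_ids = term_ids, polarity = polarity,
                 variant_id = variant_id, scope_class = scope_class,
                 attribute = attribute, start_attribute = start_attribute,
                 end_attribute = end_attribute, filters = filters,
                 hierarchy = hierarchy, closed_world = closed_world),
            class = "query_spec")
}

#' Evaluate a query specification
#'
#' Single dispatch entry over the query patterns. When a `ruleset` is
#' supplied and the cohort has not yet been enriched, abstraction rules are
#' applied (exactly once) before evaluation — interpretation precedes
#' mapping. Results are tibbles sorted on their first column, with a
#' `"note"` attribute of `"ok"`, `"do-not-know"` or `"empty-denominator"`
#' (readable via [result_note()]).
#'
#' @param spec A [query_spec()].
#' @param cohort A `pheno_cohort`.
#' @param ontology A `pheno_ontology`.
#' @param ruleset Optional `pheno_ruleset` to apply before querying.
#' @return A result tibble.
#' @export
evaluate_query <- function(spec, cohort, ontology, ruleset = NULL) {
  stopifnot(inherits(spec, "query_spec"))
  if (!is.null(ruleset) && !isTRUE(cohort$enriched)) {
    cohort <- apply_rules(cohort, ruleset, ontology)
  }
  out <- switch(
    spec$pattern,
    variants_with_trait = variants_with_trait(
      cohort, spec$term_ids[1], ontology, polarity = spec$polarity,
      hierarchy = spec$hierarchy, closed_world = spec$closed_world),
    variants_with_all_traits = variants_with_all_traits(
      cohort, spec$term_ids, ontology, hierarchy = spec$hierarchy),
    variants_always_associated = variants_always_associated(
      cohort, spec$term_ids[1], ontology, hierarchy = spec$hierarchy),
    variants_never_associated = variants_never_associated(
      cohort, spec$term_ids[1], ontology, hierarchy = spec$hierarchy,
      closed_world = spec$closed_world),
    traits_for_variant = traits_for_variant(
      cohort, spec$variant_id, spec$scope_class, ontology),
    trait_frequency = trait_frequency(
      cohort, spec$variant_id, spec$term_ids[1], ontology,
      hierarchy = spec$hierarchy),
    cohort_frequency = cohort_frequency(
      cohort, spec$term_ids[1], ontology, polarity = spec$polarity,
      hierarchy = spec$hierarchy, closed_world = spec$closed_world),
    mean_attribute = mean_attribute(
      cohort, spec$attribute, spec$filters, ontology,
      hierarchy = spec$hierarchy),
    mean_interval = mean_interval(
      cohort, spec$start_attribute, spec$end_attribute, spec$filters,
      ontology, hierarchy = spec$hierarchy)
  )
  if (is.null(attr(out, "note"))) {
    attr(out, "note") <- if ("note" %in% names(out)) out$note[1] else "ok"
  }
  if (nrow(out) > 1) out <- dplyr::arrange(out, dplyr::across(1))
  out
}

#' Note attached to a query result
#'
#' @param result A result tibble from [evaluate_query()] or a query
#'   function.
#' @return `"ok"`, `"do-not-know"` or `"empty-denominator"`.
#' @export
result_note <- function(result) {
  attr(result, "note") %||%
    (if ("note" %in% names(result) && nrow(result) > 0) result$note[1] else "ok")
}
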