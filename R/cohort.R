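#' Patient cohorts with three-valued phenotype assertions
#'
#' A `pheno_cohort` bundles four tibbles describing a patient dataset under
#' open-world semantics: missing information is *unknown*, never absence.
#' Absence of a trait is itself an asserted fact (`polarity = "absent"`).
#'
#' * `patients`: `patient_id`, `family_id`
#' * `variants`: `patient_id`, `variant_id`, `gene` (one row per carried
#'   variant; recessive disease, so a patient may carry one or two)
#' * `assertions`: `patient_id`, `term_id`, `polarity` (`present`/`absent`),
#'   `property_group` (`neurological`, `extra-neurological`,
#'   `diagnostic-study`, `other`), `onset_age_years`, `duration_weeks`,
#'   `derived` (TRUE when produced by a rule), `rule_id`
#' * `attributes`: `patient_id`, `attribute`, `value` (named clinical ages
#'   and durations, e.g. `diarrhea_onset_age`, in decimal years / weeks)
#'
#' @param patients,variants,assertions,attributes Data frames as above;
#'   missing optional columns are filled with sensible defaults.
#' @param provenance Free-text source note.
#' @return A `pheno_cohort`.
#' @examples
#' co <- cohort(
#'   patients = tibble::tibble(patient_id = "P1", family_id = "F1"),
#'   variants = tibble::tibble(patient_id = "P1", variant_id = "p.R395C"),
#'   assertions = tibble::tibble(patient_id = "P1", term_id = "Epilepsy",
#'                               polarity = "present")
#' )
#' co
#' @export
cohort <- function(patients,
                   variants = NULL,
                   assertions = NULL,
                   attributes = NULL,
                   provenance = NA_character_) {
  patients <- tibble::as_tibble(patients)
  if (!"patient_id" %in% names(patients)) {
    stop("patients table needs a patient_id column", call. = FALSE)
  }
  if (!"family_id" %in% names(patients)) patients$family_id <- patients$patient_id
  patients <- patients[, c("patient_id", "family_id")]
  dup <- unique(patients$patient_id[duplicated(patients$patient_id)])
  if (length(dup) > 0) {
    stop("duplicate patient_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }

  variants <- fill_cols(variants, list(
    patient_id = character(0), variant_id = character(0), gene = NA_character_
  ))
  assertions <- fill_cols(assertions, list(
    patient_id = character(0), term_id = character(0), polarity = character(0),
    property_group = "other", onset_age_years = NA_real_,
    duration_weeks = NA_real_, derived = FALSE, rule_id = NA_character_
  ))
  attributes <- fill_cols(attributes, list(
    patient_id = character(0), attribute = character(0), value = NA_real_
  ))
  attributes$value <- as.numeric(attributes$value)
  assertions$onset_age_years <- as.numeric(assertions$onset_age_years)
  assertions$duration_weeks <- as.numeric(assertions$duration_weeks)

  bad_pol <- setdiff(unique(assertions$polarity), c("present", "absent"))
  if (length(bad_pol) > 0) {
    stop("assertion polarity must be 'present' or 'absent', got: ",
         paste(bad_pol, collapse = ", "), call. = FALSE)
  }
  for (tab in list(variants, assertions, attributes)) {
    stray <- setdiff(unique(tab$patient_id), patients$patient_id)
    if (length(stray) > 0) {
      stop("rows reference unknown patient_id: ",
           paste(stray, collapse = ", "), call. = FALSE)
    }
  }

  structure(
    list(patients = patients, variants = variants, assertions = assertions,
         attributes = attributes,
         derivations = empty_derivations(), provenance = provenance,
         enriched = FALSE),
    class = "pheno_cohort"
  )
}

fill_cols <- function(tab, defaults) {
  if (is.null(tab)) tab <- tibble::as_tibble(defaults)
  tab <- tibble::as_tibble(tab)
  for (nm in names(defaults)) {
    if (!nm %in% names(tab)) {
      tab[[nm]] <- if (nrow(tab) == 0) defaults[[nm]][0] else defaults[[nm]]
    }
  }
  tab[, names(defaults)]
}

empty_derivations <- function() {
  tibble::tibble(patient_id = character(0), term_id = character(0),
                 polarity = character(0), rule_id = character(0),
                 support = list())
}

#' Derivation provenance of an enriched cohort
#'
#' After [apply_rules()] a cohort records, for every rule firing, which
#' patient and assertion it produced and which facts matched the antecedent.
#'
#' @param cohort A `pheno_cohort`.
#' @return A tibble: `patient_id`, `term_id`, `polarity`, `rule_id`,
#'   `support` (list of the term ids whose status satisfied the antecedent).
#' @export
derivations <- function(cohort) {
  stopifnot(inherits(cohort, "pheno_cohort"))
  cohort$derivations
}

#' Read a cohort from CSV or JSON
#'
#' The CSV long form has one row per (patient, assertion): columns
#' `patient_id`, `family_id`, `variant_ids` (semicolon-joined), optional
#' `gene`, `term_id`, `polarity`, `property_group`, `onset_age_years`,
#' `duration_weeks`, plus optional `derived` and `rule_id` for enriched
#' cohorts. A row with an empty `term_id` declares a patient with no
#' assertions. Blank cells are *missing* information, never absence. A
#' companion attributes CSV (`patient_id`, `attribute`, `value`) carries the
#' named clinical ages. The JSON form is one object per patient mirroring
#' the cohort structure.
#'
#' @param path Path to the cohort CSV or JSON file.
#' @param format `"csv"` or `"json"`.
#' @param attributes_path Optional path to the attributes CSV
#'   (`format = "csv"` only).
#' @return A `pheno_cohort`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, format = c("csv", "json"), attributes_path = NULL) {
  format <- match.arg(format)
  if (format == "json") return(read_cohort_json(path))

  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = "", progress = FALSE)
  needed <- c("patient_id", "family_id", "variant_ids", "term_id", "polarity")
  miss <- setdiff(needed, names(raw))
  if (length(miss) > 0) {
    stop("cohort CSV lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.na(raw$term_id) &
                 (is.na(raw$polarity) | !raw$polarity %in% c("present", "absent")))
  if (length(bad) > 0) {
    stop("unparseable polarity in cohort CSV row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  meta <- dplyr::distinct(raw, .data$patient_id, .data$family_id,
                          .data$variant_ids,
                          gene = if ("gene" %in% names(raw)) .data$gene else NA_character_)
  dup <- unique(meta$patient_id[duplicated(meta$patient_id)])
  if (length(dup) > 0) {
    stop("conflicting metadata for patient_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  patients <- meta[, c("patient_id", "family_id")]
  variants <- meta |>
    dplyr::filter(!is.na(.data$variant_ids), nzchar(.data$variant_ids)) |>
    dplyr::mutate(variant_id = purrr::map(.data$variant_ids,
                                          ~ stringr::str_trim(stringr::str_split_1(.x, ";")))) |>
    tidyr::unnest("variant_id") |>
    dplyr::select("patient_id", "variant_id", "gene")

  as_num <- function(x, what) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      stop("unparseable ", what, " in cohort CSV row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    out
  }
  assertions <- raw |>
    dplyr::filter(!is.na(.data$term_id), nzchar(.data$term_id)) |>
    dplyr::transmute(
      .data$patient_id, .data$term_id, .data$polarity,
      property_group = if ("property_group" %in% names(raw)) {
        dplyr::coalesce(.data$property_group, "other")
      } else "other",
      onset_age_years = as_num(
        if ("onset_age_years" %in% names(raw)) .data$onset_age_years else NA_character_,
        "onset_age_years"),
      duration_weeks = as_num(
        if ("duration_weeks" %in% names(raw)) .data$duration_weeks else NA_character_,
        "duration_weeks"),
      derived = if ("derived" %in% names(raw)) {
        dplyr::coalesce(tolower(.data$derived) == "true", FALSE)
      } else FALSE,
      rule_id = if ("rule_id" %in% names(raw)) .data$rule_id else NA_character_
    )

  attributes <- NULL
  if (!is.null(attributes_path)) {
    attributes <- readr::read_csv(
      attributes_path,
      col_types = readr::cols(patient_id = "c", attribute = "c", value = "d"),
      na = "", progress = FALSE)
  }
  cohort(patients, variants, assertions, attributes,
         provenance = paste0("read from ", path))
}

read_cohort_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  pts <- obj$patients %||% obj
  rows <- purrr::map(pts, function(p) {
    list(
      patient = tibble::tibble(patient_id = p$patient_id,
                               family_id = p$family_id %||% p$patient_id),
      variants = dplyr::bind_rows(purrr::map(p$variants, function(v) {
        tibble::tibble(patient_id = p$patient_id, variant_id = v$variant_id,
                       gene = v$gene %||% NA_character_)
      })),
      assertions = dplyr::bind_rows(purrr::map(p$assertions, function(a) {
        tibble::tibble(
          patient_id = p$patient_id, term_id = a$term_id, polarity = a$polarity,
          property_group = a$property_group %||% "other",
          onset_age_years = as.numeric(a$onset_age_years %||% NA_real_),
          duration_weeks = as.numeric(a$duration_weeks %||% NA_real_),
          derived = isTRUE(a$derived),
          rule_id = a$rule_id %||% NA_character_)
      })),
      attributes = if (length(p$attributes) > 0) {
        tibble::tibble(patient_id = p$patient_id,
                       attribute = names(p$attributes),
                       value = as.numeric(unlist(p$attributes)))
      } else NULL
    )
  })
  cohort(
    patients = dplyr::bind_rows(purrr::map(rows, "patient")),
    variants = dplyr::bind_rows(purrr::map(rows, "variants")),
    assertions = dplyr::bind_rows(purrr::map(rows, "assertions")),
    attributes = dplyr::bind_rows(purrr::compact(purrr::map(rows, "attributes"))),
    provenance = obj$provenance %||% paste0("read from ", path)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort to CSV or JSON
#'
#' Inverse of [read_cohort()]; a read/write/read round trip preserves the
#' cohort.
#'
#' @param cohort A `pheno_cohort`.
#' @param path Output path for the cohort CSV or JSON.
#' @param format `"csv"` or `"json"`.
#' @param attributes_path Output path for the companion attributes CSV
#'   (`format = "csv"`; defaults to `path` with an `_attributes.csv` suffix).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("csv", "json"),
                         attributes_path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "pheno_cohort"))
  if (format == "json") {
    pts <- purrr::pmap(cohort$patients, function(patient_id, family_id) {
      vv <- dplyr::filter(cohort$variants, .data$patient_id == !!patient_id)
      aa <- dplyr::filter(cohort$assertions, .data$patient_id == !!patient_id)
      at <- dplyr::filter(cohort$attributes, .data$patient_id == !!patient_id)
      list(
        patient_id = patient_id, family_id = family_id,
        variants = purrr::pmap(vv[, c("variant_id", "gene")], function(variant_id, gene) {
          list(variant_id = variant_id, gene = gene)
        }),
        assertions = purrr::pmap(
          aa[, c("term_id", "polarity", "property_group", "onset_age_years",
                 "duration_weeks", "derived", "rule_id")],
          function(term_id, polarity, property_group, onset_age_years,
                   duration_weeks, derived, rule_id) {
            out <- list(term_id = term_id, polarity = polarity,
                        property_group = property_group, derived = derived)
            if (!is.na(onset_age_years)) out$onset_age_years <- onset_age_years
            if (!is.na(duration_weeks)) out$duration_weeks <- duration_weeks
            if (!is.na(rule_id)) out$rule_id <- rule_id
            out
          }),
        attributes = stats::setNames(as.list(at$value), at$attribute)
      )
    })
    jsonlite::write_json(list(provenance = cohort$provenance, patients = pts),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(path))
  }

  meta <- cohort$variants |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(variant_ids = paste(.data$variant_id, collapse = ";"),
                     gene = .data$gene[1], .groups = "drop")
  base <- dplyr::left_join(cohort$patients, meta, by = "patient_id")
  long <- dplyr::left_join(base, cohort$assertions, by = "patient_id")
  long$derived <- ifelse(is.na(long$term_id), NA,
                         ifelse(long$derived, "true", "false"))
  readr::write_csv(long, path, na = "", progress = FALSE)
  if (is.null(attributes_path)) {
    attributes_path <- sub("\\.csv$", "_attributes.csv", path)
  }
  readr::write_csv(cohort$attributes, attributes_path, na = "", progress = FALSE)
  invisible(path)
}

#' Validate a cohort against an ontology
#'
#' Reports, without throwing, every issue found in a cohort: assertions on
#' terms missing from the ontology, contradictory literal presence+absence
#' pairs on the same term, negative ages or durations (all `error` level);
#' more than two variants per patient and absence asserted on an ancestor of
#' a present descendant (both `warning` level, the latter because presence
#' wins during status computation).
#'
#' @param cohort A `pheno_cohort`.
#' @param ontology A `pheno_ontology`.
#' @return A tibble of issues: `level`, `type`, `patient_id`, `term_id`,
#'   `message`. Zero rows means a clean cohort.
#' @export
validate_cohort <- function(cohort, ontology) {
  stopifnot(inherits(cohort, "pheno_cohort"), inherits(ontology, "pheno_ontology"))
  issues <- list()
  add <- function(level, type, patient_id, term_id, message) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      level = level, type = type, patient_id = patient_id,
      term_id = term_id, message = message)
  }

  aa <- cohort$assertions
  unknown <- dplyr::filter(aa, !.data$term_id %in% ontology$terms$term_id)
  for (i in seq_len(nrow(unknown))) {
    add("error", "unknown-term", unknown$patient_id[i], unknown$term_id[i],
        paste0("assertion on term not in ontology: ", unknown$term_id[i]))
  }

  contra <- aa |>
    dplyr::distinct(.data$patient_id, .data$term_id, .data$polarity) |>
    dplyr::count(.data$patient_id, .data$term_id) |>
    dplyr::filter(.data$n > 1)
  for (i in seq_len(nrow(contra))) {
    add("error", "contradiction", contra$patient_id[i], contra$term_id[i],
        "both presence and absence asserted on the same term")
  }

  neg <- dplyr::filter(aa, (!is.na(.data$onset_age_years) & .data$onset_age_years < 0) |
                         (!is.na(.data$duration_weeks) & .data$duration_weeks < 0))
  for (i in seq_len(nrow(neg))) {
    add("error", "negative-age", neg$patient_id[i], neg$term_id[i],
        "negative onset age or duration")
  }
  negat <- dplyr::filter(cohort$attributes, !is.na(.data$value) & .data$value < 0)
  for (i in seq_len(nrow(negat))) {
    add("error", "negative-age", negat$patient_id[i], NA_character_,
        paste0("negative attribute value: ", negat$attribute[i]))
  }

  nvar <- dplyr::count(cohort$variants, .data$patient_id)
  many <- dplyr::filter(nvar, .data$n > 2)
  for (i in seq_len(nrow(many))) {
    add("warning", "variant-count", many$patient_id[i], NA_character_,
        paste0(many$n[i], " variant observations (recessive disease expects 1-2)"))
  }

  # absence on a term whose strict descendant is asserted present for the
  # same patient: presence wins under hierarchy expansion, flag it
  known <- dplyr::filter(aa, .data$term_id %in% ontology$terms$term_id)
  abs_rows <- dplyr::filter(known, .data$polarity == "absent")
  pres <- dplyr::filter(known, .data$polarity == "present")
  for (i in seq_len(nrow(abs_rows))) {
    desc <- descendants(ontology, abs_rows$term_id[i])
    hit <- pres$term_id[pres$patient_id == abs_rows$patient_id[i] &
                          pres$term_id %in% desc]
    if (length(hit) > 0) {
      add("warning", "hierarchy-conflict", abs_rows$patient_id[i],
          abs_rows$term_id[i],
          paste0("absence asserted but descendant present: ",
                 paste(unique(hit), collapse = ", ")))
    }
  }

  if (length(issues) == 0) {
    tibble::tibble(level = character(0), type = character(0),
                   patient_id = character(0), term_id = character(0),
                   message = character(0))
  } else {
    dplyr::bind_rows(issues)
  }
}

#' Three-valued phenotype status of every patient
#'
#' Computes each patient's status for an ontology term under open-world
#' semantics. A patient is `present` when carrying a presence assertion on
#' the term itself or (with `hierarchy = TRUE`) on any descendant; `absent`
#' when an absence assertion sits literally on the term (absence never
#' propagates along the hierarchy); otherwise `unknown`. Presence is checked
#' before absence, so presence wins a propagated conflict. With
#' `closed_world = TRUE`, `unknown` collapses to `absent` (a blank read as
#' "not(trait)").
#'
#' @param cohort A `pheno_cohort`.
#' @param term_id A single ontology term id.
#' @param ontology A `pheno_ontology`.
#' @param hierarchy Expand the term to its descendants for presence
#'   (default `TRUE`).
#' @param closed_world Interpret missing information as absence
#'   (default `FALSE`).
#' @return A tibble `patient_id`, `status` with one row per patient and
#'   `status` in `present`, `absent`, `unknown`.
#' @examples
#' trio <- cohort(
#'   patients = tibble::tibble(patient_id = c("P1", "P2", "P3")),
#'   assertions = tibble::tibble(
#'     patient_id = c("P1", "P2"), term_id = c("Ataxia", "Epilepsy"),
#'     polarity = c("present", "absent"))
#' )
#' phenotype_status(trio, "AbnormalityOfTheCerebellum", ctx_ontology())
#' @export
phenotype_status <- function(cohort, term_id, ontology, hierarchy = TRUE,
                             closed_world = FALSE) {
  stopifnot(inherits(cohort, "pheno_cohort"))
  check_term(ontology, term_id)
  scope <- if (hierarchy) c(term_id, descendants(ontology, term_id)) else term_id
  aa <- cohort$assertions
  present_ids <- unique(aa$patient_id[aa$polarity == "present" &
                                        aa$term_id %in% scope])
  absent_ids <- unique(aa$patient_id[aa$polarity == "absent" &
                                       aa$term_id == term_id])
  status <- ifelse(cohort$patients$patient_id %in% present_ids, "present",
                   ifelse(cohort$patients$patient_id %in% absent_ids, "absent",
                          "unknown"))
  if (closed_world) status[status == "unknown"] <- "absent"
  tibble::tibble(patient_id = cohort$patients$patient_id, status = status)
}

#' @export
print.pheno_cohort <- function(x, ...) {
  cat("<pheno_cohort> ", nrow(x$patients), " patients, ",
      dplyr::n_distinct(x$patients$family_id), " families, ",
      dplyr::n_distinct(x$variants$variant_id), " variants, ",
      nrow(x$assertions), " assertions (",
      sum(x$assertions$derived), " derived)\n", sep = "")
  if (!is.na(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Tidy a cohort into its assertion table
#'
#' @param x A `pheno_cohort`.
#' @param ... Unused.
#' @return The assertions tibble joined with family ids.
#' @method tidy pheno_cohort
#' @export
tidy.pheno_cohort <- function(x, ...) {
  dplyr::left_join(x$assertions, x$patients, by = "patient_id") |>
    dplyr::relocate("family_id", .after = "patient_id")
}

#' One-row cohort summary
#'
#' @param x A `pheno_cohort`.
#' @param ... Unused.
#' @return A one-row tibble: patient, family, variant, assertion and
#'   derived-assertion counts.
#' @method glance pheno_cohort
#' @export
glance.pheno_cohort <- function(x, ...) {
  tibble::tibble(
    n_patients = nrow(x$patients),
    n_families = dplyr::n_distinct(x$patients$family_id),
    n_variants = dplyr::n_distinct(x$variants$variant_id),
    n_assertions = nrow(x$assertions),
    n_derived = sum(x$assertions$derived),
    enriched = isTRUE(x$enriched)
  )
}
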