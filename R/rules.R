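#' Horn-like abstraction rules
#'
#' Rules bridge the abstraction gap between raw clinical fields and
#' catalog-level phenotype descriptions. Each rule has a conjunctive
#' antecedent of atoms over a single patient and a consequent assertion
#' template; forward chaining is monotone (rules only add assertions), so
#' the fixpoint is unique regardless of application order.
#'
#' Three atom kinds are supported:
#' * `status-check` — the patient's three-valued status on a term must equal
#'   a polarity (`present` uses hierarchy expansion; `absent` reads literal
#'   absence assertions only — no negation as failure);
#' * `attribute-comparison` — a named clinical attribute compared against a
#'   threshold with one of `<`, `<=`, `=`, `>=`, `>` (a missing attribute
#'   never matches);
#' * `class-membership` — the patient carries at least one literal presence
#'   assertion on a term subsumed by the given class.
#'
#' @name abstraction-rules
NULL

RULE_OPS <- c("<", "<=", "=", ">=", ">")

#' Parse a rule file
#'
#' Rule files are YAML with a top-level `parameters:` mapping of named
#' thresholds and a `rules:` list. Each rule carries `id`, `when` (a list of
#' atoms) and `then` (`term`, `polarity`, `group`). Atoms are written as
#' `{status: Term, polarity: present}`, `{attribute: name, op: "<",
#' value: threshold-or-number}` or `{class: Term}`. `value` may name a
#' parameter, which is resolved at parse time.
#'
#' @param path Path to the YAML rule file, or the YAML text itself when
#'   `text = TRUE`.
#' @param text If `TRUE`, `path` is the file content.
#' @return A `pheno_ruleset`: list with `rules` (list of parsed rules) and
#'   `parameters` (named numeric vector).
#' @export
parse_rules <- function(path, text = FALSE) {
  doc <- if (text) yaml::yaml.load(paste(path, collapse = "\n"))
         else yaml::read_yaml(path)
  params <- purrr::map_dbl(doc$parameters %||% list(), as.numeric)
  if (is.null(doc$rules) || length(doc$rules) == 0) {
    rules <- list()
  } else {
    rules <- purrr::map(doc$rules, parse_one_rule, params = params)
  }
  ids <- purrr::map_chr(rules, "rule_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate rule_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(list(rules = rules, parameters = params), class = "pheno_ruleset")
}

parse_one_rule <- function(r, params) {
  id <- r$id %||% stop("rule without an id", call. = FALSE)
  fail <- function(...) stop("rule '", id, "': ", ..., call. = FALSE)
  if (is.null(r$when) || length(r$when) == 0) fail("empty antecedent")
  atoms <- purrr::map(r$when, function(a) {
    if (!is.null(a$status)) {
      pol <- a$polarity %||% fail("status-check atom without polarity")
      if (!pol %in% c("present", "absent")) fail("bad polarity: ", pol)
      list(kind = "status-check", subject = a$status, polarity = pol)
    } else if (!is.null(a$attribute)) {
      op <- a$op %||% fail("attribute-comparison atom without op")
      if (!op %in% RULE_OPS) fail("bad comparator: ", op)
      val <- a$value %||% fail("attribute-comparison atom without value")
      if (is.character(val)) {
        if (!val %in% names(params)) fail("unresolved parameter: ", val)
        val <- params[[val]]
      }
      list(kind = "attribute-comparison", subject = a$attribute,
           comparator = op, threshold = as.numeric(val))
    } else if (!is.null(a$class)) {
      list(kind = "class-membership", subject = a$class)
    } else {
      fail("unknown atom kind: ", paste(names(a), collapse = ","))
    }
  })
  then <- r$then %||% fail("missing consequent")
  if (is.null(then$term)) fail("consequent without term")
  if (is.null(then$polarity) || !then$polarity %in% c("present", "absent")) {
    fail("consequent polarity must be explicit ('present' or 'absent')")
  }
  list(rule_id = id, antecedent = atoms,
       consequent = list(term_id = then$term, polarity = then$polarity,
                         property_group = then$group %||% "other"))
}

#' Write a ruleset back to YAML
#'
#' @param ruleset A `pheno_ruleset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(ruleset, path) {
  stopifnot(inherits(ruleset, "pheno_ruleset"))
  doc <- list(
    parameters = as.list(ruleset$parameters),
    rules = purrr::map(ruleset$rules, function(r) {
      list(
        id = r$rule_id,
        when = purrr::map(r$antecedent, function(a) {
          switch(a$kind,
                 "status-check" = list(status = a$subject, polarity = a$polarity),
                 "attribute-comparison" = list(attribute = a$subject,
                                               op = a$comparator,
                                               value = a$threshold),
                 "class-membership" = list(class = a$subject))
        }),
        then = list(term = r$consequent$term_id,
                    polarity = r$consequent$polarity,
                    group = r$consequent$property_group)
      )
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @export
print.pheno_ruleset <- function(x, ...) {
  cat("<pheno_ruleset> ", length(x$rules), " rule(s), parameters: ",
      paste(names(x$parameters), x$parameters, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' The bundled CTX abstraction ruleset
#'
#' A representative ruleset for the CTX domain: presence and absence
#' abstraction of childhood-onset chronic diarrhea from diarrhea status,
#' onset age and duration; and property-group link rules attaching
#' neurological, extra-neurological and diagnostic-study manifestation
#' links. Thresholds (`childhood_onset_max_age` 16 years strict,
#' `chronic_min_duration` 4 weeks inclusive) are ruleset parameters,
#' overridable in the rule file.
#'
#' @return A `pheno_ruleset`.
#' @export
ctx_ruleset <- function() {
  parse_rules(system.file("extdata", "ctx_rules.yml", package = "phenoquery"))
}

atom_holds <- function(atom, pid, cohort, ontology) {
  aa <- cohort$assertions
  if (atom$kind == "status-check") {
    scope <- if (atom$polarity == "present") {
      c(atom$subject, descendants(ontology, atom$subject))
    } else atom$subject
    rows <- aa[aa$patient_id == pid & aa$polarity == atom$polarity &
                 aa$term_id %in% scope, , drop = FALSE]
    # presence wins: an absence status-check fails if presence also holds
    if (atom$polarity == "absent" && nrow(rows) > 0) {
      pres_scope <- c(atom$subject, descendants(ontology, atom$subject))
      if (any(aa$patient_id == pid & aa$polarity == "present" &
                aa$term_id %in% pres_scope)) {
        return(list(holds = FALSE, support = character(0)))
      }
    }
    list(holds = nrow(rows) > 0, support = unique(rows$term_id))
  } else if (atom$kind == "attribute-comparison") {
    at <- cohort$attributes
    v <- at$value[at$patient_id == pid & at$attribute == atom$subject]
    if (length(v) == 0 || all(is.na(v))) {
      return(list(holds = FALSE, support = character(0)))
    }
    v <- v[!is.na(v)][1]
    ok <- switch(atom$comparator,
                 "<" = v < atom$threshold,
                 "<=" = v <= atom$threshold,
                 "=" = v == atom$threshold,
                 ">=" = v >= atom$threshold,
                 ">" = v > atom$threshold)
    list(holds = ok, support = character(0))
  } else { # class-membership
    scope <- c(atom$subject, descendants(ontology, atom$subject))
    rows <- aa[aa$patient_id == pid & aa$polarity == "present" &
                 aa$term_id %in% scope, , drop = FALSE]
    list(holds = nrow(rows) > 0, support = unique(rows$term_id))
  }
}

#' Apply abstraction rules to a cohort
#'
#' Forward-chains the ruleset to its fixpoint over every patient. Only
#' assertions are added, marked `derived = TRUE` with their `rule_id`;
#' every firing is logged as a derivation record (see [derivations()]).
#' Re-application of the same ruleset adds nothing, and the fixpoint does
#' not depend on rule order.
#'
#' @param cohort A `pheno_cohort` (validated against `ontology`).
#' @param ruleset A `pheno_ruleset`.
#' @param ontology A `pheno_ontology`; every rule consequent term must
#'   exist in it (checked before any derivation).
#' @return The enriched `pheno_cohort` with derivation records attached.
#' @examples
#' onto <- ctx_ontology()
#' co <- cohort(
#'   patients = tibble::tibble(patient_id = "P1"),
#'   assertions = tibble::tibble(patient_id = "P1", term_id = "Diarrhea",
#'                               polarity = "present", onset_age_years = 2,
#'                               duration_weeks = 8),
#'   attributes = tibble::tibble(patient_id = c("P1", "P1"),
#'                               attribute = c("diarrhea_onset_age",
#'                                             "diarrhea_duration_weeks"),
#'                               value = c(2, 8))
#' )
#' enriched <- apply_rules(co, ctx_ruleset(), onto)
#' derivations(enriched)
#' @export
apply_rules <- function(cohort, ruleset, ontology) {
  stopifnot(inherits(cohort, "pheno_cohort"), inherits(ruleset, "pheno_ruleset"),
            inherits(ontology, "pheno_ontology"))
  bad <- purrr::keep(ruleset$rules,
                     ~ !.x$consequent$term_id %in% ontology$terms$term_id)
  if (length(bad) > 0) {
    stop("rule consequent term(s) not in ontology: ",
         paste(purrr::map_chr(bad, ~ .x$consequent$term_id), collapse = ", "),
         call. = FALSE)
  }
  ante_terms <- unique(unlist(purrr::map(ruleset$rules, function(r) {
    purrr::map_chr(purrr::keep(r$antecedent, ~ .x$kind != "attribute-comparison"),
                   "subject")
  })))
  missing_t <- setdiff(ante_terms, ontology$terms$term_id)
  if (length(missing_t) > 0) {
    stop("rule antecedent term(s) not in ontology: ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  }

  recs <- list()
  repeat {
    changed <- FALSE
    for (pid in cohort$patients$patient_id) {
      for (r in ruleset$rules) {
        # skip if this firing is already recorded
        key <- paste(pid, r$rule_id, sep = "\r")
        if (!is.null(recs[[key]])) next
        checks <- purrr::map(r$antecedent, atom_holds, pid = pid,
                             cohort = cohort, ontology = ontology)
        if (!all(purrr::map_lgl(checks, "holds"))) next
        support <- unique(unlist(purrr::map(checks, "support")))
        recs[[key]] <- tibble::tibble(
          patient_id = pid, term_id = r$consequent$term_id,
          polarity = r$consequent$polarity, rule_id = r$rule_id,
          support = list(support))
        already <- any(cohort$assertions$patient_id == pid &
                         cohort$assertions$term_id == r$consequent$term_id &
                         cohort$assertions$polarity == r$consequent$polarity)
        if (!already) {
          cohort$assertions <- dplyr::bind_rows(
            cohort$assertions,
            tibble::tibble(patient_id = pid, term_id = r$consequent$term_id,
                           polarity = r$consequent$polarity,
                           property_group = r$consequent$property_group,
                           onset_age_years = NA_real_,
                           duration_weeks = NA_real_,
                           derived = TRUE, rule_id = r$rule_id))
        }
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  new_recs <- if (length(recs) > 0) dplyr::bind_rows(recs) else empty_derivations()
  cohort$derivations <- dplyr::bind_rows(cohort$derivations, new_recs) |>
    dplyr::distinct(.data$patient_id, .data$term_id, .data$polarity,
                    .data$rule_id, .keep_all = TRUE)
  cohort$enriched <- TRUE
  cohort
}

#' Explain how a derived assertion was obtained
#'
#' Returns every derivation chain ending in an assertion on `term_id` for
#' one patient. A chain is a tibble of derivation records ordered from the
#' deepest supporting rule to the final one; assertions that were asserted
#' in the raw data (not derived) yield an empty list.
#'
#' @param cohort An enriched `pheno_cohort` (after [apply_rules()]).
#' @param patient_id,term_id The assertion to explain.
#' @return A list of chains (possibly empty); one chain per distinct rule
#'   path.
#' @export
explain_derivations <- function(cohort, patient_id, term_id) {
  stopifnot(inherits(cohort, "pheno_cohort"))
  recs <- cohort$derivations
  build <- function(pid, tid, seen) {
    here <- recs[recs$patient_id == pid & recs$term_id == tid, , drop = FALSE]
    if (nrow(here) == 0) return(list())
    out <- list()
    for (i in seq_len(nrow(here))) {
      support <- setdiff(here$support[[i]], seen)
      sub_chains <- list()
      for (s in support) {
        sub_chains <- c(sub_chains, build(pid, s, c(seen, tid)))
      }
      step <- here[i, c("patient_id", "term_id", "polarity", "rule_id")]
      if (length(sub_chains) == 0) {
        out <- c(out, list(step))
      } else {
        out <- c(out, purrr::map(sub_chains, ~ dplyr::bind_rows(.x, step)))
      }
    }
    out
  }
  build(patient_id, term_id, character(0))
}
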