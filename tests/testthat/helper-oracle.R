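# Independent brute-force reference implementations used as oracles.
# Deliberately share no traversal code with the package: reachability is
# computed by boolean matrix powers, statuses and query answers by plain
# nested loops over rows.

# Reachability matrix R[x, y] == TRUE iff y is a strict ancestor of x.
oracle_reach <- function(ontology) {
  ids <- ontology$terms$term_id
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (p in ontology$terms$parents[[i]]) A[ids[i], p] <- TRUE
  }
  R <- A
  repeat {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

oracle_ancestors <- function(ontology, term) {
  R <- oracle_reach(ontology)
  colnames(R)[R[term, ]]
}

oracle_descendants <- function(ontology, term) {
  R <- oracle_reach(ontology)
  rownames(R)[R[, term]]
}

# Per-patient three-valued status by row scanning.
oracle_status_one <- function(cohort, pid, term, reach, hierarchy = TRUE,
                              closed_world = FALSE) {
  aa <- cohort$assertions
  in_scope <- function(t) t == term || (hierarchy && reach[t, term])
  present <- FALSE
  absent <- FALSE
  for (i in seq_len(nrow(aa))) {
    if (aa$patient_id[i] != pid) next
    if (aa$polarity[i] == "present" && in_scope(aa$term_id[i])) present <- TRUE
    if (aa$polarity[i] == "absent" && aa$term_id[i] == term) absent <- TRUE
  }
  if (present) return("present")
  if (absent) return("absent")
  if (closed_world) "absent" else "unknown"
}

oracle_statuses <- function(cohort, term, reach, hierarchy = TRUE,
                            closed_world = FALSE) {
  vapply(cohort$patients$patient_id, oracle_status_one,
         character(1), cohort = cohort, term = term, reach = reach,
         hierarchy = hierarchy, closed_world = closed_world)
}

oracle_variants_with_trait <- function(cohort, term, reach,
                                       polarity = "present",
                                       hierarchy = TRUE,
                                       closed_world = FALSE) {
  st <- oracle_statuses(cohort, term, reach, hierarchy, closed_world)
  out <- character(0)
  for (i in seq_len(nrow(cohort$variants))) {
    pid <- cohort$variants$patient_id[i]
    if (st[[pid]] == polarity) out <- c(out, cohort$variants$variant_id[i])
  }
  sort(unique(out))
}

oracle_variants_with_all <- function(cohort, terms, reach, hierarchy = TRUE) {
  out <- character(0)
  for (pid in cohort$patients$patient_id) {
    all_present <- TRUE
    for (t in terms) {
      if (oracle_status_one(cohort, pid, t, reach, hierarchy) != "present") {
        all_present <- FALSE
        break
      }
    }
    if (all_present) {
      out <- c(out,
               cohort$variants$variant_id[cohort$variants$patient_id == pid])
    }
  }
  sort(unique(out))
}

oracle_associations <- function(cohort, term, reach, hierarchy = TRUE) {
  st <- oracle_statuses(cohort, term, reach, hierarchy)
  res <- list()
  for (v in sort(unique(cohort$variants$variant_id))) {
    carriers <- unique(cohort$variants$patient_id[
      cohort$variants$variant_id == v])
    sts <- st[carriers]
    cls <- if (any(sts == "present") && any(sts == "absent")) "mixed"
           else if (any(sts == "present")) "always"
           else if (any(sts == "absent")) "never"
           else "do-not-know"
    res[[v]] <- cls
  }
  res
}

oracle_traits_for_variant <- function(cohort, variant, scope, reach) {
  carriers <- unique(cohort$variants$patient_id[
    cohort$variants$variant_id == variant])
  aa <- cohort$assertions
  out <- character(0)
  for (i in seq_len(nrow(aa))) {
    if (!aa$patient_id[i] %in% carriers) next
    if (aa$polarity[i] != "present") next
    t <- aa$term_id[i]
    if (t == scope || reach[t, scope]) out <- c(out, t)
  }
  sort(unique(out))
}

oracle_trait_frequency <- function(cohort, variant, term, reach) {
  carriers <- unique(cohort$variants$patient_id[
    cohort$variants$variant_id == variant])
  if (length(carriers) == 0) return(NA_real_)
  npres <- 0
  for (pid in carriers) {
    if (oracle_status_one(cohort, pid, term, reach) == "present") {
      npres <- npres + 1
    }
  }
  floor(100 * npres / length(carriers))
}

oracle_cohort_frequency <- function(cohort, term, reach,
                                    polarity = "present") {
  st <- oracle_statuses(cohort, term, reach)
  floor(100 * sum(st == polarity) / nrow(cohort$patients))
}

oracle_mean_attribute <- function(cohort, attribute, ids) {
  vals <- numeric(0)
  at <- cohort$attributes
  for (i in seq_len(nrow(at))) {
    if (at$patient_id[i] %in% ids && at$attribute[i] == attribute &&
          !is.na(at$value[i])) {
      vals <- c(vals, at$value[i])
    }
  }
  if (length(vals) == 0) return(NA_real_)
  floor(mean(vals) * 10 + 0.5) / 10
}
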