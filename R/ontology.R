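#' Phenotype ontology objects
#'
#' A `pheno_ontology` holds the terms of an is-a phenotype hierarchy (a DAG,
#' multiple parents allowed) together with a precomputed transitive closure of
#' the parent relation. Terms live in a tibble with one row per term; the
#' hierarchy roots are terms with no parents.
#'
#' @param terms A tibble with columns `term_id`, `label`, `parents` (list of
#'   character vectors), `synonyms` (list of character vectors) and
#'   `source_tag` (one of `"HPO-derived"`, `"SNOMED-derived"`, `"new"`).
#' @return A validated `pheno_ontology` object.
#' @keywords internal
new_ontology <- function(terms) {
  stopifnot(is.data.frame(terms))
  required <- c("term_id", "label", "parents", "synonyms", "source_tag")
  missing_cols <- setdiff(required, names(terms))
  if (length(missing_cols) > 0) {
    stop("ontology terms table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  terms <- tibble::as_tibble(terms)

  dup <- terms$term_id[duplicated(terms$term_id)]
  if (length(dup) > 0) {
    stop("duplicate term_id in ontology: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }

  all_ids <- terms$term_id
  parent_map <- stats::setNames(terms$parents, all_ids)
  dangling <- purrr::imap(parent_map, function(p, id) setdiff(p, all_ids))
  dangling <- purrr::compact(purrr::map(dangling, function(x) if (length(x)) x else NULL))
  if (length(dangling) > 0) {
    bad <- names(dangling)[1]
    stop("term '", bad, "' references unknown parent(s): ",
         paste(dangling[[1]], collapse = ", "), call. = FALSE)
  }

  cyc <- find_cycle(parent_map)
  if (!is.null(cyc)) {
    stop("is-a cycle detected: ", paste(cyc, collapse = " -> "), call. = FALSE)
  }

  anc <- transitive_ancestors(parent_map)
  roots <- all_ids[purrr::map_int(parent_map, length) == 0]

  structure(
    list(terms = terms, roots = roots, ancestors = anc),
    class = "pheno_ontology"
  )
}

# Depth-first search for a directed cycle over the child -> parent edges;
# returns one cycle as a character vector, or NULL.
find_cycle <- function(parent_map) {
  state <- new.env(parent = emptyenv())  # "open" while on stack, "done" after
  path <- character(0)
  found <- NULL
  visit <- function(id) {
    if (!is.null(found)) return(invisible(NULL))
    st <- if (exists(id, envir = state, inherits = FALSE)) get(id, envir = state) else ""
    if (st == "done") return(invisible(NULL))
    if (st == "open") {
      i <- match(id, path)
      found <<- c(path[i:length(path)], id)
      return(invisible(NULL))
    }
    assign(id, "open", envir = state)
    path <<- c(path, id)
    for (p in parent_map[[id]]) visit(p)
    path <<- path[-length(path)]
    assign(id, "done", envir = state)
    invisible(NULL)
  }
  for (id in names(parent_map)) {
    visit(id)
    if (!is.null(found)) return(found)
  }
  NULL
}

# Transitive closure over parent links, memoized bottom-up.
transitive_ancestors <- function(parent_map) {
  anc <- list()
  compute <- function(id) {
    if (!is.null(anc[[id]])) return(anc[[id]])
    ps <- parent_map[[id]]
    out <- ps
    for (p in ps) out <- union(out, compute(p))
    anc[[id]] <<- out
    out
  }
  for (id in names(parent_map)) compute(id)
  anc[names(parent_map)]
}

#' Parse a phenotype ontology
#'
#' Reads an is-a phenotype ontology from either an OBO 1.2 flat-file subset
#' (stanzas `[Term]` with `id:`, `name:`, `is_a:` and `synonym:` lines) or an
#' equivalent tabular form (columns `term_id`, `label`, `parent_ids`,
#' `synonyms`, with multi-valued fields semicolon-joined, plus an optional
#' `source_tag` column). The loaded hierarchy is validated: duplicate ids,
#' dangling parent references and is-a cycles are errors.
#'
#' @param path Path to the ontology file (or a character vector of lines for
#'   `format = "obo"` when `text = TRUE`).
#' @param format Either `"obo"` or `"tabular"`.
#' @param text If `TRUE`, `path` is taken as the file content itself
#'   (character vector of lines for OBO, a single string for tabular).
#' @return A `pheno_ontology` object.
#' @examples
#' obo <- c("[Term]", "id: Root", "name: root",
#'          "[Term]", "id: A", "name: a", "is_a: Root")
#' onto <- parse_ontology(obo, format = "obo", text = TRUE)
#' ancestors(onto, "A")
#' @export
parse_ontology <- function(path, format = c("obo", "tabular"), text = FALSE) {
  format <- match.arg(format)
  if (format == "obo") {
    lines <- if (text) as.character(path) else readLines(path, warn = FALSE)
    terms <- parse_obo_terms(lines)
  } else {
    tab <- if (text) {
      readr::read_tsv(I(path), col_types = readr::cols(.default = "c"),
                      progress = FALSE)
    } else {
      readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                      progress = FALSE)
    }
    terms <- parse_tabular_terms(tab)
  }
  new_ontology(terms)
}

parse_obo_terms <- function(lines) {
  lines <- stringr::str_trim(lines)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0) {
    stop("no [Term] stanzas found in OBO input", call. = FALSE)
  }
  ends <- c(stanza_starts[-1] - 1L, length(lines))
  rows <- purrr::map2(stanza_starts, ends, function(s, e) {
    body <- lines[seq(s + 1L, e)]
    body <- body[nzchar(body) & !stringr::str_starts(body, "\\[")]
    field <- function(key) {
      hits <- body[stringr::str_starts(body, paste0(key, ":"))]
      stringr::str_trim(stringr::str_remove(hits, paste0("^", key, ":")))
    }
    id <- field("id")
    if (length(id) != 1) stop("OBO [Term] stanza without exactly one id:", call. = FALSE)
    nm <- field("name")
    is_a <- field("is_a")
    # strip trailing "! comment" annotations
    is_a <- stringr::str_trim(stringr::str_remove(is_a, "\\s*!.*$"))
    syn_raw <- field("synonym")
    syn <- stringr::str_match(syn_raw, '"([^"]*)"')[, 2]
    syn <- syn[!is.na(syn)]
    src <- field("property_value")
    tag <- "new"
    src_hit <- stringr::str_match(src, "source_tag\\s+\"?([A-Za-z-]+)\"?")[, 2]
    src_hit <- src_hit[!is.na(src_hit)]
    if (length(src_hit) >= 1) tag <- src_hit[1]
    tibble::tibble(
      term_id = id,
      label = if (length(nm) >= 1) nm[1] else id,
      parents = list(is_a),
      synonyms = list(syn),
      source_tag = tag
    )
  })
  dplyr::bind_rows(rows)
}

parse_tabular_terms <- function(tab) {
  needed <- c("term_id", "label", "parent_ids", "synonyms")
  miss <- setdiff(needed, names(tab))
  if (length(miss) > 0) {
    stop("tabular ontology lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  split_semi <- function(x) {
    purrr::map(x, function(v) {
      if (is.na(v) || !nzchar(v)) character(0)
      else stringr::str_trim(stringr::str_split_1(v, ";"))
    })
  }
  tibble::tibble(
    term_id = tab$term_id,
    label = dplyr::coalesce(tab$label, tab$term_id),
    parents = split_semi(tab$parent_ids),
    synonyms = split_semi(tab$synonyms),
    source_tag = if ("source_tag" %in% names(tab)) {
      dplyr::coalesce(tab$source_tag, "new")
    } else "new"
  )
}

#' Write an ontology to disk
#'
#' Serializes a `pheno_ontology` in the same OBO subset or tabular form
#' accepted by [parse_ontology()]; a parse/write/parse round trip preserves
#' the term and edge sets.
#'
#' @param ontology A `pheno_ontology`.
#' @param path Output file path.
#' @param format `"obo"` or `"tabular"`.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ontology, path, format = c("obo", "tabular")) {
  format <- match.arg(format)
  stopifnot(inherits(ontology, "pheno_ontology"))
  tt <- ontology$terms
  if (format == "obo") {
    chunks <- purrr::pmap(tt, function(term_id, label, parents, synonyms, source_tag) {
      c("[Term]",
        paste0("id: ", term_id),
        paste0("name: ", label),
        paste0("is_a: ", parents, recycle0 = TRUE),
        paste0('synonym: "', synonyms, '" EXACT []', recycle0 = TRUE),
        paste0('property_value: source_tag "', source_tag, '"'),
        "")
    })
    writeLines(c("format-version: 1.2", "", unlist(chunks)), path)
  } else {
    out <- tibble::tibble(
      term_id = tt$term_id,
      label = tt$label,
      parent_ids = purrr::map_chr(tt$parents, paste, collapse = ";"),
      synonyms = purrr::map_chr(tt$synonyms, paste, collapse = ";"),
      source_tag = tt$source_tag
    )
    readr::write_tsv(out, path, progress = FALSE)
  }
  invisible(path)
}

check_term <- function(ontology, term_id) {
  if (length(term_id) != 1 || !term_id %in% ontology$terms$term_id) {
    stop("unknown ontology term: ", paste(term_id, collapse = ", "),
         call. = FALSE)
  }
  invisible(term_id)
}

#' Ancestors of a term
#'
#' All terms reachable from `term_id` via one or more is-a (parent) links,
#' excluding the term itself.
#'
#' @param ontology A `pheno_ontology`.
#' @param term_id A single term id present in the ontology.
#' @return Character vector of ancestor term ids (possibly empty).
#' @export
ancestors <- function(ontology, term_id) {
  check_term(ontology, term_id)
  ontology$ancestors[[term_id]]
}

#' Descendants of a term
#'
#' All terms whose ancestors include `term_id`, excluding the term itself:
#' the terms a hierarchy-expanded query on `term_id` also covers.
#'
#' @inheritParams ancestors
#' @return Character vector of descendant term ids (possibly empty).
#' @export
descendants <- function(ontology, term_id) {
  check_term(ontology, term_id)
  ids <- ontology$terms$term_id
  ids[purrr::map_lgl(ontology$ancestors[ids], function(a) term_id %in% a)]
}

#' Subsumption test
#'
#' `TRUE` iff `general_id` equals `specific_id` or is one of its ancestors,
#' i.e. the broad class subsumes the narrow one (epilepsy is-a seizure
#' disorder is-a abnormality of the central nervous system).
#'
#' @param ontology A `pheno_ontology`.
#' @param general_id,specific_id Term ids present in the ontology.
#' @return A single logical.
#' @export
subsumes <- function(ontology, general_id, specific_id) {
  check_term(ontology, general_id)
  check_term(ontology, specific_id)
  general_id == specific_id || general_id %in% ontology$ancestors[[specific_id]]
}

#' @export
print.pheno_ontology <- function(x, ...) {
  cat("<pheno_ontology> ", nrow(x$terms), " terms, ",
      length(x$roots), " root(s): ", paste(x$roots, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ontology into its term table
#'
#' @param x A `pheno_ontology`.
#' @param ... Unused.
#' @return A tibble with one row per term: `term_id`, `label`, `parent_ids`
#'   (semicolon-joined), `n_ancestors`, `source_tag`.
#' @method tidy pheno_ontology
#' @export
tidy.pheno_ontology <- function(x, ...) {
  tibble::tibble(
    term_id = x$terms$term_id,
    label = x$terms$label,
    parent_ids = purrr::map_chr(x$terms$parents, paste, collapse = ";"),
    n_ancestors = purrr::map_int(x$ancestors[x$terms$term_id], length),
    source_tag = x$terms$source_tag
  )
}

#' One-row ontology summary
#'
#' @param x A `pheno_ontology`.
#' @param ... Unused.
#' @return A one-row tibble: `n_terms`, `n_roots`, `n_edges`, `max_depth`.
#' @method glance pheno_ontology
#' @export
glance.pheno_ontology <- function(x, ...) {
  tibble::tibble(
    n_terms = nrow(x$terms),
    n_roots = length(x$roots),
    n_edges = sum(purrr::map_int(x$terms$parents, length)),
    max_depth = max(purrr::map_int(x$ancestors[x$terms$term_id], length))
  )
}

#' The bundled CTX phenotype ontology
#'
#' Loads the cerebrotendinous xanthomatosis (CTX) phenotype management
#' ontology shipped with the package: roughly sixty terms under the four
#' hierarchy roots `Phenotype`, `AnatomicalStructure`, `DiagnosticStudy` and
#' `QualifierValue`, covering the disorders, anatomical structures,
#' diagnostic-study findings and qualifiers that CTX queries reference
#' (epilepsy, dementia, ataxia, Arnold-Chiari type I malformation, tendon
#' xanthomas, childhood-onset chronic diarrhea, cataract, ...). The internal
#' structure between named terms is a curated subset, not a full disease
#' ontology.
#'
#' @return A `pheno_ontology`.
#' @examples
#' onto <- ctx_ontology()
#' subsumes(onto, "AbnormalityOfTheCerebellum", "Ataxia")
#' @export
ctx_ontology <- function() {
  path <- system.file("extdata", "ctx_ontology.obo", package = "phenoquery")
  parse_ontology(path, format = "obo")
}
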