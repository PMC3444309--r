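#' Plot the three-valued status breakdown of a cohort
#'
#' Stacked bar chart of the proportion of patients that are present, absent
#' or unknown for each requested term, after hierarchy expansion — a visual
#' account of how much of the cohort is open-world "do not know".
#'
#' @param cohort A `pheno_cohort` (enrich with [apply_rules()] first to see
#'   derived abstractions).
#' @param term_ids Character vector of ontology term ids.
#' @param ontology A `pheno_ontology`.
#' @param hierarchy Expand terms to descendants (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_status_breakdown <- function(cohort, term_ids, ontology,
                                  hierarchy = TRUE) {
  dat <- purrr::map_dfr(term_ids, function(t) {
    st <- phenotype_status(cohort, t, ontology, hierarchy = hierarchy)
    dplyr::count(st, status = factor(.data$status,
                                     c("present", "absent", "unknown"))) |>
      dplyr::mutate(term_id = t)
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$term_id, y = .data$n,
                                    fill = .data$status)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::scale_fill_manual(values = c(present = "#b2182b",
                                          absent = "#2166ac",
                                          unknown = "grey75"),
                               drop = FALSE) +
    ggplot2::labs(x = NULL, y = "patients", fill = "status",
                  title = "Three-valued phenotype status") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Plot per-variant association classes for a trait
#'
#' For every variant with at least one carrier, shows the carrier counts by
#' status and the resulting association class (always / never / mixed /
#' do-not-know) for the given trait.
#'
#' @inheritParams plot_status_breakdown
#' @param term_id A single ontology term id.
#' @return A ggplot object.
#' @export
plot_variant_associations <- function(cohort, term_id, ontology,
                                      hierarchy = TRUE) {
  va <- variant_associations(cohort, term_id, ontology, hierarchy)
  long <- tidyr::pivot_longer(
    va, c("n_present", "n_absent", "n_unknown"),
    names_to = "status", values_to = "n", names_prefix = "n_")
  long$status <- factor(long$status, c("present", "absent", "unknown"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$variant_id,
                                     fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$association),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_manual(values = c(present = "#b2182b",
                                          absent = "#2166ac",
                                          unknown = "grey75"),
                               drop = FALSE) +
    ggplot2::labs(x = "carriers", y = NULL, fill = "status",
                  title = paste0("Variant associations with ", term_id)) +
    ggplot2::theme_minimal()
}
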