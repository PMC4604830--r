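#' Missing-data statistics for a synthetic matrix
#'
#' A cell is populated when at least one support backs it, and asserted when
#' at least one of those supports is a direct assertion; the asserted-only
#' missing fraction re-derives cell values from direct assertions alone, so
#' the difference between the two fractions is the data inference adds.
#' For an empty grid both missing fractions are defined as 1.
#'
#' @param m A `synthetic_matrix`.
#' @return A one-row tibble: `n_characters`, `n_taxa`, `n_cells`,
#'   `n_populated`, `n_asserted_cells`, `n_inferred_only_cells`,
#'   `frac_missing_with_inference`, `frac_missing_asserted_only`.
#' @export
missing_data_stats <- function(m) {
  stopifnot(inherits(m, "synthetic_matrix"))
  n_cells <- length(m$taxa) * length(m$characters)
  n_pop <- nrow(m$cells)
  asserted_cells <- distinct(m$supports[m$supports$mode == "asserted", ],
                             .data$taxon, .data$entity)
  n_asserted <- nrow(asserted_cells)
  tibble(
    n_characters = length(m$characters),
    n_taxa = length(m$taxa),
    n_cells = n_cells,
    n_populated = n_pop,
    n_asserted_cells = n_asserted,
    n_inferred_only_cells = n_pop - n_asserted,
    frac_missing_with_inference = if (n_cells == 0) 1 else 1 - n_pop / n_cells,
    frac_missing_asserted_only = if (n_cells == 0) 1 else 1 - n_asserted / n_cells
  )
}

#' Count published states entailing presence or absence per taxon and entity
#'
#' For each (taxon, entity) pair, the number of distinct published character
#' states (source, character, state triples) assigned to the taxon with at
#' least one phenotype entailing presence or absence of the entity.  States
#' are counted, not phenotypes: a state with several entailing phenotypes for
#' one entity counts once; a polymorphic cell's states each count once.  This
#' is the data table behind sampling heat maps over a clade.
#'
#' @param sources List of `source_matrix` objects.
#' @param anatomy Anatomy `ontology`.
#' @param entities Character vector of anatomy term ids (column order).
#' @param taxa Character vector of taxonomy term ids (row order).
#' @return A tibble with columns `taxon`, `entity`, `n_states`, one row per
#'   pair in the input order (zero rows for unsampled taxa are included).
#' @export
entailing_state_counts <- function(sources, anatomy, entities, taxa) {
  assert_terms(anatomy, entities)
  sup <- compute_supports(anatomy, sources, characters = entities, taxa = taxa)
  counts <- sup %>%
    distinct(.data$taxon, .data$entity, .data$matrix_id, .data$char_id, .data$state_id) %>%
    count(.data$taxon, .data$entity, name = "n_states")
  grid <- tidyr::expand_grid(taxon = taxa, entity = entities)
  left_join(grid, counts, by = c("taxon", "entity")) %>%
    mutate(n_states = if_else(is.na(.data$n_states), 0L, as.integer(.data$n_states)))
}

#' Count source matrices per taxon
#'
#' For every taxon inside the taxon expression that appears in at least one
#' source cell, the number of distinct source matrices (publications) scoring
#' it, plus its taxonomic rank when the taxonomy carries a `rank` column.
#'
#' @param sources List of `source_matrix` objects.
#' @param taxonomy Taxonomy `ontology`.
#' @param taxon_expr Class expression (or string) selecting the clade.
#' @return A tibble with columns `taxon`, `n_matrices`, `rank`, sorted by
#'   taxon.
#' @export
taxon_source_counts <- function(sources, taxonomy, taxon_expr) {
  taxa <- select_taxa(taxonomy, taxon_expr, sources)
  per_source <- purrr::map_dfr(sources, function(m) {
    tibble(taxon = unique(m$cells$taxon), matrix_id = m$matrix_id)
  })
  counts <- per_source %>%
    filter(.data$taxon %in% taxa) %>%
    distinct() %>%
    count(.data$taxon, name = "n_matrices")
  ranks <- if ("rank" %in% names(taxonomy$terms)) {
    select(taxonomy$terms, taxon = "id", rank = "rank")
  } else {
    tibble(taxon = taxonomy$terms$id, rank = NA_character_)
  }
  counts %>%
    left_join(ranks, by = "taxon") %>%
    arrange(.data$taxon)
}
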