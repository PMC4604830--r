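#' Detect and classify conflicting (BOTH-valued) cells
#'
#' A taxon carrying both presence and absence for one entity is either a true
#' polymorphism or a conflict between the underlying annotations.  Cells where
#' a single source matrix directly asserts both values are classified as
#' intra-source polymorphism and flagged excluded from conflict totals; the
#' rest are classified by the strongest evidence on each side:
#' `asserted_asserted` (direct assertions in different publications),
#' `asserted_inferred` (a direct assertion against an inference), or
#' `inferred_inferred`.  Categories are mutually exclusive and exhaustive, in
#' that precedence order.
#'
#' @param m A `synthetic_matrix` with provenance.
#' @return A tibble with one row per `BOTH` cell: `taxon`, `entity`,
#'   `category`, `excluded` (TRUE for intra-source polymorphism),
#'   `n_presence_supports`, `n_absence_supports`.  Conflicts are reported,
#'   never auto-resolved.
#' @export
detect_conflicts <- function(m) {
  stopifnot(inherits(m, "synthetic_matrix"))
  both <- m$cells[m$cells$value == "BOTH", ]
  if (nrow(both) == 0) {
    return(tibble(taxon = character(), entity = character(), category = character(),
                  excluded = logical(), n_presence_supports = integer(),
                  n_absence_supports = integer()))
  }
  sup <- semi_join(m$supports, both, by = c("taxon", "entity"))
  purrr::map_dfr(seq_len(nrow(both)), function(i) {
    s <- sup[sup$taxon == both$taxon[[i]] & sup$entity == both$entity[[i]], ]
    tibble(
      taxon = both$taxon[[i]], entity = both$entity[[i]],
      category = classify_conflict(s),
      n_presence_supports = sum(s$value == "present"),
      n_absence_supports = sum(s$value == "absent")
    )
  }) %>%
    mutate(excluded = .data$category == "intra_source_polymorphism") %>%
    select("taxon", "entity", "category", "excluded",
           "n_presence_supports", "n_absence_supports") %>%
    arrange(.data$taxon, .data$entity)
}

#' Classify the supports of one BOTH-valued cell
#'
#' @param supports Tibble of support rows for one (taxon, entity) cell, with
#'   both values represented.
#' @return One of `"intra_source_polymorphism"`, `"asserted_asserted"`,
#'   `"asserted_inferred"`, `"inferred_inferred"`.
#' @export
classify_conflict <- function(supports) {
  p <- supports[supports$value == "present", ]
  a <- supports[supports$value == "absent", ]
  stopifnot(nrow(p) > 0, nrow(a) > 0)
  intra <- intersect(p$matrix_id[p$mode == "asserted"], a$matrix_id[a$mode == "asserted"])
  if (length(intra) > 0) return("intra_source_polymorphism")
  p_ass <- any(p$mode == "asserted")
  a_ass <- any(a$mode == "asserted")
  if (p_ass && a_ass) return("asserted_asserted")
  if (p_ass || a_ass) return("asserted_inferred")
  "inferred_inferred"
}

#' Long-form conflict report with full provenance
#'
#' One row per (conflict cell, side, support): taxon, entity, category, the
#' side the support backs, and the source matrix / character / state /
#' mode behind it.  Suitable for TSV export and manual review.
#'
#' @param records Output of [detect_conflicts()].
#' @param m The `synthetic_matrix` the records came from.
#' @return A tibble.
#' @export
conflict_report <- function(records, m) {
  cols <- c("taxon", "entity", "category", "excluded", "side", "matrix_id",
            "char_id", "state_id", "mode", "phen_entity", "quality")
  if (nrow(records) == 0) {
    out <- as_tibble(setNames(rep(list(character()), length(cols)), cols))
    out$excluded <- logical()
    return(out)
  }
  sup <- semi_join(m$supports, records, by = c("taxon", "entity"))
  left_join(records, sup, by = c("taxon", "entity"),
            relationship = "many-to-many") %>%
    mutate(side = if_else(.data$value == "present", "presence", "absence")) %>%
    select(all_of(cols)) %>%
    arrange(.data$taxon, .data$entity, .data$side, .data$matrix_id,
            .data$char_id, .data$state_id)
}
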