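#' Generate the synthetic character list for an anatomical class expression
#'
#' One synthetic presence/absence character is created for every anatomy
#' class subsumed by the input expression, in lexicographic order.  Columns
#' with no support can be pruned later by [synthesize()].
#'
#' @param anatomy An anatomy `ontology`.
#' @param entity_expr A `class_expression` or expression string.
#' @return Sorted character vector of anatomy term ids.
#' @export
generate_characters <- function(anatomy, entity_expr) {
  chars <- evaluate_class_expression(anatomy, entity_expr)
  if (length(chars) == 0) warn("entity expression subsumes no anatomy class; empty matrix")
  chars
}

#' Select the taxa entering a synthetic matrix
#'
#' All taxa that appear in at least one source-matrix cell and fall inside the
#' taxon expression (a taxon qualifies if it is the named class or any
#' `is_a` descendant of it).  Higher-rank taxa are rows of their own: no
#' state ever propagates down the taxonomy.
#'
#' @param taxonomy A taxonomy `ontology`.
#' @param taxon_expr A `class_expression` or expression string.
#' @param sources List of `source_matrix` objects.
#' @return Sorted character vector of taxonomy term ids.
#' @export
select_taxa <- function(taxonomy, taxon_expr, sources) {
  clade <- evaluate_class_expression(taxonomy, taxon_expr)
  with_data <- unique(unlist(lapply(sources, function(m) unique(m$cells$taxon))))
  sort(intersect(with_data, clade))
}

# Expand every assigned (taxon, state, phenotype) into one support row per
# synthetic character it entails a value for.  Vectorized: closures are
# computed once per distinct (target, polarity) pair.
compute_supports <- function(anatomy, sources, characters, taxa) {
  empty <- empty_supports_tibble()
  assigned <- purrr::map_dfr(sources, function(m) {
    ph <- phenotype_table(m)
    if (nrow(ph) == 0 || nrow(m$cells) == 0) return(NULL)
    cells <- m$cells[m$cells$taxon %in% taxa, ]
    if (nrow(cells) == 0) return(NULL)
    out <- inner_join_safe(cells, ph, by = c("char_id", "state_id"))
    if (nrow(out) == 0) return(NULL)
    out$matrix_id <- m$matrix_id
    out
  })
  if (nrow(assigned) == 0) return(empty)
  bad <- setdiff(assigned$target, anatomy$terms$id)
  if (length(bad) > 0) {
    abort(paste0("annotations reference unknown anatomy term(s): ",
                 paste(sort(unique(bad)), collapse = ", ")))
  }
  targets <- distinct(assigned, .data$target, .data$polarity)
  expansion <- purrr::map_dfr(seq_len(nrow(targets)), function(i) {
    tg <- targets$target[[i]]
    pol <- targets$polarity[[i]]
    ent <- if (pol == "presence_type") {
      intersect(upward_closure(anatomy, tg), characters)
    } else {
      intersect(downward_closure(anatomy, tg), characters)
    }
    if (length(ent) == 0) return(NULL)
    tibble(target = tg, polarity = pol, entity = ent)
  })
  if (nrow(expansion) == 0) return(empty)
  sup <- inner_join_safe(assigned, expansion, by = c("target", "polarity"))
  sup %>%
    mutate(
      value = if_else(.data$polarity == "presence_type", "present", "absent"),
      mode = if_else(.data$target == .data$entity.y &
                       .data$quality %in% c(QUALITY_PRESENT, QUALITY_ABSENT),
                     "asserted", "inferred")
    ) %>%
    select(taxon = "taxon", entity = "entity.y", value = "value", mode = "mode",
           matrix_id = "matrix_id", char_id = "char_id", state_id = "state_id",
           phen_entity = "entity.x", quality = "quality",
           related_entity = "related_entity", phen_target = "target",
           polarity = "polarity") %>%
    distinct() %>%
    arrange(.data$taxon, .data$entity, .data$matrix_id, .data$char_id,
            .data$state_id, .data$value)
}

empty_supports_tibble <- function() {
  tibble(taxon = character(), entity = character(), value = character(),
         mode = character(), matrix_id = character(), char_id = character(),
         state_id = character(), phen_entity = character(),
         quality = character(), related_entity = character(),
         phen_target = character(), polarity = character())
}

inner_join_safe <- function(x, y, by) {
  dplyr::inner_join(x, y, by = by, relationship = "many-to-many")
}

cell_values_from_supports <- function(supports) {
  if (nrow(supports) == 0) {
    return(tibble(taxon = character(), entity = character(), value = character()))
  }
  supports %>%
    group_by(.data$taxon, .data$entity) %>%
    summarise(
      value = {
        v <- unique(.data$value)
        if (length(v) == 2) "BOTH" else if (v == "present") "PRESENT" else "ABSENT"
      },
      .groups = "drop"
    ) %>%
    arrange(.data$taxon, .data$entity)
}

#' Synthesize a presence/absence supermatrix from annotated studies
#'
#' For every (taxon, entity) pair, collects a support record for each
#' (source, character, state, phenotype) combination where the taxon is
#' assigned that state and the phenotype entails presence or absence of the
#' entity.  Cell values are a pure function of the supports: `PRESENT`,
#' `ABSENT`, or `BOTH` (polymorphism/conflict); pairs with no support are
#' missing.  A support is a direct assertion only when the phenotype targets
#' the character's entity exactly with quality "present" or "absent";
#' everything else is inference (a "present" on a subclass is inferred, not
#' asserted, support for the superclass).
#'
#' @param anatomy Anatomy `ontology`.
#' @param taxonomy Taxonomy `ontology`.
#' @param sources List of `source_matrix` objects.
#' @param entity_expr Class expression (or string) selecting the characters.
#' @param taxon_expr Class expression (or string) selecting the clade.
#' @param prune `"unsupported"` (default) drops all-missing rows and columns;
#'   `"none"` keeps the full grid.
#' @param inference When `FALSE`, only direct assertions populate cells
#'   (the asserted-only view used for missing-data comparisons).
#' @return An object of class `synthetic_matrix`: `characters`, `taxa`,
#'   `cells` (tibble of populated cells: `taxon`, `entity`, `value`),
#'   `supports` (one row per support record), the input expressions, and
#'   build metadata.
#' @export
synthesize <- function(anatomy, taxonomy, sources, entity_expr, taxon_expr,
                       prune = c("unsupported", "none"), inference = TRUE) {
  prune <- arg_match(prune)
  if (is.character(entity_expr)) entity_expr <- parse_class_expression(entity_expr)
  if (is.character(taxon_expr)) taxon_expr <- parse_class_expression(taxon_expr)
  characters <- generate_characters(anatomy, entity_expr)
  taxa <- select_taxa(taxonomy, taxon_expr, sources)
  supports <- compute_supports(anatomy, sources, characters, taxa)
  if (!inference) supports <- supports[supports$mode == "asserted", ]
  cells <- cell_values_from_supports(supports)
  if (prune == "unsupported") {
    characters <- intersect(characters, unique(cells$entity))
    taxa <- intersect(taxa, unique(cells$taxon))
  }
  new_synthetic_matrix(
    characters = characters, taxa = taxa, cells = cells, supports = supports,
    entity_expression = format(entity_expr), taxon_expression = format(taxon_expr),
    inference = inference,
    sources = tibble(matrix_id = vapply(sources, function(m) m$matrix_id, character(1)),
                     citation = vapply(sources, function(m) m$citation, character(1)))
  )
}

new_synthetic_matrix <- function(characters, taxa, cells, supports,
                                 entity_expression, taxon_expression,
                                 inference, sources, variability = NULL) {
  structure(
    list(
      characters = sort(characters), taxa = sort(taxa),
      cells = arrange(cells, .data$taxon, .data$entity),
      supports = supports,
      entity_expression = entity_expression, taxon_expression = taxon_expression,
      inference = inference,
      variability = variability,
      meta = list(tool = "phenosynth",
                  version = as.character(packageVersion("phenosynth")),
                  sources = arrange(sources, .data$matrix_id))
    ),
    class = "synthetic_matrix"
  )
}

#' @export
print.synthetic_matrix <- function(x, ...) {
  n_cells <- length(x$taxa) * length(x$characters)
  cat(sprintf("<synthetic_matrix> %d characters x %d taxa, %d populated cells (%.1f%%)\n",
              length(x$characters), length(x$taxa), nrow(x$cells),
              if (n_cells > 0) 100 * nrow(x$cells) / n_cells else 0))
  cat("  entity expression: ", x$entity_expression, "\n", sep = "")
  cat("  taxon expression:  ", x$taxon_expression, "\n", sep = "")
  if (!x$inference) cat("  (inference disabled: direct assertions only)\n")
  invisible(x)
}

#' Tabulate a synthetic matrix's cells
#'
#' @param x A `synthetic_matrix`.
#' @param complete When `TRUE`, include missing cells (value `"MISSING"`)
#'   so the result covers the full taxa-by-characters grid.
#' @param ... Unused.
#' @return A tibble with columns `taxon`, `entity`, `value`, `n_asserted`,
#'   `n_inferred`.
#' @method as_tibble synthetic_matrix
#' @export
as_tibble.synthetic_matrix <- function(x, complete = FALSE, ...) {
  counts <- x$supports %>%
    count(.data$taxon, .data$entity, .data$mode) %>%
    tidyr::pivot_wider(names_from = "mode", values_from = "n", values_fill = 0L)
  for (col in c("asserted", "inferred")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  out <- left_join(x$cells, counts, by = c("taxon", "entity")) %>%
    select("taxon", "entity", "value", n_asserted = "asserted", n_inferred = "inferred")
  if (complete) {
    grid <- tidyr::expand_grid(taxon = x$taxa, entity = x$characters)
    out <- left_join(grid, out, by = c("taxon", "entity")) %>%
      mutate(value = if_else(is.na(.data$value), "MISSING", .data$value),
             n_asserted = if_else(is.na(.data$n_asserted), 0L, .data$n_asserted),
             n_inferred = if_else(is.na(.data$n_inferred), 0L, .data$n_inferred))
  }
  arrange(out, .data$taxon, .data$entity)
}

#' Restrict a synthetic matrix to its variable characters
#'
#' Keeps characters whose column contains both presence and absence across
#' taxa (a single `BOTH` cell suffices), then drops taxa left with no
#' populated cell.  Each kept character is annotated with the basis of its
#' variability: `asserted_only` (variable on direct assertions alone),
#' `variable_only_by_inference` (has direct assertions but needs inference to
#' show both values), or `inferred_only` (no direct assertion at all).
#'
#' @param m A `synthetic_matrix`.
#' @return A `synthetic_matrix` whose `variability` field is a tibble with
#'   columns `entity`, `basis`.
#' @export
variable_subset <- function(m) {
  stopifnot(inherits(m, "synthetic_matrix"))
  col_var <- m$cells %>%
    group_by(.data$entity) %>%
    summarise(
      has_p = any(.data$value %in% c("PRESENT", "BOTH")),
      has_a = any(.data$value %in% c("ABSENT", "BOTH")),
      .groups = "drop"
    )
  keep <- sort(col_var$entity[col_var$has_p & col_var$has_a])
  cells <- m$cells[m$cells$entity %in% keep, ]
  supports <- m$supports[m$supports$entity %in% keep, ]
  taxa <- sort(unique(cells$taxon))
  supports <- supports[supports$taxon %in% taxa, ]
  variability <- purrr::map_dfr(keep, function(e) {
    sup <- supports[supports$entity == e, ]
    asserted <- sup[sup$mode == "asserted", ]
    if (nrow(asserted) == 0) return(tibble(entity = e, basis = "inferred_only"))
    avals <- cell_values_from_supports(asserted)
    a_var <- any(avals$value %in% c("PRESENT", "BOTH")) &&
      any(avals$value %in% c("ABSENT", "BOTH"))
    tibble(entity = e,
           basis = if (a_var) "asserted_only" else "variable_only_by_inference")
  })
  out <- new_synthetic_matrix(
    characters = keep, taxa = taxa, cells = cells, supports = supports,
    entity_expression = m$entity_expression, taxon_expression = m$taxon_expression,
    inference = m$inference, sources = m$meta$sources, variability = variability
  )
  out
}

#' Dump a synthetic matrix's cells to TSV
#'
#' Columns: `taxon`, `entity`, `value`, `n_asserted`, `n_inferred`.
#'
#' @param m A `synthetic_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cell_tsv <- function(m, path) {
  write_tsv_plain(as_tibble(m), path)
}

write_tsv_plain <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
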