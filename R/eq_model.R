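#' Construct an Entity-Quality phenotype annotation
#'
#' An EQ phenotype pairs an anatomical entity with a quality, optionally with
#' a second ("towards") entity.  Two framings express absence: quality
#' "absent" (PATO:0000462) inhering directly in the entity, or the
#' organism-level lacks-all-parts pattern (quality PATO:0002000 with the
#' negated class in `related_entity`).  Both normalize to the same
#' `absence_type` polarity with a single negated entity; every other quality
#' inheres in the entity and therefore implies its presence.
#'
#' @param entity Anatomy term id the quality inheres in.
#' @param quality Quality term id.
#' @param related_entity Optional anatomy term id (the "towards" filler).
#' @return A list of class `eq_phenotype` with fields `entity`, `quality`,
#'   `related_entity`, `polarity`, and `negated` (the negated class for
#'   absence-type phenotypes, `NA` otherwise).
#' @export
eq_phenotype <- function(entity, quality, related_entity = NA_character_) {
  stopifnot(is.character(entity), nzchar(entity), is.character(quality), nzchar(quality))
  related_entity <- related_entity %||% NA_character_
  polarity <- classify_phenotype_quality(quality)
  structure(
    list(
      entity = entity,
      quality = quality,
      related_entity = related_entity,
      polarity = polarity,
      negated = if (polarity == "absence_type") {
        if (!is.na(related_entity)) related_entity else entity
      } else NA_character_
    ),
    class = "eq_phenotype"
  )
}

classify_phenotype_quality <- function(quality) {
  if (quality %in% ABSENCE_QUALITIES) "absence_type" else "presence_type"
}

#' Classify an EQ phenotype as presence-type or absence-type
#'
#' Deterministic and total: absence-type iff the quality is the designated
#' "absent" (PATO:0000462) or lacks-all-parts (PATO:0002000) term; any other
#' inhering quality (shape, size, ...) implies presence of its bearer.
#'
#' @param p An `eq_phenotype` (or a quality id string).
#' @return `"presence_type"` or `"absence_type"`.
#' @export
classify_phenotype <- function(p) {
  if (inherits(p, "eq_phenotype")) return(p$polarity)
  classify_phenotype_quality(p)
}

#' @export
print.eq_phenotype <- function(x, ...) {
  cat(sprintf("<eq_phenotype %s> E=%s Q=%s%s\n", x$polarity, x$entity, x$quality,
              if (!is.na(x$related_entity)) paste0(" towards=", x$related_entity) else ""))
  invisible(x)
}

#' Construct a source matrix (one published study)
#'
#' A source matrix holds the taxa, published characters, character states with
#' their EQ annotations, and the taxon-by-character cell assignments of one
#' publication.  A cell assigned more than one state of a character is a
#' published polymorphism.
#'
#' @param matrix_id Identifier standing for one publication.
#' @param citation Free-text citation.
#' @param taxa Character vector of taxonomy term ids.
#' @param characters Tibble with columns `char_id`, `label`.
#' @param states Tibble with columns `char_id`, `state_id`, `label`.
#' @param phenotypes Tibble with columns `char_id`, `state_id`, `entity`,
#'   `quality`, `related_entity` (NA when unset).  States absent from this
#'   table are unannotated; they participate in provenance counts but never in
#'   entailment.
#' @param cells Tibble with columns `taxon`, `char_id`, `state_id` (one row
#'   per assigned state).
#' @return An object of class `source_matrix`.
#' @export
source_matrix <- function(matrix_id, citation = "", taxa, characters, states,
                          phenotypes = NULL, cells) {
  characters <- as_tibble(characters)
  states <- as_tibble(states)
  cells <- as_tibble(cells)
  if (is.null(phenotypes)) {
    phenotypes <- tibble(char_id = character(), state_id = character(),
                         entity = character(), quality = character(),
                         related_entity = character())
  }
  phenotypes <- as_tibble(phenotypes)
  if (!"related_entity" %in% names(phenotypes)) {
    phenotypes$related_entity <- NA_character_
  }
  m <- structure(
    list(matrix_id = matrix_id, citation = citation, taxa = sort(unique(taxa)),
         characters = arrange(characters, .data$char_id),
         states = arrange(states, .data$char_id, .data$state_id),
         phenotypes = arrange(phenotypes, .data$char_id, .data$state_id,
                              .data$entity, .data$quality),
         cells = arrange(distinct(cells), .data$taxon, .data$char_id, .data$state_id)),
    class = "source_matrix"
  )
  validate_source_matrix(m)
  m
}

validate_source_matrix <- function(m) {
  if (anyDuplicated(m$characters$char_id)) abort("duplicate char_id in source matrix")
  key <- paste(m$states$char_id, m$states$state_id)
  if (anyDuplicated(key)) abort("duplicate (char_id, state_id) in source matrix")
  if (any(!m$states$char_id %in% m$characters$char_id)) {
    abort("state references unknown char_id")
  }
  if (nrow(m$phenotypes) > 0) {
    pk <- paste(m$phenotypes$char_id, m$phenotypes$state_id)
    if (any(!pk %in% key)) abort("phenotype references unknown (char_id, state_id)")
  }
  if (nrow(m$cells) > 0) {
    if (any(!m$cells$taxon %in% m$taxa)) abort("cell references unknown taxon")
    ck <- paste(m$cells$char_id, m$cells$state_id)
    if (any(!ck %in% key)) abort("cell references unknown (char_id, state_id)")
  }
  unann <- anti_join(m$states, m$phenotypes, by = c("char_id", "state_id"))
  if (nrow(unann) > 0) {
    inform(paste0(m$matrix_id, ": ", nrow(unann), " unannotated state(s)"))
  }
  invisible(m)
}

#' @export
print.source_matrix <- function(x, ...) {
  cat(sprintf("<source_matrix %s> %d taxa, %d characters, %d states (%d annotated), %d cell assignments\n",
              x$matrix_id, length(x$taxa), nrow(x$characters), nrow(x$states),
              nrow(distinct(x$phenotypes, .data$char_id, .data$state_id)), nrow(x$cells)))
  invisible(x)
}

# phenotype table with polarity and negated-entity columns
phenotype_table <- function(m) {
  p <- m$phenotypes
  if (nrow(p) == 0) {
    return(mutate(p, polarity = character(), target = character()))
  }
  mutate(p,
         polarity = if_else(.data$quality %in% ABSENCE_QUALITIES,
                            "absence_type", "presence_type"),
         target = if_else(.data$polarity == "absence_type" & !is.na(.data$related_entity),
                          .data$related_entity, .data$entity))
}

#' Read a study bundle (JSON) into a source matrix
#'
#' The bundle dialect is a single JSON object:
#' ```
#' {"matrix_id": ..., "citation": ..., "taxa": [...],
#'  "characters": [{"char_id": ..., "label": ...,
#'                  "states": [{"state_id": ..., "label": ...,
#'                              "phenotypes": [{"entity": ..., "quality": ...,
#'                                              "related_entity": ...?}]}]}],
#'  "cells": [{"taxon": ..., "char_id": ..., "state_ids": [...]}]}
#' ```
#'
#' @param path Path to a JSON study bundle.
#' @return A validated `source_matrix`.
#' @export
read_study_bundle <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  b <- jsonlite::read_json(path)
  for (f in c("matrix_id", "taxa", "characters", "cells")) {
    if (is.null(b[[f]])) abort(paste0("study bundle missing /", f))
  }
  chars <- purrr::map_dfr(b$characters, function(ch) {
    if (is.null(ch$char_id)) abort("study bundle: character missing /characters/*/char_id")
    tibble(char_id = ch$char_id, label = ch$label %||% ch$char_id)
  })
  states <- purrr::map_dfr(b$characters, function(ch) {
    purrr::map_dfr(ch$states, function(s) {
      if (is.null(s$state_id)) abort("study bundle: state missing /characters/*/states/*/state_id")
      tibble(char_id = ch$char_id, state_id = s$state_id, label = s$label %||% s$state_id)
    })
  })
  phen <- purrr::map_dfr(b$characters, function(ch) {
    purrr::map_dfr(ch$states, function(s) {
      purrr::map_dfr(s$phenotypes, function(p) {
        if (is.null(p$entity) || is.null(p$quality)) {
          abort("study bundle: phenotype missing entity/quality")
        }
        tibble(char_id = ch$char_id, state_id = s$state_id,
               entity = p$entity, quality = p$quality,
               related_entity = p$related_entity %||% NA_character_)
      })
    })
  })
  cells <- purrr::map_dfr(b$cells, function(cl) {
    if (is.null(cl$taxon) || is.null(cl$char_id)) abort("study bundle: cell missing taxon/char_id")
    tibble(taxon = cl$taxon, char_id = cl$char_id,
           state_id = unlist(cl$state_ids))
  })
  # purrr::map_dfr over empty lists gives zero-column frames; restore shapes
  fix_empty <- function(df, cols) {
    if (nrow(df) > 0) return(df)
    as_tibble(setNames(rep(list(character()), length(cols)), cols))
  }
  chars <- fix_empty(chars, c("char_id", "label"))
  states <- fix_empty(states, c("char_id", "state_id", "label"))
  phen <- fix_empty(phen, c("char_id", "state_id", "entity", "quality", "related_entity"))
  cells <- fix_empty(cells, c("taxon", "char_id", "state_id"))
  source_matrix(matrix_id = b$matrix_id, citation = b$citation %||% "",
                taxa = as.character(unlist(b$taxa)), characters = chars, states = states,
                phenotypes = phen, cells = cells)
}

#' Write a source matrix as a study-bundle JSON file
#'
#' Inverse of [read_study_bundle()] (lossless round-trip).
#'
#' @param m A `source_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study_bundle <- function(m, path) {
  stopifnot(inherits(m, "source_matrix"))
  chars <- lapply(seq_len(nrow(m$characters)), function(i) {
    cid <- m$characters$char_id[[i]]
    st <- m$states[m$states$char_id == cid, ]
    states <- lapply(seq_len(nrow(st)), function(j) {
      sid <- st$state_id[[j]]
      ph <- m$phenotypes[m$phenotypes$char_id == cid & m$phenotypes$state_id == sid, ]
      phl <- lapply(seq_len(nrow(ph)), function(k) {
        p <- list(entity = ph$entity[[k]], quality = ph$quality[[k]])
        if (!is.na(ph$related_entity[[k]])) p$related_entity <- ph$related_entity[[k]]
        p
      })
      list(state_id = sid, label = st$label[[j]], phenotypes = phl)
    })
    list(char_id = cid, label = m$characters$label[[i]], states = states)
  })
  cell_groups <- m$cells %>%
    group_by(.data$taxon, .data$char_id) %>%
    summarise(state_ids = list(sort(.data$state_id)), .groups = "drop") %>%
    arrange(.data$taxon, .data$char_id)
  cells <- lapply(seq_len(nrow(cell_groups)), function(i) {
    list(taxon = cell_groups$taxon[[i]], char_id = cell_groups$char_id[[i]],
         state_ids = cell_groups$state_ids[[i]])
  })
  jsonlite::write_json(
    list(matrix_id = m$matrix_id, citation = m$citation, taxa = m$taxa,
         characters = chars, cells = cells),
    path, auto_unbox = TRUE, pretty = TRUE, null = "null", na = "null"
  )
  invisible(path)
}
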