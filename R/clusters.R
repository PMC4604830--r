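#' Find isomorphic synthetic characters
#'
#' Partitions the matrix's characters by exact column equality over all taxa,
#' including the missing-data pattern (strict isomorphism), and returns the
#' clusters with two or more members.  Identical columns typically arise from
#' ontology structure: a presence assertion on a part induces the same value
#' on every containing structure, so a part and its whole annotated only via
#' the part are isomorphic.
#'
#' @param m A `synthetic_matrix` (typically the variable subset).
#' @return A tibble with one row per cluster: `cluster_id`, `members`
#'   (list-column of sorted term ids), `size`, `inferred_only` (no member
#'   column contains a direct assertion), `n_cells` (populated cells covered
#'   by the cluster), and `signature` (the shared column, values over sorted
#'   taxa collapsed to a string).  Deterministic ordering by first member.
#' @export
find_isomorphic_clusters <- function(m) {
  stopifnot(inherits(m, "synthetic_matrix"))
  if (length(m$characters) == 0 || length(m$taxa) == 0) {
    return(empty_cluster_tibble())
  }
  grid <- as_tibble(m, complete = TRUE)
  sig <- grid %>%
    arrange(.data$entity, .data$taxon) %>%
    group_by(.data$entity) %>%
    summarise(signature = paste(.data$value, collapse = "|"),
              n_pop = sum(.data$value != "MISSING"),
              .groups = "drop")
  asserted_entities <- unique(m$supports$entity[m$supports$mode == "asserted"])
  clusters <- sig %>%
    group_by(.data$signature) %>%
    summarise(members = list(sort(.data$entity)),
              size = n(),
              n_cells = sum(.data$n_pop),
              .groups = "drop") %>%
    filter(.data$size >= 2)
  if (nrow(clusters) == 0) return(empty_cluster_tibble())
  clusters <- clusters %>%
    mutate(
      first_member = purrr::map_chr(.data$members, 1),
      inferred_only = purrr::map_lgl(.data$members,
                                     ~ !any(.x %in% asserted_entities))
    ) %>%
    arrange(.data$first_member) %>%
    mutate(cluster_id = paste0("cluster_", row_number())) %>%
    select("cluster_id", "members", "size", "inferred_only", "n_cells", "signature")
  clusters
}

empty_cluster_tibble <- function() {
  tibble(cluster_id = character(), members = list(), size = integer(),
         inferred_only = logical(), n_cells = integer(), signature = character())
}

#' Classify the ontological cause of an isomorphic cluster
#'
#' Decision cascade, first test that fires wins:
#' 1. `presence_equivalence` — every member pair carries identical
#'    presence/absence information ([presence_class_equivalent()]; `variant`
#'    selects the strict both-closure test or the presence-only variant).
#' 2. `co_assertion` — every member is supported by exactly the same published
#'    states, and those states annotate two or more of the cluster's entities
#'    (one state producing several EQ annotations, e.g. "pedal digits 6, 7,
#'    and 8 present").
#' 3. `part_containment` — the members form a chain under the reasoning
#'    closure (each pair ordered by part/subclass/precursor reachability) and
#'    all supports on each side trace to annotations targeting a single
#'    member.
#' 4. `inference_chain` — residual: identical columns produced by unrelated
#'    chains of inference from multiple entities.
#'
#' @param members Character vector of cluster member term ids.
#' @param m The `synthetic_matrix` the cluster was found in.
#' @param anatomy The anatomy `ontology`.
#' @param variant Equivalence variant passed to [presence_class_equivalent()].
#' @return One of the four cause labels.
#' @export
classify_cluster <- function(members, m, anatomy, variant = c("both", "presence")) {
  variant <- arg_match(variant)
  pairs <- utils::combn(members, 2, simplify = FALSE)
  if (all(vapply(pairs, function(p) {
    presence_class_equivalent(anatomy, p[[1]], p[[2]], variant = variant)
  }, logical(1)))) {
    return("presence_equivalence")
  }
  sup <- m$supports[m$supports$entity %in% members, ]
  if (is_co_assertion(sup, members)) return("co_assertion")
  if (is_containment_chain(sup, members, anatomy)) return("part_containment")
  "inference_chain"
}

# every member supported by the same (taxon, source, character, state) keys,
# and the shared states directly annotate >= 2 distinct cluster members
is_co_assertion <- function(sup, members) {
  keysets <- lapply(members, function(e) {
    s <- sup[sup$entity == e, ]
    sort(unique(paste(s$taxon, s$matrix_id, s$char_id, s$state_id)))
  })
  if (any(vapply(keysets, length, integer(1)) == 0)) return(FALSE)
  if (!all(vapply(keysets, identical, logical(1), y = keysets[[1]]))) return(FALSE)
  targets_per_state <- sup %>%
    filter(.data$phen_target %in% members) %>%
    distinct(.data$matrix_id, .data$char_id, .data$state_id, .data$phen_target) %>%
    count(.data$matrix_id, .data$char_id, .data$state_id)
  nrow(targets_per_state) > 0 && all(targets_per_state$n >= 2)
}

# members totally ordered by mixed-relation reachability, with each side's
# member-targeting supports tracing to a single member.  Supports whose
# phenotype targets an entity outside the cluster (say, an asserted absence of
# a structure the whole chain is part of) propagate into every member column
# alike and are not diagnostic of the cluster's cause, so they are ignored
# by the single-member test.
is_containment_chain <- function(sup, members, anatomy) {
  ups <- lapply(members, function(e) upward_closure(anatomy, e))
  names(ups) <- members
  pairs <- utils::combn(members, 2, simplify = FALSE)
  chain <- all(vapply(pairs, function(p) {
    p[[2]] %in% ups[[p[[1]]]] || p[[1]] %in% ups[[p[[2]]]]
  }, logical(1)))
  if (!chain) return(FALSE)
  member_sup <- sup[sup$phen_target %in% members, ]
  if (nrow(member_sup) == 0) return(FALSE)
  one_target <- function(side) {
    tg <- unique(member_sup$phen_target[member_sup$value == side])
    length(tg) <= 1
  }
  one_target("present") && one_target("absent")
}

#' Per-cluster report with cause classification
#'
#' @param clusters Output of [find_isomorphic_clusters()].
#' @param m The `synthetic_matrix` the clusters came from.
#' @param anatomy The anatomy `ontology` (needed for cause classification).
#' @param variant Equivalence variant (see [classify_cluster()]).
#' @return A tibble with one row per cluster (`cluster_id`, `members` as a
#'   comma-separated string, `size`, `cause`, `inferred_only`, `n_cells`) and
#'   attributes `summary` (clusters by cause) and `total_cells`.
#' @export
cluster_report <- function(clusters, m, anatomy, variant = c("both", "presence")) {
  variant <- arg_match(variant)
  if (nrow(clusters) == 0) {
    out <- tibble(cluster_id = character(), members = character(), size = integer(),
                  cause = character(), inferred_only = logical(), n_cells = integer())
    attr(out, "summary") <- tibble(cause = character(), n = integer())
    attr(out, "total_cells") <- 0L
    return(out)
  }
  out <- clusters %>%
    mutate(cause = purrr::map_chr(.data$members, classify_cluster, m = m,
                                  anatomy = anatomy, variant = variant),
           members = purrr::map_chr(.data$members, paste, collapse = ",")) %>%
    select("cluster_id", "members", "size", "cause", "inferred_only", "n_cells")
  attr(out, "summary") <- count(out, .data$cause)
  attr(out, "total_cells") <- sum(out$n_cells)
  out
}
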