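# Independent oracles used across the suite.  These deliberately avoid the
# package's BFS traversals: reachability is computed by boolean matrix powers
# (all paths up to length |terms|), and synthesis by a naive loop over every
# (source, cell, state, phenotype, entity) combination.

# reflexive-transitive reachability over the chosen relations;
# R[x, y] is TRUE iff a directed path x -> y exists (subject-to-object).
oracle_reach <- function(o, relations = c("is_a", "part_of", "develops_from")) {
  ids <- o$terms$id
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  e <- o$edges[o$edges$relation %in% relations, ]
  if (nrow(e) > 0) A[cbind(match(e$subject, ids), match(e$object, ids))] <- TRUE
  R <- diag(n) > 0
  repeat {
    R2 <- R | (R %*% A > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  dimnames(R) <- list(ids, ids)
  R
}

oracle_up <- function(o, term, relations = c("is_a", "part_of", "develops_from")) {
  R <- oracle_reach(o, relations)
  sort(colnames(R)[R[term, ]])
}

oracle_down <- function(o, term, relations = c("is_a", "part_of", "develops_from")) {
  R <- oracle_reach(o, relations)
  sort(rownames(R)[R[, term]])
}

# terms satisfying `rel some (filler_set)`: a chain of is_a/rel edges with at
# least one rel edge ending in the filler set
oracle_some <- function(o, rel, filler_set) {
  ids <- o$terms$id
  n <- length(ids)
  R <- oracle_reach(o, c("is_a", rel))
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  e <- o$edges[o$edges$relation == rel, ]
  if (nrow(e) > 0) A[cbind(match(e$subject, ids), match(e$object, ids))] <- TRUE
  Q <- (R %*% A %*% R) > 0
  f <- intersect(filler_set, ids)
  if (length(f) == 0) return(character())
  sort(ids[rowSums(Q[, f, drop = FALSE]) > 0])
}

# naive synthesis: enumerate every assigned state's phenotypes against every
# candidate entity, then reduce to cell values
oracle_synthesis_cells <- function(anatomy, sources, characters, taxa) {
  R <- oracle_reach(anatomy)
  rows <- list()
  for (m in sources) {
    ph <- m$phenotypes
    for (i in seq_len(nrow(m$cells))) {
      t <- m$cells$taxon[[i]]
      if (!t %in% taxa) next
      p <- ph[ph$char_id == m$cells$char_id[[i]] & ph$state_id == m$cells$state_id[[i]], ]
      for (k in seq_len(nrow(p))) {
        absent_q <- p$quality[[k]] %in% c("PATO:0000462", "PATO:0002000")
        target <- if (absent_q && !is.na(p$related_entity[[k]])) {
          p$related_entity[[k]]
        } else p$entity[[k]]
        for (e in characters) {
          hit <- if (absent_q) R[e, target] else R[target, e]
          if (hit) {
            rows[[length(rows) + 1]] <- data.frame(
              taxon = t, entity = e,
              value = if (absent_q) "absent" else "present"
            )
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(taxon = character(), entity = character(), value = character()))
  }
  sup <- unique(do.call(rbind, rows))
  agg <- aggregate(value ~ taxon + entity, sup, function(v) {
    if (length(unique(v)) == 2) "BOTH" else if (v[[1]] == "present") "PRESENT" else "ABSENT"
  })
  agg <- agg[order(agg$taxon, agg$entity), ]
  rownames(agg) <- NULL
  agg
}

# a tiny seeded config used where scale does not matter
tiny_config <- function(seed, ...) {
  fixture_config(seed = seed, n_anatomy_terms = 18L, n_taxa = 8L, n_sources = 2L,
                 n_layers = 3L,
                 conflicts = c(asserted_asserted = 0L, asserted_inferred = 0L,
                               inferred_inferred = 0L, intra_source_polymorphism = 0L),
                 ...)
}

# random DAG ontology without motif terms, for pure graph-theory tests
random_dag_ontology <- function(seed, n = 40L) {
  cfg <- fixture_config(seed = seed, n_anatomy_terms = n, n_taxa = 2L,
                        n_sources = 0L, n_layers = 4L,
                        conflicts = c(asserted_asserted = 0L),
                        n_equiv_pairs = 0L, n_containment_chains = 0L,
                        n_coassert_groups = 0L)
  generate_ontology(cfg)
}

expect_same_sets <- function(a, b) {
  testthat::expect_identical(sort(unique(a)), sort(unique(b)))
}

demo_dir <- function() {
  system.file("extdata", "demo", package = "phenosynth")
}
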