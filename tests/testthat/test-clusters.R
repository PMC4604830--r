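test_that("a part annotated alone drags its whole into one isomorphic cluster", {
  anatomy <- ontology(
    tibble::tibble(id = c("TOY:part", "TOY:whole", "TOY:other"),
                   label = c("part", "whole", "other")),
    tibble::tibble(subject = "TOY:part", relation = "part_of", object = "TOY:whole")
  )
  taxonomy <- ontology(
    tibble::tibble(id = c("TAXON:root", "TAXON:a", "TAXON:b"),
                   label = c("root", "a", "b"), rank = c("clade", "species", "species")),
    tibble::tibble(subject = c("TAXON:a", "TAXON:b"), relation = "is_a",
                   object = "TAXON:root"),
    namespace = "taxonomy"
  )
  src <- source_matrix(
    "STUDY:s", "", taxa = c("TAXON:a", "TAXON:b"),
    characters = tibble::tibble(char_id = c("c1", "c2"), label = c("part", "other")),
    states = tibble::tibble(char_id = c("c1", "c1", "c2"),
                            state_id = c("s1", "s2", "s1"),
                            label = c("part present", "whole absent", "other present")),
    phenotypes = tibble::tibble(char_id = c("c1", "c1", "c2"),
                                state_id = c("s1", "s2", "s1"),
                                entity = c("TOY:part", "TOY:whole", "TOY:other"),
                                quality = c("PATO:0000467", "PATO:0000462", "PATO:0000467"),
                                related_entity = NA_character_),
    cells = tibble::tibble(taxon = c("TAXON:a", "TAXON:b", "TAXON:a"),
                           char_id = c("c1", "c1", "c2"),
                           state_id = c("s1", "s2", "s1"))
  )
  m <- synthesize(anatomy, taxonomy, list(src),
                  entity_expr = "TOY:part or TOY:whole or TOY:other",
                  taxon_expr = "TAXON:root")
  cl <- find_isomorphic_clusters(m)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$members[[1]], c("TOY:part", "TOY:whole"))
  expect_false(cl$inferred_only[[1]])
  rep <- cluster_report(cl, m, anatomy)
  expect_identical(rep$cause, "part_containment")
})

test_that("all-distinct columns give no clusters", {
  fx <- suppressMessages(generate_fixture_set("toy"))
  m <- synthesize(fx$anatomy, fx$taxonomy, fx$sources,
                  entity_expr = "TOY:entepicondyle", taxon_expr = "TAXON:root")
  expect_identical(nrow(find_isomorphic_clusters(m)), 0L)
  rep <- cluster_report(find_isomorphic_clusters(m), m, fx$anatomy)
  expect_identical(nrow(rep), 0L)
})

test_that("clusters match the all-pairs column-comparison oracle", {
  for (seed in c(101, 102)) {
    fx <- suppressMessages(generate_fixture_set(tiny_config(
      seed, n_equiv_pairs = 1L, n_containment_chains = 1L, n_coassert_groups = 1L)))
    m <- synthesize(fx$anatomy, fx$taxonomy, fx$sources, fx$entity_expr, fx$taxon_expr)
    cl <- find_isomorphic_clusters(m)
    # oracle: build full columns from the cells table and compare all pairs
    col_of <- function(e) {
      v <- setNames(rep("MISSING", length(m$taxa)), m$taxa)
      sel <- m$cells[m$cells$entity == e, ]
      v[sel$taxon] <- sel$value
      paste(v, collapse = ";")
    }
    cols <- vapply(m$characters, col_of, character(1))
    oracle_groups <- split(names(cols), cols)
    oracle_clusters <- sort(vapply(
      Filter(function(g) length(g) >= 2, oracle_groups),
      function(g) paste(sort(g), collapse = ","), character(1)
    ))
    got <- sort(vapply(cl$members, paste, character(1), collapse = ","))
    expect_identical(unname(got), unname(oracle_clusters))
  }
})

test_that("cluster causes classify by the ontological cascade", {
  fx <- suppressMessages(generate_fixture_set(fixture_preset("small", seed = 7)))
  m <- synthesize(fx$anatomy, fx$taxonomy, fx$sources, fx$entity_expr, fx$taxon_expr)
  v <- variable_subset(m)
  rep <- cluster_report(find_isomorphic_clusters(v), v, fx$anatomy)
  motifs <- fx$ledger$cluster_motifs
  cause_of <- function(members) rep$cause[rep$members == paste(members, collapse = ",")]
  expect_identical(cause_of(sort(motifs$equiv_pairs[[1]])), "presence_equivalence")
  expect_identical(cause_of(sort(motifs$chains[[1]])), "part_containment")
  expect_identical(cause_of(sort(motifs$coassert[[1]])), "co_assertion")
})

test_that("coincidentally identical columns fall through to inference_chain", {
  anatomy <- ontology(c("TOY:u", "TOY:v"))   # unrelated terms
  taxonomy <- ontology(
    tibble::tibble(id = c("TAXON:root", "TAXON:a"), label = c("root", "a"),
                   rank = c("clade", "species")),
    tibble::tibble(subject = "TAXON:a", relation = "is_a", object = "TAXON:root"),
    namespace = "taxonomy"
  )
  src <- source_matrix(
    "STUDY:s", "", taxa = "TAXON:a",
    characters = tibble::tibble(char_id = c("c1", "c2"), label = c("u", "v")),
    states = tibble::tibble(char_id = c("c1", "c2"), state_id = "s1",
                            label = c("u present", "v present")),
    phenotypes = tibble::tibble(char_id = c("c1", "c2"), state_id = "s1",
                                entity = c("TOY:u", "TOY:v"),
                                quality = "PATO:0000467",
                                related_entity = NA_character_),
    cells = tibble::tibble(taxon = "TAXON:a", char_id = c("c1", "c2"), state_id = "s1")
  )
  m <- synthesize(anatomy, taxonomy, list(src),
                  entity_expr = "TOY:u or TOY:v", taxon_expr = "TAXON:root")
  rep <- cluster_report(find_isomorphic_clusters(m), m, anatomy)
  expect_identical(rep$cause, "inference_chain")
})

test_that("equivalent pairs are always isomorphic and report totals add up", {
  for (seed in 111:113) {
    fx <- suppressMessages(generate_fixture_set(tiny_config(seed, n_equiv_pairs = 2L)))
    m <- synthesize(fx$anatomy, fx$taxonomy, fx$sources, fx$entity_expr, fx$taxon_expr)
    cl <- find_isomorphic_clusters(m)
    membership <- setNames(rep(NA_integer_, length(m$characters)), m$characters)
    for (i in seq_len(nrow(cl))) membership[cl$members[[i]]] <- i
    for (pair in fx$ledger$cluster_motifs$equiv_pairs) {
      if (all(pair %in% m$characters) &&
          any(paste(m$supports$entity) %in% pair)) {
        expect_true(presence_class_equivalent(fx$anatomy, pair[[1]], pair[[2]]))
        expect_identical(membership[[pair[[1]]]], membership[[pair[[2]]]])
        expect_false(is.na(membership[[pair[[1]]]]))
      }
    }
    rep <- cluster_report(cl, m, fx$anatomy)
    expect_identical(attr(rep, "total_cells"), sum(rep$n_cells))
    expect_identical(sum(attr(rep, "summary")$n), nrow(rep))
  }
})
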