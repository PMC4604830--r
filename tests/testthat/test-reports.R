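test_that("missing-data statistics partition the populated cells", {
  fx <- suppressMessages(generate_fixture_set(tiny_config(121)))
  m <- synthesize(fx$anatomy, fx$taxonomy, fx$sources, fx$entity_expr, fx$taxon_expr)
  st <- missing_data_stats(m)
  expect_identical(st$n_populated, st$n_asserted_cells + st$n_inferred_only_cells)
  expect_identical(st$n_cells, st$n_characters * st$n_taxa)
  expect_gte(st$frac_missing_with_inference, 0)
  expect_lte(st$frac_missing_with_inference, 1)
  # brute-force recount from the supports table
  pop <- unique(paste(m$supports$taxon, m$supports$entity))
  ass <- unique(paste(m$supports$taxon, m$supports$entity)[m$supports$mode == "asserted"])
  expect_identical(st$n_populated, length(pop))
  expect_identical(st$n_asserted_cells, length(ass))
  expect_equal(st$frac_missing_with_inference, 1 - length(pop) / st$n_cells)
})

test_that("empty matrices report fully missing data", {
  st2 <- two_study_setup()
  m <- synthesize(st2$anatomy, st2$taxonomy, list(),
                  entity_expr = "TOY:scapula", taxon_expr = "TAXON:root")
  st <- missing_data_stats(m)
  expect_identical(st$n_cells, 0L)
  expect_identical(st$frac_missing_with_inference, 1)
  expect_identical(st$frac_missing_asserted_only, 1)
})

test_that("entailing-state counts follow the entailment closure on the toy ontology", {
  o <- toy_fin_limb_ontology()
  taxonomy <- ontology(
    tibble::tibble(id = c("TAXON:root", "TAXON:a", "TAXON:b"),
                   label = c("root", "a", "b"), rank = c("clade", "species", "species")),
    tibble::tibble(subject = c("TAXON:a", "TAXON:b"), relation = "is_a",
                   object = "TAXON:root"),
    namespace = "taxonomy"
  )
  # one absence assertion on the whole increments all its parts' columns
  src <- source_matrix(
    "STUDY:s", "", taxa = "TAXON:a",
    characters = tibble::tibble(char_id = "c1", label = "forelimb"),
    states = tibble::tibble(char_id = "c1", state_id = "s1", label = "forelimb absent"),
    phenotypes = tibble::tibble(char_id = "c1", state_id = "s1",
                                entity = "TOY:forelimb", quality = "PATO:0000462",
                                related_entity = NA_character_),
    cells = tibble::tibble(taxon = "TAXON:a", char_id = "c1", state_id = "s1")
  )
  entities <- c("TOY:forelimb", "TOY:forelimb-skeleton", "TOY:humerus",
                "TOY:entepicondyle", "TOY:forelimb-bud")
  counts <- entailing_state_counts(list(src), o, entities, c("TAXON:a", "TAXON:b"))
  got <- counts$n_states[counts$taxon == "TAXON:a"]
  names(got) <- counts$entity[counts$taxon == "TAXON:a"]
  expect_identical(got[["TOY:forelimb"]], 1L)
  expect_identical(got[["TOY:humerus"]], 1L)
  expect_identical(got[["TOY:entepicondyle"]], 1L)
  expect_identical(got[["TOY:forelimb-bud"]], 0L)  # absence does not climb
  # a taxon with no data is an explicit zero row
  expect_true(all(counts$n_states[counts$taxon == "TAXON:b"] == 0L))
})

test_that("entailing-state counts equal naive triple enumeration on fixtures", {
  fx <- suppressMessages(generate_fixture_set(tiny_config(122)))
  entities <- sort(sample(attr(fx$anatomy, "fixture_info")$base_terms, 8))
  taxa <- fx$taxonomy$terms$id[fx$taxonomy$terms$rank == "species"]
  counts <- entailing_state_counts(fx$sources, fx$anatomy, entities, taxa)
  R <- oracle_reach(fx$anatomy)
  for (i in sample(nrow(counts), 40)) {
    t <- counts$taxon[[i]]; e <- counts$entity[[i]]
    n <- 0L
    for (m in fx$sources) {
      cells <- m$cells[m$cells$taxon == t, ]
      for (j in seq_len(nrow(cells))) {
        ph <- m$phenotypes[m$phenotypes$char_id == cells$char_id[[j]] &
                             m$phenotypes$state_id == cells$state_id[[j]], ]
        hit <- FALSE
        for (k in seq_len(nrow(ph))) {
          absent_q <- ph$quality[[k]] %in% c("PATO:0000462", "PATO:0002000")
          target <- if (absent_q && !is.na(ph$related_entity[[k]])) {
            ph$related_entity[[k]]
          } else ph$entity[[k]]
          if (if (absent_q) R[e, target] else R[target, e]) hit <- TRUE
        }
        if (hit) n <- n + 1L
      }
    }
    expect_identical(counts$n_states[[i]], n)
  }
})

test_that("counts never decrease when inference is enabled", {
  fx <- suppressMessages(generate_fixture_set(tiny_config(123)))
  m_full <- synthesize(fx$anatomy, fx$taxonomy, fx$sources, fx$entity_expr, fx$taxon_expr)
  m_ass <- synthesize(fx$anatomy, fx$taxonomy, fx$sources, fx$entity_expr,
                      fx$taxon_expr, inference = FALSE)
  expect_gte(missing_data_stats(m_full)$n_populated,
             missing_data_stats(m_ass)$n_populated)
})

test_that("taxon source counts are per-publication, not per-state", {
  st <- two_study_setup()
  counts <- taxon_source_counts(st$sources, st$taxonomy, "TAXON:root")
  expect_identical(counts$n_matrices[counts$taxon == "TAXON:a"], 1L)
  expect_identical(counts$n_matrices[counts$taxon == "TAXON:b"], 2L)
  expect_identical(counts$rank, c("species", "species"))
  # duplicating a state assignment within one source changes nothing
  dup <- st$sources[[1]]
  dup$cells <- rbind(dup$cells, dup$cells[1, ])
  counts2 <- taxon_source_counts(c(list(dup), st$sources[-1]), st$taxonomy, "TAXON:root")
  expect_identical(counts2$n_matrices, counts$n_matrices)
})

test_that("reports are pure functions of their inputs", {
  fx <- suppressMessages(generate_fixture_set(tiny_config(124)))
  m <- synthesize(fx$anatomy, fx$taxonomy, fx$sources, fx$entity_expr, fx$taxon_expr)
  expect_identical(missing_data_stats(m), missing_data_stats(m))
  expect_identical(taxon_source_counts(fx$sources, fx$taxonomy, "TAXON:root"),
                   taxon_source_counts(fx$sources, fx$taxonomy, "TAXON:root"))
})
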