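# helper: one-character sources that stamp a chosen (quality, value) onto a
# shared leaf entity for one taxon
stamp_source <- function(id, taxon, quality, state_label, related = NA_character_) {
  entity <- if (!is.na(related)) "TOY:organism" else "TOY:leaf"
  source_matrix(
    id, paste("study", id), taxa = taxon,
    characters = tibble::tibble(char_id = "c1", label = "leaf character"),
    states = tibble::tibble(char_id = "c1", state_id = "s1", label = state_label),
    phenotypes = tibble::tibble(char_id = "c1", state_id = "s1", entity = entity,
                                quality = quality, related_entity = related),
    cells = tibble::tibble(taxon = taxon, char_id = "c1", state_id = "s1")
  )
}

conflict_anatomy <- function() {
  ontology(tibble::tibble(id = c("TOY:leaf", "TOY:whole", "TOY:organism"),
                          label = c("leaf", "whole", "organism")),
           tibble::tibble(subject = "TOY:leaf", relation = "part_of",
                          object = "TOY:whole"))
}

conflict_taxonomy <- function() {
  ontology(tibble::tibble(id = c("TAXON:root", "TAXON:a"), label = c("root", "a"),
                          rank = c("clade", "species")),
           tibble::tibble(subject = "TAXON:a", relation = "is_a", object = "TAXON:root"),
           namespace = "taxonomy")
}

synth_conflict <- function(sources) {
  synthesize(conflict_anatomy(), conflict_taxonomy(), sources,
             entity_expr = "TOY:leaf or TOY:whole", taxon_expr = "TAXON:root")
}

test_that("cross-source direct assertions classify as asserted_asserted", {
  m <- synth_conflict(list(
    stamp_source("STUDY:p", "TAXON:a", "PATO:0000467", "present"),
    stamp_source("STUDY:a", "TAXON:a", "PATO:0000462", "absent")
  ))
  co <- detect_conflicts(m)
  expect_identical(nrow(co), 1L)
  expect_identical(co$category, "asserted_asserted")
  expect_false(co$excluded)
})

test_that("a single source asserting both values is polymorphism and is excluded", {
  both <- source_matrix(
    "STUDY:one", "study", taxa = "TAXON:a",
    characters = tibble::tibble(char_id = "c1", label = "leaf"),
    states = tibble::tibble(char_id = "c1", state_id = c("s1", "s2"),
                            label = c("present", "absent")),
    phenotypes = tibble::tibble(char_id = "c1", state_id = c("s1", "s2"),
                                entity = "TOY:leaf",
                                quality = c("PATO:0000467", "PATO:0000462"),
                                related_entity = NA_character_),
    cells = tibble::tibble(taxon = "TAXON:a", char_id = "c1", state_id = c("s1", "s2"))
  )
  # plus a conflicting assertion from elsewhere: polymorphism takes precedence
  m <- synth_conflict(list(both, stamp_source("STUDY:x", "TAXON:a", "PATO:0000462", "absent")))
  co <- detect_conflicts(m)
  expect_identical(co$category[co$entity == "TOY:leaf"], "intra_source_polymorphism")
  expect_true(all(co$excluded[co$entity == "TOY:leaf"]))
})

test_that("inference on one or both sides classifies per the evidence cascade", {
  # shape quality => inferred presence; direct absence elsewhere
  m <- synth_conflict(list(
    stamp_source("STUDY:shape", "TAXON:a", "PATO:0000052", "oddly shaped"),
    stamp_source("STUDY:abs", "TAXON:a", "PATO:0000462", "absent")
  ))
  co <- detect_conflicts(m)
  expect_identical(co$category[co$entity == "TOY:leaf"], "asserted_inferred")
  # lacks-all-parts pattern => inferred absence; both sides inferred
  m2 <- synth_conflict(list(
    stamp_source("STUDY:shape", "TAXON:a", "PATO:0000052", "oddly shaped"),
    stamp_source("STUDY:lacks", "TAXON:a", "PATO:0002000", "lacks leaf",
                 related = "TOY:leaf")
  ))
  co2 <- detect_conflicts(m2)
  expect_identical(co2$category[co2$entity == "TOY:leaf"], "inferred_inferred")
})

test_that("conflict records partition the BOTH cells", {
  fx <- suppressMessages(generate_fixture_set(fixture_preset("small", seed = 91)))
  m <- synthesize(fx$anatomy, fx$taxonomy, fx$sources, fx$entity_expr, fx$taxon_expr)
  co <- detect_conflicts(m)
  expect_identical(nrow(co), sum(m$cells$value == "BOTH"))
  expect_identical(anyDuplicated(paste(co$taxon, co$entity)), 0L)
  expect_true(all(co$category %in% c("asserted_asserted", "asserted_inferred",
                                     "inferred_inferred", "intra_source_polymorphism")))
  # category counts recover the injection ledger exactly
  led <- fx$ledger$conflict_sites
  got <- co[order(co$taxon, co$entity), c("taxon", "entity", "category")]
  expect_equal(as.data.frame(got), as.data.frame(led), ignore_attr = TRUE)
})

test_that("removing one side of a conflict yields a single-valued cell", {
  fx <- suppressMessages(generate_fixture_set(fixture_preset("small", seed = 92)))
  m <- synthesize(fx$anatomy, fx$taxonomy, fx$sources, fx$entity_expr, fx$taxon_expr)
  co <- detect_conflicts(m)
  for (i in seq_len(nrow(co))) {
    sup <- m$supports[m$supports$taxon == co$taxon[[i]] &
                        m$supports$entity == co$entity[[i]], ]
    one_side <- phenosynth:::cell_values_from_supports(sup[sup$value == "present", ])
    expect_identical(one_side$value, "PRESENT")
  }
})

test_that("the conflict report is empty for conflict-free matrices and complete otherwise", {
  clean <- synth_conflict(list(stamp_source("STUDY:p", "TAXON:a", "PATO:0000467", "present")))
  rep0 <- conflict_report(detect_conflicts(clean), clean)
  expect_identical(nrow(rep0), 0L)
  m <- synth_conflict(list(
    stamp_source("STUDY:p", "TAXON:a", "PATO:0000467", "present"),
    stamp_source("STUDY:a", "TAXON:a", "PATO:0000462", "absent")
  ))
  co <- detect_conflicts(m)
  rep <- conflict_report(co, m)
  expect_setequal(rep$side, c("presence", "absence"))
  expect_identical(nrow(rep), co$n_presence_supports + co$n_absence_supports)
})
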