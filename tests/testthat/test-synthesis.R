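test_that("character generation evaluates and sorts the entity expression", {
  o <- toy_fin_limb_ontology()
  expect_identical(generate_characters(o, "part_of some (TOY:forelimb)"),
                   c("TOY:entepicondyle", "TOY:forelimb-skeleton", "TOY:humerus"))
  expect_identical(generate_characters(o, "TOY:entepicondyle"), "TOY:entepicondyle")
  expect_warning(
    generate_characters(o, "connected_to some (TOY:forelimb)"),
    "no anatomy class"
  )
})

test_that("taxon selection respects both the data and the clade", {
  st <- two_study_setup()
  expect_identical(select_taxa(st$taxonomy, "TAXON:root", st$sources),
                   c("TAXON:a", "TAXON:b"))
  # genus selects only its species with data
  expect_identical(select_taxa(st$taxonomy, "TAXON:g1", st$sources),
                   c("TAXON:a", "TAXON:b"))
  outside <- ontology(
    tibble::tibble(id = c("TAXON:root", "TAXON:other", "TAXON:a", "TAXON:b"),
                   label = c("r", "o", "a", "b"),
                   rank = c("clade", "clade", "species", "species")),
    tibble::tibble(subject = c("TAXON:other", "TAXON:a", "TAXON:b"),
                   relation = "is_a",
                   object = c("TAXON:root", "TAXON:other", "TAXON:root")),
    namespace = "taxonomy"
  )
  # a richly annotated taxon outside the clade is excluded
  expect_identical(select_taxa(outside, "TAXON:other", st$sources), "TAXON:a")
})

test_that("a shape quality on a part populates the whole by inference alone", {
  st <- two_study_setup()
  m <- synthesize(st$anatomy, st$taxonomy, st$sources,
                  entity_expr = "TOY:scapula or TOY:blade or TOY:girdle",
                  taxon_expr = "TAXON:root")
  cells <- tidy(m)
  a_scap <- cells[cells$taxon == "TAXON:a" & cells$entity == "TOY:scapula", ]
  expect_identical(a_scap$value, "PRESENT")
  expect_identical(a_scap$n_asserted, 0L)
  expect_gt(a_scap$n_inferred, 0L)
  # the direct assertion on the exact entity is flagged asserted
  b_scap <- m$supports[m$supports$taxon == "TAXON:b" & m$supports$entity == "TOY:scapula" &
                         m$supports$matrix_id == "STUDY:direct", ]
  expect_identical(unique(b_scap$mode), "asserted")
  # absence of the part says nothing about the whole
  b_cells <- cells[cells$taxon == "TAXON:b" & cells$entity == "TOY:scapula", ]
  expect_identical(b_cells$value, "PRESENT")
  # but the girdle above is populated purely by inference
  expect_identical(cells$value[cells$taxon == "TAXON:a" & cells$entity == "TOY:girdle"],
                   "PRESENT")
})

test_that("an empty source list yields an empty matrix", {
  st <- two_study_setup()
  m <- synthesize(st$anatomy, st$taxonomy, list(),
                  entity_expr = "TOY:scapula", taxon_expr = "TAXON:root")
  expect_length(m$characters, 0)
  expect_length(m$taxa, 0)
  expect_identical(nrow(m$cells), 0L)
})

test_that("synthesized cells equal the naive enumeration oracle on fixtures", {
  for (seed in c(81, 82)) {
    fx <- suppressMessages(generate_fixture_set(tiny_config(seed)))
    m <- synthesize(fx$anatomy, fx$taxonomy, fx$sources, fx$entity_expr, fx$taxon_expr,
                    prune = "none")
    want <- oracle_synthesis_cells(
      fx$anatomy, fx$sources,
      characters = generate_characters(fx$anatomy, fx$entity_expr),
      taxa = select_taxa(fx$taxonomy, fx$taxon_expr, fx$sources)
    )
    got <- as.data.frame(m$cells)
    rownames(got) <- NULL
    expect_equal(got, want)
  }
})

test_that("every support replays through entails()", {
  fx <- suppressMessages(generate_fixture_set(tiny_config(83)))
  m <- synthesize(fx$anatomy, fx$taxonomy, fx$sources, fx$entity_expr, fx$taxon_expr)
  sup <- m$supports
  for (i in seq_len(nrow(sup))) {
    p <- eq_phenotype(sup$phen_entity[[i]], sup$quality[[i]], sup$related_entity[[i]])
    v <- entails(fx$anatomy, p, sup$entity[[i]])
    expect_identical(tolower(v$value), sup$value[[i]])
  }
})

test_that("the variable subset keeps exactly the two-valued columns with the right basis", {
  st <- two_study_setup()
  m <- synthesize(st$anatomy, st$taxonomy, st$sources,
                  entity_expr = "TOY:scapula or TOY:blade or TOY:girdle",
                  taxon_expr = "TAXON:root")
  v <- variable_subset(m)
  # blade: asserted absent (study 1, taxon b) + inferred-by-shape present
  expect_identical(v$characters, "TOY:blade")
  expect_identical(v$variability$basis, "variable_only_by_inference")
  # all-PRESENT columns (scapula, girdle) were dropped
  expect_false("TOY:scapula" %in% v$characters)
  # column-scan oracle on a fixture
  fx <- suppressMessages(generate_fixture_set(tiny_config(84)))
  mf <- synthesize(fx$anatomy, fx$taxonomy, fx$sources, fx$entity_expr, fx$taxon_expr)
  vf <- variable_subset(mf)
  per_col <- split(mf$cells$value, mf$cells$entity)
  want <- sort(names(per_col)[vapply(per_col, function(vv) {
    any(vv %in% c("PRESENT", "BOTH")) && any(vv %in% c("ABSENT", "BOTH"))
  }, logical(1))])
  expect_identical(vf$characters, want)
  # no all-missing taxon rows survive
  expect_true(all(vf$taxa %in% unique(vf$cells$taxon)))
})

test_that("inferred-only characters are labelled as such in the variable subset", {
  fx <- suppressMessages(generate_fixture_set(tiny_config(85, shape_quality_rate = 1)))
  m <- synthesize(fx$anatomy, fx$taxonomy, fx$sources, fx$entity_expr, fx$taxon_expr)
  v <- variable_subset(m)
  sup_by_char <- split(v$supports$mode, v$supports$entity)
  for (i in seq_len(nrow(v$variability))) {
    e <- v$variability$entity[[i]]
    if (!any(sup_by_char[[e]] == "asserted")) {
      expect_identical(v$variability$basis[[i]], "inferred_only")
    }
  }
})

test_that("disabling inference populates a subset of the full run's cells", {
  fx <- suppressMessages(generate_fixture_set(tiny_config(86)))
  full <- synthesize(fx$anatomy, fx$taxonomy, fx$sources, fx$entity_expr, fx$taxon_expr)
  asserted <- synthesize(fx$anatomy, fx$taxonomy, fx$sources, fx$entity_expr,
                         fx$taxon_expr, inference = FALSE)
  key_full <- paste(full$cells$taxon, full$cells$entity)
  key_ass <- paste(asserted$cells$taxon, asserted$cells$entity)
  expect_true(all(key_ass %in% key_full))
  expect_lte(nrow(asserted$cells), nrow(full$cells))
})

test_that("identical inputs serialize byte-identically", {
  f1 <- withr::local_tempfile(fileext = ".xml")
  f2 <- withr::local_tempfile(fileext = ".xml")
  for (f in c(f1, f2)) {
    fx <- suppressMessages(generate_fixture_set(tiny_config(87)))
    m <- synthesize(fx$anatomy, fx$taxonomy, fx$sources, fx$entity_expr, fx$taxon_expr)
    write_nexml(m, f)
  }
  expect_identical(readLines(f1), readLines(f2))
})

test_that("annotations naming unknown terms are a hard error listing offenders", {
  st <- two_study_setup()
  bad <- suppressMessages(source_matrix(
    "STUDY:bad", "", taxa = "TAXON:a",
    characters = tibble::tibble(char_id = "c1", label = "x"),
    states = tibble::tibble(char_id = "c1", state_id = "s1", label = "y"),
    phenotypes = tibble::tibble(char_id = "c1", state_id = "s1",
                                entity = "TOY:nonexistent", quality = "PATO:0000467",
                                related_entity = NA_character_),
    cells = tibble::tibble(taxon = "TAXON:a", char_id = "c1", state_id = "s1")
  ))
  expect_error(
    synthesize(st$anatomy, st$taxonomy, list(bad),
               entity_expr = "TOY:scapula", taxon_expr = "TAXON:root"),
    "TOY:nonexistent"
  )
})
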