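#' The five-term fin-to-limb toy ontology
#'
#' Entepicondyle part_of humerus part_of forelimb skeleton part_of forelimb;
#' forelimb develops_from forelimb bud.  The smallest ontology on which all
#' qualitative presence/absence entailments can be demonstrated: presence of
#' the humerus entails presence of the forelimb skeleton, forelimb, and
#' forelimb bud; absence of the forelimb bud entails absence of everything
#' downstream; absence of the humerus entails absence of the entepicondyle
#' but says nothing about the forelimb.
#'
#' @return An anatomy `ontology` with five `TOY:` terms.
#' @export
toy_fin_limb_ontology <- function() {
  ontology(
    tibble(id = c("TOY:entepicondyle", "TOY:humerus", "TOY:forelimb-skeleton",
                  "TOY:forelimb", "TOY:forelimb-bud"),
           label = c("entepicondyle", "humerus", "forelimb skeleton",
                     "forelimb", "forelimb bud")),
    tibble(subject = c("TOY:entepicondyle", "TOY:humerus",
                       "TOY:forelimb-skeleton", "TOY:forelimb"),
           relation = c("part_of", "part_of", "part_of", "develops_from"),
           object = c("TOY:humerus", "TOY:forelimb-skeleton",
                      "TOY:forelimb", "TOY:forelimb-bud")),
    namespace = "anatomy"
  )
}

#' Configuration for the fixture generator
#'
#' Defines the study conditions the generator emulates: a layered random
#' anatomy DAG with partonomy, subclass, and developmental edges plus
#' cluster-inducing motifs; a ranked taxonomy tree; and a set of overlapping
#' EQ-annotated study bundles with controlled annotation density, absence
#' frequency, shape-quality (inference-forcing) annotations, and injected
#' conflicts with ground-truth labels.  The same seed always yields identical
#' output.
#'
#' @param seed Integer RNG seed.
#' @param n_anatomy_terms Number of base anatomy terms (motif terms are added
#'   on top).
#' @param n_taxa Number of species in the taxonomy.
#' @param n_sources Number of study bundles.
#' @param n_layers Layers of the anatomy DAG (edges only run from lower to
#'   higher layers, so each relation is acyclic by construction).
#' @param edge_density Named probabilities of extra `is_a`, `develops_from`,
#'   and `connected_to` edges per term (each non-top term always gets one
#'   `part_of` or `is_a` parent).
#' @param annotation_rate Probability that a source scores a given (taxon,
#'   character) cell.
#' @param absence_rate Per-term probability that the latent truth is "absent"
#'   given that all wholes/superclasses/precursors are present.  Zero means
#'   no ABSENT cell can ever appear.
#' @param shape_quality_rate Probability that a presence-denoting state is
#'   annotated with a shape quality rather than "present" — such states entail
#'   presence without asserting it, exercising variable-only-by-inference
#'   characters.
#' @param conflicts Named integer vector of injected conflict counts; names
#'   from `asserted_asserted`, `asserted_inferred`, `inferred_inferred`,
#'   `intra_source_polymorphism`.
#' @param n_equiv_pairs,n_containment_chains,n_coassert_groups Cluster-inducing
#'   motifs: mutual-closure term pairs, three-term part chains annotated at
#'   one end, and sibling groups annotated by shared multi-entity states.
#' @param taxa_frac,entity_frac Fraction of species / annotatable entities
#'   each source samples.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           n_anatomy_terms = 60L,
                           n_taxa = 50L,
                           n_sources = 6L,
                           n_layers = 4L,
                           edge_density = c(is_a = 0.25, develops_from = 0.10,
                                            connected_to = 0.05),
                           annotation_rate = 0.35,
                           absence_rate = 0.15,
                           shape_quality_rate = 0.30,
                           conflicts = c(asserted_asserted = 2L,
                                         asserted_inferred = 2L,
                                         inferred_inferred = 2L,
                                         intra_source_polymorphism = 2L),
                           n_equiv_pairs = 1L,
                           n_containment_chains = 1L,
                           n_coassert_groups = 1L,
                           taxa_frac = 0.6,
                           entity_frac = 0.6) {
  probs <- c(edge_density, annotation_rate = annotation_rate,
             absence_rate = absence_rate, shape_quality_rate = shape_quality_rate,
             taxa_frac = taxa_frac, entity_frac = entity_frac)
  stopifnot(all(probs >= 0), all(probs <= 1),
            all(conflicts >= 0), n_anatomy_terms >= 1, n_taxa >= 1, n_sources >= 0)
  bad <- setdiff(names(conflicts),
                 c("asserted_asserted", "asserted_inferred",
                   "inferred_inferred", "intra_source_polymorphism"))
  if (length(bad) > 0) abort(paste0("unknown conflict categories: ", paste(bad, collapse = ", ")))
  structure(as.list(environment()), class = "fixture_config")
}

#' Named fixture presets
#'
#' `toy` is the deterministic toy fin-to-limb setup (ontology, a three-species
#' taxonomy, and one hand-built study bundle); `small` and `medium` are seeded
#' random configurations at two scales.
#'
#' @param preset One of `"toy"`, `"small"`, `"medium"`.
#' @param seed RNG seed (ignored by `toy`, which has no randomness).
#' @return For `toy`, a complete fixture set (see [generate_fixture_set()]);
#'   otherwise a `fixture_config`.
#' @export
fixture_preset <- function(preset = c("small", "medium", "toy"), seed = 1L) {
  preset <- arg_match(preset)
  switch(preset,
    toy = toy_fixture_set(),
    small = fixture_config(seed = seed, n_anatomy_terms = 25L, n_taxa = 15L,
                           n_sources = 3L, n_layers = 3L,
                           conflicts = c(asserted_asserted = 1L, asserted_inferred = 1L,
                                         inferred_inferred = 1L,
                                         intra_source_polymorphism = 1L)),
    medium = fixture_config(seed = seed)
  )
}

#' Generate a random layered anatomy ontology
#'
#' Base terms live on layers; every structural edge runs from a lower to a
#' higher layer, so each relation subgraph is acyclic by construction.  On top
#' of the base DAG the generator plants the requested cluster-inducing motifs:
#' mutual-closure pairs (x `part_of` y, y `is_a` x — the only construct that
#' makes two distinct terms carry identical presence/absence information),
#' three-term containment chains, co-assertion sibling groups, and an isolated
#' organism term used by the lacks-all-parts absence pattern.  Motif
#' membership is recorded in the `fixture_info` attribute.
#'
#' @param cfg A `fixture_config`.
#' @return An anatomy `ontology` with attribute `fixture_info`.
#' @export
generate_ontology <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  set.seed(cfg$seed)
  n <- cfg$n_anatomy_terms
  ids <- sprintf("TOY:a%03d", seq_len(n))
  n_layers <- min(cfg$n_layers, n)
  layer <- sort(rep_len(seq_len(n_layers), n))
  subj <- character(); rel <- character(); obj <- character()
  add_edge <- function(s, r, o) {
    subj <<- c(subj, s); rel <<- c(rel, r); obj <<- c(obj, o)
  }
  for (i in seq_len(n)) {
    if (layer[[i]] == n_layers) next
    higher <- ids[layer > layer[[i]]]
    add_edge(ids[[i]],
             if (stats::runif(1) < 0.8) "part_of" else "is_a",
             sample(higher, 1))
    for (r in c("is_a", "develops_from", "connected_to")) {
      if (stats::runif(1) < cfg$edge_density[[r]]) {
        add_edge(ids[[i]], r, sample(higher, 1))
      }
    }
  }
  labels <- sub("TOY:", "structure ", ids)
  extra_ids <- character(); extra_labels <- character()
  add_term <- function(id, label) {
    extra_ids <<- c(extra_ids, id); extra_labels <<- c(extra_labels, label)
  }
  attach_to <- function() sample(ids[layer >= max(1, n_layers - 1)], 1)
  equiv_pairs <- list()
  for (k in seq_len(cfg$n_equiv_pairs)) {
    a <- sprintf("TOY:eqA%02d", k); b <- sprintf("TOY:eqB%02d", k)
    add_term(a, paste("equivalence pair", k, "part"))
    add_term(b, paste("equivalence pair", k, "whole"))
    add_edge(a, "part_of", b)
    add_edge(b, "is_a", a)
    add_edge(b, "part_of", attach_to())
    equiv_pairs[[k]] <- c(a, b)
  }
  chains <- list()
  for (k in seq_len(cfg$n_containment_chains)) {
    ch <- sprintf("TOY:ch%02d%s", k, c("a", "b", "c"))
    for (i in 1:3) add_term(ch[[i]], paste("chain", k, "level", i))
    add_edge(ch[[1]], "part_of", ch[[2]])
    add_edge(ch[[2]], "part_of", ch[[3]])
    add_edge(ch[[3]], "part_of", attach_to())
    chains[[k]] <- ch
  }
  coassert <- list()
  for (k in seq_len(cfg$n_coassert_groups)) {
    parent <- sprintf("TOY:coP%02d", k)
    members <- sprintf("TOY:co%02d%s", k, c("x", "y", "z"))
    add_term(parent, paste("co-assertion parent", k))
    for (mm in members) add_term(mm, paste("co-assertion member", k, mm))
    add_edge(parent, "part_of", attach_to())
    for (mm in members) add_edge(mm, "part_of", parent)
    coassert[[k]] <- members
  }
  add_term("TOY:organism", "multicellular organism")
  o <- suppressWarnings(ontology(
    tibble(id = c(ids, extra_ids), label = c(labels, extra_labels)),
    tibble(subject = subj, relation = rel, object = obj),
    namespace = "anatomy"
  ))
  attr(o, "fixture_info") <- list(
    base_terms = ids, layer = setNames(layer, ids),
    equiv_pairs = equiv_pairs, chains = chains, coassert = coassert,
    organism = "TOY:organism",
    annotatable = c(ids, unlist(equiv_pairs))
  )
  o
}

#' Generate a ranked random taxonomy
#'
#' A three-level `is_a` tree: species under genera under a single root clade.
#' The terms tibble carries a `rank` column.
#'
#' @param cfg A `fixture_config`.
#' @return A taxonomy `ontology`.
#' @export
generate_taxonomy <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_taxa
  n_genera <- max(1L, round(n / 5))
  genera <- sprintf("TAXON:g%02d", seq_len(n_genera))
  species <- sprintf("TAXON:s%03d", seq_len(n))
  genus_of <- sample(genera, n, replace = TRUE)
  terms <- tibble(
    id = c("TAXON:root", genera, species),
    label = c("root clade", paste("genus", seq_len(n_genera)),
              paste("species", seq_len(n))),
    rank = c("clade", rep("genus", n_genera), rep("species", n))
  )
  edges <- tibble(
    subject = c(genera, species),
    relation = "is_a",
    object = c(rep("TAXON:root", n_genera), genus_of)
  )
  ontology(terms, edges, namespace = "taxonomy")
}

# latent truth consistent with closure logic: a term is absent whenever any
# whole/superclass/precursor is absent; otherwise absent with absence_rate.
# Mixed-relation cycles (equivalence motifs) are handled by sampling strongly
# connected components as single units, wholes before parts.
sample_latent_truth <- function(anatomy, taxa, absence_rate) {
  edges <- anatomy$edges[anatomy$edges$relation %in% REASONING_RELATIONS, ]
  ids <- anatomy$terms$id
  g <- igraph::graph_from_data_frame(
    edges[, c("subject", "object")], directed = TRUE, vertices = ids)
  comp <- igraph::components(g, mode = "strong")$membership
  cond <- igraph::simplify(igraph::contract(g, comp))
  ord <- rev(as.integer(igraph::topo_sort(cond, mode = "out")))
  unit_parents <- lapply(igraph::adjacent_vertices(cond, igraph::V(cond), mode = "out"),
                         as.integer)
  n_t <- length(taxa)
  absent <- matrix(FALSE, nrow = n_t, ncol = igraph::vcount(cond))
  for (u in ord) {
    pa <- unit_parents[[u]]
    forced <- if (length(pa) > 0) {
      Reduce(`|`, lapply(pa, function(p) absent[, p]))
    } else rep(FALSE, n_t)
    absent[, u] <- forced | (stats::runif(n_t) < absence_rate)
  }
  truth <- tidyr::expand_grid(taxon = taxa, entity = ids) %>%
    mutate(value = if_else(absent[cbind(match(.data$taxon, taxa),
                                        comp[match(.data$entity, ids)])],
                           "absent", "present"))
  truth
}

#' Generate an annotated knowledge base with a ground-truth ledger
#'
#' Draws a latent presence/absence assignment per (taxon, entity) consistent
#' with closure logic, then emits `n_sources` study bundles whose states carry
#' EQ phenotypes reflecting that truth: presence states use "present" or
#' (with `shape_quality_rate`) a shape quality, absence states use "absent"
#' or the organism-level lacks-all-parts pattern.  Cluster motifs planted by
#' [generate_ontology()] get their dedicated characters (chains annotated at
#' the ends, co-assertion groups via shared multi-entity states).  Injected
#' conflicts flip targeted assertions at leaf entities whose truth is
#' "present", so nothing outside the injected cell is contaminated.  The
#' ledger records the truth, every injected site with its category, and the
#' planted cluster structures.
#'
#' @param cfg A `fixture_config`.
#' @param anatomy Ontology from [generate_ontology()] (must carry
#'   `fixture_info`).
#' @param taxonomy Ontology from [generate_taxonomy()].
#' @return A list with elements `sources` (list of `source_matrix`) and
#'   `ledger` (list: `truth`, `conflict_sites`, `cluster_motifs`, `config`).
#' @export
generate_kb <- function(cfg, anatomy, taxonomy) {
  stopifnot(inherits(cfg, "fixture_config"))
  info <- attr(anatomy, "fixture_info")
  if (is.null(info)) abort("anatomy ontology lacks fixture_info; use generate_ontology()")
  set.seed(cfg$seed + 2L)
  species <- taxonomy$terms$id[taxonomy$terms$rank == "species"]
  truth <- sample_latent_truth(anatomy, species, cfg$absence_rate)
  # co-asserted siblings share one published state, so their latent truth must
  # coincide; copying the first member is consistent because the members'
  # only whole is their common parent
  for (gr in info$coassert) {
    lead <- truth$value[truth$entity == gr[[1]]]
    for (mm in gr[-1]) truth$value[truth$entity == mm] <- lead
  }
  truth_of <- setNames(truth$value, paste(truth$taxon, truth$entity))
  tval <- function(t, e) truth_of[[paste(t, e)]]

  reserved <- c(unlist(info$chains), unlist(info$coassert),
                vapply(info$coassert, function(x) sub("TOY:co(\\d+).*", "TOY:coP\\1", x[[1]]),
                       character(1)), info$organism)
  annotatable <- setdiff(info$annotatable, reserved)

  # --- conflict sites: leaf entities (empty proper downward closure) ---
  leaves <- annotatable[!annotatable %in% anatomy$edges$object[
    anatomy$edges$relation %in% REASONING_RELATIONS]]
  want <- cfg$conflicts[cfg$conflicts > 0]
  n_sites <- sum(want)
  candidates <- truth %>%
    filter(.data$entity %in% leaves, .data$value == "present") %>%
    group_by(.data$entity) %>%
    dplyr::slice_sample(n = 1) %>%
    ungroup()
  if (nrow(candidates) < n_sites) {
    abort(paste0("unsatisfiable conflict injection: need ", n_sites,
                 " leaf sites with truth 'present', have ", nrow(candidates)))
  }
  sites <- candidates[sample(nrow(candidates), n_sites), c("taxon", "entity")]
  sites$category <- rep(names(want), times = want)
  site_key <- paste(sites$taxon, sites$entity)

  # --- per-source builders ---
  src <- lapply(seq_len(cfg$n_sources), function(s) {
    new.env(parent = emptyenv())
  })
  for (s in seq_along(src)) {
    e <- src[[s]]
    e$matrix_id <- sprintf("STUDY:%02d", s)
    e$citation <- paste("Synthetic study", s)
    e$taxa <- sort(sample(species, max(2L, round(cfg$taxa_frac * length(species)))))
    e$chars <- tibble(char_id = character(), label = character())
    e$states <- tibble(char_id = character(), state_id = character(), label = character())
    e$phen <- tibble(char_id = character(), state_id = character(), entity = character(),
                     quality = character(), related_entity = character())
    e$cells <- tibble(taxon = character(), char_id = character(), state_id = character())
  }
  add_char <- function(e, char_id, label) {
    e$chars <- bind_rows(e$chars, tibble(char_id = char_id, label = label))
  }
  add_state <- function(e, char_id, state_id, label, phen) {
    e$states <- bind_rows(e$states,
                          tibble(char_id = char_id, state_id = state_id, label = label))
    e$phen <- bind_rows(e$phen, mutate(phen, char_id = char_id, state_id = state_id))
  }
  add_cell <- function(e, taxon, char_id, state_id) {
    e$cells <- bind_rows(e$cells,
                         tibble(taxon = taxon, char_id = char_id, state_id = state_id))
  }
  presence_phen <- function(entity, shape) {
    tibble(entity = entity,
           quality = if (shape) "PATO:0000052" else QUALITY_PRESENT,
           related_entity = NA_character_)
  }
  absence_phen <- function(ent, lacks) {
    if (lacks) {
      tibble(entity = "TOY:organism", quality = QUALITY_LACKS_ALL_PARTS,
             related_entity = ent)
    } else {
      tibble(entity = ent, quality = QUALITY_ABSENT, related_entity = NA_character_)
    }
  }

  # --- regular characters ---
  for (s in seq_along(src)) {
    e <- src[[s]]
    ents <- sort(sample(annotatable, max(1L, round(cfg$entity_frac * length(annotatable)))))
    for (i in seq_along(ents)) {
      ent <- ents[[i]]
      cid <- sprintf("c%03d", i)
      add_char(e, cid, paste("state of", ent))
      shape <- stats::runif(1) < cfg$shape_quality_rate
      add_state(e, cid, "sP", if (shape) paste(ent, "oddly shaped") else paste(ent, "present"),
                presence_phen(ent, shape))
      lacks <- stats::runif(1) < 0.5
      add_state(e, cid, "sA", paste(ent, "absent"), absence_phen(ent, lacks))
      for (t in e$taxa) {
        if (paste(t, ent) %in% site_key) next
        if (stats::runif(1) < cfg$annotation_rate) {
          add_cell(e, t, cid, if (tval(t, ent) == "present") "sP" else "sA")
        }
      }
    }
  }

  # --- cluster motif characters ---
  motif_src <- function(k) src[[1L + ((k - 1L) %% length(src))]]
  if (length(src) > 0) {
    for (k in seq_along(info$chains)) {
      ch <- info$chains[[k]]
      e <- motif_src(k)
      cid <- sprintf("chain%02d", k)
      add_char(e, cid, paste("chain character", k))
      add_state(e, cid, "sP", paste(ch[[1]], "present"), presence_phen(ch[[1]], shape = FALSE))
      add_state(e, cid, "sA", paste(ch[[3]], "absent"), absence_phen(ch[[3]], lacks = FALSE))
      for (t in e$taxa) {
        if (stats::runif(1) >= 0.9) next
        if (tval(t, ch[[1]]) == "present") add_cell(e, t, cid, "sP")
        else if (tval(t, ch[[3]]) == "absent") add_cell(e, t, cid, "sA")
      }
    }
    for (k in seq_along(info$coassert)) {
      gr <- info$coassert[[k]]
      e <- motif_src(k + length(info$chains))
      cid <- sprintf("coassert%02d", k)
      add_char(e, cid, paste("co-assertion character", k))
      add_state(e, cid, "sP", paste(paste(gr, collapse = ", "), "present"),
                bind_rows(lapply(gr, presence_phen, shape = FALSE)))
      add_state(e, cid, "sA", paste(paste(gr, collapse = ", "), "absent"),
                bind_rows(lapply(gr, absence_phen, lacks = FALSE)))
      for (t in e$taxa) {
        if (stats::runif(1) >= 0.9) next
        add_cell(e, t, cid, if (tval(t, gr[[1]]) == "present") "sP" else "sA")
      }
    }
  }

  # --- conflict injection ---
  if (nrow(sites) > 0 && length(src) == 0) abort("conflict injection requires >= 1 source")
  for (i in seq_len(nrow(sites))) {
    t <- sites$taxon[[i]]; ent <- sites$entity[[i]]; cat <- sites$category[[i]]
    s1 <- src[[1L + ((i - 1L) %% length(src))]]
    s2 <- src[[1L + (i %% length(src))]]
    if (cat == "intra_source_polymorphism") s2 <- s1
    s1$taxa <- sort(union(s1$taxa, t)); s2$taxa <- sort(union(s2$taxa, t))
    cid1 <- sprintf("conf%02dp", i); cid2 <- sprintf("conf%02da", i)
    p_phen <- presence_phen(ent, shape = cat %in% c("asserted_inferred", "inferred_inferred"))
    a_phen <- absence_phen(ent, lacks = cat == "inferred_inferred")
    if (cat == "intra_source_polymorphism") {
      add_char(s1, cid1, paste("polymorphic character for", ent))
      add_state(s1, cid1, "sP", paste(ent, "present"), p_phen)
      add_state(s1, cid1, "sA", paste(ent, "absent"), a_phen)
      add_cell(s1, t, cid1, "sP")
      add_cell(s1, t, cid1, "sA")
    } else {
      add_char(s1, cid1, paste("conflict presence side for", ent))
      add_state(s1, cid1, "sP", paste(ent, "state"), p_phen)
      add_cell(s1, t, cid1, "sP")
      add_char(s2, cid2, paste("conflict absence side for", ent))
      add_state(s2, cid2, "sA", paste(ent, "state"), a_phen)
      add_cell(s2, t, cid2, "sA")
    }
  }

  sources <- lapply(src, function(e) {
    source_matrix(matrix_id = e$matrix_id, citation = e$citation, taxa = e$taxa,
                  characters = e$chars, states = e$states, phenotypes = e$phen,
                  cells = e$cells)
  })
  ledger <- list(
    truth = truth,
    conflict_sites = arrange(sites, .data$taxon, .data$entity),
    cluster_motifs = list(equiv_pairs = info$equiv_pairs,
                          chains = info$chains,
                          coassert = info$coassert),
    config = cfg
  )
  list(sources = sources, ledger = ledger)
}

#' Generate a complete fixture set
#'
#' Ontology + taxonomy + study bundles + ground-truth ledger, plus the entity
#' and taxon expressions that cover the whole fixture (the union of every
#' anatomy class, and the taxonomy root).
#'
#' @param cfg A `fixture_config` (or a preset name for [fixture_preset()]).
#' @param seed Seed used when `cfg` is a preset name.
#' @return A list: `anatomy`, `taxonomy`, `sources`, `ledger`, `entity_expr`,
#'   `taxon_expr`.
#' @export
generate_fixture_set <- function(cfg = fixture_config(), seed = 1L) {
  if (is.character(cfg)) {
    out <- fixture_preset(cfg, seed = seed)
    if (!inherits(out, "fixture_config")) return(out)
    cfg <- out
  }
  anatomy <- generate_ontology(cfg)
  taxonomy <- generate_taxonomy(cfg)
  kb <- generate_kb(cfg, anatomy, taxonomy)
  list(
    anatomy = anatomy, taxonomy = taxonomy,
    sources = kb$sources, ledger = kb$ledger,
    entity_expr = paste(setdiff(anatomy$terms$id, "TOY:organism"), collapse = " or "),
    taxon_expr = "TAXON:root"
  )
}

# deterministic fixture around the toy fin-to-limb ontology; no randomness
toy_fixture_set <- function() {
  anatomy <- toy_fin_limb_ontology()
  taxonomy <- ontology(
    tibble(id = c("TAXON:root", "TAXON:fishA", "TAXON:tetrapodA", "TAXON:tetrapodB"),
           label = c("root clade", "finned species", "limbed species A", "limbed species B"),
           rank = c("clade", "species", "species", "species")),
    tibble(subject = c("TAXON:fishA", "TAXON:tetrapodA", "TAXON:tetrapodB"),
           relation = "is_a", object = "TAXON:root"),
    namespace = "taxonomy"
  )
  demo <- source_matrix(
    matrix_id = "STUDY:demo", citation = "Demo study (synthetic)",
    taxa = c("TAXON:fishA", "TAXON:tetrapodA", "TAXON:tetrapodB"),
    characters = tibble(char_id = c("c001", "c002", "c003"),
                        label = c("humerus shape", "forelimb bud", "entepicondyle")),
    states = tibble(
      char_id = c("c001", "c001", "c002", "c002", "c003", "c003"),
      state_id = c("s1", "s2", "s1", "s2", "s1", "s2"),
      label = c("humerus L-shaped", "humerus absent", "forelimb bud present",
                "forelimb bud absent", "entepicondyle present", "entepicondyle absent")
    ),
    phenotypes = tibble(
      char_id = c("c001", "c001", "c002", "c002", "c003", "c003"),
      state_id = c("s1", "s2", "s1", "s2", "s1", "s2"),
      entity = c("TOY:humerus", "TOY:humerus", "TOY:forelimb-bud", "TOY:organism",
                 "TOY:entepicondyle", "TOY:entepicondyle"),
      quality = c("PATO:0000052", QUALITY_ABSENT, QUALITY_PRESENT,
                  QUALITY_LACKS_ALL_PARTS, QUALITY_PRESENT, QUALITY_ABSENT),
      related_entity = c(NA, NA, NA, "TOY:forelimb-bud", NA, NA)
    ),
    cells = tibble(
      taxon = c("TAXON:tetrapodA", "TAXON:fishA", "TAXON:tetrapodA",
                "TAXON:tetrapodB", "TAXON:tetrapodB"),
      char_id = c("c001", "c002", "c002", "c003", "c003"),
      state_id = c("s1", "s2", "s1", "s1", "s2")
    )
  )
  list(
    anatomy = anatomy, taxonomy = taxonomy, sources = list(demo),
    ledger = NULL,
    entity_expr = paste(anatomy$terms$id, collapse = " or "),
    taxon_expr = "TAXON:root"
  )
}

#' Write a fixture set to disk
#'
#' Emits `anatomy.obo`, `taxonomy.obo`, one `study-*.json` bundle per source,
#' and (when present) `ledger.json` into `dir`.
#'
#' @param fx A fixture set from [generate_fixture_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_obo(fx$anatomy, file.path(dir, "anatomy.obo"))
  write_obo(fx$taxonomy, file.path(dir, "taxonomy.obo"))
  for (m in fx$sources) {
    write_study_bundle(m, file.path(dir, paste0(
      "study-", gsub("[^A-Za-z0-9]", "_", m$matrix_id), ".json")))
  }
  if (!is.null(fx$ledger)) {
    led <- fx$ledger
    jsonlite::write_json(
      list(truth = led$truth, conflict_sites = led$conflict_sites,
           cluster_motifs = led$cluster_motifs,
           config = unclass(led$config)[setdiff(names(led$config), "")]),
      file.path(dir, "ledger.json"), auto_unbox = TRUE, pretty = TRUE
    )
  }
  writeLines(c(fx$entity_expr, fx$taxon_expr), file.path(dir, "expressions.txt"))
  invisible(dir)
}
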