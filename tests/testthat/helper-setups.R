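# A hand-built two-study setup used across several tests: a scapula-like
# part chain where one study annotates only a shape quality on the part.
two_study_setup <- function() {
  anatomy <- ontology(
    tibble::tibble(id = c("TOY:blade", "TOY:scapula", "TOY:girdle", "TOY:organism"),
                   label = c("scapular blade", "scapula", "girdle", "organism")),
    tibble::tibble(subject = c("TOY:blade", "TOY:scapula"),
                   relation = "part_of",
                   object = c("TOY:scapula", "TOY:girdle"))
  )
  taxonomy <- ontology(
    tibble::tibble(id = c("TAXON:root", "TAXON:g1", "TAXON:a", "TAXON:b"),
                   label = c("root", "genus 1", "species a", "species b"),
                   rank = c("clade", "genus", "species", "species")),
    tibble::tibble(subject = c("TAXON:g1", "TAXON:a", "TAXON:b"),
                   relation = "is_a",
                   object = c("TAXON:root", "TAXON:g1", "TAXON:g1")),
    namespace = "taxonomy"
  )
  s1 <- suppressMessages(source_matrix(
    "STUDY:shape", "Shape study", taxa = c("TAXON:a", "TAXON:b"),
    characters = tibble::tibble(char_id = "c1", label = "scapular blade width"),
    states = tibble::tibble(char_id = "c1", state_id = c("s1", "s2"),
                            label = c("blade wide", "blade absent")),
    phenotypes = tibble::tibble(char_id = "c1", state_id = c("s1", "s2"),
                                entity = c("TOY:blade", "TOY:blade"),
                                quality = c("PATO:0000052", "PATO:0000462"),
                                related_entity = NA_character_),
    cells = tibble::tibble(taxon = c("TAXON:a", "TAXON:b"), char_id = "c1",
                           state_id = c("s1", "s2"))
  ))
  s2 <- source_matrix(
    "STUDY:direct", "Direct study", taxa = "TAXON:b",
    characters = tibble::tibble(char_id = "c1", label = "scapula"),
    states = tibble::tibble(char_id = "c1", state_id = "s1", label = "scapula present"),
    phenotypes = tibble::tibble(char_id = "c1", state_id = "s1",
                                entity = "TOY:scapula", quality = "PATO:0000467",
                                related_entity = NA_character_),
    cells = tibble::tibble(taxon = "TAXON:b", char_id = "c1", state_id = "s1")
  )
  list(anatomy = anatomy, taxonomy = taxonomy, sources = list(s1, s2))
}
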