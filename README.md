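# phenosynth

Ontology-driven synthesis of presence/absence morphological supermatrices
from Entity–Quality (EQ) annotated character data.

Comparative morphologists publish character matrices as free text, study by
study. When each character state carries EQ annotations — an anatomy-ontology
entity plus a PATO quality — the presence and absence of structures becomes
computable across studies. `phenosynth` is for systematists and phenomics
researchers who want to aggregate such annotated studies into one synthetic
entity-by-taxon presence/absence matrix, with complete per-cell provenance,
and to audit what inference contributed to it.

## The model

Reasoning runs over the anatomy ontology's structural graph — `is_a`,
`part_of`, `develops_from` — with presence and absence as dual closures:

- **Presence propagates upward.** A quality inhering in a structure implies
  the structure is present (*implies_presence_of*), and presence of a part,
  subclass, or derived structure entails presence of every whole, superclass,
  and developmental precursor reachable by mixed chains of the three
  relations. A present humerus ⇒ present forelimb skeleton ⇒ present
  forelimb ⇒ present forelimb bud.
- **Absence propagates downward** (the *lacks_all_parts_of_type* pattern).
  An absent forelimb bud ⇒ no forelimb ⇒ no forelimb skeleton ⇒ no humerus.
  An absent humerus says nothing about the forelimb — absence never climbs.

A synthetic character is one anatomy class selected by an OWL-style class
expression (for example `part_of some ('paired limb/fin' or 'girdle
skeleton')`); taxa are the `is_a` descendants of a taxon class that carry
data. Each cell is `PRESENT`, `ABSENT`, `BOTH` (polymorphism/conflict), or
missing, as a pure function of its support records, each flagged *asserted*
(the exact entity with quality "present"/"absent") or *inferred* (everything
else, including shape qualities on the exact entity). On top of the matrix
the package detects and classifies conflicting cells, finds isomorphic
character clusters and their ontological causes, and computes missing-data
and sampling reports. A seeded fixture generator (random ontologies,
taxonomies, annotated study bundles, ground-truth ledger) makes the whole
pipeline testable offline.

## Worked example

The five-term fin-to-limb toy ontology, a three-species taxonomy, and one
annotated demo study ship with the package:

```r
library(phenosynth)

fx <- generate_fixture_set("toy")
m <- synthesize(fx$anatomy, fx$taxonomy, fx$sources,
                entity_expr = "part_of some (TOY:forelimb) or TOY:forelimb or TOY:forelimb-bud",
                taxon_expr = "TAXON:root")
m
#> <synthetic_matrix> 5 characters x 3 taxa, 14 populated cells (93.3%)
#>   entity expression: part_of some (TOY:forelimb) or TOY:forelimb or TOY:forelimb-bud
#>   taxon expression:  TAXON:root

tidy(m)
#> # A tibble: 14 × 5
#>    taxon           entity                value   n_asserted n_inferred
#>  1 TAXON:fishA     TOY:entepicondyle     ABSENT           0          1
#>  2 TAXON:fishA     TOY:forelimb          ABSENT           0          1
#>  ...
#>  7 TAXON:tetrapodA TOY:forelimb-bud      PRESENT          1          1
#>  ...
#> 10 TAXON:tetrapodB TOY:entepicondyle     BOTH             2          0
```

The fish's single lacks-all-parts annotation on the forelimb bud fills its
entire column set by inference (five `ABSENT` cells, zero direct
assertions); the L-shaped-humerus state in tetrapod A entails four `PRESENT`
cells the source never asserted; and tetrapod B's entepicondyle is `BOTH` —
which `detect_conflicts()` classifies:

```r
detect_conflicts(m)
#> # A tibble: 1 × 6
#>   taxon           entity            category                  excluded ...
#> 1 TAXON:tetrapodB TOY:entepicondyle intra_source_polymorphism TRUE
```

Both values trace to direct assertions in one study, so this is true
polymorphism, excluded from conflict totals. `glance(m)` summarizes: 14 of
15 cells populated, only 2 by direct assertion. `variable_subset()`,
`find_isomorphic_clusters()`, `missing_data_stats()`, and `write_nexml()`
continue the pipeline; `autoplot(m)` draws the bird's-eye cell map.

Shell entry points wrap the same functions:

```sh
Rscript inst/cli/phenosynth-fixtures.R --seed 7 --preset small --out /tmp/kb
Rscript inst/cli/phenosynth-synthesize.R \
  --anatomy /tmp/kb/anatomy.obo --taxonomy /tmp/kb/taxonomy.obo --kb /tmp/kb \
  --entity-expr "$(sed -n 1p /tmp/kb/expressions.txt)" \
  --taxon-expr TAXON:root --out /tmp/matrix.xml --reports /tmp/reports
```

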