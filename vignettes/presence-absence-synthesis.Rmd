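---
title: "Synthesizing presence/absence supermatrices from EQ-annotated morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing presence/absence supermatrices from EQ-annotated morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosynth)
```

## The problem

Comparative morphology is published as character-by-taxon matrices whose
states are free text ("humerus L-shaped", "scapular blade wide").  When those
states carry Entity–Quality (EQ) annotations — an anatomy-ontology class plus
a quality-ontology class — the presence or absence of anatomical structures
becomes computable across studies.  `phenosynth` turns a collection of such
annotated studies, together with an anatomy ontology and a taxonomy, into a
single synthetic presence/absence supermatrix, with per-cell provenance, and
derives the analyses that matter for judging such a matrix: conflict
detection, isomorphic-character clustering, and missing-data accounting.

## The entailment model

All reasoning runs over a typed directed graph of ontology terms with three
structural relations: `is_a` (subclass), `part_of` (partonomy), and
`develops_from` (developmental precursor).  An edge always points from the
more specific thing to what it depends on: a humerus is `part_of` the
forelimb skeleton, a forelimb `develops_from` a forelimb bud.

Two dual closures carry all presence/absence logic:

* **Presence propagates upward.**  Any quality inhering in a structure
  implies that structure is present, and the presence of a structure implies
  the presence of every whole, superclass, and developmental precursor
  reachable from it by chains of the three relations
  (`upward_closure()`).  A present humerus means a present forelimb
  skeleton, forelimb, and forelimb bud.
* **Absence propagates downward.**  A structure asserted absent entails the
  absence of everything below it under the same relations
  (`downward_closure()`).  An absent forelimb bud means no forelimb, no
  forelimb skeleton, no humerus.  Crucially, absence does *not* climb: an
  absent humerus says nothing about the forelimb.

Mixed chains are allowed in one closure (`is_a` interleaved with `part_of`
and `develops_from`), so a quality on a subclass informs a character for the
superclass's whole.  The absence side mirrors the presence side exactly,
including `is_a` (absence of "digit" entails absence of "digit 2"), which is
what organism-level lacks-all-parts semantics requires.  `connected_to` is
loaded and usable in class expressions but never participates in these
closures, since connectivity is evidence of neither containment nor
derivation.

Acyclicity is enforced per relation, not on the mixed graph.  A mixed-graph
cycle (say `x part_of y` together with `y is_a x`) is legal, triggers a
warning at load, and is exactly the configuration that makes two distinct
terms carry identical presence/absence information.  Traversals keep a
visited set, so termination never depends on data cleanliness.

A small but useful fact about equivalence falls out of this semantics: if two
terms have equal presence-supporter sets, each lies in the other's downward
closure, so the two terms are mutually reachable — and then their
absence-supporter sets coincide as well.  The "presence-only" and
"both-closure" variants of `presence_class_equivalent()` therefore agree on
every pair; both are kept in the interface, and the necessity claim — that
equivalent presence classes always yield isomorphic characters — is a
theorem here, property-tested in the suite.

## From annotations to cells

A phenotype is absence-type exactly when its quality is "absent"
(PATO:0000462) or lacks-all-parts (PATO:0002000, with the negated class in
the `towards` slot); any other quality implies presence of its bearer.  For a
synthetic character (one anatomy class) and a taxon, every assigned published
state contributes one support record per phenotype that entails a value, and
the cell is `PRESENT`, `ABSENT`, or `BOTH` as a pure function of its
supports; no supports means missing.  A support is a *direct assertion* only
when the phenotype targets the character's entity exactly with quality
"present" or "absent" — a "present" on "femur bone" is inferred, not
asserted, support for "hindlimb", and a shape quality is always inference
even on the exact entity.

Characters come from an OWL-style class expression (unions and existential
restrictions over the four relations; `rel some (filler)` requires at least
one `rel` edge, so a forelimb is not `part_of some` forelimb).  Taxa come
from the `is_a` descendants of the taxon expression, restricted to taxa that
actually carry data; higher-rank taxa are rows of their own and no state ever
propagates down the taxonomy, since a genus-level observation is not an
observation of each species.

## Derived analyses

**Conflicts.**  `BOTH` cells are classified by a strongest-evidence cascade:
if one source directly asserts both values the cell is true intra-source
polymorphism (excluded from conflict totals); otherwise both-sides-asserted,
one-side-asserted, or inference-only.  The cascade is a deliberate design
choice: a cell can carry mixed support modes on one side, and precedence by
the strongest evidence yields the three-way conflict tabulation users expect.
Conflicts are reported with full provenance, never auto-resolved.

**Isomorphic clusters.**  Characters with identical columns — including the
missing pattern, so "identical" means identical under every taxon — are
grouped, and each cluster's ontological cause is classified by a cascade:
mutual presence-class equivalence; co-assertion (the members' supports all
trace to the same published states, each annotating two or more of the
members, as with "pedal digits 6, 7, and 8 present"); containment chains
(members totally ordered by the structural closure, with member-targeting
supports tracing to a single member per side); and a residual
inference-chain category.  Supports whose phenotype targets an entity
*outside* the cluster (an asserted absence of some structure the whole chain
is part of) hit every member column alike, so they are ignored when deciding
between containment and residual — they carry no information about why the
members coincide.

**Reports.**  Missing-data statistics count a cell as asserted if any support
is a direct assertion, and re-derive the asserted-only view to quantify what
inference adds; per-taxon source counts and per-(taxon, entity)
entailing-state counts (states, not phenotypes, are the unit; a polymorphic
cell's states each count once) feed sampling heat maps.

## The synthetic-data generator

Real EQ corpora cannot be shipped, so `generate_fixture_set()` builds the
study conditions from scratch, with a ground-truth ledger:

* a layered random anatomy DAG (edges only climb layers, so each relation is
  acyclic by construction) with planted motifs: equivalence pairs
  (`x part_of y`, `y is_a x`), three-term containment chains annotated only
  at their ends, and co-asserted sibling groups sharing multi-entity states;
* a ranked taxonomy tree (species under genera under one root);
* a latent presence/absence truth per (taxon, entity), sampled wholes-first
  so closure consistency is constructive rather than rejection-sampled
  (strongly connected components from equivalence motifs are sampled as
  single units); a term is absent when any of its wholes is absent, otherwise
  absent with probability `absence_rate`;
* per-source study bundles: each source samples a fraction of taxa and
  entities, writes a two-state character per entity, and assigns states
  according to the latent truth with probability `annotation_rate`.  With
  probability `shape_quality_rate` a presence state uses a shape quality
  instead of "present" — entailing presence without asserting it, which is
  the mechanism that makes characters variable only through inference;
  absence states use "absent" or the lacks-all-parts pattern at even odds;
* injected conflicts of all four categories at leaf entities (empty proper
  downward closure) whose truth at the chosen taxon is "present": the
  contradicting absence cannot propagate anywhere else, so every cell outside
  an injected site still matches the latent truth, and category recovery is
  exact because normal annotation is suppressed at the injected sites.

Defaults (60 anatomy terms over 4 layers, 50 species, 6 sources, annotation
rate 0.35, absence rate 0.15, shape-quality rate 0.30, two injected conflicts
per category, one motif of each kind) are chosen to resemble a modest
multi-study corpus: enough overlap between sources for cross-source conflict
to be possible, enough absence for variable characters to be common, and
enough shape-quality annotation that inference visibly reduces missing data.
The generator emulates annotation structure, not biology: labels are
synthetic, there is no fossil-style taphonomic missingness (missingness is
independent given the truth), no post-composed entities (only named classes
plus the `towards` slot), and no annotation error beyond the injected
conflicts.  Passing tests therefore demonstrate correctness of the reasoning
and bookkeeping, not robustness to curation noise.

## Numerical and design choices

* All outputs are deterministically ordered (lexicographic term ids); NeXML
  serialization is byte-stable with `timestamp = FALSE`, which is how the
  golden-file test pins the demo output.
* `BOTH` is encoded in NeXML as a `polymorphic_state_set` over symbols 0/1,
  not an uncertainty set: both values are supported, which is polymorphism,
  not ignorance.  Missing cells are simply absent from their row.  Cell
  provenance rides in a small declared `ps:` meta vocabulary (JSON content
  per support record); NeXML files are checked by a structural validator
  (namespace, block presence, id uniqueness, reference integrity, state
  symbols) plus round-trip tests.
* Empty grids define both missing-data fractions as 1.
* Label resolution in expressions is exact match after quote normalization;
  ambiguity is an error, never a guess.
* Published polymorphism (one taxon, two states of one character, one
  source) contributes all states' supports independently.
* Pruning defaults to dropping all-missing rows and columns;
  `variable_subset()` is a separate explicit call, and after subsetting any
  taxon left with no populated cell is dropped.

Problem sizes in the test suite are the package's own validation protocol:
100 random ontologies of 20–80 terms with an exhaustive all-pairs
matrix-power oracle for the reasoner; 20 generator runs at the default scale
for truth recovery; 100 small runs for the cluster-necessity theorem; the
enumeration oracle for synthesis runs at a scale where a naive quintuple loop
is feasible.

## Known limitations

Only named-class entities (plus `towards`) are supported — no post-composed
entity expressions inside annotations.  The OBO reader covers the restricted
dialect the writer emits, not full OBO 1.4.  Expressions support unions and
existential restrictions only; intersection and negation are rejected
loudly.  Character dependency revealed by isomorphic clusters is reported,
not corrected: merging or reweighting clustered characters is a judgment the
tool deliberately leaves to the analyst.
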