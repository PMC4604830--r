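#' Entities whose asserted presence entails presence of `entity`
#'
#' The set of terms E0 such that any presence-type phenotype on E0 entails
#' presence of `entity`: the reflexive-transitive closure of `entity` toward
#' parts, subclasses, and developmental derivatives.  Presence propagates
#' upward (a present humerus means a present forelimb skeleton, forelimb, and
#' forelimb bud), so the supporters of an entity sit at or below it.
#'
#' @param o An anatomy `ontology`.
#' @param entity A term id in `o`.
#' @return Sorted character vector of term ids (always contains `entity`:
#'   a present humerus is a present humerus).
#' @export
presence_supporters <- function(o, entity) {
  downward_closure(o, entity, REASONING_RELATIONS)
}

#' Entities whose asserted absence entails absence of `entity`
#'
#' The dual of [presence_supporters()]: absence propagates downward (an absent
#' forelimb bud means an absent forelimb, forelimb skeleton, and humerus), so
#' the absence supporters of an entity are its wholes, superclasses, and
#' developmental precursors.
#'
#' @inheritParams presence_supporters
#' @return Sorted character vector of term ids (always contains `entity`).
#' @export
absence_supporters <- function(o, entity) {
  upward_closure(o, entity, REASONING_RELATIONS)
}

#' Decide what an EQ phenotype entails about an anatomical entity
#'
#' Returns `PRESENT` when a presence-type phenotype's entity lies in the
#' presence supporters of `entity`; `ABSENT` when an absence-type phenotype's
#' negated class lies in the absence supporters; otherwise `NONE`.  The
#' witness chain is the edge path supporting the verdict (empty for `NONE`
#' and for the reflexive case).
#'
#' @param o An anatomy `ontology`.
#' @param p An `eq_phenotype`.
#' @param entity Term id the verdict is about.
#' @return A list of class `entailment_verdict` with `value` (one of
#'   `"PRESENT"`, `"ABSENT"`, `"NONE"`) and `chain` (tibble of
#'   `subject`, `relation`, `object` edges; PRESENT chains run upward from the
#'   phenotype's entity, ABSENT chains run downward from the negated class).
#' @export
entails <- function(o, p, entity) {
  stopifnot(inherits(p, "eq_phenotype"))
  assert_terms(o, entity)
  value <- "NONE"
  chain <- tibble(subject = character(), relation = character(), object = character())
  if (p$polarity == "presence_type") {
    if (has_term(o, p$entity) && entity %in% upward_closure(o, p$entity)) {
      value <- "PRESENT"
      chain <- witness_path(o, from = p$entity, to = entity)
    }
  } else {
    if (has_term(o, p$negated) && entity %in% downward_closure(o, p$negated)) {
      value <- "ABSENT"
      chain <- witness_path(o, from = entity, to = p$negated)
    }
  }
  structure(list(value = value, chain = chain), class = "entailment_verdict")
}

#' @export
print.entailment_verdict <- function(x, ...) {
  cat("<entailment_verdict> ", x$value, "\n", sep = "")
  if (nrow(x$chain) > 0) print(x$chain)
  invisible(x)
}

# shortest upward edge path from -> to over the reasoning relations;
# empty tibble when from == to (reflexive case)
witness_path <- function(o, from, to) {
  empty <- tibble(subject = character(), relation = character(), object = character())
  if (from == to) return(empty)
  maps <- o$adj$fwd[intersect(REASONING_RELATIONS, names(o$adj$fwd))]
  parent <- list()
  visited <- from
  frontier <- from
  found <- FALSE
  while (length(frontier) > 0 && !found) {
    nxt <- character()
    for (rel in names(maps)) {
      m <- maps[[rel]]
      for (v in intersect(frontier, names(m))) {
        for (w in m[[v]]) {
          if (!(w %in% visited)) {
            parent[[w]] <- c(v, rel)
            visited <- c(visited, w)
            nxt <- c(nxt, w)
            if (w == to) found <- TRUE
          }
        }
      }
    }
    frontier <- nxt
  }
  if (!found) return(empty)
  edges <- empty
  v <- to
  while (v != from) {
    pr <- parent[[v]]
    edges <- bind_rows(tibble(subject = pr[[1]], relation = pr[[2]], object = v), edges)
    v <- pr[[1]]
  }
  edges
}

#' Test whether two entities carry identical presence/absence information
#'
#' Two synthetic characters are guaranteed isomorphic when every possible
#' annotation says the same thing about both entities.  The `"both"` variant
#' (default) requires equality of the presence-supporter *and*
#' absence-supporter sets; the `"presence"` variant compares presence
#' supporters only, mirroring the equivalence of `implies_presence_of`
#' expressions that a description-logic classifier reports.  Presence-only
#' equivalence does not by itself force identical columns when absence
#' assertions are in play, which is why both variants are exposed.
#'
#' @param o An anatomy `ontology`.
#' @param x,y Term ids.
#' @param variant `"both"` or `"presence"`.
#' @return Logical scalar.
#' @export
presence_class_equivalent <- function(o, x, y, variant = c("both", "presence")) {
  variant <- arg_match(variant)
  if (!identical(presence_supporters(o, x), presence_supporters(o, y))) return(FALSE)
  if (variant == "presence") return(TRUE)
  identical(absence_supporters(o, x), absence_supporters(o, y))
}

#' Replay an entailment verdict's witness chain
#'
#' Audit helper: checks that the chain is a connected path in the ontology
#' running in the direction the verdict requires, and that following it one
#' edge at a time reproduces the verdict.
#'
#' @param o An anatomy `ontology`.
#' @param v An `entailment_verdict`.
#' @param from Start term (the phenotype's entity for PRESENT, the entity
#'   under test for ABSENT).
#' @param to End term.
#' @return Logical scalar.
#' @export
replay_chain <- function(o, v, from, to) {
  if (v$value == "NONE") return(nrow(v$chain) == 0)
  if (nrow(v$chain) == 0) return(from == to)
  key <- paste(o$edges$subject, o$edges$relation, o$edges$object)
  ck <- paste(v$chain$subject, v$chain$relation, v$chain$object)
  if (!all(ck %in% key)) return(FALSE)
  at <- from
  for (i in seq_len(nrow(v$chain))) {
    if (v$chain$subject[[i]] != at) return(FALSE)
    at <- v$chain$object[[i]]
  }
  at == to
}
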