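#' Construct an ontology from terms and edges
#'
#' An ontology is a typed directed multigraph over CURIE-style term
#' identifiers.  An edge `(s, part_of, o)` reads "s part_of o": upward
#' (subject to object) always points toward wholes, superclasses, and
#' developmental targets.  Only four relations participate:
#' `is_a`, `part_of`, `develops_from`, and `connected_to`.
#'
#' Validation enforces: declared endpoints for every edge, per-relation
#' acyclicity for `is_a`/`part_of`/`develops_from`, deduplicated edges, and
#' (for taxonomies) `is_a`-only edge sets.  A cycle in the mixed graph across
#' relations is permitted (real ontologies contain benign ones, and they are
#' what makes two terms carry identical presence information); traversals
#' always terminate because they keep a visited set.
#'
#' @param terms A data frame with columns `id` and `label` (one row per term),
#'   or a character vector of ids (labels default to the ids).  Extra columns
#'   (e.g. `rank` on a taxonomy) are kept.
#' @param edges A data frame with columns `subject`, `relation`, `object`.
#'   May be empty.
#' @param namespace One of `"anatomy"`, `"taxonomy"`, `"quality"`.
#' @return An object of class `ontology`.
#' @examples
#' o <- ontology(c("TOY:a", "TOY:b"),
#'               tibble::tibble(subject = "TOY:a", relation = "part_of",
#'                              object = "TOY:b"))
#' upward_closure(o, "TOY:a")
#' @export
ontology <- function(terms, edges = NULL, namespace = c("anatomy", "taxonomy", "quality")) {
  namespace <- arg_match(namespace)
  if (is.character(terms)) {
    terms <- tibble(id = terms, label = terms)
  }
  terms <- as_tibble(terms)
  if (!all(c("id", "label") %in% names(terms))) {
    if (!"label" %in% names(terms)) terms$label <- terms$id
  }
  stopifnot(all(nzchar(terms$id)))
  if (anyDuplicated(terms$id)) {
    abort(paste0("duplicate term ids: ",
                 paste(unique(terms$id[duplicated(terms$id)]), collapse = ", ")))
  }
  if (is.null(edges)) {
    edges <- tibble(subject = character(), relation = character(), object = character())
  }
  edges <- as_tibble(edges)[, c("subject", "relation", "object")]
  edges <- distinct(edges)
  terms <- arrange(terms, .data$id)
  edges <- arrange(edges, .data$subject, .data$relation, .data$object)
  o <- structure(
    list(namespace = namespace, terms = terms, edges = edges),
    class = "ontology"
  )
  validate_ontology(o)
  o$adj <- build_adjacency(edges)
  o
}

# forward: subject -> objects, reverse: object -> subjects, per relation
build_adjacency <- function(edges) {
  per_rel <- split(edges, edges$relation)
  fwd <- lapply(per_rel, function(e) split(e$object, e$subject))
  rev <- lapply(per_rel, function(e) split(e$subject, e$object))
  list(fwd = fwd, rev = rev)
}

#' Validate an ontology object
#'
#' Checks the invariants documented in [ontology()].  Called by the
#' constructor and by [read_obo()]; exposed so fixtures can be re-checked.
#'
#' @param o An `ontology`.
#' @return `o`, invisibly.  Errors on violation; warns on a mixed-relation
#'   cycle (benign, traversals still terminate).
#' @export
validate_ontology <- function(o) {
  stopifnot(inherits(o, "ontology"))
  ids <- o$terms$id
  bad <- setdiff(c(o$edges$subject, o$edges$object), ids)
  if (length(bad) > 0) {
    abort(paste0("edge endpoints not declared as terms: ", paste(bad, collapse = ", ")))
  }
  unknown_rel <- setdiff(unique(o$edges$relation), ALL_RELATIONS)
  if (length(unknown_rel) > 0) {
    abort(paste0("unknown relations: ", paste(unknown_rel, collapse = ", ")))
  }
  if (o$namespace == "taxonomy" && any(o$edges$relation != "is_a")) {
    abort("taxonomy ontologies may contain only is_a edges")
  }
  for (rel in intersect(unique(o$edges$relation), REASONING_RELATIONS)) {
    e <- o$edges[o$edges$relation == rel, ]
    cyc <- find_cycle(e$subject, e$object, ids)
    if (!is.null(cyc)) {
      abort(paste0("cycle in ", rel, " edges: ", paste(cyc, collapse = " -> ")))
    }
  }
  mixed <- o$edges[o$edges$relation %in% REASONING_RELATIONS, ]
  if (nrow(mixed) > 0 && !is.null(find_cycle(mixed$subject, mixed$object, ids))) {
    warn("mixed-relation cycle present; closures still terminate (visited-set BFS)")
  }
  invisible(o)
}

# Kahn's algorithm; returns one cycle (as a vector of term ids) or NULL.
find_cycle <- function(subject, object, ids) {
  succ <- split(object, factor(subject, levels = ids))
  indeg <- table(factor(object, levels = ids))
  queue <- ids[indeg == 0]
  indeg <- as.integer(indeg)
  names(indeg) <- ids
  seen <- 0L
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (w in succ[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (seen == length(ids)) return(NULL)
  # walk backwards inside the residual graph to recover a cycle
  residual <- ids[indeg > 0]
  pred <- split(subject, factor(object, levels = ids))
  v <- residual[[1]]
  path <- character()
  while (!(v %in% path)) {
    path <- c(path, v)
    v <- intersect(pred[[v]], residual)[[1]]
  }
  cyc <- c(path[which(path == v):length(path)], v)
  cyc
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology: %s> %d terms, %d edges\n",
              x$namespace, nrow(x$terms), nrow(x$edges)))
  if (nrow(x$edges) > 0) {
    print(count(x$edges, .data$relation))
  }
  invisible(x)
}

has_term <- function(o, id) id %in% o$terms$id

assert_terms <- function(o, ids) {
  missing <- setdiff(ids, o$terms$id)
  if (length(missing) > 0) {
    abort(paste0("unknown term(s) in ", o$namespace, " ontology: ",
                 paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

closure_bfs <- function(adj_maps, start) {
  visited <- structure(rep(TRUE, length(start)), names = start)
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- character()
    for (m in adj_maps) {
      hit <- frontier[frontier %in% names(m)]
      if (length(hit) > 0) nxt <- c(nxt, unlist(m[hit], use.names = FALSE))
    }
    nxt <- unique(nxt)
    nxt <- nxt[!(nxt %in% names(visited))]
    if (length(nxt) > 0) {
      visited <- c(visited, structure(rep(TRUE, length(nxt)), names = nxt))
    }
    frontier <- nxt
  }
  sort(names(visited))
}

#' Reflexive-transitive closure toward wholes/superclasses/precursor targets
#'
#' Returns every term reachable from `start` by repeatedly following edges in
#' subject-to-object direction whose relation is in `relations`, in any
#' interleaving, plus `start` itself.  With the default relation set this is
#' the set of structures whose presence is entailed by the presence of
#' `start`: the presence of a humerus entails the presence of the forelimb
#' skeleton and forelimb it is part of, and of the forelimb bud the forelimb
#' develops from.
#'
#' @param o An `ontology`.
#' @param start A term id in `o`.
#' @param relations Character vector of relations to traverse.
#' @return Sorted character vector of term ids (always contains `start`).
#' @seealso [downward_closure()], [presence_supporters()]
#' @export
upward_closure <- function(o, start, relations = REASONING_RELATIONS) {
  stopifnot(length(relations) > 0)
  assert_terms(o, start)
  closure_bfs(o$adj$fwd[intersect(relations, names(o$adj$fwd))], start)
}

#' Reflexive-transitive closure toward parts/subclasses/derivatives
#'
#' The dual of [upward_closure()]: follows edges object-to-subject.  With the
#' default relation set this is the set of structures whose absence is
#' entailed by the absence of `start` (an absent forelimb bud entails an
#' absent forelimb, forelimb skeleton, and humerus).
#'
#' @inheritParams upward_closure
#' @return Sorted character vector of term ids (always contains `start`).
#' @export
downward_closure <- function(o, start, relations = REASONING_RELATIONS) {
  stopifnot(length(relations) > 0)
  assert_terms(o, start)
  closure_bfs(o$adj$rev[intersect(relations, names(o$adj$rev))], start)
}

# closure of a *set* of seeds (used by expression evaluation); no term check
closure_set <- function(o, seeds, relations, direction = c("up", "down")) {
  direction <- arg_match(direction)
  maps <- if (direction == "up") o$adj$fwd else o$adj$rev
  if (length(seeds) == 0) return(character())
  closure_bfs(maps[intersect(relations, names(maps))], unique(seeds))
}

#' Read an ontology from a restricted OBO 1.4 file
#'
#' Supports `[Term]` stanzas with `id`, `name`, `is_a`, and
#' `relationship: part_of / develops_from / connected_to` tags.  Trailing
#' `! comment` text is stripped.  Any other relationship type is skipped with
#' a warning; any other tag is silently ignored.
#'
#' @param path Path to an OBO file.
#' @param namespace Ontology namespace (see [ontology()]).
#' @return A validated `ontology`.
#' @export
read_obo <- function(path, namespace = c("anatomy", "taxonomy", "quality")) {
  namespace <- arg_match(namespace)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  ids <- character(); labels <- character()
  subj <- character(); rel <- character(); obj <- character()
  cur <- NA_character_
  in_term <- FALSE
  unknown_rels <- character()
  strip <- function(x) stringr::str_trim(sub("!.*$", "", x))
  for (i in seq_along(lines)) {
    line <- stringr::str_trim(lines[[i]])
    if (line == "[Term]") { in_term <- TRUE; cur <- NA_character_; next }
    if (grepl("^\\[", line)) { in_term <- FALSE; next }
    if (!in_term || line == "") next
    m <- regmatches(line, regexec("^([a-zA-Z_]+):\\s*(.*)$", line))[[1]]
    if (length(m) != 3) abort(paste0("OBO parse failure at line ", i, ": ", line))
    tag <- m[[2]]; value <- m[[3]]
    if (tag == "id") {
      cur <- strip(value)
      ids <- c(ids, cur)
      labels <- c(labels, cur)
    } else if (tag == "name") {
      if (is.na(cur)) abort(paste0("OBO parse failure at line ", i, ": name before id"))
      labels[length(labels)] <- strip(value)
    } else if (tag == "is_a") {
      subj <- c(subj, cur); rel <- c(rel, "is_a"); obj <- c(obj, strip(value))
    } else if (tag == "relationship") {
      parts <- strsplit(strip(value), "\\s+")[[1]]
      if (length(parts) != 2) abort(paste0("OBO parse failure at line ", i, ": ", line))
      if (parts[[1]] %in% setdiff(ALL_RELATIONS, "is_a")) {
        subj <- c(subj, cur); rel <- c(rel, parts[[1]]); obj <- c(obj, parts[[2]])
      } else {
        unknown_rels <- c(unknown_rels, parts[[1]])
      }
    }
  }
  if (length(unknown_rels) > 0) {
    warn(paste0("ignored unknown relationship type(s): ",
                paste(unique(unknown_rels), collapse = ", ")))
  }
  ontology(tibble(id = ids, label = labels),
           tibble(subject = subj, relation = rel, object = obj),
           namespace = namespace)
}

#' Write an ontology in the restricted OBO dialect read by [read_obo()]
#'
#' @param o An `ontology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(o, path) {
  stopifnot(inherits(o, "ontology"))
  out <- c("format-version: 1.4", "")
  edges_by_subj <- split(o$edges, factor(o$edges$subject, levels = o$terms$id))
  for (i in seq_len(nrow(o$terms))) {
    id <- o$terms$id[[i]]
    out <- c(out, "[Term]", paste0("id: ", id), paste0("name: ", o$terms$label[[i]]))
    e <- edges_by_subj[[id]]
    if (!is.null(e) && nrow(e) > 0) {
      for (j in seq_len(nrow(e))) {
        if (e$relation[[j]] == "is_a") {
          out <- c(out, paste0("is_a: ", e$object[[j]]))
        } else {
          out <- c(out, paste0("relationship: ", e$relation[[j]], " ", e$object[[j]]))
        }
      }
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}
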