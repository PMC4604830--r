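#' Parse an OWL-style class expression
#'
#' Grammar (whitespace-insensitive):
#' ```
#' expr := atom ("or" atom)*
#' atom := name | relation "some" "(" expr ")" | "(" expr ")"
#' name := CURIE | 'single-quoted label'
#' ```
#' Relations are `is_a`, `part_of`, `develops_from`, `connected_to`.  Curly
#' and straight quotes are both accepted.  Only unions and existential
#' restrictions are supported; these are the constructs presence/absence
#' synthesis inputs use (for example
#' `part_of some ('paired limb/fin' or 'girdle skeleton') or
#'  connected_to some ('paired limb/fin' or 'girdle skeleton')`).
#'
#' @param text Expression string.
#' @return A `class_expression` parse tree: a union of atoms, each either
#'   `named` (a CURIE or quoted label) or `some` (relation + filler
#'   expression).
#' @export
parse_class_expression <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  tokens <- tokenize_expression(text)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens
  st$pos <- 1L
  e <- parse_union(st)
  if (st$pos <= length(st$tokens)) {
    abort(paste0("syntax error at token ", st$pos, ": unexpected '",
                 st$tokens[[st$pos]]$value, "'"))
  }
  e
}

tokenize_expression <- function(text) {
  # normalize curly quotes to straight
  text <- gsub("[‘’]", "'", text)
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(") { tokens <- c(tokens, list(list(type = "lparen", value = "("))); i <- i + 1L; next }
    if (ch == ")") { tokens <- c(tokens, list(list(type = "rparen", value = ")"))); i <- i + 1L; next }
    if (ch == "'") {
      j <- regexpr("'", substr(text, i + 1L, n), fixed = TRUE)
      if (j < 0) abort(paste0("syntax error at position ", i, ": unterminated quote"))
      label <- substr(text, i + 1L, i + j - 1L)
      tokens <- c(tokens, list(list(type = "label", value = label)))
      i <- i + j + 1L
      next
    }
    m <- regexpr("^[A-Za-z0-9_:.\\-]+", substr(text, i, n))
    if (m < 0) abort(paste0("syntax error at position ", i, ": unexpected '", ch, "'"))
    word <- regmatches(substr(text, i, n), m)
    type <- if (tolower(word) == "or") "or"
            else if (tolower(word) == "some") "some"
            else if (word %in% ALL_RELATIONS) "relation"
            else if (word %in% c("and", "not")) {
              abort(paste0("unsupported construct '", word,
                           "': only unions and existential restrictions are supported"))
            }
            else "name"
    tokens <- c(tokens, list(list(type = type, value = word)))
    i <- i + attr(m, "match.length")
  }
  tokens
}

peek <- function(st) if (st$pos <= length(st$tokens)) st$tokens[[st$pos]] else NULL
advance <- function(st) { st$pos <- st$pos + 1L; st$tokens[[st$pos - 1L]] }
expect <- function(st, type) {
  tk <- peek(st)
  if (is.null(tk) || tk$type != type) {
    abort(paste0("syntax error at token ", st$pos, ": expected ", type,
                 if (!is.null(tk)) paste0(", got '", tk$value, "'") else ", got end of input"))
  }
  advance(st)
}

parse_union <- function(st) {
  atoms <- list(parse_atom(st))
  while (!is.null(peek(st)) && peek(st)$type == "or") {
    advance(st)
    atoms <- c(atoms, list(parse_atom(st)))
  }
  # flatten nested unions produced by parenthesized expressions
  flat <- list()
  for (a in atoms) {
    if (identical(a$type, "union")) flat <- c(flat, a$atoms) else flat <- c(flat, list(a))
  }
  structure(list(type = "union", atoms = flat), class = "class_expression")
}

parse_atom <- function(st) {
  tk <- peek(st)
  if (is.null(tk)) abort("syntax error: unexpected end of input")
  if (tk$type == "lparen") {
    advance(st)
    e <- parse_union(st)
    expect(st, "rparen")
    return(e)
  }
  if (tk$type == "relation") {
    advance(st)
    expect(st, "some")
    expect(st, "lparen")
    filler <- parse_union(st)
    expect(st, "rparen")
    return(list(type = "some", relation = tk$value, filler = filler))
  }
  if (tk$type %in% c("name", "label")) {
    advance(st)
    return(list(type = "named", name = tk$value, quoted = tk$type == "label"))
  }
  abort(paste0("syntax error at token ", st$pos, ": unexpected '", tk$value, "'"))
}

#' @export
format.class_expression <- function(x, ...) {
  fmt_atom <- function(a) {
    if (identical(a$type, "named")) {
      if (isTRUE(a$quoted)) paste0("'", a$name, "'") else a$name
    } else if (identical(a$type, "some")) {
      paste0(a$relation, " some (", fmt_union(a$filler), ")")
    } else {
      paste0("(", fmt_union(a), ")")
    }
  }
  fmt_union <- function(u) paste(vapply(u$atoms, fmt_atom, character(1)), collapse = " or ")
  fmt_union(x)
}

#' @export
print.class_expression <- function(x, ...) {
  cat("<class_expression> ", format(x), "\n", sep = "")
  invisible(x)
}

resolve_name <- function(o, atom) {
  if (!isTRUE(atom$quoted) && has_term(o, atom$name)) return(atom$name)
  hits <- o$terms$id[o$terms$label == atom$name]
  if (length(hits) == 1) return(hits)
  if (length(hits) == 0) {
    abort(paste0("cannot resolve '", atom$name, "' in ", o$namespace, " ontology"))
  }
  abort(paste0("ambiguous label '", atom$name, "': candidates ",
               paste(hits, collapse = ", ")))
}

#' Evaluate a class expression against an ontology
#'
#' A named class evaluates to its `is_a` descendants (every class is subsumed
#' by itself and its superclasses).  An existential restriction
#' `rel some (filler)` evaluates to every term with a chain of `is_a` and
#' `rel` edges, containing at least one `rel` edge, ending in the filler set:
#' a humerus is `part_of some` forelimb, but a forelimb is not `part_of some`
#' forelimb.  A union evaluates to the union of its atoms.
#'
#' @param o An `ontology`.
#' @param e A `class_expression` from [parse_class_expression()], or a string
#'   (parsed on the fly).
#' @return Sorted character vector of term ids subsumed by the expression.
#' @examples
#' o <- toy_fin_limb_ontology()
#' evaluate_class_expression(o, "part_of some (TOY:forelimb)")
#' @export
evaluate_class_expression <- function(o, e) {
  if (is.character(e)) e <- parse_class_expression(e)
  eval_union(o, e)
}

eval_union <- function(o, u) {
  stopifnot(identical(u$type, "union"))
  sort(unique(unlist(lapply(u$atoms, eval_atom, o = o))))
}

eval_atom <- function(o, a) {
  if (identical(a$type, "named")) {
    return(downward_closure(o, resolve_name(o, a), "is_a"))
  }
  if (identical(a$type, "some")) {
    filler <- eval_union(o, a$filler)
    # G: every term that reaches the filler set via {is_a, rel} chains
    g <- closure_set(o, filler, c("is_a", a$relation), "down")
    # A: terms with at least one rel edge landing inside G
    rel_edges <- o$adj$rev[[a$relation]]
    if (is.null(rel_edges)) return(character())
    a_set <- unique(unlist(rel_edges[intersect(names(rel_edges), g)], use.names = FALSE))
    # anything that reaches A via {is_a, rel} qualifies (prefix before the
    # witnessing rel edge may itself mix is_a and rel edges)
    closure_set(o, a_set, c("is_a", a$relation), "down")
  } else {
    eval_union(o, a)
  }
}
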