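## EL class expressions and axioms.
##
## Expressions are the three EL constructors: a concept name, a conjunction,
## and an existential restriction. They are plain lists with class "elExpr";
## structural identity is defined through a canonical key (exprKey), under
## which conjunction is flattened, de-duplicated and sorted, making it
## commutative, associative and idempotent by construction.

#' Concept name expression
#'
#' @param id Concept identifier (single character string).
#' @return An object of class \code{elExpr}.
#' @examples
#' elName("818983003")
#' @export
elName <- function(id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(kind = "name", id = id), class = "elExpr")
}

#' Existential restriction expression
#'
#' Builds the EL construct "role some filler".
#'
#' @param role Role (object property) identifier.
#' @param filler An \code{elExpr} or a concept id string.
#' @return An object of class \code{elExpr}.
#' @examples
#' elSome("all-or-part-of", "X-entire-liver")
#' @export
elSome <- function(role, filler) {
  stopifnot(is.character(role), length(role) == 1L, nzchar(role))
  filler <- as.elExpr(filler)
  structure(list(kind = "some", role = role, filler = filler),
            class = "elExpr")
}

#' Conjunction expression
#'
#' Builds the EL conjunction of two or more expressions. Nested conjunctions
#' are flattened and the conjuncts stored sorted by canonical key, so that
#' conjunction is order-insensitive. A conjunction of one distinct conjunct
#' collapses to that conjunct.
#'
#' @param ... Expressions (\code{elExpr} or concept id strings).
#' @return An object of class \code{elExpr}.
#' @examples
#' elAnd("X-disorder-root", elSome("finding-site", "X-liver-S"))
#' @export
elAnd <- function(...) {
  args <- lapply(list(...), as.elExpr)
  if (length(args) == 0L)
    stop("a conjunction needs at least one conjunct")
  flat <- list()
  for (a in args) {
    if (a$kind == "and") flat <- c(flat, a$args) else flat <- c(flat, list(a))
  }
  keys <- vapply(flat, exprKey, character(1))
  flat <- flat[.orderC(keys)][!duplicated(.sortC(keys))]
  if (length(flat) == 1L) return(flat[[1L]])
  structure(list(kind = "and", args = flat), class = "elExpr")
}

#' @rdname elName
#' @param x Object to coerce: an \code{elExpr} is returned unchanged, a
#'   character id becomes a name expression.
#' @export
as.elExpr <- function(x) {
  if (inherits(x, "elExpr")) return(x)
  if (is.character(x) && length(x) == 1L) return(elName(x))
  stop("cannot interpret object of class '", paste(class(x), collapse = "/"),
       "' as an EL expression")
}

#' Canonical key of an expression
#'
#' The key is a deterministic string serialisation under which two
#' expressions are structurally equal iff their keys are identical.
#'
#' @param e An \code{elExpr}.
#' @return A character string.
#' @export
exprKey <- function(e) {
  switch(e$kind,
    name = e$id,
    some = paste0("some(", e$role, ",", exprKey(e$filler), ")"),
    and  = paste0("and(",
                  paste(vapply(e$args, exprKey, character(1)), collapse = ","),
                  ")"),
    stop("unknown expression kind: ", e$kind))
}

#' Structural equality of expressions
#'
#' @param a,b \code{elExpr} objects.
#' @return Logical scalar.
#' @export
exprEqual <- function(a, b) identical(exprKey(a), exprKey(b))

## Ids of all concept names / roles mentioned in an expression.
exprConceptIds <- function(e) {
  switch(e$kind,
    name = e$id,
    some = exprConceptIds(e$filler),
    and  = unique(unlist(lapply(e$args, exprConceptIds))))
}

exprRoleIds <- function(e) {
  switch(e$kind,
    name = character(0),
    some = unique(c(e$role, exprRoleIds(e$filler))),
    and  = unique(unlist(lapply(e$args, exprRoleIds))))
}

#' @export
print.elExpr <- function(x, ...) {
  cat("<EL expression> ", exprKey(x), "\n", sep = "")
  invisible(x)
}

#' SubClassOf axiom
#'
#' @param sub,sup Expressions (\code{elExpr} or concept id strings).
#' @return An object of class \code{elAxiom}.
#' @examples
#' subClassOf("X-entire-lobe-of-liver",
#'            elSome("regional-part-of", "X-entire-liver"))
#' @export
subClassOf <- function(sub, sup) {
  structure(list(kind = "subclass", left = as.elExpr(sub),
                 right = as.elExpr(sup)),
            class = "elAxiom")
}

#' EquivalentClasses axiom
#'
#' The left side must be a concept name (the name-equals-definition form).
#'
#' @param name Concept id string or name expression.
#' @param definition The defining expression.
#' @return An object of class \code{elAxiom}.
#' @examples
#' equivalentClasses("X-liver-S", elSome("all-or-part-of", "X-entire-liver"))
#' @export
equivalentClasses <- function(name, definition) {
  left <- as.elExpr(name)
  if (left$kind != "name")
    stop("the left side of an EquivalentClasses axiom must be a concept name")
  structure(list(kind = "equivalent", left = left,
                 right = as.elExpr(definition)),
            class = "elAxiom")
}

#' Canonical key of an axiom
#'
#' @param ax An \code{elAxiom}.
#' @return A character string; identical keys mean structurally equal axioms.
#' @export
axiomKey <- function(ax) {
  paste0(ax$kind, "[", exprKey(ax$left), "|", exprKey(ax$right), "]")
}

#' @export
print.elAxiom <- function(x, ...) {
  op <- if (x$kind == "subclass") "SubClassOf" else "EquivalentClasses"
  cat("<EL axiom> ", op, "(", exprKey(x$left), ", ", exprKey(x$right), ")\n",
      sep = "")
  invisible(x)
}
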