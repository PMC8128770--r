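## Normalization of an EL ontology into the four normal-form rule shapes
##
##   sub  : A is-a B
##   conj : A1 and A2 is-a B
##   exR  : A is-a (r some B)
##   exL  : (r some A) is-a B
##
## with A, B named concepts, possibly fresh. Fresh names are a
## deterministic function of the (canonical) expression they stand for:
## "N-" followed by the expression key. The "N-" prefix is reserved and
## rejected for declared ids, so fresh names can never collide. The
## transformation is polarity-aware and entailment-preserving over the
## declared names: equivalences split into two inclusions, right-hand
## sides are expanded recursively, left-hand complex expressions are named
## bottom-up, and n-ary conjunctions fold into binary conjunction rules.

.freshPrefix <- "N-"

.isFresh <- function(id) startsWith(id, .freshPrefix)

#' Normalize an ontology to EL normal form
#'
#' @param ont An \code{\linkS4class{Ontology}}.
#' @return A list with \code{rules} (the normal-form rules, each a list
#'   with a \code{type} field among sub/conj/exR/exL) and \code{names}
#'   (the concept-name universe: every declared id plus the fresh names
#'   introduced).
#' @examples
#' ont <- addPartonomyRoles(emptyOntology())
#' ont <- makeSEPTriplet(ont, "liver")
#' length(normalizeOntology(ont)$rules)
#' @export
normalizeOntology <- function(ont) {
  rules <- list()
  fresh <- character(0)
  emit <- function(rule) rules[[length(rules) + 1L]] <<- rule
  newFresh <- function(key) {
    nm <- paste0(.freshPrefix, key)
    fresh[nm] <<- nm
    nm
  }
  expandedRight <- character(0)

  ## Name a left-position expression bottom-up; the returned name N
  ## carries rules ensuring e is-a N is derivable wherever e holds.
  nameOfLeft <- function(e) {
    switch(e$kind,
      name = e$id,
      some = {
        f <- nameOfLeft(e$filler)
        nm <- newFresh(paste0("some(", e$role, ",", f, ")"))
        emit(list(type = "exL", r = e$role, a = f, b = nm))
        nm
      },
      and = foldConj(.sortC(vapply(e$args, nameOfLeft, character(1))),
                     target = NULL))
  }

  ## Fold named conjuncts into binary conj rules; if target is given the
  ## last rule lands on it, otherwise a fresh name is returned.
  foldConj <- function(parts, target) {
    k <- length(parts)
    if (k == 1L) {
      if (is.null(target)) return(parts)
      emit(list(type = "sub", a = parts, b = target))
      return(target)
    }
    acc <- parts[1L]
    for (i in 2:k) {
      tgt <- if (i == k && !is.null(target)) target
             else newFresh(paste0("and(", acc, ",", parts[i], ")"))
      emit(list(type = "conj", a1 = acc, a2 = parts[i], b = tgt))
      acc <- tgt
    }
    acc
  }

  ## Emit rules deriving b is-a e for a named b and arbitrary e.
  expandRight <- function(b, e) {
    switch(e$kind,
      name = emit(list(type = "sub", a = b, b = e$id)),
      and  = for (arg in e$args) expandRight(b, arg),
      some = {
        f <- e$filler
        if (f$kind == "name") {
          emit(list(type = "exR", a = b, r = e$role, b = f$id))
        } else {
          nm <- newFresh(exprKey(f))
          if (!nm %in% expandedRight) {
            expandedRight <<- c(expandedRight, nm)
            expandRight(nm, f)
          }
          emit(list(type = "exR", a = b, r = e$role, b = nm))
        }
      })
    invisible(NULL)
  }

  normInclusion <- function(L, R) {
    if (L$kind == "name") {
      expandRight(L$id, R)
    } else if (R$kind == "name") {
      switch(L$kind,
        and  = foldConj(.sortC(vapply(L$args, nameOfLeft, character(1))),
                        target = R$id),
        some = {
          f <- nameOfLeft(L$filler)
          emit(list(type = "exL", r = L$role, a = f, b = R$id))
        })
    } else {
      nm <- nameOfLeft(L)
      expandRight(nm, R)
    }
  }

  for (ax in axioms(ont)) {
    normInclusion(ax$left, ax$right)
    if (ax$kind == "equivalent") normInclusion(ax$right, ax$left)
  }
  ## drop structurally duplicated rules (deterministic order retained)
  if (length(rules)) {
    keys <- vapply(rules, function(r) paste(unlist(r), collapse = "\r"),
                   character(1))
    rules <- rules[!duplicated(keys)]
  }
  list(rules = rules,
       names = c(.sortC(names(ont@concepts)), .sortC(unname(fresh))))
}
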