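## EL completion-rule saturation and taxonomy construction.
##
## The saturation computes, for the normalized rule set, the least
## fixpoint of the standard EL completion rules:
##   - inclusion rule        (A in S(X), A is-a B           => B in S(X))
##   - conjunction rule      (A1, A2 in S(X), A1^A2 is-a B  => B in S(X))
##   - existential intro     (A in S(X), A is-a r some B    => (X,B) in R(r))
##   - existential-on-left   ((X,Y) in R(r), A in S(Y),
##                            r some A is-a B               => B in S(X))
##   - role hierarchy        ((X,Y) in R(r), r sub s        => (X,Y) in R(s))
##   - role chain            ((X,Y) in R(r1), (Y,Z) in R(r2),
##                            r1 o r2 sub s                 => (X,Z) in R(s))
## Transitivity of a role r is encoded as the chain r o r sub s with
## s = r. The subsumption state is held in logical matrices (S for
## concept membership, one matrix per role for the role relations), so a
## full pass over the rules is a handful of vectorised operations; passes
## repeat until the fixpoint. The procedure is polynomial in the input
## and terminates because the state only grows and is bounded.

.saturate <- function(norm, roles, chains) {
  nms <- norm$names
  n <- length(nms)
  idx <- seq_len(n)
  names(idx) <- nms
  S <- diag(TRUE, n)
  rids <- names(roles)
  R <- lapply(rids, function(r) matrix(FALSE, n, n))
  names(R) <- rids

  ## effective chain set: declared chains plus r o r -> r for transitive r
  chainTab <- lapply(chains, function(ch) c(ch$lhs, ch$rhs))
  for (r in roles)
    if (isTRUE(r$transitive)) chainTab <- c(chainTab, list(c(r$id, r$id,
                                                             r$id)))
  if (length(chainTab))
    chainTab <- unique(chainTab)
  ## role hierarchy edges child -> parent
  hierTab <- Filter(Negate(is.null), lapply(roles, function(r)
    if (!is.na(r$parent)) c(r$id, r$parent)))

  byType <- split(norm$rules,
                  vapply(norm$rules, `[[`, character(1), "type"))
  subA  <- idx[vapply(byType$sub,  `[[`, character(1), "a")]
  subB  <- idx[vapply(byType$sub,  `[[`, character(1), "b")]
  cjA1  <- idx[vapply(byType$conj, `[[`, character(1), "a1")]
  cjA2  <- idx[vapply(byType$conj, `[[`, character(1), "a2")]
  cjB   <- idx[vapply(byType$conj, `[[`, character(1), "b")]
  exRA  <- idx[vapply(byType$exR,  `[[`, character(1), "a")]
  exRr  <- vapply(byType$exR, `[[`, character(1), "r")
  exRB  <- idx[vapply(byType$exR,  `[[`, character(1), "b")]
  exLr  <- vapply(byType$exL, `[[`, character(1), "r")
  exLA  <- idx[vapply(byType$exL,  `[[`, character(1), "a")]
  exLB  <- idx[vapply(byType$exL,  `[[`, character(1), "b")]

  size <- function() sum(S) + sum(vapply(R, sum, numeric(1)))
  repeat {
    before <- size()
    for (k in seq_along(subA))
      S[, subB[k]] <- S[, subB[k]] | S[, subA[k]]
    for (k in seq_along(cjB))
      S[, cjB[k]] <- S[, cjB[k]] | (S[, cjA1[k]] & S[, cjA2[k]])
    for (k in seq_along(exRA))
      R[[exRr[k]]][, exRB[k]] <- R[[exRr[k]]][, exRB[k]] | S[, exRA[k]]
    for (k in seq_along(exLA))
      S[, exLB[k]] <- S[, exLB[k]] |
        (R[[exLr[k]]] %*% S[, exLA[k], drop = FALSE] > 0)
    for (h in hierTab)
      R[[h[2L]]] <- R[[h[2L]]] | R[[h[1L]]]
    for (ch in chainTab)
      R[[ch[3L]]] <- R[[ch[3L]]] | (R[[ch[1L]]] %*% R[[ch[2L]]] > 0)
    if (size() == before) break
  }
  dimnames(S) <- list(nms, nms)
  S
}

#' Classify an ontology
#'
#' Normalizes the ontology, saturates the EL completion rules, restricts
#' the subsumption closure to the declared (non-fresh) concepts, groups
#' mutually subsuming concepts into equivalence classes (represented by
#' their lexicographically least id), and transitively reduces the
#' resulting partial order into a direct-parent map. Output ordering is
#' deterministic: ids are sorted lexicographically throughout.
#'
#' @param ont An \code{\linkS4class{Ontology}}.
#' @return A \code{\linkS4class{Taxonomy}}.
#' @examples
#' ont <- addPartonomyRoles(emptyOntology())
#' ont <- makeSEPTriplet(ont, "liver")
#' tax <- classify(ont)
#' entails(tax, sepTriplet(ont, "liver")$entire,
#'         sepTriplet(ont, "liver")$structure)
#' @export
classify <- function(ont) {
  validateOntology(ont)
  ids <- conceptIds(ont)
  norm <- normalizeOntology(ont)
  S <- .saturate(norm, ont@roles, ont@chains)
  closure <- S[ids, ids, drop = FALSE]

  ## equivalence classes: mutual subsumption; representative = least id
  mutual <- closure & t(closure)
  rep <- vapply(seq_along(ids),
                function(i) ids[which(mutual[i, ])[1L]], character(1))
  names(rep) <- ids
  eqs <- split(ids, rep)
  eqs <- eqs[.sortC(names(eqs))]

  reps <- .sortC(unique(rep))
  Cs <- closure[reps, reps, drop = FALSE]
  diag(Cs) <- FALSE
  red <- Cs & !((Cs %*% Cs) > 0)
  direct <- lapply(seq_along(reps),
                   function(i) reps[red[i, ]])
  names(direct) <- reps

  recs <- ont@concepts[ids]
  new("Taxonomy", concepts = ids, closure = closure, direct = direct,
      equivalences = eqs, representative = rep,
      semanticClass = vapply(recs, `[[`, character(1), "semanticClass"),
      fsn = vapply(recs, `[[`, character(1), "fsn"))
}

#' Subsumption query
#'
#' \code{entails(x, sub, super)} is \code{TRUE} iff the pair is in the
#' classified subsumption closure (reflexive: every concept entails
#' itself).
#'
#' @param x A \code{\linkS4class{Taxonomy}}, or an
#'   \code{\linkS4class{Ontology}} (classified on the fly).
#' @param sub,super Declared concept ids.
#' @return Logical scalar.
#' @export
setGeneric("entails", function(x, sub, super) standardGeneric("entails"))

#' @rdname entails
#' @export
setMethod("entails", "Taxonomy", function(x, sub, super) {
  for (id in c(sub, super))
    if (!id %in% x@concepts) stop("unknown concept id: '", id, "'")
  unname(x@closure[sub, super])
})

#' @rdname entails
#' @export
setMethod("entails", "Ontology", function(x, sub, super) {
  entails(classify(x), sub, super)
})

#' Taxonomy accessors
#'
#' @param tax A \code{\linkS4class{Taxonomy}}.
#' @param id A declared concept id.
#' @return \code{ancestors}/\code{descendants}: sorted character vectors
#'   of strict ancestors or descendants; \code{directParents}: the direct
#'   parent representatives of the concept's equivalence class;
#'   \code{closurePairs}: a two-column character matrix of all
#'   non-reflexive (sub, super) pairs in deterministic order;
#'   \code{equivalenceClasses}: the list of mutually subsuming groups.
#' @export
ancestors <- function(tax, id) {
  if (!id %in% tax@concepts) stop("unknown concept id: '", id, "'")
  setdiff(tax@concepts[tax@closure[id, ]], id)
}

#' @rdname ancestors
#' @export
descendants <- function(tax, id) {
  if (!id %in% tax@concepts) stop("unknown concept id: '", id, "'")
  setdiff(tax@concepts[tax@closure[, id]], id)
}

#' @rdname ancestors
#' @export
directParents <- function(tax, id) {
  if (!id %in% tax@concepts) stop("unknown concept id: '", id, "'")
  tax@direct[[tax@representative[[id]]]]
}

#' @rdname ancestors
#' @export
closurePairs <- function(tax) {
  cl <- tax@closure
  diag(cl) <- FALSE
  w <- which(cl, arr.ind = TRUE)
  m <- cbind(sub = tax@concepts[w[, 1L]], super = tax@concepts[w[, 2L]])
  m[.orderC(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' @rdname ancestors
#' @export
equivalenceClasses <- function(tax) tax@equivalences

#' Re-close the direct-parent map
#'
#' Reconstructs the full subsumption closure from the transitively
#' reduced direct-parent DAG together with the equivalence classes: the
#' round trip \code{directClosure(classify(ont))} must reproduce
#' \code{classify(ont)}'s closure exactly.
#'
#' @param tax A \code{\linkS4class{Taxonomy}}.
#' @return A logical closure matrix with the same dimnames as
#'   \code{tax@closure}.
#' @export
directClosure <- function(tax) {
  reps <- .sortC(unique(tax@representative))
  k <- length(reps)
  A <- matrix(FALSE, k, k, dimnames = list(reps, reps))
  for (r in reps)
    A[r, tax@direct[[r]]] <- TRUE
  ## Warshall closure over representatives
  for (m in seq_len(k))
    A <- A | (A[, m] %o% A[m, ])
  diag(A) <- TRUE
  ids <- tax@concepts
  out <- A[tax@representative[ids], tax@representative[ids], drop = FALSE]
  dimnames(out) <- list(ids, ids)
  out
}

setMethod("show", "Taxonomy", function(object) {
  n <- length(object@concepts)
  cl <- object@closure
  diag(cl) <- FALSE
  cat("Taxonomy over", n, "concepts\n")
  cat("  subsumption pairs (strict):", sum(cl), "\n")
  cat("  equivalence classes:", length(object@equivalences), "\n")
  roots <- names(Filter(function(p) length(p) == 0L, object@direct))
  cat("  roots:", length(roots), "\n")
  invisible(NULL)
})
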