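## Seeded random EL ontology generation and an independent naive
## entailment oracle.
##
## The generator is used for property testing the classifier; the oracle
## is a deliberately slow, unindexed brute-force fixpoint that shares no
## code with the normalization or saturation machinery in
## normalize.R/reasoner.R: it performs its own (equivalence-style,
## n-ary) naming of complex subexpressions and re-scans every rule
## against every concept until nothing changes.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generator configuration
#'
#' @param nConcepts,nRoles,nAxioms Positive counts.
#' @param pExistential,pConjunction Probabilities in [0, 1] that a
#'   generated (sub)expression is an existential restriction or a
#'   conjunction; their sum must not exceed 1. With
#'   \code{pExistential = 0} the output is a propositional-Horn ontology
#'   of names and conjunctions.
#' @param maxDepth Expression nesting bound (0 = names only).
#' @param transitiveFraction Probability that a generated role is
#'   transitive.
#' @param seed Integer seed; the same configuration and seed always
#'   produce the identical ontology.
#' @return A validated configuration list for \code{\link{randomELOntology}}.
#' @export
genConfig <- function(nConcepts = 8L, nRoles = 2L, nAxioms = 12L,
                      pExistential = 0.4, pConjunction = 0.3,
                      maxDepth = 2L, transitiveFraction = 0.5,
                      seed = 1L) {
  stopifnot(nConcepts >= 1L, nRoles >= 0L, nAxioms >= 0L, maxDepth >= 0L)
  for (p in c(pExistential, pConjunction, transitiveFraction))
    if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)
      stop("probabilities must be single numbers in [0, 1]")
  if (pExistential + pConjunction > 1)
    stop("pExistential + pConjunction must not exceed 1")
  list(nConcepts = as.integer(nConcepts), nRoles = as.integer(nRoles),
       nAxioms = as.integer(nAxioms), pExistential = pExistential,
       pConjunction = pConjunction, maxDepth = as.integer(maxDepth),
       transitiveFraction = transitiveFraction, seed = as.integer(seed))
}

#' Generate a seeded random EL ontology
#'
#' @param cfg A configuration from \code{\link{genConfig}}, or the seed
#'   may be supplied directly through \code{...} arguments forwarded to
#'   \code{genConfig}.
#' @param ... Passed to \code{\link{genConfig}} when \code{cfg} is
#'   missing.
#' @return A valid \code{\linkS4class{Ontology}} within the configured
#'   bounds.
#' @examples
#' ont <- randomELOntology(genConfig(nConcepts = 6, seed = 42))
#' length(conceptIds(ont))
#' @export
randomELOntology <- function(cfg = genConfig(...), ...) {
  .withSeed(cfg$seed, {
    cids <- sprintf("X-C%02d", seq_len(cfg$nConcepts))
    rids <- if (cfg$nRoles) sprintf("X-r%d", seq_len(cfg$nRoles))
            else character(0)
    ont <- emptyOntology()
    roleParent <- rep(NA_character_, cfg$nRoles)
    for (i in seq_len(cfg$nRoles)) {
      parent <- NA_character_
      if (i > 1L && runif(1) < 0.4)
        parent <- rids[sample.int(i - 1L, 1L)]
      roleParent[i] <- parent
      ont <- addRole(ont, rids[i], parent = parent,
                     transitive = runif(1) < cfg$transitiveFraction)
    }
    ## an occasional regular chain r1 o r2 -> r1 to exercise the chain rule
    if (cfg$nRoles >= 2L && runif(1) < 0.5) {
      pair <- sample(rids, 2L)
      ont <- addChain(ont, c(pair[1L], pair[2L]), pair[1L])
    }
    randExpr <- function(depth) {
      u <- runif(1)
      if (depth > 0L && cfg$nRoles > 0L && u < cfg$pExistential) {
        elSome(sample(rids, 1L), randExpr(depth - 1L))
      } else if (depth > 0L && u < cfg$pExistential + cfg$pConjunction) {
        elAnd(randExpr(depth - 1L), randExpr(depth - 1L))
      } else {
        elName(sample(cids, 1L))
      }
    }
    axs <- list()
    defined <- character(0)
    for (i in seq_len(cfg$nAxioms)) {
      if (runif(1) < 0.25) {
        nm <- sample(cids, 1L)
        if (nm %in% defined) next
        rhs <- randExpr(cfg$maxDepth)
        if (rhs$kind == "name" && rhs$id == nm) next
        defined <- c(defined, nm)
        axs <- c(axs, list(equivalentClasses(nm, rhs)))
      } else {
        axs <- c(axs, list(subClassOf(randExpr(cfg$maxDepth),
                                      randExpr(cfg$maxDepth))))
      }
    }
    for (id in cids)
      ont <- addConcept(ont, conceptRef(id, primitive = !id %in% defined))
    for (ax in axs) ont <- addAxiom(ont, ax)
    validateOntology(ont)
    ont
  })
}

## ---- independent naive oracle -------------------------------------------

.oracleName <- function(e) {
  if (e$kind == "name") e$id else paste0("Q-", exprKey(e))
}

.oracleCollect <- function(e, acc) {
  if (e$kind != "name") {
    acc[[.oracleName(e)]] <- e
    inner <- if (e$kind == "some") list(e$filler) else e$args
    for (x in inner) acc <- .oracleCollect(x, acc)
  }
  acc
}

#' Naive brute-force subsumption closure (oracle)
#'
#' An independent witness for \code{\link{classify}}: every complex
#' subexpression is given a definitional name, and the resulting rules
#' are applied by exhaustively re-scanning all rules against all concepts
#' and all role pairs until a full pass adds nothing. No indexing, no
#' normalization sharing with the classifier. Guarded to small
#' ontologies since the point is correctness, not speed.
#'
#' @param ont An \code{\linkS4class{Ontology}}.
#' @param guard Maximum number of declared concepts accepted.
#' @return A two-column character matrix of all strict (sub, super)
#'   pairs over declared concepts, ordered like
#'   \code{\link{closurePairs}}.
#' @export
naiveClosure <- function(ont, guard = 15L) {
  if (length(ont@concepts) > guard)
    stop("oracle size guard exceeded: ", length(ont@concepts),
         " concepts > ", guard)
  incl <- list()
  for (ax in axioms(ont)) {
    incl <- c(incl, list(list(l = ax$left, r = ax$right)))
    if (ax$kind == "equivalent")
      incl <- c(incl, list(list(l = ax$right, r = ax$left)))
  }
  subex <- list()
  for (p in incl) {
    subex <- .oracleCollect(p$l, subex)
    subex <- .oracleCollect(p$r, subex)
  }
  universe <- .sortC(c(names(ont@concepts), names(subex)))
  subRules <- lapply(incl, function(p)
    c(.oracleName(p$l), .oracleName(p$r)))
  someDefs <- list()   # q <-> exists r . f
  andDefs <- list()    # q <-> intersection of parts
  for (q in names(subex)) {
    e <- subex[[q]]
    if (e$kind == "some")
      someDefs <- c(someDefs, list(list(q = q, r = e$role,
                                        f = .oracleName(e$filler))))
    else
      andDefs <- c(andDefs, list(list(q = q,
        parts = vapply(e$args, .oracleName, character(1)))))
  }
  S <- stats::setNames(as.list(universe), universe)  # reflexive start
  rids <- names(ont@roles)
  empty <- matrix(character(0), 0L, 2L)
  Rel <- stats::setNames(rep(list(empty), length(rids)), rids)
  addPair <- function(r, x, y) {
    m <- Rel[[r]]
    if (!any(m[, 1L] == x & m[, 2L] == y)) {
      Rel[[r]] <<- rbind(m, c(x, y))
      TRUE
    } else FALSE
  }
  roleParents <- function(r) {
    out <- character(0)
    cur <- ont@roles[[r]]$parent
    while (!is.na(cur)) { out <- c(out, cur); cur <- ont@roles[[cur]]$parent }
    out
  }
  parentsOf <- stats::setNames(lapply(rids, roleParents), rids)
  chainRules <- lapply(ont@chains, function(ch) c(ch$lhs, ch$rhs))
  for (r in rids)
    if (isTRUE(ont@roles[[r]]$transitive))
      chainRules <- c(chainRules, list(c(r, r, r)))

  repeat {
    changed <- FALSE
    for (x in universe) {
      sx <- S[[x]]
      for (rule in subRules)
        if (rule[1L] %in% sx && !rule[2L] %in% sx)
          sx <- c(sx, rule[2L])
      for (d in andDefs) {
        if (d$q %in% sx)
          for (p in d$parts) if (!p %in% sx) sx <- c(sx, p)
        if (all(d$parts %in% sx) && !d$q %in% sx) sx <- c(sx, d$q)
      }
      if (length(sx) != length(S[[x]])) { S[[x]] <- sx; changed <- TRUE }
      for (d in someDefs)
        if (d$q %in% sx)
          if (addPair(d$r, x, d$f)) changed <- TRUE
    }
    for (r in rids) {
      m <- Rel[[r]]
      for (k in seq_len(nrow(m))) {
        for (d in someDefs)
          if (d$r == r && d$f %in% S[[m[k, 2L]]] &&
              !d$q %in% S[[m[k, 1L]]]) {
            S[[m[k, 1L]]] <- c(S[[m[k, 1L]]], d$q)
            changed <- TRUE
          }
        for (p in parentsOf[[r]])
          if (addPair(p, m[k, 1L], m[k, 2L])) changed <- TRUE
      }
    }
    for (ch in chainRules) {
      m1 <- Rel[[ch[1L]]]
      for (k1 in seq_len(nrow(m1))) {
        m2 <- Rel[[ch[2L]]]
        for (k2 in seq_len(nrow(m2)))
          if (m1[k1, 2L] == m2[k2, 1L])
            if (addPair(ch[3L], m1[k1, 1L], m2[k2, 2L])) changed <- TRUE
      }
    }
    if (!changed) break
  }
  ids <- .sortC(names(ont@concepts))
  out <- NULL
  for (x in ids) {
    sup <- .sortC(intersect(setdiff(S[[x]], x), ids))
    if (length(sup))
      out <- rbind(out, cbind(sub = rep(x, length(sup)), super = sup))
  }
  if (is.null(out)) out <- cbind(sub = character(0), super = character(0))
  out
}

#' Naive entailment check (oracle)
#'
#' @param ont A small \code{\linkS4class{Ontology}} (see the size guard
#'   of \code{\link{naiveClosure}}).
#' @param sub,super Declared concept ids.
#' @param guard Passed to \code{\link{naiveClosure}}.
#' @return Logical scalar; reflexively \code{TRUE} for \code{sub ==
#'   super}.
#' @export
naiveEntails <- function(ont, sub, super, guard = 15L) {
  for (id in c(sub, super))
    if (!id %in% names(ont@concepts))
      stop("unknown concept id: '", id, "'")
  if (sub == super) return(TRUE)
  cl <- naiveClosure(ont, guard = guard)
  any(cl[, 1L] == sub & cl[, 2L] == super)
}
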