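#' @import methods
NULL

#' Ontology container
#'
#' An EL ontology: named concepts with their descriptions, roles (object
#' properties) with an acyclic hierarchy and transitivity flags, role chains,
#' and the stated SubClassOf / EquivalentClasses axioms. Objects are built
#' incrementally with \code{\link{emptyOntology}}, \code{\link{addConcept}},
#' \code{\link{addRole}}, \code{\link{addChain}} and \code{\link{addAxiom}};
#' assembly is order-independent.
#'
#' @slot concepts Named list of concept records (one per concept id), each a
#'   list with fields \code{id}, \code{fsn}, \code{preferred},
#'   \code{synonyms}, \code{primitive}, \code{semanticClass}.
#' @slot roles Named list of role records (\code{id}, \code{name},
#'   \code{parent}, \code{transitive}).
#' @slot chains List of role chains, each \code{list(lhs = c(r1, r2),
#'   rhs = s)} meaning r1 o r2 is a subproperty of s.
#' @slot axioms Named list of \code{elAxiom} objects, keyed by
#'   \code{\link{axiomKey}} (structural duplicates are impossible).
#' @slot seps Named list registering SEP triplets created by
#'   \code{\link{makeSEPTriplet}} (builder metadata; not serialised).
#' @export
setClass("Ontology",
  representation(concepts = "list", roles = "list", chains = "list",
                 axioms = "list", seps = "list"),
  prototype(concepts = list(), roles = list(), chains = list(),
            axioms = list(), seps = list()))

setValidity("Ontology", function(object) {
  msgs <- character(0)
  cids <- names(object@concepts)
  rids <- names(object@roles)
  if (anyDuplicated(cids))
    msgs <- c(msgs, "duplicate concept ids")
  if (anyDuplicated(rids))
    msgs <- c(msgs, "duplicate role ids")
  fsns <- vapply(object@concepts, function(x) x$fsn, character(1),
                 USE.NAMES = FALSE)
  if (anyDuplicated(fsns))
    msgs <- c(msgs, paste0("duplicate FSN: ",
                           paste(unique(fsns[duplicated(fsns)]),
                                 collapse = ", ")))
  ## role hierarchy must be acyclic
  for (r in object@roles) {
    seen <- character(0)
    cur <- r$id
    while (!is.na(cur)) {
      if (cur %in% seen) {
        msgs <- c(msgs, paste0("role hierarchy cycle through '", cur, "'"))
        break
      }
      seen <- c(seen, cur)
      p <- object@roles[[cur]]
      cur <- if (is.null(p)) NA_character_ else p$parent
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Classified taxonomy
#'
#' The result of \code{\link{classify}}: the full subsumption closure over
#' declared (non-fresh) concepts, the transitively reduced direct-parent
#' map over equivalence-class representatives, and the equivalence classes
#' of mutually subsuming concepts.
#'
#' @slot concepts Character vector of the declared concept ids, sorted.
#' @slot closure Logical matrix; \code{closure[sub, super]} is \code{TRUE}
#'   iff sub is subsumed by super. Reflexive and transitive.
#' @slot direct Named list mapping each equivalence-class representative to
#'   the character vector of its direct parent representatives.
#' @slot equivalences Named list mapping each representative (the
#'   lexicographically least member) to all ids in its class.
#' @slot representative Named character vector mapping every concept id to
#'   its equivalence-class representative.
#' @slot semanticClass Named character vector with each concept's semantic
#'   class (used by impact-diff filtering and reports).
#' @slot fsn Named character vector of fully specified names.
#' @export
setClass("Taxonomy",
  representation(concepts = "character", closure = "matrix",
                 direct = "list", equivalences = "list",
                 representative = "character",
                 semanticClass = "character", fsn = "character"))

setValidity("Taxonomy", function(object) {
  n <- length(object@concepts)
  cl <- object@closure
  if (!is.logical(cl) || nrow(cl) != n || ncol(cl) != n)
    return("closure must be an n x n logical matrix")
  if (n > 0L && !all(diag(cl)))
    return("closure must be reflexive")
  TRUE
})

#' Classification impact diff
#'
#' Subsumption pairs gained and lost between two taxonomies, optionally
#' restricted to concepts of given semantic classes. Produced by
#' \code{\link{diffTaxonomies}}; rendered by \code{\link{impactReport}}.
#'
#' @slot gained Two-column character matrix (sub, super) of pairs present
#'   only in the later taxonomy.
#' @slot lost Two-column character matrix of pairs present only in the
#'   earlier taxonomy.
#' @slot filter Character vector of semantic classes the diff was
#'   restricted to (length zero means unrestricted).
#' @slot fsn Named character vector of fully specified names for reporting.
#' @export
setClass("ImpactDiff",
  representation(gained = "matrix", lost = "matrix", filter = "character",
                 fsn = "character"))

setValidity("ImpactDiff", function(object) {
  g <- apply(object@gained, 1L, paste, collapse = "\r")
  l <- apply(object@lost, 1L, paste, collapse = "\r")
  if (length(intersect(g, l)))
    return("gained and lost pair sets must be disjoint")
  TRUE
})
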