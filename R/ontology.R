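## Ontology assembly and accessors.

.SEMANTIC_CLASSES <- c("entire", "part", "structure", "cavity", "wall",
                       "segment", "cross_section", "clinical_region",
                       "content", "disorder", "procedure", "other")

#' Create an empty ontology
#'
#' @return An \code{\linkS4class{Ontology}} with no concepts, roles, chains
#'   or axioms.
#' @examples
#' ont <- emptyOntology()
#' length(conceptIds(ont))
#' @export
emptyOntology <- function() new("Ontology")

#' Concept record constructor
#'
#' @param id Concept identifier (SNOMED CT SCTIDs where published; local
#'   ids carry the reserved \code{"X-"} prefix so they can never collide
#'   with SCTIDs).
#' @param fsn Fully specified name, including the semantic-tag suffix,
#'   e.g. \code{"Liver structure (body structure)"}. Defaults to
#'   \code{preferred} plus \code{" (body structure)"}.
#' @param preferred Preferred term.
#' @param synonyms Character vector of additional synonyms.
#' @param primitive \code{TRUE} for SubClassOf-only (primitive) concepts,
#'   \code{FALSE} for fully defined concepts, which must carry exactly one
#'   EquivalentClasses axiom.
#' @param semanticClass One of the semantic classes used by the trunk
#'   model: entire, part, structure, cavity, wall, segment, cross_section,
#'   clinical_region, content, disorder, procedure, other.
#' @return A concept record (plain list) accepted by \code{\link{addConcept}}.
#' @export
conceptRef <- function(id, preferred = id,
                       fsn = paste0(preferred, " (body structure)"),
                       synonyms = character(0), primitive = TRUE,
                       semanticClass = "other") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(fsn), length(fsn) == 1L,
            is.character(preferred), length(preferred) == 1L,
            is.logical(primitive), length(primitive) == 1L)
  semanticClass <- match.arg(semanticClass, .SEMANTIC_CLASSES)
  list(id = id, fsn = fsn, preferred = preferred,
       synonyms = as.character(synonyms), primitive = primitive,
       semanticClass = semanticClass)
}

#' Add a concept to an ontology
#'
#' Rejects duplicate ids and duplicate FSNs. The single-allocation synonym
#' policy is enforced for the bare term \code{"Abdomen"}: at most one
#' concept per ontology may carry it as preferred term, and a violation
#' names both offending concepts.
#'
#' @param ont An \code{\linkS4class{Ontology}}.
#' @param concept A record from \code{\link{conceptRef}} (or an id string
#'   for a default primitive concept).
#' @return The updated ontology.
#' @examples
#' ont <- addConcept(emptyOntology(),
#'   conceptRef("818983003", preferred = "Abdomen",
#'     fsn = paste0("Structure of abdominopelvic cavity and/or content of ",
#'                  "abdominopelvic cavity and/or anterior abdominal wall ",
#'                  "(body structure)"),
#'     semanticClass = "clinical_region"))
#' @export
addConcept <- function(ont, concept) {
  if (is.character(concept)) concept <- conceptRef(concept)
  stopifnot(is(ont, "Ontology"))
  id <- concept$id
  if (startsWith(id, "N-"))
    stop("concept ids may not start with 'N-' (reserved for ",
         "normalization fresh names): '", id, "'")
  if (id %in% names(ont@concepts))
    stop("duplicate concept id: '", id, "' is already declared")
  if (id %in% names(ont@roles))
    stop("id '", id, "' is already declared as a role")
  fsns <- vapply(ont@concepts, function(x) x$fsn, character(1),
                 USE.NAMES = FALSE)
  if (concept$fsn %in% fsns)
    stop("duplicate FSN: '", concept$fsn, "'")
  if (identical(concept$preferred, "Abdomen")) {
    prev <- Filter(function(x) identical(x$preferred, "Abdomen"),
                   ont@concepts)
    if (length(prev))
      stop("the preferred term 'Abdomen' is restricted to a single ",
           "concept: already carried by '", prev[[1L]]$id,
           "', also requested for '", id, "'")
  }
  ont@concepts[[id]] <- concept
  validObject(ont)
  ont
}

#' Add a role (object property) to an ontology
#'
#' @param ont An \code{\linkS4class{Ontology}}.
#' @param id Role identifier.
#' @param name Display name (defaults to the id).
#' @param parent Optional parent role id (must already be declared).
#' @param transitive Whether the role is transitive; transitivity is
#'   realised at classification time as the chain r o r -> r.
#' @return The updated ontology.
#' @export
addRole <- function(ont, id, name = id, parent = NA_character_,
                    transitive = FALSE) {
  stopifnot(is(ont, "Ontology"), is.character(id), length(id) == 1L)
  if (id %in% names(ont@roles))
    stop("duplicate role id: '", id, "'")
  if (id %in% names(ont@concepts))
    stop("id '", id, "' is already declared as a concept")
  if (!is.na(parent) && !parent %in% names(ont@roles))
    stop("undeclared parent role: '", parent, "'")
  ont@roles[[id]] <- list(id = id, name = name, parent = parent,
                          transitive = isTRUE(transitive))
  validObject(ont)
  ont
}

#' Add a role chain to an ontology
#'
#' Declares the inclusion \code{lhs[1] o lhs[2]} into \code{rhs}. Chains
#' must be regular in the EL sense: the right-hand role has to occur in the
#' chain itself (as for transitivity r o r -> r) or be a strict super-role
#' of both chain components, which rules out cyclic chain dependencies.
#'
#' @param ont An \code{\linkS4class{Ontology}}.
#' @param lhs Character vector of two declared role ids.
#' @param rhs A declared role id.
#' @return The updated ontology.
#' @export
addChain <- function(ont, lhs, rhs) {
  stopifnot(is(ont, "Ontology"), length(lhs) == 2L, length(rhs) == 1L)
  for (r in c(lhs, rhs))
    if (!r %in% names(ont@roles))
      stop("undeclared role in chain: '", r, "'")
  if (!rhs %in% lhs) {
    sup <- function(r) {
      out <- character(0)
      while (!is.na(r)) { out <- c(out, r); r <- ont@roles[[r]]$parent }
      out
    }
    if (!(rhs %in% sup(lhs[1L]) && rhs %in% sup(lhs[2L])))
      stop("irregular role chain: '", rhs,
           "' is neither a chain component nor a common super-role")
  }
  key <- paste(lhs[1L], lhs[2L], rhs, sep = "|")
  keys <- vapply(ont@chains,
                 function(ch) paste(ch$lhs[1L], ch$lhs[2L], ch$rhs,
                                    sep = "|"),
                 character(1))
  if (!key %in% keys)
    ont@chains <- c(ont@chains, list(list(lhs = lhs, rhs = rhs)))
  ont
}

#' Add an axiom to an ontology
#'
#' Every concept and role id referenced by the axiom must already be
#' declared. Adding a structural duplicate is a silent no-op, so axiom
#' addition is idempotent.
#'
#' @param ont An \code{\linkS4class{Ontology}}.
#' @param axiom An \code{elAxiom} from \code{\link{subClassOf}} or
#'   \code{\link{equivalentClasses}}.
#' @return The updated ontology.
#' @export
addAxiom <- function(ont, axiom) {
  stopifnot(is(ont, "Ontology"), inherits(axiom, "elAxiom"))
  cids <- unique(c(exprConceptIds(axiom$left), exprConceptIds(axiom$right)))
  rids <- unique(c(exprRoleIds(axiom$left), exprRoleIds(axiom$right)))
  missingC <- setdiff(cids, names(ont@concepts))
  if (length(missingC))
    stop("axiom references undeclared concept id: '", missingC[1L], "'")
  missingR <- setdiff(rids, names(ont@roles))
  if (length(missingR))
    stop("axiom references undeclared role id: '", missingR[1L], "'")
  key <- axiomKey(axiom)
  if (!key %in% names(ont@axioms))
    ont@axioms[[key]] <- axiom
  ont
}

#' Remove an axiom from an ontology
#'
#' Used by the impact-QA workflow to script "what if this statement were
#' dropped" edits. Removing an axiom that is not present is a no-op.
#'
#' @param ont An \code{\linkS4class{Ontology}}.
#' @param axiom An \code{elAxiom}.
#' @return The updated ontology.
#' @export
removeAxiom <- function(ont, axiom) {
  stopifnot(is(ont, "Ontology"), inherits(axiom, "elAxiom"))
  key <- axiomKey(axiom)
  ont@axioms[[key]] <- NULL
  ont
}

#' @describeIn emptyOntology Ids of all declared concepts (sorted).
#' @param ont An \code{\linkS4class{Ontology}}.
#' @export
conceptIds <- function(ont) .sortC(names(ont@concepts))

#' Concept metadata table
#'
#' @param ont An \code{\linkS4class{Ontology}}.
#' @return A data.frame with one row per concept (sorted by id): id, fsn,
#'   preferred term, pipe-separated synonyms, primitive flag and semantic
#'   class.
#' @export
conceptTable <- function(ont) {
  ids <- conceptIds(ont)
  recs <- ont@concepts[ids]
  data.frame(
    id = ids,
    fsn = vapply(recs, `[[`, character(1), "fsn"),
    preferred = vapply(recs, `[[`, character(1), "preferred"),
    synonyms = vapply(recs, function(x) paste(x$synonyms, collapse = "|"),
                      character(1)),
    primitive = vapply(recs, `[[`, logical(1), "primitive"),
    semanticClass = vapply(recs, `[[`, character(1), "semanticClass"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Look up a concept record
#'
#' @param ont An \code{\linkS4class{Ontology}}.
#' @param id Concept id.
#' @return The concept record list, or an error for unknown ids.
#' @export
getConcept <- function(ont, id) {
  rec <- ont@concepts[[id]]
  if (is.null(rec)) stop("unknown concept id: '", id, "'")
  rec
}

#' @describeIn emptyOntology Ids of all declared roles (sorted).
#' @export
roleIds <- function(ont) .sortC(names(ont@roles))

#' @describeIn emptyOntology The list of stated axioms, in sorted key order.
#' @export
axioms <- function(ont) {
  if (!length(ont@axioms)) return(list())
  ont@axioms[.orderC(names(ont@axioms))]
}

#' Full ontology invariant check
#'
#' Beyond the structural validity enforced at every assembly step, this
#' verifies the definition-status contract: a concept is non-primitive iff
#' it is the named left side of exactly one EquivalentClasses axiom.
#' Called by \code{\link{classify}} and the writers.
#'
#' @param ont An \code{\linkS4class{Ontology}}.
#' @return Invisibly \code{TRUE}, or an error describing the violation.
#' @export
validateOntology <- function(ont) {
  validObject(ont)
  defCount <- integer(0)
  for (ax in ont@axioms) {
    if (ax$kind == "equivalent") {
      id <- ax$left$id
      defCount[id] <- if (is.na(defCount[id])) 1L else defCount[id] + 1L
    }
  }
  for (rec in ont@concepts) {
    k <- defCount[rec$id]
    k <- if (is.na(k)) 0L else k
    if (rec$primitive && k > 0L)
      stop("primitive concept '", rec$id,
           "' has an EquivalentClasses definition")
    if (!rec$primitive && k != 1L)
      stop("fully defined concept '", rec$id, "' must have exactly one ",
           "EquivalentClasses definition, found ", k)
  }
  invisible(TRUE)
}

#' Structural equality of ontologies
#'
#' Two ontologies are structurally equal when they declare the same
#' concepts (with identical descriptions, flags and classes), the same
#' roles, the same chains, and the same set of axioms up to structural
#' axiom equality. The SEP builder registry is metadata and is ignored.
#'
#' @param a,b \code{\linkS4class{Ontology}} objects.
#' @return Logical scalar.
#' @export
ontologyEqual <- function(a, b) {
  chainKeys <- function(o) .sortC(vapply(o@chains, function(ch)
    paste(ch$lhs[1L], ch$lhs[2L], ch$rhs, sep = "|"), character(1)))
  roleKeys <- function(o) {
    ids <- roleIds(o)
    vapply(o@roles[ids], function(r)
      paste(r$id, r$name, r$parent, r$transitive, sep = "\r"), character(1),
      USE.NAMES = FALSE)
  }
  identical(conceptTable(a), conceptTable(b)) &&
    identical(roleKeys(a), roleKeys(b)) &&
    identical(chainKeys(a), chainKeys(b)) &&
    identical(.sortC(names(a@axioms)), .sortC(names(b@axioms)))
}

#' Standard partonomy role box
#'
#' Installs the seven roles used throughout the anatomical model:
#' the transitive \code{all-or-part-of}; \code{proper-part-of} beneath it
#' (transitive); the three specific part relations (\code{regional-},
#' \code{constitutional-}, \code{systemic-part-of}) beneath
#' \code{proper-part-of}; and the non-transitive dependent-concept roles
#' \code{finding-site} and \code{procedure-site}. One mereological chain
#' accompanies the hierarchy: all-or-part-of composed with
#' proper-part-of is included in proper-part-of (whatever is all or part
#' of something that is a proper part of a whole is itself a proper part
#' of that whole). Together with the transitivity of all-or-part-of this
#' is the minimal regular role box under which a part assertion places
#' the child's Structure class beneath the parent's Part and Structure
#' classes.
#'
#' @param ont An \code{\linkS4class{Ontology}}.
#' @return The updated ontology.
#' @export
addPartonomyRoles <- function(ont) {
  ont <- addRole(ont, "all-or-part-of", "All or part of", transitive = TRUE)
  ont <- addRole(ont, "proper-part-of", "Proper part of",
                 parent = "all-or-part-of", transitive = TRUE)
  ont <- addRole(ont, "regional-part-of", "Regional part of",
                 parent = "proper-part-of")
  ont <- addRole(ont, "constitutional-part-of", "Constitutional part of",
                 parent = "proper-part-of")
  ont <- addRole(ont, "systemic-part-of", "Systemic part of",
                 parent = "proper-part-of")
  ont <- addRole(ont, "finding-site", "Finding site")
  ont <- addRole(ont, "procedure-site", "Procedure site")
  ont <- addChain(ont, c("all-or-part-of", "proper-part-of"),
                  "proper-part-of")
  ont
}

setMethod("show", "Ontology", function(object) {
  cat("Ontology with", length(object@concepts), "concepts,",
      length(object@roles), "roles,", length(object@chains), "chains,",
      length(object@axioms), "axioms\n")
  ndef <- sum(!vapply(object@concepts, `[[`, logical(1), "primitive"))
  cat("  fully defined concepts:", ndef, "\n")
  if (length(object@seps))
    cat("  SEP triplets:", length(object@seps), "\n")
  invisible(NULL)
})
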