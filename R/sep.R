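## SEP (Structure - Entire - Part) triplets and the wall/cavity/contents
## aggregation patterns.
##
## For an anatomical entity X the triplet comprises:
##   Entire X            -- instantiated by whole entities of kind X
##   X part              -- EquivalentTo 'proper-part-of some Entire X'
##   Structure of X      -- EquivalentTo 'all-or-part-of some Entire X'
## plus Entire X SubClassOf Structure of X (the "all of" reading of
## all-or-part-of, asserted instead of making the role reflexive) and
## X part SubClassOf Structure of X.

.sepDefaultIds <- function(label) {
  slug <- gsub("[^A-Za-z0-9]+", "-", tolower(label))
  c(entire = paste0("X-", slug, "-E"),
    part = paste0("X-", slug, "-P"),
    structure = paste0("X-", slug, "-S"))
}

#' Create a SEP triplet for an anatomical entity
#'
#' Adds the three concepts and four axioms of the Structure-Entire-Part
#' pattern. The Part and Structure concepts carry EquivalentClasses
#' definitions (non-primitive); the Entire concept is primitive. The
#' triplet is registered on the ontology and can be retrieved with
#' \code{\link{sepTriplet}}.
#'
#' @param ont An \code{\linkS4class{Ontology}} whose role box contains
#'   \code{all-or-part-of} and \code{proper-part-of}
#'   (see \code{\link{addPartonomyRoles}}).
#' @param label Human-readable entity label, e.g. \code{"liver"}; names the
#'   concepts "Entire <label>", "<label> part" (capitalised), and
#'   "Structure of <label>".
#' @param ids Optional character vector with entries \code{entire},
#'   \code{part}, \code{structure} giving explicit concept ids (used to
#'   attach published SCTIDs); defaults to reserved local \code{"X-"} ids
#'   derived from the label.
#' @param terms Optional character vector like \code{ids} overriding the
#'   three preferred terms.
#' @param fsns Optional character vector like \code{ids} overriding the
#'   fully specified names (default: preferred term plus
#'   \code{" (body structure)"}).
#' @param semanticClasses Character vector like \code{ids} with the three
#'   semantic classes; defaults to entire/part/structure.
#' @return The updated ontology.
#' @examples
#' ont <- addPartonomyRoles(emptyOntology())
#' ont <- makeSEPTriplet(ont, "liver")
#' sepTriplet(ont, "liver")$structure
#' @export
makeSEPTriplet <- function(ont, label, ids = NULL, terms = NULL,
                           semanticClasses = NULL, fsns = NULL) {
  stopifnot(is(ont, "Ontology"), is.character(label), length(label) == 1L)
  if (!nzchar(label)) stop("entity label must be non-empty")
  dft <- .sepDefaultIds(label)
  if (!is.null(ids)) dft[names(ids)] <- ids
  ids <- dft
  cap <- paste0(toupper(substring(label, 1L, 1L)), substring(label, 2L))
  dftTerms <- c(entire = paste0("Entire ", label),
                part = paste0(cap, " part"),
                structure = paste0("Structure of ", label))
  if (!is.null(terms)) dftTerms[names(terms)] <- terms
  terms <- dftTerms
  dftCls <- c(entire = "entire", part = "part", structure = "structure")
  if (!is.null(semanticClasses)) dftCls[names(semanticClasses)] <-
    semanticClasses
  cls <- dftCls
  dftFsn <- c(entire = paste0(terms[["entire"]], " (body structure)"),
              part = paste0(terms[["part"]], " (body structure)"),
              structure = paste0(terms[["structure"]], " (body structure)"))
  if (!is.null(fsns)) dftFsn[names(fsns)] <- fsns
  clash <- intersect(ids, names(ont@concepts))
  if (length(clash))
    stop("SEP triplet id collision: '", clash[1L], "' is already declared")
  for (nm in c("entire", "part", "structure"))
    ont <- addConcept(ont, conceptRef(ids[[nm]], preferred = terms[[nm]],
                                      fsn = dftFsn[[nm]],
                                      primitive = nm == "entire",
                                      semanticClass = cls[[nm]]))
  ont <- addAxiom(ont, equivalentClasses(
    ids[["structure"]], elSome("all-or-part-of", ids[["entire"]])))
  ont <- addAxiom(ont, equivalentClasses(
    ids[["part"]], elSome("proper-part-of", ids[["entire"]])))
  ont <- addAxiom(ont, subClassOf(ids[["entire"]], ids[["structure"]]))
  ont <- addAxiom(ont, subClassOf(ids[["part"]], ids[["structure"]]))
  ont@seps[[label]] <- as.list(ids)
  ont
}

#' Retrieve a registered SEP triplet
#'
#' @param ont An \code{\linkS4class{Ontology}}.
#' @param label The entity label passed to \code{\link{makeSEPTriplet}}.
#' @return A list with the \code{entire}, \code{part} and \code{structure}
#'   concept ids.
#' @export
sepTriplet <- function(ont, label) {
  t <- ont@seps[[label]]
  if (is.null(t)) stop("no SEP triplet registered for label '", label, "'")
  t
}

#' @describeIn sepTriplet All registered triplets.
#' @export
sepTriplets <- function(ont) ont@seps

#' Assert a part-whole relation between two entire concepts
#'
#' States that every instance of the child entity is a regional,
#' constitutional or systemic part of some instance of the parent entity.
#' After classification the child's Structure class is subsumed by the
#' parent's Part and Structure classes (part propagation through the
#' all-or-part-of chain).
#'
#' @param ont An \code{\linkS4class{Ontology}}.
#' @param childEntire,parentEntire Declared "Entire" concept ids.
#' @param kind One of \code{"regional"}, \code{"constitutional"},
#'   \code{"systemic"}.
#' @return The updated ontology.
#' @export
assertPart <- function(ont, childEntire, parentEntire,
                       kind = c("regional", "constitutional", "systemic")) {
  kind <- match.arg(kind)
  for (id in c(childEntire, parentEntire))
    if (!id %in% names(ont@concepts))
      stop("unknown concept id: '", id, "'")
  role <- paste0(kind, "-part-of")
  addAxiom(ont, subClassOf(childEntire, elSome(role, parentEntire)))
}

#' Create the cavity / content / intra aggregation pattern
#'
#' For a label L, creates the primitive aggregation concept
#' "Intra-L structure" (the cavity and/or its contents), the cavity
#' structure "Structure of L cavity" and the contents aggregate
#' "Content of L cavity", with both subsumed by the intra concept. A wall
#' concept "Structure of wall of L" is created as a sibling: walls bound
#' the space but are deliberately not subsumed by the intra concept.
#'
#' @param ont An \code{\linkS4class{Ontology}}.
#' @param label Non-empty region label, e.g. \code{"abdominopelvic"}.
#' @param ids Optional character vector with entries \code{intra},
#'   \code{cavity}, \code{content}, \code{wall} overriding the default
#'   \code{"X-"} ids.
#' @return The updated ontology.
#' @examples
#' ont <- addPartonomyRoles(emptyOntology())
#' ont <- makeCavityWallContent(ont, "abdominopelvic")
#' @export
makeCavityWallContent <- function(ont, label, ids = NULL) {
  stopifnot(is(ont, "Ontology"), is.character(label), length(label) == 1L)
  if (!nzchar(label)) stop("region label must be non-empty")
  slug <- gsub("[^A-Za-z0-9]+", "-", tolower(label))
  dft <- c(intra = paste0("X-intra-", slug, "-S"),
           cavity = paste0("X-", slug, "-cavity-S"),
           content = paste0("X-", slug, "-content-S"),
           wall = paste0("X-", slug, "-wall-S"))
  if (!is.null(ids)) dft[names(ids)] <- ids
  ids <- dft
  clash <- intersect(ids, names(ont@concepts))
  if (length(clash))
    stop("cavity pattern id collision: '", clash[1L], "'")
  ont <- addConcept(ont, conceptRef(ids[["intra"]],
    preferred = paste0("Intra-", label, " structure"),
    semanticClass = "structure"))
  ont <- addConcept(ont, conceptRef(ids[["cavity"]],
    preferred = paste0("Structure of ", label, " cavity"),
    semanticClass = "cavity"))
  ont <- addConcept(ont, conceptRef(ids[["content"]],
    preferred = paste0("Content of ", label, " cavity"),
    semanticClass = "content"))
  ont <- addConcept(ont, conceptRef(ids[["wall"]],
    preferred = paste0("Structure of wall of ", label),
    semanticClass = "wall"))
  ont <- addAxiom(ont, subClassOf(ids[["cavity"]], ids[["intra"]]))
  ont <- addAxiom(ont, subClassOf(ids[["content"]], ids[["intra"]]))
  ont
}

#' Define a dependent disorder or procedure concept
#'
#' Creates the fully defined concept "Disorder of <label>" (or
#' "Procedure on <label>") as the conjunction of the dependent-hierarchy
#' root and an existential over the site role. Subsumption between
#' dependent concepts then follows the site hierarchy under
#' classification: if site A is subsumed by site B, the disorder of A is
#' classified under the disorder of B.
#'
#' @param ont An \code{\linkS4class{Ontology}}.
#' @param label Label naming the dependent concept.
#' @param site Declared concept id of the anatomical site.
#' @param kind \code{"disorder"} (finding-site) or \code{"procedure"}
#'   (procedure-site).
#' @param id Optional explicit concept id; defaults to a local
#'   \code{"X-"} id derived from kind and label.
#' @return The updated ontology. The dependent root concepts
#'   (\code{X-disorder-root} / \code{X-procedure-root}) are created on
#'   first use.
#' @export
defineDependent <- function(ont, label, site,
                            kind = c("disorder", "procedure"), id = NULL) {
  kind <- match.arg(kind)
  if (!site %in% names(ont@concepts))
    stop("unknown site concept id: '", site, "'")
  root <- paste0("X-", kind, "-root")
  if (!root %in% names(ont@concepts))
    ont <- addConcept(ont, conceptRef(root,
      preferred = if (kind == "disorder") "Disorder" else "Procedure",
      fsn = paste0(if (kind == "disorder") "Disorder" else "Procedure",
                   " (", kind, ")"),
      semanticClass = kind))
  slug <- gsub("[^A-Za-z0-9]+", "-", tolower(label))
  if (is.null(id)) id <- paste0("X-", kind, "-", slug)
  pref <- if (kind == "disorder") paste0("Disorder of ", label)
          else paste0("Procedure on ", label)
  ont <- addConcept(ont, conceptRef(id, preferred = pref,
    fsn = paste0(pref, " (", kind, ")"),
    primitive = FALSE, semanticClass = kind))
  role <- if (kind == "disorder") "finding-site" else "procedure-site"
  addAxiom(ont, equivalentClasses(id, elAnd(root, elSome(role, site))))
}
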