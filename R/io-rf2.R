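## Simplified RF2-style tab-delimited release bundle.
##
## Three UTF-8, LF-terminated, header-carrying files, rows sorted by id:
##   concepts.tsv      id, primitive (0/1), semanticClass
##   descriptions.tsv  conceptId, term, type (FSN / preferred / synonym);
##                     role display names ride along with the role id in
##                     the conceptId column
##   axioms.tsv        owlExpression -- one functional-syntax statement
##                     per row (class axioms, role declarations, role
##                     hierarchy, transitivity, chains)
## The dialect deliberately drops effectiveTime/moduleId/active columns:
## it is a semantics exchange format, not a release-management one, but
## converts to and from the full layout by adding or ignoring columns
## (unknown columns are ignored on read with a warning).

.writeTSV <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(colnames(df), collapse = "\t"),
             if (nrow(df)) do.call(paste,
               c(unname(as.list(df)), sep = "\t")))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

#' Write an ontology as a simplified RF2 bundle
#'
#' @param ont An \code{\linkS4class{Ontology}}.
#' @param dir Output directory (created if necessary).
#' @return Invisibly, the three file paths. Repeated writes of the same
#'   ontology are byte-identical.
#' @export
writeRF2 <- function(ont, dir) {
  validateOntology(ont)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cs <- conceptTable(ont)
  concepts <- data.frame(id = cs$id,
                         primitive = as.integer(cs$primitive),
                         semanticClass = cs$semanticClass,
                         stringsAsFactors = FALSE)
  desc <- NULL
  for (id in conceptIds(ont)) {
    rec <- ont@concepts[[id]]
    desc <- rbind(desc,
      data.frame(conceptId = id, term = rec$fsn, type = "FSN",
                 stringsAsFactors = FALSE),
      data.frame(conceptId = id, term = rec$preferred, type = "preferred",
                 stringsAsFactors = FALSE),
      if (length(rec$synonyms))
        data.frame(conceptId = id, term = .sortC(rec$synonyms),
                   type = "synonym", stringsAsFactors = FALSE))
  }
  for (id in roleIds(ont))
    desc <- rbind(desc,
      data.frame(conceptId = id, term = ont@roles[[id]]$name,
                 type = "preferred", stringsAsFactors = FALSE))
  if (is.null(desc))
    desc <- data.frame(conceptId = character(0), term = character(0),
                       type = character(0), stringsAsFactors = FALSE)
  roleLines <- .ofnRoleLines(ont)
  axLines <- .sortC(vapply(axioms(ont), renderAxiomOFN, character(1),
                         USE.NAMES = FALSE))
  ## role labels live in descriptions.tsv; drop them from the axiom rows
  roleLines <- roleLines[!startsWith(roleLines, "AnnotationAssertion")]
  ax <- data.frame(owlExpression = c(roleLines, axLines),
                   stringsAsFactors = FALSE)
  paths <- file.path(dir, c("concepts.tsv", "descriptions.tsv",
                            "axioms.tsv"))
  .writeTSV(concepts, paths[1L])
  .writeTSV(desc, paths[2L])
  .writeTSV(ax, paths[3L])
  invisible(paths)
}

.readTSV <- function(path, required) {
  if (!file.exists(path)) stop("missing bundle file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty bundle file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  missing <- setdiff(required, header)
  if (length(missing))
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(header, required)
  if (length(extra))
    warning("ignoring unknown column(s) in ", basename(path), ": ",
            paste(extra, collapse = ", "))
  rows <- lapply(seq_along(lines)[-1L], function(k) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1L]]
    ## trailing empty fields are dropped by strsplit; pad
    if (length(f) < length(header))
      f <- c(f, rep("", length(header) - length(f)))
    if (length(f) != length(header))
      stop("malformed row in ", basename(path), " at line ", k, ": ",
           length(f), " fields, expected ", length(header))
    stats::setNames(f, header)[required]
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (!nrow(out))
    out <- stats::setNames(
      as.data.frame(matrix(character(0), 0L, length(required)),
                    stringsAsFactors = FALSE), required)
  colnames(out) <- required
  out
}

#' Read a simplified RF2 bundle
#'
#' @param dir Directory holding \code{concepts.tsv},
#'   \code{descriptions.tsv} and \code{axioms.tsv}.
#' @return An \code{\linkS4class{Ontology}}; the round trip through
#'   \code{\link{writeRF2}} is structurally equal.
#' @export
readRF2 <- function(dir) {
  concepts <- .readTSV(file.path(dir, "concepts.tsv"),
                       c("id", "primitive", "semanticClass"))
  desc <- .readTSV(file.path(dir, "descriptions.tsv"),
                   c("conceptId", "term", "type"))
  ax <- .readTSV(file.path(dir, "axioms.tsv"), "owlExpression")
  ## reuse the functional-syntax reader by wrapping the axiom rows in a
  ## minimal document, then attach the tabular metadata
  tmp <- tempfile(fileext = ".ofn")
  on.exit(unlink(tmp))
  writeLines(c(.ofnPrefix, "Ontology(<urn:trunk-sep:ontology>",
               if (nrow(concepts))
                 paste0("Declaration(Class(:", concepts$id, "))"),
               ax$owlExpression, ")"), tmp)
  skel <- readOFN(tmp)
  ont <- emptyOntology()
  remaining <- names(skel@roles)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(r)
      is.na(skel@roles[[r]]$parent) ||
        skel@roles[[r]]$parent %in% names(ont@roles), logical(1))]
    if (!length(ready))
      stop("unresolvable role hierarchy in bundle")
    for (r in ready) {
      rd <- skel@roles[[r]]
      nm <- desc$term[desc$conceptId == r & desc$type == "preferred"]
      ont <- addRole(ont, r, name = if (length(nm)) nm[1L] else r,
                     parent = rd$parent, transitive = rd$transitive)
    }
    remaining <- setdiff(remaining, ready)
  }
  for (ch in skel@chains) ont <- addChain(ont, ch$lhs, ch$rhs)
  equivLeft <- unique(vapply(Filter(function(a) a$kind == "equivalent",
                                    skel@axioms),
                             function(a) a$left$id, character(1)))
  for (k in .orderC(concepts$id)) {
    id <- concepts$id[k]
    fsn <- desc$term[desc$conceptId == id & desc$type == "FSN"]
    pref <- desc$term[desc$conceptId == id & desc$type == "preferred"]
    syn <- desc$term[desc$conceptId == id & desc$type == "synonym"]
    pref <- if (length(pref)) pref[1L] else id
    fsn <- if (length(fsn)) fsn[1L]
           else paste0(pref, " (body structure)")
    ont <- addConcept(ont, conceptRef(id, preferred = pref, fsn = fsn,
      synonyms = syn, primitive = concepts$primitive[k] != "0",
      semanticClass = concepts$semanticClass[k]))
  }
  for (ax1 in skel@axioms) ont <- addAxiom(ont, ax1)
  validateOntology(ont)
  ont
}
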