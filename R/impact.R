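## Classification impact diffing: the iterative QA loop of comparing the
## taxonomy before and after an ontology edit and reviewing every gained
## and lost subsumption, typically restricted to dependent hierarchies
## (disorders, procedures). Diffs are computed on full closures, not on
## direct parents: transitive reduction churns under edits, while closure
## diffs capture exactly the relationships gained or lost.

.pairKey <- function(m) {
  if (nrow(m)) paste(m[, 1L], m[, 2L], sep = "\r") else character(0)
}

#' Diff two classified taxonomies
#'
#' @param before,after \code{\linkS4class{Taxonomy}} objects from
#'   \code{\link{classify}}.
#' @param filter Optional character vector of semantic classes; when
#'   given, only pairs whose subclass concept belongs to one of the
#'   classes are reported (e.g. \code{"disorder"} to review the disorder
#'   hierarchy only).
#' @return An \code{\linkS4class{ImpactDiff}} with the gained pairs
#'   (present only after) and lost pairs (present only before), each a
#'   deterministically ordered (sub, super) matrix over named, non-fresh
#'   concepts.
#' @examples
#' ont <- addPartonomyRoles(emptyOntology())
#' ont <- makeSEPTriplet(ont, "liver")
#' ont <- makeSEPTriplet(ont, "lobe of liver")
#' ont2 <- assertPart(ont, sepTriplet(ont, "lobe of liver")$entire,
#'                    sepTriplet(ont, "liver")$entire, "regional")
#' d <- diffTaxonomies(classify(ont), classify(ont2))
#' nrow(gained(d))
#' @export
diffTaxonomies <- function(before, after, filter = NULL) {
  stopifnot(is(before, "Taxonomy"), is(after, "Taxonomy"))
  b <- closurePairs(before)
  a <- closurePairs(after)
  bk <- .pairKey(b)
  ak <- .pairKey(a)
  gained <- a[!ak %in% bk, , drop = FALSE]
  lost <- b[!bk %in% ak, , drop = FALSE]
  if (!is.null(filter)) {
    keep <- function(m, tax, other) {
      if (!nrow(m)) return(m)
      cls <- ifelse(m[, 1L] %in% names(tax@semanticClass),
                    tax@semanticClass[m[, 1L]],
                    other@semanticClass[m[, 1L]])
      m[cls %in% filter, , drop = FALSE]
    }
    gained <- keep(gained, after, before)
    lost <- keep(lost, before, after)
  }
  fsn <- c(before@fsn, after@fsn)
  fsn <- fsn[!duplicated(names(fsn))]
  new("ImpactDiff", gained = gained, lost = lost,
      filter = if (is.null(filter)) character(0) else filter,
      fsn = fsn)
}

#' @describeIn diffTaxonomies Gained (sub, super) pairs.
#' @param x An \code{\linkS4class{ImpactDiff}}.
#' @export
gained <- function(x) x@gained

#' @describeIn diffTaxonomies Lost (sub, super) pairs.
#' @export
lost <- function(x) x@lost

#' Render an impact diff as a human-readable report
#'
#' Lists every gained and lost subsumption with fully specified names, in
#' stable order. When a curated entailment suite is supplied, a pair that
#' gains a subsumption the suite expects to be absent is tagged as a
#' containment-law violation, and a pair that loses an expected
#' subsumption is tagged as a lost required relationship.
#'
#' @param diff An \code{\linkS4class{ImpactDiff}}.
#' @param suites Optional data.frame with columns \code{sub},
#'   \code{super}, \code{expected}, \code{source} (see
#'   \code{\link{positiveSuite}} and \code{\link{negativeSuite}}; rbind
#'   them to cross-reference both).
#' @return Character vector of report lines (also printed with
#'   \code{cat} when \code{print = TRUE}).
#' @param print Whether to cat the report to the console.
#' @export
impactReport <- function(diff, suites = NULL, print = FALSE) {
  stopifnot(is(diff, "ImpactDiff"))
  lines <- character(0)
  tag <- function(sub, super, direction) {
    if (is.null(suites)) return("")
    hit <- suites$sub == sub & suites$super == super
    if (!any(hit)) return("")
    exp <- suites$expected[hit][1L]
    src <- suites$source[hit][1L]
    if (direction == "gained" && !exp)
      paste0("  !! violates containment law (curated non-entailment: ",
             src, ")")
    else if (direction == "lost" && exp)
      paste0("  !! loses curated entailment (", src, ")")
    else
      ""
  }
  fsnOf <- function(id) {
    f <- diff@fsn[id]
    if (is.na(f)) id else unname(f)
  }
  emit <- function(m, word) {
    if (!nrow(m)) return()
    lines <<- c(lines, paste0(word, " subsumptions (", nrow(m), "):"))
    for (i in seq_len(nrow(m)))
      lines <<- c(lines,
        paste0("  ", word, ": '", fsnOf(m[i, 1L]), "' IS-A '",
               fsnOf(m[i, 2L]), "'",
               tag(m[i, 1L], m[i, 2L],
                   if (word == "gained") "gained" else "lost")))
  }
  if (nrow(diff@gained) == 0L && nrow(diff@lost) == 0L) {
    lines <- "no classification changes"
  } else {
    emit(diff@gained, "gained")
    emit(diff@lost, "lost")
  }
  if (length(diff@filter))
    lines <- c(paste0("filter: semantic class in {",
                      paste(diff@filter, collapse = ", "), "}"), lines)
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}

#' Machine-readable impact diff table
#'
#' @param diff An \code{\linkS4class{ImpactDiff}}.
#' @return A data.frame with columns \code{change} (gained/lost),
#'   \code{sub}, \code{super}, in stable order.
#' @export
impactTable <- function(diff) {
  out <- rbind(
    if (nrow(diff@gained))
      data.frame(change = "gained", sub = diff@gained[, 1L],
                 super = diff@gained[, 2L], stringsAsFactors = FALSE),
    if (nrow(diff@lost))
      data.frame(change = "lost", sub = diff@lost[, 1L],
                 super = diff@lost[, 2L], stringsAsFactors = FALSE))
  if (is.null(out))
    out <- data.frame(change = character(0), sub = character(0),
                      super = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

setMethod("show", "ImpactDiff", function(object) {
  cat("ImpactDiff:", nrow(object@gained), "gained,",
      nrow(object@lost), "lost subsumption pairs\n")
  if (length(object@filter))
    cat("  filtered to semantic classes:",
        paste(object@filter, collapse = ", "), "\n")
  invisible(NULL)
})
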