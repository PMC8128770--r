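## OWL 2 functional-syntax subset: writer and reader.
##
## Supported constructs: Declaration(Class/ObjectProperty),
## AnnotationAssertion (labels, preferred/alternate terms, semantic
## class), SubClassOf, EquivalentClasses, ObjectSomeValuesFrom,
## ObjectIntersectionOf, SubObjectPropertyOf (including
## ObjectPropertyChain) and TransitiveObjectProperty. Anything outside
## the EL subset (ObjectUnionOf, ObjectComplementOf, ...) is rejected on
## read, naming the construct and line. Output is deterministic and
## byte-stable: fixed header, ids and axioms in sorted order.

.ofnPrefix <- "Prefix(:=<urn:trunk-sep:>)"

.ofnQuote <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  paste0("\"", x, "\"")
}

.ofnExpr <- function(e) {
  switch(e$kind,
    name = paste0(":", e$id),
    some = paste0("ObjectSomeValuesFrom(:", e$role, " ",
                  .ofnExpr(e$filler), ")"),
    and  = paste0("ObjectIntersectionOf(",
                  paste(vapply(e$args, .ofnExpr, character(1)),
                        collapse = " "), ")"))
}

#' Serialize one axiom to functional syntax
#'
#' @param ax An \code{elAxiom}.
#' @return A single character string, e.g.
#'   \code{"SubClassOf(:a ObjectSomeValuesFrom(:r :b))"}.
#' @export
renderAxiomOFN <- function(ax) {
  op <- if (ax$kind == "subclass") "SubClassOf" else "EquivalentClasses"
  paste0(op, "(", .ofnExpr(ax$left), " ", .ofnExpr(ax$right), ")")
}

.ofnRoleLines <- function(ont) {
  out <- character(0)
  for (id in roleIds(ont)) {
    r <- ont@roles[[id]]
    out <- c(out,
      paste0("Declaration(ObjectProperty(:", id, "))"),
      paste0("AnnotationAssertion(rdfs:label :", id, " ",
             .ofnQuote(r$name), ")"),
      if (!is.na(r$parent))
        paste0("SubObjectPropertyOf(:", id, " :", r$parent, ")"),
      if (r$transitive)
        paste0("TransitiveObjectProperty(:", id, ")"))
  }
  chains <- vapply(ont@chains, function(ch)
    paste0("SubObjectPropertyOf(ObjectPropertyChain(:", ch$lhs[1L], " :",
           ch$lhs[2L], ") :", ch$rhs, ")"), character(1))
  c(out, .sortC(chains))
}

.ofnConceptLines <- function(ont) {
  out <- character(0)
  for (id in conceptIds(ont)) {
    rec <- ont@concepts[[id]]
    out <- c(out,
      paste0("Declaration(Class(:", id, "))"),
      paste0("AnnotationAssertion(rdfs:label :", id, " ",
             .ofnQuote(rec$fsn), ")"),
      paste0("AnnotationAssertion(skos:prefLabel :", id, " ",
             .ofnQuote(rec$preferred), ")"),
      vapply(.sortC(rec$synonyms), function(s)
        paste0("AnnotationAssertion(skos:altLabel :", id, " ",
               .ofnQuote(s), ")"), character(1)),
      paste0("AnnotationAssertion(:semanticClass :", id, " ",
             .ofnQuote(rec$semanticClass), ")"))
  }
  out
}

#' Write an ontology as an OWL functional-syntax file
#'
#' Repeated writes of the same ontology are byte-identical.
#'
#' @param ont An \code{\linkS4class{Ontology}}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeOFN <- function(ont, path) {
  validateOntology(ont)
  axLines <- vapply(axioms(ont), renderAxiomOFN, character(1),
                    USE.NAMES = FALSE)
  lines <- c(.ofnPrefix,
             "Ontology(<urn:trunk-sep:ontology>",
             .ofnRoleLines(ont),
             .ofnConceptLines(ont),
             .sortC(axLines),
             ")")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

## ---- reader -------------------------------------------------------------

.ofnTokenize <- function(lines) {
  toks <- list()
  for (ln in seq_along(lines)) {
    s <- lines[[ln]]
    i <- 1L
    n <- nchar(s)
    while (i <= n) {
      ch <- substr(s, i, i)
      if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
      if (ch %in% c("(", ")")) {
        toks[[length(toks) + 1L]] <- list(t = ch, line = ln)
        i <- i + 1L
      } else if (ch == "\"") {
        j <- i + 1L
        val <- ""
        while (j <= n) {
          cj <- substr(s, j, j)
          if (cj == "\\") {
            val <- paste0(val, substr(s, j + 1L, j + 1L))
            j <- j + 2L
          } else if (cj == "\"") break
          else { val <- paste0(val, cj); j <- j + 1L }
        }
        if (j > n) stop("unterminated string literal at line ", ln)
        toks[[length(toks) + 1L]] <- list(t = "str", v = val, line = ln)
        i <- j + 1L
      } else {
        rest <- substr(s, i, n)
        sym <- regmatches(rest, regexpr("^[^\\s()\"]+", rest,
                                        perl = TRUE))[[1L]]
        toks[[length(toks) + 1L]] <- list(t = "sym", v = sym, line = ln)
        i <- i + nchar(sym)
      }
    }
  }
  toks
}

.localId <- function(sym, line) {
  if (!startsWith(sym, ":"))
    stop("expected a prefixed id at line ", line, ", found '", sym, "'")
  substring(sym, 2L)
}

#' Read an ontology from an OWL functional-syntax file
#'
#' Accepts the EL subset written by \code{\link{writeOFN}}; an
#' unsupported OWL construct (e.g. \code{ObjectUnionOf}) is rejected
#' with its name and line number.
#'
#' @param path File path.
#' @return An \code{\linkS4class{Ontology}}; the round trip
#'   \code{readOFN(writeOFN(ont, p))} is structurally equal to
#'   \code{ont}.
#' @export
readOFN <- function(path) {
  toks <- .ofnTokenize(readLines(path, warn = FALSE))
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  nextTok <- function() {
    tk <- peek()
    if (is.null(tk)) stop("unexpected end of file")
    pos <<- pos + 1L
    tk
  }
  expect <- function(type, what = type) {
    tk <- nextTok()
    if (tk$t != type)
      stop("expected ", what, " at line ", tk$line)
    tk
  }
  ## parse a class expression starting at current position
  parseExpr <- function() {
    tk <- nextTok()
    if (tk$t != "sym")
      stop("expected a class expression at line ", tk$line)
    if (startsWith(tk$v, ":"))
      return(elName(.localId(tk$v, tk$line)))
    if (tk$v == "ObjectSomeValuesFrom") {
      expect("(")
      role <- nextTok()
      r <- .localId(role$v, role$line)
      filler <- parseExpr()
      expect(")")
      return(elSome(r, filler))
    }
    if (tk$v == "ObjectIntersectionOf") {
      expect("(")
      args <- list()
      while (!is.null(peek()) && peek()$t != ")")
        args[[length(args) + 1L]] <- parseExpr()
      expect(")")
      return(do.call(elAnd, args))
    }
    stop("unsupported OWL construct '", tk$v, "' at line ", tk$line)
  }
  skipBalanced <- function() {  # consumes a balanced (...) group
    expect("(")
    depth <- 1L
    while (depth > 0L) {
      tk <- nextTok()
      if (tk$t == "(") depth <- depth + 1L
      if (tk$t == ")") depth <- depth - 1L
    }
  }

  conceptsDecl <- character(0)
  rolesDecl <- character(0)
  ann <- list()   # per id: fsn / preferred / synonyms / semanticClass
  roleParent <- list()
  roleTrans <- character(0)
  roleName <- list()
  chains <- list()
  axs <- list()
  equivLeft <- character(0)

  note <- function(id) if (is.null(ann[[id]]))
    ann[[id]] <<- list(fsn = NA_character_, preferred = NA_character_,
                       synonyms = character(0),
                       semanticClass = "other")

  while (!is.null(peek())) {
    tk <- nextTok()
    if (tk$t == ")") next
    if (tk$t != "sym") stop("unexpected token at line ", tk$line)
    kw <- tk$v
    if (kw == "Prefix") { skipBalanced(); next }
    if (kw == "Ontology") {
      expect("(")
      iri <- nextTok()   # ontology IRI
      next
    }
    if (kw == "Declaration") {
      expect("(")
      inner <- nextTok()
      expect("(")
      idTok <- nextTok()
      id <- .localId(idTok$v, idTok$line)
      expect(")"); expect(")")
      if (inner$v == "Class") conceptsDecl <- c(conceptsDecl, id)
      else if (inner$v == "ObjectProperty") rolesDecl <- c(rolesDecl, id)
      else stop("unsupported declaration '", inner$v, "' at line ",
                inner$line)
      next
    }
    if (kw == "AnnotationAssertion") {
      expect("(")
      prop <- nextTok()
      idTok <- nextTok()
      id <- .localId(idTok$v, idTok$line)
      lit <- expect("str", "a string literal")
      expect(")")
      note(id)
      if (prop$v == "rdfs:label") {
        if (id %in% rolesDecl) roleName[[id]] <- lit$v
        else ann[[id]]$fsn <- lit$v
      } else if (prop$v == "skos:prefLabel") ann[[id]]$preferred <- lit$v
      else if (prop$v == "skos:altLabel")
        ann[[id]]$synonyms <- c(ann[[id]]$synonyms, lit$v)
      else if (prop$v == ":semanticClass") ann[[id]]$semanticClass <- lit$v
      next
    }
    if (kw == "SubObjectPropertyOf") {
      expect("(")
      first <- nextTok()
      if (first$t == "sym" && first$v == "ObjectPropertyChain") {
        expect("(")
        a <- .localId(nextTok()$v, first$line)
        b <- .localId(nextTok()$v, first$line)
        expect(")")
        s <- .localId(nextTok()$v, first$line)
        expect(")")
        chains <- c(chains, list(list(lhs = c(a, b), rhs = s)))
      } else {
        child <- .localId(first$v, first$line)
        parent <- .localId(nextTok()$v, first$line)
        expect(")")
        roleParent[[child]] <- parent
      }
      next
    }
    if (kw == "TransitiveObjectProperty") {
      expect("(")
      r <- .localId(nextTok()$v, tk$line)
      expect(")")
      roleTrans <- c(roleTrans, r)
      next
    }
    if (kw == "SubClassOf") {
      expect("(")
      l <- parseExpr(); r <- parseExpr()
      expect(")")
      axs <- c(axs, list(subClassOf(l, r)))
      next
    }
    if (kw == "EquivalentClasses") {
      expect("(")
      l <- parseExpr(); r <- parseExpr()
      expect(")")
      if (l$kind != "name")
        stop("EquivalentClasses must have a named left side (line ",
             tk$line, ")")
      equivLeft <- c(equivLeft, l$id)
      axs <- c(axs, list(equivalentClasses(l$id, r)))
      next
    }
    stop("unsupported OWL construct '", kw, "' at line ", tk$line)
  }

  ont <- emptyOntology()
  ## roles in dependency order (parents first)
  remaining <- unique(rolesDecl)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(r) {
      p <- roleParent[[r]]
      is.null(p) || p %in% names(ont@roles)
    }, logical(1))]
    if (!length(ready))
      stop("unresolvable role hierarchy (cycle or dangling parent)")
    for (r in ready) {
      p <- roleParent[[r]]
      ont <- addRole(ont, r,
                     name = if (!is.null(roleName[[r]])) roleName[[r]]
                            else r,
                     parent = if (is.null(p)) NA_character_ else p,
                     transitive = r %in% roleTrans)
    }
    remaining <- setdiff(remaining, ready)
  }
  for (ch in chains) ont <- addChain(ont, ch$lhs, ch$rhs)
  for (id in .sortC(unique(conceptsDecl))) {
    a <- ann[[id]]
    if (is.null(a))
      a <- list(fsn = NA_character_, preferred = NA_character_,
                synonyms = character(0), semanticClass = "other")
    pref <- if (is.na(a$preferred)) id else a$preferred
    fsn <- if (is.na(a$fsn)) paste0(pref, " (body structure)") else a$fsn
    ont <- addConcept(ont, conceptRef(id, preferred = pref, fsn = fsn,
      synonyms = a$synonyms, primitive = !id %in% equivLeft,
      semanticClass = a$semanticClass))
  }
  for (ax in axs) ont <- addAxiom(ont, ax)
  validateOntology(ont)
  ont
}
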