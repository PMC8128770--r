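## Shared fixtures. The trunk ontology and its taxonomy are built once
## per test run and cached; everything else is constructed inline.

.fixtureCache <- new.env(parent = emptyenv())

trunkOntology <- function() {
  if (is.null(.fixtureCache$ont))
    .fixtureCache$ont <- buildTrunkOntology()
  .fixtureCache$ont
}

trunkTaxonomy <- function() {
  if (is.null(.fixtureCache$tax))
    .fixtureCache$tax <- classify(trunkOntology())
  .fixtureCache$tax
}

## The liver example: SEP triplets for liver, lobe of liver and an
## abdomen-proper region, the lobe as regional part of the liver and the
## liver as constitutional part of the region.
liverFixture <- function() {
  ont <- addPartonomyRoles(emptyOntology())
  ont <- makeSEPTriplet(ont, "liver")
  ont <- makeSEPTriplet(ont, "lobe of liver")
  ont <- makeSEPTriplet(ont, "abdomen proper")
  ont <- assertPart(ont, "X-lobe-of-liver-E", "X-liver-E", "regional")
  ont <- assertPart(ont, "X-liver-E", "X-abdomen-proper-E",
                    "constitutional")
  ont
}

## All (sub, super) pairs reachable in the asserted entity-level part
## graph, per SEP label: used to cross-check the containment law.
assertedPartReachability <- function(ont) {
  seps <- sepTriplets(ont)
  entire2label <- stats::setNames(names(seps),
                                  vapply(seps, `[[`, character(1),
                                         "entire"))
  partRoles <- c("regional-part-of", "constitutional-part-of",
                 "systemic-part-of", "proper-part-of")
  edges <- list()
  for (ax in axioms(ont)) {
    if (ax$kind != "subclass") next
    l <- ax$left; r <- ax$right
    if (l$kind == "name" && r$kind == "some" &&
        r$role %in% partRoles && r$filler$kind == "name" &&
        l$id %in% names(entire2label) &&
        r$filler$id %in% names(entire2label))
      edges[[length(edges) + 1L]] <- c(entire2label[[l$id]],
                                       entire2label[[r$filler$id]])
  }
  labels <- names(seps)
  reach <- stats::setNames(lapply(labels, function(x) character(0)),
                           labels)
  for (e in edges) reach[[e[1L]]] <- union(reach[[e[1L]]], e[2L])
  repeat {
    grown <- FALSE
    for (x in labels) {
      new <- unique(unlist(reach[reach[[x]]]))
      add <- setdiff(new, reach[[x]])
      if (length(add)) { reach[[x]] <- c(reach[[x]], add); grown <- TRUE }
    }
    if (!grown) break
  }
  reach
}
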