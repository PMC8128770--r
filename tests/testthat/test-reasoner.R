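test_that("normalization splits equivalences and reaches normal form", {
  ont <- addPartonomyRoles(emptyOntology())
  ont <- addConcept(ont, conceptRef("X-ls", primitive = FALSE))
  ont <- addConcept(ont, conceptRef("X-el"))
  ont <- addAxiom(ont, equivalentClasses("X-ls",
    elSome("all-or-part-of", "X-el")))
  norm <- normalizeOntology(ont)
  types <- vapply(norm$rules, `[[`, character(1), "type")
  ## the equivalence becomes its two inclusion directions, already in
  ## normal form: no fresh name is needed for a plain definition
  expect_equal(length(norm$rules), 2L)
  expect_setequal(unique(types), c("exR", "exL"))
  expect_false(any(grepl("^N-", norm$names)))
})

test_that("an already-normal inclusion passes through unchanged", {
  ont <- addConcept(emptyOntology(), conceptRef("X-a"))
  ont <- addConcept(ont, conceptRef("X-b"))
  ont <- addAxiom(ont, subClassOf("X-a", "X-b"))
  norm <- normalizeOntology(ont)
  expect_equal(length(norm$rules), 1L)
  expect_equal(norm$rules[[1L]],
               list(type = "sub", a = "X-a", b = "X-b"))
  expect_false(any(grepl("^N-", norm$names)))
})

test_that("a defined conjunction with one existential needs 4 rules and
           1 fresh name", {
  ont <- addRole(emptyOntology(), "r")
  for (id in c("X-b", "X-c")) ont <- addConcept(ont, conceptRef(id))
  ont <- addConcept(ont, conceptRef("X-a", primitive = FALSE))
  ont <- addAxiom(ont, equivalentClasses("X-a",
    elAnd("X-b", elSome("r", "X-c"))))
  norm <- normalizeOntology(ont)
  expect_equal(length(norm$rules), 4L)
  expect_equal(sum(grepl("^N-", norm$names)), 1L)
  ## entailments over declared names agree with the oracle
  expect_identical(unname(closurePairs(classify(ont))),
                   unname(naiveClosure(ont)))
})

test_that("an empty or axiom-free ontology yields a reflexive-only
           closure", {
  ont <- emptyOntology()
  tax <- classify(ont)
  expect_equal(nrow(closurePairs(tax)), 0L)
  ont <- addConcept(ont, conceptRef("X-only"))
  tax <- classify(ont)
  expect_equal(nrow(closurePairs(tax)), 0L)
  expect_true(entails(tax, "X-only", "X-only"))
  expect_equal(directParents(tax, "X-only"), character(0))
})

test_that("classification is deterministic and idempotent", {
  ont <- liverFixture()
  t1 <- classify(ont)
  t2 <- classify(ont)
  expect_identical(closurePairs(t1), closurePairs(t2))
  expect_identical(t1@direct, t2@direct)
  expect_identical(t1@equivalences, t2@equivalences)
})

test_that("the closure grows monotonically under axiom addition", {
  ont <- liverFixture()
  before <- closurePairs(classify(ont))
  ont2 <- assertPart(ont, "X-abdomen-proper-E", "X-liver-E", "systemic")
  after <- closurePairs(classify(ont2))
  keyB <- paste(before[, 1L], before[, 2L])
  keyA <- paste(after[, 1L], after[, 2L])
  expect_true(all(keyB %in% keyA))
})

test_that("re-closing the direct-parent map reproduces the closure", {
  for (ont in list(liverFixture(),
                   randomELOntology(genConfig(nConcepts = 10,
                                              nRoles = 2, seed = 11)))) {
    tax <- classify(ont)
    expect_identical(directClosure(tax), tax@closure)
  }
})

test_that("equivalent concepts share a class led by the least id", {
  ont <- emptyOntology()
  for (id in c("X-b", "X-a", "X-c")) ont <- addConcept(ont, conceptRef(id))
  ont <- addAxiom(ont, subClassOf("X-a", "X-b"))
  ont <- addAxiom(ont, subClassOf("X-b", "X-c"))
  ont <- addAxiom(ont, subClassOf("X-c", "X-a"))
  tax <- classify(ont)
  expect_equal(unname(tax@representative),
               rep("X-a", 3L))
  expect_equal(equivalenceClasses(tax)[["X-a"]], c("X-a", "X-b", "X-c"))
})

test_that("subsumption queries reject unknown ids", {
  tax <- classify(liverFixture())
  expect_error(entails(tax, "X-liver-S", "X-nope"), "unknown")
  expect_error(ancestors(tax, "X-nope"), "unknown")
})

test_that("the classifier agrees with the naive oracle on seeded random
           ontologies", {
  mismatches <- 0L
  for (s in 1:150) {
    cfg <- genConfig(nConcepts = 3L + (s %% 10L), nRoles = s %% 4L,
                     nAxioms = 3L + (s %% 13L),
                     pExistential = 0.4, pConjunction = 0.3, seed = s)
    ont <- randomELOntology(cfg)
    if (!identical(unname(closurePairs(classify(ont))),
                   unname(naiveClosure(ont))))
      mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})
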