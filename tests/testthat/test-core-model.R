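test_that("concept declaration enforces unique ids and FSNs", {
  ont <- addConcept(emptyOntology(),
    conceptRef("818983003", preferred = "Abdomen",
      fsn = "Structure of abdominopelvic cavity and/or content of abdominopelvic cavity and/or anterior abdominal wall (body structure)",
      semanticClass = "clinical_region"))
  expect_equal(length(conceptIds(ont)), 1L)
  expect_error(addConcept(ont, conceptRef("818983003")), "818983003")
  expect_error(
    addConcept(ont, conceptRef("X-a", preferred = "Other",
                               fsn = getConcept(ont, "818983003")$fsn)),
    "duplicate FSN")
})

test_that("the bare term 'Abdomen' is allocatable to one concept only", {
  ont <- addConcept(emptyOntology(),
                    conceptRef("818983003", preferred = "Abdomen"))
  err <- tryCatch(
    addConcept(ont, conceptRef("X-imposter", preferred = "Abdomen",
                               fsn = "Imposter (body structure)")),
    error = conditionMessage)
  expect_match(err, "818983003")
  expect_match(err, "X-imposter")
  ## near-variant preferred terms are not restricted
  ont <- addConcept(ont, conceptRef("818984009",
                                    preferred = "Abdomen proper"))
  expect_equal(length(conceptIds(ont)), 2L)
})

test_that("axiom addition checks declarations and is idempotent", {
  ont <- addPartonomyRoles(emptyOntology())
  ont <- addConcept(ont, conceptRef("X-liver-E"))
  ont <- addConcept(ont, conceptRef("X-abdomen-proper-E"))
  ax <- subClassOf("X-liver-E",
                   elSome("constitutional-part-of", "X-abdomen-proper-E"))
  ont <- addAxiom(ont, ax)
  expect_equal(length(axioms(ont)), 1L)
  ont <- addAxiom(ont, ax)
  expect_equal(length(axioms(ont)), 1L)
  expect_error(addAxiom(ont, subClassOf("X-liver-E", "X")), "'X'")
  expect_error(addAxiom(ont, subClassOf("X-liver-E",
                                        elSome("eats", "X-liver-E"))),
               "eats")
})

test_that("ontology assembly is order-independent", {
  concepts <- lapply(c("X-a", "X-b", "X-c"), conceptRef)
  axs <- list(subClassOf("X-a", "X-b"), subClassOf("X-b", "X-c"),
              subClassOf("X-a", elAnd("X-b", "X-c")))
  build <- function(cOrd, aOrd) {
    ont <- emptyOntology()
    for (c1 in concepts[cOrd]) ont <- addConcept(ont, c1)
    for (a1 in axs[aOrd]) ont <- addAxiom(ont, a1)
    ont
  }
  ref <- build(1:3, 1:3)
  for (k in 1:5) {
    perm <- build(sample(3L), sample(3L))
    expect_true(ontologyEqual(ref, perm))
  }
})

test_that("expression equality is structural; conjunction is commutative,
           associative and idempotent under it", {
  a <- elName("X-a"); b <- elName("X-b"); c <- elName("X-c")
  expect_true(exprEqual(elAnd(a, b), elAnd(b, a)))
  expect_true(exprEqual(elAnd(elAnd(a, b), c), elAnd(a, elAnd(b, c))))
  expect_true(exprEqual(elAnd(a, a, b), elAnd(b, a)))
  expect_false(exprEqual(elAnd(a, b), elAnd(a, c)))
  e1 <- elSome("r", elAnd(a, b))
  e2 <- elSome("r", elAnd(b, a))
  ## equivalence relation: reflexive, symmetric, transitive
  expect_true(exprEqual(e1, e1))
  expect_true(exprEqual(e1, e2) && exprEqual(e2, e1))
  e3 <- elSome("r", elAnd(b, a, a))
  expect_true(exprEqual(e1, e2) && exprEqual(e2, e3) && exprEqual(e1, e3))
  expect_false(exprEqual(elSome("r", a), elSome("s", a)))
})

test_that("role hierarchy must stay acyclic and chains regular", {
  ont <- addRole(emptyOntology(), "r1")
  ont <- addRole(ont, "r2", parent = "r1")
  expect_error(addRole(ont, "r3", parent = "r9"), "undeclared")
  expect_error(addChain(ont, c("r1", "r2"), "r9"), "undeclared")
  ## rhs must be a chain component or common super-role
  ont <- addRole(ont, "r4")
  expect_error(addChain(ont, c("r2", "r4"), "r2v2"), "undeclared")
  expect_error(addChain(ont, c("r2", "r2"), "r4"), "irregular")
  ont <- addChain(ont, c("r2", "r2"), "r1")   # common super-role: fine
  ont <- addChain(ont, c("r2", "r4"), "r4")   # component: fine
  expect_equal(length(ont@chains), 2L)
})

test_that("equivalence axioms require a named left side and definition
           status is validated", {
  expect_error(equivalentClasses(elAnd("X-a", "X-b"), elName("X-c")),
               "concept name")
  ont <- addPartonomyRoles(emptyOntology())
  ont <- addConcept(ont, conceptRef("X-a", primitive = FALSE))
  ont <- addConcept(ont, conceptRef("X-b"))
  expect_error(validateOntology(ont), "exactly one")
  ont <- addAxiom(ont, equivalentClasses("X-a",
                                         elSome("proper-part-of", "X-b")))
  expect_true(validateOntology(ont))
  ont2 <- addAxiom(ont, equivalentClasses("X-b", elName("X-a")))
  expect_error(validateOntology(ont2), "primitive")
})
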