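test_that("generation is a pure function of configuration and seed", {
  cfg <- genConfig(nConcepts = 10, nRoles = 3, nAxioms = 15, seed = 99)
  a <- randomELOntology(cfg)
  b <- randomELOntology(cfg)
  expect_true(ontologyEqual(a, b))
  dirA <- withr::local_tempdir(); dirB <- withr::local_tempdir()
  writeRF2(a, dirA); writeRF2(b, dirB)
  for (f in c("concepts.tsv", "descriptions.tsv", "axioms.tsv"))
    expect_identical(readLines(file.path(dirA, f)),
                     readLines(file.path(dirB, f)))
  c1 <- randomELOntology(genConfig(nConcepts = 10, nRoles = 3,
                                   nAxioms = 15, seed = 100))
  expect_false(ontologyEqual(a, c1))
})

test_that("the generator does not disturb the global RNG stream", {
  set.seed(5)
  first <- runif(1)
  set.seed(5)
  invisible(randomELOntology(genConfig(seed = 77)))
  expect_identical(runif(1), first)
})

test_that("boundary configurations stay within the EL fragment", {
  ## no existentials: a propositional-Horn ontology
  ont <- randomELOntology(genConfig(nConcepts = 8, nRoles = 2,
                                    nAxioms = 20, pExistential = 0,
                                    pConjunction = 0.6, seed = 4))
  kinds <- function(e) switch(e$kind,
    name = "name",
    some = "some",
    and = c("and", unlist(lapply(e$args, kinds))))
  used <- unique(unlist(lapply(axioms(ont),
    function(ax) c(kinds(ax$left), kinds(ax$right)))))
  expect_false("some" %in% used)
  ## depth 0: names only
  ont0 <- randomELOntology(genConfig(nConcepts = 5, nAxioms = 10,
                                     maxDepth = 0, seed = 8))
  used0 <- unique(unlist(lapply(axioms(ont0),
    function(ax) c(kinds(ax$left), kinds(ax$right)))))
  expect_identical(used0, "name")
})

test_that("invalid configurations are rejected", {
  expect_error(genConfig(nConcepts = 0), "nConcepts")
  expect_error(genConfig(pExistential = 1.2), "\\[0, 1\\]")
  expect_error(genConfig(pExistential = 0.8, pConjunction = 0.5),
               "exceed")
})

test_that("generated ontologies always classify without error", {
  for (s in 1:60) {
    ont <- randomELOntology(genConfig(nConcepts = 3L + (s %% 9L),
                                      nRoles = s %% 4L,
                                      nAxioms = 2L + (s %% 14L),
                                      maxDepth = 1L + (s %% 3L),
                                      seed = 1000L + s))
    tax <- classify(ont)
    expect_s4_class(tax, "Taxonomy")
    expect_true(all(diag(tax@closure)))
  }
})

test_that("the oracle is reflexive, guarded, and matches the classifier
           on the liver fixture", {
  ont <- liverFixture()
  expect_true(naiveEntails(ont, "X-liver-S", "X-liver-S"))
  expect_identical(unname(naiveClosure(ont)),
                   unname(closurePairs(classify(ont))))
  big <- randomELOntology(genConfig(nConcepts = 16, seed = 3))
  expect_error(naiveClosure(big), "guard")
  expect_error(naiveEntails(ont, "X-liver-S", "X-nope"), "unknown")
})
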