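test_that("diffing a taxonomy with itself is empty", {
  tax <- classify(liverFixture())
  d <- diffTaxonomies(tax, tax)
  expect_equal(nrow(gained(d)), 0L)
  expect_equal(nrow(lost(d)), 0L)
  expect_equal(impactReport(d), "no classification changes")
  expect_equal(nrow(impactTable(d)), 0L)
})

test_that("diff direction is antisymmetric", {
  ont <- liverFixture()
  ont2 <- assertPart(ont, "X-lobe-of-liver-E", "X-abdomen-proper-E",
                     "regional")
  t1 <- classify(ont)
  t2 <- classify(ont2)
  d12 <- diffTaxonomies(t1, t2)
  d21 <- diffTaxonomies(t2, t1)
  expect_identical(gained(d12), lost(d21))
  expect_identical(lost(d12), gained(d21))
})

test_that("adding a single axiom never loses subsumptions", {
  ont <- liverFixture()
  t1 <- classify(ont)
  edits <- list(
    assertPart(ont, "X-lobe-of-liver-E", "X-abdomen-proper-E", "systemic"),
    addAxiom(ont, subClassOf("X-liver-S", "X-abdomen-proper-S")),
    addAxiom(ont, subClassOf("X-abdomen-proper-E",
                             elSome("all-or-part-of", "X-liver-E"))))
  for (ont2 in edits)
    expect_equal(nrow(lost(diffTaxonomies(t1, classify(ont2)))), 0L)
})

test_that("removing the iliac-colon pelvic placement loses exactly the
           recomputed pairs", {
  ont <- trunkOntology()
  before <- trunkTaxonomy()
  dropped <- subClassOf("X-iliac-colon-E",
                        elSome("regional-part-of", "X-pelvic-segment-E"))
  after <- classify(removeAxiom(ont, dropped))
  d <- diffTaxonomies(before, after)
  ## independent recomputation: direct set difference of the two closures
  key <- function(m) paste(m[, 1L], m[, 2L])
  b <- closurePairs(before); a <- closurePairs(after)
  expect_setequal(key(lost(d)), setdiff(key(b), key(a)))
  expect_equal(nrow(gained(d)), 0L)
  expect_true(any(lost(d)[, 1L] == "X-iliac-colon-S" &
                  lost(d)[, 2L] == "609617007"))
})

test_that("erroneously moving the uterus into the abdomen proper is
           flagged through the dependent disorder hierarchy", {
  ont <- trunkOntology()
  before <- trunkTaxonomy()
  after <- classify(assertPart(ont, "X-uterus-E",
                               "X-intra-abdomen-proper-region-E",
                               "constitutional"))
  d <- diffTaxonomies(before, after)
  expect_equal(nrow(lost(d)), 0L)
  key <- function(m) paste(m[, 1L], m[, 2L])
  b <- closurePairs(before); a <- closurePairs(after)
  expect_setequal(key(gained(d)), setdiff(key(a), key(b)))
  g <- gained(diffTaxonomies(before, after, filter = "disorder"))
  expect_identical(unname(g),
                   cbind("X-disorder-uterus", "X-disorder-abdomen-proper"))
  ## the gained pair contradicts a curated non-entailment: the report
  ## tags the containment-law violation
  d2 <- diffTaxonomies(before, after)
  rep <- impactReport(d2, suites = rbind(positiveSuite(), negativeSuite()))
  hit <- rep[grepl("violates containment law", rep)]
  expect_true(any(grepl("uterus", hit, ignore.case = TRUE)))
})

test_that("single-pair reports name both concepts by FSN", {
  ont <- liverFixture()
  ont2 <- removeAxiom(ont, subClassOf("X-liver-E",
    elSome("constitutional-part-of", "X-abdomen-proper-E")))
  d <- diffTaxonomies(classify(ont), classify(ont2))
  rep <- impactReport(d)
  expect_true(any(grepl("Liver", rep) & grepl("abdomen proper", rep)))
  expect_true(all(grepl("lost", rep[grepl("IS-A", rep)])))
})
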