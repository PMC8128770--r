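test_that("a SEP triplet classifies Entire and Part beneath Structure", {
  ont <- addPartonomyRoles(emptyOntology())
  ont <- makeSEPTriplet(ont, "liver")
  trip <- sepTriplet(ont, "liver")
  tax <- classify(ont)
  expect_true(entails(tax, trip$entire, trip$structure))
  expect_true(entails(tax, trip$part, trip$structure))
  expect_false(entails(tax, trip$entire, trip$part))
  expect_false(entails(tax, trip$part, trip$entire))
  ## with no declared parts the Part concept has no strict descendants
  expect_equal(descendants(tax, trip$part), character(0))
  ## the four pattern axioms are present
  expect_equal(length(axioms(ont)), 4L)
  expect_error(makeSEPTriplet(ont, "liver"), "collision")
  expect_error(makeSEPTriplet(ont, ""), "non-empty")
})

test_that("independent triplets never cross-subsume", {
  ont <- addPartonomyRoles(emptyOntology())
  ont <- makeSEPTriplet(ont, "liver")
  ont <- makeSEPTriplet(ont, "lung")
  tax <- classify(ont)
  for (a in unlist(sepTriplet(ont, "liver")))
    for (b in unlist(sepTriplet(ont, "lung"))) {
      expect_false(entails(tax, a, b))
      expect_false(entails(tax, b, a))
    }
})

test_that("part assertions propagate through the structure hierarchy", {
  ont <- liverFixture()
  tax <- classify(ont)
  ## one step: lobe structure under liver structure
  expect_true(entails(tax, "X-lobe-of-liver-S", "X-liver-S"))
  ## two chained steps of different part kinds: lobe under the region
  expect_true(entails(tax, "X-lobe-of-liver-S", "X-abdomen-proper-S"))
  expect_true(entails(tax, "X-lobe-of-liver-S", "X-abdomen-proper-P"))
  ## no upward leakage
  expect_false(entails(tax, "X-liver-S", "X-lobe-of-liver-S"))
  ## agreement with the naive oracle on this fixture
  expect_identical(unname(closurePairs(tax)),
                   unname(naiveClosure(ont)))
})

test_that("a degenerate self-part assertion terminates harmlessly", {
  ont <- addPartonomyRoles(emptyOntology())
  ont <- makeSEPTriplet(ont, "liver")
  ont <- makeSEPTriplet(ont, "lung")
  ont <- assertPart(ont, "X-liver-E", "X-liver-E", "regional")
  tax <- classify(ont)
  ## Entire liver now sits under its own Part/Structure, but no
  ## subsumption appears between distinct entities
  expect_true(entails(tax, "X-liver-E", "X-liver-S"))
  expect_false(entails(tax, "X-liver-S", "X-lung-S"))
  expect_error(assertPart(ont, "X-no", "X-liver-E", "regional"),
               "unknown")
})

test_that("cavity/content aggregation: both sit under intra-, walls
           do not", {
  ont <- addPartonomyRoles(emptyOntology())
  ont <- makeCavityWallContent(ont, "abdominopelvic")
  tax <- classify(ont)
  expect_true(entails(tax, "X-abdominopelvic-cavity-S",
                      "X-intra-abdominopelvic-S"))
  expect_true(entails(tax, "X-abdominopelvic-content-S",
                      "X-intra-abdominopelvic-S"))
  expect_false(entails(tax, "X-abdominopelvic-wall-S",
                       "X-intra-abdominopelvic-S"))
  expect_true(getConcept(ont, "X-intra-abdominopelvic-S")$primitive)
  expect_error(makeCavityWallContent(ont, ""), "non-empty")
  expect_error(makeCavityWallContent(ont, "abdominopelvic"), "collision")
})

test_that("dependent concepts follow the site hierarchy", {
  ont <- liverFixture()
  ont <- defineDependent(ont, "liver", "X-liver-S", "disorder")
  ont <- defineDependent(ont, "abdomen proper", "X-abdomen-proper-S",
                         "disorder")
  tax <- classify(ont)
  expect_true(entails(tax, "X-disorder-liver",
                      "X-disorder-abdomen-proper"))
  expect_false(entails(tax, "X-disorder-abdomen-proper",
                       "X-disorder-liver"))
  ## unrelated sites give unrelated dependents
  ont2 <- makeSEPTriplet(ont, "lung")
  ont2 <- defineDependent(ont2, "lung", "X-lung-S", "disorder")
  tax2 <- classify(ont2)
  expect_false(entails(tax2, "X-disorder-lung", "X-disorder-liver"))
  expect_false(entails(tax2, "X-disorder-liver", "X-disorder-lung"))
  expect_error(defineDependent(ont, "x", "X-nope", "disorder"), "unknown")
})

test_that("two dependents on the identical site are equivalent", {
  ont <- liverFixture()
  ont <- defineDependent(ont, "liver", "X-liver-S", "disorder")
  ont <- defineDependent(ont, "hepatic organ", "X-liver-S", "disorder")
  tax <- classify(ont)
  expect_true(entails(tax, "X-disorder-liver", "X-disorder-hepatic-organ"))
  expect_true(entails(tax, "X-disorder-hepatic-organ", "X-disorder-liver"))
  expect_identical(tax@representative[["X-disorder-liver"]],
                   tax@representative[["X-disorder-hepatic-organ"]])
  ## confirmed by the independent oracle
  expect_true(naiveEntails(ont, "X-disorder-liver",
                           "X-disorder-hepatic-organ"))
  expect_true(naiveEntails(ont, "X-disorder-hepatic-organ",
                           "X-disorder-liver"))
})
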