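test_that("published identifiers resolve to the documented names", {
  ont <- trunkOntology()
  fsnOf <- function(id) getConcept(ont, id)$fsn
  expect_equal(fsnOf("67734004"),
    "Structure of thoracic segment of trunk (body structure)")
  expect_equal(fsnOf("818985005"), paste0(
    "Structure of abdominopelvic segment excluding true pelvic segment ",
    "of trunk (body structure)"))
  expect_equal(fsnOf("609617007"),
    "Structure of pelvic segment of trunk (body structure)")
  expect_equal(fsnOf("816094009"), paste0(
    "Structure of thoracic cross-sectional segment of trunk ",
    "(body structure)"))
  expect_equal(fsnOf("818981001"), paste0(
    "Structure of abdominal cross-sectional segment of trunk ",
    "(body structure)"))
  expect_equal(fsnOf("816092008"), paste0(
    "Structure of pelvic cross-sectional segment of trunk ",
    "(body structure)"))
  expect_equal(fsnOf("818983003"), paste0(
    "Structure of abdominopelvic cavity and/or content of ",
    "abdominopelvic cavity and/or anterior abdominal wall ",
    "(body structure)"))
  expect_equal(fsnOf("818984009"), paste0(
    "Structure of abdominopelvic cavity and/or intra-abdominopelvic ",
    "content and/or anterior abdominal wall excluding intra-pelvic ",
    "structure of true pelvis (body structure)"))
  expect_equal(fsnOf("12921003"), "Structure of pelvis (body structure)")
  expect_equal(fsnOf("43799004"),
    "Thoracic cavity structure (body structure)")
  expect_equal(fsnOf("818987002"),
    "Structure of abdominopelvic cavity (body structure)")
  expect_equal(fsnOf("281902004"), paste0(
    "Structure of abdominopelvic cavity excluding true pelvic cavity ",
    "(body structure)"))
  expect_equal(fsnOf("816991004"),
    "Structure of cavity of true pelvis (body structure)")
  expect_equal(fsnOf("827003001"),
    "Posterior wall of abdomen proper (body structure)")
  expect_equal(fsnOf("22943007"), "Trunk structure (body structure)")
})

test_that("each allocated preferred synonym names exactly one concept", {
  tab <- conceptTable(trunkOntology())
  for (term in c("Abdomen", "Abdomen proper", "Cross-sectional abdomen"))
    expect_equal(sum(tab$preferred == term), 1L, label = term)
  expect_equal(tab$id[tab$preferred == "Abdomen"], "818983003")
  expect_equal(tab$id[tab$preferred == "Abdomen proper"], "818984009")
  expect_equal(tab$id[tab$preferred == "Cross-sectional abdomen"],
               "818981001")
})

test_that("the curated suites are well-formed, disjoint and fully
           satisfied", {
  pos <- positiveSuite()
  neg <- negativeSuite()
  expect_gte(nrow(pos), 15L)
  expect_gte(nrow(neg), 8L)
  expect_true(all(nzchar(pos$source)) && all(nzchar(neg$source)))
  expect_equal(length(intersect(paste(pos$sub, pos$super),
                                paste(neg$sub, neg$super))), 0L)
  tax <- trunkTaxonomy()
  expect_true(all(checkSuite(tax, pos)$pass))
  expect_true(all(checkSuite(tax, neg)$pass))
})

test_that("SEP soundness holds for every triplet of the fixture", {
  ont <- trunkOntology()
  tax <- trunkTaxonomy()
  for (trip in sepTriplets(ont)) {
    expect_true(entails(tax, trip$entire, trip$structure))
    expect_true(entails(tax, trip$part, trip$structure))
    expect_false(entails(tax, trip$entire, trip$part))
    expect_false(entails(tax, trip$part, trip$entire))
  }
})

test_that("structure subsumption coincides with reachability in the
           asserted part graph (containment law)", {
  ont <- trunkOntology()
  tax <- trunkTaxonomy()
  reach <- assertedPartReachability(ont)
  seps <- sepTriplets(ont)
  for (a in names(seps))
    for (b in names(seps)) {
      if (a == b) next
      expect_equal(
        entails(tax, seps[[a]]$structure, seps[[b]]$structure),
        b %in% reach[[a]],
        label = paste(a, "within", b))
    }
})

test_that("key spatial entailments of the trunk hold or fail as
           documented", {
  tax <- trunkTaxonomy()
  i <- trunkIds()
  ## the aorta example: only the arch lies wholly in the thorax
  expect_true(entails(tax, i[["archOfAortaS"]], i[["intraThoracicS"]]))
  expect_false(entails(tax, i[["aortaS"]], i[["intraThoracicS"]]))
  ## the iliac colon reaches the pelvic segment
  expect_true(entails(tax, i[["iliacColonS"]], i[["pelvicSegmentS"]]))
  ## shared cross-sectional band sits under both imaging segments
  expect_true(entails(tax, "X-t9-t12-band-of-trunk-S", i[["csThoraxS"]]))
  expect_true(entails(tax, "X-t9-t12-band-of-trunk-S", i[["csAbdomenS"]]))
  ## disorder chain from the liver upward
  anc <- ancestors(tax, i[["disorderOfLiver"]])
  expect_true(all(c(i[["disorderOfAbdomenProper"]],
                    i[["disorderOfAbdominopelvicSegment"]]) %in% anc))
})

test_that("gender-shared true-pelvis contents classify identically under
           every contents configuration", {
  i <- trunkIds()
  shared <- c(i[["urinaryBladderS"]], i[["retropubicSpaceS"]],
              i[["presacralSpaceS"]], i[["sigmoidColonS"]],
              i[["rectumS"]], i[["pelvicUreterS"]])
  for (mode in c("both", "male", "female", "none")) {
    tax <- classify(buildTrunkOntology(contents = mode))
    for (s in shared)
      expect_true(entails(tax, s, i[["intraTruePelvisS"]]),
                  label = paste(s, "in", mode))
  }
})
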