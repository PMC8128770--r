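## The executable regional anatomy of the trunk: cavities, walls,
## segments, cross-sectional segments, clinical-region aggregates,
## exemplar contents and dependent disorder/procedure concepts, plus the
## curated positive and negative entailment suites.
##
## Published SNOMED CT identifiers are used verbatim for the concepts
## that carry them; every other concept lives in the reserved local
## "X-" namespace, which can never collide with an SCTID.

#' Published concept identifiers used by the trunk model
#'
#' A named character vector mapping readable keys to the SNOMED CT ids
#' carried by the trunk fixture: the three regional segments, the three
#' cross-sectional segments, the three clinical regions (including the
#' single concept allowed to carry the preferred term "Abdomen"), the
#' four named cavities, the posterior wall of abdomen proper, and the
#' trunk structure root.
#'
#' @export
trunkSCTIDs <- c(
  trunk                = "22943007",
  thoracicCavity       = "43799004",
  abdominopelvicCavity = "818987002",
  abdomenProperCavity  = "281902004",
  truePelvisCavity     = "816991004",
  thoracicSegment      = "67734004",
  abdomenProperSegment = "818985005",
  pelvicSegment        = "609617007",
  csThorax             = "816094009",
  csAbdomen            = "818981001",
  csPelvis             = "816092008",
  abdomen              = "818983003",
  abdomenProper        = "818984009",
  pelvicRegion         = "12921003",
  posteriorWallAbdomenProper = "827003001")

#' Stable ids of the trunk model
#'
#' Convenience lookup for frequently referenced concepts of
#' \code{\link{buildTrunkOntology}} (structure-class concepts unless
#' noted). Local ids follow the SEP naming scheme
#' \code{X-<slug>-E/P/S}.
#'
#' @return Named character vector of concept ids.
#' @export
trunkIds <- function() c(
  trunkS                = "22943007",
  thoracicCavityS       = "43799004",
  abdominopelvicCavityS = "818987002",
  abdomenProperCavityS  = "281902004",
  truePelvisCavityS     = "816991004",
  falsePelvisCavityS    = "X-cavity-of-false-pelvis-S",
  falseTruePelvisCavityS = "X-cavity-of-false-and-or-true-pelvis-S",
  intraThoracicS        = "X-intra-thoracic-region-S",
  intraAbdominopelvicS  = "X-intra-abdominopelvic-region-S",
  intraAbdomenProperS   = "X-intra-abdomen-proper-region-S",
  intraTruePelvisS      = "X-intra-true-pelvis-region-S",
  abdominopelvicContentS = "X-abdominopelvic-content-S",
  thoracicSegmentS      = "67734004",
  abdominopelvicSegmentS = "X-abdominopelvic-segment-S",
  abdomenProperSegmentS = "818985005",
  pelvicSegmentS        = "609617007",
  csThoraxS             = "816094009",
  csAbdomenS            = "818981001",
  csPelvisS             = "816092008",
  csAbdominopelvicS     = "X-abdominopelvic-cross-section-S",
  abdomen               = "818983003",
  abdomenProper         = "818984009",
  pelvicRegionS         = "12921003",
  anteriorAbdominalWallS = "X-anterior-abdominal-wall-S",
  posteriorWallAbdomenProperS = "827003001",
  pelvicWallS           = "X-pelvic-wall-S",
  chestWallS            = "X-chest-wall-S",
  lumbarVertebralColumnS = "X-lumbar-vertebral-column-S",
  perineumS             = "X-perineum-S",
  liverS                = "X-liver-S",
  lobeOfLiverS          = "X-lobe-of-liver-S",
  parenchymaOfLiverS    = "X-parenchyma-of-liver-S",
  largeIntestineS       = "X-large-intestine-S",
  largeIntestineE       = "X-large-intestine-E",
  analCanalS            = "X-anal-canal-S",
  descendingColonS      = "X-descending-colon-S",
  iliacColonS           = "X-iliac-colon-S",
  sigmoidColonS         = "X-sigmoid-colon-S",
  rectumS               = "X-rectum-S",
  urinaryBladderS       = "X-urinary-bladder-S",
  retropubicSpaceS      = "X-retropubic-space-S",
  presacralSpaceS       = "X-presacral-space-S",
  pelvicUreterS         = "X-pelvic-portion-of-ureter-S",
  uterusS               = "X-uterus-S",
  aortaS                = "X-aorta-S",
  aortaE                = "X-aorta-E",
  archOfAortaS          = "X-arch-of-aorta-S",
  abdominalAortaS       = "X-abdominal-aorta-S",
  disorderOfLiver       = "X-disorder-liver",
  disorderOfAbdomenProper = "X-disorder-abdomen-proper",
  disorderOfAbdominopelvicSegment = "X-disorder-abdominopelvic-segment",
  disorderOfUterus      = "X-disorder-uterus",
  procedureOnCsAbdomen  = "X-procedure-cross-sectional-abdomen",
  procedureOnTrunk      = "X-procedure-trunk")

#' Build the trunk regional-anatomy ontology
#'
#' Assembles the executable partonomy of the trunk: the role box, SEP
#' triplets for every volume and exemplar content, the wall concepts,
#' the cavity / intra (cavity-and-contents) aggregations, the three
#' overlapping regional segments, the cross-sectional imaging segments
#' with their shared T9-T12 band, the three clinical-region "abdomen"
#' variants with their single-allocation preferred synonyms, and
#' dependent disorder and procedure exemplars.
#'
#' @param contents \code{"both"} (default) loads male- and
#'   female-specific true-pelvis contents, \code{"male"} or
#'   \code{"female"} only the respective organs, \code{"none"} only the
#'   gender-shared six (urinary bladder, retropubic space, presacral
#'   space, sigmoid colon, rectum, pelvic portion of ureter).
#' @return A validated \code{\linkS4class{Ontology}}.
#' @examples
#' ont <- buildTrunkOntology()
#' getConcept(ont, "818983003")$preferred   # "Abdomen"
#' @export
buildTrunkOntology <- function(contents = c("both", "male", "female",
                                            "none")) {
  contents <- match.arg(contents)
  ids <- trunkIds()
  ont <- addPartonomyRoles(emptyOntology())
  sep <- function(ont, label, structureId = NULL, terms = NULL,
                  fsns = NULL, cls = "structure")
    makeSEPTriplet(ont, label,
                   ids = if (is.null(structureId)) NULL
                         else c(structure = structureId),
                   terms = terms, fsns = fsns,
                   semanticClasses = c(structure = cls))
  E <- function(label) .sepDefaultIds(label)[["entire"]]

  ## --- volumes -----------------------------------------------------------
  ont <- sep(ont, "trunk", ids[["trunkS"]],
             terms = c(structure = "Trunk structure"),
             fsns = c(structure = "Trunk structure (body structure)"))
  ont <- sep(ont, "thoracic cavity", ids[["thoracicCavityS"]],
             terms = c(structure = "Thoracic cavity"),
             fsns = c(structure = "Thoracic cavity structure (body structure)"),
             cls = "cavity")
  ont <- sep(ont, "abdominopelvic cavity", ids[["abdominopelvicCavityS"]],
             terms = c(structure = "Abdominopelvic cavity"),
             fsns = c(structure =
               "Structure of abdominopelvic cavity (body structure)"),
             cls = "cavity")
  ont <- sep(ont, "abdomen proper cavity", ids[["abdomenProperCavityS"]],
             terms = c(structure = "Abdomen proper cavity"),
             fsns = c(structure = paste0(
               "Structure of abdominopelvic cavity excluding true pelvic ",
               "cavity (body structure)")),
             cls = "cavity")
  ont <- sep(ont, "cavity of true pelvis", ids[["truePelvisCavityS"]],
             terms = c(structure = "Cavity of true pelvis"),
             fsns = c(structure =
               "Structure of cavity of true pelvis (body structure)"),
             cls = "cavity")
  ont <- sep(ont, "cavity of false pelvis",
             terms = c(structure = "Cavity of false pelvis"),
             fsns = c(structure =
               "Structure of cavity of false pelvis (body structure)"),
             cls = "cavity")

  ## intra-X: the cavity-and/or-contents aggregation entities
  ont <- sep(ont, "intra-thoracic region",
             terms = c(structure = "Intra-thoracic structure"))
  ont <- sep(ont, "intra-abdominopelvic region",
             terms = c(structure = "Intra-abdominopelvic structure"))
  ont <- sep(ont, "intra-abdomen proper region",
             terms = c(structure = "Intra-abdominal proper structure"))
  ont <- sep(ont, "intra-true pelvis region",
             terms = c(structure = "Intra-pelvic structure of true pelvis"))

  ## pelvic region (clinical): wall + cavities + contents, no perineum
  ont <- sep(ont, "pelvis", ids[["pelvicRegionS"]],
             terms = c(structure = "Pelvic region"),
             fsns = c(structure = "Structure of pelvis (body structure)"),
             cls = "clinical_region")

  ## regional segments
  ont <- sep(ont, "thoracic segment", ids[["thoracicSegmentS"]],
             terms = c(structure = "Thoracic segment of trunk"),
             fsns = c(structure = paste0(
               "Structure of thoracic segment of trunk (body structure)")),
             cls = "segment")
  ont <- sep(ont, "abdominopelvic segment",
             terms = c(structure = "Abdominopelvic segment of trunk"),
             fsns = c(structure = paste0(
               "Structure of abdominopelvic segment of trunk ",
               "(body structure)")),
             cls = "segment")
  ont <- sep(ont, "abdomen proper segment", ids[["abdomenProperSegmentS"]],
             terms = c(structure = "Abdomen proper segment of trunk"),
             fsns = c(structure = paste0(
               "Structure of abdominopelvic segment excluding true pelvic ",
               "segment of trunk (body structure)")),
             cls = "segment")
  ont <- sep(ont, "pelvic segment", ids[["pelvicSegmentS"]],
             terms = c(structure = "Structure of pelvic segment of trunk"),
             fsns = c(structure = paste0(
               "Structure of pelvic segment of trunk (body structure)")),
             cls = "segment")

  ## cross-sectional (imaging) segments; they may overlap
  ont <- sep(ont, "cross-sectional thorax", ids[["csThoraxS"]],
             terms = c(structure = "Cross-sectional thorax"),
             fsns = c(structure = paste0(
               "Structure of thoracic cross-sectional segment of trunk ",
               "(body structure)")),
             cls = "cross_section")
  ont <- sep(ont, "cross-sectional abdomen", ids[["csAbdomenS"]],
             terms = c(structure = "Cross-sectional abdomen"),
             fsns = c(structure = paste0(
               "Structure of abdominal cross-sectional segment of trunk ",
               "(body structure)")),
             cls = "cross_section")
  ont <- sep(ont, "cross-sectional pelvis", ids[["csPelvisS"]],
             terms = c(structure = "Cross-sectional pelvis"),
             fsns = c(structure = paste0(
               "Structure of pelvic cross-sectional segment of trunk ",
               "(body structure)")),
             cls = "cross_section")
  ont <- sep(ont, "abdominopelvic cross-section",
             terms = c(structure =
               "Abdominopelvic cross-sectional segment of trunk"),
             fsns = c(structure = paste0(
               "Structure of abdominopelvic cross-sectional segment of ",
               "trunk (body structure)")),
             cls = "cross_section")
  ## shared full-thickness band where cross-sectional thorax and abdomen
  ## overlap (T8/T9 down to T12/L1)
  ont <- sep(ont, "T9-T12 band of trunk",
             terms = c(structure = "Structure of T9-T12 band of trunk"),
             cls = "cross_section")

  ## walls, diaphragms and related boundary structures
  ont <- sep(ont, "chest wall",
             terms = c(structure = "Chest wall structure"), cls = "wall")
  ont <- sep(ont, "thoracic diaphragm",
             terms = c(structure = "Thoracic diaphragm structure"),
             cls = "wall")
  ont <- sep(ont, "anterior abdominal wall",
             terms = c(structure = "Structure of anterior abdominal wall"),
             cls = "wall")
  ont <- sep(ont, "posterior wall of abdomen proper",
             ids[["posteriorWallAbdomenProperS"]],
             terms = c(structure = "Posterior wall of abdomen proper"),
             fsns = c(structure =
               "Posterior wall of abdomen proper (body structure)"),
             cls = "wall")
  ont <- sep(ont, "pelvic wall",
             terms = c(structure = "Pelvic wall structure"), cls = "wall")
  ont <- sep(ont, "pelvic diaphragm",
             terms = c(structure = "Pelvic diaphragm structure"),
             cls = "wall")
  ont <- sep(ont, "lumbar vertebral column",
             terms = c(structure = "Structure of lumbar vertebral column"),
             cls = "wall")
  ont <- sep(ont, "perineum",
             terms = c(structure = "Perineum structure"))
  ont <- sep(ont, "external genitalia",
             terms = c(structure = "Structure of external genitalia"))

  ## exemplar contents
  organ <- function(ont, label, terms = NULL)
    sep(ont, label, terms = terms, cls = "content")
  ont <- organ(ont, "digestive system")
  ont <- organ(ont, "liver", terms = c(structure = "Liver structure"))
  ont <- organ(ont, "lobe of liver")
  ont <- organ(ont, "large intestine")
  ont <- organ(ont, "anal canal")
  ont <- organ(ont, "descending colon")
  ont <- organ(ont, "iliac colon")
  ont <- organ(ont, "sigmoid colon")
  ont <- organ(ont, "rectum")
  ont <- organ(ont, "urinary bladder")
  ont <- organ(ont, "retropubic space")
  ont <- organ(ont, "presacral space")
  ont <- organ(ont, "pelvic portion of ureter")
  ont <- organ(ont, "aorta")
  ont <- organ(ont, "arch of aorta")
  ont <- organ(ont, "abdominal aorta")
  male <- c("prostate", "seminal vesicle", "puboprostatic ligament")
  female <- c("uterus", "ovary", "fallopian tube")
  loaded <- c(if (contents %in% c("both", "male")) male,
              if (contents %in% c("both", "female")) female)
  for (label in loaded) ont <- organ(ont, label)

  ## standalone concepts
  ont <- addConcept(ont, conceptRef("X-entire-organ",
    preferred = "Entire organ", semanticClass = "entire"))
  ont <- addConcept(ont, conceptRef(ids[["parenchymaOfLiverS"]],
    preferred = "Structure of parenchyma of liver",
    semanticClass = "content"))
  ont <- addConcept(ont, conceptRef(ids[["abdominopelvicContentS"]],
    preferred = "Content of abdominopelvic cavity",
    semanticClass = "content"))
  ont <- addConcept(ont, conceptRef(ids[["falseTruePelvisCavityS"]],
    preferred = "Cavity of false and/or true pelvis",
    fsn = paste0("Structure of cavity of false and/or true pelvis ",
                 "(body structure)"),
    semanticClass = "cavity"))
  ont <- addConcept(ont, conceptRef(ids[["abdomen"]],
    preferred = "Abdomen",
    fsn = paste0("Structure of abdominopelvic cavity and/or content of ",
                 "abdominopelvic cavity and/or anterior abdominal wall ",
                 "(body structure)"),
    semanticClass = "clinical_region"))
  ont <- addConcept(ont, conceptRef(ids[["abdomenProper"]],
    preferred = "Abdomen proper",
    fsn = paste0("Structure of abdominopelvic cavity and/or ",
                 "intra-abdominopelvic content and/or anterior abdominal ",
                 "wall excluding intra-pelvic structure of true pelvis ",
                 "(body structure)"),
    semanticClass = "clinical_region"))

  ## --- partonomy ---------------------------------------------------------
  part <- function(ont, child, parent, kind) assertPart(ont, child, parent,
                                                        kind)
  eTrunk <- E("trunk")
  ## segments under the trunk
  ont <- part(ont, E("thoracic segment"), eTrunk, "regional")
  ont <- part(ont, E("abdominopelvic segment"), eTrunk, "regional")
  ont <- part(ont, E("abdomen proper segment"),
              E("abdominopelvic segment"), "regional")
  ont <- part(ont, E("pelvic segment"), E("abdominopelvic segment"),
              "regional")
  ## cross-sectional segments under the trunk
  ont <- part(ont, E("cross-sectional thorax"), eTrunk, "regional")
  ont <- part(ont, E("abdominopelvic cross-section"), eTrunk, "regional")
  ont <- part(ont, E("cross-sectional abdomen"),
              E("abdominopelvic cross-section"), "regional")
  ont <- part(ont, E("cross-sectional pelvis"),
              E("abdominopelvic cross-section"), "regional")
  ont <- part(ont, E("T9-T12 band of trunk"),
              E("cross-sectional thorax"), "regional")
  ont <- part(ont, E("T9-T12 band of trunk"),
              E("cross-sectional abdomen"), "regional")
  ## what constitutes each segment
  ont <- part(ont, E("intra-thoracic region"), E("thoracic segment"),
              "constitutional")
  ont <- part(ont, E("chest wall"), E("thoracic segment"), "constitutional")
  ont <- part(ont, E("thoracic diaphragm"), E("thoracic segment"),
              "constitutional")
  ont <- part(ont, E("thoracic diaphragm"), E("abdomen proper segment"),
              "constitutional")
  ont <- part(ont, E("intra-abdominopelvic region"),
              E("abdominopelvic segment"), "constitutional")
  ont <- part(ont, E("intra-abdomen proper region"),
              E("abdomen proper segment"), "constitutional")
  ont <- part(ont, E("anterior abdominal wall"),
              E("abdomen proper segment"), "constitutional")
  ont <- part(ont, E("posterior wall of abdomen proper"),
              E("abdomen proper segment"), "constitutional")
  ont <- part(ont, E("lumbar vertebral column"),
              E("posterior wall of abdomen proper"), "constitutional")
  ont <- part(ont, E("pelvis"), E("pelvic segment"), "constitutional")
  ont <- part(ont, E("perineum"), E("pelvic segment"), "constitutional")
  ont <- part(ont, E("external genitalia"), E("pelvic segment"),
              "constitutional")
  ## cross-sectional pelvis subsumes the pelvic region and the perineum
  ont <- part(ont, E("pelvis"), E("cross-sectional pelvis"),
              "constitutional")
  ont <- part(ont, E("perineum"), E("cross-sectional pelvis"),
              "constitutional")
  ont <- part(ont, E("thoracic cavity"), E("cross-sectional thorax"),
              "constitutional")
  ont <- part(ont, E("intra-abdomen proper region"),
              E("abdominopelvic cross-section"), "constitutional")
  ## intra-region nesting and cavity nesting
  ont <- part(ont, E("intra-abdomen proper region"),
              E("intra-abdominopelvic region"), "regional")
  ont <- part(ont, E("intra-true pelvis region"),
              E("intra-abdominopelvic region"), "regional")
  ont <- part(ont, E("abdomen proper cavity"),
              E("abdominopelvic cavity"), "regional")
  ont <- part(ont, E("cavity of true pelvis"),
              E("abdominopelvic cavity"), "regional")
  ont <- part(ont, E("cavity of false pelvis"),
              E("abdomen proper cavity"), "regional")
  ## each cavity is part of its cavity-and-contents region
  ont <- part(ont, E("thoracic cavity"), E("intra-thoracic region"),
              "constitutional")
  ont <- part(ont, E("abdominopelvic cavity"),
              E("intra-abdominopelvic region"), "constitutional")
  ont <- part(ont, E("abdomen proper cavity"),
              E("intra-abdomen proper region"), "constitutional")
  ont <- part(ont, E("cavity of true pelvis"),
              E("intra-true pelvis region"), "constitutional")
  ## the pelvic region: wall, diaphragm, both pelvic cavities and the
  ## true-pelvis contents; the perineum is deliberately absent
  ont <- part(ont, E("pelvic wall"), E("pelvis"), "constitutional")
  ont <- part(ont, E("pelvic diaphragm"), E("pelvis"), "constitutional")
  ont <- part(ont, E("intra-true pelvis region"), E("pelvis"),
              "constitutional")
  ont <- part(ont, E("cavity of false pelvis"), E("pelvis"),
              "constitutional")

  ## contents
  ont <- addAxiom(ont, subClassOf(E("liver"), "X-entire-organ"))
  ont <- part(ont, E("liver"), E("intra-abdomen proper region"),
              "constitutional")
  ont <- part(ont, E("liver"), E("digestive system"), "systemic")
  ont <- part(ont, E("lobe of liver"), E("liver"), "regional")
  ont <- addAxiom(ont, subClassOf(ids[["parenchymaOfLiverS"]],
    elSome("constitutional-part-of", E("liver"))))
  ont <- part(ont, E("large intestine"), E("digestive system"), "systemic")
  ont <- part(ont, E("anal canal"), E("large intestine"), "regional")
  ont <- part(ont, E("anal canal"), E("perineum"), "constitutional")
  ont <- part(ont, E("descending colon"), E("large intestine"), "regional")
  ont <- part(ont, E("descending colon"),
              E("intra-abdomen proper region"), "constitutional")
  ont <- part(ont, E("iliac colon"), E("descending colon"), "regional")
  ont <- part(ont, E("iliac colon"), E("pelvic segment"), "regional")
  ont <- part(ont, E("sigmoid colon"), E("large intestine"), "regional")
  ont <- part(ont, E("rectum"), E("large intestine"), "regional")
  shared <- c("urinary bladder", "retropubic space", "presacral space",
              "sigmoid colon", "rectum", "pelvic portion of ureter")
  for (label in c(shared, loaded))
    ont <- part(ont, E(label), E("intra-true pelvis region"),
                "constitutional")
  ont <- part(ont, E("aorta"), eTrunk, "constitutional")
  ont <- part(ont, E("arch of aorta"), E("aorta"), "regional")
  ont <- part(ont, E("arch of aorta"), E("intra-thoracic region"),
              "constitutional")
  ont <- part(ont, E("abdominal aorta"), E("aorta"), "regional")
  ont <- part(ont, E("abdominal aorta"),
              E("intra-abdomen proper region"), "constitutional")
  ## content aggregate of the abdominopelvic cavity
  ont <- addAxiom(ont, subClassOf(ids[["abdominopelvicContentS"]],
                                  ids[["intraAbdominopelvicS"]]))
  ont <- addAxiom(ont, subClassOf(E("liver"),
                                  ids[["abdominopelvicContentS"]]))
  ont <- addAxiom(ont, subClassOf(E("urinary bladder"),
                                  ids[["abdominopelvicContentS"]]))

  ## --- clinical-region aggregates (no disjunction in EL: primitive
  ## concepts with an asserted inclusion from each disjunct) -------------
  ont <- addAxiom(ont, subClassOf(ids[["truePelvisCavityS"]],
                                  ids[["falseTruePelvisCavityS"]]))
  ont <- addAxiom(ont, subClassOf(ids[["falsePelvisCavityS"]],
                                  ids[["falseTruePelvisCavityS"]]))
  ont <- addAxiom(ont, subClassOf(ids[["falseTruePelvisCavityS"]],
                                  ids[["trunkS"]]))
  ont <- addAxiom(ont, subClassOf(ids[["intraAbdominopelvicS"]],
                                  ids[["abdomen"]]))
  ont <- addAxiom(ont, subClassOf(ids[["anteriorAbdominalWallS"]],
                                  ids[["abdomen"]]))
  ont <- addAxiom(ont, subClassOf(ids[["intraAbdomenProperS"]],
                                  ids[["abdomenProper"]]))
  ont <- addAxiom(ont, subClassOf(ids[["anteriorAbdominalWallS"]],
                                  ids[["abdomenProper"]]))
  ont <- addAxiom(ont, subClassOf(ids[["abdomenProper"]],
                                  ids[["abdomen"]]))
  ont <- addAxiom(ont, subClassOf(ids[["abdomen"]], ids[["trunkS"]]))

  ## --- dependent exemplars ----------------------------------------------
  ont <- defineDependent(ont, "liver", ids[["liverS"]], "disorder")
  ont <- defineDependent(ont, "abdomen proper", ids[["abdomenProper"]],
                         "disorder")
  ont <- defineDependent(ont, "abdominopelvic segment",
                         ids[["abdominopelvicSegmentS"]], "disorder")
  if ("uterus" %in% loaded)
    ont <- defineDependent(ont, "uterus", ids[["uterusS"]], "disorder")
  ont <- defineDependent(ont, "cross-sectional abdomen",
                         ids[["csAbdomenS"]], "procedure")
  ont <- defineDependent(ont, "trunk", ids[["trunkS"]], "procedure")

  validateOntology(ont)
  ont
}

.suiteEntry <- function(sub, super, expected, source) {
  data.frame(sub = sub, super = super, expected = expected,
             source = source, stringsAsFactors = FALSE)
}

#' Curated positive entailment suite
#'
#' Subsumptions the trunk model is required to entail after
#' classification, each with an own-words anatomical rationale. The
#' positive and negative suites are disjoint.
#'
#' @return A data.frame with columns \code{sub}, \code{super},
#'   \code{expected} (all \code{TRUE}), \code{source}.
#' @export
positiveSuite <- function() {
  i <- trunkIds()
  rbind(
    .suiteEntry(i[["liverS"]], i[["intraAbdominopelvicS"]], TRUE,
      "the liver lies wholly in the abdomen proper, hence within the abdominopelvic space-and-contents"),
    .suiteEntry(i[["liverS"]], i[["intraAbdomenProperS"]], TRUE,
      "the liver is wholly contained in the abdomen proper cavity region"),
    .suiteEntry(i[["lobeOfLiverS"]], i[["liverS"]], TRUE,
      "a lobe of liver is a regional part of the liver, so its structure falls under liver structure"),
    .suiteEntry(i[["parenchymaOfLiverS"]], i[["liverS"]], TRUE,
      "liver parenchyma is a constitutional part of the liver"),
    .suiteEntry(i[["disorderOfLiver"]], i[["disorderOfAbdomenProper"]], TRUE,
      "disorders follow the site hierarchy: a liver disorder is a disorder of the abdomen proper"),
    .suiteEntry(i[["disorderOfLiver"]],
                i[["disorderOfAbdominopelvicSegment"]], TRUE,
      "a liver disorder is also a disorder of the abdominopelvic segment of trunk"),
    .suiteEntry(i[["archOfAortaS"]], i[["intraThoracicS"]], TRUE,
      "the arch of the aorta lies entirely within the thorax"),
    .suiteEntry(i[["truePelvisCavityS"]], i[["abdominopelvicCavityS"]], TRUE,
      "the cavity of the true pelvis is a regional volume of the abdominopelvic cavity"),
    .suiteEntry(i[["truePelvisCavityS"]], i[["falseTruePelvisCavityS"]], TRUE,
      "the true pelvic cavity is one disjunct of the combined false and/or true pelvic cavity"),
    .suiteEntry(i[["falsePelvisCavityS"]], i[["abdomenProperSegmentS"]], TRUE,
      "the false pelvis forms the inferior volume of the abdomen proper cavity, hence lies in the abdomen proper segment"),
    .suiteEntry(i[["falsePelvisCavityS"]], i[["pelvicSegmentS"]], TRUE,
      "the false pelvis also lies in the pelvic segment: the two segments overlap and are not disjoint"),
    .suiteEntry(i[["urinaryBladderS"]], i[["intraTruePelvisS"]], TRUE,
      "the urinary bladder is contained in the cavity of the true pelvis"),
    .suiteEntry(i[["sigmoidColonS"]], i[["intraTruePelvisS"]], TRUE,
      "the sigmoid colon is a gender-shared content of the true pelvis"),
    .suiteEntry(i[["rectumS"]], i[["intraTruePelvisS"]], TRUE,
      "the rectum is a gender-shared content of the true pelvis"),
    .suiteEntry(i[["retropubicSpaceS"]], i[["intraTruePelvisS"]], TRUE,
      "the retropubic space is a gender-shared content of the true pelvis"),
    .suiteEntry(i[["presacralSpaceS"]], i[["intraTruePelvisS"]], TRUE,
      "the presacral space is a gender-shared content of the true pelvis"),
    .suiteEntry(i[["pelvicUreterS"]], i[["intraTruePelvisS"]], TRUE,
      "the pelvic portion of the ureter is a gender-shared content of the true pelvis"),
    .suiteEntry(i[["uterusS"]], i[["abdomen"]], TRUE,
      "the uterus lies in the true pelvis, whose contents fall under the clinical 'Abdomen' aggregate"),
    .suiteEntry(i[["uterusS"]], i[["pelvicRegionS"]], TRUE,
      "true-pelvis contents belong to the pelvic region"),
    .suiteEntry(i[["iliacColonS"]], i[["pelvicSegmentS"]], TRUE,
      "the iliac colon descends below the iliac crest into the false pelvis, within the pelvic segment"),
    .suiteEntry(i[["iliacColonS"]], i[["intraAbdomenProperS"]], TRUE,
      "the iliac colon remains an intra-abdominal-proper structure (the false pelvis belongs to the abdomen proper cavity)"),
    .suiteEntry(i[["abdominalAortaS"]], i[["intraAbdominopelvicS"]], TRUE,
      "the abdominal aorta lies within the abdomen proper, hence within the abdominopelvic space-and-contents"),
    .suiteEntry(i[["abdomenProper"]], i[["abdomen"]], TRUE,
      "the clinical abdomen-proper aggregate is contained in the clinical 'Abdomen' aggregate"),
    .suiteEntry(i[["perineumS"]], i[["pelvicSegmentS"]], TRUE,
      "the pelvic segment of trunk includes the entire perineum"),
    .suiteEntry(i[["procedureOnCsAbdomen"]], i[["procedureOnTrunk"]], TRUE,
      "a cross-sectional abdominal imaging procedure is a procedure on the trunk"))
}

#' Curated negative entailment suite
#'
#' Subsumptions the trunk model must NOT entail: each would violate the
#' containment law that a structure is classified beneath another only
#' when the entity lies entirely within the superordinate boundary.
#'
#' @return A data.frame like \code{\link{positiveSuite}} with
#'   \code{expected} all \code{FALSE}.
#' @export
negativeSuite <- function() {
  i <- trunkIds()
  rbind(
    .suiteEntry(i[["analCanalS"]], i[["intraAbdominopelvicS"]], FALSE,
      "the anal canal lies below the pelvic diaphragm, so it is not entirely inside the abdominopelvic cavity"),
    .suiteEntry(i[["largeIntestineS"]], i[["intraAbdominopelvicS"]], FALSE,
      "the large intestine includes the anal canal, so it is not entirely intra-abdominopelvic"),
    .suiteEntry(i[["largeIntestineE"]], i[["abdominopelvicContentS"]], FALSE,
      "the entire large intestine is not a content of the abdominopelvic cavity"),
    .suiteEntry(i[["aortaS"]], i[["intraThoracicS"]], FALSE,
      "the aorta's abdominal segment lies outside the thorax, so the aorta cannot sit beneath the thoracic structure"),
    .suiteEntry(i[["pelvicWallS"]], i[["intraAbdominopelvicS"]], FALSE,
      "walls bound the space but are excluded from the cavity-and-contents aggregation"),
    .suiteEntry(i[["lumbarVertebralColumnS"]], i[["abdomen"]], FALSE,
      "the lumbar vertebrae belong to the posterior wall, which the clinical 'Abdomen' excludes"),
    .suiteEntry(i[["perineumS"]], i[["pelvicRegionS"]], FALSE,
      "the pelvic region is bounded by the pelvic diaphragm and excludes the perineum and external genitalia"),
    .suiteEntry(i[["posteriorWallAbdomenProperS"]], i[["abdomen"]], FALSE,
      "the posterior wall of abdomen proper bounds but is not part of the clinical 'Abdomen'"),
    .suiteEntry(i[["uterusS"]], i[["intraAbdomenProperS"]], FALSE,
      "in the native state the uterus resides in the true pelvis, not the abdomen proper"),
    .suiteEntry(i[["abdomenProperSegmentS"]], i[["pelvicSegmentS"]], FALSE,
      "the two overlapping segments share the false pelvis but neither contains the other"),
    .suiteEntry(i[["thoracicCavityS"]], i[["intraAbdominopelvicS"]], FALSE,
      "the thoracic cavity lies above the thoracic diaphragm, outside the abdominopelvic cavity"),
    .suiteEntry("X-liver-E", "X-liver-P", FALSE,
      "no whole liver is a proper part of a liver: Entire must never fall under Part"))
}

#' Evaluate a curated suite against a taxonomy
#'
#' @param tax A \code{\linkS4class{Taxonomy}} of the trunk ontology.
#' @param suite A suite data.frame (\code{\link{positiveSuite}} /
#'   \code{\link{negativeSuite}}).
#' @return The suite with an added logical column \code{holds} (what the
#'   classifier derived) and \code{pass} (\code{holds == expected}).
#' @export
checkSuite <- function(tax, suite) {
  suite$holds <- vapply(seq_len(nrow(suite)), function(k)
    entails(tax, suite$sub[k], suite$super[k]), logical(1))
  suite$pass <- suite$holds == suite$expected
  suite
}
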