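# trunkSEP

Formal-semantic machinery for regional anatomy, with a complete
executable partonomy of the human trunk.

## The problem

Clinical terminologies have to answer questions like *"is a disorder of
the liver a disorder of the abdomen?"* by machine. That requires
part–whole (meronymic) knowledge — the liver lies inside the abdomen
proper cavity — to be expressed so that a description-logic classifier
can combine it with is-a knowledge and derive every subsumption that is
anatomically warranted, and none that is not. The word *abdomen* itself
is ambiguous (abdominopelvic region? abdomen excluding the true pelvis?
the full-thickness imaging volume?), so the model must carry the
distinct clinical variants as distinct, logically defined concepts.

`trunkSEP` is for terminology authors, ontology engineers and
informaticians who want this machinery small, inspectable and testable:
an EL-fragment reasoner, the SEP modelling pattern, a curated trunk
anatomy, and the classification-diff workflow used to quality-assure
edits.

## The model

**SEP triplets.** Each anatomical entity *X* is represented by three
classes — *Entire X*, *X part*, *Structure of X* — linked by
OWL 2 EL axioms over a small mereological role box
(`all-or-part-of` ⊒ `proper-part-of` ⊒ {`regional-`, `constitutional-`,
`systemic-part-of`}):

```
Structure of X  EquivalentTo  'all-or-part-of' some 'Entire X'
X part          EquivalentTo  'proper-part-of' some 'Entire X'
Entire X        SubClassOf    Structure of X
X part          SubClassOf    Structure of X
```

A part assertion is a single axiom,
`Entire child SubClassOf '<kind>-part-of' some 'Entire parent'`.
With `all-or-part-of` transitive (r∘r ⊑ r) and the chain
`all-or-part-of ∘ proper-part-of ⊑ proper-part-of`, classification
yields `Structure(child) ⊑ Part(parent) ⊑ Structure(parent)` for every
asserted part path — the propagation that makes "disorder of liver
⊑ disorder of abdomen proper" fall out of
`Disorder of S ≡ Disorder ⊓ ∃finding-site.S`.

**Classifier.** `classify()` normalizes the ontology to the four EL
normal forms, saturates the standard completion rules (conjunction,
existential introduction, existential-on-the-left, role hierarchy, role
chains) to a least fixpoint, and returns the full subsumption closure
with equivalence classes and a transitively reduced direct-parent DAG.
A deliberately slow, independently written brute-force oracle
(`naiveClosure()`) and a seeded random ontology generator make the
classifier property-testable.

**Trunk fixture.** `buildTrunkOntology()` transcribes the regional
anatomy of the trunk — cavities, walls, overlapping regional segments,
cross-sectional imaging segments, true-pelvis contents for both sexes,
exemplar organs and dependent disorder/procedure concepts — using
published SNOMED CT identifiers where they exist (e.g. `818983003`
*Abdomen*, `818985005` *Abdomen proper segment of trunk*, `816991004`
*Structure of cavity of true pelvis*). The single-word synonym
*Abdomen* is allocated to exactly one concept; the other variants carry
*Abdomen proper* and *Cross-sectional abdomen*. Curated suites
(`positiveSuite()`, `negativeSuite()`) pin down what must and must not
be entailed (the arch of the aorta is intra-thoracic, the whole aorta
is not; the anal canal is not intra-abdominopelvic; the perineum is in
the pelvic segment but not the pelvic region; …).

**Impact QA.** `diffTaxonomies()` compares the closures before and
after an edit and reports every gained and lost subsumption, optionally
filtered to dependent hierarchies — the iterative review loop used when
anatomy changes ripple into disorders and procedures.

## Worked example

```r
library(trunkSEP)

ont <- addPartonomyRoles(emptyOntology())
ont <- makeSEPTriplet(ont, "liver")
ont <- makeSEPTriplet(ont, "lobe of liver")
ont <- makeSEPTriplet(ont, "abdomen proper")
ont <- assertPart(ont, "X-lobe-of-liver-E", "X-liver-E", "regional")
ont <- assertPart(ont, "X-liver-E", "X-abdomen-proper-E", "constitutional")

tax <- classify(ont)
tax
#> Taxonomy over 9 concepts
#>   subsumption pairs (strict): 24
#>   equivalence classes: 9
#>   roots: 1

entails(tax, "X-lobe-of-liver-S", "X-abdomen-proper-S")
#> [1] TRUE
ancestors(tax, "X-lobe-of-liver-S")
#> [1] "X-abdomen-proper-P" "X-abdomen-proper-S" "X-liver-P"
#> [4] "X-liver-S"
```

The two part assertions alone place the structure of a lobe of liver
beneath the liver's and the abdomen proper's Part and Structure
classes: part knowledge has become is-a knowledge a classifier can use.
The same machinery at full scale:

```r
trunk <- buildTrunkOntology()
trunk
#> Ontology with 167 concepts, 7 roles, 1 chains, 292 axioms
#>   fully defined concepts: 108
#>   SEP triplets: 51

ttax <- classify(trunk)
entails(ttax, "X-urinary-bladder-S", "818983003")   # bladder in "Abdomen"
#> [1] TRUE
entails(ttax, "X-anal-canal-S", "X-intra-abdominopelvic-region-S")
#> [1] FALSE    # below the pelvic diaphragm: containment law respected

sum(checkSuite(ttax, positiveSuite())$pass)
#> [1] 25
```

A command-line wrapper ships in `inst/scripts/trunksep`
(`build-trunk`, `classify`, `entails`, `diff`, `export`, `generate`);
the golden serialized fixture lives in `inst/extdata/trunk-rf2`.

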