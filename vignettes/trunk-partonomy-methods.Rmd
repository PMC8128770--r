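---
title: "Meronymic modelling and EL classification of the trunk: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meronymic modelling and EL classification of the trunk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trunkSEP)
```

This vignette records how the package models part–whole anatomy, why
the pieces are shaped the way they are, and which choices were open and
how they were settled.

## The logic fragment and its assumptions

Everything stays inside the OWL 2 EL fragment: concept names,
conjunction, existential restriction, SubClassOf/EquivalentClasses,
role hierarchies and role chains. EL has no disjunction, negation,
universal restriction or disjointness, which buys polynomial-time
classification and a simple completion-rule semantics. Two practical
consequences run through the whole model:

* **"And/or" aggregates cannot be defined, only bounded from below.**
  Clinical aggregation concepts such as the cavity of false and/or true
  pelvis, or the clinical *Abdomen* (cavity and/or content and/or
  anterior abdominal wall), are primitive concepts with an asserted
  SubClassOf from each disjunct into the aggregate. This reproduces
  every wanted subsumption; what is lost is the converse inference
  (nothing can be *derived to be* one of the disjuncts), which none of
  the curated entailments needs.
* **Disjointness is never asserted.** Whether Entire and Part classes
  are disjoint is deliberately left open: EL cannot say it, and the
  package instead *tests* the non-entailments (Entire is never beneath
  Part and vice versa) on every triplet. The same holds for the
  overlapping regional segments and cross-sectional segments: overlap
  is modelled positively by shared sub-volumes (the false pelvis; the
  T9–T12 band) asserted as parts of both parents, with no disjointness
  anywhere.

## The SEP pattern and the role box

Each entity gets Entire/Part/Structure classes with the four pattern
axioms (see the README). Two design points deserve justification:

* **Reflexivity by axiom, not by role.** "All or part of" semantically
  includes "all of". Rather than a reflexive role (outside the engine's
  rule set), the pattern asserts `Entire X SubClassOf Structure of X`
  directly. On every ontology in scope the entailments are identical,
  and the reasoner needs no reflexivity handling.
* **The minimal regular role box.** Part propagation requires exactly
  two chains: transitivity of `all-or-part-of` (r∘r ⊑ r, likewise for
  `proper-part-of`) and `all-or-part-of ∘ proper-part-of ⊑
  proper-part-of`. The second is the mereologically sound statement
  that anything that is all or part of a proper part of a whole is
  itself a proper part of that whole; without it, Structure(child)
  would reach Structure(parent) but not Part(parent). No further
  chains are admitted; in particular dependents (disorders,
  procedures) propagate only through the structure hierarchy — no
  chain composes a part relation over `finding-site`.
* **Dependent concepts use a single existential.** `Disorder of S ≡
  Disorder ⊓ ∃finding-site.S`, with no role groups: grouping exists to
  separate multiple attribute bundles, and the exemplars here carry
  exactly one attribute.

Part and Structure are flagged fully defined (each carries exactly one
EquivalentClasses axiom); Entire is primitive. The invariant
"non-primitive iff exactly one equivalence with the name on the left"
is enforced by `validateOntology()` before classification and
serialization.

## The classifier

`normalizeOntology()` is polarity-aware: right-hand sides are expanded
recursively (a definition `A ≡ B ⊓ ∃r.C` yields `A ⊑ B` and
`A ⊑ ∃r.C` directly), left-hand complex expressions are named
bottom-up, and n-ary conjunctions fold into binary conjunction rules.
Fresh names are `"N-"` plus the canonical expression key — a pure
function of the expression, so normalization is deterministic and the
prefix is reserved at declaration time to make collisions impossible.

`classify()` saturates the completion rules over logical matrices (one
subsumer matrix, one relation matrix per role) until a fixpoint; with a
few hundred names a full pass is a handful of vectorised operations and
no goal-directed optimisation is warranted. Determinism choices:

* ids are ordered byte-wise (`method = "radix"`), never by the session
  locale, wherever order is visible (canonical conjunct order,
  serialized rows, closure pair listings);
* equivalence classes are represented by their byte-order least member,
  so repeated classifications and diffs are stable;
* fresh names are excluded from every output.

The direct-parent map is the unique transitive reduction of the strict
partial order on representatives (`direct = C & !(C %*% C)`), and
`directClosure()` re-closes it as a checked round trip.

Degenerate inputs are exercised deliberately: empty ontologies classify
to a reflexive-only closure; a self-part assertion adds no subsumption
between distinct concepts; cyclic SubClassOf statements collapse into
one equivalence class rather than looping.

## The trunk model

The fixture asserts containment only where an entity lies entirely
within the boundary of the superordinate volume (the containment law).
The choices that were genuinely open:

* **Iliac colon.** The distal descending colon below the iliac crest is
  modelled as a regional part of the descending colon (hence an
  intra-abdominal-proper structure) and a regional part of the pelvic
  segment of trunk. It is *not* additionally asserted into the pelvic
  region: the pelvic-segment placement is the single load-bearing axiom
  that the scripted impact-QA scenario removes, and a redundant second
  route would mask exactly the lost-relationship signal that scenario
  demonstrates.
* **Perineum and external genitalia.** Both are constitutional parts of
  the pelvic segment; the perineum is also part of the cross-sectional
  pelvis. Neither is part of the pelvic region, which is bounded by and
  includes the pelvic diaphragm. The cross-sectional pelvis includes
  only *part* of the external genitalia — an inherently fuzzy
  containment — so no axiom links external genitalia to any
  cross-sectional segment.
* **Gendered contents.** Male- and female-specific true-pelvis contents
  are both loaded by default as plain contents; no sex axioms exist (EL
  could not express the partition anyway). A `contents` argument loads
  either subset alone, and the six gender-shared contents classify
  identically under every configuration — a tested symmetry.
* **Gravid uterus.** The uterus is asserted into the true pelvis (the
  native state). The pregnant uterus expands into the false pelvis and
  abdomen proper cavity; this is documented, not modelled — the
  clinical *Abdomen* aggregate contains the uterus in both states, which
  is the query that matters clinically.
* **A "true pelvic segment of trunk"** (excluding the false-pelvis
  volume) would be expressible but has no identified clinical use and is
  omitted.

Published SNOMED CT identifiers are used verbatim for the fourteen
concepts that carry them; every other id lives in the reserved local
`X-` namespace so fixture ids can never collide with real SCTIDs. The
single-allocation policy for the bare term *Abdomen* is enforced at
assembly time: a second concept claiming that preferred term is
rejected naming both contenders.

## The synthetic generator and the oracle

`randomELOntology()` emulates the *logical* shape of small
terminologies — random concept names, a shallow role hierarchy with
transitive roles and an occasional regular chain, random EL expressions
with bounded depth, a 1-in-4 chance that an axiom is a definition — not
their anatomical content. Defaults (8 concepts, 2 roles, 12 axioms,
existential probability 0.4, conjunction 0.3, depth 2, half of the
roles transitive) are chosen so that a generated ontology typically
exercises every completion rule while the brute-force oracle stays
fast; property tests sweep sizes up to 12 concepts and 3 roles.
Generation is a pure function of configuration and seed and leaves the
caller's RNG stream untouched.

`naiveClosure()` is the independent witness: it names every complex
subexpression definitionally (its own normalization, n-ary where the
classifier's is binary) and re-scans every rule against every concept
and every role pair until a pass adds nothing — no indexing, no shared
saturation code, guarded to 15 concepts because its job is correctness,
not speed. Passing the agreement property on 1000 seeded ontologies
shows the two engines compute the same closure on the EL fragment the
generator covers; it says nothing about constructs neither implements
(nominals, concrete domains) and, like all property testing, it samples
rather than proves.

## Serialization

The RF2-style dialect keeps three tab-delimited tables (concepts,
descriptions, axioms) and deliberately drops release-management columns
(effectiveTime, moduleId, active); unknown columns are ignored with a
warning so full-layout files convert by column addition alone. Axioms
are stored as OWL functional-syntax strings — one grammar, two
carriers — and the functional-syntax reader rejects any construct
outside the EL subset by name and line. Writers emit sorted rows over
LF-terminated UTF-8, so repeated writes are byte-identical; this is
what makes the shipped golden bundle a meaningful regression anchor.

## Problem sizes and limitations

The trunk fixture has 167 concepts, 292 axioms and 51 SEP triplets and
classifies in well under a second; the full test suite classifies it a
handful of times and sweeps 1000 random ontologies against the oracle,
completing in about a minute and a half. Known limitations: no
incremental reasoning (every query reclassifies), no general
concept-inclusion optimisation, no nominals/datatypes/disjointness, and
the anatomical scope is the trunk's regional skeleton with exemplar
contents — not a complete anatomy branch, not the nine-region surface
grid, and no vasculature beyond the aorta exemplar.
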