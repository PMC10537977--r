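---
title: "Classifying changes between ontology versions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying changes between ontology versions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontodiff)
```

## The problem and the model

Two versions of an ontology are two sets of RDF triples. `ontodiff` treats
the difference purely syntactically: the delta is the symmetric difference of
the skolemized triple sets, split into added and deleted triples. No
entailment or description-logic reasoning is performed — a triple that
becomes redundant but stays asserted is not a change, and a triple whose
content is derivable but newly asserted is one. This is the right contract
for release auditing, where the serialized artifact is the unit of
versioning.

Every delta triple is classified into exactly one of 18 **basic change**
actions by a total precedence over its shape: declaration triples first
(class, then property, resolved by the precedence concept > property >
individual when a subject is declared as several kinds), then individual
type assertions, then class and property subsumption edges, then literal
attributes split into label / comment / other, and finally other
relationships. Two consequences of this design matter in practice:

* **Synonyms are "other attributes", not labels.** Only the configured label
  and comment predicates trigger the label/comment actions; a synonym edit
  can therefore never masquerade as a rename-ish label change.
* **Individuals fold.** A brand-new individual arrives with all of its type
  assertions folded into a single `addI` (symmetrically `delI`); a type
  change on a *persisting* individual instead surfaces as paired
  `addOtherR`/`delOtherR` basics, which is exactly the shape the
  reclassification rules consume.

Composite changes then *consume* basic changes. The defining invariant —
checked at the end of every run and asserted over randomized fixtures in the
test suite — is the partition: claims are pairwise disjoint, the heuristic
and complex sets are disjoint, and every basic change is either claimed by
exactly one instance or left in the residual set. Because payload triples
are preserved through consumption, expanding every instance back to its
basics and applying adds/deletes to the old version must reproduce the new
version triple-for-triple; `apply_diff()` exists precisely to keep that
completeness property testable.

## Pipeline order, and the one exception

Detection runs in a fixed order: delta → basic classification → matcher →
merges/splits → renames → obsolescence → attribute-value changes →
subgraphs → leaves → moves → reclassifications → pruning of consumed
basics. Within the merge/split stage, merge candidates outrank split
candidates, larger groups outrank smaller ones, and remaining ties break on
the lexicographic IRI of the pivot entity; each entity joins at most one
instance. The order is part of the method's contract: consumption outcomes
depend on it, and fixing it (plus sorting every worklist) is what makes runs
bit-reproducible.

Heuristic detection generally precedes complex detection, with one
deliberate exception: obsolescence runs *before* attribute-value pairing,
and marker-flagged basics are invisible to the value-change detector.
Without this, a deprecation encoded as a label rewrite (`"X"` →
`"obsolete X"`) would always be shadowed by a `changeLabel`; with it, the
`toObsC` rule claims both the flagged added label and its deleted
counterpart, and no spurious value change is emitted.

## The matcher and its parameters

Heuristic changes are gated entirely on entity correspondences. Three
sources are supported: a built-in lexical matcher, an external mapping file
(three-column TSV or Alignment-Format RDF/XML), or none. The built-in
matcher scores delta-affected entity pairs (deleted-side × added-side, per
entity kind) by the best normalized Levenshtein similarity over the union of
their labels, synonyms and IRI local names, after lowercasing, ASCII
folding and punctuation stripping; identical local names score 1. Obsolete
entities are excluded on both sides. Two parameters matter:

* `threshold` (default **0.6**): the minimum similarity for a
  correspondence. The default mirrors the 60% alignment threshold
  conventional in biomedical ontology matching; raising it can only remove
  correspondences (anti-monotonicity is a tested property).
* the value-change similarity floor (**0.1**): deleted/added literal pairs
  on the same subject and predicate are paired greedily by descending
  similarity, and pairs below the floor are left unpaired — a wholly
  different literal is an addition plus a deletion, not a modification.
  Across an accepted rename the pairing also skips literals identical on
  both sides: a value carried unchanged through a pure IRI rename is not a
  value change.

The matcher is deliberately simple and deterministic. It does not do word
indexing, structural propagation or repair; stronger matchers are expected
to arrive as mapping files, which is why the loader accepts the alignment
interchange format read-only and leaves thresholding to the engine.

## Complex-rule decisions

Several rule details are genuinely open design space; the package fixes them
as follows and the fixture suite pins each choice with a planted case.

* **Frame of reference for vertical moves.** `pullUpC`/`pullDownC` compare
  the new parent set `B2` against the strict ancestors (resp. descendants)
  of the old parent set `B1` *in the old hierarchy* — the pre-change frame.
  Mixed reattachments (some ancestors, some unrelated) fall through to the
  lateral `moveC`. All of the entity's unclaimed subsumption-edge basics are
  consumed by the move.
* **Subgraph roots attach only to persisting parents** (or are orphan
  roots), and members are reached through added-only (deleted-only) chains.
  A member's extra edge to a persisting parent outside the subgraph — a
  partially added diamond — is *not* consumed and survives as a basic,
  keeping claims disjoint.
* **Leaves are single-parent by signature.** An added childless concept with
  two persisting parents is not an `addLeafC`; its basics stay residual.
* **Reclassification is judged in the new hierarchy**, where the asserted
  types live: the new type being a strict ancestor (descendant) of the old
  one yields `reclassIHigher` (`reclassILower`), anything else the sibling
  retype `recastI`. Hierarchy-related pairs are formed first when multiple
  type edits coexist on one individual.
* **Obsolescence markers** default to three conventions: an
  `owl:deprecated = true` flag, membership of an OBO-style obsolete
  superclass, and a case-insensitive `"obsolete"` label prefix. All three
  are configurable in the vocabulary file, as are the label, comment and
  synonym predicate sets (which must be pairwise disjoint).

## The bundled change taxonomy

Detected changes are emitted as instances of the OntoChange taxonomy shipped
in `inst/extdata/change-taxonomy.ttl`: 60 classes — 51 instantiable leaves
and 9 interior classes — plus 9 object properties and 7 data properties used
by the serializer. The interior classes are the root, the three category
classes, two attribute-change groupings, a relationship grouping, and two
*instantiable* generalizations: `moveC` above `pullUpC`/`pullDownC`, and
`recastI` above `reclassIHigher`/`reclassILower`. Lateral moves and sibling
retypes are genuinely emitted with the general action, so these two interior
classes carry signatures, unlike the pure scaffolding; the shipped
reconciliation table (`taxonomy-reconciliation.csv`) records exactly which
specializations were filed under which generalization. Class renames
(`renC`) are filed under the Complex branch although their detection
requires the matcher — the taxonomy follows the cataloguing convention for
class renames, and the engine reports `renC` in the complex set
accordingly. The split actions are defined as one source to many targets
(the mirror of the merge); the class definitions in the bundle state this
reading explicitly since change catalogues have occasionally worded the
split as the merge's duplicate.

Serialization is bidirectional: Turtle output types each instance against
the taxonomy with per-action argument properties and consumption links, JSON
output carries `{instanceId, action, category, arguments, consumed[]}`
records plus the residual basics, and both round-trip through
`parse_changes()` to identical diff content. `validate_instance()` checks
arity, role cardinalities (a merge needs at least two sources) and the
consumption contract before anything is written.

## What the synthetic generator emulates — and what it does not

`generate_base()` builds a rooted class DAG (mostly a tree, with occasional
second parents), labels, comments and SKOS synonyms on concepts, a binary
subsumption tree of properties, typed and labelled individuals,
cross-relationships, and pre-deprecated entities. Labels are pronounceable
pseudo-words so lexical similarity behaves non-degenerately.
`plant_changes()` applies a script of change actions on pairwise-disjoint
entity sets and records the expected instances, the expected residual
basics and the perfect mapping — constructed from the script alone, never by
running the engine, so the ledger is an independent oracle. The standard
suite (six fixed-seed pairs) covers all 51 leaf actions, both instantiable
generalizations, and the adversarial shapes: multi-parent leaves,
many-to-many mappings, label-encoded deprecation, partially added
subgraphs.

What passing the suite shows: the rules implement their definitions exactly,
the partition holds, reconstruction is complete, and the precedence
decisions behave as documented. What it does not show: performance or recall
on real release pairs. Real biomedical releases have annotation axioms, OWL
class expressions, reification, multilingual labels at scale and
idiosyncratic deprecation conventions that the generator does not imitate;
triples it cannot interpret flow through as `*OtherA`/`*OtherR` basics
rather than composite changes, by design.

Mirror symmetry — swapping the versions and transposing the mapping mirrors
every action (`add↔del`, `merge↔split`, `pullUp↔pullDown`, `toObs↔revObs`,
`reclassIHigher↔reclassILower`) — holds on all unambiguous fixtures and is
tested there. The deliberate exception is the many-to-many adversarial
shape: merge-over-split precedence is direction-asymmetric, so its
resolution does not mirror, and the fixture documents that.

## Numerical and engineering choices

* Blank nodes are skolemized deterministically (two refinement rounds over
  neighbourhood signatures, first-occurrence tie-break), so identical input
  bytes always produce identical skolem IRIs and triple sets stay
  comparable across versions. No structural blank-node *matching* is
  attempted — how blank-node-heavy axioms should diff is left open, and
  they flow through as opaque skolemized triples.
* Plain literals and explicit `xsd:string` literals are normalized to one
  form; literal identity is lexical form + datatype + language tag.
* Change identifiers are content hashes (a double-pass 32-bit FNV-1a,
  implemented vectorised in R), so ids are stable across runs and machines;
  they are identifiers, not cryptographic digests.
* Cycles in subsumption are tolerated everywhere (visited-set traversals);
  undeclared entities yield empty ancestor sets with a warning, never
  errors.
* All worklists are sorted with locale-independent (radix) ordering; with
  the matcher disabled, repeated runs produce byte-identical serializations.

Test problem sizes are deliberately modest: suite bases of 20–60 concepts
and up to 28 properties, two hundred randomized pairs of ~45 concepts for
the partition/reconstruction properties, and a 1k/2k/4k-triple family for a
soft quadratic-scaling guard. These sizes exercise every rule and
interaction while keeping the default test run fast; nothing in the method
depends on them.

## Known limitations

* Purely syntactic: no semantic (entailment-based) delta.
* OWL class expressions (restrictions, equivalences) and reified axiom
  annotations are ordinary triples to the classifier; changes inside them
  surface as Other-category basics.
* No cross-predicate value moves: a label becoming a synonym is a
  `delLabel` plus an `addOtherA`, never a value change.
* The matcher-comparison metric divides by the default-matcher count; its
  occasionally printed form divides by an average whose reference is not
  defined, and the function documentation records that reading rather than
  hiding it.
* OBO-format inputs must be converted to OWL upstream; the readers cover
  Turtle, N-Triples and striped RDF/XML (no RDF collections).
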