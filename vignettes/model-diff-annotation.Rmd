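---
title: "Semantic differencing of model versions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic differencing of model versions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comodiff)
```

# The problem

Versions of a computational biology model differ in ways that matter very
differently to different audiences. A curator cares about corrections of
mismatches with the publication; a modeller cares about parameter and
network changes that alter simulation results; a tool developer cares
about format-specification upgrades; nobody cares that a round trip
through an editing tool reshuffled the `listOfParameters`. `comodiff`
makes these distinctions computable: it derives a *delta* between two
model documents and attaches ontology terms to every single change, so
change sets become filterable and interpretable data rather than raw XML
noise.

# The delta model

A delta is an ordered set of operations on XML entities — element nodes,
attributes, text content — sufficient to transform document A into
document B. Four change types are distinguished: `Insertion`, `Deletion`,
`Update` and `Move`. Attribute-level differences on a surviving element
are emitted per attribute; a deleted element contributes one node
deletion plus one deletion per attribute and text payload, linked by
`wasTriggeredBy`. The defining contract, enforced by the test suite for
every generated fixture, is the *patch round trip*:
`apply_delta(a, compute_delta(a, b))` is canonically equal to `b`.

## Document equality and canonicalization

Two documents are considered equal exactly when their canonical
serializations are byte-identical. The canonical form sorts attributes by
name, collapses runs of whitespace in text content (trimmed), and renames
namespace prefixes deterministically (`n1`, `n2`, … in order of first
declaration, ordered by namespace URI within an element) so that prefix
spelling cannot masquerade as a model change. Namespace *declarations*
themselves are kept as ordinary attributes of the declaring element: this
is what lets an SBML level-2-to-level-3 upgrade surface as a single
attribute update on the root element, classified as a `ModelEncoding`
change, instead of as a rename of every element in the document.

Two simplifications are deliberate. Mixed-content interleaving (text
between sibling elements) is not preserved — model formats use element
content, and interleaved whitespace is serialization churn. Comments and
processing instructions are ignored for the same reason.

## Matching

The matcher is id-anchored and greedy rather than an optimal tree-edit
search, because model formats carry stable identifiers:

1. a global pass matches equal-tag elements whose dialect identity
   attribute has the same value, when that value is unique in both
   documents (SBML: `id`, then `metaid`; CellML: `name`, then `cmeta:id`;
   generic XML: `id`);
2. under matched parents, unmatched children are matched by equal tag and
   equal `name` attribute (unique on both sides);
3. remaining unmatched children are matched per tag by position.

The global identity pass is what allows moves across containers to be
recognised as moves rather than delete/insert pairs. Optimal edit scripts
are a non-goal: for the annotation use case the quality requirement is
the patch contract plus stable, explainable matches, not minimality.

## Move detection

Within a matched parent pair, the kept children are aligned by a longest
increasing subsequence (LIS) on their positions in B; children off the
subsequence become `Move` operations. A pure "did the sibling index
change" rule would flag every later sibling as moved whenever one sibling
is inserted or deleted; the LIS formulation reports a minimal set of
moves for same-parent reorders and is what makes the patch contract hold.
Matched nodes whose parents' matches differ are always moves.

## Patching

Operations are applied in phases: attribute/text updates and deletions
first (source addresses resolved against the pristine document, so order
within the phase cannot matter), then node deletions and move detachments
deepest-and-last first (so tag-indexed addresses stay valid), then
insertions and re-attachments in document order of B. Each insertion
records its preceding sibling in B (`afterB`); when operations are applied
in B document order that anchor is always already present, which makes
patching deterministic without any search. Unresolvable addresses and
double writes to one slot raise errors naming the offending operation.

# Annotation

Change type and XML entity are read directly off the operation. The
affected model layer is assigned from a dialect rule table — packaged as
a plain TSV (`inst/extdata/target_rules_*.tsv`) so that term placement
can be refined without code changes. Element rules use a
*nearest-enclosing-construct* principle: walking the operation's address
upwards, the first tag with a rule wins, so a MathML edit inside a
`kineticLaw` is a `KineticsDefinition` change while the same edit inside a
`functionDefinition` is a `FunctionDefinition` change. Attribute rules are
additive: a species `name` update is both an `EntityName` and (from the
enclosing element) a `ReactionNetworkDefinition` change — characterising a
change usually takes a combination of terms. Namespace-declaration
attributes map to `ModelEncoding` everywhere.

Only the XML-entity and target branches are assigned automatically.
Intention and Reason describe *why* a change was made, which is not
recoverable from the documents; they are accepted from user annotations
only, as is `ModelBehaviour` (whether dynamics changed would require
simulation, which is out of scope). All terms, user-supplied or
automatic, are validated against the vocabulary's property ranges
(`affects` → `Target`, `appliesTo` → `XmlEntity`, `hasIntention` →
`Intention`, `hasReason` → `Reason`, `wasTriggeredBy` → `Change`) before
they are stored or serialized.

## The vocabulary

The built-in vocabulary implements the core of COMODI: the five root
concepts (`Change` with its four subtypes; `XmlEntity` with three;
`Intention`, `Reason`, `Target`), the five object properties, and the
refinements the classifier assigns (`ParameterSetup` under `ModelSetup`;
`ReactionNetworkDefinition`, `FunctionDefinition`, `KineticsDefinition`
under `ModelDefinition`; `EntityName` and `EntityIdentifier` under
`ModelEncoding`) plus the user-facing reasons (`MismatchWithPublication`,
`Typo`, `ChangedSpecification`) and `Correction`. The placement of
`ChangedSpecification` under `Reason` and of the two entity-naming terms
under `ModelEncoding` reflects how they are used in filtering (why a
version changed, respectively how an entity is encoded); the released
ontology is larger, and `read_owl_vocabulary()` loads it from its OWL
file when completeness matters. The hierarchy is a tree, not a DAG:
single parents keep subsumption trivial to reason about, and nothing the
classifier assigns needs multiple inheritance. `ModelBehaviour` carries
only an opaque cross-reference towards dynamical-behaviour ontologies.

## Turtle serialization

Annotations are written as RDF/Turtle to a file *independent* of the diff
XML; each change is the IRI `<diff-file>#<operation-id>`. Independence
keeps diff files small and lets annotations be revised or discarded
without touching the delta. The writer emits no blank nodes and a fixed
prefix set, so output is byte-stable; the reader reports unknown
predicates and terms as a warning list instead of dropping them. The
`order_only` flag is derived from the delta (it is a property of the
operation, not of the RDF) and is recomputed when annotations are re-read
alongside their delta.

# Filtering

A profile keeps a change iff no include set is given or one of the
change's terms (across all branches) is subsumed by an include term, and
no term is subsumed by an exclude term. Subsumption can be switched off
for exact matching. Order-only changes — same-parent moves inside
containers whose order carries no semantics — can be dropped; the SBML
default list covers `listOfParameters`, `listOfSpecies`,
`listOfReactions`, `listOfCompartments`, `listOfUnitDefinitions` and
`listOfFunctionDefinitions`. `listOfRules` and `listOfEvents` are treated
as ordered on purpose: rule and event evaluation can interact with
document order in some tool implementations, so suppressing those moves
silently would be the wrong conservative default (the list is
user-overridable). Two named profiles ship as starting points:
`"modeller"` (keep setup/definition layers, drop annotation-layer and
order-only changes) and `"curator"` (keep everything except order-only).
`collapse_versions()` applies a profile across a version series and
returns the indices of versions that still carry changes — e.g. hiding
releases that only upgraded the SBML level.

# The fixture generator

`make_base_model()` builds a seeded core SBML L2V4 (or CellML 1.1)
document — compartment, species (the first deliberately named "Gulcose"),
parameters with seeded values, reactions with MathML kinetic laws, an RDF
annotation block. `apply_mutation()` applies one of eight scripted
mutations and returns the mutated document *plus the ground-truth
annotation* the pipeline must produce: parameter retuning
(`ParameterSetup`), typo rename (`EntityName`), species insertion and
deletion (`ReactionNetworkDefinition`, with attribute operations triggered
by the node operation), reaction deletion (kinetic-law deletion triggered
by the reaction deletion), specification upgrade (`ModelEncoding`),
annotation edits (`ModelAnnotation`) and parameter reshuffling
(order-only moves). These mutations emulate the change classes observed
in open model repositories.

What the generator does *not* emulate: real repository histories with
dozens of interleaved edits per release, SBML extension packages,
non-well-formed intermediate versions, and semantic (non-syntactic)
equivalences such as mathematically equal but rewritten kinetic laws.
Passing tests therefore demonstrate correct difference detection and
classification for scripted, well-formed core-SBML/CellML edits — they do
not certify recall on arbitrary real-world histories.

The test suite runs every mutation type across five seeds on models with
four species and two reactions (40 version pairs), a size chosen so the
whole suite exercises every code path, including cross-container moves
and composed mutations, in a few seconds.

# Numerical and procedural choices

* All randomness (base-model values, mutation target selection,
  permutations) is seed-parameterized; the RNG state is saved and
  restored around every seeded block, so library calls never perturb a
  session's RNG.
* Identical inputs yield byte-identical serialized deltas and Turtle
  files; there are no unordered traversals anywhere in the pipeline.
* Degenerate inputs are defined: a zero-species/zero-reaction model is
  valid (empty lists); diffing a document against itself yields an empty
  delta; an empty annotation set serializes to prefixes only.
* Text comparison happens after whitespace normalization, so pure
  re-indentation produces an empty delta.
* `Update` operations require `oldValue != newValue`; the diff-XML parser
  enforces the per-kind operation schema and lists every violation.

# Limitations

* Rule tables match qualified names as written (`rdf:RDF`); a document
  binding the RDF namespace to an unconventional prefix will miss the
  `ModelAnnotation` element rule (attribute and namespace rules are
  unaffected).
* The matcher assumes identity attributes are unique per document, as the
  formats require; duplicate ids degrade gracefully to structural
  matching.
* CellML connectivity changes (`component`, `connection`) are classified
  as generic `ModelDefinition`, not `ReactionNetworkDefinition`: core
  CellML has no explicit reaction list, so claiming network semantics for
  component wiring would over-interpret the encoding.
* Diffing non-XML model code is out of scope.
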