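---
title: "alignqc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{alignqc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alignqc)
```

# The problem

A reference alignment is a curated set of correspondences — pairs of
classes from two ontologies together with a relation, here
`equivalentClass`, `subClassOf`, `superClassOf`, or `relatedTo` — used as
ground truth when evaluating automatic ontology-matching systems. Such
alignments are maintained separately from the ontologies they connect,
and both sides evolve. alignqc implements ten basic sanity checks that
catch the recurring failure modes before an alignment is used for
evaluation: five usability checks (provenance, missing classes, label
drift, format, reference ambiguity, relation typing) and five content
checks (redundant equivalence targets, entailed subsumptions, lexically
evident missing correspondences, trivialness statistics). The tool is a
detector, not a repairer: every finding is evidence for a curator, and
several worked examples in the test suite are deliberate false alarms a
curator would reject.

# The model

## Ontology model

An ontology document is reduced to: named classes explicitly typed as
`owl:Class` or `rdfs:Class`; their `rdfs:label` annotations; and the
asserted `subClassOf`, `equivalentClass`, part-of and `disjointWith`
edges between those classes. Anything anonymous (blank-node class
expressions) or merely mentioned (a superclass never declared a class) is
excluded, with a loader warning — correspondences reference named
entities, and the allowance of untyped elements is itself one of the
defects the checks look for. There is deliberately **no DL reasoning**:
closure queries are plain graph reachability over asserted `subClassOf`
edges. Subclass cycles (which occur in malformed inputs) are tolerated:
members of a cycle are mutual ancestors/descendants, and the strict
closure always excludes the query class itself.

## Entailment (Check 7)

For every equivalence correspondence `a ≡ b` with `a ∈ O₁`, `b ∈ O₂`:

```
inferred(a,b) = { x ⊑ y : x ∈ desc*(a), y ∈ anc*(b) } \ {(a,b)}
              ∪ { x ⊑ y : x ∈ desc*(b), y ∈ anc*(a) } \ {(b,a)}
```

with `desc*`/`anc*` reflexive closures. The union over all equivalences
is deduplicated; pairs whose subclass lives in O₂ are reported in O₁→O₂
orientation via `superClassOf`. Two scope decisions: the generating pair
itself is excluded (it is already asserted), and entailments are **not
chained across equivalences** — each inference uses exactly one
equivalence plus the two taxonomies. The acceptance suite checks this
definition against an independent brute-force oracle (boolean
reachability matrices by repeated squaring, then exhaustive enumeration
over all cross-ontology pairs) on random DAGs up to 100 classes per side.

## Lexical layer (Checks 8, 9, 10)

Normalization splits CamelCase (including acronym boundaries:
`NCIThesaurus` → `nci thesaurus`), maps underscores and hyphens to
spaces, strips other punctuation (digits are kept as token material),
lowercases, and tokenizes. It is idempotent on its own rendering, which
the property tests verify.

*Inclusion* is contiguous token-subsequence, not substring — so "male"
is not inside "female", and "brain matter" is not inside "brain white
matter". *Head extraction* is a heuristic, not a parser: the head is the
rightmost token, unless a preposition occurs at token position ≥ 2, in
which case the head is the token immediately before the first such
preposition ("professor of biology" → *professor*, leftmost head;
"doctoral thesis" → *thesis*, rightmost). The position-≥-2 guard is a
deliberate refinement: a label that *begins* with a preposition
("InBook" → "in book") is a noun phrase with a leading particle, not an
empty head segment, and its head is still the rightmost token (*book*) —
without the guard the detector could never flag the InBook/Book kind of
pair that it is expected to surface for review. The default preposition
set is `of, in, for, by, with, at, to, from, on`; it is a parameter
because no canonical list exists for ontology labels.

Checks 8 and 9 compare **all** labels of a class (synonyms included),
falling back to the normalized local name for label-less classes; a
`label_mode = "preferred"` switch restricts to preferred labels, since it
is genuinely unknowable whether published counts of this kind used
synonyms. Check 9 suppresses pairs already covered by an equivalence
correspondence (inclusion evidence argues for subsumption only where
equivalence is not already asserted) and by an asserted subsumption
correspondence; a proposal that Check 7 also derives is still reported,
with that coverage noted in the payload — the two checks are independent
evidence sources and a curator wants to see their agreement, not have one
silence the other.

Check 10 calls an equivalence trivial iff the two classes share a
normalized label, and a subsumption trivial iff the subclass's label
strictly includes the superclass's with an identical head. By
construction these definitions are the mirror image of the Check 8/9
detectors, and a property test verifies the coupling: removing a trivial
correspondence from an alignment makes exactly that pair reappear as a
Check 8 (or 9) finding.

# Execution order and branching

`run_all()` executes 1, 2a, 2b, 3, 4, 5, 6, 7, 8, 9, 10 with three
branch rules: Check 2 is skipped when Check 1 passes (verified
provenance makes class/label drift impossible); Checks 7 and 9 are
skipped when subsumption correspondences are out of the alignment's
scope (`include_subclass = FALSE`); and Checks 6–10 are skipped when
Check 5 finds untyped relations, because they all dispatch on relation
type. The last skip can be overridden (`allow_untyped = TRUE`), in which
case 6–10 run on the typed subset — the fixture tests use this to verify
all categories in one run. Every skip is recorded with its reason, and
findings are sorted so that two runs on identical inputs produce
byte-identical reports.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cleanup` | `FALSE` | strip all whitespace and surrounding quotes from entity references before lookup; every repair is logged. Off by default: repairing is a change of evidence. |
| `force_untyped` | `FALSE` | treat all relation markings as unknown, for files whose uniform markings are known to be technical artifacts |
| `allow_untyped` | `FALSE` | run 6–10 on the typed subset despite Check 5 findings |
| `include_subclass` | `TRUE` | whether ⊑ correspondences are in scope (controls 7 and 9) |
| `label_mode` | `"all"` | synonym labels vs preferred label only in 8/9/10 |
| `preposition_set` | 9 common English prepositions | head-extraction delimiter tokens |
| `import_depth_limit` | 10 | recursion bound for `owl:imports`; cyclic imports load once regardless |

# The fixture generator

`generate_fixture()` is first-class, tested code, not a throwaway
helper. It builds two random tree taxonomies over a generated
pseudo-word vocabulary, constructs the *correct complete* alignment for
the lexical material it planted (equivalences for shared-label pairs,
subsumptions for inclusion-plus-head pairs), then applies defects in a
fixed order — structural (class deletion with child reattachment, extra
equivalence targets), lexical (renames, label swaps, namespace twins for
ambiguity), file-level (whitespace corruption, blanked relation cells) —
recording for each category the exact finding keys the corresponding
check must produce.

Two construction rules make the manifest exact *by construction* rather
than by running the checks:

* every lexical family consumes **fresh vocabulary tokens**, so no
  unplanned label identity or inclusion can arise between unrelated
  classes; and
* classes participating in subsumption correspondences are kept as
  isolated taxonomy roots, so an omitted subsumption can never be
  re-derived by Check 7 through an equivalence — its absence must
  surface lexically, in Check 9, which is the planted signal.

Defaults state the world once: 30 classes per side, two thirds of them
in correspondences (20), trivial fraction 0.6 — the share reported for
mature curated anatomy alignments — tree depth 4, all defect counts 0.
`trivial_fraction × n_correspondences` must be an integer; the generator
validates every feasibility constraint and names the violated one.

What the generator does **not** emulate: realistic anatomical
vocabulary, skewed label-length and synonym distributions, large flat
siblings sets, multilingual labels, or property restrictions. A green
planted-defect test therefore establishes that each check recovers
exactly the defects of its category under clean separability — it does
not establish detector precision on real, lexically tangled ontologies,
where Checks 8 and 9 are expected to raise curator-rejectable proposals
(that behavior is exercised separately by the worked false-alarm
examples).

# Numerical and degenerate-input choices

* Resolution statuses, not errors: a reference that cannot be resolved
  is `missing` or `ambiguous`, and the affected correspondence is
  excluded from the content checks with its exclusion counted.
* Malformed rows/cells are skipped with logged provenance; only an
  unreadable file, unparsable RDF, or a file with zero parseable
  correspondences is fatal.
* Duplicate correspondences keep the first occurrence, both on raw
  tokens at parse time and on resolved pairs after resolution.
* Preferred-label selection: untagged label first, then English, then
  document order — the multilingual case is genuinely unspecified
  territory and this is the conservative, deterministic choice.
* Preposition-only labels raise a degenerate-label error in head
  extraction; inside the checks they simply yield no head evidence.
* Findings are sorted by (category, entities, evidence); all set-valued
  outputs are sorted before comparison or serialization.

# Known limitations

* No logical coherence or consistency checking of the alignment against
  the ontologies (a complementary, reasoning-based concern).
* No EDOAL complex correspondences, instance or property
  correspondences — classes only.
* The RDF readers cover the constructs ontology documents actually use
  (typed nodes, resource/literal properties, blank nodes, imports);
  exotic RDF/XML abbreviations (`rdf:li`, reification) and Turtle
  collections are parsed permissively but not modeled.
* Remote ontologies are never fetched; a URL reference is itself a
  Check 1 finding, and failed imports are warnings.
* The head heuristic is a stand-in for syntactic analysis and is
  intentionally replaceable (it is a pure function of the token list).
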