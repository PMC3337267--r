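# alignqc — quality checks for ontology alignments

Manually curated reference alignments are the ground truth against which
ontology-matching systems are scored, but they decay: classes get deleted
from newer ontology releases, labels drift, alignment tables refer to
classes by ambiguous local names, relation types go missing, one class
ends up with several equivalence targets, and correspondences that are
logically or lexically evident are simply absent. `alignqc` loads the two
input ontologies and the alignment and runs **ten basic quality checks**
in a fixed order, reporting typed findings for a human curator — it never
repairs anything itself.

| Check | Question | Typical finding |
|---|---|---|
| 1 | Correct input ontologies given? | only download URLs, no versions |
| 2a | Referenced classes still present? | `missing_class` |
| 2b | URI/label pairs still valid? | `label_changed`, `swap_suspicion` |
| 3 | Standard distribution format? | `non_standard_format`, `malformed_row` |
| 4 | Class references unique? | `ambiguous_ref` (local names) |
| 5 | Relation types explicit? | `untyped_relation` |
| 6 | ≤ 1 equivalence target per class? | `multi_target` + target-pair relation |
| 7 | ⊆ entailed by ≡ + taxonomy | `inferred_subclass_new` |
| 8 | Identical labels without ≡? | `label_identity_missing_equiv` |
| 9 | Label inclusion + same head without ⊆? | `inclusion_missing_subclass` |
| 10 | How many correspondences are trivial? | `trivial` partition + fraction |

The content checks rest on two formal ingredients:

* **Entailment (Check 7).** An asserted equivalence `a ≡ b` between
  `a ∈ O₁` and `b ∈ O₂` entails `x ⊑ y` for every `x ∈ desc*(a)` and
  `y ∈ anc*(b)` (reflexive closures over asserted `subClassOf`, the
  generating pair itself excluded, no chaining across equivalences), and
  symmetrically for subclasses of `b` against superclasses of `a`.
* **Lexical evidence (Checks 8–10).** Labels are normalized (CamelCase
  split, underscore/hyphen removal, lowercasing, tokenization). Identity
  of normalized labels is evidence for `≡`; strict token-level inclusion
  with an identical syntactic head ("doctoral thesis" ⊐ "thesis", heads
  both *thesis*) is evidence for `⊑` with the longer label on the
  subclass side. A correspondence detectable by these means alone is
  *trivial*; the trivial fraction calibrates how hard an alignment really
  is for a matching system (the non-trivial part is what recall+ style
  measures look at).

Ontologies are read from RDF/XML or Turtle (asserted edges only — no DL
reasoning); alignments from the Alignment API RDF format or a delimited
table. A fixture generator builds synthetic ontology pairs with planted
defects and an exact expected-findings manifest, so the whole pipeline is
testable offline.

## Worked example

Generate a fixture with planted defects and run all checks:

```r
library(alignqc)
fx <- generate_fixture(fixture_spec(
  defect_rates = list(deleted_class = 2, omitted_trivial_equiv = 1,
                      multi_target = 1, whitespace_corruption = 1),
  seed = 11), "fixture_dir")
reports <- run_all(fx$paths$alignment, fx$paths$onto1, fx$paths$onto2,
                   qc_options(cleanup = TRUE,
                              mapping_tables = fx$mapping_tables))
writeLines(report_to_text(reports, max_findings = 2))
```

Output (abridged):

```
Check 1   findings
  [no_ontology_reference] onto1 — alignment does not reference this input ontology
Check 2a  findings
  missing_refs = 2, distinct_missing_classes = 2, affected_correspondences = 2
  [missing_class] onto2|MovuvoVemani — referenced at line 9, not found in ontology 2
Check 2b  pass
Check 3   findings
  [non_standard_format] fixture_dir/alignment.csv — alignment is distributed as a delimited table, ...
Check 4   pass
Check 5   pass
Check 6   findings
  [multi_target] onto1|http://example.org/onto1#DuteRire — targets {...#DuteRire, ...#VuboLupete}; ...
Check 7   findings
  inferred_total = 106, inferred_new = 106, excluded_correspondences = 2
Check 8   findings
  [label_identity_missing_equiv] ...onto1#DanupoTukilu|...onto2#DanupoTukilu — shared normalized label
Check 9   pass
Check 10  findings
  trivial = 11, non_trivial = 7, excluded = 2, trivial_fraction = 0.6111111
```

Reading this: the two deleted classes surface in Check 2a (the
whitespace-corrupted reference does *not*, because `cleanup = TRUE`
repaired it — rerun with `cleanup = FALSE` to see it as a third missing
class); the planted extra equivalence target surfaces in Check 6; the
omitted trivial equivalence resurfaces as the Check 8 pair; Check 7 lists
every subsumption the surviving equivalences entail; and Check 10's
fraction reflects the partition after two correspondences were excluded
for unresolvable references.

`qc_exit_code(reports)` gives the CLI convention: 0 all pass/skipped,
1 findings, 2 fatal error.

## Command line

```sh
exec/alignqc run -a alignment.rdf -1 onto1.owl -2 onto2.owl --json
exec/alignqc run -a table.csv -1 o1.owl -2 o2.owl --cleanup --no-subclass
exec/alignqc fixture --out fx/ --seed 7 --defect deleted_class=3
exec/alignqc infer -a a.rdf -1 o1.owl -2 o2.owl --out inferred.rdf
exec/alignqc trivial -a a.rdf -1 o1.owl -2 o2.owl
```

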