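Package: alignqc
Title: Quality Checks for Ontology Alignments
Version: 0.1.0
Authors@R:
    person("alignqc", "developers", email = "alignqc@example.org",
           role = c("aut", "cre"))
Description: Validates reference alignments between pairs of OWL/RDF(S)
    ontologies with ten basic quality checks: input provenance, missing
    classes, label drift against a curated mapping table, distribution
    format, ambiguity of class references, relation typing, multiple
    equivalence targets, subClassOf correspondences entailed by asserted
    equivalences plus the class taxonomies, lexically evident missing
    equivalences and subsumptions, and trivial-correspondence statistics.
    Includes parsers for RDF/XML and Turtle ontology documents and for the
    Alignment API RDF format as well as delimited alignment tables, a
    synthetic fixture generator that plants known defects for testing, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
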