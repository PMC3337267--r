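# Unit tests for the ten checks and the orchestrator.

# a small two-ontology anatomy world used by several checks
anatomy_world <- function() {
  doc1 <- toy_doc(
    c(Brain = "brain", Cortex = "cortex", RenalPapilla = "renal papilla",
      BrainWhiteMatter = "brain white matter",
      DoctoralThesis = "doctoral thesis"),
    subclass = list(c("Cortex", "Brain"), c("BrainWhiteMatter", "Brain")),
    ns = NS_A)
  doc2 <- toy_doc(
    c(Brain = "brain", Cerebrum = "cerebrum", RenalPapilla = "renal papilla",
      Thesis = "thesis"),
    subclass = list(c("Cerebrum", "Brain")),
    ns = NS_B)
  list(doc1 = doc1, doc2 = doc2)
}

u1 <- function(x) paste0(NS_A, x)
u2 <- function(x) paste0(NS_B, x)

test_that("check 1 passes only for bundled, versioned, matching inputs", {
  w <- anatomy_world()
  f <- tempfile(fileext = ".csv")
  writeLines("Brain,Brain,equivalentClass", f)
  al <- parse_alignment(f, dialect = "delimited", has_header = FALSE)

  al$onto1_ref <- w$doc1$ontology_iri; al$onto2_ref <- w$doc2$ontology_iri
  expect_equal(check1_input_provenance(al, w$doc1, w$doc2)$status, "pass")

  al$onto1_ref <- ""
  r <- check1_input_provenance(al, w$doc1, w$doc2)
  expect_equal(finding_keys(r, "no_ontology_reference"), "onto1")

  al$onto1_ref <- "http://download.example/onto.owl"
  r <- check1_input_provenance(al, w$doc1, w$doc2)
  expect_equal(nrow(r$findings[r$findings$category ==
                                 "remote_ontology_reference", ]), 1L)

  al$onto1_ref <- w$doc1$ontology_iri
  doc1_nv <- w$doc1; doc1_nv$version_info <- ""
  r <- check1_input_provenance(al, doc1_nv, w$doc2)
  expect_equal(finding_keys(r, "version_unverifiable"), "onto1")
})

test_that("check 2a counts missing classes and affected correspondences", {
  w <- anatomy_world()
  al <- alignment_from_df(data.frame(
    uri1 = c("Brain", "RenalPapilla"), uri2 = c("Brain", "RenalPapilla"),
    relation = "equivalentClass"), w$doc1, w$doc2)
  expect_equal(check2a_missing_classes(al, w$doc1, w$doc2)$status, "pass")

  # 2 deleted classes on side 2, referenced by 3 correspondences
  al <- alignment_from_df(data.frame(
    uri1 = c("Brain", "Cortex", "RenalPapilla"),
    uri2 = c("GoneA", "GoneA", "GoneB"),
    relation = "equivalentClass"), w$doc1, w$doc2)
  r <- check2a_missing_classes(al, w$doc1, w$doc2)
  expect_equal(r$status, "findings")
  expect_equal(nrow(r$findings), 3L)
  expect_equal(r$summary_counts$distinct_missing_classes, 2L)
  expect_equal(r$summary_counts$affected_correspondences, 3L)
  expect_error(check2a_missing_classes(parse_alignment(al$source_path,
                                                       dialect = "delimited"),
                                       w$doc1, w$doc2), "resolved")
})

test_that("check 2b flags label changes, swaps, and vanished URIs", {
  doc <- toy_doc(c(C1 = "Cerebral Cortex", C2 = "stable",
                   W = "brain grey matter", G = "brain white matter"),
                 ns = NS_A)
  tab <- data.frame(
    uri = u1(c("C1", "C2", "W", "G", "Gone")),
    expected_label = c("Cortex", "stable", "brain white matter",
                       "brain grey matter", "whatever"),
    stringsAsFactors = FALSE)
  r <- check2b_label_changes(list(onto1 = tab), doc, doc)
  expect_equal(finding_keys(r, "label_changed"), paste0("onto1|", u1("C1")))
  expect_match(r$findings$evidence[r$findings$category == "label_changed"],
               "from 'Cortex' to 'Cerebral Cortex'")
  expect_equal(finding_keys(r, "swap_suspicion"),
               paste0("onto1|", u1("G"), "|", u1("W")))
  expect_equal(finding_keys(r, "missing_class"), paste0("onto1|", u1("Gone")))
  # without a table the check is not applicable
  expect_equal(check2b_label_changes(NULL, doc, doc)$status, "not_applicable")
})

test_that("check 3 accepts only clean Alignment API documents", {
  w <- anatomy_world()
  al_api <- alignment_from_df(data.frame(uri1 = "Brain", uri2 = "Brain",
                                         relation = "equivalentClass"),
                              w$doc1, w$doc2)
  out <- tempfile(fileext = ".rdf")
  write_alignment(al_api, out)
  expect_equal(check3_format(parse_alignment(out))$status, "pass")

  f <- tempfile(fileext = ".csv")
  writeLines(c("entity1,entity2,relation", "Brain,Brain,equivalentClass",
               "NoSecond,,equivalentClass", ",AlsoBad,subClassOf"), f)
  r <- check3_format(parse_alignment(f, dialect = "delimited"))
  expect_equal(sum(r$findings$category == "non_standard_format"), 1L)
  expect_equal(sum(r$findings$category == "malformed_row"), 2L)
})

test_that("check 4 reports each ambiguous reference with its candidates", {
  doc1 <- toy_doc(c(Brain = "brain"), ns = NS_A)
  doc2 <- ontology_document(
    classes = data.frame(uri = c(u2("Lung"), "http://test.example/other#Lung",
                                 u2("Heart")), stringsAsFactors = FALSE),
    ontology_iri = "http://test.example/b", version_info = "1")
  al <- alignment_from_df(data.frame(
    uri1 = c("Brain", "Brain"), uri2 = c("Lung", "Heart"),
    relation = c("equivalentClass", "subClassOf")), doc1, doc2)
  r <- check4_reference_ambiguity(al, doc1, doc2)
  expect_equal(finding_keys(r, "ambiguous_ref"), "onto2|Lung")
  expect_match(r$findings$evidence[1], "other#Lung")
  # URI references can never be ambiguous
  al2 <- alignment_from_df(data.frame(uri1 = u1("Brain"), uri2 = u2("Heart"),
                                      relation = "equivalentClass"),
                           doc1, doc2)
  expect_equal(check4_reference_ambiguity(al2, doc1, doc2)$status, "pass")
})

test_that("check 5 flags untyped relations, including forced ones", {
  w <- anatomy_world()
  al <- alignment_from_df(data.frame(
    uri1 = c("Brain", "Cortex", "RenalPapilla"),
    uri2 = c("Brain", "Cerebrum", "RenalPapilla"),
    relation = c("equivalentClass", "", "")), w$doc1, w$doc2)
  r <- check5_relation_types(al)
  expect_equal(nrow(r$findings), 2L)
  expect_equal(r$summary_counts$untyped, 2L)

  al_forced <- alignment_from_df(data.frame(
    uri1 = "Brain", uri2 = "Brain", relation = "equivalentClass"),
    w$doc1, w$doc2, force_untyped = TRUE)
  r <- check5_relation_types(al_forced)
  expect_equal(nrow(r$findings), 1L)
  expect_match(r$findings$evidence[1], "forced")
})

test_that("check 6 classifies the relation between multiple targets", {
  doc1 <- toy_doc(c(A = "a", B = "b"), ns = NS_A)
  doc2 <- toy_doc(
    c(P = "p", Q = "q", R = "r", S = "s", T = "t", Parent = "parent"),
    subclass = list(c("Q", "P"), c("S", "Parent"), c("T", "Parent")),
    equiv = list(c("P", "R")), ns = NS_B)
  al <- alignment_from_df(data.frame(
    uri1 = c("A", "A", "A", "B", "B"),
    uri2 = c("P", "Q", "R", "S", "T"),
    relation = "equivalentClass"), doc1, doc2)
  r <- check6_multiple_targets(al, doc1, doc2)
  expect_equal(finding_keys(r, "multi_target"),
               paste0("onto1|", u1(c("A", "B"))))
  ev_a <- r$findings$evidence[r$findings$entities == paste0("onto1|", u1("A"))]
  expect_match(ev_a, "equivalentClass")
  expect_match(ev_a, "subClassOf")
  ev_b <- r$findings$evidence[r$findings$entities == paste0("onto1|", u1("B"))]
  expect_match(ev_b, "sibling")
})

test_that("check 6 runs in both directions and passes on injective alignments", {
  doc1 <- toy_doc(c(A = "a", B = "b"), partof = list(c("A", "B")), ns = NS_A)
  doc2 <- toy_doc(c(P = "p", Q = "q"), disjoint = list(c("P", "Q")), ns = NS_B)
  inj <- alignment_from_df(data.frame(uri1 = c("A", "B"), uri2 = c("P", "Q"),
                                      relation = "equivalentClass"),
                           doc1, doc2)
  expect_equal(check6_multiple_targets(inj, doc1, doc2)$status, "pass")

  rev <- alignment_from_df(data.frame(uri1 = c("A", "B"), uri2 = c("P", "P"),
                                      relation = "equivalentClass"),
                           doc1, doc2)
  r <- check6_multiple_targets(rev, doc1, doc2)
  expect_equal(finding_keys(r, "multi_target"), paste0("onto2|", u2("P")))
  expect_match(r$findings$evidence[1], "partOf")
})

test_that("check 7 on the smallest nontrivial closure", {
  # equiv(a, b); a has one child a2, b has one parent b2
  doc1 <- toy_doc(c(A = "a", A2 = "a2"), subclass = list(c("A2", "A")),
                  ns = NS_A)
  doc2 <- toy_doc(c(B = "b", B2 = "b2"), subclass = list(c("B", "B2")),
                  ns = NS_B)
  al <- alignment_from_df(data.frame(uri1 = "A", uri2 = "B",
                                     relation = "equivalentClass"),
                          doc1, doc2)
  inferred <- infer_subclass_correspondences(al, doc1, doc2)
  expect_equal(nrow(inferred), 3L)
  expect_setequal(paste(inferred$sub, inferred$super),
                  c(paste(u1("A2"), u2("B")), paste(u1("A2"), u2("B2")),
                    paste(u1("A"), u2("B2"))))
  r <- check7_inferred_subclass(al, doc1, doc2)
  expect_equal(r$summary_counts$inferred_total, 3L)
  expect_equal(r$summary_counts$inferred_new, 3L)
})

test_that("check 7 is empty on flat taxonomies and labels present pairs", {
  doc1 <- toy_doc(c(A = "a", A2 = "a2"), subclass = list(c("A2", "A")),
                  ns = NS_A)
  doc2 <- toy_doc(c(B = "b"), ns = NS_B)
  flat1 <- toy_doc(c(A = "a"), ns = NS_A)
  al_flat <- alignment_from_df(data.frame(uri1 = "A", uri2 = "B",
                                          relation = "equivalentClass"),
                               flat1, doc2)
  expect_equal(check7_inferred_subclass(al_flat, flat1,
                                        doc2)$summary_counts$inferred_total, 0L)

  al <- alignment_from_df(data.frame(
    uri1 = c("A", "A2"), uri2 = c("B", "B"),
    relation = c("equivalentClass", "subClassOf")), doc1, doc2)
  r <- check7_inferred_subclass(al, doc1, doc2)
  expect_equal(r$summary_counts$inferred_total, 1L)
  expect_equal(r$summary_counts$inferred_new, 0L)
  expect_equal(r$findings$category, "inferred_subclass_present")
})

test_that("check 7 equals brute-force entailment on a random fixture", {
  set.seed(2024)
  doc1 <- random_dag_doc(20, NS_A, p = 0.12)
  doc2 <- random_dag_doc(20, NS_B, p = 0.12)
  df <- data.frame(uri1 = sample(doc1$classes$uri, 5),
                   uri2 = sample(doc2$classes$uri, 5),
                   relation = "equivalentClass")
  al <- alignment_from_df(df, doc1, doc2)
  inferred <- infer_subclass_correspondences(al, doc1, doc2)

  R1 <- closure_matrix(doc1); R2 <- closure_matrix(doc2)
  desc_refl <- function(R, u) c(u, rownames(R)[R[, u]])
  anc_refl <- function(R, u) c(u, colnames(R)[R[u, ]])
  expected <- character()
  for (k in seq_len(nrow(df))) {
    a <- df$uri1[k]; b <- df$uri2[k]
    for (x in desc_refl(R1, a)) for (y in anc_refl(R2, b)) {
      if (!(x == a && y == b)) expected <- c(expected, paste(x, y, 1))
    }
    for (x in desc_refl(R2, b)) for (y in anc_refl(R1, a)) {
      if (!(x == b && y == a)) expected <- c(expected, paste(x, y, 2))
    }
  }
  expect_setequal(paste(inferred$sub, inferred$super, inferred$sub_side),
                  unique(expected))
})

label_world <- function() {
  doc1 <- toy_doc(c(RenalPapilla = "renal papilla", RecordLabel = "record label",
                    InBook = "", Brain = "brain"), ns = NS_A)
  doc2 <- toy_doc(c(RenalPapilla = "renal papilla", Label = "label",
                    Book = "", Cerebrum = "brain"), ns = NS_B)
  list(doc1 = doc1, doc2 = doc2)
}

test_that("check 8 finds identical labels lacking an equivalence", {
  w <- label_world()
  al <- alignment_from_df(data.frame(uri1 = "RenalPapilla",
                                     uri2 = "RenalPapilla",
                                     relation = "equivalentClass"),
                          w$doc1, w$doc2)
  r <- check8_label_identity(al, w$doc1, w$doc2)
  # "brain" pair is missing; "renal papilla" pair is covered
  expect_equal(finding_keys(r, "label_identity_missing_equiv"),
               paste0(u1("Brain"), "|", u2("Cerebrum")))
  # adding the missing equivalence silences the check (monotonicity)
  al2 <- alignment_from_df(data.frame(
    uri1 = c("RenalPapilla", "Brain"), uri2 = c("RenalPapilla", "Cerebrum"),
    relation = "equivalentClass"), w$doc1, w$doc2)
  expect_equal(check8_label_identity(al2, w$doc1, w$doc2)$status, "pass")
})

test_that("check 8 reports literally shared URIs separately", {
  shared <- "http://thirdparty.example/time#Instant"
  doc1 <- ontology_document(
    classes = data.frame(uri = c(u1("A"), shared), stringsAsFactors = FALSE),
    labels = data.frame(uri = u1("A"), text = "alpha", lang = "",
                        stringsAsFactors = FALSE),
    ontology_iri = "http://test.example/a", version_info = "1")
  doc2 <- ontology_document(
    classes = data.frame(uri = c(u2("B"), shared), stringsAsFactors = FALSE),
    labels = data.frame(uri = u2("B"), text = "beta", lang = "",
                        stringsAsFactors = FALSE),
    ontology_iri = "http://test.example/b", version_info = "1")
  al <- alignment_from_df(data.frame(uri1 = u1("A"), uri2 = u2("B"),
                                     relation = "equivalentClass"),
                          doc1, doc2)
  r <- check8_label_identity(al, doc1, doc2)
  expect_equal(finding_keys(r, "shared_uri"), paste0(shared, "|", shared))
  expect_length(finding_keys(r, "label_identity_missing_equiv"), 0L)
})

test_that("check 9 proposes subsumptions from inclusion plus equal heads", {
  w <- label_world()
  al <- alignment_from_df(data.frame(uri1 = "Brain", uri2 = "Cerebrum",
                                     relation = "equivalentClass"),
                          w$doc1, w$doc2)
  r <- check9_label_inclusion(al, w$doc1, w$doc2)
  keys <- finding_keys(r, "inclusion_missing_subclass")
  # RecordLabel (local-name fallback "record label") below Label, and
  # InBook below Book: both detected, direction longer -> subclass
  expect_true(paste0(u1("RecordLabel"), "|subClassOf|", u2("Label")) %in% keys)
  expect_true(paste0(u1("InBook"), "|subClassOf|", u2("Book")) %in% keys)
})

test_that("check 9 respects heads, direction, and existing correspondences", {
  doc1 <- toy_doc(c(ArchOfAorta = "arch of aorta",
                    DoctoralThesis = "doctoral thesis"), ns = NS_A)
  doc2 <- toy_doc(c(Aorta = "aorta", Thesis = "thesis"), ns = NS_B)
  al0 <- alignment_from_df(data.frame(uri1 = "DoctoralThesis", uri2 = "Thesis",
                                      relation = "subClassOf"), doc1, doc2)
  r <- check9_label_inclusion(al0, doc1, doc2)
  # thesis pair asserted; aorta pair has different heads: nothing to report
  expect_equal(r$status, "pass")

  # suppression by an equivalence correspondence
  al1 <- alignment_from_df(data.frame(uri1 = "DoctoralThesis", uri2 = "Thesis",
                                      relation = "equivalentClass"),
                           doc1, doc2)
  expect_equal(check9_label_inclusion(al1, doc1, doc2)$status, "pass")

  # without any correspondence the proposal appears, oriented sub first
  al2 <- alignment_from_df(data.frame(uri1 = "ArchOfAorta", uri2 = "Aorta",
                                      relation = "equivalentClass"),
                           doc1, doc2)
  r2 <- check9_label_inclusion(al2, doc1, doc2)
  expect_equal(finding_keys(r2, "inclusion_missing_subclass"),
               paste0(u1("DoctoralThesis"), "|subClassOf|", u2("Thesis")))
})

test_that("check 9 notes proposals already inferred by check 7", {
  doc1 <- toy_doc(c(Thing = "entity", DoctoralThesis = "doctoral thesis"),
                  subclass = list(c("DoctoralThesis", "Thing")), ns = NS_A)
  doc2 <- toy_doc(c(Item = "entity item", Thesis = "thesis"),
                  subclass = list(c("Item", "Thesis")), ns = NS_B)
  al <- alignment_from_df(data.frame(uri1 = "DoctoralThesis", uri2 = "Item",
                                     relation = "equivalentClass"),
                          doc1, doc2)
  r <- check9_label_inclusion(al, doc1, doc2)
  idx <- which(r$findings$entities ==
                 paste0(u1("DoctoralThesis"), "|subClassOf|", u2("Thesis")))
  expect_length(idx, 1L)
  expect_match(r$findings$evidence[idx], "already inferred by Check 7")
})

test_that("check 10 partitions correspondences exactly", {
  doc1 <- toy_doc(c(RenalPapilla = "renal papilla", Nostril = "nostril",
                    DoctoralThesis = "doctoral thesis", Blue = "blue marker"),
                  ns = NS_A)
  doc2 <- toy_doc(c(RenalPapilla = "renal papilla", ExternalNare = "external nare",
                    Thesis = "thesis", Marker = "marker"), ns = NS_B)
  al <- alignment_from_df(data.frame(
    uri1 = c("RenalPapilla", "Nostril", "DoctoralThesis", "Blue"),
    uri2 = c("RenalPapilla", "ExternalNare", "Thesis", "Marker"),
    relation = c("equivalentClass", "equivalentClass", "subClassOf",
                 "subClassOf")), doc1, doc2)
  r <- check10_trivial(al, doc1, doc2)
  keys <- finding_keys(r, "trivial")
  expect_setequal(keys, c(
    paste0(u1("RenalPapilla"), "|equivalentClass|", u2("RenalPapilla")),
    paste0(u1("DoctoralThesis"), "|subClassOf|", u2("Thesis")),
    paste0(u1("Blue"), "|subClassOf|", u2("Marker"))))
  expect_equal(r$summary_counts$trivial, 3L)
  expect_equal(r$summary_counts$non_trivial, 1L)   # the synonym pair
  expect_equal(r$summary_counts$trivial_fraction, 0.75)
})

test_that("checks 8/10 and 9/10 detectors are mutually consistent", {
  # every trivial equivalence, if removed, must be re-detected by check 8;
  # every trivial subsumption by check 9 (and vice versa)
  set.seed(5)
  fx <- generate_fixture(fixture_spec(seed = 50), tempfile())
  doc1 <- fx$doc1; doc2 <- fx$doc2
  al <- resolve_references(parse_alignment(fx$paths$alignment,
                                           dialect = "delimited"),
                           doc1, doc2)
  r10 <- check10_trivial(al, doc1, doc2)
  trivial_keys <- finding_keys(r10, "trivial")
  corr <- al$correspondences
  for (key in sample(trivial_keys, min(4, length(trivial_keys)))) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    drop <- which(corr$resolved_uri1 == parts[1] &
                    corr$relation == parts[2] &
                    corr$resolved_uri2 == parts[3])
    al_min <- al
    al_min$correspondences <- corr[-drop, , drop = FALSE]
    al_min$candidates1 <- al$candidates1[-drop]
    al_min$candidates2 <- al$candidates2[-drop]
    if (parts[2] == "equivalentClass") {
      r8 <- check8_label_identity(al_min, doc1, doc2)
      expect_true(paste0(parts[1], "|", parts[3]) %in%
                    finding_keys(r8, "label_identity_missing_equiv"))
    } else {
      r9 <- check9_label_inclusion(al_min, doc1, doc2)
      expect_true(key %in% finding_keys(r9, "inclusion_missing_subclass"))
    }
  }
})

test_that("run_all follows the execution order and branching rules", {
  fx <- generate_fixture(fixture_spec(seed = 8), tempfile())
  reports <- run_all(fx$paths$alignment, fx$paths$onto1, fx$paths$onto2,
                     qc_options())
  expect_equal(names(reports),
               c("1", "2a", "2b", "3", "4", "5", "6", "7", "8", "9", "10"))
  # delimited fixture: check 1 fails, 2a runs, 2b lacks tables
  expect_equal(reports[["1"]]$status, "findings")
  expect_equal(reports[["2a"]]$status, "pass")
  expect_equal(reports[["2b"]]$status, "not_applicable")

  # subclass correspondences out of scope: 7 and 9 skipped
  no_sub <- run_all(fx$paths$alignment, fx$doc1, fx$doc2,
                    qc_options(include_subclass = FALSE))
  expect_equal(no_sub[["7"]]$status, "skipped")
  expect_equal(no_sub[["9"]]$status, "skipped")
  expect_equal(no_sub[["8"]]$status, "pass")

  # forcing untyped relations blocks checks 6-10
  forced <- run_all(fx$paths$alignment, fx$doc1, fx$doc2,
                    qc_options(force_untyped = TRUE))
  expect_equal(forced[["5"]]$status, "findings")
  for (id in c("6", "7", "8", "9", "10")) {
    expect_equal(forced[[id]]$status, "skipped", info = id)
  }

  # check 1 pass (alignment_api fixture) skips check 2 entirely
  fx_api <- generate_fixture(fixture_spec(seed = 8, dialect = "alignment_api"),
                             tempfile())
  api_reports <- run_all(fx_api$paths$alignment, fx_api$paths$onto1,
                         fx_api$paths$onto2, qc_options())
  expect_equal(api_reports[["1"]]$status, "pass")
  expect_equal(api_reports[["2a"]]$status, "skipped")
  expect_equal(api_reports[["2b"]]$status, "skipped")
})

test_that("reports are deterministic across runs", {
  spec <- full_defect_spec(13L)
  fx <- generate_fixture(spec, tempfile())
  opts <- qc_options(cleanup = TRUE, allow_untyped = TRUE,
                     mapping_tables = fx$mapping_tables)
  r1 <- run_all(fx$paths$alignment, fx$paths$onto1, fx$paths$onto2, opts)
  r2 <- run_all(fx$paths$alignment, fx$paths$onto1, fx$paths$onto2, opts)
  for (id in names(r1)) {
    expect_identical(r1[[id]]$findings, r2[[id]]$findings, info = id)
    expect_identical(r1[[id]]$summary_counts, r2[[id]]$summary_counts,
                     info = id)
  }
  expect_identical(as.character(report_to_json(r1)),
                   as.character(report_to_json(r2)))
})

test_that("JSON report serialization matches the documented shape", {
  fx <- generate_fixture(fixture_spec(seed = 4), tempfile())
  reports <- run_all(fx$paths$alignment, fx$doc1, fx$doc2, qc_options())
  parsed <- jsonlite::fromJSON(report_to_json(reports),
                               simplifyVector = FALSE)
  expect_length(parsed, 11L)
  expect_setequal(vapply(parsed, `[[`, "", "check_id"),
                  c("1", "2a", "2b", "3", "4", "5", "6", "7", "8", "9", "10"))
  for (p in parsed) {
    expect_true(all(c("status", "summary_counts", "findings") %in% names(p)))
  }
})
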