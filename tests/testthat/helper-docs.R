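# Shared builders: in-code ontology documents, random DAGs with an
# independent closure oracle, and quick alignment construction via the
# delimited on-disk round trip.

NS_A <- "http://test.example/a#"
NS_B <- "http://test.example/b#"

# labels: named character vector local_name -> label (label may be "")
# subclass/partof/equiv/disjoint: list of c(child_local, parent_local)
toy_doc <- function(labels, subclass = list(), partof = list(),
                    equiv = list(), disjoint = list(), ns = NS_A,
                    ontology_iri = sub("#$", "", ns), version_info = "1.0") {
  uris <- paste0(ns, names(labels))
  lab_rows <- labels[nzchar(labels)]
  to_edges <- function(pairs) {
    if (length(pairs) == 0) return(alignqc:::edge_df())
    alignqc:::edge_df(paste0(ns, vapply(pairs, `[`, "", 1)),
                      paste0(ns, vapply(pairs, `[`, "", 2)))
  }
  lab_df <- if (length(lab_rows) == 0) NULL else
    data.frame(uri = paste0(ns, names(lab_rows)), text = unname(lab_rows),
               lang = rep("", length(lab_rows)), stringsAsFactors = FALSE)
  ontology_document(
    classes = data.frame(uri = uris, stringsAsFactors = FALSE),
    labels = lab_df,
    subclass_edges = to_edges(subclass), partof_edges = to_edges(partof),
    equivalence_edges = to_edges(equiv), disjoint_edges = to_edges(disjoint),
    ontology_iri = ontology_iri, version_info = version_info
  )
}

# random DAG document: edges go from higher to lower index (child -> parent)
random_dag_doc <- function(n, ns, p = 0.08) {
  locals <- sprintf("C%03d", seq_len(n))
  uris <- paste0(ns, locals)
  from <- character(); to <- character()
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (stats::runif(1) < p) {
        from <- c(from, uris[i]); to <- c(to, uris[j])
      }
    }
  }
  ontology_document(
    classes = data.frame(uri = uris, stringsAsFactors = FALSE),
    subclass_edges = alignqc:::edge_df(from, to),
    ontology_iri = sub("#$", "", ns), version_info = "1.0"
  )
}

# independent oracle: boolean reachability matrix by repeated squaring;
# M[x, y] TRUE iff y is a strict ancestor of x
closure_matrix <- function(doc) {
  uris <- doc$classes$uri
  n <- length(uris)
  M <- matrix(FALSE, n, n, dimnames = list(uris, uris))
  e <- doc$taxonomy$subclass_edges
  M[cbind(e$from, e$to)] <- TRUE
  R <- M
  repeat {
    Rn <- R | ((R %*% R) > 0)
    if (identical(Rn, R)) break
    R <- Rn
  }
  R
}

# write a (uri1, uri2, relation) data frame as a delimited alignment and
# parse + resolve it back; relation uses the keyword family
alignment_from_df <- function(df, doc1, doc2, cleanup = FALSE,
                              force_untyped = FALSE) {
  path <- tempfile(fileext = ".csv")
  writeLines(c("entity1,entity2,relation",
               paste(df$uri1, df$uri2, df$relation, sep = ",")), path)
  al <- parse_alignment(path, dialect = "delimited",
                        force_untyped = force_untyped)
  resolve_references(al, doc1, doc2, cleanup = cleanup)
}

finding_keys <- function(report, category) {
  sort(report$findings$entities[report$findings$category == category])
}

# a fixture spec exercising every defect category at once
full_defect_spec <- function(seed) {
  k <- 1L + (seed %% 2L)   # vary counts across seeds
  fixture_spec(
    n_classes_per_side = 33L,
    defect_rates = list(deleted_class = k, renamed_label = k + 1L,
                        swapped_label_pair = 1L, whitespace_corruption = k,
                        ambiguous_local_name = 1L, multi_target = k,
                        omitted_trivial_equiv = k,
                        omitted_trivial_subclass = 1L,
                        untyped_relation = 1L),
    trivial_fraction = 0.5, seed = seed)
}
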