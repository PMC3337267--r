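# Synthetic fixture generator.
#
# Builds a pair of random ontologies over a generated vocabulary together
# with a correct, complete alignment, then plants a requested number of
# defects of each category and records exactly which findings each check
# must produce. Every lexical family (a correspondence, a filler class, a
# renamed label, ...) consumes fresh vocabulary tokens, so no unplanned
# label identity or inclusion can arise: the manifest is exact by
# construction, not by running the checks.

FIXTURE_NS1 <- "http://example.org/onto1#"
FIXTURE_NS2 <- "http://example.org/onto2#"
FIXTURE_NS_ALT <- "http://example.org/imported#"

DEFECT_CATEGORIES <- c("deleted_class", "renamed_label", "swapped_label_pair",
                       "whitespace_corruption", "ambiguous_local_name",
                       "multi_target", "omitted_trivial_equiv",
                       "omitted_trivial_subclass", "untyped_relation")

#' Specification of a synthetic fixture
#'
#' Defaults describe a small but fully featured test world: 30 classes per
#' side, 20 correspondences (two thirds of the classes participate), a 60%
#' trivial fraction (the order of magnitude observed in mature
#' manually curated anatomy alignments), and no defects.
#'
#' @param n_classes_per_side Classes per ontology (before defects).
#' @param max_depth Maximum taxonomy depth of the generated trees.
#' @param label_vocabulary_size Number of distinct pseudo-word tokens
#'   available; the generator errors when the spec needs more.
#' @param defect_rates Named list of planted-defect counts; see
#'   `DEFECT_CATEGORIES` for the recognised names (unlisted categories
#'   default to 0).
#' @param trivial_fraction Fraction of correspondences that must be
#'   trivial; `trivial_fraction * n_correspondences` must be an integer.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @param dialect `"delimited"` (local-name references; required for
#'   ambiguity defects) or `"alignment_api"` (URI references).
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_classes_per_side = 30L, max_depth = 4L,
                         label_vocabulary_size = 250L,
                         defect_rates = list(), trivial_fraction = 0.6,
                         seed = 1L,
                         dialect = c("delimited", "alignment_api")) {
  dialect <- match.arg(dialect)
  unknown <- setdiff(names(defect_rates), DEFECT_CATEGORIES)
  if (length(unknown) > 0L) {
    stop("unknown defect categor", if (length(unknown) > 1) "ies: " else "y: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  rates <- stats::setNames(rep(0L, length(DEFECT_CATEGORIES)),
                           DEFECT_CATEGORIES)
  for (nm in names(defect_rates)) rates[[nm]] <- as.integer(defect_rates[[nm]])
  if (any(rates < 0L)) stop("defect counts must be non-negative", call. = FALSE)

  n <- as.integer(n_classes_per_side)
  n_corr <- as.integer(floor(2 * n / 3))
  n_trivial <- trivial_fraction * n_corr
  if (abs(n_trivial - round(n_trivial)) > 1e-9) {
    stop("infeasible spec: trivial_fraction * ", n_corr,
         " correspondences = ", n_trivial, " is not an integer",
         call. = FALSE)
  }
  n_trivial <- as.integer(round(n_trivial))
  te <- as.integer(ceiling(2 * n_trivial / 3)); ts <- n_trivial - te
  n_nontrivial <- n_corr - n_trivial
  ne <- as.integer(ceiling(2 * n_nontrivial / 3)); ns <- n_nontrivial - ne
  fillers <- n - n_corr

  need <- function(cond, msg) if (!cond) stop("infeasible spec: ", msg,
                                              call. = FALSE)
  need(n >= 6L, "need at least 6 classes per side")
  need(te >= rates[["omitted_trivial_equiv"]] +
         rates[["whitespace_corruption"]] + rates[["multi_target"]],
       paste0("trivial equivalences (", te, ") cannot host omitted_trivial_equiv + ",
              "whitespace_corruption + multi_target"))
  need(ts >= rates[["omitted_trivial_subclass"]],
       paste0("trivial subsumptions (", ts, ") < omitted_trivial_subclass"))
  need(ne >= rates[["deleted_class"]] + rates[["ambiguous_local_name"]],
       paste0("non-trivial equivalences (", ne,
              ") cannot host deleted_class + ambiguous_local_name"))
  need(ns >= rates[["untyped_relation"]],
       paste0("non-trivial subsumptions (", ns, ") < untyped_relation"))
  need(fillers >= rates[["renamed_label"]],
       paste0("filler classes per side (", fillers, ") < renamed_label"))
  need(fillers >= rates[["multi_target"]] + 2L * rates[["swapped_label_pair"]],
       paste0("filler classes per side (", fillers,
              ") cannot host multi_target targets + swapped_label_pair"))
  if (rates[["ambiguous_local_name"]] > 0L && dialect != "delimited") {
    stop("infeasible spec: ambiguous_local_name defects require local-name ",
         "references (dialect = 'delimited')", call. = FALSE)
  }
  tokens_needed <- 2L * te + 2L * ts + 4L * ne + 4L * ns + 4L * fillers +
    2L * rates[["renamed_label"]] + 2L * rates[["ambiguous_local_name"]]
  need(label_vocabulary_size >= tokens_needed,
       paste0("label_vocabulary_size (", label_vocabulary_size,
              ") < tokens required (", tokens_needed, ")"))

  structure(list(n_classes_per_side = n, max_depth = as.integer(max_depth),
                 label_vocabulary_size = as.integer(label_vocabulary_size),
                 defect_rates = as.list(rates),
                 trivial_fraction = trivial_fraction, seed = as.integer(seed),
                 dialect = dialect,
                 counts = list(n_corr = n_corr, trivial_equiv = te,
                               trivial_sub = ts, nontrivial_equiv = ne,
                               nontrivial_sub = ns, fillers = fillers)),
            class = "fixture_spec")
}

# pronounceable pseudo-word tokens, deterministically from the active RNG
make_tokens <- function(n) {
  consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s",
                  "t", "v", "z")
  vowels <- c("a", "e", "i", "o", "u")
  out <- character(0)
  while (length(out) < n) {
    k <- sample(2:3, 1)
    word <- paste0(paste0(sample(consonants, k, replace = TRUE),
                          sample(vowels, k, replace = TRUE)), collapse = "")
    if (word %in% out || word %in% DEFAULT_PREPOSITIONS) next
    out <- c(out, word)
  }
  out
}

camel_case <- function(label) {
  toks <- strsplit(label, " ", fixed = TRUE)[[1]]
  paste0(toupper(substring(toks, 1, 1)), substring(toks, 2), collapse = "")
}

# random forest over the given uris respecting max_depth; returns edge df
random_tree_edges <- function(uris, max_depth) {
  if (length(uris) <= 1L) return(edge_df())
  depth <- stats::setNames(integer(length(uris)), uris)
  from <- character(); to <- character()
  for (i in seq_along(uris)) {
    if (i == 1L || stats::runif(1) < 0.2) { depth[i] <- 0L; next }
    eligible <- which(depth[seq_len(i - 1L)] < max_depth - 1L)
    if (length(eligible) == 0L) { depth[i] <- 0L; next }
    parent <- eligible[sample.int(length(eligible), 1L)]
    depth[i] <- depth[parent] + 1L
    from <- c(from, uris[i]); to <- c(to, uris[parent])
  }
  edge_df(from, to)
}

#' Generate a synthetic ontology pair, alignment, and defect manifest
#'
#' Writes `onto1.owl`, `onto2.owl` (RDF/XML), the alignment file
#' (`alignment.csv` or `alignment.rdf`), per-side URI-label mapping tables
#' (`mapping1.csv`, `mapping2.csv`), and `manifest.json` into `dir`. The
#' manifest records, for every planted defect, the exact finding keys the
#' corresponding check must produce (`manifest$expected`), computed from
#' the generator's own bookkeeping.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the written `doc1`/`doc2`
#'   ([ontology_document()]s), file `paths`, `mapping_tables`, and the
#'   `manifest`.
#' @export
generate_fixture <- function(spec, dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  cnt <- spec$counts
  rates <- spec$defect_rates
  tokens <- make_tokens(spec$label_vocabulary_size)
  next_token <- local({
    i <- 0L
    function(k = 1L) {
      out <- tokens[(i + 1L):(i + k)]
      i <<- i + k
      out
    }
  })
  two_token_label <- function() paste(next_token(2L), collapse = " ")

  # --- build the stated world: classes and a correct complete alignment
  cls <- function(side) {
    data.frame(uri = character(), label = character(), role = character(),
               stringsAsFactors = FALSE)
  }
  c1 <- cls(1); c2 <- cls(2)
  add_class <- function(side, label, role, ns = NULL) {
    ns <- if (!is.null(ns)) ns else if (side == 1L) FIXTURE_NS1 else FIXTURE_NS2
    row <- data.frame(uri = paste0(ns, camel_case(label)), label = label,
                      role = role, stringsAsFactors = FALSE)
    if (side == 1L) c1 <<- rbind(c1, row) else c2 <<- rbind(c2, row)
    row$uri
  }
  corr <- data.frame(uri1 = character(), uri2 = character(),
                     relation = character(), pool = character(),
                     stringsAsFactors = FALSE)
  add_corr <- function(u1, u2, rel, pool) {
    corr <<- rbind(corr, data.frame(uri1 = u1, uri2 = u2, relation = rel,
                                    pool = pool, stringsAsFactors = FALSE))
  }

  for (i in seq_len(cnt$trivial_equiv)) {
    lab <- two_token_label()
    add_corr(add_class(1L, lab, "trivial_equiv"),
             add_class(2L, lab, "trivial_equiv"),
             "equivalentClass", "trivial_equiv")
  }
  for (i in seq_len(cnt$nontrivial_equiv)) {
    add_corr(add_class(1L, two_token_label(), "nontrivial_equiv"),
             add_class(2L, two_token_label(), "nontrivial_equiv"),
             "equivalentClass", "nontrivial_equiv")
  }
  for (i in seq_len(cnt$trivial_sub)) {
    # alternate noun-phrase templates: "modifier head" / "head of modifier"
    tk <- next_token(2L)
    sub_label <- if (i %% 2L == 0L) paste(tk[1], "of", tk[2])
                 else paste(tk[2], tk[1])
    add_corr(add_class(1L, sub_label, "trivial_sub"),
             add_class(2L, tk[1], "trivial_sub"),
             "subClassOf", "trivial_sub")
  }
  for (i in seq_len(cnt$nontrivial_sub)) {
    add_corr(add_class(1L, two_token_label(), "nontrivial_sub"),
             add_class(2L, two_token_label(), "nontrivial_sub"),
             "subClassOf", "nontrivial_sub")
  }
  filler1 <- vapply(seq_len(cnt$fillers), function(i) {
    add_class(1L, two_token_label(), "filler")
  }, "")
  filler2 <- vapply(seq_len(cnt$fillers), function(i) {
    add_class(2L, two_token_label(), "filler")
  }, "")

  # taxonomies: subsumption-correspondence classes stay isolated roots so
  # that no planted-then-omitted subsumption can be re-derived via an
  # equivalence (their absence must surface lexically, in Check 9)
  tree_classes <- function(cl) {
    cl$uri[cl$role %in% c("trivial_equiv", "nontrivial_equiv", "filler")]
  }
  edges1 <- random_tree_edges(tree_classes(c1), spec$max_depth)
  edges2 <- random_tree_edges(tree_classes(c2), spec$max_depth)

  # mapping tables reflect the world before lexical defects
  mapping1 <- data.frame(uri = c1$uri, expected_label = c1$label,
                         stringsAsFactors = FALSE)
  mapping2 <- data.frame(uri = c2$uri, expected_label = c2$label,
                         stringsAsFactors = FALSE)

  manifest <- list(
    spec = list(n_classes_per_side = spec$n_classes_per_side,
                trivial_fraction = spec$trivial_fraction,
                n_correspondences = cnt$n_corr, seed = spec$seed,
                dialect = spec$dialect, defect_rates = rates),
    planted = list(), expected = list()
  )
  pool_idx <- function(pool) which(corr$pool == pool)
  ref_of <- function(uri) {
    if (spec$dialect == "delimited") local_name(uri) else uri
  }

  # --- defect slices (disjoint by construction; validated in fixture_spec)
  te_idx <- pool_idx("trivial_equiv")
  omit_te <- te_idx[seq_len(rates$omitted_trivial_equiv)]
  ws_idx <- te_idx[rates$omitted_trivial_equiv + seq_len(rates$whitespace_corruption)]
  mt_idx <- te_idx[rates$omitted_trivial_equiv + rates$whitespace_corruption +
                     seq_len(rates$multi_target)]
  ts_idx <- pool_idx("trivial_sub")
  omit_ts <- ts_idx[seq_len(rates$omitted_trivial_subclass)]
  ne_idx <- pool_idx("nontrivial_equiv")
  del_idx <- ne_idx[seq_len(rates$deleted_class)]
  amb_idx <- ne_idx[rates$deleted_class + seq_len(rates$ambiguous_local_name)]
  ns_idx <- pool_idx("nontrivial_sub")
  unt_idx <- ns_idx[seq_len(rates$untyped_relation)]

  # structural defects -----------------------------------------------------
  # deleted classes: remove the onto2 member of selected equivalences,
  # reattaching orphaned children to the grandparent (or making them roots)
  deleted_uris <- corr$uri2[del_idx]
  for (u in deleted_uris) {
    parents <- edges2$to[edges2$from == u]
    children <- edges2$from[edges2$to == u]
    edges2 <- edges2[edges2$from != u & edges2$to != u, , drop = FALSE]
    if (length(parents) > 0L) {
      edges2 <- rbind(edges2, edge_df(children, rep(parents[1],
                                                    length(children))))
    }
  }
  c2 <- c2[!c2$uri %in% deleted_uris, , drop = FALSE]
  mapping2 <- mapping2[!mapping2$uri %in% deleted_uris, , drop = FALSE]
  manifest$planted$deleted_class <- deleted_uris

  # multiple targets: a second equivalence target for selected classes
  mt_targets <- filler2[seq_len(rates$multi_target)]
  for (k in seq_along(mt_idx)) {
    add_corr(corr$uri1[mt_idx[k]], mt_targets[k], "equivalentClass",
             "multi_target_extra")
  }
  manifest$planted$multi_target <- corr$uri1[mt_idx]

  # lexical defects ---------------------------------------------------------
  ren_uris <- filler1[seq_len(rates$renamed_label)]
  for (u in ren_uris) c1$label[c1$uri == u] <- two_token_label()
  manifest$planted$renamed_label <- ren_uris

  swap_pool <- filler2[rates$multi_target + seq_len(2L * rates$swapped_label_pair)]
  swap_pairs <- list()
  if (rates$swapped_label_pair > 0L) {
    for (k in seq_len(rates$swapped_label_pair)) {
      ua <- swap_pool[2L * k - 1L]; ub <- swap_pool[2L * k]
      la <- c2$label[c2$uri == ua]; lb <- c2$label[c2$uri == ub]
      c2$label[c2$uri == ua] <- lb; c2$label[c2$uri == ub] <- la
      swap_pairs[[k]] <- sort(c(ua, ub))
    }
  }
  manifest$planted$swapped_label_pair <- swap_pairs

  # ambiguity: a second class with the same local name in another namespace
  amb_locals <- character()
  for (i in amb_idx) {
    target_local <- local_name(corr$uri1[i])
    alt_label <- two_token_label()
    alt_uri <- paste0(FIXTURE_NS_ALT, target_local)
    c1 <- rbind(c1, data.frame(uri = alt_uri, label = alt_label,
                               role = "ambiguity_twin",
                               stringsAsFactors = FALSE))
    amb_locals <- c(amb_locals, target_local)
  }
  manifest$planted$ambiguous_local_name <- amb_locals

  # file-level defects ------------------------------------------------------
  raw1 <- vapply(corr$uri1, ref_of, "")
  raw2 <- vapply(corr$uri2, ref_of, "")
  rel_out <- corr$relation
  ws_records <- list()
  for (i in ws_idx) {
    tok <- raw1[i]
    pos <- max(2L, nchar(tok) %/% 2L)
    corrupted <- paste0(substring(tok, 1, pos - 1L), " ",
                        substring(tok, pos))
    ws_records[[length(ws_records) + 1L]] <-
      list(original = tok, corrupted = corrupted)
    raw1[i] <- corrupted
  }
  manifest$planted$whitespace_corruption <- ws_records
  rel_out[unt_idx] <- ""
  manifest$planted$untyped_relation <-
    data.frame(entity1 = raw1[unt_idx], entity2 = raw2[unt_idx],
               stringsAsFactors = FALSE)
  manifest$planted$omitted_trivial_equiv <-
    data.frame(uri1 = corr$uri1[omit_te], uri2 = corr$uri2[omit_te],
               stringsAsFactors = FALSE)
  manifest$planted$omitted_trivial_subclass <-
    data.frame(sub = corr$uri1[omit_ts], super = corr$uri2[omit_ts],
               stringsAsFactors = FALSE)
  keep_rows <- setdiff(seq_len(nrow(corr)), c(omit_te, omit_ts))

  # --- expected findings per check, from bookkeeping alone
  rel_keyword <- c(equivalentClass = "equivalentClass",
                   subClassOf = "subClassOf")
  manifest$expected <- list(
    missing_class = sort(paste0("onto2|", vapply(deleted_uris, ref_of, ""))),
    missing_class_without_cleanup = sort(c(
      paste0("onto2|", vapply(deleted_uris, ref_of, "")),
      paste0("onto1|", vapply(ws_records, `[[`, "", "corrupted")))),
    label_changed = sort(paste0("onto1|", ren_uris)),
    swap_suspicion = sort(vapply(swap_pairs, function(p) {
      paste0("onto2|", p[1], "|", p[2])
    }, "")),
    ambiguous_ref = sort(paste0("onto1|", amb_locals)),
    untyped_relation = sort(paste(raw1[unt_idx], raw2[unt_idx], sep = "|")),
    multi_target = sort(paste0("onto1|", corr$uri1[mt_idx])),
    label_identity_missing_equiv = sort(paste(corr$uri1[omit_te],
                                              corr$uri2[omit_te], sep = "|")),
    inclusion_missing_subclass = sort(paste(corr$uri1[omit_ts], "subClassOf",
                                            corr$uri2[omit_ts], sep = "|")),
    trivial = sort(paste(corr$uri1, corr$relation, corr$uri2,
                         sep = "|")[setdiff(
                           c(te_idx, ts_idx), c(omit_te, omit_ts))])
  )

  # --- materialize documents and files
  build_doc <- function(cl, edges, iri, version) {
    ontology_document(
      classes = data.frame(uri = cl$uri, stringsAsFactors = FALSE),
      labels = data.frame(uri = cl$uri, text = cl$label,
                          lang = rep("", nrow(cl)), stringsAsFactors = FALSE),
      subclass_edges = edges, ontology_iri = iri, version_info = version
    )
  }
  doc1 <- build_doc(c1, edges1, sub("#$", "", FIXTURE_NS1), "1.0")
  doc2 <- build_doc(c2, edges2, sub("#$", "", FIXTURE_NS2), "1.0")
  p_onto1 <- file.path(dir, "onto1.owl")
  p_onto2 <- file.path(dir, "onto2.owl")
  write_ontology_rdfxml(doc1, p_onto1)
  write_ontology_rdfxml(doc2, p_onto2)

  if (spec$dialect == "delimited") {
    p_align <- file.path(dir, "alignment.csv")
    rel_cells <- ifelse(rel_out[keep_rows] == "", "",
                        unname(rel_keyword[rel_out[keep_rows]]))
    writeLines(c("entity1,entity2,relation",
                 paste(raw1[keep_rows], raw2[keep_rows], rel_cells,
                       sep = ",")),
               p_align)
  } else {
    p_align <- file.path(dir, "alignment.rdf")
    sym <- c(equivalentClass = "=", subClassOf = "<")
    tmp_corr <- new_correspondence_df(raw1[keep_rows], raw2[keep_rows],
                                      rel_out[keep_rows],
                                      row_provenance =
                                        paste0("gen ", keep_rows))
    tmp_corr$relation <- ifelse(rel_out[keep_rows] == "",
                                "unknown", rel_out[keep_rows])
    tmp_corr$resolution1 <- "resolved"; tmp_corr$resolved_uri1 <- raw1[keep_rows]
    tmp_corr$resolution2 <- "resolved"; tmp_corr$resolved_uri2 <- raw2[keep_rows]
    al <- new_alignment(tmp_corr, onto1_ref = doc1$ontology_iri,
                        onto2_ref = doc2$ontology_iri)
    write_alignment(al, p_align, "alignment_api")
  }
  p_map1 <- file.path(dir, "mapping1.csv")
  p_map2 <- file.path(dir, "mapping2.csv")
  utils::write.csv(mapping1, p_map1, row.names = FALSE)
  utils::write.csv(mapping2, p_map2, row.names = FALSE)
  p_manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, p_manifest, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  invisible(list(
    doc1 = doc1, doc2 = doc2,
    mapping_tables = list(onto1 = mapping1, onto2 = mapping2),
    manifest = manifest,
    paths = list(onto1 = p_onto1, onto2 = p_onto2, alignment = p_align,
                 mapping1 = p_map1, mapping2 = p_map2,
                 manifest = p_manifest, dir = dir)
  ))
}
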