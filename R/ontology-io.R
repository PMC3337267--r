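# Ontology loading, class extraction and taxonomy-closure queries.

PARTOF_PREDICATES <- c(
  "http://purl.obolibrary.org/obo/BFO_0000050",
  "http://www.obofoundry.org/ro/ro.owl#part_of"
)

is_partof_predicate <- function(p) {
  p %in% PARTOF_PREDICATES | grepl("[#/](partOf|part_of)$", p)
}

#' Local name of an IRI
#'
#' The terminal segment of an IRI: the substring after the last `#` if one
#' is present, otherwise after the last `/`.
#'
#' @param uri Character vector of IRIs.
#' @return Character vector of local names.
#' @examples
#' local_name("http://dbpedia.org/ontology/AnatomicalStructure")
#' @export
local_name <- function(uri) {
  out <- uri
  has_hash <- grepl("#", uri, fixed = TRUE)
  out[has_hash] <- sub("^.*#", "", uri[has_hash])
  out[!has_hash] <- sub("^.*/", "", uri[!has_hash])
  out
}

edge_df <- function(from = character(), to = character()) {
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' Construct an ontology document object
#'
#' Programmatic constructor used by [load_ontology()], the fixture
#' generator, and tests. `classes` holds one row per named, explicitly
#' typed class; `taxonomy` holds the asserted edge sets.
#'
#' @param classes Data frame with columns `uri`, `local_name`,
#'   `explicitly_typed`, `deprecated`.
#' @param labels Data frame with columns `uri`, `text`, `lang` (empty string
#'   for untagged labels), in document order.
#' @param subclass_edges,equivalence_edges,partof_edges,disjoint_edges Data
#'   frames with columns `from`, `to`. Subclass and part-of edges are
#'   directed child -> parent / part -> whole; equivalence and disjointness
#'   are stored as given but treated symmetrically.
#' @param ontology_iri,version_info,source_location Document metadata
#'   (empty strings when unknown).
#' @param imports_resolved,imports_failed Character vectors of import IRIs.
#' @param warnings Character vector of loader warnings.
#' @return An object of class `ontology_document`.
#' @export
ontology_document <- function(classes, labels = NULL,
                              subclass_edges = edge_df(),
                              equivalence_edges = edge_df(),
                              partof_edges = edge_df(),
                              disjoint_edges = edge_df(),
                              ontology_iri = "", version_info = "",
                              source_location = "",
                              imports_resolved = character(),
                              imports_failed = character(),
                              warnings = character()) {
  stopifnot(is.data.frame(classes), all(c("uri") %in% names(classes)))
  if (!"local_name" %in% names(classes)) {
    classes$local_name <- local_name(classes$uri)
  }
  if (!"explicitly_typed" %in% names(classes)) classes$explicitly_typed <- TRUE
  if (!"deprecated" %in% names(classes)) classes$deprecated <- FALSE
  if (anyDuplicated(classes$uri)) {
    stop("duplicate class URIs in ontology document", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- data.frame(uri = character(), text = character(),
                         lang = character(), stringsAsFactors = FALSE)
  }
  taxonomy <- list(subclass_edges = subclass_edges,
                   equivalence_edges = equivalence_edges,
                   partof_edges = partof_edges,
                   disjoint_edges = disjoint_edges)
  for (nm in names(taxonomy)) {
    e <- taxonomy[[nm]]
    bad <- !(e$from %in% classes$uri) | !(e$to %in% classes$uri)
    if (any(bad)) {
      stop("taxonomy edge endpoints missing from class set (", nm, ")",
           call. = FALSE)
    }
  }
  structure(
    list(ontology_iri = ontology_iri, version_info = version_info,
         source_location = source_location, classes = classes,
         labels = labels, taxonomy = taxonomy,
         imports_resolved = imports_resolved,
         imports_failed = imports_failed, warnings = warnings),
    class = "ontology_document"
  )
}

#' @export
print.ontology_document <- function(x, ...) {
  cat("<ontology_document> ",
      if (nzchar(x$ontology_iri)) x$ontology_iri else "(no ontology IRI)",
      "\n", sep = "")
  cat("  classes: ", nrow(x$classes),
      "  subclass edges: ", nrow(x$taxonomy$subclass_edges),
      "  equivalence: ", nrow(x$taxonomy$equivalence_edges),
      "  partOf: ", nrow(x$taxonomy$partof_edges),
      "  disjoint: ", nrow(x$taxonomy$disjoint_edges), "\n", sep = "")
  if (nzchar(x$version_info)) cat("  version: ", x$version_info, "\n", sep = "")
  if (length(x$imports_failed)) {
    cat("  failed imports: ", paste(x$imports_failed, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Load an ontology document
#'
#' Parses an RDF/XML or Turtle ontology, optionally resolving `owl:imports`
#' recursively, and extracts named classes (subjects explicitly typed as
#' `owl:Class` or `rdfs:Class`), their labels, and the asserted subclass,
#' equivalence, part-of, and disjointness edges. Nodes that appear only as
#' a superclass, domain or range — or anonymous (blank-node) classes — are
#' not treated as classes; edges touching them are dropped with a warning.
#'
#' @param source Path to the document (a URL is recorded but, by design,
#'   never fetched: failed remote imports become `imports_failed` entries).
#' @param resolve_imports Follow `owl:imports` declarations that point to
#'   readable local files (relative IRIs are resolved against the importing
#'   document's directory). Cyclic imports are loaded exactly once.
#' @param import_depth_limit Maximum recursion depth; deeper imports are
#'   recorded as warnings and skipped.
#' @param format Passed to the triple reader; `"auto"` detects by extension.
#' @return An [ontology_document()].
#' @export
load_ontology <- function(source, resolve_imports = TRUE,
                          import_depth_limit = 10L,
                          format = c("auto", "rdfxml", "turtle")) {
  format <- match.arg(format)
  if (grepl("^https?://", source)) {
    stop("remote ontology sources are not fetched; download '", source,
         "' and load the local file", call. = FALSE)
  }
  if (!file.exists(source)) {
    stop("ontology source not readable: '", source, "'", call. = FALSE)
  }
  state <- new.env(parent = emptyenv())
  state$visited <- character()
  state$warnings <- character()
  state$imports_resolved <- character()
  state$imports_failed <- character()
  triples <- load_triples_recursive(source, format, resolve_imports,
                                    import_depth_limit, depth = 0L,
                                    state = state)
  build_ontology_document(triples, source, state)
}

load_triples_recursive <- function(source, format, resolve_imports,
                                   depth_limit, depth, state) {
  key <- normalizePath(source, mustWork = FALSE)
  if (key %in% state$visited) return(empty_triples())
  state$visited <- c(state$visited, key)
  triples <- read_rdf_triples(source, format)
  if (!resolve_imports) return(triples)

  imports <- triples$object[triples$predicate == owl_iri("imports") &
                            !triples$is_literal]
  for (imp in unique(imports)) {
    if (depth >= depth_limit) {
      state$warnings <- c(state$warnings,
                          paste0("import depth limit reached at '", imp, "'"))
      state$imports_failed <- c(state$imports_failed, imp)
      next
    }
    candidate <- import_candidate_path(imp, source)
    if (is.na(candidate)) {
      state$imports_failed <- c(state$imports_failed, imp)
      state$warnings <- c(state$warnings,
                          paste0("failed to resolve import '", imp, "'"))
      next
    }
    state$imports_resolved <- c(state$imports_resolved, imp)
    triples <- rbind(triples,
                     load_triples_recursive(candidate, "auto",
                                            resolve_imports, depth_limit,
                                            depth + 1L, state))
  }
  triples
}

# An import IRI is resolvable when it names an existing local file, either
# directly, as file://, or relative to the importing document's directory
# (also trying just the IRI's terminal segment, the usual bundling layout).
import_candidate_path <- function(iri, importing_source) {
  cands <- character()
  if (grepl("^file://", iri)) cands <- c(cands, sub("^file://", "", iri))
  if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*://", iri)) cands <- c(cands, iri)
  dir <- dirname(importing_source)
  cands <- c(cands, file.path(dir, iri), file.path(dir, basename(iri)),
             file.path(dir, local_name(iri)))
  for (cand in cands) {
    if (file.exists(cand) && !dir.exists(cand)) return(cand)
  }
  NA_character_
}

build_ontology_document <- function(triples, source, state) {
  type_p <- rdf_iri("type")
  class_types <- c(owl_iri("Class"), rdfs_iri("Class"))
  typed <- triples$subject[triples$predicate == type_p &
                           triples$object %in% class_types]
  typed <- unique(typed)
  named <- typed[is_absolute_iri(typed)]
  if (length(named) < length(typed)) {
    state$warnings <- c(state$warnings,
                        sprintf("%d anonymous class(es) excluded",
                                length(typed) - length(named)))
  }
  named <- sort(named)

  deprecated_subjects <- triples$subject[
    triples$predicate == owl_iri("deprecated") &
    tolower(triples$object) %in% c("true", "1")]

  classes <- data.frame(
    uri = named,
    local_name = local_name(named),
    explicitly_typed = TRUE,
    deprecated = named %in% deprecated_subjects,
    stringsAsFactors = FALSE
  )

  lab <- triples[triples$predicate == rdfs_iri("label") &
                 triples$subject %in% named & triples$is_literal, ,
                 drop = FALSE]
  labels <- data.frame(uri = lab$subject, text = lab$object,
                       lang = lab$lang, stringsAsFactors = FALSE)

  keep_edges <- function(predicate_mask, kind) {
    e <- triples[predicate_mask & !triples$is_literal, , drop = FALSE]
    ok <- e$subject %in% named & e$object %in% named
    dropped <- sum(!ok)
    if (dropped > 0L) {
      state$warnings <- c(state$warnings,
                          sprintf("%d %s edge(s) dropped (endpoint not a named, explicitly typed class)",
                                  dropped, kind))
    }
    unique(edge_df(e$subject[ok], e$object[ok]))
  }

  subclass <- keep_edges(triples$predicate == rdfs_iri("subClassOf"),
                         "subClassOf")
  equivalence <- keep_edges(triples$predicate == owl_iri("equivalentClass"),
                            "equivalentClass")
  partof <- keep_edges(is_partof_predicate(triples$predicate), "partOf")
  disjoint <- keep_edges(triples$predicate == owl_iri("disjointWith"),
                         "disjointWith")

  onto_subjects <- triples$subject[triples$predicate == type_p &
                                   triples$object == owl_iri("Ontology")]
  ontology_iri <- if (length(onto_subjects) > 0L &&
                      is_absolute_iri(onto_subjects[1])) onto_subjects[1] else ""
  vinfo <- triples$object[triples$predicate == owl_iri("versionInfo") &
                          triples$subject %in% onto_subjects]
  version_info <- if (length(vinfo) > 0L) vinfo[1] else ""

  ontology_document(
    classes = classes, labels = labels,
    subclass_edges = subclass, equivalence_edges = equivalence,
    partof_edges = partof, disjoint_edges = disjoint,
    ontology_iri = ontology_iri, version_info = version_info,
    source_location = source,
    imports_resolved = unique(state$imports_resolved),
    imports_failed = unique(state$imports_failed),
    warnings = state$warnings
  )
}

# ---- closure queries ---------------------------------------------------

# adjacency list over subclass edges; direction "up" maps child -> parents
subclass_adjacency <- function(doc, direction = c("up", "down")) {
  direction <- match.arg(direction)
  e <- doc$taxonomy$subclass_edges
  if (direction == "up") split(e$to, e$from) else split(e$from, e$to)
}

reachable_strict <- function(adj, uri) {
  seen <- character()
  frontier <- adj[[uri]]
  while (length(frontier) > 0L) {
    frontier <- setdiff(unique(frontier), seen)
    seen <- c(seen, frontier)
    frontier <- unlist(adj[frontier], use.names = FALSE)
  }
  setdiff(seen, uri)
}

check_known_uri <- function(doc, uri) {
  if (!uri %in% doc$classes$uri) {
    stop("unknown class URI: '", uri, "'", call. = FALSE)
  }
}

#' Ancestors and descendants in the asserted class taxonomy
#'
#' Transitive closure over the asserted `subClassOf` edges. The strict
#' closure excludes the query class itself even on cyclic input (members of
#' a subclass cycle are mutual ancestors/descendants of each other);
#' `reflexive = TRUE` adds the query class.
#'
#' @param doc An [ontology_document()].
#' @param uri Class IRI; must be a class of `doc`.
#' @param reflexive Include `uri` itself in the result.
#' @return Character vector of class IRIs (unsorted set).
#' @export
ancestors <- function(doc, uri, reflexive = FALSE) {
  check_known_uri(doc, uri)
  out <- reachable_strict(subclass_adjacency(doc, "up"), uri)
  if (reflexive) union(out, uri) else out
}

#' @rdname ancestors
#' @export
descendants <- function(doc, uri, reflexive = FALSE) {
  check_known_uri(doc, uri)
  out <- reachable_strict(subclass_adjacency(doc, "down"), uri)
  if (reflexive) union(out, uri) else out
}

# Strict closure for every class at once; returns named list uri -> set.
# Used by the entailment check, where per-query BFS would be quadratic.
all_closures <- function(doc, direction = c("up", "down")) {
  adj <- subclass_adjacency(doc, match.arg(direction))
  out <- lapply(doc$classes$uri, function(u) reachable_strict(adj, u))
  names(out) <- doc$classes$uri
  out
}

# ---- label helpers -----------------------------------------------------

labels_of <- function(doc, uri) {
  doc$labels$text[doc$labels$uri == uri]
}

#' Preferred label of a class
#'
#' Selection order: first untagged label, then first English-tagged label
#' (`en` or `en-*`), then the first label in document order; classes with
#' no label fall back to the local name.
#'
#' @inheritParams ancestors
#' @return Length-one character vector.
#' @export
preferred_label <- function(doc, uri) {
  idx <- which(doc$labels$uri == uri)
  if (length(idx) == 0L) {
    return(doc$classes$local_name[doc$classes$uri == uri])
  }
  lang <- doc$labels$lang[idx]
  pick <- idx[lang == ""][1]
  if (is.na(pick)) pick <- idx[grepl("^en(-|$)", lang)][1]
  if (is.na(pick)) pick <- idx[1]
  doc$labels$text[pick]
}

# All lexical handles of a class for label-based checks: every label, and
# the local name as fallback when the class has no label at all. With
# mode = "preferred", only the preferred label.
lexical_handles <- function(doc, uri, mode = c("all", "preferred")) {
  mode <- match.arg(mode)
  if (mode == "preferred") return(preferred_label(doc, uri))
  labs <- labels_of(doc, uri)
  if (length(labs) == 0L) {
    labs <- doc$classes$local_name[doc$classes$uri == uri]
  }
  unique(labs)
}

# ---- RDF/XML writer (used by the fixture generator) --------------------

#' Write an ontology document as RDF/XML
#'
#' Serializes classes, labels and asserted edges. Part-of edges are written
#' with the OBO `BFO_0000050` property IRI.
#'
#' @param doc An [ontology_document()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ontology_rdfxml <- function(doc, path) {
  root <- xml2::xml_new_root(
    "rdf:RDF",
    "xmlns:rdf" = RDF_NS, "xmlns:rdfs" = RDFS_NS, "xmlns:owl" = OWL_NS,
    "xmlns:obo" = "http://purl.obolibrary.org/obo/"
  )
  if (nzchar(doc$ontology_iri)) {
    onto <- xml2::xml_add_child(root, "owl:Ontology",
                                "rdf:about" = doc$ontology_iri)
    if (nzchar(doc$version_info)) {
      xml2::xml_add_child(onto, "owl:versionInfo", doc$version_info)
    }
    for (imp in doc$imports_resolved) {
      xml2::xml_add_child(onto, "owl:imports", "rdf:resource" = imp)
    }
  }
  edges_by_from <- function(e) split(e$to, e$from)
  sub_by <- edges_by_from(doc$taxonomy$subclass_edges)
  eq_by <- edges_by_from(doc$taxonomy$equivalence_edges)
  po_by <- edges_by_from(doc$taxonomy$partof_edges)
  dj_by <- edges_by_from(doc$taxonomy$disjoint_edges)
  for (i in seq_len(nrow(doc$classes))) {
    uri <- doc$classes$uri[i]
    cl <- xml2::xml_add_child(root, "owl:Class", "rdf:about" = uri)
    li <- which(doc$labels$uri == uri)
    for (j in li) {
      lab <- xml2::xml_add_child(cl, "rdfs:label", doc$labels$text[j])
      if (nzchar(doc$labels$lang[j])) {
        xml2::xml_set_attr(lab, "xml:lang", doc$labels$lang[j])
      }
    }
    for (p in sub_by[[uri]]) {
      xml2::xml_add_child(cl, "rdfs:subClassOf", "rdf:resource" = p)
    }
    for (p in eq_by[[uri]]) {
      xml2::xml_add_child(cl, "owl:equivalentClass", "rdf:resource" = p)
    }
    for (p in po_by[[uri]]) {
      xml2::xml_add_child(cl, "obo:BFO_0000050", "rdf:resource" = p)
    }
    for (p in dj_by[[uri]]) {
      xml2::xml_add_child(cl, "owl:disjointWith", "rdf:resource" = p)
    }
    if (doc$classes$deprecated[i]) {
      xml2::xml_add_child(cl, "owl:deprecated", "true")
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}
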