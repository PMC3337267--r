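# Alignment parsing/writing and entity-reference resolution.
#
# Two on-disk dialects are supported: the Alignment API RDF format
# (RDF/XML: Alignment > map > Cell > entity1/entity2/relation/measure) and
# a delimited table (by default comma-separated entity1, entity2, relation
# columns), the shape in which informally published alignments circulate.

RELATIONS <- c("equivalentClass", "subClassOf", "superClassOf",
               "relatedTo", "unknown")

# "=", "<", ">" map bijectively onto equivalence and the two subsumption
# directions; recognised keyword families are matched case-insensitively;
# any other printable symbol means "some relation, but not one we can use"
# (relatedTo); an absent symbol is unknown.
map_relation_symbol <- function(sym) {
  vapply(sym, function(s) {
    s <- trimws(if (is.na(s)) "" else s)
    if (!nzchar(s)) return("unknown")
    if (s == "=") return("equivalentClass")
    if (s == "<") return("subClassOf")
    if (s == ">") return("superClassOf")
    key <- tolower(gsub("[^[:alnum:]]", "", s))
    if (key %in% c("equivalent", "equivalentclass", "equiv", "eq")) {
      return("equivalentClass")
    }
    if (key %in% c("subclass", "subclassof", "subsumedby")) {
      return("subClassOf")
    }
    if (key %in% c("superclass", "superclassof", "subsumes")) {
      return("superClassOf")
    }
    if (key %in% c("related", "relatedto", "rel")) return("relatedTo")
    "relatedTo"
  }, "", USE.NAMES = FALSE)
}

relation_symbol <- function(rel) {
  c(equivalentClass = "=", subClassOf = "<", superClassOf = ">",
    relatedTo = "related", unknown = "")[rel]
}

infer_ref_kind <- function(token) {
  ifelse(is_absolute_iri(gsub("[[:space:]]+", "", token)),
         "uri", "local_name")
}

new_correspondence_df <- function(entity1_raw = character(),
                                  entity2_raw = character(),
                                  relation = character(),
                                  confidence = numeric(),
                                  row_provenance = character()) {
  n <- length(entity1_raw)
  data.frame(
    entity1_raw = entity1_raw, entity2_raw = entity2_raw,
    ref_kind1 = infer_ref_kind(entity1_raw),
    ref_kind2 = infer_ref_kind(entity2_raw),
    relation = relation,
    confidence = if (length(confidence)) confidence else rep(NA_real_, n),
    row_provenance = row_provenance,
    resolution1 = rep("unresolved", n), resolved_uri1 = rep("", n),
    resolution2 = rep("unresolved", n), resolved_uri2 = rep("", n),
    repaired1 = rep(FALSE, n), repaired2 = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
}

warning_df <- function(row_provenance = character(), message = character()) {
  data.frame(row_provenance = row_provenance, message = message,
             stringsAsFactors = FALSE)
}

new_alignment <- function(correspondences, onto1_ref = "", onto2_ref = "",
                          source_format = "alignment_api",
                          parse_warnings = warning_df(),
                          source_path = "", candidates1 = NULL,
                          candidates2 = NULL) {
  n <- nrow(correspondences)
  structure(
    list(correspondences = correspondences,
         candidates1 = if (is.null(candidates1)) rep(list(character()), n)
                       else candidates1,
         candidates2 = if (is.null(candidates2)) rep(list(character()), n)
                       else candidates2,
         onto1_ref = onto1_ref, onto2_ref = onto2_ref,
         source_format = source_format, parse_warnings = parse_warnings,
         source_path = source_path, resolved = FALSE),
    class = "alignment"
  )
}

#' @export
print.alignment <- function(x, ...) {
  cat("<alignment> ", nrow(x$correspondences), " correspondence(s), format: ",
      x$source_format, "\n", sep = "")
  tab <- table(x$correspondences$relation)
  if (length(tab)) {
    cat("  relations: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$parse_warnings)) {
    cat("  parse warnings: ", nrow(x$parse_warnings), "\n", sep = "")
  }
  invisible(x)
}

#' Parse an alignment file
#'
#' Reads either an Alignment API RDF document or a delimited table into an
#' `alignment` object. Malformed rows/cells are skipped and recorded in
#' `parse_warnings`, never fatal; duplicate correspondences (same raw
#' entity pair and relation) keep their first occurrence and log the rest.
#'
#' @param source Path to the alignment file.
#' @param dialect `"auto"` (XML content sniffing), `"alignment_api"`, or
#'   `"delimited"`.
#' @param delimiter Cell separator for the delimited dialect.
#' @param column_order Character vector naming the delimited columns; a
#'   permutation of `c("entity1", "entity2", "relation")` (`"relation"` may
#'   be omitted, leaving relations unknown).
#' @param has_header `TRUE`, `FALSE`, or `NA` to auto-detect (a first row
#'   whose cells repeat the column names).
#' @param force_untyped Treat every relation as `unknown` regardless of the
#'   symbol in the file (for distributions whose relation markings are
#'   known to be unreliable technical artifacts).
#' @return An `alignment` object; references are unresolved until
#'   [resolve_references()] is applied.
#' @export
parse_alignment <- function(source,
                            dialect = c("auto", "alignment_api", "delimited"),
                            delimiter = ",",
                            column_order = c("entity1", "entity2", "relation"),
                            has_header = NA,
                            force_untyped = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(source)) {
    stop("alignment source not readable: '", source, "'", call. = FALSE)
  }
  if (dialect == "auto") {
    head_txt <- readChar(source, nchars = min(file.size(source), 2048L),
                         useBytes = TRUE)
    dialect <- if (grepl("^\\s*<\\?xml|^\\s*<rdf:RDF|^\\s*<", head_txt)) {
      "alignment_api"
    } else "delimited"
  }
  al <- if (dialect == "alignment_api") {
    parse_alignment_api(source)
  } else {
    parse_alignment_delimited(source, delimiter, column_order, has_header)
  }
  if (force_untyped) {
    al$correspondences$relation <- rep("unknown",
                                       nrow(al$correspondences))
    al$forced_untyped <- TRUE
  } else {
    al$forced_untyped <- FALSE
  }
  al
}

parse_alignment_api <- function(source) {
  doc <- tryCatch(xml2::read_xml(source), error = function(e) {
    stop("failed to parse Alignment API document '", source, "': ",
         conditionMessage(e), call. = FALSE)
  })
  align_node <- xml2::xml_find_first(doc, "//*[local-name() = 'Alignment']")
  if (inherits(align_node, "xml_missing")) {
    stop("no Alignment element found in '", source, "'", call. = FALSE)
  }
  onto_ref <- function(which) {
    node <- xml2::xml_find_first(align_node,
                                 paste0("./*[local-name() = '", which, "']"))
    if (inherits(node, "xml_missing")) return("")
    res <- xml2::xml_attr(node, "resource")
    if (!is.na(res)) return(res)
    inner <- xml2::xml_find_first(node, ".//*[@*[local-name() = 'about']]")
    if (!inherits(inner, "xml_missing")) {
      about <- xml2::xml_attr(inner, "about")
      if (!is.na(about)) return(about)
    }
    trimws(xml2::xml_text(node))
  }
  cells <- xml2::xml_find_all(align_node, ".//*[local-name() = 'Cell']")
  warnings <- warning_df()
  rows <- list()
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    prov <- paste0("cell ", i)
    ent <- function(which) {
      node <- xml2::xml_find_first(cell,
                                   paste0("./*[local-name() = '", which, "']"))
      if (inherits(node, "xml_missing")) return(NA_character_)
      res <- xml2::xml_attr(node, "resource")
      if (!is.na(res)) return(res)
      txt <- trimws(xml2::xml_text(node))
      if (nzchar(txt)) txt else NA_character_
    }
    e1 <- ent("entity1"); e2 <- ent("entity2")
    if (is.na(e1) || is.na(e2)) {
      warnings <- rbind(warnings,
                        warning_df(prov, "cell missing entity1 or entity2"))
      next
    }
    rel_node <- xml2::xml_find_first(cell, "./*[local-name() = 'relation']")
    rel_sym <- if (inherits(rel_node, "xml_missing")) NA_character_
               else xml2::xml_text(rel_node)
    meas_node <- xml2::xml_find_first(cell, "./*[local-name() = 'measure']")
    conf <- if (inherits(meas_node, "xml_missing")) NA_real_
            else suppressWarnings(as.numeric(xml2::xml_text(meas_node)))
    rows[[length(rows) + 1L]] <- list(e1 = e1, e2 = e2, rel = rel_sym,
                                      conf = conf, prov = prov)
  }
  corr <- rows_to_corr(rows)
  dd <- dedup_correspondences(corr, warnings)
  new_alignment(dd$corr, onto1_ref = onto_ref("onto1"),
                onto2_ref = onto_ref("onto2"),
                source_format = "alignment_api",
                parse_warnings = dd$warnings, source_path = source)
}

rows_to_corr <- function(rows) {
  new_correspondence_df(
    entity1_raw = vapply(rows, `[[`, "", "e1"),
    entity2_raw = vapply(rows, `[[`, "", "e2"),
    relation = map_relation_symbol(vapply(rows, function(r) {
      if (is.na(r$rel)) NA_character_ else r$rel
    }, NA_character_)),
    confidence = vapply(rows, `[[`, NA_real_, "conf"),
    row_provenance = vapply(rows, `[[`, "", "prov")
  )
}

parse_alignment_delimited <- function(source, delimiter, column_order,
                                      has_header) {
  column_order <- match.arg(column_order,
                            c("entity1", "entity2", "relation"),
                            several.ok = TRUE)
  if (!all(c("entity1", "entity2") %in% column_order)) {
    stop("column_order must include entity1 and entity2", call. = FALSE)
  }
  lines <- readLines(source, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    stop("no parseable correspondences in '", source, "' (file is empty)",
         call. = FALSE)
  }
  cells <- strsplit(lines, delimiter, fixed = TRUE)
  if (is.na(has_header)) {
    first <- tolower(trimws(cells[[1]]))
    has_header <- any(first %in% c("entity1", "entity2", "relation",
                                   "class1", "class2", "source", "target"))
  }
  start <- if (has_header) 2L else 1L
  warnings <- warning_df()
  rows <- list()
  rel_pos <- match("relation", column_order)
  for (i in seq(from = start, length.out = max(0L, length(lines) - start + 1L))) {
    prov <- paste0("line ", line_no[i])
    cs <- cells[[i]]
    vals <- rep(NA_character_, length(column_order))
    vals[seq_len(min(length(cs), length(column_order)))] <-
      cs[seq_len(min(length(cs), length(column_order)))]
    names(vals) <- column_order
    e1 <- vals[["entity1"]]; e2 <- vals[["entity2"]]
    blank <- function(x) is.na(x) || !nzchar(trimws(x))
    if (blank(e1) || blank(e2)) {
      warnings <- rbind(warnings,
                        warning_df(prov, "missing entity value; row skipped"))
      next
    }
    rel <- if (is.na(rel_pos)) NA_character_ else vals[["relation"]]
    rows[[length(rows) + 1L]] <- list(e1 = trimws(e1), e2 = trimws(e2),
                                      rel = rel, conf = NA_real_, prov = prov)
  }
  if (length(rows) == 0L) {
    stop("no parseable correspondences in '", source, "' (",
         nrow(warnings), " malformed row(s))", call. = FALSE)
  }
  corr <- rows_to_corr(rows)
  dd <- dedup_correspondences(corr, warnings)
  new_alignment(dd$corr, source_format = "delimited",
                parse_warnings = dd$warnings, source_path = source)
}

dedup_correspondences <- function(corr, warnings,
                                  key1 = corr$entity1_raw,
                                  key2 = corr$entity2_raw) {
  key <- paste(key1, key2, corr$relation, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warnings <- rbind(warnings, warning_df(
      corr$row_provenance[dup],
      paste0("duplicate correspondence (first kept): ",
             corr$entity1_raw[dup], " / ", corr$entity2_raw[dup])))
  }
  list(corr = corr[!dup, , drop = FALSE], warnings = warnings,
       kept = !dup)
}

repair_token <- function(token) {
  t <- gsub("[[:space:]]+", "", token)
  gsub("^[\"']+|[\"']+$", "", t)
}

#' Resolve alignment entity references against two ontologies
#'
#' URI references resolve by exact IRI match against the corresponding
#' side's class set; local-name references resolve by local-name lookup
#' over that side's classes (imports included): zero matches is `missing`,
#' one is `resolved`, two or more is `ambiguous` (candidates recorded).
#' With `cleanup = TRUE`, raw tokens are first repaired — all whitespace
#' stripped, surrounding quotes trimmed — and every repair is logged;
#' cleanup never decreases the number of resolved references.
#'
#' @param alignment An `alignment` from [parse_alignment()].
#' @param doc1,doc2 [ontology_document()]s for the two sides.
#' @param cleanup Repair raw tokens before lookup.
#' @return The alignment with resolution statuses, candidates, a `repairs`
#'   data frame, and duplicates on resolved pairs removed (logged).
#' @export
resolve_references <- function(alignment, doc1, doc2, cleanup = FALSE) {
  stopifnot(inherits(alignment, "alignment"),
            inherits(doc1, "ontology_document"),
            inherits(doc2, "ontology_document"))
  corr <- alignment$correspondences
  repairs <- data.frame(row_provenance = character(), side = integer(),
                        original = character(), repaired = character(),
                        stringsAsFactors = FALSE)
  resolve_side <- function(raw, doc, side) {
    uri_set <- doc$classes$uri
    ln_map <- split(doc$classes$uri, doc$classes$local_name)
    n <- length(raw)
    resolution <- character(n); uri <- character(n)
    candidates <- vector("list", n); repaired_flag <- logical(n)
    for (i in seq_len(n)) {
      token <- raw[i]
      if (cleanup) {
        fixed <- repair_token(token)
        if (fixed != token) {
          repaired_flag[i] <- TRUE
          repairs <<- rbind(repairs, data.frame(
            row_provenance = corr$row_provenance[i], side = side,
            original = token, repaired = fixed, stringsAsFactors = FALSE))
          token <- fixed
        }
      }
      if (is_absolute_iri(token)) {
        hit <- token %in% uri_set
        resolution[i] <- if (hit) "resolved" else "missing"
        uri[i] <- if (hit) token else ""
        candidates[[i]] <- if (hit) token else character()
      } else {
        cands <- ln_map[[token]]
        if (is.null(cands)) cands <- character()
        resolution[i] <- if (length(cands) == 0L) "missing"
                         else if (length(cands) == 1L) "resolved"
                         else "ambiguous"
        uri[i] <- if (length(cands) == 1L) cands else ""
        candidates[[i]] <- sort(cands)
      }
    }
    list(resolution = resolution, uri = uri, candidates = candidates,
         repaired = repaired_flag)
  }
  s1 <- resolve_side(corr$entity1_raw, doc1, 1L)
  s2 <- resolve_side(corr$entity2_raw, doc2, 2L)
  corr$resolution1 <- s1$resolution; corr$resolved_uri1 <- s1$uri
  corr$repaired1 <- s1$repaired
  corr$resolution2 <- s2$resolution; corr$resolved_uri2 <- s2$uri
  corr$repaired2 <- s2$repaired

  # second deduplication pass: distinct raw tokens may resolve to the same
  # class pair
  key1 <- ifelse(corr$resolved_uri1 != "", corr$resolved_uri1,
                 corr$entity1_raw)
  key2 <- ifelse(corr$resolved_uri2 != "", corr$resolved_uri2,
                 corr$entity2_raw)
  dd <- dedup_correspondences(corr, alignment$parse_warnings, key1, key2)
  alignment$correspondences <- dd$corr
  alignment$candidates1 <- s1$candidates[dd$kept]
  alignment$candidates2 <- s2$candidates[dd$kept]
  alignment$parse_warnings <- dd$warnings
  alignment$repairs <- repairs
  alignment$resolved <- TRUE
  alignment
}

#' Write an alignment
#'
#' Serializes a fully resolved alignment; parsing the result back yields
#' the same set of (entity pair, relation) correspondences. Unresolved
#' references are refused.
#'
#' @param alignment A resolved `alignment`.
#' @param dest Output path.
#' @param dialect `"alignment_api"` (RDF/XML) or `"delimited"`.
#' @param delimiter Separator for the delimited dialect.
#' @return `dest`, invisibly.
#' @export
write_alignment <- function(alignment, dest,
                            dialect = c("alignment_api", "delimited"),
                            delimiter = ",") {
  dialect <- match.arg(dialect)
  corr <- alignment$correspondences
  bad <- corr$resolution1 != "resolved" | corr$resolution2 != "resolved"
  if (any(bad)) {
    stop("cannot write alignment with unresolved references: ",
         paste(unique(c(corr$entity1_raw[bad & corr$resolution1 != "resolved"],
                        corr$entity2_raw[bad & corr$resolution2 != "resolved"])),
               collapse = ", "), call. = FALSE)
  }
  if (dialect == "delimited") {
    header <- paste(c("entity1", "entity2", "relation"), collapse = delimiter)
    body <- paste(corr$resolved_uri1, corr$resolved_uri2,
                  relation_symbol(corr$relation), sep = delimiter)
    writeLines(c(header, body), dest)
    return(invisible(dest))
  }
  ALIGN_NS <- "http://knowledgeweb.semanticweb.org/heterogeneity/alignment"
  root <- xml2::xml_new_root("rdf:RDF", "xmlns:rdf" = RDF_NS,
                             xmlns = ALIGN_NS)
  al <- xml2::xml_add_child(root, "Alignment")
  xml2::xml_add_child(al, "xml", "yes")
  xml2::xml_add_child(al, "level", "0")
  xml2::xml_add_child(al, "type", "??")
  if (nzchar(alignment$onto1_ref)) {
    xml2::xml_add_child(al, "onto1", "rdf:resource" = alignment$onto1_ref)
  }
  if (nzchar(alignment$onto2_ref)) {
    xml2::xml_add_child(al, "onto2", "rdf:resource" = alignment$onto2_ref)
  }
  for (i in seq_len(nrow(corr))) {
    map <- xml2::xml_add_child(al, "map")
    cell <- xml2::xml_add_child(map, "Cell")
    xml2::xml_add_child(cell, "entity1", "rdf:resource" = corr$resolved_uri1[i])
    xml2::xml_add_child(cell, "entity2", "rdf:resource" = corr$resolved_uri2[i])
    sym <- relation_symbol(corr$relation[i])
    if (nzchar(sym)) xml2::xml_add_child(cell, "relation", sym)
    if (!is.na(corr$confidence[i])) {
      xml2::xml_add_child(cell, "measure", format(corr$confidence[i]))
    }
  }
  xml2::write_xml(root, dest)
  invisible(dest)
}
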