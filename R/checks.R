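# The ten quality checks.
#
# Each check consumes a parsed (and, where required, reference-resolved)
# alignment plus the two loaded ontology documents, and returns a
# `check_report`: a status, a deterministic table of findings, and summary
# counts. Checks never repair anything; they report evidence for a human
# curator.

finding_df <- function(check_id = character(), category = character(),
                       entities = character(), evidence = character()) {
  data.frame(check_id = check_id, category = category, entities = entities,
             evidence = evidence, stringsAsFactors = FALSE)
}

entity_key <- function(...) paste(..., sep = "|")

check_report <- function(check_id, findings = finding_df(),
                         summary_counts = list(), status = NULL,
                         reason = "") {
  if (nrow(findings) > 0L) {
    findings <- findings[order(findings$category, findings$entities,
                               findings$evidence), , drop = FALSE]
    rownames(findings) <- NULL
  }
  if (is.null(status)) status <- if (nrow(findings) == 0L) "pass" else "findings"
  if (!"by_category" %in% names(summary_counts)) {
    summary_counts$by_category <- as.list(table(findings$category))
  }
  structure(list(check_id = check_id, status = status, findings = findings,
                 summary_counts = summary_counts, reason = reason),
            class = "check_report")
}

skipped_report <- function(check_id, reason) {
  check_report(check_id, status = "skipped", reason = reason,
               summary_counts = list(by_category = list()))
}

#' @export
print.check_report <- function(x, ...) {
  cat("Check ", x$check_id, ": ", x$status, sep = "")
  if (nzchar(x$reason)) cat(" (", x$reason, ")", sep = "")
  cat("\n")
  if (nrow(x$findings) > 0L) {
    tab <- table(x$findings$category)
    for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
  }
  invisible(x)
}

require_resolved <- function(alignment) {
  if (!isTRUE(alignment$resolved)) {
    stop("alignment references must be resolved first; call resolve_references()",
         call. = FALSE)
  }
}

corr_both_resolved <- function(corr) {
  corr$resolution1 == "resolved" & corr$resolution2 == "resolved"
}

# resolved equivalence pairs as a data frame (uri1 in doc1, uri2 in doc2)
equivalence_pairs <- function(alignment) {
  corr <- alignment$correspondences
  keep <- corr_both_resolved(corr) & corr$relation == "equivalentClass"
  data.frame(uri1 = corr$resolved_uri1[keep], uri2 = corr$resolved_uri2[keep],
             stringsAsFactors = FALSE)
}

# resolved subsumption pairs oriented sub -> super; sub_side records which
# ontology the subclass lives in
subclass_pairs <- function(alignment) {
  corr <- alignment$correspondences
  keep <- corr_both_resolved(corr)
  sub1 <- keep & corr$relation == "subClassOf"
  sub2 <- keep & corr$relation == "superClassOf"
  data.frame(
    sub = c(corr$resolved_uri1[sub1], corr$resolved_uri2[sub2]),
    super = c(corr$resolved_uri2[sub1], corr$resolved_uri1[sub2]),
    sub_side = c(rep(1L, sum(sub1)), rep(2L, sum(sub2))),
    stringsAsFactors = FALSE
  )
}

# ---- Check 1: input provenance -----------------------------------------

#' Check 1: are the correct input ontologies given?
#'
#' Passes only when the alignment references both ontologies, the
#' references point at the bundled documents that were actually loaded
#' (not at remote download URLs), and both documents carry version
#' information; anything less leaves the originally used ontology versions
#' unverifiable.
#'
#' @param alignment An `alignment`.
#' @param doc1,doc2 Loaded [ontology_document()]s.
#' @return A `check_report` with check_id `"1"`.
#' @export
check1_input_provenance <- function(alignment, doc1, doc2) {
  findings <- finding_df()
  side <- function(ref, doc, which) {
    if (!nzchar(ref)) {
      findings <<- rbind(findings, finding_df(
        "1", "no_ontology_reference", which,
        "alignment does not reference this input ontology"))
    } else if (grepl("^https?://", ref) && ref != doc$ontology_iri) {
      findings <<- rbind(findings, finding_df(
        "1", "remote_ontology_reference", entity_key(which, ref),
        "reference is a download URL, not a bundled document"))
    } else if (!ref %in% c(doc$ontology_iri, doc$source_location,
                           basename(doc$source_location))) {
      findings <<- rbind(findings, finding_df(
        "1", "reference_mismatch", entity_key(which, ref),
        paste0("loaded document has IRI '", doc$ontology_iri, "'")))
    }
    if (!nzchar(doc$version_info)) {
      findings <<- rbind(findings, finding_df(
        "1", "version_unverifiable", which,
        "loaded document carries no owl:versionInfo"))
    }
  }
  side(alignment$onto1_ref, doc1, "onto1")
  side(alignment$onto2_ref, doc2, "onto2")
  check_report("1", findings)
}

# ---- Check 2a: missing classes -----------------------------------------

#' Check 2a: classes referenced by the alignment but absent from the
#' ontologies
#'
#' One finding per entity reference whose resolution is `missing`. The
#' summary distinguishes distinct missing classes from affected
#' correspondences (a correspondence is affected when either side is
#' missing).
#'
#' @inheritParams check1_input_provenance
#' @return A `check_report` with check_id `"2a"`.
#' @export
check2a_missing_classes <- function(alignment, doc1, doc2) {
  require_resolved(alignment)
  corr <- alignment$correspondences
  findings <- finding_df()
  missing_tokens <- character()
  for (s in 1:2) {
    res <- corr[[paste0("resolution", s)]]
    raw <- corr[[paste0("entity", s, "_raw")]]
    idx <- which(res == "missing")
    if (length(idx) > 0L) {
      findings <- rbind(findings, finding_df(
        "2a", "missing_class", entity_key(paste0("onto", s), raw[idx]),
        paste0("referenced at ", corr$row_provenance[idx],
               ", not found in ontology ", s)))
      missing_tokens <- c(missing_tokens, paste0(s, ":", raw[idx]))
    }
  }
  affected <- sum(corr$resolution1 == "missing" | corr$resolution2 == "missing")
  check_report("2a", findings, summary_counts = list(
    missing_refs = nrow(findings),
    distinct_missing_classes = length(unique(missing_tokens)),
    affected_correspondences = affected))
}

# ---- Check 2b: label changes against a mapping table -------------------

#' Check 2b: URI/label pairs that no longer hold
#'
#' Compares a curated mapping table of (URI, expected label) rows per side
#' against the current preferred labels. Rows whose URI vanished are
#' reported as `missing_class` evidence; rows whose expected labels
#' reappear exchanged on each other's URIs are paired into one
#' `swap_suspicion` finding (a shifted-row artifact); remaining mismatches
#' are `label_changed` findings carrying old and new label.
#'
#' @param mapping_tables List with elements `onto1` and/or `onto2`, each a
#'   data frame with columns `uri` and `expected_label`, or `NULL` when no
#'   table is available (the check is then not applicable).
#' @param doc1,doc2 Loaded [ontology_document()]s.
#' @return A `check_report` with check_id `"2b"`.
#' @export
check2b_label_changes <- function(mapping_tables, doc1, doc2) {
  if (is.null(mapping_tables) ||
      (is.null(mapping_tables$onto1) && is.null(mapping_tables$onto2))) {
    return(check_report("2b", status = "not_applicable",
                        reason = "no URI-label mapping table supplied",
                        summary_counts = list(by_category = list())))
  }
  findings <- finding_df()
  one_side <- function(tab, doc, which) {
    if (is.null(tab)) return(invisible())
    stopifnot(all(c("uri", "expected_label") %in% names(tab)))
    present <- tab$uri %in% doc$classes$uri
    for (i in which(!present)) {
      findings <<- rbind(findings, finding_df(
        "2b", "missing_class", entity_key(which, tab$uri[i]),
        paste0("mapping-table class no longer present (expected label '",
               tab$expected_label[i], "')")))
    }
    tab <- tab[present, , drop = FALSE]
    current <- vapply(tab$uri, function(u) preferred_label(doc, u), "")
    changed <- which(current != tab$expected_label)
    # swap detection among changed rows: expected labels traded places
    swapped <- integer()
    if (length(changed) >= 2L) {
      for (ii in seq_along(changed)) {
        for (jj in seq_len(ii - 1L)) {
          i <- changed[ii]; j <- changed[jj]
          if (tab$expected_label[i] == current[j] &&
              tab$expected_label[j] == current[i]) {
            us <- sort(c(tab$uri[i], tab$uri[j]))
            findings <<- rbind(findings, finding_df(
              "2b", "swap_suspicion",
              entity_key(which, us[1], us[2]),
              paste0("labels '", tab$expected_label[i], "' and '",
                     tab$expected_label[j], "' appear exchanged")))
            swapped <- c(swapped, i, j)
          }
        }
      }
    }
    for (i in setdiff(changed, swapped)) {
      norm_equal <- rendered(normalize_label(current[i])) ==
        rendered(normalize_label(tab$expected_label[i]))
      findings <<- rbind(findings, finding_df(
        "2b", "label_changed", entity_key(which, tab$uri[i]),
        paste0("label changed from '", tab$expected_label[i], "' to '",
               current[i], "'",
               if (norm_equal) " (equal after normalization)" else "")))
    }
  }
  one_side(mapping_tables$onto1, doc1, "onto1")
  one_side(mapping_tables$onto2, doc2, "onto2")
  check_report("2b", findings)
}

# ---- Check 3: distribution format --------------------------------------

#' Check 3: is the alignment distributed in the standard format?
#'
#' Passes only for Alignment API documents that parsed without warnings.
#' Delimited sources yield a `non_standard_format` finding plus one
#' `malformed_row` finding per parse warning.
#'
#' @param alignment An `alignment` (parse warnings are carried on it).
#' @return A `check_report` with check_id `"3"`.
#' @export
check3_format <- function(alignment) {
  findings <- finding_df()
  if (alignment$source_format != "alignment_api") {
    findings <- rbind(findings, finding_df(
      "3", "non_standard_format", alignment$source_path,
      paste0("alignment is distributed as a ", alignment$source_format,
             " table, not in the Alignment API format")))
  }
  pw <- alignment$parse_warnings
  if (nrow(pw) > 0L) {
    findings <- rbind(findings, finding_df(
      "3", "malformed_row", pw$row_provenance, pw$message))
  }
  check_report("3", findings)
}

# ---- Check 4: reference ambiguity --------------------------------------

#' Check 4: are class references unique?
#'
#' One finding per entity reference that resolved ambiguously (a local
#' name matching classes in two or more namespaces of the merged
#' ontology), with the candidate IRIs as payload.
#'
#' @inheritParams check1_input_provenance
#' @return A `check_report` with check_id `"4"`.
#' @export
check4_reference_ambiguity <- function(alignment, doc1, doc2) {
  require_resolved(alignment)
  corr <- alignment$correspondences
  findings <- finding_df()
  for (s in 1:2) {
    res <- corr[[paste0("resolution", s)]]
    raw <- corr[[paste0("entity", s, "_raw")]]
    cands <- alignment[[paste0("candidates", s)]]
    for (i in which(res == "ambiguous")) {
      findings <- rbind(findings, finding_df(
        "4", "ambiguous_ref", entity_key(paste0("onto", s), raw[i]),
        paste0("candidates: ", paste(cands[[i]], collapse = ", "))))
    }
  }
  check_report("4", findings)
}

# ---- Check 5: relation typing ------------------------------------------

#' Check 5: are relation types explicitly specified?
#'
#' Flags every correspondence whose relation is `unknown` — either absent
#' from the file or deliberately forced to unknown because the file's
#' uniform markings are known to be a technical artifact. When findings
#' exist, the orchestrator skips the type-dependent checks 6-10 unless
#' overridden.
#'
#' @param alignment An `alignment`.
#' @return A `check_report` with check_id `"5"`.
#' @export
check5_relation_types <- function(alignment) {
  corr <- alignment$correspondences
  idx <- which(corr$relation == "unknown")
  findings <- if (length(idx) == 0L) finding_df() else finding_df(
    "5", "untyped_relation",
    entity_key(corr$entity1_raw[idx], corr$entity2_raw[idx]),
    if (isTRUE(alignment$forced_untyped)) {
      "relation markings treated as unreliable (forced untyped)"
    } else paste0("no relation type at ", corr$row_provenance[idx]))
  check_report("5", findings,
               summary_counts = list(untyped = length(idx)))
}

# ---- Check 6: multiple equivalence targets -----------------------------

classify_target_pair <- function(doc, a, b) {
  e <- doc$taxonomy
  any_edge <- function(edges) {
    any((edges$from == a & edges$to == b) | (edges$from == b & edges$to == a))
  }
  if (any_edge(e$equivalence_edges)) return("equivalentClass")
  if (any_edge(e$subclass_edges)) return("subClassOf")
  if (any_edge(e$partof_edges)) return("partOf")
  if (any_edge(e$disjoint_edges)) return("disjoint")
  parents <- function(u) e$subclass_edges$to[e$subclass_edges$from == u]
  if (length(intersect(parents(a), parents(b))) > 0L) return("sibling")
  "none"
}

#' Check 6: classes with several equivalence targets
#'
#' A class should map to at most one class of the other ontology by an
#' equivalentClass relation. Run in both directions; for every source
#' class with two or more targets, one finding lists the targets and, for
#' each target pair, the relation asserted between them in their home
#' ontology (equivalentClass | subClassOf | partOf | disjoint | sibling |
#' none) — an equivalentClass link hints at an implicit merge candidate,
#' anything else at a redundant or wrong correspondence.
#'
#' @inheritParams check1_input_provenance
#' @return A `check_report` with check_id `"6"`.
#' @export
check6_multiple_targets <- function(alignment, doc1, doc2) {
  require_resolved(alignment)
  eq <- equivalence_pairs(alignment)
  findings <- finding_df()
  one_direction <- function(source, target, target_doc, which) {
    by_source <- split(target, source)
    for (src in names(by_source)) {
      targets <- sort(unique(by_source[[src]]))
      if (length(targets) < 2L) next
      rels <- character()
      for (i in seq_along(targets)) {
        for (j in seq_len(i - 1L)) {
          rels <- c(rels, paste0(targets[j], " ~ ", targets[i], ": ",
                                 classify_target_pair(target_doc, targets[j],
                                                      targets[i])))
        }
      }
      findings <<- rbind(findings, finding_df(
        "6", "multi_target", entity_key(which, src),
        paste0("targets {", paste(targets, collapse = ", "),
               "}; relations between targets: ",
               paste(rels, collapse = "; "))))
    }
  }
  one_direction(eq$uri1, eq$uri2, doc2, "onto1")
  one_direction(eq$uri2, eq$uri1, doc1, "onto2")
  check_report("6", findings,
               summary_counts = list(multi_target_sources = nrow(findings)))
}

# ---- Check 7: subsumptions entailed by equivalences --------------------

#' Entailed cross-ontology subsumptions
#'
#' An asserted equivalence between a in O1 and b in O2 logically entails
#' x subClassOf y for every subclass x of a and superclass y of b, and
#' symmetrically for subclasses of b against superclasses of a. Closures
#' are reflexive on both sides, the generating pair itself is excluded,
#' and entailments are not chained across several equivalences.
#'
#' @inheritParams check1_input_provenance
#' @return Data frame with columns `sub`, `super`, `sub_side` (1 when the
#'   subclass lives in `doc1`, 2 otherwise) and `new` (not already a
#'   subsumption correspondence of the alignment), deduplicated.
#' @export
infer_subclass_correspondences <- function(alignment, doc1, doc2) {
  require_resolved(alignment)
  eq <- equivalence_pairs(alignment)
  up1 <- all_closures(doc1, "up"); down1 <- all_closures(doc1, "down")
  up2 <- all_closures(doc2, "up"); down2 <- all_closures(doc2, "down")
  subs <- character(); supers <- character(); sides <- integer()
  for (k in seq_len(nrow(eq))) {
    a <- eq$uri1[k]; b <- eq$uri2[k]
    x <- c(a, down1[[a]]); y <- c(b, up2[[b]])
    fam <- expand.grid(sub = x, super = y, stringsAsFactors = FALSE)
    fam <- fam[!(fam$sub == a & fam$super == b), , drop = FALSE]
    subs <- c(subs, fam$sub); supers <- c(supers, fam$super)
    sides <- c(sides, rep(1L, nrow(fam)))
    x2 <- c(b, down2[[b]]); y2 <- c(a, up1[[a]])
    fam2 <- expand.grid(sub = x2, super = y2, stringsAsFactors = FALSE)
    fam2 <- fam2[!(fam2$sub == b & fam2$super == a), , drop = FALSE]
    subs <- c(subs, fam2$sub); supers <- c(supers, fam2$super)
    sides <- c(sides, rep(2L, nrow(fam2)))
  }
  inferred <- data.frame(sub = subs, super = supers, sub_side = sides,
                         stringsAsFactors = FALSE)
  inferred <- inferred[!duplicated(paste(inferred$sub, inferred$super,
                                         inferred$sub_side)), , drop = FALSE]
  asserted <- subclass_pairs(alignment)
  inferred$new <- !paste(inferred$sub, inferred$super) %in%
    paste(asserted$sub, asserted$super)
  inferred[order(inferred$sub, inferred$super), , drop = FALSE]
}

#' Check 7: subClassOf correspondences inferable from equivalences
#'
#' Reports every cross-ontology subsumption entailed by the alignment's
#' equivalentClass correspondences combined with the two class taxonomies
#' (see [infer_subclass_correspondences()]), labeled `new` when absent
#' from the alignment. Subclasses living in O2 are reported in O1-to-O2
#' orientation via superClassOf.
#'
#' @inheritParams check1_input_provenance
#' @return A `check_report` with check_id `"7"` and summary counts
#'   `inferred_total` and `inferred_new`.
#' @export
check7_inferred_subclass <- function(alignment, doc1, doc2) {
  inferred <- infer_subclass_correspondences(alignment, doc1, doc2)
  findings <- if (nrow(inferred) == 0L) finding_df() else finding_df(
    "7",
    ifelse(inferred$new, "inferred_subclass_new", "inferred_subclass_present"),
    ifelse(inferred$sub_side == 1L,
           entity_key(inferred$sub, "subClassOf", inferred$super),
           entity_key(inferred$super, "superClassOf", inferred$sub)),
    paste0("entailed by an equivalence plus taxonomy; subclass in onto",
           inferred$sub_side))
  corr <- alignment$correspondences
  excluded <- sum(!corr_both_resolved(corr) &
                  corr$relation == "equivalentClass")
  check_report("7", findings, summary_counts = list(
    inferred_total = nrow(inferred),
    inferred_new = sum(inferred$new),
    excluded_correspondences = excluded))
}

# ---- Checks 8/9: lexical evidence --------------------------------------

# normalized handle table: one row per (class, handle) with tokens + head
handle_table <- function(doc, label_mode, preposition_set) {
  uris <- doc$classes$uri
  rows <- lapply(uris, function(u) {
    hs <- lexical_handles(doc, u, label_mode)
    hs <- hs[nzchar(trimws(hs))]
    if (length(hs) == 0L) return(NULL)
    norm <- lapply(hs, function(h) tryCatch(normalize_label(h),
                                            error = function(e) NULL))
    keep <- !vapply(norm, is.null, NA)
    norm <- norm[keep]
    if (length(norm) == 0L) return(NULL)
    data.frame(
      uri = u,
      handle = vapply(norm, rendered, ""),
      head = vapply(norm, function(nl) {
        tryCatch(extract_head(nl, preposition_set),
                 error = function(e) NA_character_)
      }, NA_character_),
      n_tokens = vapply(norm, function(nl) length(nl$tokens), 0L),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(uri = character(), handle = character(),
                      head = character(), n_tokens = integer(),
                      stringsAsFactors = FALSE)
  }
  out[!duplicated(paste(out$uri, out$handle)), , drop = FALSE]
}

#' Check 8: label identity without an equivalence correspondence
#'
#' Over all cross-ontology class pairs, flags each pair where some label
#' (or the local-name fallback) of one class normalizes identically to
#' some label of the other while no equivalentClass correspondence links
#' the pair. Pairs whose URIs are literally identical (both ontologies
#' import the same third-party class) are reported as `shared_uri`
#' instead.
#'
#' @inheritParams check1_input_provenance
#' @param label_mode `"all"` compares every label (synonyms included);
#'   `"preferred"` restricts to the preferred label.
#' @param preposition_set Passed to head extraction (used by Check 9/10).
#' @return A `check_report` with check_id `"8"`; findings count class
#'   pairs.
#' @export
check8_label_identity <- function(alignment, doc1, doc2,
                                  label_mode = c("all", "preferred"),
                                  preposition_set = DEFAULT_PREPOSITIONS) {
  require_resolved(alignment)
  label_mode <- match.arg(label_mode)
  h1 <- handle_table(doc1, label_mode, preposition_set)
  h2 <- handle_table(doc2, label_mode, preposition_set)
  eq <- equivalence_pairs(alignment)
  eq_keys <- paste(eq$uri1, eq$uri2)
  shared <- intersect(h1$handle, h2$handle)
  m1 <- split(h1$uri, h1$handle)
  m2 <- split(h2$uri, h2$handle)
  seen <- character()
  findings <- finding_df()
  for (lab in sort(shared)) {
    for (u1 in unique(m1[[lab]])) {
      for (u2 in unique(m2[[lab]])) {
        key <- paste(u1, u2)
        if (key %in% seen) next
        seen <- c(seen, key)
        if (u1 == u2) {
          findings <- rbind(findings, finding_df(
            "8", "shared_uri", entity_key(u1, u2),
            paste0("both ontologies contain the same class URI (label '",
                   lab, "')")))
        } else if (!key %in% eq_keys) {
          findings <- rbind(findings, finding_df(
            "8", "label_identity_missing_equiv", entity_key(u1, u2),
            paste0("shared normalized label '", lab,
                   "' but no equivalentClass correspondence")))
        }
      }
    }
  }
  check_report("8", findings,
               summary_counts = list(pairs = nrow(findings)))
}

#' Check 9: label inclusion with equal heads but no subsumption
#' correspondence
#'
#' Flags cross-ontology class pairs where one class's label strictly
#' includes the other's and both share the same syntactic head — evidence
#' that the longer-labeled class is a subclass of the shorter-labeled one
#' — while no such subClassOf-based correspondence exists in the
#' alignment. Pairs already covered by an equivalentClass correspondence
#' are suppressed (the lexical evidence then argues for nothing new); the
#' payload notes when Check 7 already inferred the proposed subsumption.
#' The check is a detector, not an oracle: proposals are meant for human
#' review.
#'
#' @inheritParams check8_label_identity
#' @return A `check_report` with check_id `"9"`; findings count class
#'   pairs, oriented longer-label class as subclass.
#' @export
check9_label_inclusion <- function(alignment, doc1, doc2,
                                   label_mode = c("all", "preferred"),
                                   preposition_set = DEFAULT_PREPOSITIONS) {
  require_resolved(alignment)
  label_mode <- match.arg(label_mode)
  h1 <- handle_table(doc1, label_mode, preposition_set)
  h2 <- handle_table(doc2, label_mode, preposition_set)
  eq <- equivalence_pairs(alignment)
  eq_keys <- paste(eq$uri1, eq$uri2)
  asserted <- subclass_pairs(alignment)
  asserted_keys <- paste(asserted$sub, asserted$super)
  inferred <- infer_subclass_correspondences(alignment, doc1, doc2)
  inferred_keys <- paste(inferred$sub, inferred$super)

  heads <- intersect(h1$head[!is.na(h1$head)], h2$head[!is.na(h2$head)])
  b1 <- split(seq_len(nrow(h1)), h1$head)
  b2 <- split(seq_len(nrow(h2)), h2$head)
  seen <- character()
  findings <- finding_df()
  for (hd in sort(heads)) {
    for (i in b1[[hd]]) {
      for (j in b2[[hd]]) {
        u1 <- h1$uri[i]; u2 <- h2$uri[j]
        if (u1 == u2) next
        inc <- label_inclusion(normalize_label(h1$handle[i]),
                               normalize_label(h2$handle[j]))
        if (!inc %in% c("a_includes_b", "b_includes_a")) next
        # longer label proposed as subclass
        if (inc == "a_includes_b") {
          sub <- u1; super <- u2; sub_side <- 1L
          sub_lab <- h1$handle[i]; super_lab <- h2$handle[j]
        } else {
          sub <- u2; super <- u1; sub_side <- 2L
          sub_lab <- h2$handle[j]; super_lab <- h1$handle[i]
        }
        pair_key <- paste(sub, super)
        if (pair_key %in% seen) next
        if (paste(u1, u2) %in% eq_keys) next
        if (pair_key %in% asserted_keys) next
        seen <- c(seen, pair_key)
        already <- pair_key %in% inferred_keys
        findings <- rbind(findings, finding_df(
          "9", "inclusion_missing_subclass",
          if (sub_side == 1L) entity_key(sub, "subClassOf", super)
          else entity_key(super, "superClassOf", sub),
          paste0("label '", sub_lab, "' includes '", super_lab,
                 "' with identical head '", hd, "'",
                 if (already) "; already inferred by Check 7" else "")))
      }
    }
  }
  check_report("9", findings,
               summary_counts = list(pairs = nrow(findings)))
}

# ---- Check 10: trivialness ---------------------------------------------

#' Check 10: trivial-correspondence statistics
#'
#' Partitions the resolved, relation-typed correspondences into trivial
#' and non-trivial. An equivalentClass correspondence is trivial when some
#' normalized label (or local-name fallback) of one side is identical to
#' one of the other; a subsumption correspondence is trivial when a label
#' of the subclass strictly includes a label of the superclass with the
#' same syntactic head. Correspondences with unresolved references or
#' unusable relation types are excluded from the partition.
#'
#' @inheritParams check8_label_identity
#' @return A `check_report` with check_id `"10"`; findings list the
#'   trivial correspondences; summary counts carry `trivial`,
#'   `non_trivial` and `trivial_fraction`.
#' @export
check10_trivial <- function(alignment, doc1, doc2,
                            label_mode = c("all", "preferred"),
                            preposition_set = DEFAULT_PREPOSITIONS) {
  require_resolved(alignment)
  label_mode <- match.arg(label_mode)
  h1 <- handle_table(doc1, label_mode, preposition_set)
  h2 <- handle_table(doc2, label_mode, preposition_set)
  handles1 <- split(seq_len(nrow(h1)), h1$uri)
  handles2 <- split(seq_len(nrow(h2)), h2$uri)
  corr <- alignment$correspondences
  usable <- corr_both_resolved(corr) &
    corr$relation %in% c("equivalentClass", "subClassOf", "superClassOf")
  trivial <- logical(nrow(corr))
  is_trivial_equiv <- function(u1, u2) {
    length(intersect(h1$handle[handles1[[u1]]],
                     h2$handle[handles2[[u2]]])) > 0L
  }
  is_trivial_sub <- function(sub_handles, super_handles) {
    for (a in sub_handles) {
      for (b in super_handles) {
        if (inclusion_head_evidence(a, b, preposition_set)) return(TRUE)
      }
    }
    FALSE
  }
  for (i in which(usable)) {
    u1 <- corr$resolved_uri1[i]; u2 <- corr$resolved_uri2[i]
    trivial[i] <- switch(corr$relation[i],
      equivalentClass = is_trivial_equiv(u1, u2),
      subClassOf = is_trivial_sub(h1$handle[handles1[[u1]]],
                                  h2$handle[handles2[[u2]]]),
      superClassOf = is_trivial_sub(h2$handle[handles2[[u2]]],
                                    h1$handle[handles1[[u1]]]))
  }
  idx <- which(usable & trivial)
  findings <- if (length(idx) == 0L) finding_df() else finding_df(
    "10", "trivial",
    entity_key(corr$resolved_uri1[idx], corr$relation[idx],
               corr$resolved_uri2[idx]),
    "detectable by normalized label identity / head analysis alone")
  n_usable <- sum(usable)
  n_trivial <- length(idx)
  check_report("10", findings, summary_counts = list(
    trivial = n_trivial,
    non_trivial = n_usable - n_trivial,
    excluded = nrow(corr) - n_usable,
    trivial_fraction = if (n_usable > 0L) n_trivial / n_usable else NA_real_))
}
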