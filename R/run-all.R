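# Orchestrator: the proposed execution order of the ten checks, plus
# report serialization.

#' Options for a quality-check run
#'
#' @param include_subclass Is the alignment supposed to incorporate
#'   subClassOf-based correspondences? When `FALSE`, checks 7 and 9 are
#'   reported as skipped.
#' @param cleanup Repair whitespace/quote damage in entity references
#'   before resolution (see [resolve_references()]).
#' @param force_untyped Treat every relation marking in the alignment file
#'   as unknown (for files whose uniform markings are a technical
#'   artifact); checks 6-10 are then skipped.
#' @param allow_untyped Run checks 6-10 on the typed subset even when
#'   Check 5 reports untyped relations (override of the default skip).
#' @param mapping_tables Optional URI-label tables for Check 2b; see
#'   [check2b_label_changes()].
#' @param label_mode `"all"` or `"preferred"`; see [check8_label_identity()].
#' @param preposition_set Tokens treated as prepositions in head
#'   extraction.
#' @param dialect,delimiter,column_order,has_header Passed to
#'   [parse_alignment()] when the alignment argument of [run_all()] is a
#'   file path.
#' @return A list of class `qc_options`.
#' @export
qc_options <- function(include_subclass = TRUE, cleanup = FALSE,
                       force_untyped = FALSE, allow_untyped = FALSE,
                       mapping_tables = NULL,
                       label_mode = c("all", "preferred"),
                       preposition_set = DEFAULT_PREPOSITIONS,
                       dialect = "auto", delimiter = ",",
                       column_order = c("entity1", "entity2", "relation"),
                       has_header = NA) {
  structure(list(include_subclass = include_subclass, cleanup = cleanup,
                 force_untyped = force_untyped,
                 allow_untyped = allow_untyped,
                 mapping_tables = mapping_tables,
                 label_mode = match.arg(label_mode),
                 preposition_set = preposition_set, dialect = dialect,
                 delimiter = delimiter, column_order = column_order,
                 has_header = has_header),
            class = "qc_options")
}

#' Run all ten quality checks in the proposed order
#'
#' Execution order is 1, 2a, 2b, 3, 4, 5, 6, 7, 8, 9, 10 with the
#' branching rules: Check 2 is skipped when Check 1 passes; checks 7 and 9
#' are skipped when subClassOf-based correspondences are out of scope; and
#' checks 6-10 are skipped when Check 5 reports untyped relations (unless
#' `allow_untyped` overrides, in which case they run on the typed subset).
#' Every skip is recorded with its reason.
#'
#' @param alignment An `alignment` object or a path to an alignment file.
#' @param doc1,doc2 Loaded [ontology_document()]s (or paths, loaded with
#'   defaults).
#' @param options A [qc_options()] list.
#' @return A list of `check_report`s (class `qc_report_set`), in execution
#'   order.
#' @export
run_all <- function(alignment, doc1, doc2, options = qc_options()) {
  stopifnot(inherits(options, "qc_options"))
  if (is.character(doc1)) doc1 <- load_ontology(doc1)
  if (is.character(doc2)) doc2 <- load_ontology(doc2)
  if (is.character(alignment)) {
    alignment <- parse_alignment(alignment, dialect = options$dialect,
                                 delimiter = options$delimiter,
                                 column_order = options$column_order,
                                 has_header = options$has_header,
                                 force_untyped = options$force_untyped)
  } else if (options$force_untyped) {
    alignment$correspondences$relation <-
      rep("unknown", nrow(alignment$correspondences))
    alignment$forced_untyped <- TRUE
  }
  if (!isTRUE(alignment$resolved)) {
    alignment <- resolve_references(alignment, doc1, doc2,
                                    cleanup = options$cleanup)
  }

  reports <- list()
  add <- function(r) reports[[length(reports) + 1L]] <<- r

  r1 <- check1_input_provenance(alignment, doc1, doc2)
  add(r1)
  if (r1$status == "pass") {
    add(skipped_report("2a", "Check 1 passed; input provenance is verified"))
    add(skipped_report("2b", "Check 1 passed; input provenance is verified"))
  } else {
    add(check2a_missing_classes(alignment, doc1, doc2))
    add(check2b_label_changes(options$mapping_tables, doc1, doc2))
  }
  add(check3_format(alignment))
  add(check4_reference_ambiguity(alignment, doc1, doc2))
  r5 <- check5_relation_types(alignment)
  add(r5)

  untyped_block <- r5$status == "findings" && !options$allow_untyped
  skip_untyped <- function(id) {
    skipped_report(id, "untyped relations present (Check 5); relation types are required")
  }
  if (untyped_block) {
    add(skip_untyped("6"))
  } else {
    add(check6_multiple_targets(alignment, doc1, doc2))
  }
  if (!options$include_subclass) {
    add(skipped_report("7", "subClassOf-based correspondences out of scope"))
  } else if (untyped_block) {
    add(skip_untyped("7"))
  } else {
    add(check7_inferred_subclass(alignment, doc1, doc2))
  }
  if (untyped_block) {
    add(skip_untyped("8"))
  } else {
    add(check8_label_identity(alignment, doc1, doc2, options$label_mode,
                              options$preposition_set))
  }
  if (!options$include_subclass) {
    add(skipped_report("9", "subClassOf-based correspondences out of scope"))
  } else if (untyped_block) {
    add(skip_untyped("9"))
  } else {
    add(check9_label_inclusion(alignment, doc1, doc2, options$label_mode,
                               options$preposition_set))
  }
  if (untyped_block) {
    add(skip_untyped("10"))
  } else {
    add(check10_trivial(alignment, doc1, doc2, options$label_mode,
                        options$preposition_set))
  }
  names(reports) <- vapply(reports, `[[`, "", "check_id")
  structure(reports, class = "qc_report_set")
}

#' @export
print.qc_report_set <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}

#' Serialize a report set to JSON
#'
#' The shipped schema (`inst/extdata/report-schema.json`) describes the
#' output: an array of per-check objects with `check_id`, `status`,
#' `reason`, `summary_counts` and a `findings` array.
#'
#' @param reports A `qc_report_set` from [run_all()].
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(reports, path = NULL) {
  payload <- lapply(unname(reports), function(r) {
    list(check_id = r$check_id, status = r$status, reason = r$reason,
         summary_counts = r$summary_counts,
         findings = if (nrow(r$findings) == 0L) list() else
           lapply(seq_len(nrow(r$findings)), function(i) {
             list(category = r$findings$category[i],
                  entities = strsplit(r$findings$entities[i], "|",
                                      fixed = TRUE)[[1]],
                  evidence = r$findings$evidence[i])
           }))
  })
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Render a report set as human-readable text
#'
#' @inheritParams report_to_json
#' @param max_findings Per-check cap on the number of finding lines shown.
#' @return Character vector of lines.
#' @export
report_to_text <- function(reports, max_findings = 20L) {
  out <- character()
  for (r in reports) {
    line <- sprintf("Check %-3s %s", r$check_id, r$status)
    if (nzchar(r$reason)) line <- paste0(line, " (", r$reason, ")")
    out <- c(out, line)
    sc <- r$summary_counts[setdiff(names(r$summary_counts), "by_category")]
    if (length(sc) > 0L) {
      out <- c(out, paste0("  ", paste(names(sc),
                                       vapply(sc, format, ""),
                                       sep = " = ", collapse = ", ")))
    }
    n <- nrow(r$findings)
    if (n > 0L) {
      shown <- seq_len(min(n, max_findings))
      out <- c(out, sprintf("  [%s] %s — %s",
                            r$findings$category[shown],
                            r$findings$entities[shown],
                            r$findings$evidence[shown]))
      if (n > max_findings) {
        out <- c(out, sprintf("  ... %d further finding(s)",
                              n - max_findings))
      }
    }
  }
  out
}

#' Exit code for a report set
#'
#' 0 when every check passed, was skipped, or was not applicable; 1 when
#' any check produced findings.
#' @inheritParams report_to_json
#' @return Integer exit code.
#' @export
qc_exit_code <- function(reports) {
  if (all(vapply(reports, `[[`, "", "status") %in%
          c("pass", "skipped", "not_applicable"))) 0L else 1L
}
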