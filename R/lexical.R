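# Term normalization, syntactic-head extraction and label inclusion.
#
# These are the lexical primitives behind the label-identity, label-
# inclusion and trivialness checks. Normalization follows the usual
# ontology-matching recipe: CamelCase splitting, underscore/hyphen removal,
# lowercasing.

#' Default preposition set for head extraction
#'
#' Tokens treated as phrase-internal prepositions when locating the
#' syntactic head of a label ("professor *of biology*" has leftmost head
#' "professor").
#' @export
DEFAULT_PREPOSITIONS <- c("of", "in", "for", "by", "with", "at", "to",
                          "from", "on")

#' Normalize a class label
#'
#' Pipeline: split CamelCase at lower-to-upper transitions and at acronym
#' boundaries (`"ABCDef"` splits as `"ABC Def"`), replace underscores and
#' hyphens with spaces, strip remaining punctuation (digits are kept),
#' lowercase, and tokenize on whitespace. The result is idempotent:
#' normalizing the rendered form of a normalized label is a fixpoint.
#'
#' @param text A non-empty string.
#' @return An object of class `normalized_label`: list with `source_text`
#'   and `tokens` (ordered lowercase tokens).
#' @examples
#' normalize_label("AnatomicalStructure")$tokens
#' normalize_label("brain_white_matter")$tokens
#' @export
normalize_label <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- text
  s <- gsub("([[:lower:][:digit:]])([[:upper:]])", "\\1 \\2", s)
  s <- gsub("([[:upper:]]+)([[:upper:]][[:lower:]])", "\\1 \\2", s)
  s <- gsub("[_-]+", " ", s)
  s <- gsub("[^[:alnum:][:space:]]+", "", s)
  s <- tolower(trimws(gsub("[[:space:]]+", " ", s)))
  if (!nzchar(s)) {
    stop("cannot normalize empty label: '", text, "'", call. = FALSE)
  }
  structure(list(source_text = text,
                 tokens = strsplit(s, " ", fixed = TRUE)[[1]]),
            class = "normalized_label")
}

#' @export
print.normalized_label <- function(x, ...) {
  cat("<normalized_label> '", x$source_text, "' -> [",
      paste(x$tokens, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

rendered <- function(label) paste(label$tokens, collapse = " ")

as_normalized <- function(x) {
  if (inherits(x, "normalized_label")) x else normalize_label(x)
}

#' Syntactic head of a normalized label
#'
#' Heuristic: if a preposition occurs at token position two or later, the
#' head is the token immediately before the first such preposition
#' (leftmost-head reading, as in "professor of biology" -> "professor");
#' otherwise the head is the rightmost token (as in "doctoral thesis" ->
#' "thesis"). A label whose tokens are all prepositions is degenerate.
#'
#' @param label A `normalized_label` (or a string, normalized on the fly).
#' @param preposition_set Tokens treated as prepositions.
#' @return The head token.
#' @examples
#' extract_head(normalize_label("professor of biology"))
#' extract_head(normalize_label("doctoral thesis"))
#' @export
extract_head <- function(label, preposition_set = DEFAULT_PREPOSITIONS) {
  label <- as_normalized(label)
  toks <- label$tokens
  if (all(toks %in% preposition_set)) {
    stop("degenerate label (prepositions only): '", label$source_text, "'",
         call. = FALSE)
  }
  inner <- which(toks %in% preposition_set)
  inner <- inner[inner >= 2L]
  if (length(inner) > 0L) toks[inner[1] - 1L] else toks[length(toks)]
}

#' Token-level inclusion between two normalized labels
#'
#' `identical` when the token sequences are equal; `a_includes_b` when b's
#' token sequence occurs as a contiguous subsequence of a's (and they are
#' not equal); symmetrically `b_includes_a`; otherwise `none`. Inclusion is
#' token-level, not substring-level, so "male" does not match inside
#' "female".
#'
#' @param a,b `normalized_label` objects (or strings).
#' @return One of `"identical"`, `"a_includes_b"`, `"b_includes_a"`,
#'   `"none"`.
#' @export
label_inclusion <- function(a, b) {
  a <- as_normalized(a); b <- as_normalized(b)
  ta <- a$tokens; tb <- b$tokens
  if (identical(ta, tb)) return("identical")
  if (contains_contiguous(ta, tb)) return("a_includes_b")
  if (contains_contiguous(tb, ta)) return("b_includes_a")
  "none"
}

contains_contiguous <- function(long, short) {
  nl <- length(long); ns <- length(short)
  if (ns >= nl) return(FALSE)
  for (start in seq_len(nl - ns + 1L)) {
    if (identical(long[start:(start + ns - 1L)], short)) return(TRUE)
  }
  FALSE
}

# Does the (sub, super) label pair carry subsumption evidence: sub's label
# strictly includes super's and both share the same syntactic head? Heads
# that are degenerate (preposition-only labels) yield FALSE.
inclusion_head_evidence <- function(sub_label, super_label,
                                    preposition_set = DEFAULT_PREPOSITIONS) {
  sub_label <- as_normalized(sub_label)
  super_label <- as_normalized(super_label)
  if (label_inclusion(sub_label, super_label) != "a_includes_b") return(FALSE)
  h1 <- tryCatch(extract_head(sub_label, preposition_set),
                 error = function(e) NA_character_)
  h2 <- tryCatch(extract_head(super_label, preposition_set),
                 error = function(e) NA_character_)
  !is.na(h1) && !is.na(h2) && h1 == h2
}
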