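#' Base-pairing rule for RNA duplex and fold scoring
#'
#' Defines which RNA base pairs count as paired and how strongly each pair
#' class scores. Canonical Watson-Crick pairs (G:C, A:U) always pair; the
#' non-canonical G:U wobble pair is included when `allow_wobble = TRUE`.
#' Scores must satisfy G:C >= A:U >= G:U > 0 so that a G:C pair is literally
#' stronger than the wobble it may replace.
#'
#' The defaults (G:C = 3, A:U = 2, G:U = 1) are a transparent integer scale,
#' not free energies: only the ordering and additivity are used by the
#' screening and folding code.
#'
#' @param allow_wobble Should G:U wobble pairs count as paired? Default `TRUE`.
#' @param pair_scores Named numeric vector with entries `"G:C"`, `"A:U"`,
#'   `"G:U"` giving non-negative per-pair scores.
#' @return An object of class `base_pair_rule`.
#' @examples
#' rule <- base_pair_rule()
#' can_pair("G", "U", rule)
#' can_pair("G", "U", base_pair_rule(allow_wobble = FALSE))
#' @export
base_pair_rule <- function(allow_wobble = TRUE,
                           pair_scores = c("G:C" = 3, "A:U" = 2, "G:U" = 1)) {
  required <- c("G:C", "A:U", "G:U")
  if (!all(required %in% names(pair_scores))) {
    abort("`pair_scores` must name all of \"G:C\", \"A:U\" and \"G:U\".")
  }
  pair_scores <- pair_scores[required]
  if (any(pair_scores <= 0)) {
    abort("All pair scores must be strictly positive.")
  }
  if (!(pair_scores[["G:C"]] >= pair_scores[["A:U"]] &&
        pair_scores[["A:U"]] >= pair_scores[["G:U"]])) {
    abort("Pair scores must satisfy G:C >= A:U >= G:U.")
  }
  structure(
    list(allow_wobble = isTRUE(allow_wobble), pair_scores = pair_scores),
    class = "base_pair_rule"
  )
}

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

rna_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

check_rna_alphabet <- function(seq, what = "sequence") {
  b <- rna_chars(seq)
  bad <- which(!b %in% RNA_BASES)
  if (length(bad) > 0) {
    abort(sprintf(
      "Invalid %s: unknown base(s) %s at position(s) %s (alphabet is A, C, G, U).",
      what,
      paste(unique(b[bad]), collapse = ", "),
      paste(bad, collapse = ", ")
    ))
  }
  invisible(b)
}

#' Classify an RNA base pair
#'
#' Returns the pair class of two bases under a pairing rule: `"G:C"`, `"A:U"`
#' or `"G:U"` (orientation-insensitive), or `NA` when the bases do not pair
#' (for example the A:G mismatch that arises from stem-breaking
#' substitutions).
#'
#' @param b1,b2 Single RNA bases (`"A"`, `"C"`, `"G"`, `"U"`).
#' @param rule A [base_pair_rule()].
#' @return A pair-class string, or `NA_character_` for a mismatch.
#' @export
pair_class <- function(b1, b2, rule = base_pair_rule()) {
  key <- paste(sort(c(b1, b2)), collapse = "")
  out <- switch(key,
    "CG" = "G:C",
    "AU" = "A:U",
    "GU" = if (rule$allow_wobble) "G:U" else NA_character_,
    NA_character_
  )
  out %||% NA_character_
}

#' Can two RNA bases pair?
#'
#' `TRUE` iff the unordered pair is G:C or A:U, or G:U when the rule allows
#' wobble pairing. Symmetric in its base arguments.
#'
#' @inheritParams pair_class
#' @return Logical scalar.
#' @examples
#' can_pair("A", "G") # the A:G mismatch never pairs
#' @export
can_pair <- function(b1, b2, rule = base_pair_rule()) {
  for (b in c(b1, b2)) {
    if (!b %in% RNA_BASES) {
      abort(sprintf("Unknown base \"%s\" (alphabet is A, C, G, U).", b))
    }
  }
  !is.na(pair_class(b1, b2, rule))
}

# 4x4 logical pairing matrix over RNA_BASES; vectorised workhorse used by the
# duplex and fold code so can_pair() stays scalar and readable
pairing_matrix <- function(rule = base_pair_rule()) {
  m <- matrix(FALSE, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  m["G", "C"] <- m["C", "G"] <- TRUE
  m["A", "U"] <- m["U", "A"] <- TRUE
  if (rule$allow_wobble) m["G", "U"] <- m["U", "G"] <- TRUE
  m
}

# per-ordered-pair score matrix (0 where unpaired)
score_matrix <- function(rule = base_pair_rule()) {
  s <- matrix(0, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  s["G", "C"] <- s["C", "G"] <- rule$pair_scores[["G:C"]]
  s["A", "U"] <- s["U", "A"] <- rule$pair_scores[["A:U"]]
  if (rule$allow_wobble) s["G", "U"] <- s["U", "G"] <- rule$pair_scores[["G:U"]]
  s
}

#' Reverse complement of an RNA sequence
#'
#' @param seq RNA string over A, C, G, U.
#' @return The reverse complement RNA string.
#' @export
rna_reverse_complement <- function(seq) {
  b <- check_rna_alphabet(seq)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(unname(comp[b])), collapse = "")
}
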