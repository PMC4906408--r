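#' Construct a guide RNA
#'
#' A guide RNA (sgRNA) spacer is the 20-nt target-specific 5' portion of the
#' guide; position 1 is the 5' (PAM-distal) end and position 20 is adjacent to
#' the PAM. DNA input (containing T) is transliterated to U and the
#' transliteration recorded in the `from_dna` field, since users often paste
#' genomic target sequences.
#'
#' @param spacer A 20-nt sequence over A/C/G/U (or A/C/G/T, transliterated).
#' @param id Guide label; defaults to the spacer itself.
#' @param gg_applied Has the T7 5'-GG substitution been applied? When `TRUE`,
#'   positions 1 and 2 must be G.
#' @return A list of class `guide_rna` with fields `id`, `spacer`,
#'   `gg_applied`, `from_dna`.
#' @seealso [apply_gg_substitution()], [read_guide_list()]
#' @export
guide_rna <- function(spacer, id = spacer, gg_applied = FALSE) {
  if (!is.character(spacer) || length(spacer) != 1) {
    abort("`spacer` must be a single string.")
  }
  spacer <- toupper(str_trim(spacer))
  from_dna <- grepl("T", spacer, fixed = TRUE)
  if (from_dna) spacer <- gsub("T", "U", spacer, fixed = TRUE)
  if (nchar(spacer) != 20) {
    abort(sprintf("Spacer must be exactly 20 nt, got %d.", nchar(spacer)))
  }
  check_rna_alphabet(spacer, "spacer")
  if (isTRUE(gg_applied) && substr(spacer, 1, 2) != "GG") {
    abort("`gg_applied = TRUE` but positions 1-2 are not GG.")
  }
  structure(
    list(id = as.character(id), spacer = spacer,
         gg_applied = isTRUE(gg_applied), from_dna = from_dna),
    class = "guide_rna"
  )
}

#' @export
print.guide_rna <- function(x, ...) {
  cat(sprintf("<guide_rna> %s  %s%s%s\n", x$id, x$spacer,
              if (x$gg_applied) "  [5'GG]" else "",
              if (x$from_dna) "  [T->U]" else ""))
  invisible(x)
}

as_guide_rna <- function(x) {
  if (inherits(x, "guide_rna")) x else guide_rna(x)
}

#' Apply the T7 5'-GG substitution to a guide
#'
#' In vitro transcription from a T7 promoter requires the transcript to begin
#' with guanines, so the first two spacer positions are substituted with G
#' before synthesis. Screening should be run on the sequence that will
#' actually be transcribed, hence this operation. Idempotent.
#'
#' @param g A [guide_rna()] or a 20-nt spacer string.
#' @return The guide with positions 1-2 set to G and `gg_applied = TRUE`.
#' @export
apply_gg_substitution <- function(g) {
  g <- as_guide_rna(g)
  spacer <- paste0("GG", substr(g$spacer, 3, 20))
  guide_rna(spacer, id = g$id, gg_applied = TRUE)
}

#' Read a guide list file into a tibble
#'
#' Reads a plain-text guide list: one 20-nt spacer per line, or a two-column
#' TSV of `id<TAB>spacer`. Blank lines are skipped; input order is preserved.
#' Lines whose spacer is not 20 nt or contains a non-A/C/G/U/T character are
#' reported per line (with the line number) and dropped; reading fails only
#' when no valid line remains. T is transliterated to U with a notice.
#'
#' @param path Path to the guide list file.
#' @param quiet Suppress per-line warnings and transliteration notices.
#' @return A tibble with columns `id`, `spacer`, `line` (source line number)
#'   and `from_dna`. When a file has no id column the line number is used as
#'   the id.
#' @export
read_guide_list <- function(path, quiet = FALSE) {
  if (!file.exists(path)) abort(sprintf("Guide list file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(str_trim(lines) != "")
  if (length(keep) == 0) abort(sprintf("No guide lines in %s.", path))

  rows <- list()
  errors <- character()
  n_dna <- 0L
  for (ln in keep) {
    fields <- strsplit(str_trim(lines[ln]), "\t", fixed = TRUE)[[1]]
    if (length(fields) >= 2) {
      id <- fields[1]; spacer <- fields[2]
    } else {
      id <- as.character(ln); spacer <- fields[1]
    }
    g <- tryCatch(guide_rna(spacer, id = id), error = function(e) e)
    if (inherits(g, "error")) {
      errors <- c(errors, sprintf("line %d: %s", ln, conditionMessage(g)))
      next
    }
    if (g$from_dna) n_dna <- n_dna + 1L
    rows[[length(rows) + 1]] <- tibble(
      id = g$id, spacer = g$spacer, line = ln, from_dna = g$from_dna
    )
  }
  if (length(errors) > 0 && !quiet) {
    warn(paste(c("Skipped invalid guide line(s):", errors), collapse = "\n"))
  }
  if (length(rows) == 0) {
    abort(sprintf("No valid guide lines in %s:\n%s", path,
                  paste(errors, collapse = "\n")))
  }
  if (n_dna > 0 && !quiet) {
    inform(sprintf("Transliterated T to U in %d guide(s) (DNA input).", n_dna))
  }
  bind_rows(rows)
}

#' Write a guide list file
#'
#' Inverse of [read_guide_list()]: writes one spacer per line, or
#' `id<TAB>spacer` when `with_ids = TRUE`.
#'
#' @param guides A tibble with columns `id` and `spacer`, or a character
#'   vector of spacers.
#' @param path Output path.
#' @param with_ids Write the two-column TSV dialect.
#' @return `path`, invisibly.
#' @export
write_guide_list <- function(guides, path, with_ids = FALSE) {
  if (is.character(guides)) guides <- tibble(id = guides, spacer = guides)
  lines <- if (with_ids) paste(guides$id, guides$spacer, sep = "\t") else guides$spacer
  writeLines(lines, path)
  invisible(path)
}
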