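#' Construct an sgRNA scaffold (constant region / backbone)
#'
#' The scaffold is the invariant 3' portion of the sgRNA that binds Cas9. It
#' contains several internally paired stem regions (repeat:anti-repeat duplex
#' and stem loops); annotating them lets backbone-duplex hits report which
#' structural region a spacer interaction falls in.
#'
#' Stem-region intervals are 1-based inclusive on the scaffold sequence and
#' must not overlap.
#'
#' @param sequence RNA string (A/C/G/U; T transliterated to U).
#' @param name Scaffold label, e.g. `"standard"` or `"extended"`.
#' @param stem_regions Optional tibble/data frame with columns `label`,
#'   `start`, `end`.
#' @return An object of class `scaffold`.
#' @seealso [read_scaffold()], [builtin_scaffold()]
#' @export
scaffold <- function(sequence, name = "scaffold", stem_regions = NULL) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    abort("`sequence` must be a single non-empty string.")
  }
  sequence <- gsub("T", "U", toupper(str_trim(sequence)), fixed = TRUE)
  check_rna_alphabet(sequence, "scaffold sequence")
  n <- nchar(sequence)
  if (is.null(stem_regions)) {
    stem_regions <- tibble(label = character(), start = integer(), end = integer())
  } else {
    stem_regions <- as_tibble(stem_regions)
    if (!all(c("label", "start", "end") %in% names(stem_regions))) {
      abort("`stem_regions` needs columns label, start, end.")
    }
    stem_regions <- stem_regions |>
      mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
      arrange(.data$start)
    if (any(stem_regions$start < 1 | stem_regions$end > n |
            stem_regions$start > stem_regions$end)) {
      abort("Stem regions must lie within [1, scaffold length].")
    }
    if (nrow(stem_regions) > 1 &&
        any(stem_regions$start[-1] <= stem_regions$end[-nrow(stem_regions)])) {
      abort("Stem regions must not overlap.")
    }
  }
  structure(
    list(name = as.character(name), sequence = sequence,
         stem_regions = stem_regions),
    class = "scaffold"
  )
}

#' @export
print.scaffold <- function(x, ...) {
  cat(sprintf("<scaffold> %s (%d nt, %d annotated stem region(s))\n",
              x$name, nchar(x$sequence), nrow(x$stem_regions)))
  cat(" ", x$sequence, "\n")
  invisible(x)
}

#' Read a scaffold from plain-text config files
#'
#' The sequence file holds the scaffold sequence (one line; lines starting
#' with `#` or `>` are ignored). An optional sidecar TSV with columns
#' `label`, `start`, `end` annotates stem regions. By convention the sidecar
#' lives next to the sequence file as `<file>.regions.tsv` and is picked up
#' automatically.
#'
#' @param path Path to the sequence file.
#' @param regions_path Path to the stem-region TSV; `NULL` looks for the
#'   conventional sidecar, `NA` skips region annotation.
#' @param name Scaffold name; defaults to the file name.
#' @return A [scaffold()].
#' @export
read_scaffold <- function(path, regions_path = NULL, name = NULL) {
  if (!file.exists(path)) abort(sprintf("Scaffold file not found: %s", path))
  lines <- str_trim(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !grepl("^[#>]", lines)]
  if (length(lines) == 0) abort(sprintf("No sequence in scaffold file %s.", path))
  sequence <- paste(lines, collapse = "")
  if (is.null(regions_path)) {
    cand <- paste0(sub("\\.txt$", "", path), ".regions.tsv")
    regions_path <- if (file.exists(cand)) cand else NA
  }
  regions <- if (!is.na(regions_path)) {
    readr::read_tsv(regions_path, show_col_types = FALSE)
  } else NULL
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  scaffold(sequence, name = name, stem_regions = regions)
}

#' Built-in synthetic scaffolds
#'
#' Ships two example scaffolds, `"standard"` and `"extended"` (the extended
#' one carries a lengthened repeat:anti-repeat duplex). Both are SYNTHETIC
#' stand-ins with the architecture of a real sgRNA constant region — four
#' annotated internal stems, of which `stem_loop_2` is the most weakly
#' paired — not any published scaffold sequence. Supply your own scaffold
#' via [read_scaffold()] for real screening.
#'
#' @param name `"standard"` or `"extended"`.
#' @return A [scaffold()].
#' @export
builtin_scaffold <- function(name = c("standard", "extended")) {
  name <- match.arg(name)
  path <- system.file(
    "extdata", sprintf("scaffold_%s_synthetic.txt", name),
    package = "guideqc", mustWork = TRUE
  )
  read_scaffold(path, name = name)
}
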