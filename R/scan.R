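#' Build a substitution-counting PSSM from a consensus sequence
#'
#' The matrix scores 0 for the consensus base and 1 for any other base at
#' each position, so the score of a window is its Hamming distance to the
#' consensus and the genome scan literally minimizes the number of
#' substitutions relative to the query.
#'
#' @param seq DNA consensus (A/C/G/T), at least 4 nt.
#' @return An object of class `pssm` with fields `width`, `scores`
#'   (4 x width matrix, rows A/C/G/T), `mode = "mismatch_count"`,
#'   `consensus`.
#' @export
pssm_from_consensus <- function(seq) {
  seq <- toupper(str_trim(seq))
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!b %in% DNA_BASES)
  if (length(bad) > 0) {
    abort(sprintf("Invalid consensus: non-A/C/G/T base at position(s) %s.",
                  paste(bad, collapse = ", ")))
  }
  if (length(b) < 4) abort("PSSM width must be at least 4.")
  scores <- matrix(1, 4, length(b), dimnames = list(DNA_BASES, NULL))
  scores[cbind(match(b, DNA_BASES), seq_along(b))] <- 0
  structure(
    list(width = length(b), scores = scores, mode = "mismatch_count",
         consensus = seq),
    class = "pssm"
  )
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> width %d, mode %s%s\n", x$width, x$mode,
              if (!is.null(x$consensus)) paste0(", consensus ", x$consensus) else ""))
  invisible(x)
}

#' Score a single site against a PSSM
#'
#' @param site DNA string of length `pssm$width`.
#' @param pssm A `pssm` object.
#' @return Numeric score (substitution count in mismatch mode; lower is a
#'   better match).
#' @export
score_site <- function(site, pssm) {
  b <- strsplit(toupper(site), "", fixed = TRUE)[[1]]
  if (length(b) != pssm$width) {
    abort(sprintf("Site length %d != PSSM width %d.", length(b), pssm$width))
  }
  idx <- match(b, DNA_BASES)
  if (anyNA(idx)) abort("Site contains a non-A/C/G/T base.")
  sum(pssm$scores[cbind(idx, seq_len(pssm$width))])
}

#' Read a JASPAR-like position frequency matrix
#'
#' Accepts the JASPAR text dialect (`A [ 1 2 3 ]` rows, optional `>` header)
#' or a bare whitespace-separated numeric matrix. Orientation (4 rows of
#' base counts vs. 4 columns) is auto-detected from the shape; an ambiguous
#' 4 x 4 matrix is taken as rows = bases. Counts are converted to a weighted
#' scoring matrix by per-position pseudocount addition, normalisation to
#' frequencies and a negative-log transform, so lower scores again mean
#' better matches and the ranking convention matches mismatch-count mode.
#'
#' @param path Path to the matrix file.
#' @param pseudocount Added to every count (default 0.25 per base).
#' @return A `pssm` with `mode = "weighted"`; the raw counts are kept in
#'   `$counts` for round-tripping via [write_pfm()].
#' @export
read_pfm <- function(path, pseudocount = 0.25) {
  if (!file.exists(path)) abort(sprintf("PFM file not found: %s", path))
  lines <- str_trim(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !grepl("^>", lines)]
  if (length(lines) == 0) abort(sprintf("No matrix rows in %s.", path))

  row_bases <- character()
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    base <- NA_character_
    if (grepl("^[ACGTacgt]\\b", ln)) {
      base <- toupper(substr(ln, 1, 1))
      ln <- substr(ln, 2, nchar(ln))
    }
    ln <- gsub("[][]", " ", ln)
    vals <- suppressWarnings(as.numeric(strsplit(str_trim(ln), "\\s+")[[1]]))
    if (anyNA(vals) || length(vals) == 0) {
      abort(sprintf("Malformed matrix row at line %d of %s.", i, path))
    }
    row_bases <- c(row_bases, base)
    rows[[i]] <- vals
  }
  widths <- lengths(rows)
  if (length(unique(widths)) != 1) {
    abort(sprintf("Ragged matrix in %s: row widths %s.", path,
                  paste(widths, collapse = ", ")))
  }
  m <- do.call(rbind, rows)
  if (nrow(m) != 4 && ncol(m) == 4) {
    m <- t(m)
    row_bases <- rep(NA_character_, 4)
  }
  if (nrow(m) != 4) {
    abort(sprintf("Matrix in %s must have 4 base rows (or columns), got %d x %d.",
                  path, nrow(m), ncol(m)))
  }
  if (!anyNA(row_bases) && setequal(row_bases, DNA_BASES)) {
    m <- m[match(DNA_BASES, row_bases), , drop = FALSE]
  }
  rownames(m) <- DNA_BASES
  if (ncol(m) < 4) abort("PSSM width must be at least 4.")
  if (any(m < 0)) abort(sprintf("Negative counts in %s.", path))

  counts <- m + pseudocount
  freqs <- sweep(counts, 2, colSums(counts), "/")
  structure(
    list(width = ncol(m), scores = -log(freqs), mode = "weighted",
         consensus = paste(DNA_BASES[apply(m, 2, which.max)], collapse = ""),
         counts = m, pseudocount = pseudocount),
    class = "pssm"
  )
}

#' Write a PSSM's count matrix in JASPAR text format
#'
#' @param pssm A `pssm` from [read_pfm()] (must carry `$counts`).
#' @param path Output path.
#' @param name Header name after `>`.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pssm, path, name = "pssm") {
  if (is.null(pssm$counts)) abort("This PSSM has no count matrix to write.")
  lines <- c(
    paste0(">", name),
    map_chr(DNA_BASES, function(b) {
      paste0(b, " [ ", paste(format(pssm$counts[b, ], trim = TRUE),
                             collapse = " "), " ]")
    })
  )
  writeLines(lines, path)
  invisible(path)
}

comp_dna <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#' @param seq DNA string over A/C/G/T/N.
#' @return Reverse complement string.
#' @export
dna_reverse_complement <- function(seq) {
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (any(!b %in% names(comp_dna))) abort("Non-A/C/G/T/N base in DNA sequence.")
  paste(rev(unname(comp_dna[b])), collapse = "")
}

# coerce FASTA path / DNAStringSet / named character vector to named
# uppercase character vector
as_dna_set <- function(seqs) {
  if (is.character(seqs) && length(seqs) == 1 && file.exists(seqs)) {
    seqs <- Biostrings::readDNAStringSet(seqs)
  }
  if (inherits(seqs, "DNAStringSet")) {
    seqs <- setNames(as.character(seqs), names(seqs))
  }
  if (!is.character(seqs)) abort("`seqs` must be a FASTA path, DNAStringSet or character vector.")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  toupper(seqs)
}

# score all + strand windows of one sequence; NA where window has N
window_scores <- function(codes, scores) {
  w <- ncol(scores)
  n <- length(codes)
  if (n < w) return(numeric(0))
  total <- numeric(n - w + 1)
  for (k in seq_len(w)) {
    v <- scores[, k][codes[k:(n - w + k)]]
    total <- total + v
  }
  unname(total)
}

#' Scan sequences for best PSSM matches
#'
#' Scores every window of width `pssm$width` on the requested strand(s) of
#' each sequence and returns the `top_k` lowest-scoring (fewest
#' substitutions / best weighted match) hits in deterministic order: score
#' ascending, ties broken by sequence id, then start, then strand (`+`
#' before `-`). Windows containing N are skipped; sequences shorter than
#' the matrix width are skipped with a notice.
#'
#' @param seqs FASTA file path, `Biostrings::DNAStringSet`, or named
#'   character vector of DNA sequences.
#' @param pssm A `pssm` object.
#' @param top_k Number of hits to return (default 10).
#' @param both_strands Also scan the reverse strand (default `TRUE`).
#' @param max_score Optional ceiling: drop hits scoring above it (e.g. a
#'   maximum substitution count).
#' @return A tibble of hits: `seq_id`, `start`, `end` (1-based inclusive on
#'   the forward strand), `strand`, `site` (the matching strand's
#'   sequence), `score`, `rank`.
#' @export
scan_pssm <- function(seqs, pssm, top_k = 10, both_strands = TRUE,
                      max_score = Inf) {
  seqs <- as_dna_set(seqs)
  w <- pssm$width
  # reverse-strand hits = forward windows scored with the reverse-complement
  # matrix (rows swapped A<->T, C<->G; columns reversed)
  rc_scores <- pssm$scores[match(unname(comp_dna[DNA_BASES]), DNA_BASES),
                           rev(seq_len(w)), drop = FALSE]
  rownames(rc_scores) <- DNA_BASES

  out <- list()
  for (sid in names(seqs)) {
    s <- seqs[[sid]]
    if (nchar(s) < w) {
      inform(sprintf("Skipping %s: shorter (%d nt) than matrix width %d.",
                     sid, nchar(s), w))
      next
    }
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    if (any(!b %in% names(comp_dna))) {
      abort(sprintf("Sequence %s contains a base outside A/C/G/T/N.", sid))
    }
    codes <- match(b, DNA_BASES) # N -> NA, poisons its windows
    fwd <- window_scores(codes, pssm$scores)
    starts <- seq_along(fwd)
    ok <- !is.na(fwd)
    if (any(ok)) {
      out[[length(out) + 1]] <- tibble(
        seq_id = sid, start = starts[ok], end = starts[ok] + w - 1L,
        strand = "+",
        site = substring(s, starts[ok], starts[ok] + w - 1L),
        score = fwd[ok]
      )
    }
    if (both_strands) {
      rev_sc <- window_scores(codes, rc_scores)
      ok <- !is.na(rev_sc)
      if (any(ok)) {
        out[[length(out) + 1]] <- tibble(
          seq_id = sid, start = starts[ok], end = starts[ok] + w - 1L,
          strand = "-",
          site = map_chr(substring(s, starts[ok], starts[ok] + w - 1L),
                         dna_reverse_complement),
          score = rev_sc[ok]
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  strand = character(), site = character(), score = double(),
                  rank = integer()))
  }
  bind_rows(out) |>
    filter(.data$score <= max_score) |>
    arrange(.data$score, .data$seq_id, .data$start, .data$strand) |>
    head(n = top_k) |>
    mutate(rank = row_number())
}

#' Convert scan hits to BED intervals
#'
#' @param hits Tibble from [scan_pssm()] (1-based inclusive coordinates).
#' @param path Optional path to write a BED6 file.
#' @return Tibble in BED convention (0-based half-open): `chrom`,
#'   `chromStart`, `chromEnd`, `name`, `score`, `strand`.
#' @export
hits_to_bed <- function(hits, path = NULL) {
  bed <- tibble(
    chrom = hits$seq_id,
    chromStart = hits$start - 1L,
    chromEnd = hits$end,
    name = paste0("hit", hits$rank),
    score = hits$score,
    strand = hits$strand
  )
  if (!is.null(path)) {
    readr::write_tsv(bed, path, col_names = FALSE)
  }
  bed
}
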