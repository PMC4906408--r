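#' Screen configuration
#'
#' Thresholds controlling when a predicted duplex flags a guide.
#'
#' A stem is reported by the duplex finders when it reaches `min_stem`
#' canonical-equivalent pairs; a stem that contains at least one G:U wobble
#' pair must reach `min_stem + wobble_extra` pairs to flag a guide, since
#' wobble-containing hairpins are tolerated until hardened to G:C.
#'
#' @param min_stem Minimum stem length in pairs (default 4).
#' @param min_loop Minimum hairpin loop, in nt, for intra-spacer stems
#'   (default 3).
#' @param allow_wobble Count G:U wobble pairs as paired (default `TRUE`).
#' @param wobble_extra Extra stem length demanded of wobble-containing stems
#'   before they flag (default 1).
#' @param min_stability Minimum stem stability score for a hit to flag
#'   (default 0, i.e. stem length alone decides).
#' @param pair_scores Passed to [base_pair_rule()].
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(min_stem = 4, min_loop = 3, allow_wobble = TRUE,
                          wobble_extra = 1, min_stability = 0,
                          pair_scores = c("G:C" = 3, "A:U" = 2, "G:U" = 1)) {
  if (min_stem < 2) abort("`min_stem` must be at least 2.")
  if (min_loop < 0) abort("`min_loop` must be non-negative.")
  structure(
    list(min_stem = as.integer(min_stem), min_loop = as.integer(min_loop),
         wobble_extra = as.integer(wobble_extra),
         min_stability = min_stability,
         rule = base_pair_rule(allow_wobble, pair_scores)),
    class = "screen_config"
  )
}

empty_hits <- function() {
  tibble(
    kind = character(), spacer_start = integer(), spacer_end = integer(),
    partner_start = integer(), partner_end = integer(),
    stem_len = integer(), loop_len = integer(), pairs = character(),
    n_wobble = integer(), stability = double(), scaffold_region = character()
  )
}

sort_hits <- function(hits) {
  hits |>
    arrange(desc(.data$stability), .data$spacer_start, .data$partner_start) |>
    mutate()
}

#' Find intra-spacer hairpin stems
#'
#' Enumerates every maximal antiparallel self-complementary stem within a
#' 20-nt spacer: positions `spacer_start..spacer_end` pairing with
#' `partner_start..partner_end` (also on the spacer, 3' arm), separated by a
#' loop of at least `min_loop` nt. Maximal means the stem cannot be extended
#' by one more valid pair outward or inward (inward extension must keep the
#' loop legal); sub-stems of a maximal stem are not reported. Hits are sorted
#' by stability (descending), then by 5' position.
#'
#' @param g A [guide_rna()] or spacer string.
#' @param rule A [base_pair_rule()].
#' @param min_stem Minimum stem length in pairs (>= 2).
#' @param min_loop Minimum loop length in nt.
#' @return A tibble of duplex hits with `kind = "intra_spacer"`; pairs are
#'   recorded 5'-arm outermost first as a `|`-separated string.
#' @export
find_intra_spacer_duplexes <- function(g, rule = base_pair_rule(),
                                       min_stem = 4, min_loop = 3) {
  if (min_stem < 2) abort("`min_stem` must be at least 2.")
  g <- as_guide_rna(g)
  b <- rna_chars(g$spacer)
  n <- length(b)
  idx <- match(b, RNA_BASES)
  P <- pairing_matrix(rule)

  rows <- list()
  if (n < min_loop + 2) return(empty_hits())
  for (i in seq_len(n - min_loop - 1)) {
    for (j in n:(i + min_loop + 1)) {
      if (!P[idx[i], idx[j]]) next
      # outer pair (i, j) must not be outward-extendable
      if (i > 1 && j < n && P[idx[i - 1], idx[j + 1]]) next
      # grow inward while pairable and loop stays legal
      len <- 1L
      while (i + len < j - len &&
             (j - len) - (i + len) - 1 >= min_loop &&
             P[idx[i + len], idx[j - len]]) {
        len <- len + 1L
      }
      if (len < min_stem) next
      k <- 0:(len - 1)
      cls <- map_chr(k, function(d) pair_class(b[i + d], b[j - d], rule))
      rows[[length(rows) + 1]] <- tibble(
        kind = "intra_spacer",
        spacer_start = i, spacer_end = i + len - 1L,
        partner_start = j - len + 1L, partner_end = j,
        stem_len = len,
        loop_len = (j - len + 1L) - (i + len - 1L) - 1L,
        pairs = paste(cls, collapse = "|"),
        n_wobble = sum(cls == "G:U"),
        stability = stem_stability(cls, rule),
        scaffold_region = NA_character_
      )
    }
  }
  if (length(rows) == 0) return(empty_hits())
  sort_hits(bind_rows(rows))
}

#' Find spacer-backbone duplexes
#'
#' Enumerates every maximal antiparallel duplex between a spacer substring
#' and a scaffold (backbone) substring of at least `min_stem` pairs. The 5'
#' end of the spacer arm pairs the 3' end of the scaffold arm. Each hit is
#' annotated with the annotated scaffold stem region(s) its scaffold arm
#' overlaps, if any. Ordering and maximality conventions match
#' [find_intra_spacer_duplexes()].
#'
#' @param g A [guide_rna()] or spacer string.
#' @param s A [scaffold()].
#' @param rule A [base_pair_rule()].
#' @param min_stem Minimum duplex length in pairs.
#' @return A tibble of duplex hits with `kind = "spacer_backbone"`;
#'   `partner_*` coordinates are on the scaffold, `loop_len` is `NA`.
#' @export
find_spacer_backbone_duplexes <- function(g, s, rule = base_pair_rule(),
                                          min_stem = 4) {
  if (!inherits(s, "scaffold")) abort("`s` must be a scaffold object.")
  g <- as_guide_rna(g)
  sb <- rna_chars(g$spacer)
  cb <- rna_chars(s$sequence)
  n <- length(sb); m <- length(cb)
  si <- match(sb, RNA_BASES); ci <- match(cb, RNA_BASES)
  P <- pairing_matrix(rule)

  rows <- list()
  for (i in seq_len(n)) {
    for (jend in seq_len(m)) {
      if (!P[si[i], ci[jend]]) next
      # outward extension: spacer i-1 with scaffold jend+1
      if (i > 1 && jend < m && P[si[i - 1], ci[jend + 1]]) next
      len <- 1L
      while (i + len <= n && jend - len >= 1 &&
             P[si[i + len], ci[jend - len]]) {
        len <- len + 1L
      }
      if (len < min_stem) next
      k <- 0:(len - 1)
      cls <- map_chr(k, function(d) pair_class(sb[i + d], cb[jend - d], rule))
      p_start <- jend - len + 1L
      ov <- s$stem_regions |>
        filter(.data$start <= jend, .data$end >= p_start)
      rows[[length(rows) + 1]] <- tibble(
        kind = "spacer_backbone",
        spacer_start = i, spacer_end = i + len - 1L,
        partner_start = p_start, partner_end = jend,
        stem_len = len, loop_len = NA_integer_,
        pairs = paste(cls, collapse = "|"),
        n_wobble = sum(cls == "G:U"),
        stability = stem_stability(cls, rule),
        scaffold_region = if (nrow(ov)) paste(ov$label, collapse = ",") else NA_character_
      )
    }
  }
  if (length(rows) == 0) return(empty_hits())
  sort_hits(bind_rows(rows))
}

# which reported hits meet the flagging thresholds
passing_hits <- function(hits, config) {
  need <- config$min_stem + ifelse(hits$n_wobble > 0, config$wobble_extra, 0L)
  hits[hits$stem_len >= need & hits$stability >= config$min_stability, ,
       drop = FALSE]
}

#' Classify a single guide for internal interactions
#'
#' Runs the intra-spacer and (when a scaffold is supplied) spacer-backbone
#' duplex searches and flags the guide when any hit meets the flagging
#' thresholds of the [screen_config()]. The verdict is a pure function of
#' the spacer (after optional 5'-GG substitution), the scaffold and the
#' configuration.
#'
#' @param g A [guide_rna()] or spacer string.
#' @param s A [scaffold()], or `NULL` to skip backbone screening.
#' @param config A [screen_config()].
#' @param gg Apply [apply_gg_substitution()] before screening.
#' @return A list of class `screen_verdict`: `guide`, `flags` (subset of
#'   `internal_hairpin`, `backbone_interaction`), `hits` (tibble of hits
#'   meeting thresholds), `clean`.
#' @export
classify_guide <- function(g, s = NULL, config = screen_config(), gg = FALSE) {
  g <- as_guide_rna(g)
  if (gg) g <- apply_gg_substitution(g)
  intra <- passing_hits(
    find_intra_spacer_duplexes(g, config$rule, config$min_stem, config$min_loop),
    config
  )
  backbone <- if (!is.null(s)) {
    passing_hits(
      find_spacer_backbone_duplexes(g, s, config$rule, config$min_stem),
      config
    )
  } else empty_hits()
  flags <- c(
    if (nrow(intra) > 0) "internal_hairpin",
    if (nrow(backbone) > 0) "backbone_interaction"
  )
  structure(
    list(guide = g, flags = flags %||% character(),
         hits = sort_hits(bind_rows(intra, backbone)),
         clean = length(flags) == 0),
    class = "screen_verdict"
  )
}

#' @export
print.screen_verdict <- function(x, ...) {
  cat(sprintf("<screen_verdict> %s  %s  %s\n", x$guide$id, x$guide$spacer,
              if (x$clean) "clean" else paste(x$flags, collapse = "+")))
  if (nrow(x$hits)) print(x$hits)
  invisible(x)
}

#' Screen a table of guides for internal interactions
#'
#' Data-frame-first wrapper over [classify_guide()]: takes a tibble of
#' guides (as returned by [read_guide_list()]), screens each one, and
#' returns one row per guide in input order with flag columns and the
#' per-guide hits nested in a list-column.
#'
#' @param guides Tibble with columns `id` and `spacer` (a character vector
#'   of spacers also works).
#' @param scaffold A [scaffold()] or `NULL` (intra-spacer screening only).
#' @param gg Apply the 5'-GG substitution before screening.
#' @param config A [screen_config()].
#' @return A tibble of class `guide_screen` with columns `id`, `spacer`
#'   (post-substitution), `gg_applied`, `internal_hairpin`,
#'   `backbone_interaction`, `clean`, `n_hits`, `hits` (list of tibbles).
#' @examples
#' screen_guides(c("GGGGAAAUUCCCCAAAAAAA", "GACUGCAUCGUACGAACAAU"))
#' @export
screen_guides <- function(guides, scaffold = NULL, gg = FALSE,
                          config = screen_config()) {
  if (is.character(guides)) {
    guides <- tibble(id = guides, spacer = guides)
  }
  guides <- as_tibble(guides)
  if (!all(c("id", "spacer") %in% names(guides))) {
    abort("`guides` needs columns id and spacer.")
  }
  verdicts <- pmap(list(guides$id, guides$spacer), function(id, spacer) {
    classify_guide(guide_rna(spacer, id = id), s = scaffold,
                   config = config, gg = gg)
  })
  out <- tibble(
    id = guides$id,
    spacer = map_chr(verdicts, ~ .x$guide$spacer),
    gg_applied = gg,
    internal_hairpin = map_lgl(verdicts, ~ "internal_hairpin" %in% .x$flags),
    backbone_interaction = map_lgl(verdicts, ~ "backbone_interaction" %in% .x$flags),
    clean = map_lgl(verdicts, ~ .x$clean),
    n_hits = map_int(verdicts, ~ nrow(.x$hits)),
    hits = map(verdicts, ~ .x$hits)
  )
  class(out) <- c("guide_screen", class(out))
  out
}

#' Serialize screen results
#'
#' `"list"` format mirrors the classic screening-script output: one line per
#' flagged guide (`id<TAB>spacer<TAB>flags`), clean guides omitted. `"tsv"`
#' emits one row per reported hit with full coordinates, pair string, wobble
#' count and stability. Output is deterministic for a given screen.
#'
#' @param screen A `guide_screen` tibble from [screen_guides()].
#' @param format `"list"` or `"tsv"`.
#' @param path Optional file to write to.
#' @return The report as a single string (invisibly when `path` is given).
#' @export
screen_report <- function(screen, format = c("list", "tsv"), path = NULL) {
  format <- match.arg(format)
  if (format == "list") {
    flagged <- screen[!screen$clean, , drop = FALSE]
    flags <- pmap(list(flagged$internal_hairpin, flagged$backbone_interaction),
                  function(h, b) paste(c(if (h) "internal_hairpin",
                                         if (b) "backbone_interaction"),
                                       collapse = "+"))
    text <- if (nrow(flagged) == 0) "" else {
      paste0(paste(flagged$id, flagged$spacer, unlist(flags, use.names = FALSE),
                   sep = "\t", collapse = "\n"), "\n")
    }
  } else {
    long <- screen |>
      select(all_of(c("id", "hits"))) |>
      tidyr::unnest("hits")
    text <- readr::format_tsv(long)
  }
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}
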