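# Deterministic generators for every input class. Each generator is a pure
# function of (parameters, seed), self-verifies its advertised ground truth
# with the package's search functions before returning, and errors rather
# than emitting a fixture that violates its label.

sample_bases <- function(n, alphabet = RNA_BASES, gc = NULL) {
  if (is.null(gc)) {
    sample(alphabet, n, replace = TRUE)
  } else {
    w <- ifelse(alphabet %in% c("G", "C"), gc / 2, (1 - gc) / 2)
    sample(alphabet, n, replace = TRUE, prob = w)
  }
}

#' Generate a spacer with one planted hairpin stem
#'
#' Builds a 20-nt spacer containing exactly one antiparallel stem of the
#' requested geometry (stem length, loop length, number of G:U wobble
#' pairs), with flanking sequence rejection-sampled so no secondary stem of
#' length >= `min_stem` arises and the planted stem is exactly maximal.
#' When a scaffold is supplied, candidates whose screening verdict would
#' also flag a backbone interaction are rejected, so the guide's verdict is
#' purely the planted hairpin.
#'
#' @param stem_len Pairs in the planted stem (>= 2).
#' @param loop_len Loop nucleotides between the arms (>= `min_loop`).
#' @param n_wobble How many planted pairs are G:U wobbles.
#' @param seed Integer seed; same arguments + seed give the identical spacer.
#' @param min_stem Secondary-structure exclusion threshold (default 4).
#' @param min_loop Minimum loop used for verification (default 3).
#' @param scaffold Optional [scaffold()] to keep the spacer backbone-clean
#'   against.
#' @param gc Optional GC fraction for flank/loop base composition.
#' @param max_tries Rejection-sampling budget.
#' @return A [guide_rna()] with attribute `"planted"` — a one-row tibble of
#'   the planted stem's coordinates.
#' @export
make_hairpin_spacer <- function(stem_len = 4, loop_len = 5, n_wobble = 0,
                                seed = 1, min_stem = 4, min_loop = 3,
                                scaffold = NULL, gc = NULL, max_tries = 5000) {
  if (stem_len < 2) abort("`stem_len` must be >= 2.")
  if (n_wobble > stem_len) abort("`n_wobble` cannot exceed `stem_len`.")
  if (loop_len < min_loop) abort("`loop_len` must be >= `min_loop`.")
  if (2 * stem_len + loop_len > 20) {
    abort("Infeasible geometry: 2*stem_len + loop_len exceeds 20 nt.")
  }
  rule <- base_pair_rule(allow_wobble = TRUE)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      flank_total <- 20 - 2 * stem_len - loop_len
      pre <- sample.int(flank_total + 1, 1) - 1L
      post <- flank_total - pre
      arm1 <- sample_bases(stem_len, gc = gc)
      comp <- c(A = "U", C = "G", G = "C", U = "A")
      arm2 <- rev(unname(comp[arm1]))
      if (n_wobble > 0) {
        wpos <- sample.int(stem_len, n_wobble)
        for (p in wpos) {
          if (runif(1) < 0.5) {
            arm1[p] <- "G"
          } else {
            arm1[p] <- "U"
          }
          arm2[stem_len - p + 1] <- if (arm1[p] == "G") "U" else "G"
        }
      }
      spacer <- paste(
        c(sample_bases(pre, gc = gc), arm1, sample_bases(loop_len, gc = gc),
          arm2, sample_bases(post, gc = gc)),
        collapse = ""
      )
      i <- pre + 1L
      j <- pre + 2L * stem_len + loop_len
      planted <- tibble(
        spacer_start = i, spacer_end = i + stem_len - 1L,
        partner_start = j - stem_len + 1L, partner_end = j,
        stem_len = stem_len, loop_len = loop_len, n_wobble = n_wobble
      )
      # the planted stem must be recovered exactly (so it is maximal with
      # the requested geometry) and be the only stem at the reporting
      # threshold; for sub-threshold plants nothing may reach min_stem
      hits <- find_intra_spacer_duplexes(spacer, rule,
                                         min_stem = min(stem_len, min_stem),
                                         min_loop = min_loop)
      is_planted <- hits$spacer_start == planted$spacer_start &
        hits$spacer_end == planted$spacer_end &
        hits$partner_start == planted$partner_start &
        hits$partner_end == planted$partner_end &
        hits$n_wobble == n_wobble
      found <- any(is_planted) &&
        sum(hits$stem_len >= min_stem) == as.integer(stem_len >= min_stem) &&
        (stem_len >= min_stem || nrow(hits) == 1)
      if (found && !is.null(scaffold)) {
        # verdict-level check: no backbone hit may reach the flagging
        # thresholds, so the guide's screen outcome is the planted hairpin
        v <- classify_guide(spacer, s = scaffold,
                            config = screen_config(min_stem = min_stem,
                                                   min_loop = min_loop))
        found <- !("backbone_interaction" %in% v$flags)
      }
      if (found) {
        g <- guide_rna(spacer, id = sprintf("hairpin_s%d", seed))
        attr(g, "planted") <- planted
        return(g)
      }
    }
    abort(sprintf("No valid hairpin spacer found in %d tries.", max_tries))
  })
}

#' Generate a spacer complementary to the scaffold
#'
#' Plants the reverse complement of a scaffold window into the spacer so
#' the guide carries a spacer-backbone duplex of the requested length while
#' its screening verdict stays free of the internal-hairpin flag.
#'
#' @param stem_len Pairs in the planted backbone duplex.
#' @param scaffold A [scaffold()] to interact with.
#' @param seed Integer seed.
#' @param min_stem Intra-spacer exclusion threshold (default 4).
#' @param min_loop Loop threshold used for intra-spacer verification.
#' @param max_tries Rejection-sampling budget.
#' @return A [guide_rna()] with attribute `"planted"` giving spacer and
#'   scaffold coordinates of the planted duplex.
#' @export
make_backbone_spacer <- function(stem_len = 6, scaffold = builtin_scaffold(),
                                 seed = 1, min_stem = 4, min_loop = 3,
                                 max_tries = 5000) {
  if (stem_len < 2) abort("`stem_len` must be >= 2.")
  if (stem_len > 20) abort("`stem_len` cannot exceed the 20-nt spacer.")
  m <- nchar(scaffold$sequence)
  if (stem_len > m) abort("`stem_len` exceeds the scaffold length.")
  rule <- base_pair_rule(allow_wobble = TRUE)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      j <- sample.int(m - stem_len + 1, 1)
      window <- substr(scaffold$sequence, j, j + stem_len - 1)
      arm <- rna_reverse_complement(window)
      pre <- sample.int(20 - stem_len + 1, 1) - 1L
      spacer <- paste0(
        paste(sample_bases(pre), collapse = ""), arm,
        paste(sample_bases(20 - stem_len - pre), collapse = "")
      )
      planted <- tibble(
        spacer_start = pre + 1L, spacer_end = pre + stem_len,
        partner_start = j, partner_end = j + stem_len - 1L,
        stem_len = stem_len
      )
      v <- classify_guide(spacer, s = scaffold,
                          config = screen_config(min_stem = min_stem,
                                                 min_loop = min_loop))
      if (!identical(v$flags, "backbone_interaction")) next
      bb <- find_spacer_backbone_duplexes(spacer, scaffold, rule,
                                          min_stem = stem_len)
      covered <- any(
        bb$spacer_start <= planted$spacer_start &
          bb$spacer_end >= planted$spacer_end &
          bb$partner_start <= planted$partner_start &
          bb$partner_end >= planted$partner_end
      )
      if (covered) {
        g <- guide_rna(spacer, id = sprintf("backbone_s%d", seed))
        attr(g, "planted") <- planted
        return(g)
      }
    }
    abort(sprintf("No valid backbone-interacting spacer found in %d tries.",
                  max_tries))
  })
}

#' Generate a structure-free spacer
#'
#' Searches for a 20-mer with no intra-spacer stem of >= `min_stem` pairs
#' (and, when a scaffold is given, no spacer-backbone duplex of >=
#' `min_stem` pairs) by iteratively mutating a base inside any offending
#' stem. The result is verified with [classify_guide()]; the function
#' errors rather than return a structured spacer.
#'
#' @param seed Integer seed.
#' @param scaffold Optional [scaffold()] to be clean against (short toy
#'   scaffolds recommended: against a full-length scaffold with wobble
#'   pairing almost every 20-mer forms some 4-pair duplex).
#' @param config A [screen_config()] defining cleanliness.
#' @param max_tries Mutation-search budget.
#' @return A clean [guide_rna()].
#' @export
make_clean_spacer <- function(seed = 1, scaffold = NULL,
                              config = screen_config(), max_tries = 2000) {
  with_seed(seed, {
    spacer <- paste(sample_bases(20), collapse = "")
    for (try in seq_len(max_tries)) {
      v <- classify_guide(spacer, s = scaffold, config = config)
      if (v$clean) {
        g <- guide_rna(spacer, id = sprintf("clean_s%d", seed))
        return(g)
      }
      # mutate one position inside the strongest offending stem
      hit <- v$hits[1, ]
      pos <- sample(hit$spacer_start:hit$spacer_end, 1)
      b <- rna_chars(spacer)
      b[pos] <- sample(setdiff(RNA_BASES, b[pos]), 1)
      spacer <- paste(b, collapse = "")
    }
    abort(sprintf("No clean spacer found in %d mutation steps.", max_tries))
  })
}

#' Simulate a single-turnover cleavage curve
#'
#' Draws fraction-cleaved measurements from the [hill_sigmoid()] model at a
#' dilution series, with optional Gaussian noise truncated to \[0, 1\].
#'
#' @param ec50 True half-maximal concentration, nM.
#' @param f_max True plateau (default 0.9; gels rarely reach complete
#'   cleavage).
#' @param hill Hill exponent (default 2).
#' @param concentrations Concentration series (default twofold dilutions
#'   from 600 to 37.5 nM, [serial_dilution()]).
#' @param noise_sd Gaussian noise standard deviation on the fraction scale
#'   (default 0).
#' @param replicates Number of replicates (default 2, matching the "at
#'   least two independent assays" convention).
#' @param seed Integer seed.
#' @param guide_id Label for the simulated guide.
#' @param refolded Metadata flag carried through (the generator does not
#'   model refolding).
#' @return A tibble: `guide_id`, `concentration_nM`, `replicate`,
#'   `fraction`, `refolded`.
#' @export
simulate_cleavage_curve <- function(ec50, f_max = 0.9, hill = 2,
                                    concentrations = serial_dilution(),
                                    noise_sd = 0, replicates = 2, seed = 1,
                                    guide_id = "sim", refolded = FALSE) {
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  with_seed(seed, {
    tidyr::expand_grid(
      replicate = seq_len(replicates),
      concentration_nM = concentrations
    ) |>
      mutate(
        guide_id = guide_id,
        fraction = pmin(1, pmax(0,
          hill_sigmoid(.data$concentration_nM, f_max, ec50, hill) +
            rnorm(n(), 0, noise_sd)
        )),
        refolded = refolded
      ) |>
      select(all_of(c("guide_id", "concentration_nM", "replicate",
                      "fraction", "refolded")))
  })
}

#' Generate a random genome with planted PSSM sites
#'
#' Builds a uniform-random DNA background and embeds the requested sites,
#' each after applying a chosen number of random substitutions (and
#' reverse-complementing for minus-strand plants). Site placements must not
#' overlap. The returned manifest records ground truth for scan tests.
#'
#' @param length Background length in bp.
#' @param sites A data frame (or list of lists) with columns/fields
#'   `sequence`, and optionally `substitutions` (default 0), `position`
#'   (1-based start; `NA` = random non-overlapping placement) and `strand`
#'   (`"+"`/`"-"`, default `"+"`).
#' @param seed Integer seed.
#' @param seq_id Name of the generated sequence.
#' @return A list with `sequences` (named character vector, FASTA-ready)
#'   and `manifest` (tibble: `seq_id`, `start`, `end`, `strand`,
#'   `sequence`, `planted_site`, `substitutions`).
#' @export
plant_genome <- function(length, sites, seed = 1, seq_id = "chr_sim") {
  if (is.data.frame(sites)) sites <- purrr::transpose(as.list(as_tibble(sites)))
  sites <- map(sites, function(s) {
    list(
      sequence = toupper(s$sequence),
      substitutions = s$substitutions %||% 0L,
      position = s$position %||% NA_integer_,
      strand = s$strand %||% "+"
    )
  })
  with_seed(seed, {
    bg <- sample_bases(length, alphabet = DNA_BASES)
    occupied <- rep(FALSE, length)
    manifest <- list()
    for (s in sites) {
      w <- nchar(s$sequence)
      if (w > length) abort("Planted site longer than the genome.")
      site <- strsplit(s$sequence, "", fixed = TRUE)[[1]]
      if (s$substitutions > 0) {
        pos <- sample.int(w, s$substitutions)
        for (p in pos) site[p] <- sample(setdiff(DNA_BASES, site[p]), 1)
      }
      planted <- paste(site, collapse = "")
      if (s$strand == "-") {
        site <- strsplit(dna_reverse_complement(planted), "", fixed = TRUE)[[1]]
      }
      start <- s$position
      if (is.na(start)) {
        for (k in seq_len(1000)) {
          cand <- sample.int(length - w + 1, 1)
          if (!any(occupied[cand:(cand + w - 1)])) { start <- cand; break }
        }
        if (is.na(start)) abort("Could not place site without overlap.")
      }
      if (start < 1 || start + w - 1 > length) {
        abort("Site placement outside the genome.")
      }
      if (any(occupied[start:(start + w - 1)])) {
        abort("Planted sites overlap.")
      }
      occupied[start:(start + w - 1)] <- TRUE
      bg[start:(start + w - 1)] <- site
      manifest[[length(manifest) + 1]] <- tibble(
        seq_id = seq_id, start = as.integer(start),
        end = as.integer(start + w - 1L), strand = s$strand,
        sequence = s$sequence, planted_site = planted,
        substitutions = as.integer(s$substitutions)
      )
    }
    list(
      sequences = setNames(paste(bg, collapse = ""), seq_id),
      manifest = bind_rows(manifest)
    )
  })
}
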