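# Independent brute-force oracles. These deliberately re-derive expected
# results from first principles (exhaustive enumeration, direct string
# arithmetic) and share no code with the package internals they check.

oracle_can_pair <- function(b1, b2, wobble = TRUE) {
  key <- paste0(b1, b2)
  key %in% c("GC", "CG", "AU", "UA") ||
    (wobble && key %in% c("GU", "UG"))
}

oracle_pair_score <- function(b1, b2,
                              scores = c("G:C" = 3, "A:U" = 2, "G:U" = 1),
                              wobble = TRUE) {
  key <- paste0(b1, b2)
  if (key %in% c("GC", "CG")) return(scores[["G:C"]])
  if (key %in% c("AU", "UA")) return(scores[["A:U"]])
  if (wobble && key %in% c("GU", "UG")) return(scores[["G:U"]])
  0
}

# exhaustively enumerate every maximal antiparallel intra-sequence stem by
# checking all (i, j, len) triples directly
oracle_intra_stems <- function(spacer, wobble = TRUE, min_stem = 4,
                               min_loop = 3) {
  b <- strsplit(spacer, "", fixed = TRUE)[[1]]
  n <- length(b)
  out <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (len in seq_len(n)) {
        i2 <- i + len - 1
        j1 <- j - len + 1
        if (i2 >= j1 || j > n) next
        if (j1 - i2 - 1 < min_loop) next
        ok <- TRUE
        for (k in 0:(len - 1)) {
          if (!oracle_can_pair(b[i + k], b[j - k], wobble)) { ok <- FALSE; break }
        }
        if (!ok) next
        # outward extension possible?
        if (i > 1 && j < n && oracle_can_pair(b[i - 1], b[j + 1], wobble)) next
        # inward extension possible (loop must stay legal)?
        if (i + len < j - len &&
            (j - len) - (i + len) - 1 >= min_loop &&
            oracle_can_pair(b[i + len], b[j - len], wobble)) next
        if (len < min_stem) next
        wob <- 0
        stab <- 0
        for (k in 0:(len - 1)) {
          key <- paste0(sort(c(b[i + k], b[j - k])), collapse = "")
          if (key == "GU") wob <- wob + 1
          stab <- stab + oracle_pair_score(b[i + k], b[j - k], wobble = wobble)
        }
        out[[length(out) + 1]] <- data.frame(
          spacer_start = i, spacer_end = i2, partner_start = j1,
          partner_end = j, stem_len = len, n_wobble = wob, stability = stab
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(spacer_start = integer(), spacer_end = integer(),
                      partner_start = integer(), partner_end = integer(),
                      stem_len = integer(), n_wobble = integer(),
                      stability = numeric()))
  }
  df <- do.call(rbind, out)
  df[order(-df$stability, df$spacer_start, df$partner_start), , drop = FALSE]
}

# exhaustively enumerate every maximal antiparallel spacer-vs-scaffold duplex
oracle_backbone_stems <- function(spacer, scaf, wobble = TRUE, min_stem = 4) {
  s <- strsplit(spacer, "", fixed = TRUE)[[1]]
  cc <- strsplit(scaf, "", fixed = TRUE)[[1]]
  n <- length(s); m <- length(cc)
  out <- list()
  for (i in seq_len(n)) {
    for (jend in seq_len(m)) {
      for (len in seq_len(min(n, m))) {
        if (i + len - 1 > n || jend - len + 1 < 1) next
        ok <- TRUE
        for (k in 0:(len - 1)) {
          if (!oracle_can_pair(s[i + k], cc[jend - k], wobble)) { ok <- FALSE; break }
        }
        if (!ok) next
        if (i > 1 && jend < m && oracle_can_pair(s[i - 1], cc[jend + 1], wobble)) next
        if (i + len <= n && jend - len >= 1 &&
            oracle_can_pair(s[i + len], cc[jend - len], wobble)) next
        if (len < min_stem) next
        out[[length(out) + 1]] <- data.frame(
          spacer_start = i, spacer_end = i + len - 1,
          partner_start = jend - len + 1, partner_end = jend, stem_len = len
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(spacer_start = integer(), spacer_end = integer(),
                      partner_start = integer(), partner_end = integer(),
                      stem_len = integer()))
  }
  do.call(rbind, out)
}

# enumerate ALL non-crossing, loop-legal structures of a short sequence and
# return the maximum total pair score (independent of the DP recursion: this
# one branches on the FIRST base of each interval)
oracle_fold_max <- function(seq, wobble = TRUE, min_loop = 3,
                            scores = c("G:C" = 3, "A:U" = 2, "G:U" = 1)) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  best_in <- function(i, j) {
    if (i >= j) return(0)
    # option 1: i unpaired
    best <- best_in(i + 1, j)
    # option 2: i paired with some k
    ks <- seq_len(j)
    for (k in ks[ks >= i + min_loop + 1]) {
      if (!oracle_can_pair(b[i], b[k], wobble)) next
      cand <- oracle_pair_score(b[i], b[k], scores, wobble) +
        best_in(i + 1, k - 1) + best_in(k + 1, j)
      if (cand > best) best <- cand
    }
    best
  }
  best_in(1, n)
}

# score every window of every sequence against a PSSM by direct per-base
# lookup; returns a data frame of all (seq_id, start, strand, score)
oracle_scan_all <- function(seqs, pssm_scores, both_strands = TRUE) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  w <- ncol(pssm_scores)
  rows <- list()
  score_window <- function(site) {
    bs <- strsplit(site, "", fixed = TRUE)[[1]]
    if (any(bs == "N")) return(NA_real_)
    sum(vapply(seq_len(w), function(k) pssm_scores[bs[k], k], numeric(1)))
  }
  for (sid in names(seqs)) {
    s <- seqs[[sid]]
    if (nchar(s) < w) next
    for (st in seq_len(nchar(s) - w + 1)) {
      site <- substr(s, st, st + w - 1)
      sc <- score_window(site)
      if (!is.na(sc)) {
        rows[[length(rows) + 1]] <- data.frame(
          seq_id = sid, start = st, strand = "+", score = sc
        )
      }
      if (both_strands) {
        rc <- paste(rev(unname(comp[strsplit(site, "", fixed = TRUE)[[1]]])),
                    collapse = "")
        sc <- score_window(rc)
        if (!is.na(sc)) {
          rows[[length(rows) + 1]] <- data.frame(
            seq_id = sid, start = st, strand = "-", score = sc
          )
        }
      }
    }
  }
  do.call(rbind, rows)
}

random_spacer <- function(n = 20) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

toy_scaffold <- function() {
  read_scaffold(system.file("extdata", "scaffold_toy_synthetic.txt",
                            package = "guideqc"))
}

# compare the package's intra-spacer hits with the oracle enumeration
expect_matches_oracle <- function(spacer, wobble = TRUE, min_stem = 4,
                                  min_loop = 3) {
  rule <- base_pair_rule(allow_wobble = wobble)
  got <- find_intra_spacer_duplexes(spacer, rule, min_stem, min_loop)
  want <- oracle_intra_stems(spacer, wobble, min_stem, min_loop)
  expect_equal(nrow(got), nrow(want), info = spacer)
  if (nrow(want) > 0) {
    cols <- c("spacer_start", "spacer_end", "partner_start", "partner_end",
              "stem_len", "n_wobble", "stability")
    expect_equal(as.data.frame(got[cols]), as.data.frame(want[cols]),
                 ignore_attr = TRUE, info = spacer)
  }
}
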