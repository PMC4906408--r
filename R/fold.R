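#' Maximum-pairing RNA fold (Nussinov dynamic programming)
#'
#' Computes a pseudoknot-free secondary structure maximizing the total pair
#' score under a [base_pair_rule()], with a minimum hairpin-loop size. This is
#' a transparent maximum-weight pairing score, not a nearest-neighbour
#' free-energy model: free-energy prediction only sometimes mirrors observed
#' guide activity, whereas the monotonicity properties that matter for
#' screening (more pairs never score less; G:C outranks G:U) hold exactly
#' here.
#'
#' The traceback is deterministic: within an interval, pairing the rightmost
#' base is preferred over leaving it unpaired on score ties, and its partner
#' is the leftmost (5'-most) base achieving the optimum — so pairing the
#' interval ends wins over bifurcation on ties.
#'
#' @param seq RNA string (A/C/G/U; T transliterated to U).
#' @param rule A [base_pair_rule()].
#' @param min_loop Minimum number of unpaired bases enclosed by a pair
#'   (default 3 nt, the steric minimum for a hairpin loop).
#' @return An object of class `fold_result`: list with `sequence`,
#'   `pair_list` (two-column matrix of 1-based i < j), `score`, and
#'   `dot_bracket`.
#' @examples
#' max_pair_fold("GGGAAACCC")
#' @export
max_pair_fold <- function(seq, rule = base_pair_rule(), min_loop = 3) {
  seq <- gsub("T", "U", toupper(seq), fixed = TRUE)
  b <- check_rna_alphabet(seq)
  n <- length(b)
  idx <- match(b, RNA_BASES)
  S <- score_matrix(rule)
  M <- matrix(0, n, n)

  if (n > min_loop + 1) {
    for (span in (min_loop + 1):(n - 1)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- M[i, j - 1]
        for (k in i:(j - min_loop - 1)) {
          s <- S[idx[k], idx[j]]
          if (s > 0) {
            left <- if (k > i) M[i, k - 1] else 0
            cand <- left + M[k + 1, j - 1] + s
            if (cand > best) best <- cand
          }
        }
        M[i, j] <- best
      }
    }
  }

  # iterative traceback with the documented tie-breaks
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    if (j - i < min_loop + 1) next
    target <- M[i, j]
    if (target == 0) next
    paired <- FALSE
    for (k in i:(j - min_loop - 1)) {
      s <- S[idx[k], idx[j]]
      if (s > 0) {
        left <- if (k > i) M[i, k - 1] else 0
        if (left + M[k + 1, j - 1] + s == target) {
          pairs <- rbind(pairs, c(k, j))
          if (k > i) stack[[length(stack) + 1]] <- c(i, k - 1L)
          stack[[length(stack) + 1]] <- c(k + 1L, j - 1L)
          paired <- TRUE
          break
        }
      }
    }
    if (!paired) stack[[length(stack) + 1]] <- c(i, j - 1L)
  }

  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  score <- if (nrow(pairs)) sum(S[cbind(idx[pairs[, 1]], idx[pairs[, 2]])]) else 0
  stopifnot(score == M[1, n])
  structure(
    list(sequence = seq, pair_list = pairs, score = score,
         dot_bracket = pairs_to_dot_bracket(pairs, n),
         min_loop = min_loop, rule = rule),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$dot_bracket, "\n", sep = "")
  cat(sprintf("score %g, %d pair(s)\n", x$score, nrow(x$pair_list)))
  invisible(x)
}

#' Convert a pair list to dot-bracket notation
#'
#' @param pairs Two-column matrix of 1-based (i, j) pairs, i < j, non-crossing.
#' @param n Sequence length.
#' @return A dot-bracket string of length `n`.
#' @export
pairs_to_dot_bracket <- function(pairs, n) {
  db <- rep(".", n)
  if (length(pairs)) {
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  paste(db, collapse = "")
}

#' Parse dot-bracket notation into a pair list
#'
#' @param db Dot-bracket string using `(`, `)` and `.`.
#' @return Two-column matrix of (i, j) pairs sorted by i.
#' @export
dot_bracket_to_pairs <- function(db) {
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  for (p in seq_along(chars)) {
    if (chars[p] == "(") {
      open <- c(open, p)
    } else if (chars[p] == ")") {
      if (length(open) == 0) abort("Unbalanced dot-bracket string.")
      pairs <- rbind(pairs, c(open[length(open)], p))
      open <- open[-length(open)]
    } else if (chars[p] != ".") {
      abort(sprintf("Unknown dot-bracket character \"%s\".", chars[p]))
    }
  }
  if (length(open) > 0) abort("Unbalanced dot-bracket string.")
  pairs[order(pairs[, 1]), , drop = FALSE]
}

#' Stability score of a duplex stem
#'
#' The stability of a stem is the sum of its per-pair scores under the rule
#' in force: adding a pair always increases it, and replacing a G:U wobble
#' with a G:C strictly increases it — the orderings that experimentally
#' distinguish hardened, extended and broken stems.
#'
#' @param pairs Character vector of pair classes (`"G:C"`, `"A:U"`, `"G:U"`),
#'   a `|`-separated string of them (as stored in duplex-hit tibbles), or a
#'   one-row duplex-hit tibble with a `pairs` column.
#' @param rule A [base_pair_rule()].
#' @return Numeric stability score.
#' @examples
#' stem_stability(c("G:C", "G:C", "G:C", "G:C")) # 12 under defaults
#' stem_stability("G:C|G:C|G:C|G:U")             # 10
#' @export
stem_stability <- function(pairs, rule = base_pair_rule()) {
  if (is.data.frame(pairs)) pairs <- pairs$pairs
  if (length(pairs) == 1 && grepl("|", pairs, fixed = TRUE)) {
    pairs <- strsplit(pairs, "|", fixed = TRUE)[[1]]
  }
  if (!all(pairs %in% names(rule$pair_scores))) {
    abort("Unknown pair class; expected G:C, A:U or G:U.")
  }
  sum(rule$pair_scores[pairs])
}
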