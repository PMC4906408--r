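test_that("consensus matrices score Hamming distance", {
  m <- pssm_from_consensus("ACGT")
  expect_equal(m$width, 4)
  expect_equal(score_site("ACGT", m), 0)
  expect_equal(score_site("TGCA", m), 4) # full complement = width
  set.seed(14)
  cons <- random_dna(12)
  m <- pssm_from_consensus(cons)
  for (k in 1:100) {
    s <- random_dna(12)
    hamming <- sum(strsplit(s, "")[[1]] != strsplit(cons, "")[[1]])
    expect_equal(score_site(s, m), hamming)
  }
  expect_error(pssm_from_consensus("ACGU"), "non-A/C/G/T")
  expect_error(pssm_from_consensus("ACG"), "at least 4")
})

test_that("JASPAR-like matrices read in either orientation and round-trip", {
  path <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(
    ">toy",
    "A [ 10  0  0  5  3  1 ]",
    "C [  0 10  0  5  3  2 ]",
    "G [  0  0 10  5  2  3 ]",
    "T [  0  0  0  5  2  4 ]"
  ), path)
  m <- read_pfm(path)
  expect_equal(m$width, 6)
  expect_identical(m$mode, "weighted")
  # consensus base scores strictly best at informative positions
  expect_lt(m$scores["A", 1], min(m$scores[c("C", "G", "T"), 1]))

  # transposed (positions-as-rows) orientation gives the same matrix
  path2 <- withr::local_tempfile(fileext = ".pfm")
  writeLines(apply(t(m$counts), 1, paste, collapse = " "), path2)
  m2 <- read_pfm(path2)
  expect_equal(m2$scores, m$scores, ignore_attr = TRUE)

  # uniform counts score every base equally at every position
  path3 <- withr::local_tempfile(fileext = ".pfm")
  writeLines(rep("2 2 2 2 2", 4), path3)
  mu <- read_pfm(path3)
  expect_true(all(abs(sweep(mu$scores, 2, mu$scores[1, ])) < 1e-12))

  # write -> read preserves scores to machine precision
  out <- withr::local_tempfile(fileext = ".pfm")
  write_pfm(m, out)
  expect_equal(read_pfm(out)$scores, m$scores, tolerance = 1e-15)

  writeLines(c("A [ 1 2 ]", "C [ 1 ]"), path)
  expect_error(read_pfm(path), "Ragged")
  writeLines(c("1 2 x 4"), path)
  expect_error(read_pfm(path), "Malformed")
})

test_that("scan finds exact and substituted plants on both strands", {
  hit <- scan_pssm(c(chr = "AAAAATTTTTGGGGG"), pssm_from_consensus("TTTTT"),
                   top_k = 1, both_strands = FALSE)
  expect_equal(hit$start, 6L)
  expect_equal(hit$score, 0)

  pg <- plant_genome(10000, list(list(sequence = "ACGGTTACAGATTACGGATC",
                                      substitutions = 2)), seed = 31)
  m <- pssm_from_consensus("ACGGTTACAGATTACGGATC")
  best <- scan_pssm(pg$sequences, m, top_k = 1, both_strands = TRUE)
  expect_equal(best$start, pg$manifest$start)
  expect_equal(best$score, 2)

  # reverse-strand plant only appears when both strands are scanned
  rev_pg <- plant_genome(5000, list(list(sequence = "ACGGTTACAGATTACGGATC",
                                         strand = "-")), seed = 7)
  plus_only <- scan_pssm(rev_pg$sequences, m, top_k = 1, both_strands = FALSE)
  expect_gt(plus_only$score, 0)
  both <- scan_pssm(rev_pg$sequences, m, top_k = 1, both_strands = TRUE)
  expect_equal(both$strand, "-")
  expect_equal(both$start, rev_pg$manifest$start)
  expect_equal(both$score, 0)
  expect_identical(both$site, "ACGGTTACAGATTACGGATC")
})

test_that("scan agrees with naive all-window scoring in both modes", {
  set.seed(88)
  genome <- c(c1 = random_dna(3000), c2 = random_dna(1500))
  for (mode in c("mismatch", "weighted")) {
    m <- if (mode == "mismatch") {
      pssm_from_consensus(random_dna(10))
    } else {
      path <- withr::local_tempfile()
      writeLines(vapply(1:4, function(i) paste(sample(0:9, 10, TRUE),
                                               collapse = " "), ""), path)
      read_pfm(path)
    }
    want <- oracle_scan_all(genome, m$scores, both_strands = TRUE)
    want <- want[order(want$score, want$seq_id, want$start,
                       want$strand), ][1:25, ]
    got <- scan_pssm(genome, m, top_k = 25, both_strands = TRUE)
    expect_equal(got$score, want$score)
    expect_equal(got$start, want$start)
    expect_equal(got$seq_id, want$seq_id)
    expect_equal(got$strand, want$strand)
  }
})

test_that("strand handling is consistent under reverse complementation", {
  set.seed(5)
  s <- random_dna(800)
  m <- pssm_from_consensus(random_dna(8))
  fwd <- scan_pssm(c(x = s), m, top_k = 1e9, both_strands = TRUE)
  rc <- scan_pssm(c(x = dna_reverse_complement(s)), m, top_k = 1e9,
                  both_strands = TRUE)
  # multiset of scores per strand swaps
  expect_equal(sort(fwd$score[fwd$strand == "+"]),
               sort(rc$score[rc$strand == "-"]))
  expect_equal(sort(fwd$score[fwd$strand == "-"]),
               sort(rc$score[rc$strand == "+"]))
})

test_that("N-containing windows and too-short records are skipped", {
  m <- pssm_from_consensus("ACGTAC")
  res <- scan_pssm(c(ok = "ACGTACGTACGT", bad = "ACGNACGTAC"), m,
                   top_k = 100, both_strands = FALSE)
  expect_false(any(res$seq_id == "bad" & res$start <= 4))
  expect_message(
    short <- scan_pssm(c(tiny = "ACG"), m, top_k = 5, both_strands = FALSE),
    "Skipping"
  )
  expect_equal(nrow(short), 0)
})

test_that("substituting a planted site never improves its mismatch score", {
  set.seed(19)
  cons <- random_dna(15)
  m <- pssm_from_consensus(cons)
  prev <- 0
  site <- cons
  for (k in 1:6) {
    b <- strsplit(site, "")[[1]]
    pos <- sample(which(b == strsplit(cons, "")[[1]]), 1)
    b[pos] <- sample(setdiff(c("A", "C", "G", "T"), b[pos]), 1)
    site <- paste(b, collapse = "")
    sc <- score_site(site, m)
    expect_gte(sc, prev)
    prev <- sc
  }
})

test_that("BED export converts to 0-based half-open coordinates", {
  hits <- scan_pssm(c(chr = "AAAAATTTTTGGGGG"), pssm_from_consensus("TTTTT"),
                    top_k = 1, both_strands = FALSE)
  bed <- hits_to_bed(hits)
  expect_equal(bed$chromStart, hits$start - 1L)
  expect_equal(bed$chromEnd, hits$end)
  path <- withr::local_tempfile(fileext = ".bed")
  hits_to_bed(hits, path)
  expect_equal(length(readLines(path)), nrow(hits))
})
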