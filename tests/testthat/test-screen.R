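test_that("a planted GGGG/CCCC stem is found exactly once with correct geometry", {
  sp <- paste0("GGGG", "AAAAA", "CCCC", "AUAUCAU") # stem 1-4 vs 10-13, loop 5
  hits <- find_intra_spacer_duplexes(sp, min_stem = 4)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$stem_len, 4L)
  expect_equal(hits$n_wobble, 0L)
  expect_equal(hits$loop_len, 5L)
  expect_equal(hits$stability, 12)
  expect_matches_oracle(sp)
})

test_that("a poly-pyrimidine spacer has no stems with or without wobble", {
  sp <- "CUCUCUCUCUCUCUCUCUCU"
  expect_equal(nrow(find_intra_spacer_duplexes(
    sp, base_pair_rule(allow_wobble = FALSE))), 0)
  expect_equal(nrow(find_intra_spacer_duplexes(
    sp, base_pair_rule(allow_wobble = TRUE))), 0)
})

test_that("a wobble-containing stem appears only when wobble pairing is on", {
  # GGUG pairs CGCC with one G:U at stem position 3 (U:G)
  sp <- paste0("GGUG", "AAAAA", "CGCC", "AUAUCAU")
  on <- find_intra_spacer_duplexes(sp, base_pair_rule(allow_wobble = TRUE),
                                   min_stem = 4)
  off <- find_intra_spacer_duplexes(sp, base_pair_rule(allow_wobble = FALSE),
                                    min_stem = 4)
  planted <- on[on$spacer_start == 1 & on$partner_end == 13, ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$n_wobble, 1L)
  expect_equal(nrow(off), 0)
  expect_matches_oracle(sp, wobble = TRUE)
  expect_matches_oracle(sp, wobble = FALSE)
})

test_that("intra-spacer search matches exhaustive enumeration on random spacers", {
  set.seed(2024)
  for (k in 1:250) {
    sp <- random_spacer()
    expect_matches_oracle(sp, wobble = TRUE)
    expect_matches_oracle(sp, wobble = FALSE, min_stem = 3)
  }
})

test_that("backbone duplexes are found against toy scaffolds and labelled by region", {
  sp <- paste0("AAUACCCCAUAAUAAUAACA") # CCCC at 5-8
  sc <- scaffold("AAGGGGAA", name = "toy",
                 stem_regions = data.frame(label = "core", start = 3, end = 6))
  hits <- find_spacer_backbone_duplexes(sp, sc, min_stem = 4)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$spacer_start, 5L)
  expect_equal(hits$spacer_end, 8L)
  expect_equal(hits$partner_start, 3L)
  expect_equal(hits$partner_end, 6L)
  expect_identical(hits$scaffold_region, "core")
  expect_true(is.na(hits$loop_len))

  # no complementarity at all
  none <- find_spacer_backbone_duplexes(
    paste(rep("A", 20), collapse = ""),
    scaffold("AAAAAAAA"), min_stem = 4
  )
  expect_equal(nrow(none), 0)
  expect_error(find_spacer_backbone_duplexes(sp, "AAGGGGAA"), "scaffold")
})

test_that("backbone search matches exhaustive enumeration on random spacer/scaffold pairs", {
  set.seed(77)
  for (k in 1:40) {
    sp <- random_spacer()
    sc_seq <- random_spacer(sample(15:40, 1))
    for (wobble in c(TRUE, FALSE)) {
      got <- find_spacer_backbone_duplexes(
        sp, scaffold(sc_seq), base_pair_rule(allow_wobble = wobble), min_stem = 3
      )
      want <- oracle_backbone_stems(sp, sc_seq, wobble, min_stem = 3)
      expect_equal(nrow(got), nrow(want), info = paste(sp, sc_seq, wobble))
      if (nrow(want) > 0) {
        cols <- c("spacer_start", "spacer_end", "partner_start", "partner_end",
                  "stem_len")
        # two distinct stems can share both start coordinates (different
        # diagonals), so break ties on every column
        full_sort <- function(d) d[do.call(order, d[cols]), ]
        got_o <- full_sort(as.data.frame(got[cols]))
        want_o <- full_sort(want[cols])
        expect_equal(got_o, want_o, ignore_attr = TRUE)
      }
    }
  }
})

test_that("stem extension never removes a hit or lowers its stability", {
  # family: stems of increasing length planted at a fixed location
  loop <- "AAAAA"
  for (len in 4:7) {
    arm <- paste(rep("G", len), collapse = "")
    arm2 <- paste(rep("C", len), collapse = "")
    pad <- paste(rep("A", 20 - 2 * len - nchar(loop)), collapse = "")
    sp <- paste0(arm, loop, arm2, pad)
    hits <- find_intra_spacer_duplexes(sp, min_stem = 4)
    expect_gte(nrow(hits), 1)
    if (len > 4) {
      prev_arm <- paste(rep("G", len - 1), collapse = "")
      prev_sp <- paste0(prev_arm, loop, paste(rep("C", len - 1), collapse = ""),
                        paste(rep("A", 20 - 2 * (len - 1) - nchar(loop)),
                              collapse = ""))
      prev <- find_intra_spacer_duplexes(prev_sp, min_stem = 4)
      expect_gt(max(hits$stability), max(prev$stability))
    }
  }
})

test_that("hardening a G:U wobble to G:C strictly raises stability; breaking a pair removes the hit", {
  wob <- paste0("GGUG", "AAAAA", "CGCC", "AUAUCAU")
  hard <- paste0("GGCG", "AAAAA", "CGCC", "AUAUCAU") # U -> C hardens to G:C
  h_w <- find_intra_spacer_duplexes(wob, min_stem = 4)
  h_h <- find_intra_spacer_duplexes(hard, min_stem = 4)
  expect_gt(h_h$stability[1], h_w$stability[1])
  expect_equal(h_h$n_wobble[1], 0L)

  # break: C -> A creates an A:G mismatch in the planted stem
  broken <- paste0("GGGG", "AAAAA", "CACC", "AUAUCAU")
  h_b <- find_intra_spacer_duplexes(broken, min_stem = 4)
  expect_equal(nrow(h_b), 0)
})

test_that("classification flags hairpin, backbone and clean guides correctly", {
  toy <- toy_scaffold()
  hp <- make_hairpin_spacer(seed = 11, scaffold = toy)
  bb <- make_backbone_spacer(scaffold = toy, seed = 11)
  cl <- make_clean_spacer(seed = 11, scaffold = toy)

  v_hp <- classify_guide(hp, toy)
  v_bb <- classify_guide(bb, toy)
  v_cl <- classify_guide(cl, toy)
  expect_identical(v_hp$flags, "internal_hairpin")
  expect_identical(v_bb$flags, "backbone_interaction")
  expect_true(v_cl$clean)
  expect_identical(v_cl$flags, character(0))
  expect_equal(nrow(v_cl$hits), 0)
  # clean <=> no hit meets thresholds <=> flags empty
  expect_identical(v_hp$clean, nrow(v_hp$hits) == 0)
})

test_that("wobble stems must be one pair longer than canonical stems to flag", {
  cfg <- screen_config() # min_stem 4, wobble_extra 1
  wob4 <- paste0("GGUG", "AAAAA", "CGCC", "AUAUCAU") # 4-stem with one G:U
  v4 <- classify_guide(wob4, config = cfg)
  expect_true(v4$clean)
  wob5 <- paste0("GGUGG", "AAAAA", "CCGCC", "AUCAU") # 5-stem with one G:U
  v5 <- classify_guide(wob5, config = cfg)
  expect_identical(v5$flags, "internal_hairpin")
  expect_equal(v5$hits$n_wobble[1], 1L)
})

test_that("screening a guide table preserves input order and is deterministic", {
  toy <- toy_scaffold()
  guides <- tibble::tibble(
    id = c("g1", "g2", "g3"),
    spacer = c(make_hairpin_spacer(seed = 21, scaffold = toy)$spacer,
               make_clean_spacer(seed = 21, scaffold = toy)$spacer,
               make_backbone_spacer(scaffold = toy, seed = 21)$spacer)
  )
  scr1 <- screen_guides(guides, scaffold = toy)
  scr2 <- screen_guides(guides, scaffold = toy)
  expect_identical(scr1$id, guides$id)
  expect_identical(scr1$internal_hairpin, c(TRUE, FALSE, FALSE))
  expect_identical(scr1$backbone_interaction, c(FALSE, FALSE, TRUE))
  expect_identical(scr1$clean, c(FALSE, TRUE, FALSE))
  expect_identical(screen_report(scr1, "tsv"), screen_report(scr2, "tsv"))
})

test_that("screen reports serialize flagged guides (list) and full hits (tsv)", {
  toy <- toy_scaffold()
  guides <- tibble::tibble(
    id = c("a", "b", "c"),
    spacer = c(make_clean_spacer(seed = 31, scaffold = toy)$spacer,
               make_hairpin_spacer(seed = 31, scaffold = toy)$spacer,
               make_clean_spacer(seed = 32, scaffold = toy)$spacer)
  )
  scr <- screen_guides(guides, scaffold = toy)
  listing <- screen_report(scr, "list")
  expect_equal(length(strsplit(listing, "\n")[[1]]), 1)
  expect_match(listing, "^b\t")

  tsv <- screen_report(scr, "tsv")
  expect_match(tsv, "spacer_start")
  lines <- strsplit(tsv, "\n")[[1]]
  expect_equal(length(lines) - 1, sum(scr$n_hits))

  # empty screen: header-only tsv and empty list
  empty <- screen_guides(guides[0, ], scaffold = toy)
  expect_identical(screen_report(empty, "list"), "")
  expect_equal(length(strsplit(screen_report(empty, "tsv"), "\n")[[1]]), 1)
})

test_that("verdicts react to the 5'-GG substitution option", {
  # hairpin planted in positions 1-2 is destroyed by forcing GG when the
  # substitution breaks complementarity
  sp <- paste0("CCCC", "AAAAA", "GGGG", "AUAUCAU")
  plain <- classify_guide(sp)
  expect_identical(plain$flags, "internal_hairpin")
  after <- classify_guide(sp, gg = TRUE)
  expect_identical(after$guide$spacer, paste0("GG", substr(sp, 3, 20)))
  expect_equal(nrow(find_intra_spacer_duplexes(after$guide$spacer,
                                               min_stem = 4)),
               nrow(after$hits))
})
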