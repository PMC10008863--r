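test_that("complementation follows IUPAC rules", {
  expect_equal(dna_complement("ACGT"), "TGCA")
  expect_equal(dna_complement("ACGT", reverse = TRUE), "ACGT")
  expect_equal(dna_complement(dna_complement("TGCA")), "TGCA")
  expect_equal(dna_complement("ACGU"), "TGCA")  # U treated as T
  expect_error(dna_complement("ACXGT"), "position 3")
  # cross-check the transliteration against Biostrings on random IUPAC
  set.seed(5)
  for (i in 1:20) {
    s <- random_seq(40, c("A", "C", "G", "T", "N", "R", "Y", "S", "W",
                          "K", "M", "B", "D", "H", "V"))
    expect_identical(dna_complement(s),
                     as.character(Biostrings::complement(
                       Biostrings::DNAString(s))))
    expect_identical(dna_complement(s, reverse = TRUE),
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(s))))
  }
})

test_that("local_align reproduces hand-enumerated optima", {
  o <- local_align("GGACGTGG", "ACGT", bfe_scheme())
  expect_equal(o$score, 22)  # 5 + 6 + 6 + 5
  expect_equal(c(o$tested_start, o$tested_end), c(3, 6))
  expect_equal(o$n_identities, 4)
  expect_equal(o$n_gap_columns, 0)

  expect_equal(local_align("AAAA", "AAAA", bfe_scheme())$score, 20)

  o <- local_align("ACGT", "TTTT", bfe_scheme())
  expect_equal(o$score, 5)  # single T:T column at tested position 4
  expect_equal(o$tested_start, 4)

  expect_error(local_align("", "ACGT"), "non-empty")
})

test_that("empty sentinel appears exactly when nothing scores positive", {
  # all columns mismatch: mRNA all A vs complemented intron all T
  o <- find_oms("AAAA", "AAAA", bfe_scheme())
  expect_true(is_empty_oms(o))
  expect_equal(o$score, 0)
  expect_equal(o$n_columns, 0)
  # a single positive pair forces a non-empty OMS
  o <- find_oms("AAAT", "AAAA", bfe_scheme())  # complement intron = TTTT
  expect_false(is_empty_oms(o))
  expect_equal(o$score, 5)
})

test_that("find_oms maps the segment back onto the original intron", {
  o <- find_oms("GGACGTGG", "TGCA")  # complement of TGCA is ACGT
  expect_equal(o$score, 22)
  expect_equal(c(o$tested_start, o$tested_end), c(3, 6))
  expect_equal(c(o$intron_start, o$intron_end), c(1, 4))
  expect_equal(o$intron_oms_seq, "TGCA")
  expect_equal(o$mrna_oms_seq, "ACGT")

  # an intron equal to its own reversal: both orientations coincide
  a <- find_oms("GGTGGTGG", "ACCA", orientation = "complement")
  b <- find_oms("GGTGGTGG", "ACCA", orientation = "reverse_complement")
  expect_equal(a$score, b$score)
  expect_equal(a$score, 22)

  # determinism: identical reruns
  x <- find_oms("GATTACAGATTACA", "TGGCAT")
  y <- find_oms("GATTACAGATTACA", "TGGCAT")
  expect_identical(x, y)
})

test_that("reverse-complement orientation reports reversed coordinates", {
  # plant an exact reverse-complement of mRNA 4..13 inside the intron
  mrna <- "GGGTTACGGATCGAAGGG"
  seg <- substr(mrna, 4, 13)
  intron <- paste0("AAAAA", dna_complement(seg, reverse = TRUE), "AAAAA")
  o <- find_oms(mrna, intron, orientation = "reverse_complement")
  expect_equal(c(o$tested_start, o$tested_end), c(4, 13))
  expect_equal(c(o$intron_start, o$intron_end), c(6, 15))
  expect_equal(o$intron_oms_seq, dna_complement(seg, reverse = TRUE))
})

test_that("score_alignment re-scores columns and affine gaps exactly", {
  expect_equal(score_alignment("ACGT", "ACGT", bfe_scheme()), 22)
  expect_equal(score_alignment("A-T", "AAT", bfe_scheme()), -40)
  expect_equal(score_alignment("G", "G", sw_scheme()), 5)
  expect_error(score_alignment("AC", "A", bfe_scheme()), "equal length")
  expect_error(score_alignment("A-", "A-", bfe_scheme()), "two gaps")
})

test_that("reported scores are self-consistent with column re-scoring", {
  set.seed(21)
  for (i in 1:25) {
    x <- random_seq(sample(20:60, 1))
    y <- random_seq(sample(10:30, 1))
    for (s in list(bfe_scheme(), sw_scheme())) {
      o <- local_align(x, y, s)
      if (is_empty_oms(o)) next
      expect_equal(score_alignment(o$tested_aln, o$aligned_aln, s),
                   o$score)
      expect_lte(o$n_identities, o$n_columns - o$n_gap_columns)
      expect_gte(o$score, max(s$matrix))  # >= best single pair
    }
  }
})

test_that("small instances match brute force and stay gapless", {
  set.seed(33)
  for (i in 1:40) {
    x <- random_seq(sample(3:8, 1))
    y <- random_seq(sample(3:8, 1))
    for (s in list(bfe_scheme(), sw_scheme())) {
      o <- local_align(x, y, s)
      expect_equal(o$score, brute_force_local_score(x, y, s))
      # gap open 50 > any gain available on < 9 columns
      expect_equal(o$n_gap_columns, 0)
    }
  }
})

test_that("optimal score agrees with Biostrings pairwiseAlignment", {
  set.seed(44)
  for (i in 1:30) {
    x <- random_seq(sample(15:60, 1))
    y <- random_seq(sample(10:40, 1))
    for (s in list(bfe_scheme(), sw_scheme())) {
      dp <- local_align(x, y, s)$score
      if (dp > 0)
        expect_equal(dp, biostrings_local_score(x, y, s))
    }
  }
})

test_that("appending sequence never decreases the optimal local score", {
  set.seed(55)
  for (i in 1:15) {
    x <- random_seq(12); y <- random_seq(12)
    s0 <- local_align(x, y)$score
    expect_gte(local_align(paste0(x, random_seq(5)), y)$score, s0)
    expect_gte(local_align(x, paste0(random_seq(5), y))$score, s0)
  }
})

test_that("BFE score is bracketed by uniform +5/-4 and +6/-4 schemes", {
  mk <- function(match) {
    m <- matrix(-4L, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                           c("A", "C", "G", "T")))
    diag(m) <- as.integer(match)
    scoring_scheme(paste0("U", match), m)
  }
  set.seed(66)
  for (i in 1:10) {
    x <- random_seq(30); y <- random_seq(20)
    o <- local_align(x, y, bfe_scheme())
    if (is_empty_oms(o)) next
    fixed5 <- score_alignment(o$tested_aln, o$aligned_aln, mk(5))
    fixed6 <- score_alignment(o$tested_aln, o$aligned_aln, mk(6))
    expect_gte(o$score, fixed5)
    expect_lte(o$score, fixed6)
  }
})
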