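test_that("length normalization maps bases onto 1..100 as defined", {
  expect_equal(normalize_site(10, 50), 20L)   # integral branch
  expect_equal(normalize_site(1, 200), 1L)    # 0.5 -> floor 0 + 1
  expect_equal(normalize_site(200, 200), 100L)
  for (L in c(1L, 7L, 99L, 100L, 101L, 977L))
    expect_equal(normalize_site(L, L), 100L)
  expect_equal(normalize_site(1, 1), 100L)
  expect_error(normalize_site(0, 10), "out of range")
  expect_error(normalize_site(11, 10), "out of range")
})

test_that("matched score vectors put 1 exactly on covered bins", {
  full <- fake_oms_row("t", "t_intron1", 1L, 500L, 500L)
  expect_equal(matched_score_vector(full, 500), rep(1L, 100))
  empty <- fake_oms_row("t", "t_intron1", NA_integer_, NA_integer_, 500L)
  expect_equal(matched_score_vector(empty, 500), rep(0L, 100))
  v <- matched_score_vector(list(tested_start = 1, tested_end = 10), 100)
  expect_equal(which(v == 1L), 1:10)
})

test_that("matched frequency is the elementwise mean", {
  ones <- rep(1L, 100); zeros <- rep(0L, 100)
  expect_equal(matched_frequency(rbind(ones, zeros)), rep(0.5, 100))
  expect_equal(matched_frequency(rbind(ones)), rep(1, 100))
  half_a <- c(rep(1L, 50), rep(0L, 50))
  expect_equal(matched_frequency(rbind(half_a, rev(half_a))),
               rep(0.5, 100))
  expect_error(matched_frequency(matrix(0, 0, 100)), "at least one")
})

test_that("average matched frequency is the mean coverage fraction", {
  expect_equal(average_matched_frequency(c(20, 40), c(100, 100)), 0.3)
  expect_equal(average_matched_frequency(c(50, 80), c(50, 80)), 1)
  expect_equal(average_matched_frequency(c(0, 0), c(10, 10)), 0)
  expect_error(relative_matched_frequency(rep(0, 100), 0),
               "no matched segments")
  expect_error(average_matched_frequency(numeric(0), numeric(0)), "N = 0")
})

test_that("RF is coverage over its average and averages to one", {
  p <- relative_matched_frequency(rep(0.3, 100), 0.3)
  expect_equal(p$rf, rep(1, 100))
  expect_equal(relative_matched_frequency(rep(0.6, 100), 0.3)$rf,
               rep(2, 100))
  set.seed(12)
  models <- sim_models(sim_spec(n_genes = 25, seed = 12))
  prof <- rf_profile(oms_table(models))
  expect_equal(mean(prof$rf), 1, tolerance = 1e-12)
  expect_true(all(prof$bins >= 0 & prof$bins <= 1))
  expect_equal(prof$rf, prof$bins / prof$avg_f)
})

test_that("bin coverage conserves segment length within rounding", {
  set.seed(13)
  for (i in 1:50) {
    L <- sample(150:2000, 1)
    s <- sample(seq_len(L), 1)
    e <- min(L, s + sample(10:40, 1))
    v <- matched_score_vector(list(tested_start = s, tested_end = e), L)
    ks <- normalize_site(s, L); ke <- normalize_site(e, L)
    expect_equal(sum(v), ke - ks + 1)
    # discretization error of the covered fraction is at most two bins
    expect_lte(abs(sum(v) / 100 - (e - s + 1) / L), 0.02)
  }
})

test_that("OMR detection returns maximal RF>1 runs", {
  expect_equal(nrow(detect_omr(rep(1, 100))), 0)  # strict inequality
  rf <- rep(0.9, 100); rf[80:98] <- 1.5; rf[90] <- 2.5
  d <- detect_omr(rf)
  expect_equal(nrow(d), 1)
  expect_equal(c(d$start_bin, d$end_bin, d$peak_rf), c(80, 98, 2.5))
  rf2 <- rep(0.9, 100); rf2[5:12] <- 1.2; rf2[60:70] <- 1.4
  d2 <- detect_omr(rf2)
  expect_equal(d2$start_bin, c(5, 60))
  expect_equal(d2$end_bin, c(12, 70))
})

test_that("site profiles report exact coverage around the anchor", {
  # one transcript, anchor = AUG at cds_start = 101, OMS covering
  # anchor-10 .. anchor+10 exactly
  m <- fake_model("t1", utr5 = 100L, utr3 = 120L, cds_len = 300L)
  oms <- fake_oms_row("t1", "t1_intron1", 91L, 111L, nchar(m$mrna_seq))
  sp <- site_profile(list(t1 = m), oms, "AUG")
  expect_equal(sp$offsets, -60:60)
  expect_equal(sp$f, as.numeric(abs(sp$offsets) <= 10))
  expect_gt(sp$rf[61], 1)

  # UAA anchor is the first base of the stop codon
  sp2 <- site_profile(list(t1 = m), oms, "UAA")
  anchor <- m$cds_end - 2
  expect_equal(sp2$f, as.numeric(91 <= anchor + sp2$offsets &
                                   anchor + sp2$offsets <= 111))

  # all-empty OMS set has no average coverage
  empty <- fake_oms_row("t1", "t1_intron1", NA_integer_, NA_integer_,
                        nchar(m$mrna_seq))
  expect_error(site_profile(list(t1 = m), empty, "AUG"))
})

test_that("site profiles respect UTR filters and junction grouping", {
  short5 <- fake_model("s", utr5 = 30L, utr3 = 120L)
  ok <- fake_model("t1", utr5 = 100L, utr3 = 120L, cds_len = 300L)
  oms <- rbind(
    fake_oms_row("s", "s_intron1", 1L, 20L, nchar(short5$mrna_seq)),
    fake_oms_row("t1", "t1_intron1", 91L, 111L, nchar(ok$mrna_seq)))
  sp <- site_profile(list(s = short5, t1 = ok), oms, "AUG")
  expect_equal(sp$n_pairs, 1)  # short-5'UTR transcript excluded

  # junction grouping: 3 junctions -> first/middle/last anchors
  ee <- fake_model("e", utr5 = 100L, utr3 = 150L, cds_len = 300L,
                   ee = c(120L, 260L, 400L))
  oe <- fake_oms_row("e", "e_intron1", 110L, 130L, nchar(ee$mrna_seq))
  f1 <- site_profile(list(e = ee), oe, "EE_first")
  expect_equal(f1$f[61], 1)  # OMS covers the first junction
  fl <- site_profile(list(e = ee), oe, "EE_last")
  expect_equal(sum(fl$f), 0)  # but not the last one
  fm <- site_profile(list(e = ee), oe, "EE_middle")
  expect_equal(fm$n_units, 1)
})

test_that("region comparison is a Welch test with degenerate guards", {
  expect_warning(r <- compare_regions(rep(1, 4), rep(1, 4)))
  expect_equal(r$t, 0); expect_equal(r$p, 1)
  set.seed(14)
  a <- rnorm(6, 0, 1e-4); b <- 1 + rnorm(6, 0, 1e-4)
  r2 <- compare_regions(a, b)
  expect_lt(r2$p, 0.01)
  expect_error(compare_regions(1, c(1, 2)))
})
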