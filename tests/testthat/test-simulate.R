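test_that("generation is byte-deterministic in the seed", {
  s <- sim_spec(n_genes = 4, seed = 17, plant_rate = 0.5)
  a <- generate_dataset(s)
  b <- generate_dataset(s)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$gff_lines, b$gff_lines)
  expect_identical(a$truth, b$truth)
  c <- generate_dataset(sim_spec(n_genes = 4, seed = 18,
                                 plant_rate = 0.5))
  expect_false(identical(as.character(a$genome),
                         as.character(c$genome)))
})

test_that("no plants means an empty truth table", {
  ds <- generate_dataset(sim_spec(n_genes = 3, seed = 2, plant_rate = 0))
  expect_equal(nrow(ds$truth), 0)
})

test_that("generated models parse cleanly on both strands", {
  spec <- sim_spec(n_genes = 10, seed = 19)
  models <- sim_models(spec)
  expect_length(models, 10)
  strands <- vapply(models, `[[`, character(1), "strand")
  expect_setequal(unique(strands), c("+", "-"))
  for (m in models) {
    expect_equal(substr(m$mrna_seq, m$cds_start, m$cds_start + 2), "ATG")
    expect_equal(substr(m$mrna_seq, m$cds_end - 2, m$cds_end), "TAA")
    expect_true(all(nchar(m$introns) >= 40))
    expect_gte(m$utr5_len, 50)
    expect_gte(m$utr3_len, 80)
  }
})

test_that("truth coordinates point at exact complementary copies", {
  spec <- sim_spec(n_genes = 10, seed = 20, plant_rate = 1,
                   plant_region = "3UTR", plant_identity = 1)
  ds <- generate_dataset(spec)
  models <- sim_models(ds)
  expect_gt(nrow(ds$truth), 0)
  for (i in seq_len(nrow(ds$truth))) {
    tr <- ds$truth[i, ]
    m <- models[[tr$mrna_id]]
    k <- as.integer(sub(".*_intron", "", tr$intron_id))
    mseg <- substr(m$mrna_seq, tr$mrna_start, tr$mrna_end)
    iseg <- substr(m$introns[[k]], tr$intron_start, tr$intron_end)
    expect_identical(dna_complement(iseg), mseg)
    # planted interval sits in the 3'UTR as requested
    expect_gte(tr$mrna_start, m$cds_end + 1)
  }
})

test_that("reverse-complement plants honour that orientation", {
  spec <- sim_spec(n_genes = 6, seed = 21, plant_rate = 1,
                   plant_region = "CDS", plant_identity = 1,
                   orientation = "reverse_complement")
  ds <- generate_dataset(spec)
  models <- sim_models(ds)
  tr <- ds$truth[1, ]
  m <- models[[tr$mrna_id]]
  k <- as.integer(sub(".*_intron", "", tr$intron_id))
  mseg <- substr(m$mrna_seq, tr$mrna_start, tr$mrna_end)
  iseg <- substr(m$introns[[k]], tr$intron_start, tr$intron_end)
  expect_identical(dna_complement(iseg, reverse = TRUE), mseg)
  o <- find_oms(m$mrna_seq, m$introns[[k]],
                orientation = "reverse_complement")
  expect_gte(o$score, 5 * (tr$mrna_end - tr$mrna_start + 1))
})

test_that("the aligner recovers planted perfect-identity segments", {
  spec <- sim_spec(n_genes = 30, seed = 22, plant_rate = 1,
                   plant_region = "3UTR", plant_identity = 1,
                   plant_len_range = c(25L, 25L))
  ds <- generate_dataset(spec)
  models <- sim_models(ds)
  oms <- oms_table(models)
  hits <- 0L
  for (i in seq_len(nrow(ds$truth))) {
    tr <- ds$truth[i, ]
    r <- oms[oms$intron_id == tr$intron_id, ]
    ov <- min(r$mrna_end, tr$mrna_end) - max(r$mrna_start,
                                             tr$mrna_start) + 1
    plen <- tr$mrna_end - tr$mrna_start + 1
    # the optimal segment may extend past a perfect plant while flanking
    # score stays positive, so recovery is judged by plant coverage
    if (!is.na(ov) && ov / plen >= 0.8) hits <- hits + 1L
  }
  expect_gte(hits / nrow(ds$truth), 0.9)
})

test_that("intron lengths follow the declared long/short mixture", {
  spec <- sim_spec(n_genes = 400, seed = 23)
  models <- sim_models(spec)
  len <- pairing_manifest(models)$intron_length
  expect_gte(length(len), 800)
  # discrete lengths: compare unit-jittered values against the
  # continuous mixture of uniforms
  mix_cdf <- function(t)
    0.5 * stats::punif(t, 39.5, 80.5) + 0.5 * stats::punif(t, 80.5,
                                                           400.5)
  jit <- intronmatch:::with_local_seed(23,
    len + stats::runif(length(len), -0.5, 0.5))
  ks <- suppressWarnings(stats::ks.test(jit, mix_cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("infeasible plant specifications are rejected", {
  spec <- sim_spec(n_genes = 2, seed = 3, plant_rate = 1,
                   plant_region = "5UTR",
                   plant_len_range = c(300L, 300L))
  expect_error(generate_dataset(spec), "infeasible")
})

test_that("written datasets round-trip through the file readers", {
  dir <- tempfile()
  ds <- generate_dataset(sim_spec(n_genes = 3, seed = 29), dir = dir)
  expect_true(all(file.exists(ds$paths)))
  parsed <- parse_gene_models(ds$paths["gff3"], ds$paths["genome"])
  expect_length(parsed$models, 3)
  expect_equal(nrow(parsed$rejected), 0)
  unlink(dir, recursive = TRUE)
})
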