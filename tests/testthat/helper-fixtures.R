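# Toy single-gene fixtures built in code.
#
# Plus-strand layout on a 300 bp contig:
#   exon1 = 1..100, exon2 = 151..300 (one 50 bp intron), CDS = 21..280
# -> mRNA 250 bp, utr5 = 20, utr3 = 20, CDS length 210 (multiple of 3),
#    EE junction at mRNA position 100.
# The minus-strand mirror reverse-complements the contig and mirrors all
# coordinates, so both parses must yield the identical mRNA.

toy_plus_genome <- function(seed = 101) {
  set.seed(seed)
  ch <- strsplit(random_seq(300), "")[[1]]
  ch[21:23] <- c("A", "T", "G")
  ch[278:280] <- c("T", "A", "A")
  paste(ch, collapse = "")
}

toy_gff <- function(strand = "+", cds_end = 280) {
  if (strand == "+") {
    ex <- list(c(1, 100), c(151, 300))
    cds <- c(21, cds_end)
  } else {
    ex <- list(c(1, 150), c(201, 300))
    cds <- c(301 - cds_end, 280)
  }
  lines <- c(
    "##gff-version 3",
    sprintf("chrT\ttest\tgene\t1\t300\t.\t%s\t.\tID=gene1", strand),
    sprintf("chrT\ttest\tmRNA\t1\t300\t.\t%s\t.\tID=tx1;Parent=gene1",
            strand))
  for (k in seq_along(ex))
    lines <- c(lines, sprintf(
      "chrT\ttest\texon\t%d\t%d\t.\t%s\t.\tID=tx1.e%d;Parent=tx1",
      ex[[k]][1], ex[[k]][2], strand, k))
  for (k in seq_along(ex)) {
    lo <- max(cds[1], ex[[k]][1]); hi <- min(cds[2], ex[[k]][2])
    if (lo <= hi)
      lines <- c(lines, sprintf(
        "chrT\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=tx1.c;Parent=tx1",
        lo, hi, strand))
  }
  lines
}

parse_toy <- function(strand = "+", cds_end = 280, genome = NULL) {
  if (is.null(genome)) genome <- toy_plus_genome()
  if (strand == "-") genome <- dna_complement(genome, reverse = TRUE)
  gff <- tempfile(fileext = ".gff3")
  on.exit(unlink(gff))
  writeLines(toy_gff(strand, cds_end), gff)
  parse_gene_models(gff, Biostrings::DNAStringSet(c(chrT = genome)))
}

# Minimal hand-built transcript model for filter / profile tests; only
# structural fields need to be meaningful.
fake_model <- function(transcript_id, gene_id = transcript_id,
                       intron_lens = 60L, utr5 = 60L, utr3 = 100L,
                       cds_len = 150L, ee = integer(0),
                       mrna_seq = NULL) {
  if (is.null(mrna_seq))
    mrna_seq <- strrep("A", utr5 + cds_len + utr3)
  structure(list(
    gene_id = gene_id, transcript_id = transcript_id, chrom = "chrT",
    strand = "+", mrna_seq = mrna_seq,
    cds_start = utr5 + 1L, cds_end = utr5 + cds_len,
    ee_junctions = as.integer(ee),
    introns = vapply(intron_lens, function(n) strrep("A", n),
                     character(1)),
    utr5_len = as.integer(utr5), utr3_len = as.integer(utr3)),
    class = "transcript_model")
}

# minimal OMS-table row for profile tests
fake_oms_row <- function(mrna_id, intron_id, mrna_start, mrna_end,
                         mrna_length, intron_length = 100L,
                         scheme = "BFE") {
  data.frame(
    mrna_id = mrna_id, intron_id = intron_id, intron_index = 1L,
    scheme = scheme, orientation = "complement",
    mrna_start = mrna_start, mrna_end = mrna_end,
    intron_start = 1L,
    intron_end = if (is.na(mrna_start)) NA_integer_ else
      mrna_end - mrna_start + 1L,
    score = 10L, identities = 2L,
    columns = if (is.na(mrna_start)) 0L else
      mrna_end - mrna_start + 1L,
    gap_columns = 0L, match_rate = 100,
    mrna_length = mrna_length, intron_length = intron_length,
    intron_class = classify_intron(intron_length),
    mrna_oms_seq = "", intron_oms_seq = "",
    stringsAsFactors = FALSE)
}
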