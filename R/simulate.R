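#' Specification for the synthetic gene-model generator
#'
#' Describes the synthetic dataset: single-isoform protein-coding gene
#' models with uniform exon/intron/UTR length distributions, an i.i.d.
#' background with a chosen G+C fraction, and optional planted
#' complementary segments between an intron and a chosen mRNA region.
#' Defaults emulate the filtered study conditions: introns of at least
#' 40 bp in a roughly even long/short mixture around the 80 bp class
#' boundary, 5'UTRs of at least 50 bp and 3'UTRs of at least 80 bp (so
#' site windows are eligible), and a background G+C of 0.36.
#'
#' @param n_genes Number of genes.
#' @param seed Seed; identical seeds give byte-identical output.
#' @param exon_count_range Min/max exons per gene.
#' @param cds_codon_range Min/max internal codons (CDS = ATG + codons +
#'   TAA).
#' @param intron_short_range,intron_long_range Length ranges (bp) of the
#'   short and long intron components.
#' @param long_frac Fraction of introns drawn from the long component.
#' @param utr5_range,utr3_range UTR length ranges (bp).
#' @param gc Background G+C fraction.
#' @param plant_rate Fraction of (mRNA, intron) pairs receiving a planted
#'   complementary segment.
#' @param plant_region Where on the mRNA the segment is planted:
#'   `"5UTR"`, `"CDS"`, `"3UTR"`, `"AUG"`, `"UAA"` or `"EE"` (the last
#'   three are +/-`plant_window` bp around the site).
#' @param plant_window Half-width of site-anchored plant regions (bp).
#' @param plant_len_range Min/max planted segment length (bp).
#' @param plant_identity Fraction of planted positions left perfectly
#'   complementary (the rest are mutated on the intron side).
#' @param plant_gc If not `NA`, the planted segment is generated with
#'   this G+C and written into both molecules; if `NA` the mRNA content
#'   is left untouched and only the intron receives the complement copy.
#' @param orientation Complementation convention the plant copies, so the
#'   aligner can rediscover it: `"complement"` or `"reverse_complement"`.
#' @param intergenic Intergenic spacer length (bp).
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_genes = 100, seed = 1,
                     exon_count_range = c(2L, 5L),
                     cds_codon_range = c(80L, 200L),
                     intron_short_range = c(40L, 80L),
                     intron_long_range = c(81L, 400L),
                     long_frac = 0.5,
                     utr5_range = c(50L, 150L),
                     utr3_range = c(80L, 250L),
                     gc = 0.36,
                     plant_rate = 0,
                     plant_region = "3UTR",
                     plant_window = 60L,
                     plant_len_range = c(20L, 30L),
                     plant_identity = 1.0,
                     plant_gc = NA_real_,
                     orientation = c("complement", "reverse_complement"),
                     intergenic = 200L) {
  orientation <- match.arg(orientation)
  plant_region <- match.arg(plant_region,
                            c("5UTR", "CDS", "3UTR", "AUG", "UAA", "EE"))
  stopifnot(n_genes >= 1, long_frac >= 0, long_frac <= 1,
            gc > 0, gc < 1, plant_rate >= 0, plant_rate <= 1,
            plant_identity >= 0, plant_identity <= 1,
            intron_short_range[1] >= 1, utr5_range[1] >= 1,
            utr3_range[1] >= 1, plant_len_range[1] >= 1)
  structure(as.list(environment()), class = "sim_spec")
}

random_dna <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

sample_range <- function(rng) {
  if (rng[1] >= rng[2]) as.integer(rng[1]) else
    sample(seq.int(rng[1], rng[2]), 1L)
}

mutate_positions <- function(seq, n_mut) {
  if (n_mut <= 0) return(list(seq = seq, realized = 1))
  ch <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(ch), n_mut)
  for (p in pos) {
    alt <- setdiff(c("A", "C", "G", "T"), ch[p])
    ch[p] <- sample(alt, 1L)
  }
  list(seq = paste(ch, collapse = ""),
       realized = 1 - n_mut / length(ch))
}

plant_region_interval <- function(region, window, utr5, cds_start,
                                  cds_end, L, junctions) {
  iv <- switch(region,
    `5UTR` = c(1L, utr5),
    CDS = c(cds_start + 3L, cds_end - 3L),
    `3UTR` = c(cds_end + 1L, L),
    AUG = c(cds_start - window, cds_start + window),
    UAA = c(cds_end - 2L - window, cds_end - 2L + window),
    EE = {
      j <- junctions[sample.int(length(junctions), 1L)]
      c(j - window, j + window)
    })
  c(max(1L, iv[1]), min(L, iv[2]))
}

sim_one_gene <- function(spec, gi) {
  utr5 <- sample_range(spec$utr5_range)
  utr3 <- sample_range(spec$utr3_range)
  ncod <- sample_range(spec$cds_codon_range)
  mrna <- paste0(random_dna(utr5, spec$gc),
                 "ATG", random_dna(3L * ncod, spec$gc), "TAA",
                 random_dna(utr3, spec$gc))
  L <- nchar(mrna)
  cds_start <- utr5 + 1L
  cds_end <- utr5 + 3L * ncod + 6L
  n_exons <- sample_range(spec$exon_count_range)
  min_exon <- 30L
  while (n_exons > 1L && L < n_exons * min_exon) n_exons <- n_exons - 1L
  extra <- L - n_exons * min_exon
  cuts <- if (n_exons > 1L)
    sort(sample.int(extra + 1L, n_exons - 1L, replace = TRUE) - 1L) else
    integer(0)
  exon_len <- min_exon + diff(c(0L, cuts, extra))
  junctions <- utils::head(cumsum(exon_len), -1L)

  n_introns <- n_exons - 1L
  intron_len <- integer(n_introns)
  for (k in seq_len(n_introns)) {
    long <- stats::runif(1) < spec$long_frac
    intron_len[k] <- sample_range(
      if (long) spec$intron_long_range else spec$intron_short_range)
  }

  # decide plants first (they may rewrite the mRNA), then cut exons
  plants <- list()
  for (k in seq_len(n_introns)) {
    if (stats::runif(1) >= spec$plant_rate) next
    plen <- sample_range(spec$plant_len_range)
    iv <- plant_region_interval(spec$plant_region, spec$plant_window,
                                utr5, cds_start, cds_end, L, junctions)
    if (iv[2] - iv[1] + 1L < plen)
      stop(sprintf("infeasible spec: plant of %d bp does not fit region %s (%d bp)",
                   plen, spec$plant_region, iv[2] - iv[1] + 1L))
    if (intron_len[k] < plen)
      stop("infeasible spec: plant longer than intron")
    ms <- iv[1] + sample.int(iv[2] - iv[1] + 1L - plen + 1L, 1L) - 1L
    me <- ms + plen - 1L
    if (!is.na(spec$plant_gc)) {
      substr(mrna, ms, me) <- random_dna(plen, spec$plant_gc)
      # keep annotated start/stop codons intact
      substr(mrna, cds_start, cds_start + 2L) <- "ATG"
      substr(mrna, cds_end - 2L, cds_end) <- "TAA"
    }
    plants[[length(plants) + 1L]] <-
      list(k = k, ms = ms, me = me, plen = plen)
  }

  introns <- vapply(intron_len, function(n) random_dna(n, spec$gc),
                    character(1))
  truth <- list()
  for (p in plants) {
    mseg <- substr(mrna, p$ms, p$me)
    iseg <- dna_complement(mseg,
                           reverse = spec$orientation ==
                             "reverse_complement")
    mut <- mutate_positions(iseg,
                            floor((1 - spec$plant_identity) * p$plen))
    is <- sample.int(intron_len[p$k] - p$plen + 1L, 1L)
    ie <- is + p$plen - 1L
    substr(introns[p$k], is, ie) <- mut$seq
    truth[[length(truth) + 1L]] <- data.frame(
      mrna_id = sprintf("t%04d", gi),
      intron_id = sprintf("t%04d_intron%d", gi, p$k),
      mrna_start = p$ms, mrna_end = p$me,
      intron_start = is, intron_end = ie,
      identity = mut$realized,
      plant_gc = if (is.na(spec$plant_gc)) gc_content(mseg) else
        spec$plant_gc,
      stringsAsFactors = FALSE)
  }

  list(mrna = mrna, exon_len = exon_len, introns = introns,
       cds_start = cds_start, cds_end = cds_end,
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

# GFF3 feature lines for one gene placed at genomic offset g0 (1-based)
gene_gff_lines <- function(g, gi, chrom, g0, strand) {
  exon_len <- g$exon_len
  n_exons <- length(exon_len)
  intron_len <- nchar(g$introns)
  pre_len <- sum(exon_len) + sum(intron_len)
  tx_start <- cumsum(c(0L, utils::head(exon_len, -1L))) + 1L
  tx_end <- cumsum(exon_len)
  pre_off <- cumsum(c(0L, intron_len))[seq_len(n_exons)] +
    (tx_start - 1L)
  # pre-mRNA coordinates of each exon
  pre_s <- pre_off - (tx_start - 1L) + tx_start
  pre_s <- tx_start + cumsum(c(0L, intron_len))[seq_len(n_exons)]
  pre_e <- pre_s + exon_len - 1L
  to_genomic <- function(ps, pe) {
    if (strand == "+") c(g0 + ps - 1L, g0 + pe - 1L)
    else c(g0 + pre_len - pe, g0 + pre_len - ps)
  }
  gid <- sprintf("g%04d", gi); tid <- sprintf("t%04d", gi)
  lines <- character(0)
  add <- function(type, s, e, phase, attrs)
    lines[[length(lines) + 1L]] <<- paste(
      chrom, "intronmatch_sim", type, s, e, ".", strand, phase, attrs,
      sep = "\t")
  gspan <- c(g0, g0 + pre_len - 1L)
  add("gene", gspan[1], gspan[2], ".", sprintf("ID=%s", gid))
  add("mRNA", gspan[1], gspan[2], ".",
      sprintf("ID=%s;Parent=%s", tid, gid))
  for (k in seq_len(n_exons)) {
    gc <- to_genomic(pre_s[k], pre_e[k])
    add("exon", gc[1], gc[2], ".",
        sprintf("ID=%s.exon%d;Parent=%s", tid, k, tid))
  }
  # CDS pieces: intersect the transcript CDS interval with each exon
  cds_cum <- 0L
  for (k in seq_len(n_exons)) {
    lo <- max(g$cds_start, tx_start[k])
    hi <- min(g$cds_end, tx_end[k])
    if (lo > hi) next
    phase <- (3L - cds_cum %% 3L) %% 3L
    ps <- pre_s[k] + (lo - tx_start[k])
    pe <- pre_s[k] + (hi - tx_start[k])
    gc <- to_genomic(ps, pe)
    add("CDS", gc[1], gc[2], phase,
        sprintf("ID=%s.cds;Parent=%s", tid, tid))
    cds_cum <- cds_cum + (hi - lo + 1L)
  }
  list(lines = unlist(lines), pre_len = pre_len)
}

#' Generate a synthetic genome, annotation and ground truth
#'
#' Builds the dataset described by a [sim_spec()]: a single-contig genome
#' holding every gene (strands alternate so both are represented), GFF3
#' annotation with gene/mRNA/exon/CDS features, and a truth table of
#' planted complementary segments with 1-based inclusive coordinates on
#' both molecules. With a fixed seed the output is byte-identical across
#' runs.
#'
#' @param spec A [sim_spec()].
#' @param dir If non-`NULL`, write `genome.fa`, `genes.gff3` and
#'   `truth.tsv` there.
#' @return A list of class `sim_dataset`: `genome` (`DNAStringSet`),
#'   `gff_lines` (character), `truth` (data.frame), `spec`, and `paths`
#'   when written.
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  with_local_seed(spec$seed, {
    chrom <- "chr1"
    chunks <- character(0)
    gff <- c("##gff-version 3")
    truth <- list()
    offset <- 0L
    for (gi in seq_len(spec$n_genes)) {
      strand <- if (gi %% 2L == 1L) "+" else "-"
      g <- sim_one_gene(spec, gi)
      pre <- {
        parts <- character(0)
        tx_s <- cumsum(c(0L, utils::head(g$exon_len, -1L))) + 1L
        for (k in seq_along(g$exon_len)) {
          parts <- c(parts, substr(g$mrna, tx_s[k],
                                   tx_s[k] + g$exon_len[k] - 1L))
          if (k < length(g$exon_len)) parts <- c(parts, g$introns[k])
        }
        paste(parts, collapse = "")
      }
      genomic <- if (strand == "+") pre else
        dna_complement(pre, reverse = TRUE)
      spacer <- random_dna(spec$intergenic, spec$gc)
      chunks <- c(chunks, spacer, genomic)
      g0 <- offset + spec$intergenic + 1L
      gl <- gene_gff_lines(g, gi, chrom, g0, strand)
      gff <- c(gff, gl$lines)
      offset <- offset + spec$intergenic + nchar(pre)
      if (!is.null(g$truth)) truth[[length(truth) + 1L]] <- g$truth
    }
    chunks <- c(chunks, random_dna(spec$intergenic, spec$gc))
    genome <- Biostrings::DNAStringSet(
      stats::setNames(paste(chunks, collapse = ""), chrom))
    truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
      mrna_id = character(), intron_id = character(),
      mrna_start = integer(), mrna_end = integer(),
      intron_start = integer(), intron_end = integer(),
      identity = numeric(), plant_gc = numeric(),
      stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    ds <- structure(list(genome = genome, gff_lines = gff,
                         truth = truth, spec = spec),
                    class = "sim_dataset")
    if (!is.null(dir)) ds$paths <- write_sim_dataset(ds, dir)
    ds
  })
}

#' Write a simulated dataset to disk
#'
#' @param ds A `sim_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written.
#' @export
write_sim_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             gff3 = file.path(dir, "genes.gff3"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(ds$genome, paths["genome"])
  writeLines(ds$gff_lines, paths["gff3"])
  utils::write.table(ds$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' Transcript models of a simulated dataset
#'
#' Routes the simulated genome + annotation through the real GFF3/FASTA
#' parser ([parse_gene_models()]), so simulation tests exercise the same
#' code path as real data.
#'
#' @param x A [sim_spec()] or a `sim_dataset`.
#' @return Named list of transcript models.
#' @export
sim_models <- function(x) {
  ds <- if (inherits(x, "sim_spec")) generate_dataset(x) else x
  stopifnot(inherits(ds, "sim_dataset"))
  gff_path <- tempfile(fileext = ".gff3")
  on.exit(unlink(gff_path))
  writeLines(ds$gff_lines, gff_path)
  parsed <- parse_gene_models(gff_path, ds$genome)
  if (nrow(parsed$rejected))
    warning("simulated transcripts rejected by the parser: ",
            paste(parsed$rejected$transcript_id, collapse = ", "))
  parsed$models
}
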