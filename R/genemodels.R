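#' Build transcript models from a genome FASTA and GFF3 annotation
#'
#' One model is built per `mRNA` feature: exons are spliced in transcript
#' order (minus-strand genes are reverse-complemented into 5'->3'
#' orientation), introns are the gaps between consecutive exons, and the
#' CDS span is mapped onto mRNA coordinates. Transcripts with structural
#' problems (CDS outside exons, CDS length not a multiple of 3,
#' overlapping exons, missing contig) are rejected individually and
#' reported, never failing the whole parse. A non-ATG start codon raises a
#' warning only: the site anchor is always the annotated CDS boundary.
#'
#' @param gff3 Path to a GFF3 file (gene/mRNA/exon/CDS features with
#'   ID/Parent attributes), or a `GRanges` already imported from one.
#' @param genome Path to the genome FASTA, or a named `DNAStringSet`.
#' @return A list with `models` (named list of `transcript_model`
#'   objects) and `rejected` (data.frame of transcript_id, reason).
#'   Each model carries `gene_id`, `transcript_id`, `strand`, `mrna_seq`,
#'   `cds_start`, `cds_end` (1-based inclusive on the mRNA, stop codon
#'   included), `ee_junctions` (mRNA position of the last base of each
#'   non-terminal exon), `introns` (character vector, transcript order),
#'   `utr5_len` and `utr3_len`.
#' @export
parse_gene_models <- function(gff3, genome) {
  gr <- if (methods::is(gff3, "GRanges")) gff3 else
    rtracklayer::import(gff3, format = "gff3")
  dna <- if (methods::is(genome, "DNAStringSet")) genome else
    Biostrings::readDNAStringSet(genome)
  names(dna) <- sub("\\s.*$", "", names(dna))

  type <- as.character(gr$type)
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    rep(NA_character_, length(gr))
  parents <- if (!is.null(gr$Parent))
    vapply(as.list(gr$Parent), function(p)
      if (length(p)) as.character(p)[1] else NA_character_,
      character(1)) else rep(NA_character_, length(gr))

  mrna_idx <- which(type == "mRNA")
  models <- list()
  rej <- list()
  for (i in mrna_idx) {
    tid <- ids[i]
    res <- tryCatch(
      build_transcript_model(gr, dna, i, tid, parents, type, ids),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      rej[[length(rej) + 1L]] <- data.frame(
        transcript_id = tid, reason = res, stringsAsFactors = FALSE)
    } else {
      models[[tid]] <- res
    }
  }
  rejected <- if (length(rej)) do.call(rbind, rej) else
    data.frame(transcript_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  list(models = models, rejected = rejected)
}

build_transcript_model <- function(gr, dna, i, tid, parents, type, ids) {
  chrom <- as.character(GenomicRanges::seqnames(gr[i]))
  strand <- as.character(GenomicRanges::strand(gr[i]))
  if (!chrom %in% names(dna)) stop("missing contig ", chrom)
  ex <- gr[type == "exon" & parents == tid]
  cds <- gr[type == "CDS" & parents == tid]
  if (length(ex) == 0L) stop("no exons")
  if (length(cds) == 0L) stop("no CDS")
  ex <- ex[order(GenomicRanges::start(ex))]
  es <- GenomicRanges::start(ex); ee <- GenomicRanges::end(ex)
  if (length(ex) > 1L && any(es[-1] <= ee[-length(ex)]))
    stop("overlapping exons")
  clen <- length(dna[[chrom]])
  if (any(es < 1L) || any(ee > clen)) stop("exon outside contig")

  # every CDS feature must sit inside an exon
  cs <- GenomicRanges::start(cds); ce <- GenomicRanges::end(cds)
  inside <- vapply(seq_along(cds), function(k)
    any(es <= cs[k] & ce[k] <= ee), logical(1))
  if (!all(inside)) stop("CDS not contained in exons")

  exon_seqs <- vapply(seq_along(ex), function(k)
    as.character(Biostrings::subseq(dna[[chrom]], es[k], ee[k])),
    character(1))
  intr_seqs <- if (length(ex) > 1L)
    vapply(seq_len(length(ex) - 1L), function(k)
      as.character(Biostrings::subseq(dna[[chrom]], ee[k] + 1L,
                                      es[k + 1L] - 1L)),
      character(1)) else character(0)
  mrna <- paste(exon_seqs, collapse = "")
  if (strand == "-") {
    mrna <- dna_complement(mrna, reverse = TRUE)
    intr_seqs <- rev(vapply(intr_seqs, dna_complement, character(1),
                            reverse = TRUE, USE.NAMES = FALSE))
  }
  if (any(nchar(intr_seqs) < 1L)) stop("zero-length intron")

  # genomic -> transcript coordinate map
  exlen <- ee - es + 1L
  cum <- cumsum(exlen)
  g2t <- function(g) {
    k <- which(es <= g & g <= ee)
    if (length(k) != 1L) stop("CDS boundary outside exons")
    tpos <- (if (k > 1L) cum[k - 1L] else 0L) + (g - es[k] + 1L)
    if (strand == "-") sum(exlen) - tpos + 1L else tpos
  }
  cds_lo <- min(cs); cds_hi <- max(ce)
  t1 <- g2t(cds_lo); t2 <- g2t(cds_hi)
  cds_start <- min(t1, t2); cds_end <- max(t1, t2)
  if ((cds_end - cds_start + 1L) %% 3L != 0L)
    stop("CDS length not a multiple of 3")
  start_codon <- substr(mrna, cds_start, cds_start + 2L)
  if (!identical(start_codon, "ATG"))
    warning(sprintf("%s: annotated start codon is %s, not ATG",
                    tid, start_codon))
  junc <- if (length(exlen) > 1L) {
    tl <- if (strand == "-") rev(exlen) else exlen
    utils::head(cumsum(tl), -1L)
  } else integer(0)

  structure(list(
    gene_id = if (!is.na(parents[i])) parents[i] else tid,
    transcript_id = tid, chrom = chrom, strand = strand,
    mrna_seq = toupper(mrna),
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    ee_junctions = as.integer(junc),
    introns = toupper(intr_seqs),
    utr5_len = as.integer(cds_start - 1L),
    utr3_len = as.integer(nchar(mrna) - cds_end)),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model %s (%s%s)> mRNA %d bp, CDS %d..%d, %d intron(s), 5'UTR %d bp, 3'UTR %d bp\n",
              x$transcript_id, x$chrom, x$strand, nchar(x$mrna_seq),
              x$cds_start, x$cds_end, length(x$introns),
              x$utr5_len, x$utr3_len))
  invisible(x)
}

#' Dataset filters on transcript models
#'
#' Drops genes with more than one annotated mRNA (when `single_isoform`),
#' genes with any intron shorter than `min_intron` bases, and genes named
#' in `exclude_ids` (externally supplied, e.g. ncRNA/repeat containing
#' genes). The boundary is inclusive: an intron of exactly `min_intron`
#' bases is retained.
#'
#' @param models Named list of transcript models (or the list returned by
#'   [parse_gene_models()], whose `$models` element is used).
#' @param min_intron Minimum intron length in bp (default 40).
#' @param single_isoform Drop genes with multiple transcripts.
#' @param exclude_ids Gene or transcript identifiers to drop.
#' @return A list with `models` (retained) and `report` (data.frame of
#'   gene_id, transcript_id, reason for each drop).
#' @export
filter_dataset <- function(models, min_intron = 40, single_isoform = TRUE,
                           exclude_ids = character()) {
  if (!is.null(models$models)) models <- models$models
  report <- list()
  keep <- rep(TRUE, length(models))
  gene_ids <- vapply(models, `[[`, character(1), "gene_id")
  tx_ids <- vapply(models, `[[`, character(1), "transcript_id")
  drop <- function(i, reason) {
    keep[i] <<- FALSE
    report[[length(report) + 1L]] <<- data.frame(
      gene_id = gene_ids[i], transcript_id = tx_ids[i], reason = reason,
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(models)) {
    if (gene_ids[i] %in% exclude_ids || tx_ids[i] %in% exclude_ids) {
      drop(i, "excluded_id"); next
    }
    if (single_isoform && sum(gene_ids == gene_ids[i]) > 1L) {
      drop(i, "alternative_splicing"); next
    }
    if (length(models[[i]]$introns) &&
        any(nchar(models[[i]]$introns) < min_intron)) {
      drop(i, sprintf("intron<%d", min_intron)); next
    }
  }
  if (!any(keep)) warning("all transcripts filtered out")
  list(models = models[keep],
       report = if (length(report)) do.call(rbind, report) else
         data.frame(gene_id = character(), transcript_id = character(),
                    reason = character(), stringsAsFactors = FALSE))
}

#' Long/short intron classification
#'
#' Introns of at most `threshold` bases are `short`; longer ones `long`.
#'
#' @param length Intron length(s) in bp.
#' @param threshold Class boundary (default 80 bp; 80 itself is short).
#' @return Character vector of `"short"`/`"long"`.
#' @examples
#' classify_intron(c(40, 80, 81))  # short short long
#' @export
classify_intron <- function(length, threshold = 80) {
  stopifnot(all(length >= 1))
  ifelse(length <= threshold, "short", "long")
}

#' UTR-length filter for functional-site window analyses
#'
#' Transcripts with a 5'UTR shorter than `min_utr5` or a 3'UTR shorter
#' than `min_utr3` are removed so that the +/-60 bp windows around the
#' start and stop codons avoid boundary effects. The global RF analysis
#' uses the unfiltered set; this filter applies to site windows only.
#'
#' @param models Named list of transcript models.
#' @param min_utr5,min_utr3 Minimum UTR lengths in bp (defaults 50 and 80,
#'   boundaries inclusive).
#' @return The retained subset of `models`.
#' @export
utr_site_filter <- function(models, min_utr5 = 50, min_utr3 = 80) {
  if (!is.null(models$models)) models <- models$models
  keep <- vapply(models, function(m)
    m$utr5_len >= min_utr5 && m$utr3_len >= min_utr3, logical(1))
  models[keep]
}

#' Pairing manifest for a transcript-model set
#'
#' @param models Named list of transcript models.
#' @return A data.frame with one row per (mRNA, intron) pair: `mrna_id`,
#'   `intron_id`, `intron_index`, `intron_length`, `class`.
#' @export
pairing_manifest <- function(models) {
  if (!is.null(models$models)) models <- models$models
  rows <- lapply(models, function(m) {
    if (!length(m$introns)) return(NULL)
    data.frame(
      mrna_id = m$transcript_id,
      intron_id = sprintf("%s_intron%d", m$transcript_id,
                          seq_along(m$introns)),
      intron_index = seq_along(m$introns),
      intron_length = nchar(m$introns),
      class = classify_intron(nchar(m$introns)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write per-class FASTA files for a model set
#'
#' Writes mRNA, intron (named `transcriptID_intronN`), CDS, 5'UTR and
#' 3'UTR sequences of a transcript-model set to a directory.
#'
#' @param models Named list of transcript models.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_class_fasta <- function(models, dir) {
  if (!is.null(models$models)) models <- models$models
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  getseq <- function(f) Biostrings::DNAStringSet(
    stats::setNames(vapply(models, f, character(1)),
                    vapply(models, `[[`, character(1), "transcript_id")))
  paths <- character()
  w <- function(set, file) {
    p <- file.path(dir, file)
    Biostrings::writeXStringSet(set[nchar(set) > 0], p)
    paths <<- c(paths, p)
  }
  w(getseq(function(m) m$mrna_seq), "mrna.fa")
  w(getseq(function(m) substr(m$mrna_seq, m$cds_start, m$cds_end)),
    "cds.fa")
  w(getseq(function(m) substr(m$mrna_seq, 1, m$utr5_len)), "utr5.fa")
  w(getseq(function(m) substr(m$mrna_seq, m$cds_end + 1,
                              nchar(m$mrna_seq))), "utr3.fa")
  intr <- unlist(lapply(models, function(m)
    stats::setNames(as.list(m$introns),
                    sprintf("%s_intron%d", m$transcript_id,
                            seq_along(m$introns)))), recursive = FALSE)
  if (length(intr))
    w(Biostrings::DNAStringSet(unlist(intr)), "introns.fa")
  invisible(paths)
}
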