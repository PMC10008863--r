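#' Complement (optionally reverse-complement) a DNA/RNA sequence
#'
#' Uracil is mapped to thymine on input; IUPAC ambiguity codes are
#' complemented per the IUPAC rules; output is uppercase DNA.
#'
#' @param seq Single nucleotide string (IUPAC alphabet, U accepted).
#' @param reverse If `TRUE`, return the reverse complement.
#' @return The complemented (or reverse-complemented) sequence.
#' @examples
#' dna_complement("ACGT")                 # "TGCA"
#' dna_complement("ACGT", reverse = TRUE) # "ACGT"
#' @export
dna_complement <- function(seq, reverse = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("Uu", "Tt", toupper(seq))
  bad <- regexpr("[^ATGCSWRYKMBVHDN]", s)
  if (bad > 0L)
    stop(sprintf("non-IUPAC symbol '%s' at position %d",
                 substr(s, bad, bad), bad))
  # IUPAC complement as a transliteration (verified against
  # Biostrings::complement in the test suite)
  s <- chartr("ATGCRYKMBVHD", "TACGYRMKVBDH", s)
  if (reverse)
    s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  s
}

oms_record <- function(res, scheme, orientation,
                       tested_id = NA_character_,
                       aligned_id = NA_character_,
                       intron_start = NA_integer_,
                       intron_end = NA_integer_,
                       intron_oms_seq = NA_character_,
                       mrna_oms_seq = NA_character_) {
  structure(list(
    tested_id = tested_id, aligned_id = aligned_id,
    tested_start = res$t_start, tested_end = res$t_end,
    aligned_start = res$a_start, aligned_end = res$a_end,
    intron_start = intron_start, intron_end = intron_end,
    score = res$score,
    n_identities = res$n_identities, n_columns = res$n_columns,
    n_gap_columns = res$n_gap_columns,
    tested_aln = res$tested_aln, aligned_aln = res$aligned_aln,
    mrna_oms_seq = mrna_oms_seq, intron_oms_seq = intron_oms_seq,
    scheme_name = scheme$name, orientation = orientation),
    class = "oms")
}

#' @export
print.oms <- function(x, ...) {
  if (is_empty_oms(x)) {
    cat(sprintf("<oms %s> empty (no positively scoring column)\n",
                x$scheme_name))
  } else {
    cat(sprintf("<oms %s/%s> score %d, tested %d..%d, aligned %d..%d, %d/%d identities, %d gap col\n",
                x$scheme_name, x$orientation, x$score,
                x$tested_start, x$tested_end,
                x$aligned_start, x$aligned_end,
                x$n_identities, x$n_columns, x$n_gap_columns))
    cat(" ", x$tested_aln, "\n ", x$aligned_aln, "\n", sep = "")
  }
  invisible(x)
}

#' Is this an empty (sentinel) optimal matched segment?
#'
#' @param oms An object returned by [local_align()] or [find_oms()].
#' @return `TRUE` when no positively scoring alignment column existed.
#' @export
is_empty_oms <- function(oms) oms$n_columns == 0L

check_dna <- function(seq, what) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop(what, " must be a single non-empty string")
  chartr("Uu", "Tt", toupper(seq))
}

#' Optimal local alignment of two sequences
#'
#' Runs the three-state Gotoh local-alignment recurrence under affine gaps
#' and returns the single optimal matched segment. Ties are broken
#' deterministically: smallest tested end coordinate, then smallest
#' aligned end coordinate; the traceback prefers stopping at score zero,
#' then a paired column, then a gap in the aligned sequence, then a gap in
#' the tested sequence. When no alignment column can score positively the
#' empty sentinel (score 0, zero length) is returned.
#'
#' @param tested Tested sequence (the mRNA in this package's pipeline).
#' @param aligned Aligned sequence (the complemented intron).
#' @param scheme A [scoring_scheme()] or scheme name (`"BFE"`, `"SW"`).
#' @return An object of class `oms`; see [find_oms()] for the field list.
#' @examples
#' local_align("GGACGTGG", "ACGT", bfe_scheme())$score  # 22
#' @export
local_align <- function(tested, aligned, scheme = bfe_scheme()) {
  scheme <- get_scheme(scheme)
  tested <- check_dna(tested, "tested")
  aligned <- check_dna(aligned, "aligned")
  res <- .gotoh_local(tested, aligned, scheme$matrix, scheme$alphabet,
                      scheme$gap_open, scheme$gap_ext)
  mseq <- if (res$n_columns > 0L)
    substr(tested, res$t_start, res$t_end) else NA_character_
  oms_record(res, scheme, orientation = NA_character_,
             mrna_oms_seq = mseq)
}

#' Optimal matched segment between an mRNA and one of its introns
#'
#' The intron is complemented (or reverse-complemented), the mRNA is
#' locally aligned against it as the tested sequence, and the aligned-side
#' interval is mapped back onto the ORIGINAL intron, whose matched
#' sub-sequence is the OMS in the intron.
#'
#' @param mrna Mature mRNA sequence (tested sequence).
#' @param intron Intron sequence, 5'->3' in transcript orientation.
#' @param scheme A [scoring_scheme()] or its name.
#' @param orientation `"complement"` (plain complement, the default) or
#'   `"reverse_complement"` (antiparallel-hybridization variant).
#' @param tested_id,aligned_id Optional identifiers carried into the result.
#' @return An `oms` object with 1-based inclusive coordinates on the mRNA
#'   (`tested_start/tested_end`) and on the original intron
#'   (`intron_start/intron_end`), the alignment score, identity/column/gap
#'   counts, the two gapped alignment strings, and the matched
#'   sub-sequences of both molecules.
#' @examples
#' oms <- find_oms("GGACGTGG", "TGCA")
#' oms$score         # 22
#' oms$intron_start  # 1
#' @export
find_oms <- function(mrna, intron, scheme = bfe_scheme(),
                     orientation = c("complement", "reverse_complement"),
                     tested_id = NA_character_,
                     aligned_id = NA_character_) {
  orientation <- match.arg(orientation)
  scheme <- get_scheme(scheme)
  mrna <- check_dna(mrna, "mrna")
  intron <- check_dna(intron, "intron")
  caligned <- dna_complement(intron,
                             reverse = orientation == "reverse_complement")
  res <- .gotoh_local(mrna, caligned, scheme$matrix, scheme$alphabet,
                      scheme$gap_open, scheme$gap_ext)
  if (res$n_columns == 0L)
    return(oms_record(res, scheme, orientation, tested_id, aligned_id))
  li <- nchar(intron)
  if (orientation == "reverse_complement") {
    is <- li - res$a_end + 1L
    ie <- li - res$a_start + 1L
  } else {
    is <- res$a_start
    ie <- res$a_end
  }
  oms_record(res, scheme, orientation, tested_id, aligned_id,
             intron_start = is, intron_end = ie,
             intron_oms_seq = substr(intron, is, ie),
             mrna_oms_seq = substr(mrna, res$t_start, res$t_end))
}

#' Re-score a gapped alignment column by column
#'
#' Self-consistency checker: sums pair scores over paired columns and
#' subtracts `gap_open + (g-1)*gap_ext` for every gap run of length `g`.
#' For any OMS produced by this package the result equals the reported
#' alignment score.
#'
#' @param tested_aln,aligned_aln Equal-length gapped strings (`-` = gap).
#' @param scheme A [scoring_scheme()] or its name.
#' @return The alignment score (numeric).
#' @examples
#' score_alignment("ACGT", "ACGT", bfe_scheme())  # 22
#' @export
score_alignment <- function(tested_aln, aligned_aln,
                            scheme = bfe_scheme()) {
  scheme <- get_scheme(scheme)
  if (nchar(tested_aln) != nchar(aligned_aln))
    stop("gapped strings must have equal length")
  a <- strsplit(toupper(tested_aln), "")[[1]]
  b <- strsplit(toupper(aligned_aln), "")[[1]]
  if (any(a == "-" & b == "-")) stop("column with two gaps")
  gap <- a == "-" | b == "-"
  score <- 0
  if (any(!gap)) {
    sym <- rownames(scheme$matrix)
    ia <- match(a[!gap], sym); ib <- match(b[!gap], sym)
    if (anyNA(ia) || anyNA(ib)) stop("symbol outside scheme alphabet")
    score <- sum(scheme$matrix[cbind(ia, ib)])
  }
  if (any(gap)) {
    runs <- rle(gap)
    glen <- runs$lengths[runs$values]
    score <- score - sum(scheme$gap_open + (glen - 1) * scheme$gap_ext)
  }
  as.numeric(score)
}

#' OMS table for a set of transcript models
#'
#' Runs [find_oms()] for every (mRNA, intron) pair of a transcript-model
#' set and returns one row per pair. Pairs whose best alignment is empty
#' get score 0, NA coordinates and zero lengths; they still count towards
#' the pair total N used by the RF statistics.
#'
#' @param models A list of transcript models from [parse_gene_models()] or
#'   [sim_models()].
#' @param scheme A [scoring_scheme()] or its name.
#' @param orientation `"complement"` or `"reverse_complement"`.
#' @return A data.frame with columns `mrna_id`, `intron_id`,
#'   `intron_index`, `scheme`, `orientation`, `mrna_start`, `mrna_end`,
#'   `intron_start`, `intron_end`, `score`, `identities`, `columns`,
#'   `gap_columns`, `match_rate`, plus `mrna_length`, `intron_length`,
#'   `intron_class` and the matched sub-sequences used by the sequence
#'   statistics.
#' @export
oms_table <- function(models, scheme = bfe_scheme(),
                      orientation = c("complement", "reverse_complement")) {
  orientation <- match.arg(orientation)
  scheme <- get_scheme(scheme)
  n <- sum(vapply(models, function(m) length(m$introns), integer(1)))
  col <- list(
    mrna_id = character(n), intron_id = character(n),
    intron_index = integer(n),
    mrna_start = integer(n), mrna_end = integer(n),
    intron_start = integer(n), intron_end = integer(n),
    score = integer(n), identities = integer(n), columns = integer(n),
    gap_columns = integer(n), mrna_length = integer(n),
    intron_length = integer(n),
    mrna_oms_seq = character(n), intron_oms_seq = character(n))
  r <- 0L
  for (m in models) {
    for (k in seq_along(m$introns)) {
      iid <- sprintf("%s_intron%d", m$transcript_id, k)
      o <- find_oms(m$mrna_seq, m$introns[[k]], scheme, orientation,
                    tested_id = m$transcript_id, aligned_id = iid)
      r <- r + 1L
      col$mrna_id[r] <- m$transcript_id
      col$intron_id[r] <- iid
      col$intron_index[r] <- k
      col$mrna_start[r] <- if (is_empty_oms(o)) NA_integer_ else
        o$tested_start
      col$mrna_end[r] <- if (is_empty_oms(o)) NA_integer_ else
        o$tested_end
      col$intron_start[r] <- o$intron_start
      col$intron_end[r] <- o$intron_end
      col$score[r] <- o$score
      col$identities[r] <- o$n_identities
      col$columns[r] <- o$n_columns
      col$gap_columns[r] <- o$n_gap_columns
      col$mrna_length[r] <- nchar(m$mrna_seq)
      col$intron_length[r] <- nchar(m$introns[[k]])
      col$mrna_oms_seq[r] <- if (is.na(o$mrna_oms_seq)) "" else
        o$mrna_oms_seq
      col$intron_oms_seq[r] <- if (is.na(o$intron_oms_seq)) "" else
        o$intron_oms_seq
    }
  }
  data.frame(
    mrna_id = col$mrna_id, intron_id = col$intron_id,
    intron_index = col$intron_index,
    scheme = rep(scheme$name, n), orientation = rep(orientation, n),
    mrna_start = col$mrna_start, mrna_end = col$mrna_end,
    intron_start = col$intron_start, intron_end = col$intron_end,
    score = col$score, identities = col$identities,
    columns = col$columns, gap_columns = col$gap_columns,
    match_rate = ifelse(col$columns > 0L,
                        100 * col$identities / col$columns, NA_real_),
    mrna_length = col$mrna_length, intron_length = col$intron_length,
    intron_class = classify_intron(pmax(col$intron_length, 1L)),
    mrna_oms_seq = col$mrna_oms_seq,
    intron_oms_seq = col$intron_oms_seq,
    stringsAsFactors = FALSE)
}
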