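#' Match rate of an OMS alignment
#'
#' Percent of identical columns among all alignment columns (gaps
#' included in the denominator).
#'
#' @param oms An `oms` object, or anything with `n_identities` and
#'   `n_columns` (aliases `identities`/`columns`).
#' @return Match rate in percent, or `NA` for an empty OMS.
#' @export
match_rate <- function(oms) {
  nid <- if (!is.null(oms$n_identities)) oms$n_identities else
    oms$identities
  nc <- if (!is.null(oms$n_columns)) oms$n_columns else oms$columns
  ifelse(nc >= 1L, 100 * nid / nc, NA_real_)
}

#' G+C content of a sequence
#'
#' Fraction (#G + #C) / (#A + #C + #G + #T); ambiguity symbols are
#' excluded from numerator and denominator.
#'
#' @param seq Nucleotide string(s).
#' @return Fraction(s) in \[0, 1\]; `NA` when no unambiguous base exists.
#' @examples
#' gc_content("ACGT")  # 0.5
#' @export
gc_content <- function(seq) {
  vapply(seq, function(s) {
    ch <- strsplit(chartr("Uu", "Tt", toupper(s)), "")[[1]]
    n_gc <- sum(ch %in% c("G", "C"))
    n <- sum(ch %in% c("A", "C", "G", "T"))
    if (n == 0L) NA_real_ else n_gc / n
  }, numeric(1), USE.NAMES = FALSE)
}

# integer codes 1..4 for A,C,G,T; 0 for anything else
seq_to_code <- function(s) {
  lut <- integer(256)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt("a")] <- 1L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("g")] <- 3L; lut[utf8ToInt("t")] <- 4L
  lut[utf8ToInt(chartr("Uu", "Tt", s)) ]
}

# base (4) and dinucleotide (16) counts of one sequence; pairs broken by
# ambiguity symbols are dropped
count_dinuc <- function(s) {
  code <- seq_to_code(s)
  base <- tabulate(code, nbins = 4L)
  n <- length(code)
  if (n >= 2L) {
    a <- code[-n]; b <- code[-1L]
    ok <- a > 0L & b > 0L
    pair <- tabulate((a[ok] - 1L) * 4L + b[ok], nbins = 16L)
  } else pair <- integer(16L)
  list(base = base, pair = pair)
}

d2_from_counts <- function(base, pair) {
  nb <- sum(base); np <- sum(pair)
  if (np < 1L) stop("no adjacent base pairs to count")
  p <- base / nb
  pij <- pair / np
  pipj <- as.vector(outer(p, p))
  pos <- pij > 0 & pipj > 0
  d2 <- sum(pij[pos] * log2(pij[pos] / pipj[pos]))
  approx <- sum((pij[pos] - pipj[pos])^2 / pipj[pos]) / (2 * log(2))
  list(d2 = max(0, d2), d2_approx = approx, n_pairs = np, n_bases = nb)
}

#' Second-order informational redundancy D2
#'
#' Mutual information between adjacent bases:
#' `D2 = sum_ij p_ij log2(p_ij / (p_i p_j))` over the 16 dinucleotides,
#' with `0 * log 0 = 0`. Marginals `p_i` are the single-base frequencies
#' of the analyzed sequence(s); joint probabilities come from adjacent
#' pairs counted *within* each sequence (no cross-sequence adjacency).
#' `D2 = 0` for an infinite independent-base sequence; for a finite
#' sequence of `N` bases the 99%-confidence fluctuation bound is
#' `15.65/N`. The chi-squared-style quadratic approximation is emitted as
#' a labeled secondary value (`d2_approx`).
#'
#' @param seqs One or more nucleotide strings.
#' @param mode `"pooled"` (counts summed over all sequences, one D2) or
#'   `"per-sequence-mean"` (mean of per-sequence D2 values).
#' @return A list of class `d2_result`: `d2` (bits), `d2_approx`,
#'   `n_pairs_counted`, `n_bases`, `fluctuation_bound` (= 15.65/N with N
#'   the total base count), `significant` (`d2 >= bound`), `mode`.
#' @examples
#' d2_redundancy("AAAAAA")$d2    # 0
#' d2_redundancy("ACACAC")$d2    # about 1.03 bits
#' @export
d2_redundancy <- function(seqs, mode = c("pooled", "per-sequence-mean")) {
  mode <- match.arg(mode)
  seqs <- seqs[nchar(seqs) > 0]
  if (!length(seqs)) stop("empty input")
  counts <- lapply(seqs, count_dinuc)
  if (mode == "pooled") {
    base <- Reduce(`+`, lapply(counts, `[[`, "base"))
    pair <- Reduce(`+`, lapply(counts, `[[`, "pair"))
    r <- d2_from_counts(base, pair)
  } else {
    usable <- counts[vapply(counts, function(x) sum(x$pair) >= 1L,
                            logical(1))]
    if (!length(usable)) stop("no adjacent base pairs to count")
    per <- lapply(usable, function(x) d2_from_counts(x$base, x$pair))
    r <- list(d2 = mean(vapply(per, `[[`, numeric(1), "d2")),
              d2_approx = mean(vapply(per, `[[`, numeric(1),
                                      "d2_approx")),
              n_pairs = sum(vapply(per, `[[`, numeric(1), "n_pairs")),
              n_bases = sum(vapply(per, `[[`, numeric(1), "n_bases")))
  }
  bound <- d2_bound(r$n_bases)
  structure(list(d2 = r$d2, d2_approx = r$d2_approx,
                 n_pairs_counted = r$n_pairs, n_bases = r$n_bases,
                 fluctuation_bound = bound,
                 significant = r$d2 >= bound, mode = mode),
            class = "d2_result")
}

#' @export
print.d2_result <- function(x, ...) {
  cat(sprintf("<d2_result %s> D2 = %.5f bits (approx %.5f), N = %d bases, bound 15.65/N = %.5f, %s\n",
              x$mode, x$d2, x$d2_approx, x$n_bases, x$fluctuation_bound,
              if (x$significant) "significant at 99%" else
                "not significant"))
  invisible(x)
}

#' Fluctuation bound of D2
#'
#' For a finite sequence of `N` bases, `D2` values up to `15.65/N` are
#' compatible with independent bases at the 99% confidence level
#' (equivalently, the 0.99 quantile of chi-squared with 9 degrees of
#' freedom divided by `2 N ln 2`).
#'
#' @param N Total base count.
#' @return The bound `15.65/N`.
#' @examples
#' d2_bound(1565)  # 0.01
#' @export
d2_bound <- function(N) {
  stopifnot(all(N >= 1))
  15.65 / N
}

hist_table <- function(x, width, lo = NULL, hi = NULL) {
  x <- x[is.finite(x)]
  if (!length(x))
    return(data.frame(bin_low = numeric(), bin_high = numeric(),
                      count = integer(), fraction = numeric()))
  if (is.null(lo)) lo <- floor(min(x) / width) * width
  if (is.null(hi)) hi <- ceiling(max(x) / width + 1e-9) * width
  if (hi <= lo) hi <- lo + width
  breaks <- seq(lo, hi, by = width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  data.frame(bin_low = utils::head(breaks, -1),
             bin_high = breaks[-1],
             count = h$counts,
             fraction = h$counts / length(x))
}

#' Sequence-feature report of an OMS table
#'
#' Histograms of match rate (5% bins), intron-side OMS length (1 bp
#' bins) and OMS G+C content (0.05 bins), plus D2 for the sequence
#' classes CDS, 5'UTR, 3'UTR and OMS (the matched segments on the
#' introns), each in pooled and per-sequence-mean mode.
#'
#' @param oms A data.frame from [oms_table()].
#' @param models The transcript models behind it.
#' @return A list with `match_rate_hist`, `length_hist`, `gc_hist`
#'   (data.frames) and `d2_report` (class, mode, n_bases, d2, d2_approx,
#'   bound, significant).
#' @export
class_statistics <- function(oms, models) {
  if (!is.null(models$models)) models <- models$models
  nonempty <- oms[oms$columns > 0L, , drop = FALSE]
  omslen <- nchar(nonempty$intron_oms_seq)
  classes <- list(
    CDS = vapply(models, function(m)
      substr(m$mrna_seq, m$cds_start, m$cds_end), character(1)),
    `5UTR` = vapply(models, function(m)
      substr(m$mrna_seq, 1, m$utr5_len), character(1)),
    `3UTR` = vapply(models, function(m)
      substr(m$mrna_seq, m$cds_end + 1, nchar(m$mrna_seq)),
      character(1)),
    OMS = nonempty$intron_oms_seq)
  rows <- list()
  for (cl in names(classes)) {
    seqs <- classes[[cl]][nchar(classes[[cl]]) > 1]
    if (!length(seqs)) next
    for (mode in c("pooled", "per-sequence-mean")) {
      d <- d2_redundancy(seqs, mode)
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, mode = mode, n_bases = d$n_bases, d2 = d$d2,
        d2_approx = d$d2_approx, bound = d$fluctuation_bound,
        significant = d$significant, stringsAsFactors = FALSE)
    }
  }
  list(
    match_rate_hist = hist_table(nonempty$match_rate, 5, 0, 100),
    length_hist = hist_table(omslen, 1),
    gc_hist = hist_table(gc_content(nonempty$intron_oms_seq), 0.05, 0, 1),
    d2_report = do.call(rbind, rows))
}
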