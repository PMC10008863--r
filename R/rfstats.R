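#' Length-normalized relative base site
#'
#' Maps the `j`-th base of a sequence of length `L` onto the 1..100
#' relative coordinate: `k = 100*j/L` when that is an integer, otherwise
#' `floor(100*j/L) + 1`. The last base always maps to 100. Integer
#' arithmetic is used throughout, so the mapping is exact.
#'
#' @param j 1-based base position(s).
#' @param L Sequence length.
#' @return Integer relative site(s) in 1..100.
#' @examples
#' normalize_site(10, 50)   # 20
#' normalize_site(1, 200)   # 1
#' normalize_site(137, 137) # 100
#' @export
normalize_site <- function(j, L) {
  j <- as.integer(j); L <- as.integer(L)
  stopifnot(length(L) == 1L, L >= 1L)
  if (any(j < 1L) || any(j > L)) stop("position out of range 1..L")
  num <- 100L * j
  k <- num %/% L
  ifelse(num %% L == 0L, k, k + 1L)
}

#' Matched score vector of one OMS on the normalized mRNA
#'
#' Value 1 on every relative site covered by the optimal matched segment,
#' 0 elsewhere. An empty OMS yields the all-zero vector.
#'
#' @param oms An `oms` object, or a list/row with `tested_start` and
#'   `tested_end` (alias `mrna_start`/`mrna_end`).
#' @param L Length of the (un-normalized) mRNA.
#' @return Integer vector of length 100 over \{0, 1\}.
#' @export
matched_score_vector <- function(oms, L) {
  s <- if (!is.null(oms$tested_start)) oms$tested_start else oms$mrna_start
  e <- if (!is.null(oms$tested_end)) oms$tested_end else oms$mrna_end
  v <- integer(100)
  if (is.null(s) || is.na(s)) return(v)
  ks <- normalize_site(s, L)
  ke <- normalize_site(e, L)
  v[ks:ke] <- 1L
  v
}

#' Matched frequency over N score vectors
#'
#' Elementwise mean of the per-pair matched score vectors: the empirical
#' probability that each relative site falls inside an OMS.
#'
#' @param vectors A matrix with one row per pair (100 columns), or a list
#'   of 100-vectors.
#' @return Numeric vector `F` of length 100, values in \[0, 1\].
#' @export
matched_frequency <- function(vectors) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  if (!is.matrix(vectors) || ncol(vectors) != 100L || nrow(vectors) < 1L)
    stop("need at least one 100-bin score vector")
  colMeans(vectors)
}

#' Average matched frequency
#'
#' The dataset constant `<F> = (1/N) * sum_i l_i / L_i`, where `l_i` is
#' the OMS length on the i-th (un-normalized) mRNA and `L_i` the mRNA
#' length. Empty OMSs contribute `l_i = 0`.
#'
#' @param oms_lengths Per-pair OMS lengths on the mRNA.
#' @param mrna_lengths Per-pair mRNA lengths.
#' @return `<F>` in \[0, 1\].
#' @export
average_matched_frequency <- function(oms_lengths, mrna_lengths) {
  if (length(oms_lengths) == 0L) stop("N = 0 pairs")
  if (length(oms_lengths) != length(mrna_lengths))
    stop("length mismatch")
  if (any(oms_lengths > mrna_lengths)) stop("OMS longer than its mRNA")
  mean(oms_lengths / mrna_lengths)
}

#' Relative matched frequency profile
#'
#' `RF(k) = F(k) / <F>`; sites with RF > 1 are preferred interaction
#' positions.
#'
#' @param f 100-bin matched frequency vector.
#' @param avg_f The dataset average `<F>` (must be > 0).
#' @param n_pairs Number of pairs behind `f`.
#' @param scheme_name,orientation Metadata labels.
#' @return An object of class `rf_profile` with fields `bins` (F),
#'   `avg_f`, `rf`, `n_pairs`, `scheme_name`, `orientation`.
#' @export
relative_matched_frequency <- function(f, avg_f, n_pairs = NA_integer_,
                                       scheme_name = NA_character_,
                                       orientation = NA_character_) {
  if (length(f) != 100L) stop("F must have 100 bins")
  if (!is.finite(avg_f) || avg_f <= 0)
    stop("no matched segments: <F> must be positive")
  structure(list(bins = as.numeric(f), avg_f = avg_f,
                 rf = as.numeric(f) / avg_f,
                 n_pairs = n_pairs, scheme_name = scheme_name,
                 orientation = orientation),
            class = "rf_profile")
}

#' @export
print.rf_profile <- function(x, ...) {
  cat(sprintf("<rf_profile %s/%s> N = %s pairs, <F> = %.4f, mean RF = %.4f, max RF = %.2f (bin %d)\n",
              x$scheme_name, x$orientation, x$n_pairs, x$avg_f,
              mean(x$rf), max(x$rf), which.max(x$rf)))
  invisible(x)
}

#' @export
plot.rf_profile <- function(x, ...) {
  graphics::plot(seq_len(100), x$rf, type = "l", xlab = "relative site",
                 ylab = "RF", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' RF profile of an OMS table
#'
#' Runs the full normalization pipeline: per-pair matched score vectors on
#' the 100-bin relative coordinate, their elementwise mean `F`, the
#' dataset constant `<F>`, and `RF = F / <F>`. Because all tested
#' sequences live on the normalized coordinate, `<F>` uses the
#' segment length on that coordinate with `L_i = 100`
#' (`l_i = k_e - k_s + 1`); the mean of RF over the 100 bins is then
#' exactly 1.
#'
#' @param oms A data.frame from [oms_table()] (needs `mrna_start`,
#'   `mrna_end`, `mrna_length`).
#' @return An `rf_profile` object.
#' @export
rf_profile <- function(oms) {
  stopifnot(nrow(oms) >= 1L)
  s <- oms$mrna_start; e <- oms$mrna_end
  L <- oms$mrna_length
  num_s <- 100L * s; num_e <- 100L * e
  ks <- ifelse(num_s %% L == 0L, num_s %/% L, num_s %/% L + 1L)
  ke <- ifelse(num_e %% L == 0L, num_e %/% L, num_e %/% L + 1L)
  vecs <- matrix(0L, nrow(oms), 100L)
  for (i in seq_len(nrow(oms)))
    if (!is.na(ks[i])) vecs[i, ks[i]:ke[i]] <- 1L
  f <- matched_frequency(vecs)
  avg_f <- average_matched_frequency(rowSums(vecs),
                                     rep(100L, nrow(vecs)))
  relative_matched_frequency(
    f, avg_f, n_pairs = nrow(oms),
    scheme_name = if (nrow(oms)) oms$scheme[1] else NA_character_,
    orientation = if (nrow(oms)) oms$orientation[1] else NA_character_)
}

#' Optimal matched regions of an RF profile
#'
#' Maximal runs of consecutive bins with RF strictly greater than 1.
#'
#' @param profile An `rf_profile`, or a bare numeric RF vector.
#' @return A data.frame with `start_bin`, `end_bin`, `peak_rf` (possibly
#'   zero rows).
#' @export
detect_omr <- function(profile) {
  rf <- if (inherits(profile, "rf_profile")) profile$rf else
    as.numeric(profile)
  above <- rf > 1
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    start_bin = starts[keep], end_bin = ends[keep],
    peak_rf = vapply(keep, function(k)
      max(rf[starts[k]:ends[k]]), numeric(1)))
}

site_anchor <- function(model, site_type) {
  switch(site_type,
         AUG = model$cds_start,
         UAA = model$cds_end - 2L,  # first base of the stop codon
         stop("unknown site type: ", site_type))
}

#' Matched-frequency profile around a functional site
#'
#' Un-normalized +/-`window` bp profile anchored at the first base of the
#' start codon (`AUG`), the first base of the stop codon (`UAA`), or an
#' exon-exon junction (`EE_first`, `EE_middle`, `EE_last`; the junction
#' origin is the last base of the upstream exon). For AUG/UAA the
#' UTR-length filter ([utr_site_filter()]) is applied first; every anchor
#' additionally requires the full window inside the mRNA. Each eligible
#' (transcript, intron, anchor) unit contributes one coverage vector;
#' `f(d)` is the fraction of units whose OMS covers `anchor + d`, and
#' `rf(d) = f(d) / <F>` where `<F>` is the average covered fraction
#' ([average_matched_frequency()]) over the distinct
#' pairs contributing to the window.
#'
#' Junction grouping: the first junction of a transcript is `EE_first`,
#' the last is `EE_last`, interior ones are `EE_middle`; a two-exon
#' transcript's single junction counts as both first and last.
#'
#' @param models Named list of transcript models (unfiltered).
#' @param oms A data.frame from [oms_table()] on the same models.
#' @param site_type One of `"AUG"`, `"UAA"`, `"EE_first"`, `"EE_middle"`,
#'   `"EE_last"`.
#' @param window Half-width of the window in bp (default 60).
#' @param intron_class `"all"`, `"long"` or `"short"`.
#' @param min_utr5,min_utr3 UTR filters applied for AUG/UAA anchors.
#' @return An object of class `site_profile`: `site_type`, `offsets`
#'   (-window..window), `f`, `rf`, `avg_f`, `n_units`, `n_pairs`,
#'   `intron_class`.
#' @export
site_profile <- function(models, oms, site_type, window = 60,
                         intron_class = c("all", "long", "short"),
                         min_utr5 = 50, min_utr3 = 80) {
  if (!is.null(models$models)) models <- models$models
  intron_class <- match.arg(intron_class)
  site_type <- match.arg(site_type,
                         c("AUG", "UAA", "EE_first", "EE_middle",
                           "EE_last"))
  if (site_type %in% c("AUG", "UAA"))
    models <- utr_site_filter(models, min_utr5, min_utr3)
  if (intron_class != "all")
    oms <- oms[oms$intron_class == intron_class, , drop = FALSE]
  offsets <- seq.int(-window, window)
  cover <- list()
  pair_key <- character()
  for (m in models) {
    rows <- which(oms$mrna_id == m$transcript_id)
    if (!length(rows)) next
    L <- nchar(m$mrna_seq)
    anchors <- if (site_type %in% c("AUG", "UAA")) {
      site_anchor(m, site_type)
    } else {
      j <- m$ee_junctions
      if (!length(j)) integer(0)
      else switch(site_type,
                  EE_first = j[1],
                  EE_last = j[length(j)],
                  EE_middle = if (length(j) > 2L)
                    j[-c(1L, length(j))] else integer(0))
    }
    anchors <- anchors[anchors - window >= 1L & anchors + window <= L]
    if (!length(anchors)) next
    for (a in anchors) {
      for (r in rows) {
        s <- oms$mrna_start[r]; e <- oms$mrna_end[r]
        pos <- a + offsets
        cover[[length(cover) + 1L]] <-
          if (is.na(s)) integer(length(offsets)) else
            as.integer(s <= pos & pos <= e)
        pair_key <- c(pair_key, oms$intron_id[r])
      }
    }
  }
  if (!length(cover))
    stop("no eligible transcripts for site type ", site_type)
  f <- colMeans(do.call(rbind, cover))
  upairs <- match(unique(pair_key), oms$intron_id)
  l <- ifelse(is.na(oms$mrna_start[upairs]), 0L,
              oms$mrna_end[upairs] - oms$mrna_start[upairs] + 1L)
  avg_f <- average_matched_frequency(l, oms$mrna_length[upairs])
  if (avg_f <= 0) stop("no matched segments in the window pair set")
  structure(list(site_type = site_type, offsets = offsets, f = f,
                 rf = f / avg_f, avg_f = avg_f,
                 n_units = length(cover), n_pairs = length(upairs),
                 intron_class = intron_class),
            class = "site_profile")
}

#' @export
print.site_profile <- function(x, ...) {
  cat(sprintf("<site_profile %s/%s> %d units (%d pairs), <F> = %.4f, peak RF = %.2f at %+d bp\n",
              x$site_type, x$intron_class, x$n_units, x$n_pairs, x$avg_f,
              max(x$rf), x$offsets[which.max(x$rf)]))
  invisible(x)
}

#' Welch t-test between two RF regions
#'
#' Descriptive two-sided Welch test on per-bin (or per-offset) RF values
#' of two named regions, as used for region contrasts. Degenerate input
#' (both samples constant and identical) returns `t = 0`, `p = 1` with a
#' warning rather than an error.
#'
#' @param values_a,values_b Numeric samples (n >= 2 each).
#' @return A list with `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
compare_regions <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (isTRUE(all.equal(mean(values_a), mean(values_b)))) {
      warning("zero-variance identical samples; returning p = 1")
      return(list(t = 0, p = 1, df = NA_real_,
                  mean_a = mean(values_a), mean_b = mean(values_b)))
    }
    warning("zero-variance samples with different means; returning p = 0")
    return(list(t = Inf, p = 0, df = NA_real_,
                mean_a = mean(values_a), mean_b = mean(values_b)))
  }
  tt <- stats::t.test(values_a, values_b)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       mean_a = mean(values_a), mean_b = mean(values_b))
}
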