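# Brute-force local-alignment oracle: DP-free branch-and-bound
# enumeration of all local alignments. Every alignment starts and is
# recorded column by column; branches are cut only with an exact upper
# bound (all remaining columns could be best-scoring pairs), so the
# maximum returned is exact. Gap columns cost gap_open for the first and
# gap_ext for each further column of a run, matching the package's gap
# model.
brute_force_local_score <- function(tested, aligned, scheme) {
  a <- strsplit(toupper(tested), "")[[1]]
  b <- strsplit(toupper(aligned), "")[[1]]
  sm <- scheme$matrix
  sym <- rownames(sm)
  ai <- match(a, sym)
  bi <- match(b, sym)
  stopifnot(!anyNA(ai), !anyNA(bi))
  go <- scheme$gap_open
  ge <- scheme$gap_ext
  maxs <- max(sm)
  n <- length(ai)
  m <- length(bi)
  best <- 0
  rec <- function(i, j, score, last) {
    if (score > best) best <<- score
    bound <- score + maxs * min(n - i, m - j)
    if (bound <= best) return(invisible())
    if (i < n && j < m)
      rec(i + 1L, j + 1L, score + sm[ai[i + 1L], bi[j + 1L]], 0L)
    if (i < n)
      rec(i + 1L, j, score - (if (last == 1L) ge else go), 1L)
    if (j < m)
      rec(i, j + 1L, score - (if (last == 2L) ge else go), 2L)
  }
  # an optimal local alignment can always be trimmed to start (and end)
  # on a positively scoring pair column
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s0 <- sm[ai[i], bi[j]]
      if (s0 > 0) rec(i, j, s0, 0L)
    }
  }
  best
}

random_seq <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# independent reference via Biostrings: EMBOSS-water gap cost
# open + (g-1)*ext corresponds to Biostrings gapOpening = open - ext,
# gapExtension = ext (Biostrings charges opening plus extension for
# every gap column)
biostrings_local_score <- function(tested, aligned, scheme) {
  sm <- scheme$matrix
  storage.mode(sm) <- "double"
  p <- Biostrings::pairwiseAlignment(
    pattern = tested, subject = aligned, type = "local",
    substitutionMatrix = sm,
    gapOpening = scheme$gap_open - scheme$gap_ext,
    gapExtension = scheme$gap_ext)
  Biostrings::score(p)
}
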