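# run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# deterministic sub-seed for component `idx` of a top-level seed, kept
# inside 32-bit integer range
derive_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(idx) * 12289L) %%
               2147483629)
}

#' Composition-constrained shuffle of a sequence
#'
#' Uniform random permutation of the letters: the mononucleotide
#' composition (exact base multiset) is preserved, all positional
#' structure is destroyed. Uses the current RNG stream.
#'
#' @param seq Single nucleotide string.
#' @return The shuffled sequence.
#' @export
cc_shuffle <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  ch <- strsplit(seq, "")[[1]]
  paste(ch[sample.int(length(ch))], collapse = "")
}

cc_shuffle_models <- function(models) {
  lapply(models, function(m) {
    m$mrna_seq <- cc_shuffle(m$mrna_seq)
    m$introns <- vapply(m$introns, cc_shuffle, character(1),
                        USE.NAMES = FALSE)
    m
  })
}

#' Null RF profile from composition-constrained shuffles
#'
#' For each replicate, every mRNA and every intron of the model set is
#' independently shuffled (composition preserved), the full OMS + RF
#' pipeline is re-run, and the per-bin RF values are collected. Each
#' replicate draws from its own RNG stream derived from `(seed,
#' replicate)`, so runs are reproducible and order-independent.
#'
#' @param models Named list of transcript models.
#' @param n_replicates Number of shuffle replicates (default 10).
#' @param seed Top-level seed.
#' @param scheme A [scoring_scheme()] or its name.
#' @param orientation `"complement"` or `"reverse_complement"`.
#' @return A list of class `null_rf`: `rf_mean` and `rf_se` (per-bin mean
#'   and Monte-Carlo standard error of RF across replicates; `rf_se` is
#'   `NA` when `n_replicates = 1`), `f_mean`, `avg_f_mean`, `n_replicates`,
#'   `n_pairs`, `scheme_name`, `orientation`, and `rf_replicates` (the
#'   replicate-by-bin matrix).
#' @export
null_rf_profile <- function(models, n_replicates = 10, seed = 1,
                            scheme = bfe_scheme(),
                            orientation = c("complement",
                                            "reverse_complement")) {
  orientation <- match.arg(orientation)
  scheme <- get_scheme(scheme)
  if (!is.null(models$models)) models <- models$models
  stopifnot(length(models) >= 1L, n_replicates >= 1L)
  rf_mat <- matrix(NA_real_, nrow = n_replicates, ncol = 100)
  f_mat <- matrix(NA_real_, nrow = n_replicates, ncol = 100)
  avg_fs <- numeric(n_replicates)
  n_pairs <- NA_integer_
  for (r in seq_len(n_replicates)) {
    prof <- with_local_seed(derive_seed(seed, r), {
      shuffled <- cc_shuffle_models(models)
      rf_profile(oms_table(shuffled, scheme, orientation))
    })
    rf_mat[r, ] <- prof$rf
    f_mat[r, ] <- prof$bins
    avg_fs[r] <- prof$avg_f
    n_pairs <- prof$n_pairs
  }
  structure(list(
    rf_mean = colMeans(rf_mat),
    rf_se = if (n_replicates > 1L)
      apply(rf_mat, 2, stats::sd) / sqrt(n_replicates) else
        rep(NA_real_, 100),
    f_mean = colMeans(f_mat),
    avg_f_mean = mean(avg_fs),
    n_replicates = n_replicates, n_pairs = n_pairs,
    scheme_name = scheme$name, orientation = orientation,
    rf_replicates = rf_mat),
    class = "null_rf")
}

#' @export
print.null_rf <- function(x, ...) {
  cat(sprintf("<null_rf %s/%s> %d replicates x %d pairs, mean RF = %.4f, max |RF-1| = %.3f\n",
              x$scheme_name, x$orientation, x$n_replicates, x$n_pairs,
              mean(x$rf_mean), max(abs(x$rf_mean - 1))))
  invisible(x)
}
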