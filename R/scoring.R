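#' @useDynLib intronmatch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# IUPAC DNA alphabet used by both built-in substitution matrices.
IUPAC_ALPHABET <- c("A", "T", "G", "C", "S", "W", "R", "Y", "K", "M",
                    "B", "V", "H", "D", "N")

# EDNAFULL / NUC4.4 nucleotide substitution matrix (published integer
# values, row/column order A T G C S W R Y K M B V H D N).
ednafull_matrix <- function() {
  v <- c(
     5, -4, -4, -4, -4,  1,  1, -4, -4,  1, -4, -1, -1, -1, -2,
    -4,  5, -4, -4, -4,  1, -4,  1,  1, -4, -1, -4, -1, -1, -2,
    -4, -4,  5, -4,  1, -4,  1, -4,  1, -4, -1, -1, -4, -1, -2,
    -4, -4, -4,  5,  1, -4, -4,  1, -4,  1, -1, -1, -1, -4, -2,
    -4, -4,  1,  1, -1, -4, -2, -2, -2, -2, -1, -1, -3, -3, -1,
     1,  1, -4, -4, -4, -1, -2, -2, -2, -2, -3, -3, -1, -1, -1,
     1, -4,  1, -4, -2, -2, -1, -4, -2, -2, -3, -1, -3, -1, -1,
    -4,  1, -4,  1, -2, -2, -4, -1, -2, -2, -1, -3, -1, -3, -1,
    -4,  1,  1, -4, -2, -2, -2, -2, -1, -4, -1, -3, -3, -1, -1,
     1, -4, -4,  1, -2, -2, -2, -2, -4, -1, -3, -1, -1, -3, -1,
    -4, -1, -1, -1, -1, -3, -3, -1, -1, -3, -1, -2, -2, -2, -1,
    -1, -4, -1, -1, -1, -3, -1, -3, -3, -1, -2, -1, -2, -2, -1,
    -1, -1, -4, -1, -3, -1, -3, -1, -3, -1, -2, -2, -1, -2, -1,
    -1, -1, -1, -4, -3, -1, -1, -3, -1, -3, -2, -2, -2, -1, -1,
    -2, -2, -2, -2, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1)
  m <- matrix(as.integer(v), nrow = 15, byrow = TRUE,
              dimnames = list(IUPAC_ALPHABET, IUPAC_ALPHABET))
  m
}

# Binding-free-energy weighted matrix, defined in complemented-aligned
# space: after the intron is complemented, a correct A:T (or T:A) base pair
# appears as an identical A/A or T/T column and scores +5; a correct G:C
# (C:G) pair appears as G/G or C/C and scores +6 (the ~2:3 ratio of A:T vs
# G:C pairing energies). Every other column, including any ambiguity
# symbol, scores the mismatch penalty -4.
bfe_matrix <- function() {
  m <- matrix(-4L, nrow = 15, ncol = 15,
              dimnames = list(IUPAC_ALPHABET, IUPAC_ALPHABET))
  m["A", "A"] <- 5L
  m["T", "T"] <- 5L
  m["G", "G"] <- 6L
  m["C", "C"] <- 6L
  m
}

#' Alignment scoring schemes
#'
#' A scoring scheme bundles a pair-score (substitution) matrix over the
#' IUPAC DNA alphabet with affine gap penalties. A gap of length `g` costs
#' `gap_open + (g - 1) * gap_ext` (EMBOSS `water` semantics). Two built-ins
#' are provided:
#'
#' * `sw_scheme()` — the classic EDNAFULL (NUC4.4) matrix: +5 for a match,
#'   -4 for an A/C/G/T mismatch, published integer scores for ambiguity
#'   codes.
#' * `bfe_scheme()` — binding-free-energy weighting: A:T base pairs score
#'   +5, G:C base pairs +6, any wrong pairing -4. Because alignment runs
#'   against the *complemented* intron, these appear as identity scores in
#'   the matrix.
#'
#' Both built-ins use `gap_open = 50`, `gap_ext = 5`, which effectively
#' forbids gaps in short matched segments.
#'
#' @param name Label for a custom scheme.
#' @param matrix Integer substitution matrix with identical row and column
#'   names (single-character symbols).
#' @param gap_open Non-negative penalty for the first column of a gap.
#' @param gap_ext Non-negative penalty per additional gap column.
#' @return An object of class `scoring_scheme`.
#' @examples
#' bfe <- bfe_scheme()
#' pair_score(bfe, "A", "A")  # complemented-space A:T pair -> 5
#' pair_score(bfe, "G", "G")  # G:C pair -> 6
#' pair_score(bfe, "A", "C")  # mismatch -> -4
#' @export
scoring_scheme <- function(name, matrix, gap_open = 50, gap_ext = 5) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix) ||
      is.null(rownames(matrix)) ||
      !identical(rownames(matrix), colnames(matrix)))
    stop("`matrix` must be square with identical row/col names")
  if (any(nchar(rownames(matrix)) != 1L))
    stop("matrix symbols must be single characters")
  if (gap_open < 0 || gap_ext < 0)
    stop("gap penalties must be non-negative")
  storage.mode(matrix) <- "integer"
  structure(list(name = name, matrix = matrix,
                 gap_open = as.integer(gap_open),
                 gap_ext = as.integer(gap_ext),
                 alphabet = paste(rownames(matrix), collapse = "")),
            class = "scoring_scheme")
}

#' @rdname scoring_scheme
#' @export
bfe_scheme <- function() scoring_scheme("BFE", bfe_matrix())

#' @rdname scoring_scheme
#' @export
sw_scheme <- function() scoring_scheme("SW", ednafull_matrix())

#' Look up a scheme by name
#'
#' @param name `"BFE"` or `"SW"` (case-insensitive).
#' @return A `scoring_scheme`.
#' @export
get_scheme <- function(name) {
  if (inherits(name, "scoring_scheme")) return(name)
  switch(toupper(name),
         BFE = bfe_scheme(),
         SW = sw_scheme(),
         stop("unknown scoring scheme: ", name))
}

#' @rdname scoring_scheme
#' @param scheme A `scoring_scheme`.
#' @param x,y Single symbols (characters) to score as one aligned column.
#' @export
pair_score <- function(scheme, x, y) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  m <- scheme$matrix
  if (!(x %in% rownames(m)) || !(y %in% rownames(m)))
    stop("symbol outside scheme alphabet")
  as.numeric(m[x, y])
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme '%s'>: %d-letter alphabet, gap open %d, gap extend %d\n",
              x$name, nrow(x$matrix), x$gap_open, x$gap_ext))
  invisible(x)
}
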