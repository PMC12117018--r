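# Shared low-level helpers: local RNG scoping, DNA string utilities and the
# one-hot trick for fast pairwise Hamming distances.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG seed
#'
#' All stochastic functions in the package take an explicit integer `seed`.
#' When it is non-NULL the global RNG state is saved, the seed applied, and
#' the previous state restored afterwards, so seeded calls never perturb the
#' caller's random stream.
#'
#' @param seed integer seed or NULL (use the current RNG stream).
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Uniformly random DNA sequences
#' @param n number of sequences.
#' @param len sequence length in bases.
#' @return Character vector of `n` sequences over A/C/G/T.
#' @keywords internal
#' @noRd
random_dna <- function(n, len) {
  if (n == 0L) {
    return(character(0))
  }
  m <- matrix(sample(DNA_BASES, as.double(n) * len, replace = TRUE), nrow = n)
  do.call(paste0, lapply(seq_len(len), function(j) m[, j]))
}

# Encode equal-length sequences as an integer matrix (A=1, C=2, G=3, T=4);
# non-ACGT characters become NA.
seq_to_int_matrix <- function(x) {
  len <- unique(nchar(x))
  if (length(len) != 1L) {
    stop("all sequences must have equal length")
  }
  matrix(match(unlist(strsplit(x, "", fixed = TRUE)), DNA_BASES),
         nrow = length(x), ncol = len, byrow = TRUE)
}

# Minimum off-diagonal pairwise Hamming distance of the rows of an integer
# base matrix, via one-hot cross-products (4 dense matrix multiplications
# instead of n^2 string comparisons).
min_pairwise_hamming <- function(mat) {
  n <- nrow(mat)
  if (n < 2L) {
    stop("need at least two sequences")
  }
  L <- ncol(mat)
  matches <- matrix(0, n, n)
  for (b in 1:4) {
    ind <- (mat == b) * 1
    matches <- matches + tcrossprod(ind)
  }
  d <- L - matches
  diag(d) <- Inf
  min(d)
}

#' Hamming distance between equal-length sequences
#'
#' Number of mismatching positions between two strings. Vectorized over
#' pairs; shorter arguments are recycled.
#'
#' @param a,b character vectors of sequences.
#' @return Integer vector of distances.
#' @examples
#' hamming_distance("ACGT", "TGCA")
#' @export
hamming_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  if (any(nchar(a) != nchar(b))) {
    stop("sequences must have equal length")
  }
  out <- integer(n)
  for (i in seq_len(n)) {
    out[i] <- sum(utf8ToInt(a[i]) != utf8ToInt(b[i]))
  }
  out
}

# Reverse complement for plain character vectors.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
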