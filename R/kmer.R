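# Length-invariant k-mer composition features with Gaussian random projection.
#
# A protein sequence over the 25-letter alphabet is scanned with a sliding
# window of size k (default 3), giving a count vector over the 25^3 = 15,625
# possible 3-mers; normalizing by the total count yields a frequency vector
# that sums to 1 regardless of sequence length. A random matrix with i.i.d.
# N(0, 1/d) entries compresses it to d dimensions while approximately
# preserving pairwise distances (Johnson-Lindenstrauss).

.kmer <- new.env(parent = emptyenv())
.kmer$cache <- new.env(parent = emptyenv())

#' Enumerate the k-mer vocabulary
#'
#' All alphabet^k strings in lexicographic order with respect to the alphabet's
#' own symbol order; this order defines the coordinate system of the count and
#' frequency vectors.
#'
#' @param k word length.
#' @param alphabet string of distinct symbols (default [PROTEIN_ALPHABET]).
#' @return character vector of length `nchar(alphabet)^k`.
#' @export
kmer_vocabulary <- function(k = 3L, alphabet = PROTEIN_ALPHABET) {
  syms <- strsplit(alphabet, "")[[1]]
  grid <- do.call(expand.grid,
                  c(rep(list(syms), k), stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste0, collapse = "")
}

#' Count k-mers in a sequence
#'
#' Sliding window of size `k`; the count vector is indexed by the
#' lexicographic vocabulary of [kmer_vocabulary()]. Characters outside the
#' alphabet count as the catch-all X. Total count equals
#' `nchar(sequence) - k + 1`.
#'
#' @param sequence amino-acid string with `nchar >= k`.
#' @param k word length (default 3).
#' @param alphabet symbol set (default the 25-letter protein alphabet).
#' @return integer vector of length `alphabet^k`.
#' @export
count_kmers <- function(sequence, k = 3L, alphabet = PROTEIN_ALPHABET) {
  A <- nchar(alphabet)
  syms <- strsplit(alphabet, "")[[1]]
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  if (n < k)
    stop(sprintf("count_kmers: sequence length %d < k = %d (minimum length %d)",
                 n, k, k))
  idx <- match(chars, syms)
  idx[is.na(idx)] <- A  # catch-all = last symbol
  idx <- idx - 1L
  # polynomial code of each window, first character most significant
  code <- integer(n - k + 1L)
  for (j in seq_len(k)) code <- code * A + idx[j:(n - k + j)]
  tabulate(code + 1L, nbins = A^k)
}

#' Normalize k-mer counts to frequencies
#'
#' Divides by the total count so the vector sums to 1, making the
#' representation invariant to sequence length.
#'
#' @param counts nonnegative count vector with a positive total.
#' @return numeric frequency vector of the same length.
#' @export
normalize_counts <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("normalize_counts: all counts are zero")
  counts / total
}

#' Normalized k-mer frequency vector of a sequence
#' @inheritParams count_kmers
#' @return frequency vector of length `alphabet^k`, cached per sequence.
#' @export
kmer_frequencies <- function(sequence, k = 3L, alphabet = PROTEIN_ALPHABET) {
  key <- paste0(k, ":", sequence)
  if (exists(key, envir = .kmer$cache)) return(get(key, envir = .kmer$cache))
  f <- normalize_counts(count_kmers(sequence, k, alphabet))
  assign(key, f, envir = .kmer$cache)
  f
}

#' Gaussian random projection matrix
#'
#' Entries i.i.d. N(0, 1/d); the same seed always reproduces the same matrix,
#' and the seed is stored in model checkpoints so inference regenerates the
#' training-time projection.
#'
#' @param D input dimension; @param d target dimension (1 <= d <= D);
#' @param seed integer RNG seed.
#' @return D x d numeric matrix.
#' @export
make_projection <- function(D, d, seed = 1L) {
  if (d < 1 || D < 1) stop("make_projection: dimensions must be positive")
  if (D < d) stop("make_projection: target dimension d exceeds input D")
  with_seed(seed, function() matrix(stats::rnorm(D * d, 0, sqrt(1 / d)), D, d))
}

#' Project a frequency vector
#' @param frequencies numeric vector of length `nrow(R)`.
#' @param R projection matrix from [make_projection()].
#' @return numeric vector of length `ncol(R)`.
#' @export
project_kmer <- function(frequencies, R) {
  if (length(frequencies) != nrow(R))
    stop(sprintf("project_kmer: length(frequencies) = %d but nrow(R) = %d",
                 length(frequencies), nrow(R)))
  as.numeric(matrix(frequencies, 1L) %*% R)
}

#' Export a k-mer vector as sparse triplets
#' @param frequencies k-mer frequency vector.
#' @param path output TSV path (columns: index, kmer, frequency).
#' @param k,alphabet vocabulary parameters used for naming.
#' @export
export_kmer_sparse <- function(frequencies, path, k = 3L,
                               alphabet = PROTEIN_ALPHABET) {
  nz <- which(frequencies > 0)
  vocab <- kmer_vocabulary(k, alphabet)
  utils::write.table(
    data.frame(index = nz, kmer = vocab[nz], frequency = frequencies[nz]),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Sparse B x 25^k matrix of cached k-mer frequencies for a set of sequences.
kmer_matrix <- function(sequences, k = 3L, alphabet = PROTEIN_ALPHABET) {
  A <- nchar(alphabet)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (b in seq_along(sequences)) {
    f <- kmer_frequencies(sequences[b], k, alphabet)
    nz <- which(f > 0)
    ii <- c(ii, rep(b, length(nz))); jj <- c(jj, nz); xx <- c(xx, f[nz])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(sequences), A^k))
}
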