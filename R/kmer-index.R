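# Integer encoding of DNA and canonical k-mer indexing.
#
# Sequences are encoded base-per-base as 0..3 (A,C,G,T); N (and any masked
# base) becomes NA and poisons every k-mer window it touches, so masked
# positions never contribute features or motif matches. A k-mer maps to the
# integer sum codes[t] * 4^(k-1-t); for k <= 12 these ids fit comfortably in
# a 32-bit integer (4^12 = 16,777,216).

BASE_CODES <- local({
  v <- rep(NA_integer_, 256)
  v[utf8ToInt("A")] <- 0L; v[utf8ToInt("C")] <- 1L
  v[utf8ToInt("G")] <- 2L; v[utf8ToInt("T")] <- 3L
  v
})

seq_to_codes <- function(seq) {
  BASE_CODES[utf8ToInt(seq)]
}

codes_to_seq <- function(codes) {
  paste(c("A", "C", "G", "T")[codes + 1L], collapse = "")
}

# All k-mer ids along a code vector; element i is the id of the k-mer
# starting at position i (1-based); NA where the window contains N.
kmer_ids <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(integer(0))
  m <- embed(codes, k)          # row i = codes[i+k-1], ..., codes[i]
  as.integer(m %*% 4^(seq_len(k) - 1L))
}

# Reverse-complement of k-mer ids, computed digit-wise (vectorized).
revcomp_ids <- function(ids, k) {
  out <- numeric(length(ids))
  x <- as.numeric(ids)
  for (t in seq_len(k) - 1L) {           # t = exponent of the source digit
    digit <- (x %/% 4^t) %% 4
    out <- out + (3 - digit) * 4^(k - 1L - t)
  }
  as.integer(out)
}

kmer_to_id <- function(words) {
  vapply(words, function(w) {
    codes <- seq_to_codes(w)
    if (anyNA(codes)) return(NA_integer_)
    as.integer(sum(codes * 4^(rev(seq_along(codes)) - 1L)))
  }, integer(1), USE.NAMES = FALSE)
}

id_to_kmer <- function(ids, k) {
  vapply(as.numeric(ids), function(x) {
    digits <- (x %/% 4^((k - 1L):0)) %% 4
    codes_to_seq(as.integer(digits))
  }, character(1))
}

#' Number of canonical k-mers
#'
#' Size of the reverse-complement-collapsed k-mer feature space for even k:
#' \eqn{(4^k - 4^{k/2})/2 + 4^{k/2}} (non-palindromic pairs collapse,
#' reverse-complement palindromes stand alone). For the default k = 8 this
#' is 32,896.
#'
#' @param k Even word length >= 2.
#' @return Integer count.
#' @export
count_canonical_kmers <- function(k) {
  if (k < 2 || k %% 2 != 0) stop("only even k >= 2 is supported")
  as.integer((4^k - 4^(k / 2)) / 2 + 4^(k / 2))
}

#' Canonical form of k-mers
#'
#' The canonical form of a word is the lexicographic minimum of the word and
#' its reverse complement, giving strand-neutral k-mer features. Words
#' containing \code{N} are not indexable and return \code{NA}.
#'
#' @param kmer Character vector of equal-length words over A,C,G,T (N
#'   tolerated, yields NA).
#' @return Character vector of canonical words (NA where skipped).
#' @export
canonical_kmer <- function(kmer) {
  if (length(kmer) == 0L) return(character(0))
  has_n <- grepl("N", kmer, fixed = TRUE)
  out <- rep(NA_character_, length(kmer))
  ok <- !has_n
  if (any(ok)) {
    rc <- revcomp(kmer[ok])
    out[ok] <- pmin(kmer[ok], rc)
  }
  out
}

# Cached canonical index per k: maps every k-mer id to a feature column.
.kmer_index_cache <- new.env(parent = emptyenv())

#' Canonical k-mer index
#'
#' Builds (and caches) the bijection between canonical k-mers and feature
#' columns for even k. Column order is by increasing canonical k-mer id,
#' i.e. lexicographic in the canonical word.
#'
#' @param k Even word length (default 8, practical up to 10).
#' @return List with elements \code{k}, \code{n_features},
#'   \code{canon_col} (integer vector of length 4^k mapping id+1 to column)
#'   and \code{kmers} (canonical word per column).
#' @export
kmer_index <- function(k = 8L) {
  if (k < 2 || k %% 2 != 0) stop("only even k >= 2 is supported")
  if (k > 10) stop("index table too large for k > 10")
  key <- as.character(k)
  if (!is.null(.kmer_index_cache[[key]])) return(.kmer_index_cache[[key]])
  ids <- 0:(4^k - 1)
  canon <- pmin(ids, revcomp_ids(ids, k))
  cols <- match(canon, sort(unique(canon)))
  idx <- list(k = as.integer(k),
              n_features = length(unique(canon)),
              canon_col = as.integer(cols),
              kmers = id_to_kmer(sort(unique(canon)), k))
  stopifnot(idx$n_features == count_canonical_kmers(k))
  .kmer_index_cache[[key]] <- idx
  idx
}

# Canonical feature-column indices for one sequence (NA windows dropped).
seq_feature_cols <- function(seq, index) {
  if (nchar(seq) < index$k) stop("sequence shorter than k")
  ids <- kmer_ids(seq_to_codes(seq), index$k)
  cols <- index$canon_col[ids + 1L]
  cols[!is.na(cols)]
}

#' k-mer spectrum feature vector
#'
#' Raw occurrence counts of every canonical k-mer over all positions of a
#' sequence (overlapping windows; windows containing N are skipped; no
#' normalization, so a classifier score decomposes exactly into a positional
#' weight sum).
#'
#' @param seq A single sequence.
#' @param index A \code{\link{kmer_index}}.
#' @return Sparse numeric vector (\code{Matrix::sparseVector}) of length
#'   \code{index$n_features}.
#' @export
feature_vector <- function(seq, index = kmer_index()) {
  cols <- seq_feature_cols(seq, index)
  counts <- tabulate(cols, nbins = index$n_features)
  nz <- which(counts > 0L)
  Matrix::sparseVector(x = as.numeric(counts[nz]), i = nz,
                       length = index$n_features)
}

#' k-mer spectrum feature matrix
#'
#' Stacks \code{\link{feature_vector}} counts for many sequences into a
#' sparse matrix (rows = sequences, columns = canonical k-mers).
#'
#' @param seqs Character vector of sequences.
#' @param index A \code{\link{kmer_index}}.
#' @return \code{dgCMatrix} of dimension \code{length(seqs) x n_features}.
#' @export
feature_matrix <- function(seqs, index = kmer_index()) {
  triplets <- lapply(seq_along(seqs), function(i) {
    cols <- seq_feature_cols(seqs[[i]], index)
    if (length(cols) == 0L) return(NULL)
    tab <- tabulate(cols, nbins = index$n_features)
    nz <- which(tab > 0L)
    cbind(i = i, j = nz, x = tab[nz])
  })
  tr <- do.call(rbind, triplets)
  if (is.null(tr)) tr <- cbind(i = integer(0), j = integer(0), x = numeric(0))
  Matrix::sparseMatrix(i = tr[, "i"], j = tr[, "j"], x = as.numeric(tr[, "x"]),
                       dims = c(length(seqs), index$n_features))
}
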