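#' All k-mers over \{A,C,G,T\} in lexicographic order
#'
#' @param k k-mer length.
#' @return character vector of length 4^k.
#' @export
kmer_alphabet <- function(k) {
  stopifnot(k >= 1)
  mkAllStrings <- Biostrings::mkAllStrings
  sort(mkAllStrings(c("A", "C", "G", "T"), k))
}

#' Count overlapping k-mers on the given strand
#'
#' Counts every overlapping window of length k; windows containing N
#' contribute to no k-mer. No reverse-complement collapsing: genomes are
#' used as given. When the sequence is N-free the counts sum to
#' L - k + 1.
#'
#' @param seq a nucleotide string (or \link[Biostrings]{DNAString}) over
#'   \{A,C,G,T,N\}.
#' @param k k-mer length; must not exceed the sequence length.
#' @return named integer vector of length 4^k in lexicographic k-mer
#'   order.
#' @export
count_kmers <- function(seq, k) {
  dna <- as_dna(seq)
  if (k < 1) stop("k must be >= 1")
  if (length(dna) < k) stop("k larger than sequence length")
  cnt <- Biostrings::oligonucleotideFrequency(dna, width = k, step = 1)
  cnt[order(names(cnt))]
}

#' @keywords internal
as_dna <- function(seq) {
  if (is(seq, "DNAString")) return(seq)
  Biostrings::DNAString(toupper(as.character(seq)))
}

#' Per-base nucleotide probabilities
#'
#' \eqn{p_i} = count of base i / number of non-N bases, estimated from
#' the sequence itself. N is excluded from the denominator.
#'
#' @param seq a nucleotide string over \{A,C,G,T,N\}.
#' @return named numeric vector (A, C, G, T) summing to 1.
#' @export
nucleotide_probs <- function(seq) {
  dna <- as_dna(seq)
  freq <- Biostrings::alphabetFrequency(dna)[c("A", "C", "G", "T")]
  tot <- sum(freq)
  if (tot == 0) stop("sequence has no unambiguous bases")
  freq / tot
}

#' Modified k-mer frequency of a genome
#'
#' The observed count of each k-mer w is corrected by its chance
#' expectation under the sequence's own base composition:
#' \deqn{f_m(w) = f_o(w) - f_c(w), \quad
#'       f_c(w) = P_w \{L - (k-1)\}, \quad
#'       P_w = \prod_{i=1}^{k} p_i}
#' where \eqn{f_o} is the overlapping-window count, \eqn{p_i} the
#' probability of the i-th base of w in the sequence, and L the number of
#' unambiguous (non-N) bases. This removes the length and composition
#' bias of raw counts; for an N-free sequence the entries sum to zero
#' exactly, since the window counts sum to L-k+1 and the \eqn{P_w} sum
#' to 1.
#'
#' @param seq nucleotide string over \{A,C,G,T,N\}.
#' @param k k-mer length (default 6).
#' @return object of class \code{"kmer_features"}: numeric vector of
#'   length 4^k (lexicographic k-mer order) with attributes \code{k} and
#'   \code{L}.
#' @export
modified_frequency <- function(seq, k = 6) {
  fo <- count_kmers(seq, k)
  p <- nucleotide_probs(seq)
  L <- sum(Biostrings::alphabetFrequency(as_dna(seq))[c("A","C","G","T")])
  # P_w as the outer product of per-position marginals, in lexicographic
  # order: position 1 varies slowest.
  pw <- Reduce(function(acc, i) as.vector(outer(acc, p)), seq_len(k),
               accumulate = FALSE, init = 1)
  names(pw) <- NULL
  fm <- as.numeric(fo) - pw * (L - (k - 1))
  structure(setNames(fm, names(fo)), k = k, L = L,
            class = "kmer_features")
}

#' @export
print.kmer_features <- function(x, ...) {
  cat("modified k-mer frequencies: k =", attr(x, "k"),
      " dim =", length(x), " L =", attr(x, "L"), "\n")
  print(head(unclass(x), 8))
  invisible(x)
}

#' Modified k-mer feature matrix for a genome collection
#'
#' @param genomes named \link[Biostrings]{DNAStringSet}.
#' @param k k-mer length (default 6).
#' @return numeric matrix, one row per genome (rownames = IDs), one
#'   column per k-mer in lexicographic order.
#' @export
kmer_feature_matrix <- function(genomes, k = 6) {
  feats <- t(vapply(seq_along(genomes),
                    function(i) as.numeric(modified_frequency(genomes[[i]], k)),
                    numeric(4^k)))
  dimnames(feats) <- list(names(genomes), kmer_alphabet(k))
  feats
}

#' Write / read a feature matrix as TSV
#'
#' Dense numeric table, header row of k-mers, one row per genome ID;
#' meant for inspection and cross-implementation comparison.
#'
#' @param m feature matrix from \code{\link{kmer_feature_matrix}}.
#' @param path output TSV path.
#' @return \code{path} (write) or the matrix (read), invisibly for write.
#' @export
write_feature_matrix <- function(m, path) {
  write.table(data.frame(id = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}
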