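#' Canonical k-mer hashing
#'
#' Hashes each k-mer under strand canonicalization: the lexicographically
#' smaller of the 2-bit encodings (A<C<G<T) of the k-mer and its reverse
#' complement is passed through a fixed invertible 64-bit mixer. A k-mer and
#' its reverse complement therefore share a hash; the strand flag records
#' which orientation won. Invertibility makes the map from canonical k-mers
#' to hashes a bijection.
#'
#' @param kmers Character vector of equal-length A/C/G/T strings (length
#'   1..31). K-mers containing any other character are ambiguous.
#' @return A data.frame with columns `hash` (16-digit lowercase hex string;
#'   `NA` for ambiguous k-mers) and `strand` (0 forward, 1 reverse).
#' @export
#' @examples
#' canonical_kmer_hash(c("ACGTACGTACGTACG", "CGTACGTACGTACGT"))
canonical_kmer_hash <- function(kmers) {
  stopifnot(is.character(kmers), length(kmers) >= 1)
  res <- .kmer_hash_cpp(kmers)
  data.frame(hash = res$hash, strand = res$strand, stringsAsFactors = FALSE)
}

#' FracMinHash selection predicate
#'
#' Selects a hash iff `h < floor(2^64 / rate)`, i.e. the hash falls in the
#' lowest `1/rate` fraction of the 64-bit range. The predicate is pointwise:
#' whether a k-mer is selected never depends on any other k-mer, so a
#' genome's selected set is a subset-stable sample.
#'
#' @param hash Character vector of 16-digit hex hashes (as produced by
#'   [canonical_kmer_hash()]).
#' @param rate Subsampling rate `gamma >= 1`; expected selected fraction is
#'   `1/rate`. `rate = 1` selects everything.
#' @return Logical vector (`NA` where `hash` is `NA`).
#' @export
fracminhash_select <- function(hash, rate) {
  stopifnot(is.numeric(rate), length(rate) == 1, rate >= 1)
  .fmh_select_cpp(as.character(hash), as.double(rate))
}
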