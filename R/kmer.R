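#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings over A/C/G/T (case-insensitive).
#' @return character vector of reverse complements, uppercased.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(x) {
  x <- toupper(x)
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Canonical form of a k-mer
#'
#' The canonical form is the lexicographically smaller of a k-mer and its
#' reverse complement, so that both strands of a sequence yield the same
#' k-mer content.
#'
#' @param kmer a single DNA string over A/C/G/T.
#' @return the canonical k-mer (uppercase).
#' @examples
#' canonical_form("TTT")  # "AAA"
#' @export
canonical_form <- function(kmer) {
  kmer <- toupper(kmer)
  if (grepl("[^ACGT]", kmer)) {
    stop(structure(
      class = c("readscreen_invalid_kmer", "error", "condition"),
      list(message = sprintf("k-mer contains non-ACGT characters: %s", kmer),
           call = sys.call(-1))))
  }
  rc <- revcomp(kmer)
  if (rc < kmer) rc else kmer
}

#' Extract canonical k-mer records from a sequence
#'
#' Slides a window of width `k` over the sequence; every window made only of
#' A/C/G/T yields one record with its 0-based start position, canonical
#' k-mer, and seeded hash. Windows containing any other character (e.g. N)
#' are skipped.
#'
#' @param sequence a single DNA string.
#' @param k k-mer length (1--31).
#' @param hash_seed integer seed for the hash function.
#' @param identity logical; if `TRUE` the hash is the 2-bit encoding of the
#'   canonical k-mer (A=0, C=1, G=2, T=3, big-endian), exact for `k <= 26`
#'   and intended for brute-force verification only.
#' @return a data.frame with columns `position`, `canon`, `hash`, ordered by
#'   position. Sequences shorter than `k` give zero rows.
#' @export
extract_kmers <- function(sequence, k, hash_seed = 0L, identity = FALSE) {
  stopifnot(length(sequence) == 1L, k >= 1)
  sequence <- toupper(sequence)
  sc <- kmer_scan_cpp(sequence, as.integer(k), as.double(hash_seed), identity)
  if (length(sc$pos) == 0L) {
    return(data.frame(position = integer(0), canon = character(0),
                      hash = numeric(0)))
  }
  fw <- substring(sequence, sc$pos + 1L, sc$pos + k)
  rc <- revcomp(fw)
  data.frame(position = sc$pos,
             canon = ifelse(rc < fw, rc, fw),
             hash = sc$hash)
}

#' Hash one canonical k-mer
#'
#' @param canon a canonical k-mer (the function canonicalizes its input, so
#'   an already-canonical k-mer hashes to itself).
#' @inheritParams extract_kmers
#' @return a hash value as a double (integral, < 2^53).
#' @export
hash_kmer <- function(canon, hash_seed = 0L, identity = FALSE) {
  sc <- kmer_scan_cpp(toupper(canon), nchar(canon), as.double(hash_seed),
                      identity)
  sc$hash[1L]
}

# hash values (pos + hash) for one sequence, production path: no strings
seq_hashes <- function(sequence, params) {
  kmer_scan_cpp(toupper(sequence), as.integer(params$k),
                as.double(params$hash_seed), isTRUE(params$identity_hash))
}
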