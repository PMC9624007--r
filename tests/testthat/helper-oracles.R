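# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own primitives (no revcomp()/extract_kmers() calls)
# so that agreement is meaningful.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_canonical <- function(kmer) {
  rc <- oracle_revcomp(kmer)
  if (rc < kmer) rc else kmer
}

# double-loop canonical k-mer extraction; returns data.frame(position, canon)
oracle_kmers <- function(seq, k) {
  pos <- integer(0); canon <- character(0)
  n <- nchar(seq)
  if (n >= k) {
    for (i in 0:(n - k)) {
      w <- substr(seq, i + 1, i + k)
      if (!grepl("[^ACGT]", w)) {
        pos <- c(pos, i)
        canon <- c(canon, oracle_canonical(w))
      }
    }
  }
  data.frame(position = pos, canon = canon)
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_kmer <- function(k) rand_seq(k)

# identity-hash parameters for exact brute-force comparisons
id_params <- function(k, read_length = max(k, 100), seed = 0L) {
  screen_params(k = k, read_length = read_length, error_rate = 0,
                target_matches = 10L, hash_seed = seed,
                identity_hash = TRUE)
}

# 2-bit big-endian encoding oracle for identity hashing
oracle_encode <- function(kmer) {
  v <- c(A = 0, C = 1, G = 2, T = 3)[strsplit(kmer, "")[[1]]]
  sum(v * 4^(rev(seq_along(v)) - 1))
}
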