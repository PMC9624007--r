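# Synthetic communities and long-read simulation with ground truth.

BASES <- c("A", "C", "G", "T")
BASE_CODES <- utf8ToInt("ACGT")

random_genome <- function(n) {
  intToUtf8(BASE_CODES[sample.int(4L, n, replace = TRUE)])
}

# substitute each position independently with probability d; substitutions
# always change the base (uniform over the other three)
mutate_sequence <- function(seq, d) {
  codes <- utf8ToInt(seq)
  hit <- which(runif(length(codes)) < d)
  if (length(hit)) {
    cur <- match(codes[hit], BASE_CODES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    codes[hit] <- BASE_CODES[((cur - 1L + shift) %% 4L) + 1L]
  }
  list(seq = intToUtf8(codes), n_sub = length(hit))
}

#' Specification of a synthetic community
#'
#' Describes a community of uniform-random genomes, optionally containing
#' clusters of highly similar genomes: each cluster's members are
#' independent mutants of a shared random ancestor at a controlled per-base
#' divergence. Singletons emulate an easy, mutually dissimilar community;
#' clusters emulate the hard case where near-identical genomes force ties.
#'
#' @param n_genomes total number of genomes.
#' @param genome_length genome length in bp (single contig each).
#' @param n_clusters number of similar-genome clusters (0 for none).
#' @param cluster_size members per cluster (`n_clusters * cluster_size <=
#'   n_genomes`; the remainder are singletons).
#' @param within_cluster_divergence per-base substitution probability
#'   between a cluster member and the ancestor, in \[0, 0.5). Two members at
#'   divergence d share a fraction of about `(1-d)^(2k)` of their k-mers.
#' @param rng_seed integer seed.
#' @return an object of class `community_spec`.
#' @export
community_spec <- function(n_genomes, genome_length, n_clusters = 0L,
                           cluster_size = 2L,
                           within_cluster_divergence = 0,
                           rng_seed = 1L) {
  if (n_clusters * cluster_size > n_genomes)
    stop("n_clusters * cluster_size must be <= n_genomes")
  if (within_cluster_divergence < 0 || within_cluster_divergence >= 0.5)
    stop("within_cluster_divergence must be in [0, 0.5)")
  structure(list(n_genomes = as.integer(n_genomes),
                 genome_length = as.integer(genome_length),
                 n_clusters = as.integer(n_clusters),
                 cluster_size = as.integer(cluster_size),
                 within_cluster_divergence =
                   as.numeric(within_cluster_divergence),
                 rng_seed = as.integer(rng_seed)),
            class = "community_spec")
}

#' Generate a synthetic community
#'
#' Singleton genomes are independent i.i.d. uniform ACGT sequences; cluster
#' members are generated by mutating a common random ancestor at the
#' specified divergence (substitutions only). The manifest records each
#' genome's cluster, ancestor and divergence.
#'
#' @param spec a [community_spec].
#' @return a list with `genomes` (named character vector, deterministic for
#'   a given spec) and `manifest` (data.frame: `genome_id`, `cluster`,
#'   `divergence`, `length`; `cluster` is `NA` for singletons).
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$rng_seed)
  genomes <- character(0)
  manifest <- list()
  for (cl in seq_len(spec$n_clusters)) {
    ancestor <- random_genome(spec$genome_length)
    for (m in seq_len(spec$cluster_size)) {
      id <- sprintf("cluster%02d_m%d", cl, m)
      # the first member is the ancestor itself, so a pair at divergence d
      # is separated by d (not 2d) substitutions per base
      genomes[[id]] <- if (m == 1L) ancestor else
        mutate_sequence(ancestor, spec$within_cluster_divergence)$seq
      manifest[[id]] <- data.frame(
        genome_id = id, cluster = cl,
        divergence = if (m == 1L) 0 else spec$within_cluster_divergence)
    }
  }
  n_single <- spec$n_genomes - spec$n_clusters * spec$cluster_size
  for (i in seq_len(n_single)) {
    id <- sprintf("genome%02d", i)
    genomes[[id]] <- random_genome(spec$genome_length)
    manifest[[id]] <- data.frame(genome_id = id, cluster = NA_integer_,
                                 divergence = 0)
  }
  manifest <- do.call(rbind, manifest)
  manifest$length <- spec$genome_length
  rownames(manifest) <- NULL
  list(genomes = genomes, manifest = manifest)
}

#' Simulate long reads with uniformly placed substitution errors
#'
#' Draws reads of fixed length from uniform random start positions and
#' strands, then substitutes each base independently with probability
#' `error_rate` (errors are introduced after strand selection, i.e. on the
#' read as sequenced). Ground truth (source genome, start, strand, number
#' of injected errors) is recorded per read.
#'
#' @param genomes named character vector of genome sequences.
#' @param read_length read length R in bp (must not exceed any genome).
#' @param error_rate per-base substitution probability in \[0, 1).
#' @param coverage target coverage c; each genome yields
#'   `round(c * n / R)` reads. Ignored when `n_reads_per_genome` is given.
#' @param n_reads_per_genome explicit per-genome read count.
#' @param seed integer seed.
#' @return a list with `reads` (named character vector) and `truth`
#'   (data.frame: `read_id`, `genome_id`, `start` 0-based, `strand`,
#'   `n_errors`).
#' @export
simulate_reads <- function(genomes, read_length = 10000L, error_rate = 0.01,
                           coverage = 10, n_reads_per_genome = NULL,
                           seed = 1L) {
  stopifnot(error_rate >= 0, error_rate < 1)
  lens <- nchar(genomes)
  if (any(read_length > lens))
    stop("read_length exceeds a genome's length")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  reads <- character(0)
  truth <- list()
  for (g in names(genomes)) {
    n <- lens[[g]]
    nr <- if (is.null(n_reads_per_genome))
      round(coverage * n / read_length) else n_reads_per_genome
    if (nr < 1L) next
    starts <- sample.int(n - read_length + 1L, nr, replace = TRUE) - 1L
    strands <- sample(c("+", "-"), nr, replace = TRUE)
    for (i in seq_len(nr)) {
      rid <- sprintf("%s_read%04d", g, i)
      sq <- substr(genomes[[g]], starts[i] + 1L, starts[i] + read_length)
      if (strands[i] == "-") sq <- revcomp(sq)
      mut <- mutate_sequence(sq, error_rate)
      reads[[rid]] <- mut$seq
      truth[[rid]] <- data.frame(read_id = rid, genome_id = g,
                                 start = starts[i], strand = strands[i],
                                 n_errors = mut$n_sub)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(reads = reads, truth = truth)
}
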