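#' Experiment parameters governing screen sizing
#'
#' Bundles the quantities that determine how many k-mers each genome's
#' reduced representation must retain: the k-mer length, the expected read
#' length and per-base error rate of the reads to be classified, and the
#' number of stored hashes a read should share with its true source
#' ("target matches").
#'
#' @param k k-mer length (1--31; 21 by default, the usual choice for
#'   genome-scale sketching).
#' @param read_length expected read length R in bp.
#' @param error_rate expected per-base substitution error rate e, in \[0, 1).
#' @param target_matches desired number of shared hashes t per read.
#' @param hash_seed integer seed for the k-mer hash; screens are comparable
#'   only at equal seed.
#' @param identity_hash logical; use the exact 2-bit identity hash instead of
#'   the production hash (verification only, requires `k <= 26`).
#' @return an object of class `screen_params`.
#' @examples
#' screen_params(k = 21, read_length = 10000, error_rate = 0.01,
#'               target_matches = 100)
#' @export
screen_params <- function(k = 21L, read_length = 10000L, error_rate = 0.01,
                          target_matches = 100L, hash_seed = 1L,
                          identity_hash = FALSE) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 31L) stop("k must be in 1..31")
  if (read_length < k) stop("read_length must be >= k")
  if (!is.finite(error_rate) || error_rate < 0 || error_rate >= 1)
    stop("error_rate must be in [0, 1)")
  if (target_matches < 1) stop("target_matches must be >= 1")
  if (identity_hash && k > 26L) stop("identity hashing requires k <= 26")
  structure(list(k = k, read_length = as.integer(read_length),
                 error_rate = as.numeric(error_rate),
                 target_matches = as.integer(target_matches),
                 hash_seed = as.integer(hash_seed),
                 identity_hash = isTRUE(identity_hash)),
            class = "screen_params")
}

#' @export
print.screen_params <- function(x, ...) {
  cat(sprintf(
    "screen_params: k=%d read_length=%d error_rate=%g target_matches=%d seed=%d%s\n",
    x$k, x$read_length, x$error_rate, x$target_matches, x$hash_seed,
    if (x$identity_hash) " [identity hash]" else ""))
  invisible(x)
}

#' Method parameters for screen construction
#'
#' @param method one of `"uniform"`, `"minhash"`, `"weighted_minhash"`
#'   (alias `"wmh"`), `"order_minhash"` (alias `"omh"`), `"minimizer"`.
#' @param sublist_length L, the length of the ordered sublists stored by
#'   order MinHash (required for that method, `>= 2`).
#' @param weight_multiplier M `>= 1`; weighted MinHash multiplies the weight
#'   of hashes unique to one genome by M (M = 1 is plain weighted MinHash).
#' @return an object of class `method_params`. The minimizer window
#'   multiplier is fixed at 2, so that a genome of size n yields about s
#'   minimizers with window `w = 2n/s`.
#' @export
method_params <- function(method = c("minhash", "uniform", "weighted_minhash",
                                     "order_minhash", "minimizer",
                                     "wmh", "omh"),
                          sublist_length = NULL, weight_multiplier = 1L) {
  method <- match.arg(method)
  method <- switch(method, wmh = "weighted_minhash", omh = "order_minhash",
                   method)
  if (method == "order_minhash") {
    if (is.null(sublist_length) || sublist_length < 2)
      stop("order_minhash requires sublist_length L >= 2")
    sublist_length <- as.integer(sublist_length)
  } else {
    sublist_length <- NULL
  }
  if (weight_multiplier < 1) stop("weight_multiplier must be >= 1")
  structure(list(method = method, sublist_length = sublist_length,
                 weight_multiplier = as.integer(weight_multiplier),
                 window_multiplier = 2L),
            class = "method_params")
}

#' Per-genome sketch/sample size
#'
#' The number of k-mers a genome's reduced representation must retain so
#' that a read of length R shares, in expectation, t error-free stored
#' hashes with its source:
#' \deqn{s = \lceil t \cdot n / (R \cdot (1-e)^k) \rceil}
#' The factor \eqn{1/(1-e)^k} oversamples to compensate for k-mers broken by
#' sequencing error. The result is capped at the number of available k-mer
#' positions, `n - k + 1`.
#'
#' @param params a [screen_params] object.
#' @param genome_size genome size n in bp (total across contigs).
#' @return integer sketch size.
#' @examples
#' p <- screen_params(k = 21, read_length = 10000, error_rate = 0,
#'                    target_matches = 100)
#' sketch_size(p, 1e6)  # 10000
#' @export
sketch_size <- function(params, genome_size) {
  stopifnot(inherits(params, "screen_params"))
  if (genome_size < params$k) stop("genome_size must be >= k")
  s <- ceiling(params$target_matches * genome_size /
                 (params$read_length *
                    (1 - params$error_rate)^params$k))
  min(s, genome_size - params$k + 1)
}

#' Probability that a k-mer is unaffected by sequencing error
#'
#' With independent per-base errors at rate e, a k-mer survives error-free
#' with probability `(1-e)^k`. At e = 1\% and k = 21 about 81\% of k-mers
#' remain error free; at e = 5\% only about 34\%.
#'
#' @param e per-base error rate in \[0, 1).
#' @param k k-mer length.
#' @return the error-free probability.
#' @export
error_free_kmer_fraction <- function(e, k) {
  stopifnot(all(e >= 0 & e < 1), all(k >= 1))
  (1 - e)^k
}
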