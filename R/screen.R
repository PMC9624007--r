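# Screen construction: the five per-genome k-mer selection strategies and
# the screen-level dispatcher.

#' Construct a genome sketch object
#'
#' Container for one genome's reduced representation: the selected canonical
#' k-mer hashes, plus optional per-hash weights (weighted MinHash) or genome
#' positions and ordered sublists (order MinHash). Exposed so that toy
#' screens can be assembled hash-by-hash in tests and examples.
#'
#' @param genome_id genome identifier.
#' @param genome_size genome size in bp (total across contigs).
#' @param hashes numeric vector of distinct hash values.
#' @param weights optional numeric vector parallel to `hashes`.
#' @param positions optional data.frame with columns `position`, `hash`,
#'   sorted by position (order MinHash).
#' @param sublists optional list of ordered length-L hash vectors.
#' @return an object of class `genome_sketch`.
#' @export
genome_sketch <- function(genome_id, genome_size, hashes, weights = NULL,
                          positions = NULL, sublists = NULL) {
  hashes <- as.numeric(hashes)
  if (anyDuplicated(hashes)) stop("sketch hashes must be distinct")
  if (!is.null(weights) && length(weights) != length(hashes))
    stop("weights must be parallel to hashes")
  structure(list(genome_id = as.character(genome_id),
                 genome_size = as.integer(genome_size),
                 hashes = hashes, weights = weights,
                 positions = positions, sublists = sublists),
            class = "genome_sketch")
}

#' @export
print.genome_sketch <- function(x, ...) {
  cat(sprintf("genome_sketch '%s': %d bp, %d hashes%s%s\n", x$genome_id,
              x$genome_size, length(x$hashes),
              if (!is.null(x$weights)) ", weighted" else "",
              if (!is.null(x$sublists))
                sprintf(", %d sublists", length(x$sublists)) else ""))
  invisible(x)
}

# normalize genome input to a named list of character vectors (one element
# per genome; each element the genome's contig sequences)
as_genome_list <- function(genomes) {
  if (inherits(genomes, "DNAStringSet")) {
    genomes <- as.character(genomes)
  }
  if (is.character(genomes) && length(genomes) == 1L && file.exists(genomes)) {
    genomes <- read_fasta(genomes)
  }
  if (is.character(genomes)) genomes <- as.list(genomes)
  if (!is.list(genomes) || length(genomes) == 0L)
    stop("no genomes supplied")
  if (is.null(names(genomes)) || any(names(genomes) == ""))
    names(genomes) <- paste0("genome_", seq_along(genomes))
  lapply(genomes, toupper)
}

# per-record scans glued into concatenated coordinates
genome_scan <- function(seqs, params) {
  lens <- nchar(seqs)
  offs <- cumsum(c(0L, lens))[seq_along(seqs)]
  scans <- lapply(seqs, seq_hashes, params = params)
  list(pos = unlist(lapply(seq_along(scans),
                           function(i) scans[[i]]$pos + offs[i])),
       hash = unlist(lapply(scans, `[[`, "hash")),
       n = sum(lens), scans = scans, offs = offs, lens = lens)
}

#' Build a uniform sample of a genome
#'
#' Selects a k-mer every n/s bases: target start positions `round(i*n/s)`
#' for i = 0..s-1 in the concatenated coordinate space. If a target window
#' is invalid (contains N or falls past a contig's last window), the nearest
#' valid window to the right is taken instead (wrapping to the last valid
#' window if none remains).
#'
#' @param genome character vector of contig sequences for one genome.
#' @param s sample size.
#' @param params a [screen_params] object.
#' @param genome_id identifier stored in the sketch.
#' @return a `genome_sketch`.
#' @export
build_uniform <- function(genome, s, params, genome_id = "genome") {
  gs <- genome_scan(genome, params)
  nav <- length(gs$pos)
  if (nav == 0L) stop("genome has no valid k-mer windows")
  if (s >= nav) {
    if (s > nav)
      warning("requested sample size exceeds valid k-mer windows; ",
              "returning all ", nav, " k-mers")
    sel <- seq_len(nav)
  } else {
    targets <- round((seq_len(s) - 1) * gs$n / s)
    # smallest j with pos[j] >= target; fall back to the last valid window
    j <- findInterval(targets - 0.5, gs$pos) + 1L
    j[j > nav] <- nav
    sel <- unique(j)
  }
  sk <- genome_sketch(genome_id, gs$n, unique(gs$hash[sel]))
  attr(sk, "sel_positions") <- gs$pos[sel]
  sk
}

#' Build a MinHash (bottom-s) sketch of a genome
#'
#' Hashes every canonical k-mer with a single seeded hash function and keeps
#' the s smallest distinct values, via a bounded max-heap (memory
#' proportional to s, one pass).
#'
#' @inheritParams build_uniform
#' @param s sketch size.
#' @return a `genome_sketch`; fewer than s distinct k-mers saturate to the
#'   full distinct set.
#' @export
build_minhash <- function(genome, s, params, genome_id = "genome") {
  gs <- genome_scan(genome, params)
  genome_sketch(genome_id, gs$n, bottom_s_cpp(gs$hash, as.integer(s)))
}

#' Build a windowed-minimizer sample of a genome
#'
#' Slides a window of `w = max(1, floor(2n/s))` consecutive k-mer positions
#' over each contig and keeps the k-mer with the smallest hash per window
#' (leftmost on ties). The doubling of n/s reflects the expected two
#' minimizers per w bases, so about s distinct minimizers survive genome-wide.
#'
#' @inheritParams build_minhash
#' @return a `genome_sketch`; the window used is recorded in attribute `"w"`
#'   and the selected concatenated positions in `"sel_positions"`.
#' @export
build_minimizer <- function(genome, s, params, genome_id = "genome") {
  gs <- genome_scan(genome, params)
  w <- max(1L, as.integer(floor(2 * gs$n / s)))
  pos <- numeric(0); hash <- numeric(0)
  for (i in seq_along(gs$scans)) {
    sc <- gs$scans[[i]]
    if (length(sc$hash) == 0L) next
    idx <- minimizer_indices_cpp(sc$hash, w) + 1L
    pos <- c(pos, sc$pos[idx] + gs$offs[i])
    hash <- c(hash, sc$hash[idx])
  }
  sk <- genome_sketch(genome_id, gs$n, unique(hash))
  attr(sk, "w") <- w
  attr(sk, "sel_positions") <- pos
  sk
}

#' Build an order MinHash sketch of a genome
#'
#' Selects the bottom-s hashes as in [build_minhash], orders them by their
#' (first) genome position, and partitions consecutive runs into
#' `floor(s/L)` disjoint sublists of exactly L hashes; a trailing remainder
#' shorter than L is dropped. The positional ordering makes similarity
#' order-sensitive: rearranged sequences with identical k-mer content score
#' lower than collinear ones.
#'
#' @inheritParams build_minhash
#' @param L sublist length (`2 <= L <= s`).
#' @return a `genome_sketch` with `positions` and `sublists` populated.
#' @export
build_order_minhash <- function(genome, s, L, params, genome_id = "genome") {
  if (s < L) stop("order MinHash requires s >= L")
  gs <- genome_scan(genome, params)
  sel <- bottom_s_cpp(gs$hash, as.integer(s))
  keep <- !is.na(match(gs$hash, sel))
  ph <- data.frame(position = gs$pos[keep], hash = gs$hash[keep])
  ph <- ph[order(ph$hash, ph$position), ]
  ph <- ph[!duplicated(ph$hash), ]          # first occurrence per hash
  ph <- ph[order(ph$position), ]
  rownames(ph) <- NULL
  nfull <- floor(nrow(ph) / L)
  sublists <- if (nfull > 0) {
    split(ph$hash[seq_len(nfull * L)], rep(seq_len(nfull), each = L))
  } else list()
  genome_sketch(genome_id, gs$n, sel, positions = ph,
                sublists = unname(sublists))
}

#' Annotate a screen's sketches with discriminativeness weights
#'
#' The weight of a stored hash is the number of genomes in the screen minus
#' the number of genomes whose sketch contains the hash, so hashes shared by
#' everything weigh 0 and hashes unique to one genome weigh the most. Unique
#' hashes are additionally multiplied by M, letting highly informative
#' k-mers dominate tie-breaking.
#'
#' @param sketches a list of `genome_sketch` objects built with the same
#'   parameters and seed.
#' @param M weight multiplier for unique hashes (M = 1 leaves plain weights).
#' @return the list with `weights` filled in on every sketch.
#' @export
annotate_weights <- function(sketches, M = 1L) {
  G <- length(sketches)
  stopifnot(G >= 1)
  all_h <- unlist(lapply(sketches, `[[`, "hashes"), use.names = FALSE)
  uh <- unique(all_h)
  occ <- tabulate(match(all_h, uh), nbins = length(uh))
  lapply(sketches, function(sk) {
    o <- occ[match(sk$hashes, uh)]
    sk$weights <- ifelse(o == 1L, (G - 1) * M, G - o)
    sk
  })
}

#' Build a screen of reference genomes
#'
#' Computes each genome's sketch size from [sketch_size] and dispatches to
#' the selected strategy; weighted MinHash builds bottom-s sketches and then
#' annotates weights across the whole screen.
#'
#' @param genomes genomes as a path to a multi-record FASTA (one record per
#'   genome), a named character vector of sequences, a named list of contig
#'   vectors (multi-contig genomes), or a `DNAStringSet`.
#' @param method a [method_params] object (or a method name).
#' @param params a [screen_params] object.
#' @return an object of class `screen`: named list of sketches plus the
#'   parameters and method that built them.
#' @examples
#' p <- screen_params(k = 11, read_length = 200, error_rate = 0,
#'                    target_matches = 20, hash_seed = 7)
#' g <- c(gA = paste(sample(c("A","C","G","T"), 2000, TRUE), collapse = ""))
#' scr <- build_screen(g, method_params("minhash"), p)
#' @export
build_screen <- function(genomes, method = method_params("minhash"),
                         params = screen_params()) {
  if (is.character(method)) method <- method_params(method)
  stopifnot(inherits(method, "method_params"),
            inherits(params, "screen_params"))
  gl <- as_genome_list(genomes)
  sketches <- lapply(names(gl), function(id) {
    seqs <- gl[[id]]
    s <- sketch_size(params, sum(nchar(seqs)))
    switch(method$method,
      uniform = build_uniform(seqs, s, params, id),
      minhash = ,
      weighted_minhash = build_minhash(seqs, s, params, id),
      order_minhash = build_order_minhash(seqs, s, method$sublist_length,
                                          params, id),
      minimizer = build_minimizer(seqs, s, params, id))
  })
  names(sketches) <- names(gl)
  if (method$method == "weighted_minhash")
    sketches <- annotate_weights(sketches, method$weight_multiplier)
  structure(list(sketches = sketches, params = params, method = method),
            class = "screen")
}

#' @export
print.screen <- function(x, ...) {
  sizes <- vapply(x$sketches, function(s) length(s$hashes), numeric(1))
  cat(sprintf("screen: %d genomes, method=%s, k=%d, seed=%d\n",
              length(x$sketches), x$method$method, x$params$k,
              x$params$hash_seed))
  cat(sprintf("  stored hashes: total %d (per genome %d..%d)\n",
              sum(sizes), min(sizes), max(sizes)))
  invisible(x)
}

#' @export
summary.screen <- function(object, ...) {
  data.frame(genome_id = names(object$sketches),
             genome_size = vapply(object$sketches, `[[`, integer(1),
                                  "genome_size"),
             n_hashes = vapply(object$sketches,
                               function(s) length(s$hashes), integer(1)),
             row.names = NULL)
}

#' Add genomes to an existing screen
#'
#' New sketches are built with the screen's stored parameters; existing
#' sketches are untouched except that weighted-MinHash weights are
#' recomputed (they depend on the genome count and hash occupancy).
#'
#' @param screen a `screen`.
#' @param genomes genomes in any form accepted by [build_screen].
#' @return the extended screen.
#' @export
screen_add <- function(screen, genomes) {
  stopifnot(inherits(screen, "screen"))
  extra <- build_screen(genomes, screen$method, screen$params)
  if (any(names(extra$sketches) %in% names(screen$sketches)))
    stop("duplicate genome_id")
  screen$sketches <- c(screen$sketches, extra$sketches)
  if (screen$method$method == "weighted_minhash")
    screen$sketches <- annotate_weights(screen$sketches,
                                        screen$method$weight_multiplier)
  screen
}

#' Remove genomes from a screen
#'
#' @param screen a `screen`.
#' @param genome_ids ids to drop.
#' @return the reduced screen (weights recomputed for weighted MinHash).
#' @export
screen_remove <- function(screen, genome_ids) {
  stopifnot(inherits(screen, "screen"))
  missing <- setdiff(genome_ids, names(screen$sketches))
  if (length(missing)) stop("unknown genome_id: ",
                            paste(missing, collapse = ", "))
  screen$sketches <- screen$sketches[setdiff(names(screen$sketches),
                                             genome_ids)]
  if (length(screen$sketches) == 0L) stop("cannot remove every genome")
  if (screen$method$method == "weighted_minhash")
    screen$sketches <- annotate_weights(screen$sketches,
                                        screen$method$weight_multiplier)
  screen
}

#' Estimate Jaccard similarity from two bottom-s sketches
#'
#' Mash-style merged estimator: the bottom-s' of the union of the two
#' sketches (s' = the smaller sketch size) is taken as a random sample of
#' the union of the two k-mer sets, and the fraction of it present in both
#' sketches estimates the Jaccard coefficient.
#'
#' @param a,b `genome_sketch` objects from the same parameters/seed.
#' @return estimated Jaccard similarity in \[0, 1\].
#' @export
sketch_jaccard <- function(a, b) {
  s <- min(length(a$hashes), length(b$hashes))
  merged <- bottom_s_cpp(c(a$hashes, b$hashes), as.integer(s))
  sum(merged %in% a$hashes & merged %in% b$hashes) / s
}
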