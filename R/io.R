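# FASTA I/O, plain-text screen persistence and classification reports.

SCREEN_FORMAT_VERSION <- 1L

#' Read a FASTA file
#'
#' @param path FASTA file, optionally gzipped.
#' @return named character vector of uppercased sequences, in file order;
#'   names are the first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e)
                   stop("malformed FASTA '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  if (length(ss) == 0L) stop("FASTA file '", path, "' contains no records")
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

fmt_hash <- function(h) sprintf("%.0f", h)

#' Save a screen (and optional sketch tree) as versioned plain text
#'
#' The container is a diffable key-value header followed by per-genome
#' hash lists (decimal, one per line, with weight or position columns where
#' the method stores them) and, if present, the sketch tree's nodes.
#' Screens built with the identity hash are flagged in the header so they
#' are never mixed with production screens.
#'
#' @param screen a `screen`.
#' @param path output path.
#' @param tree optional `sketch_tree` serialized alongside.
#' @return `path`, invisibly.
#' @export
save_screen <- function(screen, path, tree = NULL) {
  stopifnot(inherits(screen, "screen"))
  p <- screen$params; m <- screen$method
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("#readscreen_screen\tv%d", SCREEN_FORMAT_VERSION)
  w("#k\t%d", p$k)
  w("#read_length\t%d", p$read_length)
  w("#error_rate\t%.10g", p$error_rate)
  w("#target_matches\t%d", p$target_matches)
  w("#hash_seed\t%d", p$hash_seed)
  w("#identity_hash\t%s", if (p$identity_hash) "1" else "0")
  w("#method\t%s", m$method)
  w("#sublist_length\t%s",
    if (is.null(m$sublist_length)) "NA" else as.character(m$sublist_length))
  w("#weight_multiplier\t%d", m$weight_multiplier)
  w("#n_genomes\t%d", length(screen$sketches))
  for (sk in screen$sketches) {
    w(">%s\t%d\t%d", sk$genome_id, sk$genome_size, length(sk$hashes))
    if (!is.null(sk$weights)) {
      writeLines(paste(fmt_hash(sk$hashes), sk$weights, sep = "\t"), con)
    } else if (!is.null(sk$positions)) {
      # decimal-sorted hash list first, then the positional ordering
      writeLines(fmt_hash(sk$hashes), con)
      w("@positions\t%d", nrow(sk$positions))
      writeLines(paste(sk$positions$position,
                       fmt_hash(sk$positions$hash), sep = "\t"), con)
    } else {
      writeLines(fmt_hash(sk$hashes), con)
    }
  }
  if (!is.null(tree)) {
    stopifnot(inherits(tree, "sketch_tree"))
    w("#tree\tdownsample=%s\tf=%.10g\trng_seed=%d",
      tree$params$downsample_mode, tree$params$f, tree$params$rng_seed)
    w("#tree_newick\t%s", sketch_tree_newick(tree))
    for (nd in tree$nodes) {
      w("@node\t%d\t%s\t%s\t%d\t%d",
        nd$node_id,
        if (is.null(nd$children)) "leaf" else
          paste(nd$children, collapse = ","),
        paste(nd$genome_ids, collapse = ","),
        nd$height, length(nd$hashes))
      if (!is.null(nd$children)) writeLines(fmt_hash(nd$hashes), con)
    }
  }
  invisible(path)
}

#' Load a screen saved by [save_screen]
#'
#' @param path container path.
#' @return a list with `screen` and `tree` (`NULL` if none was saved).
#'   Refuses containers with an unknown format version.
#' @export
load_screen <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#readscreen_screen"))
    stop("'", path, "' is not a readscreen screen container")
  ver <- sub("^#readscreen_screen\tv", "", lines[1])
  if (as.integer(ver) != SCREEN_FORMAT_VERSION)
    stop("unsupported screen format version: ", ver)
  hdr <- list()
  i <- 2L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    kv <- strsplit(lines[i], "\t")[[1]]
    hdr[[sub("^#", "", kv[1])]] <- kv[2]
    i <- i + 1L
  }
  p <- screen_params(k = as.integer(hdr$k),
                     read_length = as.integer(hdr$read_length),
                     error_rate = as.numeric(hdr$error_rate),
                     target_matches = as.integer(hdr$target_matches),
                     hash_seed = as.integer(hdr$hash_seed),
                     identity_hash = hdr$identity_hash == "1")
  m <- method_params(hdr$method,
                     sublist_length = if (hdr$sublist_length == "NA") NULL
                     else as.integer(hdr$sublist_length),
                     weight_multiplier = as.integer(hdr$weight_multiplier))
  n_genomes <- as.integer(hdr$n_genomes)
  sketches <- list()
  tree <- NULL
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      rec <- strsplit(sub("^>", "", ln), "\t")[[1]]
      nh <- as.integer(rec[3])
      body <- lines[i + seq_len(nh)]
      i <- i + nh + 1L
      weights <- positions <- NULL
      if (m$method == "weighted_minhash") {
        parts <- strsplit(body, "\t")
        hashes <- as.numeric(vapply(parts, `[`, character(1), 1L))
        weights <- as.numeric(vapply(parts, `[`, character(1), 2L))
      } else {
        hashes <- as.numeric(body)
      }
      if (m$method == "order_minhash" && startsWith(lines[i], "@positions")) {
        np <- as.integer(strsplit(lines[i], "\t")[[1]][2])
        pp <- strsplit(lines[i + seq_len(np)], "\t")
        positions <- data.frame(
          position = as.integer(vapply(pp, `[`, character(1), 1L)),
          hash = as.numeric(vapply(pp, `[`, character(1), 2L)))
        i <- i + np + 1L
      }
      sk <- genome_sketch(rec[1], as.integer(rec[2]), hashes,
                          weights = weights, positions = positions)
      if (!is.null(positions)) {
        L <- m$sublist_length
        nfull <- floor(nrow(positions) / L)
        sk$sublists <- if (nfull > 0)
          unname(split(positions$hash[seq_len(nfull * L)],
                       rep(seq_len(nfull), each = L))) else list()
      }
      sketches[[rec[1]]] <- sk
    } else if (startsWith(ln, "#tree\t")) {
      tp <- strsplit(sub("^#tree\t", "", ln), "\t")[[1]]
      tpv <- sub("^[a-z_]+=", "", tp)
      tparams <- tree_params(downsample_mode = tpv[1],
                             f = as.numeric(tpv[2]),
                             rng_seed = as.integer(tpv[3]))
      i <- i + 1L
      nwk <- sub("^#tree_newick\t", "", lines[i])
      i <- i + 1L
      nodes <- list()
      while (i <= length(lines) && startsWith(lines[i], "@node")) {
        fl <- strsplit(lines[i], "\t")[[1]]
        node_id <- as.integer(fl[2])
        children <- if (fl[3] == "leaf") NULL
                    else as.integer(strsplit(fl[3], ",")[[1]])
        gids <- strsplit(fl[4], ",")[[1]]
        nh <- as.integer(fl[6])
        i <- i + 1L
        if (is.null(children)) {
          hashes <- sketches[[gids]]$hashes
        } else {
          hashes <- as.numeric(lines[i + seq_len(nh) - 1L])
          i <- i + nh
        }
        nodes[[node_id]] <- list(node_id = node_id, children = children,
                                 genome_ids = gids,
                                 hashes = hashes,
                                 height = as.integer(fl[5]))
      }
      G <- length(sketches)
      tree <- structure(
        list(nodes = nodes, root = 2L * G - 1L, n_genomes = G,
             hclust = ape_to_hclust(nwk), params = tparams,
             screen_params = p, method = m),
        class = "sketch_tree")
      next
    } else {
      i <- i + 1L
    }
  }
  if (length(sketches) != n_genomes)
    stop("screen container truncated: expected ", n_genomes, " genomes")
  screen <- structure(list(sketches = sketches, params = p, method = m),
                      class = "screen")
  list(screen = screen, tree = tree)
}

# round-trip helper: a Newick string back to an hclust-like object for
# topology export; merge heights are not preserved in the container
ape_to_hclust <- function(nwk) {
  phy <- ape::read.tree(text = nwk)
  tryCatch(stats::as.hclust(ape::compute.brlen(ape::multi2di(phy))),
           error = function(e) NULL)
}

#' Write a per-read classification report
#'
#' Writes the per-read TSV (schema: `read_id`, `predicted`, `score`,
#' `n_shared`, `tied_with`, `status`, plus `group` when present) preceded by
#' a `#`-prefixed summary block echoing the evaluation metrics and any
#' parameters supplied.
#'
#' @param results data.frame from a classify function.
#' @param path output path.
#' @param metrics optional `classification_metrics` from [evaluate].
#' @param params optional `screen_params` echoed into the summary.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, metrics = NULL, params = NULL) {
  stopifnot(nrow(results) >= 1L)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("#readscreen_report\tn_reads=%d", nrow(results))
  if (!is.null(params))
    w("#params\tk=%d\tread_length=%d\terror_rate=%g\ttarget_matches=%d\tseed=%d",
      params$k, params$read_length, params$error_rate,
      params$target_matches, params$hash_seed)
  w("#n_classified\t%d", sum(results$status == "classified"))
  w("#n_unclassified\t%d", sum(results$status == "unclassified"))
  w("#n_tied\t%d", sum(nzchar(results$tied_with)))
  if (!is.null(metrics)) {
    w("#accuracy\t%.6f", metrics$accuracy)
    w("#unclassified_fraction\t%.6f", metrics$unclassified_fraction)
    w("#tie_fraction\t%.6f", metrics$tie_fraction)
    for (r in seq_len(nrow(metrics$per_genome)))
      w("#per_genome\t%s\t%d\t%.6f", metrics$per_genome$genome_id[r],
        metrics$per_genome$n_reads[r], metrics$per_genome$accuracy[r])
  }
  cols <- intersect(c("read_id", "predicted", "score", "n_shared",
                      "tied_with", "status", "group"), names(results))
  write.table(results[, cols], con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
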