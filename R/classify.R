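# Read scoring and classification against flat screens and sketch trees.

# Inverted index over a screen's stored hashes (CSR layout): sorted unique
# hash values plus, per value, the genomes (and weights) carrying it.
screen_index <- function(screen) {
  sk <- screen$sketches
  all_h <- unlist(lapply(sk, `[[`, "hashes"), use.names = FALSE)
  gidx <- rep.int(seq_along(sk), vapply(sk, function(s) length(s$hashes),
                                        integer(1)))
  wts <- if (screen$method$method == "weighted_minhash") {
    unlist(lapply(sk, `[[`, "weights"), use.names = FALSE)
  }
  o <- order(all_h)
  all_h <- all_h[o]; gidx <- gidx[o]
  if (!is.null(wts)) wts <- wts[o]
  newv <- !duplicated(all_h)
  starts <- which(newv)
  list(u = all_h[newv], starts = starts,
       ends = c(starts[-1L] - 1L, length(all_h)),
       gidx = gidx, wts = wts, G = length(sk), ids = names(sk))
}

# membership of x (numeric, any order) in sorted vector u -> index or NA
match_sorted <- function(x, u) {
  j <- findInterval(x, u)
  j[j > 0L & u[pmax(j, 1L)] != x] <- 0L
  j
}

# per-genome shared-hash counts (and weighted sums) for one read hash set
score_against_index <- function(read_hashes, idx) {
  j <- match_sorted(read_hashes, idx$u)
  j <- j[j > 0L]
  primary <- integer(idx$G)
  wsum <- numeric(idx$G)
  if (length(j)) {
    cnt <- idx$ends[j] - idx$starts[j] + 1L
    rows <- sequence(cnt) + rep.int(idx$starts[j] - 1L, cnt)
    g <- idx$gidx[rows]
    primary <- tabulate(g, nbins = idx$G)
    if (!is.null(idx$wts)) {
      rs <- rowsum(idx$wts[rows], g)
      wsum[as.integer(rownames(rs))] <- rs[, 1L]
    }
  }
  list(primary = primary, wsum = wsum)
}

# longest common subsequence length of two orderings of the same distinct
# elements == longest increasing subsequence of the cross-ranks
lcs_perm <- function(a, b) {
  m <- match(a, b)
  m <- m[!is.na(m)]
  tails <- integer(0)
  for (x in m) {
    p <- findInterval(x - 1L, tails) + 1L
    if (p > length(tails)) tails <- c(tails, x) else tails[p] <- x
  }
  length(tails)
}

#' Score a read's hash set against one genome sketch
#'
#' The primary score is the shared-hash count. Weighted MinHash adds a
#' secondary score, the summed weights of the shared hashes; order MinHash's
#' secondary score is the length of the longest common subsequence between
#' the shared hashes ordered by read position and ordered by stored genome
#' position (perfect collinearity gives secondary == primary).
#'
#' @param read_hashes numeric vector of the read's canonical k-mer hashes in
#'   read-position order (as produced by the k-mer scan; order matters only
#'   for the order MinHash secondary score), or a list with component `hash`.
#' @param sketch a `genome_sketch`.
#' @param method a [method_params] object or method name.
#' @return integer vector `c(primary, secondary)`.
#' @export
score_read <- function(read_hashes, sketch, method) {
  if (is.character(method)) method <- method_params(method)
  if (is.list(read_hashes) && !is.null(read_hashes$hash))
    read_hashes <- read_hashes$hash
  read_hashes <- read_hashes[!duplicated(read_hashes)]
  hit <- !is.na(match(read_hashes, sketch$hashes))
  primary <- sum(hit)
  secondary <- 0L
  if (method$method == "weighted_minhash") {
    if (is.null(sketch$weights))
      stop("sketch has no weights; method/sketch mismatch")
    secondary <- sum(sketch$weights[match(read_hashes[hit], sketch$hashes)])
  } else if (method$method == "order_minhash") {
    if (is.null(sketch$positions))
      stop("sketch has no positions; method/sketch mismatch")
    # dedup keeps first occurrences, so read order == read-position order
    by_read <- read_hashes[hit]
    by_read <- by_read[!is.na(match(by_read, sketch$positions$hash))]
    by_genome <- sketch$positions$hash[
      !is.na(match(sketch$positions$hash, by_read))]
    secondary <- if (length(by_read) > 1L) lcs_perm(by_read, by_genome)
                 else length(by_read)
  }
  c(primary = as.integer(primary), secondary = as.integer(secondary))
}

# hash a read (or accept prehashed list(pos, hash))
read_scan <- function(read, params) {
  if (is.list(read) && !is.null(read$hash)) return(read)
  seq_hashes(read, params)
}

# winner selection shared by flat/grouped classification; rng must be seeded
# by the caller
pick_winner <- function(primary, secondary, min_shared) {
  top <- max(primary)
  if (top < min_shared) {
    return(list(win = NA_integer_, tied = integer(0), top = top))
  }
  cand <- which(primary == top)
  if (length(cand) > 1L) {
    s2 <- secondary[cand]
    cand <- cand[s2 == max(s2)]
  }
  win <- if (length(cand) > 1L) cand[sample.int(length(cand), 1L)] else cand
  list(win = win, tied = cand, top = top)
}

# secondary scores for candidate genomes only (OMH needs positions; WMH
# comes precomputed from the index)
omh_secondary <- function(read_hashes, screen, cand) {
  vapply(cand, function(g) {
    score_read(read_hashes, screen$sketches[[g]],
               screen$method)[["secondary"]]
  }, integer(1))
}

#' Classify reads against a flat screen
#'
#' Each read's canonical k-mer hash set is scored against every sketch; the
#' winner is the maximum by (shared-hash count, method-specific secondary
#' score), with remaining ties broken uniformly at random. Reads whose best
#' shared-hash count falls below `min_shared` are left `UNCLASSIFIED`.
#'
#' @param reads named character vector of read sequences.
#' @param screen a `screen`.
#' @param min_shared minimum shared hashes to call a read classified
#'   (default 1; use 5 for real reads).
#' @param seed integer seed for tie resolution.
#' @return a data.frame with one row per read: `read_id`, `predicted`,
#'   `score` (shared hashes with the winner), `secondary`, `n_shared`,
#'   `tied_with` (comma-separated ids at equal top score, empty if no tie)
#'   and `status` (`classified`/`unclassified`).
#' @export
classify_reads <- function(reads, screen, min_shared = 1L, seed = 1L) {
  stopifnot(inherits(screen, "screen"), length(reads) >= 1L)
  if (is.null(names(reads))) names(reads) <- paste0("read_", seq_along(reads))
  idx <- screen_index(screen)
  omh <- screen$method$method == "order_minhash"
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- length(reads)
  predicted <- character(n); score <- integer(n); secondary2 <- numeric(n)
  n_shared <- integer(n); tied_with <- character(n); status <- character(n)
  for (i in seq_len(n)) {
    scan <- read_scan(reads[[i]], screen$params)
    rh <- scan$hash[!duplicated(scan$hash)]
    sc <- score_against_index(rh, idx)
    secondary <- sc$wsum
    if (omh && length(rh)) {
      top <- max(sc$primary)
      if (top >= min_shared) {
        cand <- which(sc$primary == top)
        secondary <- numeric(idx$G)
        if (length(cand) > 1L)
          secondary[cand] <- omh_secondary(rh, screen, idx$ids[cand])
      }
    }
    w <- pick_winner(sc$primary, secondary, min_shared)
    if (is.na(w$win)) {
      predicted[i] <- "UNCLASSIFIED"; score[i] <- 0L; secondary2[i] <- 0
      n_shared[i] <- as.integer(w$top); tied_with[i] <- ""
      status[i] <- "unclassified"
    } else {
      predicted[i] <- idx$ids[w$win]; score[i] <- as.integer(w$top)
      secondary2[i] <- secondary[w$win]; n_shared[i] <- as.integer(w$top)
      tied_with[i] <- if (length(w$tied) > 1L)
        paste(idx$ids[w$tied], collapse = ",") else ""
      status[i] <- "classified"
    }
  }
  res <- data.frame(read_id = names(reads), predicted = predicted,
                    score = score, secondary = secondary2,
                    n_shared = n_shared, tied_with = tied_with,
                    status = status)
  attr(res, "n_compared") <- length(idx$gidx)
  res
}

#' Classify a single read against a flat screen
#'
#' Single-read wrapper around [classify_reads].
#'
#' @param read one read sequence (character).
#' @inheritParams classify_reads
#' @return an object of class `classification_result`: a list with
#'   `read_id`, `predicted` (genome id or `"UNCLASSIFIED"`), `score`,
#'   `secondary`, `n_shared`, `tied_with` (character vector) and `status`.
#' @export
classify_flat <- function(read, screen, min_shared = 1L, seed = 1L) {
  df <- classify_reads(stats::setNames(as.character(read)[1L], "read"),
                       screen, min_shared = min_shared, seed = seed)
  res <- list(read_id = df$read_id, predicted = df$predicted,
              score = df$score, secondary = df$secondary,
              n_shared = df$n_shared,
              tied_with = if (nzchar(df$tied_with))
                strsplit(df$tied_with, ",")[[1]] else character(0),
              status = df$status)
  class(res) <- "classification_result"
  res
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("read '%s' -> %s (shared=%d%s)%s\n", x$read_id, x$predicted,
              x$n_shared,
              if (x$secondary > 0) sprintf(", secondary=%g", x$secondary)
              else "",
              if (length(x$tied_with) > 1L)
                sprintf(" [tie among %s]",
                        paste(x$tied_with, collapse = ",")) else ""))
  invisible(x)
}

#' Classify a read by greedy descent through a sketch tree
#'
#' Starting at the root, the read is scored against each child's stored
#' hashes and descent continues into the strict maximum. If no child
#' reaches `min_shared` the read is `UNCLASSIFIED` at that node. On a tie,
#' `tie_mode = "random"` picks a child at random (seeded) and
#' `tie_mode = "stop"` halts and reports the tied node's subtree of
#' candidate genomes. A leaf yields that genome.
#'
#' @param read one read sequence.
#' @param sketch_tree a `sketch_tree` from [build_sketch_tree].
#' @param min_shared classification threshold on shared hashes.
#' @param tie_mode `"random"` or `"stop"`.
#' @param seed integer seed for random tie descent.
#' @return a `classification_result`; in tie-stop mode `predicted` is
#'   `"subtree:<node_id>"` with the member genomes in `candidates`, and
#'   `status` is `"tie_stopped"`. Attribute `"n_compared"` records the
#'   number of stored hashes scored along the path.
#' @export
classify_tree <- function(read, sketch_tree, min_shared = 1L,
                          tie_mode = c("random", "stop"), seed = 1L) {
  stopifnot(inherits(sketch_tree, "sketch_tree"))
  tie_mode <- match.arg(tie_mode)
  scan <- read_scan(read, sketch_tree$screen_params)
  rh <- unique(scan$hash)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  node <- sketch_tree$nodes[[sketch_tree$root]]
  n_compared <- 0L
  depth <- 0L
  result <- function(predicted, status, score, candidates) {
    res <- list(read_id = "read", predicted = predicted, score = score,
                secondary = 0, n_shared = score, tied_with = character(0),
                candidates = candidates, status = status, depth = depth)
    class(res) <- "classification_result"
    attr(res, "n_compared") <- n_compared
    res
  }
  while (!is.null(node$children)) {
    kids <- sketch_tree$nodes[node$children]
    sc <- vapply(kids, function(ch) {
      sum(!is.na(match(rh, ch$hashes)))
    }, numeric(1))
    n_compared <- n_compared + sum(vapply(kids, function(ch)
      length(ch$hashes), numeric(1)))
    top <- max(sc)
    if (top < min_shared)
      return(result("UNCLASSIFIED", "unclassified", 0L, character(0)))
    cand <- which(sc == top)
    if (length(cand) > 1L) {
      if (tie_mode == "stop") {
        return(result(sprintf("subtree:%d", node$node_id), "tie_stopped",
                      as.integer(top), node$genome_ids))
      }
      cand <- cand[sample.int(length(cand), 1L)]
    }
    node <- kids[[cand]]
    depth <- depth + 1L
  }
  result(node$genome_ids, "classified",
         as.integer(sum(!is.na(match(rh, node$hashes)))), node$genome_ids)
}

#' Classify reads through a sketch tree
#'
#' Vectorized wrapper over [classify_tree].
#'
#' @param reads named character vector of read sequences.
#' @inheritParams classify_tree
#' @return a data.frame in the [classify_reads] schema (tie-stopped rows
#'   carry the subtree label in `predicted` and its genomes in `tied_with`);
#'   attribute `"n_compared"` holds the mean stored hashes scored per read.
#' @export
classify_tree_reads <- function(reads, sketch_tree, min_shared = 1L,
                                tie_mode = c("random", "stop"), seed = 1L) {
  tie_mode <- match.arg(tie_mode)
  if (is.null(names(reads))) names(reads) <- paste0("read_", seq_along(reads))
  n <- length(reads)
  comp <- numeric(n)
  predicted <- character(n); score <- integer(n); n_shared <- integer(n)
  tied_with <- character(n); status <- character(n)
  for (i in seq_len(n)) {
    r <- classify_tree(reads[[i]], sketch_tree, min_shared = min_shared,
                       tie_mode = tie_mode, seed = seed + i)
    comp[i] <- attr(r, "n_compared")
    predicted[i] <- if (length(r$predicted) == 1L) r$predicted else
      paste(r$predicted, collapse = ",")
    score[i] <- r$score; n_shared[i] <- r$n_shared
    tied_with[i] <- if (r$status == "tie_stopped")
      paste(r$candidates, collapse = ",") else ""
    status[i] <- r$status
  }
  res <- data.frame(read_id = names(reads), predicted = predicted,
                    score = score, secondary = 0, n_shared = n_shared,
                    tied_with = tied_with, status = status)
  attr(res, "n_compared") <- mean(comp)
  res
}

#' Group-level classification (host/contaminant separation)
#'
#' Runs flat classification, then maps each winning genome to its group
#' label, supporting the two-level report of a host-vs-contaminant call
#' plus the exact source genome.
#'
#' @inheritParams classify_reads
#' @param groups named character vector mapping every genome id to a group
#'   label (e.g. `"host"`, `"contaminant"`).
#' @return the [classify_reads] data.frame with an extra `group` column
#'   (`UNCLASSIFIED` for unclassified reads).
#' @export
classify_grouped <- function(reads, screen, groups, min_shared = 1L,
                             seed = 1L) {
  missing <- setdiff(names(screen$sketches), names(groups))
  if (length(missing))
    stop("genomes missing from groups: ", paste(missing, collapse = ", "))
  res <- classify_reads(reads, screen, min_shared = min_shared, seed = seed)
  res$group <- ifelse(res$status == "unclassified", "UNCLASSIFIED",
                      unname(groups[res$predicted]))
  res
}

#' Evaluate classification results against ground truth
#'
#' Accuracy is the fraction of reads whose prediction equals the true
#' source genome (randomly resolved ties count as correct only when the
#' resolution hit the truth). Also reports the unclassified and tie
#' fractions, a per-genome accuracy table, and group-level accuracy when
#' groups are given.
#'
#' @param results data.frame from [classify_reads]/[classify_grouped].
#' @param truth named character vector (or data.frame with `read_id`,
#'   `genome_id`) mapping every read to its true source genome.
#' @param groups optional named character vector mapping genome ids to
#'   group labels.
#' @return an object of class `classification_metrics`.
#' @export
evaluate <- function(results, truth, groups = NULL) {
  if (is.data.frame(truth))
    truth <- stats::setNames(truth$genome_id, truth$read_id)
  if (!all(results$read_id %in% names(truth)))
    stop("truth must cover all reads")
  tg <- unname(truth[results$read_id])
  correct <- results$predicted == tg
  per <- data.frame(genome_id = sort(unique(tg)))
  per$n_reads <- as.integer(table(tg)[per$genome_id])
  per$n_correct <- vapply(per$genome_id, function(g)
    sum(correct & tg == g), numeric(1))
  per$accuracy <- per$n_correct / per$n_reads
  m <- list(n = nrow(results),
            accuracy = mean(correct),
            unclassified_fraction = mean(results$status == "unclassified"),
            tie_fraction = mean(nzchar(results$tied_with)),
            per_genome = per)
  if (!is.null(groups)) {
    tgroup <- unname(groups[tg])
    m$group_accuracy <- mean(results$group == tgroup)
    m$per_group <- vapply(sort(unique(tgroup)), function(g)
      mean(results$group[tgroup == g] == g), numeric(1))
  }
  class(m) <- "classification_metrics"
  m
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("classification of %d reads\n", x$n))
  cat(sprintf("  accuracy:     %.4f\n", x$accuracy))
  cat(sprintf("  unclassified: %.4f\n", x$unclassified_fraction))
  cat(sprintf("  ties:         %.4f\n", x$tie_fraction))
  if (!is.null(x$group_accuracy))
    cat(sprintf("  group accuracy: %.4f (%s)\n", x$group_accuracy,
                paste(sprintf("%s=%.4f", names(x$per_group), x$per_group),
                      collapse = ", ")))
  invisible(x)
}
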