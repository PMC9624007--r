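# Hierarchical clustering of sketches and construction of the downsampled
# sketch tree used for pruned classification.

#' Pairwise Jaccard distances between a screen's sketches
#'
#' `distance(i, j) = 1 - |Hi ∩ Hj| / |Hi ∪ Hj|` over the stored hash sets.
#'
#' @param screen a `screen` with at least two sketches.
#' @return a symmetric numeric matrix with zero diagonal, dimnames =
#'   genome ids.
#' @export
sketch_distance_matrix <- function(screen) {
  stopifnot(inherits(screen, "screen"))
  sk <- screen$sketches
  G <- length(sk)
  if (G < 2) stop("need at least two sketches")
  d <- matrix(0, G, G, dimnames = list(names(sk), names(sk)))
  for (i in seq_len(G - 1)) {
    hi <- sk[[i]]$hashes
    for (j in (i + 1):G) {
      hj <- sk[[j]]$hashes
      inter <- sum(!is.na(match(hi, hj)))
      d[i, j] <- d[j, i] <- 1 - inter / (length(hi) + length(hj) - inter)
    }
  }
  d
}

#' Average-linkage hierarchy over sketch distances
#'
#' Agglomerative clustering (UPGMA) of the Jaccard distance matrix;
#' deterministic given the input order. Ties in merge height are resolved by
#' `stats::hclust`'s fixed scan order, yielding a binary merge tree.
#'
#' @param distances symmetric distance matrix from [sketch_distance_matrix].
#' @return an `hclust` object with `n` leaves and `n - 1` merges.
#' @export
linkage_tree <- function(distances) {
  hclust(as.dist(distances), method = "average")
}

#' Sketch-tree construction parameters
#'
#' @param downsample_mode `"none"`, `"constant"` (each internal node keeps
#'   `floor(|union|/f)` hashes) or `"height"` (a node at height h keeps
#'   `floor(|union|/f^h)`, compounding towards the root).
#' @param f downsampling factor `>= 1`.
#' @param rng_seed master seed; each node subsamples with a sub-seed derived
#'   from `(rng_seed, node_id)` so subtree rebuilds are stable.
#' @return an object of class `tree_params`.
#' @export
tree_params <- function(downsample_mode = c("none", "constant", "height"),
                        f = 1, rng_seed = 1L) {
  downsample_mode <- match.arg(downsample_mode)
  if (f < 1) stop("f must be >= 1")
  structure(list(downsample_mode = downsample_mode, f = as.numeric(f),
                 rng_seed = as.integer(rng_seed)),
            class = "tree_params")
}

node_subseed <- function(master, node_id) {
  as.integer((as.numeric(master) * 48271 + node_id * 16807) %% 2147483647)
}

#' Build a sketch tree over a clustered screen
#'
#' Leaves carry the genomes' full sketches; each internal node stores a
#' seeded uniform random subsample (without replacement) of the union of
#' its children's hashes, per the downsampling mode. With no downsampling
#' every internal node is the exact union, and the root contains the whole
#' screen.
#'
#' @param screen a `screen`.
#' @param tree an `hclust` from [linkage_tree]; computed from the screen's
#'   own sketch distances when `NULL`.
#' @param params a [tree_params] object.
#' @return an object of class `sketch_tree`: a list with `nodes` (leaves
#'   `1..G`, internal nodes `G+1..2G-1` in merge order, root last), the
#'   originating `screen` params/method, and `params`.
#' @export
build_sketch_tree <- function(screen, tree = NULL, params = tree_params()) {
  stopifnot(inherits(screen, "screen"), inherits(params, "tree_params"))
  if (is.null(tree)) tree <- linkage_tree(sketch_distance_matrix(screen))
  stopifnot(inherits(tree, "hclust"))
  G <- length(screen$sketches)
  if (length(tree$order) != G) stop("tree leaves must match screen sketches")
  ids <- tree$labels
  if (!setequal(ids, names(screen$sketches)))
    stop("tree labels must match screen genome ids")
  nodes <- vector("list", 2 * G - 1)
  for (i in seq_len(G)) {
    sk <- screen$sketches[[ids[i]]]
    nodes[[i]] <- list(node_id = i, children = NULL,
                       genome_ids = sk$genome_id, hashes = sk$hashes,
                       height = 0L)
  }
  for (m in seq_len(G - 1)) {
    ch <- tree$merge[m, ]
    ch_id <- ifelse(ch < 0, -ch, G + ch)
    a <- nodes[[ch_id[1]]]; b <- nodes[[ch_id[2]]]
    u <- unique(c(a$hashes, b$hashes))
    h <- max(a$height, b$height) + 1L
    keep <- length(u)
    if (params$downsample_mode == "constant") {
      keep <- floor(length(u) / params$f)
    } else if (params$downsample_mode == "height") {
      keep <- floor(length(u) / params$f^h)
    }
    if (keep < 1) {
      warning("downsampling would empty node ", G + m, "; clamped to 1 hash")
      keep <- 1L
    }
    if (keep < length(u)) {
      old <- get0(".Random.seed", envir = globalenv())
      set.seed(node_subseed(params$rng_seed, G + m))
      u <- sample(u, keep)
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }
    nodes[[G + m]] <- list(node_id = G + m, children = ch_id,
                           genome_ids = c(a$genome_ids, b$genome_ids),
                           hashes = u, height = h)
  }
  structure(list(nodes = nodes, root = 2L * G - 1L, n_genomes = G,
                 hclust = tree, params = params,
                 screen_params = screen$params, method = screen$method),
            class = "sketch_tree")
}

#' @export
print.sketch_tree <- function(x, ...) {
  root <- x$nodes[[x$root]]
  cat(sprintf(
    "sketch_tree: %d genomes, %d nodes, downsample=%s f=%g, root holds %d hashes\n",
    x$n_genomes, length(x$nodes), x$params$downsample_mode, x$params$f,
    length(root$hashes)))
  invisible(x)
}

#' Export a sketch tree's topology as Newick
#'
#' @param tree a `sketch_tree`.
#' @param path optional file to write to.
#' @return the Newick string (invisibly when written to a file).
#' @export
sketch_tree_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "sketch_tree"))
  phy <- ape::as.phylo(tree$hclust)
  nwk <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
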