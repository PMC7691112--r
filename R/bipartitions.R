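# Bipartition machinery, the tree topology score, and the randomized-topology
# baseline.  All topology comparison is done on the UNROOTED trees: a
# bipartition is the split of the leaf set induced by removing one edge, and
# only nontrivial splits (both sides >= 2 leaves) carry topological
# information.  Splits are canonicalized against a fixed alphabetical leaf
# ordering so equal bipartitions compare equal regardless of rooting or side
# order; the root's two-child split is counted once.

# Precompute, for a tree and a canonical label ordering, the descendant-tip
# membership of every edge plus the canonical 0/1-string keys of all
# nontrivial bipartitions.  `labels` must be the sorted union of leaf labels.
bip_cache <- function(tree, labels = sort(tree$tip.label)) {
  n <- length(tree$tip.label)
  pos <- match(tree$tip.label, labels)
  if (anyNA(pos)) stop("tree labels not contained in canonical label set",
                       call. = FALSE)
  nnode <- tree$Nnode
  edge <- tree$edge
  M <- matrix(FALSE, n + nnode, n)
  M[cbind(seq_len(n), pos)] <- TRUE
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    M[p, ] <- M[p, ] | M[ch, ]
  }
  D <- M[edge[, 2], , drop = FALSE]        # edges x tips: tips below each edge
  sizes <- rowSums(D)
  nontriv <- which(sizes >= 2 & sizes <= n - 2)
  keys <- character(length(nontriv))
  for (j in seq_along(nontriv)) {
    z <- D[nontriv[j], ]
    if (z[1]) z <- !z                      # side excluding the first label
    keys[j] <- paste(as.integer(z), collapse = "")
  }
  keep <- !duplicated(keys)                # root split appears on two edges
  list(n = n, labels = labels, pos = pos, edge = edge, D = D,
       keys = keys[keep], key_edge = nontriv[keep])
}

# Canonical key of a leaf subset given the cache's label ordering.
split_key <- function(members, cache) {
  z <- logical(cache$n)
  z[members] <- TRUE
  if (z[1]) z <- !z
  paste(as.integer(z), collapse = "")
}

#' Nontrivial bipartitions of an unrooted tree
#'
#' Each internal edge of the unrooted tree splits the leaves into two
#' complementary sets; splits with a singleton side are trivial and omitted.
#' For an unrooted binary tree with n leaves there are exactly n - 3
#' nontrivial bipartitions.
#'
#' @param tree a `phylo` object.
#' @return a list of bipartitions, each a list with elements `side` and
#'   `complement` (sorted character vectors of leaf labels).  Trees with
#'   fewer than 4 leaves yield an empty list.
#' @examples
#' bipartitions(read_newick("((A:1,B:1):1,(C:1,D:1):1);"))
#' @export
bipartitions <- function(tree) {
  tree <- validate_tree(tree, require_lengths = FALSE)
  if (length(tree$tip.label) < 4) return(list())
  cache <- bip_cache(tree)
  lapply(cache$key_edge, function(e) {
    inside <- sort(cache$labels[cache$D[e, ]])
    list(side = inside, complement = setdiff(cache$labels, inside))
  })
}

#' Tree topology score (TTS)
#'
#' Percentage of the reference tree's nontrivial bipartitions that are also
#' present in the test tree.  Both trees are treated as unrooted; the
#' denominator is always the reference tree's bipartition count, so the score
#' penalizes unresolved test trees conservatively.  For two fully resolved
#' binary trees the score is symmetric in its arguments.
#'
#' @param reference the true (reference) tree, a `phylo` object with >= 4
#'   leaves.
#' @param test the tree to score against the reference; must have the same
#'   leaf set.
#' @return an object of class `tts_result`: a list with `score` (percent in
#'   \[0, 100\]), `shared` and `denominator`.
#' @examples
#' a <- read_newick("((A:1,B:1):1,((C:1,D:1):1,E:1):1);")
#' b <- read_newick("((A:1,B:1):1,((C:1,E:1):1,D:1):1);")
#' tts(a, b)$score  # 50: only the {A,B} split is shared
#' @export
tts <- function(reference, test) {
  reference <- validate_tree(reference, require_lengths = FALSE)
  test <- validate_tree(test, require_lengths = FALSE)
  ref_labs <- sort(reference$tip.label)
  test_labs <- sort(test$tip.label)
  if (!identical(ref_labs, test_labs)) {
    only_ref <- setdiff(ref_labs, test_labs)
    only_test <- setdiff(test_labs, ref_labs)
    stop("leaf sets differ; only in reference: {",
         paste(only_ref, collapse = ", "), "}; only in test: {",
         paste(only_test, collapse = ", "), "}", call. = FALSE)
  }
  if (length(ref_labs) < 4) stop("TTS requires >= 4 leaves", call. = FALSE)
  ref_keys <- bip_cache(reference, ref_labs)$keys
  test_keys <- bip_cache(test, ref_labs)$keys
  shared <- sum(ref_keys %in% test_keys)
  out <- list(score = 100 * shared / length(ref_keys), shared = shared,
              denominator = length(ref_keys))
  class(out) <- "tts_result"
  out
}

#' @export
print.tts_result <- function(x, ...) {
  cat(sprintf("TTS: %.2f%% (%d of %d reference bipartitions shared)\n",
              x$score, x$shared, x$denominator))
  invisible(x)
}

#' Uniformly random unrooted binary topology
#'
#' Draws a labeled topology uniformly over the (2n-5)!! unrooted binary
#' trees by sequential leaf insertion: starting from the unique 3-leaf tree,
#' each further leaf is attached to an edge chosen uniformly at random.
#' All branch lengths are set to 1; the score [tts()] ignores lengths.
#'
#' This is the chance baseline for topology scores: the expected TTS between
#' a fixed tree and a random topology is small (a few percent for realistic
#' leaf counts).
#'
#' @param labels character vector of >= 4 unique leaf labels.
#' @param seed integer seed; the same seed reproduces the same tree.
#' @return a `phylo` object with unit branch lengths.
#' @export
random_topology <- function(labels, seed) {
  labels <- as.character(labels)
  if (length(labels) < 4) stop("need >= 4 labels", call. = FALSE)
  if (anyDuplicated(labels)) stop("labels must be unique", call. = FALSE)
  n <- length(labels)
  with_seed(seed, {
    ord <- sample.int(n)                       # random tip id -> label map
    E <- matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L), ncol = 2, byrow = TRUE)
    if (n > 3) {
      for (k in 4:n) {
        e <- sample.int(nrow(E), 1L)
        v <- n + k - 2L                        # new internal node
        b <- E[e, 2]
        E[e, 2] <- v
        E <- rbind(E, c(v, b), c(v, k))
      }
    }
    nv <- 2L * n - 2L
    adj <- vector("list", nv)
    for (i in seq_len(nrow(E))) {
      a <- E[i, 1]; b <- E[i, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    nwk <- function(node, parent) {
      if (node <= n) return(paste0(labels[ord[node]], ":1"))
      kids <- setdiff(adj[[node]], parent)
      paste0("(", paste(vapply(kids, nwk, "", parent = node), collapse = ","),
             "):1")
    }
    root <- n + 1L
    kids <- adj[[root]]
    txt <- paste0("(", paste(vapply(kids, nwk, "", parent = root),
                             collapse = ","), ");")
    read_newick(txt)
  })
}
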