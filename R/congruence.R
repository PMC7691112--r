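# Per-site compatibility of an alignment column with a tree.  A column is
# congruent when all of its allele classes can simultaneously be connected
# (convex) subtrees of the unrooted tree.  For a biallelic column this reduces
# to: the allele split equals some edge bipartition, or one class is a
# singleton.  The general check tests pairwise vertex-disjointness of the
# allele classes' Steiner subtrees, which is exact on multifurcating trees
# as well.

DNA_INT <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# Map a character vector of bases to 1..4 with NA for anything ambiguous.
encode_bases <- function(x) {
  unname(DNA_INT[match(toupper(x), names(DNA_INT))])
}

# Core convexity check.  `members_by_class` is a list of tip-index vectors
# (classes with >= 2 members only need checking; singletons occupy just their
# own leaf and can never intersect another class's Steiner subtree).
classes_convex <- function(cache, members_by_class) {
  big <- members_by_class[lengths(members_by_class) >= 2L]
  if (length(big) <= 1L) return(TRUE)
  verts <- lapply(big, function(S) {
    cnt <- rowSums(cache$D[, S, drop = FALSE])
    ine <- cnt > 0L & cnt < length(S)
    unique(c(cache$edge[ine, 1L], cache$edge[ine, 2L]))
  })
  anyDuplicated(unlist(verts)) == 0L
}

#' Is a site pattern congruent with a tree?
#'
#' Tests whether every allele class of one alignment column can be a
#' connected subtree of the (unrooted) tree simultaneously.  Monomorphic
#' columns and columns whose minor alleles are all singletons carry no
#' conflicting signal and return `TRUE`.  Ambiguous characters (anything
#' outside A/C/G/T) are unconstrained and ignored.
#'
#' @param tree a `phylo` object.
#' @param column a named character vector mapping every leaf label to a
#'   nucleotide.
#' @return `TRUE` if the column is compatible with the tree.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1,E:1);")
#' site_is_congruent(tr, c(A = "T", B = "T", C = "G", D = "G", E = "G")) # TRUE
#' site_is_congruent(tr, c(A = "T", C = "T", B = "G", D = "G", E = "G")) # FALSE
#' @export
site_is_congruent <- function(tree, column) {
  tree <- validate_tree(tree, require_lengths = FALSE)
  labs <- tree$tip.label
  if (is.null(names(column))) {
    stop("`column` must be named by leaf label", call. = FALSE)
  }
  unknown <- setdiff(names(column), labs)
  if (length(unknown)) {
    stop("unknown label(s) in column: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bases <- rep(NA_character_, length(labs))
  bases[match(names(column), labs)] <- as.character(column)
  cache <- bip_cache(tree)
  enc <- encode_bases(bases)
  ok <- !is.na(enc)
  classes <- split(which(ok), enc[ok])
  classes_convex(cache, classes)
}

#' Congruence of many alignment columns with a tree
#'
#' Vectorized version of [site_is_congruent()] for whole alignments: biallelic
#' columns are resolved by canonical split-key lookup against the tree's
#' bipartition set; columns with three or more alleles fall back to the exact
#' convexity check.
#'
#' @param tree a `phylo` object.
#' @param alignment a character matrix (taxa in rows, rownames = leaf labels).
#' @param sites integer vector of 1-based column indices to classify
#'   (default: all columns).
#' @return a logical vector, one element per requested site.
#' @export
sites_congruence <- function(tree, alignment, sites = NULL) {
  tree <- validate_tree(tree, require_lengths = FALSE)
  alignment <- validate_alignment(alignment)
  labs <- tree$tip.label
  idx <- match(labs, rownames(alignment))
  if (anyNA(idx)) {
    stop("alignment is missing taxa: ",
         paste(labs[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  sites <- sites %||% seq_len(ncol(alignment))
  cache <- bip_cache(tree)
  keyset <- new.env(parent = emptyenv())
  for (k in cache$keys) assign(k, TRUE, envir = keyset)
  out <- logical(length(sites))
  for (j in seq_along(sites)) {
    enc <- encode_bases(alignment[idx, sites[j]])
    ok <- which(!is.na(enc))
    if (length(ok) == 0L) { out[j] <- TRUE; next }
    classes <- split(ok, enc[ok])
    big <- classes[lengths(classes) >= 2L]
    if (length(big) <= 1L) {
      out[j] <- TRUE
    } else if (length(classes) == 2L && length(ok) == cache$n) {
      # split-key lookup is only exact with no missing data in the column

      out[j] <- exists(split_key(classes[[1L]], cache), envir = keyset,
                       inherits = FALSE)
    } else {
      out[j] <- classes_convex(cache, classes)
    }
  }
  out
}
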