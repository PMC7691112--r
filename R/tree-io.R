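#' Read a Newick tree
#'
#' Parses a Newick string (or a file containing one) into an [ape::phylo]
#' object and validates it for use in the simulation and topology-comparison
#' machinery: leaf labels must be unique and non-empty, and branch lengths
#' (expected substitutions per site) must be finite and non-negative.
#'
#' @param text a Newick string, or `NULL` if `file` is given.
#' @param file path to a Newick file.
#' @return an object of class `phylo` with branch lengths.
#' @examples
#' tr <- read_newick("((A:0.1,B:0.1):0.05,C:0.15);")
#' @seealso [write_newick()]
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file)) {
    stop("supply either `text` or `file`", call. = FALSE)
  }
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(file = file) else ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w),
                               call. = FALSE)
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("Newick parse error: input is not a single well-formed tree",
         call. = FALSE)
  }
  validate_tree(tr)
}

#' Write a tree as a Newick string
#'
#' @param tree a `phylo` object.
#' @param file optional path; if omitted the Newick string is returned.
#' @param digits number of significant digits for branch lengths.
#' @return the Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  tree <- validate_tree(tree, require_lengths = FALSE)
  if (is.null(file)) {
    ape::write.tree(tree, digits = digits)
  } else {
    ape::write.tree(tree, file = file, digits = digits)
    invisible(ape::write.tree(tree, digits = digits))
  }
}

# Shared tree validation used by every entry point that accepts a tree.
validate_tree <- function(tree, require_lengths = TRUE) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a `phylo` object",
                                     call. = FALSE)
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("tree has empty leaf labels", call. = FALSE)
  dup <- labs[duplicated(labs)]
  if (length(dup)) {
    stop("duplicate leaf label(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    if (require_lengths) stop("tree has no branch lengths", call. = FALSE)
    return(tree)
  }
  bad <- !is.finite(tree$edge.length) | tree$edge.length < 0
  if (any(bad)) {
    child <- tree$edge[which(bad)[1], 2]
    who <- if (child <= length(labs)) labs[child] else paste0("node ", child)
    stop(sprintf("negative or non-finite branch length (%s) on the edge to %s",
                 format(tree$edge.length[which(bad)[1]]), who), call. = FALSE)
  }
  tree
}
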