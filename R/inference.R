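# Tree re-inference from alignments: pairwise distances, BIONJ, bootstrap
# supports by column resampling, and an adapter for an external
# maximum-likelihood program.

#' Pairwise distance matrix from an alignment
#'
#' p-distances over unambiguous shared sites (pairwise deletion), optionally
#' Jukes-Cantor corrected: `d = -(3/4) * log(1 - 4p/3)`.  Saturated pairs
#' (p > 0.74) are capped at the distance corresponding to p = 0.74 with a
#' warning, so neighbor joining stays runnable on pathological
#' high-recombination replicates.
#'
#' @param alignment a character matrix (taxa x sites) with >= 3 sequences.
#' @param correction `"JC69"` (default) or `"raw"`.
#' @return a symmetric numeric matrix with zero diagonal, labelled by taxon;
#'   attribute `correction` records the model.
#' @export
distance_matrix <- function(alignment, correction = c("JC69", "raw")) {
  correction <- match.arg(correction)
  alignment <- validate_alignment(alignment)
  if (nrow(alignment) < 3) stop("need >= 3 sequences", call. = FALSE)
  p <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(alignment)),
                               model = "raw", pairwise.deletion = TRUE))
  if (any(!is.finite(p))) {
    bad <- which(!is.finite(p) & upper.tri(p), arr.ind = TRUE)[1, ]
    stop(sprintf("no comparable sites between '%s' and '%s'",
                 rownames(p)[bad[1]], colnames(p)[bad[2]]), call. = FALSE)
  }
  if (correction == "JC69") {
    if (any(p > 0.74)) {
      warning("saturated distances (p > 0.74) capped", call. = FALSE)
      p <- pmin(p, 0.74)
    }
    p <- -0.75 * log(1 - 4 * p / 3)
  }
  diag(p) <- 0
  attr(p, "correction") <- correction
  p
}

#' BIONJ tree from a distance matrix
#'
#' Neighbor-joining agglomeration with BIONJ variance-weighted distance
#' updates; negative intermediate branch lengths are clamped to zero
#' (topology unaffected).
#'
#' @param matrix a symmetric distance matrix with taxon labels.
#' @return an unrooted `phylo` tree.
#' @export
bionj_tree <- function(matrix) {
  if (!is.matrix(matrix) || !isSymmetric(unname(matrix), tol = 1e-8)) {
    stop("`matrix` must be a symmetric distance matrix", call. = FALSE)
  }
  tr <- ape::bionj(matrix)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Distance + BIONJ tree builder
#'
#' Convenience composition of [distance_matrix()] and [bionj_tree()]; the
#' default builder throughout the pipeline.
#'
#' @param alignment a character matrix (taxa x sites).
#' @param correction distance correction, see [distance_matrix()].
#' @return an unrooted `phylo` tree.
#' @export
build_bionj <- function(alignment, correction = "JC69") {
  bionj_tree(distance_matrix(alignment, correction))
}

#' Bootstrap supports by column resampling
#'
#' Builds the point tree from the full alignment, then resamples alignment
#' columns with replacement to the original length `replicates` times,
#' rebuilds a tree from each pseudo-alignment, and scores every nontrivial
#' bipartition of the point tree by the percentage of replicate trees that
#' contain it.  The replicate RNG stream is indexed by replicate number, so
#' supports are invariant to taxon order.
#'
#' @param alignment a character matrix (taxa x sites).
#' @param builder a function `alignment -> phylo` (default [build_bionj()]).
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @return an object of class `supported_tree`: list with `tree` (the point
#'   tree), `supports` (percent per nontrivial bipartition, named by the
#'   sorted labels of one side), `mean_support`, and `replicates`.
#' @export
bootstrap_supports <- function(alignment, builder = build_bionj,
                               replicates = 100, seed) {
  alignment <- validate_alignment(alignment)
  assert_number(replicates, "replicates", lower = 1)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  point <- builder(alignment)
  labs <- sort(point$tip.label)
  cache <- bip_cache(point, labs)
  counts <- integer(length(cache$keys))
  L <- ncol(alignment)
  for (r in seq_len(replicates)) {
    idx <- with_seed(derive_seed(seed, r),
                     sample.int(L, L, replace = TRUE))
    rep_tree <- tryCatch(builder(alignment[, idx, drop = FALSE]),
                         error = function(e) {
                           stop(sprintf(
                             "builder failed on replicate %d (seed %d): %s",
                             r, derive_seed(seed, r), conditionMessage(e)),
                             call. = FALSE)
                         })
    counts <- counts + (cache$keys %in% bip_cache(rep_tree, labs)$keys)
  }
  supports <- 100 * counts / replicates
  # name each bipartition by the side not containing the first label, so the
  # name is invariant to rooting and taxon order
  names(supports) <- vapply(cache$key_edge, function(e) {
    z <- cache$D[e, ]
    if (z[1]) z <- !z
    paste(labs[z], collapse = ",")
  }, "")
  structure(list(tree = point, supports = supports,
                 mean_support = mean(supports),
                 replicates = as.integer(replicates)),
            class = "supported_tree")
}

#' @export
print.supported_tree <- function(x, ...) {
  cat(sprintf(
    "supported_tree: %d taxa, %d internal bipartitions, mean support %.1f%% (%d replicates)\n",
    length(x$tree$tip.label), length(x$supports), x$mean_support,
    x$replicates))
  invisible(x)
}

#' Attach bootstrap supports as internal node labels
#'
#' @param x a `supported_tree`.
#' @return a `phylo` with `node.label` set to the support percentages.
#' @export
as_supported_phylo <- function(x) {
  stopifnot(inherits(x, "supported_tree"))
  tr <- x$tree
  labs <- sort(tr$tip.label)
  cache <- bip_cache(tr, labs)
  ntip <- length(tr$tip.label)
  nl <- rep("", tr$Nnode)
  for (j in seq_along(cache$key_edge)) {
    ch <- cache$edge[cache$key_edge[j], 2]
    nl[ch - ntip] <- format(x$supports[j])
  }
  tr$node.label <- nl
  tr
}

#' Is an external maximum-likelihood backend available?
#'
#' @param program optional explicit program path or name.
#' @return the resolved program path, or `""` if none is found.
#' @export
ml_backend <- function(program = NULL) {
  candidates <- c(program, Sys.getenv("RECOMPHY_ML", ""),
                  "fasttree", "FastTree", "VeryFastTree")
  for (p in candidates[nzchar(candidates)]) {
    hit <- Sys.which(p)
    if (nzchar(hit)) return(unname(hit))
  }
  ""
}

#' External maximum-likelihood tree adapter
#'
#' Delegates tree inference to an external ML program run under a GTR + Gamma
#' model (FastTree-compatible command line: `-nt -gtr -gamma`) and parses its
#' Newick output.  No likelihood math is re-implemented; every pipeline stage
#' accepts this builder interchangeably with [build_bionj()].  If no backend
#' is installed the error condition has class `ml_backend_unavailable`,
#' distinguishable from an inference failure.
#'
#' @param alignment a character matrix (taxa x sites).
#' @param workdir directory for temporary files (default: a fresh tempdir).
#' @param program optional program name/path; by default `fasttree` and
#'   friends are searched on the PATH (override with the `RECOMPHY_ML`
#'   environment variable).
#' @return an unrooted `phylo` tree.
#' @export
external_ml_adapter <- function(alignment, workdir = tempfile("mlwork"),
                                program = NULL) {
  alignment <- validate_alignment(alignment)
  prog <- ml_backend(program)
  if (!nzchar(prog)) {
    stop(structure(class = c("ml_backend_unavailable", "error", "condition"),
                   list(message = paste(
                     "ML backend unavailable: no GTR+Gamma maximum-likelihood",
                     "program (e.g. fasttree) found on the PATH"),
                     call = NULL)))
  }
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  aln_file <- file.path(workdir, "aln.fasta")
  write_fasta(alignment, aln_file)
  out <- suppressWarnings(system2(prog, c("-nt", "-gtr", "-gamma", "-quiet",
                                          "-nosupport", shQuote(aln_file)),
                                  stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status") %||% 0L
  txt <- paste(out, collapse = "")
  if (status != 0 || !nzchar(txt)) {
    stop("ML program failed (exit ", status, "); output: ",
         substr(txt, 1, 500), call. = FALSE)
  }
  tr <- tryCatch(read_newick(text = txt), error = function(e) {
    stop("could not parse ML program output as Newick: ",
         conditionMessage(e), "; raw output: ", substr(txt, 1, 500),
         call. = FALSE)
  })
  tr
}

#' ML tree builder for pipelines
#'
#' Same signature as [build_bionj()]; wraps [external_ml_adapter()].
#'
#' @param alignment a character matrix (taxa x sites).
#' @return an unrooted `phylo` tree.
#' @export
build_ml <- function(alignment) external_ml_adapter(alignment)
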