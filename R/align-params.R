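# Estimation of per-species simulation parameters from a core-genome
# alignment: GC-content, transition/transversion ratio, relative substitution
# rates per codon position, and per-branch substitution means.

#' Simulation parameters for one species
#'
#' Bundles the quantities the simulator needs: GC-content of the root
#' sequence, the transition/transversion rate ratio `kappa` (K80 convention:
#' per-event transition probability is `kappa / (kappa + 2)`), relative
#' substitution rates of the three codon positions (normalized to mean 1),
#' and the alignment length in sites.
#'
#' @param gc GC fraction in \[0, 1\].
#' @param kappa transition/transversion rate ratio, > 0.
#' @param codon_rates non-negative relative rates of codon positions 1..3;
#'   rescaled so their mean is 1.
#' @param length number of sites (positive integer).
#' @return an object of class `species_params`.
#' @export
species_params <- function(gc, kappa, codon_rates = c(1, 1, 1),
                           length = 100000L) {
  assert_number(gc, "gc", 0, 1)
  assert_number(kappa, "kappa", lower = .Machine$double.eps)
  assert_number(length, "length", lower = 1)
  if (!is.numeric(codon_rates) || length(codon_rates) != 3L ||
      any(!is.finite(codon_rates)) || any(codon_rates < 0) ||
      sum(codon_rates) == 0) {
    stop("`codon_rates` must be 3 non-negative finite rates, not all zero",
         call. = FALSE)
  }
  structure(list(gc = gc, kappa = kappa,
                 codon_rates = 3 * codon_rates / sum(codon_rates),
                 length = as.integer(length)),
            class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf(
    "species_params: gc = %.3f, kappa = %.3f, codon rates = (%.3f, %.3f, %.3f), L = %d\n",
    x$gc, x$kappa, x$codon_rates[1], x$codon_rates[2], x$codon_rates[3],
    x$length))
  invisible(x)
}

#' GC-content of an alignment
#'
#' Fraction (G + C) / (A + C + G + T); ambiguous characters are excluded.
#'
#' @param alignment a character matrix (taxa x sites).
#' @return GC fraction in \[0, 1\].
#' @export
estimate_gc <- function(alignment) {
  alignment <- validate_alignment(alignment)
  gc <- sum(alignment == "G" | alignment == "C")
  at <- sum(alignment == "A" | alignment == "T")
  if (gc + at == 0) stop("alignment contains no unambiguous bases",
                         call. = FALSE)
  gc / (gc + at)
}

#' Transition/transversion ratio from pairwise differences
#'
#' Counts transition (A<->G, C<->T) and transversion differences over all
#' sequence pairs and sites (no multiple-hit correction; appropriate for the
#' low intra-species divergences this package targets) and returns the ratio
#' ti/tv.
#'
#' Note on conventions: the simulator's `kappa` is a rate ratio with
#' per-substitution transition probability `kappa / (kappa + 2)`, so at low
#' divergence the observed count ratio returned here is approximately
#' `kappa / 2`.  Recovering the simulator's parameter from data therefore
#' means doubling this estimate; parameter-recovery tests are calibrated
#' accordingly.
#'
#' @param alignment a character matrix with >= 2 sequences.
#' @param pseudocount if `TRUE`, add 1 to the transversion count so the ratio
#'   is defined when no transversions are observed.
#' @return the observed ti/tv ratio.
#' @export
estimate_kappa <- function(alignment, pseudocount = FALSE) {
  alignment <- validate_alignment(alignment)
  if (nrow(alignment) < 2) stop("need >= 2 sequences", call. = FALSE)
  enc <- matrix(encode_bases(alignment), nrow(alignment), ncol(alignment))
  ti <- 0; tv <- 0
  for (i in seq_len(nrow(enc) - 1)) {
    for (j in (i + 1):nrow(enc)) {
      a <- enc[i, ]; b <- enc[j, ]
      comp <- !is.na(a) & !is.na(b) & a != b
      if (!any(comp)) next
      prod <- a[comp] * b[comp]
      nti <- sum(prod == 3L | prod == 8L)    # 1*3 = A.G, 2*4 = C.T
      ti <- ti + nti
      tv <- tv + sum(comp) - nti
    }
  }
  if (tv == 0) {
    if (!pseudocount) {
      stop("no transversion differences observed; ",
           "use `pseudocount = TRUE` to add 1 to the transversion count",
           call. = FALSE)
    }
    tv <- 1
  }
  ti / tv
}

#' Relative substitution rates of codon positions
#'
#' The fraction of polymorphic columns (>= 2 distinct unambiguous
#' nucleotides; singletons count) is computed separately for the three codon
#' positions, and the three fractions are rescaled to mean 1.  A trailing
#' partial codon is ignored; columns with no unambiguous base at a position
#' are excluded from its denominator.  With no polymorphism at all the rates
#' default to (1, 1, 1).
#'
#' @param alignment a character matrix with length >= 3.
#' @return numeric vector of 3 relative rates with mean 1.
#' @export
estimate_codon_rates <- function(alignment) {
  alignment <- validate_alignment(alignment)
  L <- 3L * (ncol(alignment) %/% 3L)
  if (L < 3) stop("alignment must contain at least one full codon",
                  call. = FALSE)
  aln <- alignment[, seq_len(L), drop = FALSE]
  nd <- (colSums(aln == "A") > 0) + (colSums(aln == "C") > 0) +
    (colSums(aln == "G") > 0) + (colSums(aln == "T") > 0)
  posn <- rep_len(1:3, L)
  p <- vapply(1:3, function(k) {
    valid <- posn == k & nd >= 1
    if (!any(valid)) return(0)
    sum(nd[valid] >= 2) / sum(valid)
  }, numeric(1))
  if (sum(p) == 0) return(c(1, 1, 1))
  3 * p / sum(p)
}

#' Expected substitution counts per branch
#'
#' Converts branch lengths (expected substitutions per site) into the
#' Poisson mean number of substitutions m for an alignment of the given
#' length: `m = branch_length * length` (real-valued, not rounded).
#'
#' @param tree a `phylo` object with branch lengths.
#' @param length alignment length in sites (> 0).
#' @return numeric vector of per-edge means, named by the edge's child node
#'   (tip label for terminal edges, `node<id>` otherwise), in `tree$edge`
#'   order.
#' @export
branch_sub_mean <- function(tree, length) {
  tree <- validate_tree(tree)
  assert_number(length, "length", lower = .Machine$double.eps)
  m <- tree$edge.length * length
  names(m) <- lineage_names(tree)
  m
}

# Human-readable lineage id for each edge (child-node based).
lineage_names <- function(tree) {
  child <- tree$edge[, 2]
  n <- length(tree$tip.label)
  ifelse(child <= n, tree$tip.label[child], paste0("node", child))
}
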