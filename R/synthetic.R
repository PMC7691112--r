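# Synthetic species generator: trees, parameters, and covariates emulating
# the statistical structure of empirical bacterial core-genome datasets
# (13-55 strains per species, varied GC-content and transition/transversion
# ratios, uneven codon-position rates, low intra-species divergence), so the
# whole pipeline is testable without any external data.

SYNTH_RANGES <- list(
  n = c(13L, 55L),
  gc = c(0.25, 0.70),
  kappa = c(1, 4),
  divergence = c(0.005, 0.05),   # mean root-to-tip depth, subs/site
  dnds = c(0.04, 0.4)
)

#' Generate one synthetic species
#'
#' Draws a pure-birth (Yule) tree topology with exponential waiting times,
#' rescaled so the mean root-to-tip depth equals the target divergence, plus
#' simulation parameters from declared ranges: `n` uniform on 13..55, GC on
#' \[0.25, 0.70\], kappa on \[1, 4\], divergence log-uniform on
#' \[0.005, 0.05\] substitutions/site, dN/dS log-uniform on \[0.04, 0.4\]
#' (a covariate label only -- the simulator itself is neutral), and codon
#' rates with third positions fastest (r3 > r1 >= r2).
#'
#' @param seed integer seed; the same seed reproduces the species exactly.
#' @param n,gc,kappa,codon_rates,divergence,length,dnds optional overrides;
#'   overrides violating the declared invariants (e.g. `n` outside 13..55)
#'   are errors.
#' @return an object of class `synthetic_species`: list with `tree`,
#'   `params` (a [species_params()]), `n`, `divergence`, `dnds`, `seed`.
#' @export
random_species <- function(seed, n = NULL, gc = NULL, kappa = NULL,
                           codon_rates = NULL, divergence = NULL,
                           length = 100000L, dnds = NULL) {
  with_seed(seed, {
    n <- as.integer(n %||% sample(SYNTH_RANGES$n[1]:SYNTH_RANGES$n[2], 1L))
    if (n < SYNTH_RANGES$n[1] || n > SYNTH_RANGES$n[2]) {
      stop("`n` must be in [", SYNTH_RANGES$n[1], ", ", SYNTH_RANGES$n[2],
           "]", call. = FALSE)
    }
    gc <- gc %||% runif(1, SYNTH_RANGES$gc[1], SYNTH_RANGES$gc[2])
    assert_number(gc, "gc", SYNTH_RANGES$gc[1], SYNTH_RANGES$gc[2])
    kappa <- kappa %||% runif(1, SYNTH_RANGES$kappa[1], SYNTH_RANGES$kappa[2])
    assert_number(kappa, "kappa", lower = .Machine$double.eps)
    divergence <- divergence %||%
      exp(runif(1, log(SYNTH_RANGES$divergence[1]),
                log(SYNTH_RANGES$divergence[2])))
    assert_number(divergence, "divergence", lower = .Machine$double.eps)
    dnds <- dnds %||% exp(runif(1, log(SYNTH_RANGES$dnds[1]),
                                log(SYNTH_RANGES$dnds[2])))
    assert_number(dnds, "dnds", lower = .Machine$double.eps)
    if (is.null(codon_rates)) {
      slow <- sort(runif(2, 0.2, 1))            # r2 <= r1
      fast <- runif(1, max(slow) + 0.5, 3.5)    # r3 strictly fastest
      codon_rates <- c(slow[2], slow[1], fast)
    }
    params <- species_params(gc, kappa, codon_rates, length)
    tree <- ape::rphylo(n, birth = 1, death = 0)
    tree$tip.label <- sprintf("t%02d", seq_len(n))
    depths <- ape::node.depth.edgelength(tree)[seq_len(n)]
    tree$edge.length <- tree$edge.length * divergence / mean(depths)
    tree <- validate_tree(tree)
    structure(list(tree = tree, params = params, n = n,
                   divergence = divergence, dnds = dnds,
                   seed = as.integer(seed)),
              class = "synthetic_species")
  })
}

#' @export
print.synthetic_species <- function(x, ...) {
  cat(sprintf(
    "synthetic_species: n = %d taxa, divergence = %.4f subs/site, dN/dS = %.3f (seed %d)\n",
    x$n, x$divergence, x$dnds, x$seed))
  print(x$params)
  invisible(x)
}

#' Shrink internal branches to create a poorly resolved variant
#'
#' Returns a copy of the species in which a fraction of internal branches is
#' shrunk to `epsilon`, emulating real trees whose nodes are poorly
#' supported; downstream bootstrap supports for those clades collapse toward
#' chance.
#'
#' @param species a `synthetic_species`.
#' @param epsilon new length for the shrunk branches (>= 0, in
#'   substitutions/site).
#' @param fraction fraction of internal branches to shrink (default 0.5).
#' @param seed optional seed for choosing which branches; defaults to a
#'   stream derived from the species seed.
#' @return a `synthetic_species` with modified tree.
#' @export
unresolved_variant <- function(species, epsilon, fraction = 0.5,
                               seed = NULL) {
  stopifnot(inherits(species, "synthetic_species"))
  assert_number(epsilon, "epsilon", lower = 0)
  assert_number(fraction, "fraction", 0, 1)
  seed <- seed %||% derive_seed(species$seed, 777L)
  tree <- species$tree
  internal <- which(tree$edge[, 2] > length(tree$tip.label))
  k <- round(fraction * length(internal))
  if (k > 0) {
    pick <- with_seed(seed, sample(internal, k))
    tree$edge.length[pick] <- epsilon
  }
  species$tree <- tree
  species
}

#' Deterministic panel of synthetic species
#'
#' A Latin-hypercube design over `n`, GC, kappa, and divergence (log scale),
#' so a small panel spans the declared parameter ranges; a mini stand-in for
#' a large multi-species survey.
#'
#' @param n_species number of species (>= 1).
#' @param seed integer seed.
#' @param length alignment length passed to every species.
#' @return a list of `synthetic_species`.
#' @export
fixture_panel <- function(n_species, seed, length = 100000L) {
  assert_number(n_species, "n_species", lower = 1)
  with_seed(seed, {
    X <- lhs::randomLHS(n_species, 4)
    n <- as.integer(round(SYNTH_RANGES$n[1] +
                            X[, 1] * diff(SYNTH_RANGES$n)))
    gc <- SYNTH_RANGES$gc[1] + X[, 2] * diff(SYNTH_RANGES$gc)
    kappa <- SYNTH_RANGES$kappa[1] + X[, 3] * diff(SYNTH_RANGES$kappa)
    dv <- exp(log(SYNTH_RANGES$divergence[1]) +
                X[, 4] * diff(log(SYNTH_RANGES$divergence)))
    lapply(seq_len(n_species), function(i) {
      random_species(derive_seed(seed, i), n = n[i], gc = gc[i],
                     kappa = kappa[i], divergence = dv[i], length = length)
    })
  })
}
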