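# Shared fixtures, generated in code.  Heavier simulations are cached per
# test run so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# the canonical small test trees
tree5 <- function() read_newick("((A:1,B:1):1,(C:1,D:1):1,E:1);")
tree5b <- function() read_newick("((A:1,B:1):1,((C:1,D:1):1,E:1):1);")

# a 20-taxon synthetic species at desk scale
test_species <- function(length = 50000L) {
  sp <- random_species(42, n = 20, divergence = 0.02, length = length)
  sp
}

# a 20-taxon species whose internal branches are all well resolved
resolved_tree <- function(min_internal = 0.005) {
  sp <- test_species()
  tr <- sp$tree
  tr$edge.length <- pmax(tr$edge.length, min_internal)
  tr
}

# one clonal simulation shared across estimator tests
clonal_sim <- function() {
  cached("clonal_sim", {
    sp <- test_species(length = 30000L)
    evolve(sim_config(sp$tree, sp$params, rho = 0, delta = 100, seed = 11))
  })
}

# small alignment constructed from explicit columns (taxa x sites)
aln_from_cols <- function(cols, taxa) {
  m <- do.call(cbind, cols)
  rownames(m) <- taxa
  m
}

# independent brute-force congruence oracle: for every edge of the tree,
# remove it and flood-fill the two components; a biallelic split is
# congruent iff it is trivial or matches the components of some edge.
# Multi-allelic classes are checked by testing convexity class by class
# against all edge-removal component structures via connectivity of the
# class's leaves in the full graph minus other classes' Steiner... (only the
# biallelic case is used as an oracle).
oracle_biallelic_congruent <- function(tree, side_labels) {
  n <- length(tree$tip.label)
  side <- match(side_labels, tree$tip.label)
  if (length(side) < 2 || n - length(side) < 2) return(TRUE)
  edge <- tree$edge
  nv <- n + tree$Nnode
  for (e in seq_len(nrow(edge))) {
    adj <- vector("list", nv)
    for (i in seq_len(nrow(edge))[-e]) {
      a <- edge[i, 1]; b <- edge[i, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    comp <- integer(0)
    queue <- edge[e, 2]
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, adj[[v]])
    }
    tips_below <- sort(intersect(comp, seq_len(n)))
    if (identical(tips_below, sort(side)) ||
        identical(tips_below, sort(setdiff(seq_len(n), side)))) {
      return(TRUE)
    }
  }
  FALSE
}
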