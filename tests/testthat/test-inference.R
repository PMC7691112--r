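make_pair_aln <- function(p, L = 200) {
  a <- rep("A", L)
  b <- a
  if (p > 0) b[seq_len(round(p * L))] <- "G"
  rbind(A = a, B = b, C = a)
}

test_that("distance corrections follow the JC69 closed form with saturation cap", {
  d0 <- distance_matrix(make_pair_aln(0))
  expect_equal(d0["A", "B"], 0)
  expect_equal(d0["A", "C"], 0)
  d1 <- distance_matrix(make_pair_aln(0.1))
  expect_equal(d1["A", "B"], -0.75 * log(1 - 0.4 / 3), tolerance = 1e-8)
  expect_equal(distance_matrix(make_pair_aln(0.1), "raw")["A", "B"], 0.1)
  expect_warning(dcap <- distance_matrix(make_pair_aln(0.75)), "capped")
  expect_equal(dcap["A", "B"], -0.75 * log(1 - 4 * 0.74 / 3),
               tolerance = 1e-8)
  # monotone in p below the cap
  ds <- vapply(c(0.05, 0.2, 0.4, 0.6, 0.73),
               function(p) distance_matrix(make_pair_aln(p))["A", "B"],
               numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("pairs with no comparable sites are rejected by name", {
  aln <- rbind(x = c("A", "A", "N", "N"),
               y = c("N", "N", "A", "A"),
               z = c("A", "A", "A", "A"))
  expect_error(distance_matrix(aln), "x.*y")
})

test_that("bionj recovers the additive 4-taxon tree exactly", {
  # unrooted tree: A-X:1, B-X:2, X-Y:1, C-Y:3, D-Y:4
  m <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- bionj_tree(m)
  ref <- read_newick("((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(tts(ref, tr)$score, 100)
  expect_equal(sort(tr$edge.length), c(1, 1, 2, 3, 4))
  expect_error(bionj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("bionj is consistent on all 15 additive 5-taxon matrices", {
  seen <- character(0)
  seed <- 0
  while (length(seen) < 15 && seed < 500) {
    seed <- seed + 1
    tr <- random_topology(LETTERS[1:5], seed = seed)
    key <- paste(sort(vapply(bipartitions(tr), function(b)
      paste(sort(b$side), collapse = ""), "")), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    set.seed(seed + 9000)
    tr$edge.length <- runif(nrow(tr$edge), 0.5, 2)
    dm <- ape::cophenetic.phylo(tr)
    expect_equal(tts(tr, bionj_tree(dm))$score, 100, info = key)
  }
  expect_length(seen, 15)
})

test_that("bionj trees from clonal simulations match the generating tree", {
  sp <- test_species()
  tr <- sp$tree
  tr$edge.length <- pmax(tr$edge.length, 0.005)
  sim <- evolve(sim_config(tr, sp$params, rho = 0, delta = 100, seed = 17))
  expect_equal(tts(tr, build_bionj(sim$alignment))$score, 100)
})

test_that("bootstrap supports behave like clade resampling frequencies", {
  # perfect-signal alignment: 60 synapomorphy columns per true clade
  truth <- random_topology(sprintf("p%d", 1:8), seed = 2)
  cols <- list()
  for (b in bipartitions(truth)) {
    for (k in 1:60) {
      cols[[length(cols) + 1]] <-
        ifelse(truth$tip.label %in% b$side, "A", "C")
    }
  }
  for (k in 1:100) cols[[length(cols) + 1]] <- rep("G", 8)
  aln <- do.call(cbind, cols)
  rownames(aln) <- truth$tip.label
  bs <- bootstrap_supports(aln, replicates = 30, seed = 7)
  expect_equal(tts(truth, bs$tree)$score, 100)
  expect_true(all(bs$supports == 100))
  expect_equal(bs$mean_support, 100)
  # replicates = 1: supports are 0 or 100
  sim <- clonal_sim()
  b1 <- bootstrap_supports(sim$alignment[, 1:2000], replicates = 1, seed = 1)
  expect_true(all(b1$supports %in% c(0, 100)))
  # determinism
  b2 <- bootstrap_supports(sim$alignment[, 1:2000], replicates = 10, seed = 5)
  b3 <- bootstrap_supports(sim$alignment[, 1:2000], replicates = 10, seed = 5)
  expect_identical(b2$supports, b3$supports)
})

test_that("bootstrap supports are invariant to taxon order", {
  sim <- clonal_sim()
  aln <- sim$alignment[, 1:5000]
  perm <- rev(seq_len(nrow(aln)))
  b1 <- bootstrap_supports(aln, replicates = 20, seed = 4)
  b2 <- bootstrap_supports(aln[perm, ], replicates = 20, seed = 4)
  m <- match(names(b1$supports), names(b2$supports))
  expect_false(anyNA(m))
  expect_equal(unname(b1$supports), unname(b2$supports[m]))
  # supports export as internal node labels
  tr <- as_supported_phylo(b1)
  expect_length(tr$node.label, tr$Nnode)
})

test_that("the external ML adapter infers correct trees or fails cleanly", {
  sp <- random_species(12, n = 13, divergence = 0.02, length = 12000L)
  tr <- sp$tree
  tr$edge.length <- pmax(tr$edge.length, 0.005)
  sim <- evolve(sim_config(tr, sp$params, rho = 0, delta = 100, seed = 2))
  if (nzchar(ml_backend())) {
    ml <- external_ml_adapter(sim$alignment)
    expect_equal(tts(tr, ml)$score, 100)
    # both builders agree on easy data
    expect_equal(tts(tr, build_bionj(sim$alignment))$score, 100)
  } else {
    expect_error(external_ml_adapter(sim$alignment),
                 class = "ml_backend_unavailable")
  }
  # with no backend findable on the PATH, the error condition is distinctive
  old_path <- Sys.getenv("PATH")
  Sys.setenv(PATH = tempdir())
  err <- tryCatch(external_ml_adapter(sim$alignment[, 1:100]),
                  condition = function(c) c)
  Sys.setenv(PATH = old_path)
  expect_s3_class(err, "ml_backend_unavailable")
})
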