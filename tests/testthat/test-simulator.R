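test_that("root sequences honor the GC target and are reproducible", {
  s <- root_sequence(2000, gc = 1, seed = 1)
  expect_true(all(s %in% c("G", "C")))
  s2 <- root_sequence(100000, gc = 0.5, seed = 2)
  expect_lt(abs(mean(s2 %in% c("G", "C")) - 0.5), 0.005)
  expect_identical(root_sequence(50, 0.4, seed = 3),
                   root_sequence(50, 0.4, seed = 3))
  expect_error(root_sequence(10, gc = 1.5), "gc")
})

test_that("time segments partition the tree into contemporaneous slices", {
  ts <- time_segments(read_newick("((A:1,B:1):1,C:2);"))
  expect_equal(ts$start, c(0, 1))
  expect_equal(ts$end, c(1, 2))
  expect_equal(ts$n_alive, c(2, 3))
  expect_setequal(ts$alive[[2]], c("A", "B", "C"))
  expect_true("C" %in% ts$alive[[1]])
  # ultrametric balanced 4-leaf: two slices with 2 then 4 lineages
  ts2 <- time_segments(read_newick("((A:1,B:1):1,(C:1,D:1):1);"))
  expect_equal(ts2$n_alive, c(2, 4))
  # single cherry
  ts3 <- time_segments(read_newick("(A:1,B:1);"))
  expect_equal(nrow(ts3), 1)
  expect_setequal(ts3$alive[[1]], c("A", "B"))
})

test_that("clonal runs have no recombination and reproduce bit-identically", {
  sim <- clonal_sim()
  expect_equal(sim$n_events, 0)
  expect_equal(sim$r_total, 0)
  expect_equal(sim$rm, 0)
  expect_equal(nrow(sim$events), 0)
  sp <- test_species(length = 30000L)
  again <- evolve(sim_config(sp$tree, sp$params, rho = 0, delta = 100,
                             seed = 11))
  expect_identical(sim$alignment, again$alignment)
  expect_identical(sim$m_realized, again$m_realized)
  expect_error(sim_config(sp$tree, sp$params, rho = 0), "seed")
})

test_that("realized event rates follow the configured Poisson intensities", {
  sp <- test_species()
  sim <- evolve(sim_config(sp$tree, sp$params, rho = 1, delta = 100,
                           seed = 21))
  se <- sqrt(sim$n_events) / sim$m_realized
  expect_lt(abs(sim$rho_m - 1), 3 * se)
  # substitution totals are Poisson across replicates (dispersion test)
  triplet <- read_newick("(A:0.05,B:0.05,C:0.05);")
  pars <- species_params(0.5, 2, c(1, 1, 1), 5000)
  ms <- vapply(1:200, function(i)
    evolve(sim_config(triplet, pars, 0, seed = 3000 + i))$m_realized,
    numeric(1))
  ratio <- (length(ms) - 1) * var(ms) / mean(ms)
  expect_gt(ratio, qchisq(0.0005, length(ms) - 1))
  expect_lt(ratio, qchisq(0.9995, length(ms) - 1))
})

test_that("the substitution spectrum follows kappa and the codon rates", {
  sp <- random_species(5, n = 15, kappa = 3, divergence = 0.02,
                       length = 30000L)
  sim <- evolve(sim_config(sp$tree, sp$params, rho = 0, delta = 100,
                           seed = 8))
  frac_ti <- sim$ti_realized / sim$m_realized
  p <- 3 / 5                                     # kappa/(kappa+2)
  se <- sqrt(p * (1 - p) / sim$m_realized)
  expect_lt(abs(frac_ti - p), 4 * se)
  # codon rates (0,0,3): every polymorphism sits on a third position
  sp3 <- random_species(6, n = 15, codon_rates = c(0, 0, 3),
                        divergence = 0.01, length = 9999L)
  sim3 <- evolve(sim_config(sp3$tree, sp3$params, rho = 0, delta = 100,
                            seed = 9))
  nall <- (colSums(sim3$alignment == "A") > 0) +
    (colSums(sim3$alignment == "C") > 0) +
    (colSums(sim3$alignment == "G") > 0) +
    (colSums(sim3$alignment == "T") > 0)
  poly <- which(nall >= 2)
  expect_gt(length(poly), 0)
  expect_true(all(poly %% 3 == 0))
})

test_that("recombination bookkeeping is internally consistent", {
  sp <- test_species()
  sim <- evolve(sim_config(sp$tree, sp$params, rho = 2, delta = 100,
                           seed = 31))
  ev <- sim$events
  expect_equal(sum(ev$alleles_transferred), sim$r_total)
  expect_equal(sum(ev$tract_length), sim$tract_bp)
  expect_equal(nrow(ev), sim$n_events)
  expect_true(all(ev$alleles_transferred <= ev$tract_length))
  expect_true(all(ev$start >= 1 &
                    ev$start + ev$tract_length - 1 <= sp$params$length))
  expect_false(any(ev$donor == ev$recipient))
  mm <- measure_rm(sim)
  expect_lt(abs(sim$rm - mm$rho_m * mm$delta_realized * mm$nu) / sim$rm,
            1e-6)
})

test_that("recombining identical genomes transfers no alleles", {
  # branch lengths so short that no mutation ever lands, with a huge rho so
  # recombination events still occur between the (identical) lineages
  tr <- read_newick("((A:0.000001,B:0.000001):0.000001,C:0.000002);")
  pars <- species_params(0.5, 2, c(1, 1, 1), 1000)
  sim <- evolve(sim_config(tr, pars, rho = 20000, delta = 50, seed = 4))
  expect_gt(sim$n_events, 0)
  expect_equal(sim$m_realized, 0)
  expect_equal(sim$r_total, 0)
})

test_that("expected allele transfer increases with rho", {
  sp <- test_species(length = 20000L)
  mean_r <- vapply(c(0.5, 1, 2), function(rho) {
    mean(vapply(1:20, function(i)
      evolve(sim_config(sp$tree, sp$params, rho = rho, delta = 100,
                        seed = 100 * rho + i))$r_total, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})

test_that("mean realized tract length matches the geometric mean parameter", {
  sp <- test_species()
  pars <- species_params(0.5, 2, c(1, 1, 1), 100000L)
  sim <- evolve(sim_config(sp$tree, pars, rho = 2, delta = 100, seed = 6))
  expect_gte(sim$n_events, 10000)
  expect_lt(abs(sim$tract_bp / sim$n_events - 100), 3)
})
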