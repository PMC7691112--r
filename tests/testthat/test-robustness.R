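test_that("grid cells record clonal consistency and bookkeeping", {
  sp <- test_species(length = 20000L)
  g <- run_grid(sp$tree, sp$params, rho_values = 0, seed = 301)
  expect_equal(nrow(g), 1)
  expect_equal(g$rm, 0)
  expect_equal(g$rho_m, 0)
  expect_equal(g$tts, 100)
  # duplicate rho values get distinct derived seeds
  g2 <- run_grid(sp$tree, sp$params, rho_values = c(1, 1), seed = 301)
  expect_equal(nrow(g2), 2)
  expect_false(g2$seed[1] == g2$seed[2])
  expect_error(run_grid(sp$tree, sp$params, numeric(0), seed = 1),
               "non-empty")
  # a failing builder yields an NA row, not an abort
  boom <- function(alignment) stop("deliberate failure")
  expect_message(
    g3 <- run_grid(sp$tree, sp$params, rho_values = 0.5, seed = 302,
                   builder = boom),
    "failed")
  expect_true(is.na(g3$tts))
  expect_false(is.na(g3$rho))
})

test_that("realized event rates increase along the configured rho grid", {
  sp <- test_species(length = 20000L)
  rhos <- c(0.5, 1, 2)
  mean_rho_m <- vapply(seq_along(rhos), function(i) {
    g <- do.call(rbind, lapply(1:5, function(s)
      run_grid(sp$tree, sp$params, rhos[i], seed = 500 * s + i)))
    mean(g$rho_m)
  }, numeric(1))
  expect_true(all(diff(mean_rho_m) > 0))
})

test_that("spearman matches worked examples and brute-force enumeration", {
  expect_equal(spearman(1:6, 2 * (1:6))$rho, 1)
  expect_equal(spearman(1:6, -(1:6))$rho, -1)
  sp <- spearman(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(sp$rho, 0.8)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:3, 1:4), "equal length")
  skip_if_not_installed("e1071")
  set.seed(10)
  for (n in 5:7) {
    x <- rnorm(n); y <- rnorm(n)
    mine <- spearman(x, y)
    P <- e1071::permutations(n)
    rx <- rank(x); ry <- rank(y)
    svals <- apply(P, 1, function(p) sum((rx - ry[p])^2))
    s_obs <- sum((rx - ry)^2)
    p_enum <- min(1, 2 * min(mean(svals <= s_obs), mean(svals >= s_obs)))
    rho_enum <- 1 - 6 * s_obs / (n * (n^2 - 1))
    expect_equal(mine$rho, rho_enum, tolerance = 1e-12)
    expect_equal(mine$p_value, p_enum, tolerance = 1e-12)
  }
})

test_that("wilcoxon signed-rank matches full sign enumeration", {
  expect_warning(w0 <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(w0$p_value, 1)
  # constant positive shift, n = 10: exact one-sided tail 1/1024
  expect_equal(wilcoxon_signed_rank(2:11 + 5, 2:11)$p_value, 2 / 1024)
  # full enumeration oracle, with and without ties in |d|
  enum_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- signs %*% r
    mu <- sum(r) / 2
    p1 <- if (v > mu) mean(vs >= v) else mean(vs <= v)
    min(2 * p1, 1)
  }
  set.seed(3)
  for (rep in 1:5) {
    d <- round(rnorm(10), 2)
    expect_equal(wilcoxon_signed_rank(d, numeric(10))$p_value, enum_p(d))
  }
  d_tied <- c(1, -1, 2, 2, -2, 3, 4, -4, 5, 6, 6, -7)
  expect_equal(wilcoxon_signed_rank(d_tied, numeric(12))$p_value,
               enum_p(d_tied))
  # tie-free case agrees with the reference implementation
  set.seed(4)
  a <- rnorm(15); b <- rnorm(15)
  expect_equal(wilcoxon_signed_rank(a, b)$p_value,
               stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value)
})

test_that("robustness correlations find planted monotone structure", {
  set.seed(6)
  n <- 30
  bl <- runif(n, 0.001, 0.05)
  rec <- data.frame(
    mean_tts = 100 - 1200 * bl + rnorm(n, 0, 5),
    mean_branch_length = bl,
    dnds = rep(0.1, n),
    gc = runif(n, 0.25, 0.7))
  suppressMessages(tab <- correlate_robustness(rec))
  expect_true("mean_branch_length" %in% tab$covariate)
  expect_lt(tab$rho[tab$covariate == "mean_branch_length"], -0.5)
  # constant and absent covariates are skipped
  expect_false("dnds" %in% tab$covariate)
  expect_false("n" %in% tab$covariate)
  expect_false("mean_bootstrap_real" %in% tab$covariate)
})

test_that("correlations are calibrated under a shuffled (null) covariate", {
  set.seed(8)
  n <- 25
  rec0 <- data.frame(mean_tts = runif(n, 20, 100))
  pvals <- vapply(1:100, function(i) {
    rec0$gc <- sample(runif(n, 0.25, 0.7))
    suppressMessages(tab <- correlate_robustness(rec0))
    tab$p_value[tab$covariate == "gc"]
  }, numeric(1))
  expect_lt(mean(pvals < 0.05), 0.15)
  expect_gt(mean(pvals), 0.3)
})
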