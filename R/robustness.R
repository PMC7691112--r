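# The recombination-rate grid sweep and the cross-species statistical
# analyses: TTS-vs-r/m curves, bootstrap summaries, paired method comparison,
# and Spearman rank correlations of tree robustness against species
# covariates.

#' Simulate-infer-score over a grid of recombination rates
#'
#' One simulate -> infer -> TTS cycle per value of `rho`, with the realized
#' effective rate `r/m` recorded for each cell so the degradation curve can
#' be plotted against either axis.  A failed cell is recorded as `NA`, not
#' fatal.
#'
#' @param tree the true tree (`phylo`).
#' @param params a [species_params()] object.
#' @param rho_values non-negative recombination rates (events per
#'   substitution); the full published design is `seq(0, 10, by = 0.1)`.
#' @param delta mean recombination tract length in bp.
#' @param seed integer master seed; each cell uses a derived seed, recorded
#'   in the output.
#' @param builder tree builder, default [build_bionj()].
#' @param bootstrap_replicates if > 0, also compute the mean bootstrap
#'   support per cell.
#' @return a data frame with one row per grid cell: `rho`, `rm`, `rho_m`,
#'   `tts`, `mean_bootstrap`, `builder`, `seed`.
#' @export
run_grid <- function(tree, params, rho_values, delta = 100, seed,
                     builder = build_bionj, bootstrap_replicates = 0) {
  tree <- validate_tree(tree)
  if (length(rho_values) == 0 || any(rho_values < 0)) {
    stop("`rho_values` must be non-empty and non-negative", call. = FALSE)
  }
  builder_name <- if (identical(builder, build_ml)) "ml" else "bionj"
  rows <- lapply(seq_along(rho_values), function(i) {
    cell_seed <- derive_seed(seed, i)
    row <- data.frame(rho = rho_values[i], rm = NA_real_, rho_m = NA_real_,
                      tts = NA_real_, mean_bootstrap = NA_real_,
                      builder = builder_name, seed = cell_seed,
                      stringsAsFactors = FALSE)
    tryCatch({
      sim <- evolve(sim_config(tree, params, rho = rho_values[i],
                               delta = delta, seed = cell_seed))
      row$rm <- sim$rm
      row$rho_m <- sim$rho_m
      row$tts <- tts(tree, builder(sim$alignment))$score
      if (bootstrap_replicates > 0) {
        row$mean_bootstrap <- bootstrap_supports(
          sim$alignment, builder, bootstrap_replicates,
          seed = derive_seed(cell_seed, 1L))$mean_support
      }
    }, error = function(e) {
      message("grid cell rho = ", rho_values[i], " failed: ",
              conditionMessage(e))
    })
    row
  })
  do.call(rbind, rows)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks on ties; the p-value uses the exact
#' permutation distribution for n <= 9 (tie-free) and the t-approximation
#' otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a list with `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = (n <= 9 && !ties)))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on the paired differences `a - b`.  Zero differences are
#' dropped (with a warning when all are zero, returning p = 1).  The exact
#' signed-rank null distribution (computed over all 2^n sign assignments of
#' the average ranks, so ties are handled exactly) is used for up to 25
#' nonzero pairs; beyond that a normal approximation with continuity and tie
#' corrections is used.
#'
#' @param a,b paired numeric vectors.
#' @return a list with `p_value`, `statistic` (V, the positive-rank sum),
#'   `n` (nonzero pairs), and `median_difference`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length",
                                   call. = FALSE)
  d <- a - b
  d <- d[!is.na(d)]
  md <- if (length(d)) stats::median(d) else NA_real_
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1", call. = FALSE)
    return(list(p_value = 1, statistic = 0, n = 0L,
                median_difference = md))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25) {
    # exact null distribution of V over all 2^n sign assignments, by
    # convolution on doubled (integer) ranks; handles tied absolute
    # differences (average ranks) exactly, unlike psignrank
    w <- as.integer(round(2 * r))
    dist <- numeric(sum(w) + 1L)
    dist[1] <- 1
    for (wi in w) {
      dist <- dist + c(numeric(wi), dist[seq_len(length(dist) - wi)])
    }
    dist <- dist / 2^n
    v2 <- as.integer(round(2 * v))
    mu2 <- sum(w) / 2
    p1 <- if (v2 > mu2) sum(dist[(v2 + 1L):length(dist)]) else
      sum(dist[seq_len(v2 + 1L)])
    p <- min(2 * p1, 1)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(2 * pnorm(-abs(z)), 1)
  }
  list(p_value = p, statistic = v, n = n, median_difference = md)
}

#' Rank correlations of tree robustness against species covariates
#'
#' For a table of per-species records, computes the Spearman correlation of
#' `mean_tts` (average topology score across that species' simulations)
#' against each available covariate: `mean_bootstrap_real`,
#' `mean_branch_length`, `dnds`, `gc`, and `n`.  Missing cells are excluded
#' pairwise; a covariate that is absent or constant is skipped with a
#' message.
#'
#' @param records a data frame with column `mean_tts` plus any of the
#'   covariates above.
#' @return a data frame with `covariate`, `rho`, `p_value`, `n_used`.
#' @export
correlate_robustness <- function(records) {
  if (!is.data.frame(records) || is.null(records$mean_tts)) {
    stop("`records` must be a data frame with a `mean_tts` column",
         call. = FALSE)
  }
  covs <- c("mean_bootstrap_real", "mean_branch_length", "dnds", "gc", "n")
  rows <- lapply(covs, function(cv) {
    if (is.null(records[[cv]])) {
      message("covariate `", cv, "` absent; skipped")
      return(NULL)
    }
    keep <- complete.cases(records$mean_tts, records[[cv]])
    if (sum(keep) < 5) {
      message("covariate `", cv, "` has fewer than 5 complete records; skipped")
      return(NULL)
    }
    if (length(unique(records[[cv]][keep])) < 2 ||
        length(unique(records$mean_tts[keep])) < 2) {
      message("covariate `", cv, "` (or mean_tts) is constant; skipped")
      return(NULL)
    }
    sp <- spearman(records$mean_tts[keep], records[[cv]][keep])
    data.frame(covariate = cv, rho = sp$rho, p_value = sp$p_value,
               n_used = sp$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(covariate = character(), rho = numeric(),
                      p_value = numeric(), n_used = integer(),
                      stringsAsFactors = FALSE)
  }
  out
}
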