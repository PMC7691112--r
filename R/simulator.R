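# Forward-in-time evolution of a core-genome alignment along a tree with
# mutations and homologous recombination between contemporaneous lineages.
#
# The tree's branch lengths (expected substitutions/site) double as the time
# axis: every branch is cut into segments by the depths of all nodes, so that
# within a segment the set of lineages alive is constant.  Per segment, each
# lineage draws a Poisson number of substitutions (mean = segment length x
# alignment length) and of recombination events (mean = rho x that), and all
# events of all contemporaneous lineages are pooled, globally shuffled, and
# applied sequentially -- a recipient can therefore receive alleles a donor
# itself just acquired.

DNA_CHR <- c("A", "C", "G", "T")
TI_PARTNER <- c(3L, 4L, 1L, 2L)                      # A<->G, C<->T
TV_PARTNER <- rbind(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))

#' Simulation configuration
#'
#' @param tree a `phylo` tree with >= 3 leaves and branch lengths in
#'   expected substitutions per site.
#' @param params a [species_params()] object (GC, kappa, codon rates,
#'   alignment length).
#' @param rho recombination events per substitution (>= 0).
#' @param delta mean recombination tract length in bp (>= 1); tract lengths
#'   are geometric with support 1, 2, ...
#' @param seed integer seed; mandatory, every random draw derives from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(tree, params, rho, delta = 100, seed) {
  tree <- validate_tree(tree)
  if (length(tree$tip.label) < 3) stop("tree must have >= 3 leaves",
                                       call. = FALSE)
  if (!inherits(params, "species_params")) {
    stop("`params` must be a `species_params` object", call. = FALSE)
  }
  assert_number(rho, "rho", lower = 0)
  assert_number(delta, "delta", lower = 1)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  assert_number(seed, "seed")
  structure(list(tree = tree, params = params, rho = rho, delta = delta,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Random root sequence
#'
#' I.i.d. nucleotides with P(G) = P(C) = gc/2 and P(A) = P(T) = (1 - gc)/2.
#'
#' @param length number of sites.
#' @param gc GC fraction in \[0, 1\].
#' @param seed optional integer seed.
#' @return a character vector of bases.
#' @export
root_sequence <- function(length, gc, seed = NULL) {
  assert_number(length, "length", lower = 1)
  assert_number(gc, "gc", 0, 1)
  draw <- function() DNA_CHR[root_sequence_int(length, gc)]
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

root_sequence_int <- function(length, gc) {
  sample.int(4L, length, replace = TRUE,
             prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Cluster node depths that differ only by floating-point noise and return the
# interval structure: breakpoints plus, per edge, the breakpoint indices of
# its parent and child depths.
depth_intervals <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  bp <- sort(unique(depth))
  if (length(bp) > 1) {
    tol <- 1e-9 * max(1, max(bp))
    keep <- c(TRUE, diff(bp) > tol)
    bp <- bp[keep]
  }
  snap <- vapply(depth, function(d) which.min(abs(bp - d)), integer(1))
  list(bp = bp,
       pdi = snap[tree$edge[, 1]],   # breakpoint index at parent depth
       cdi = snap[tree$edge[, 2]])   # breakpoint index at child depth
}

#' Contemporaneous segments of a tree
#'
#' Divides all branches into segments of branches overlapping in time.
#' Depth is cumulative branch length from the root; breakpoints fall at
#' every distinct node depth, and a lineage (edge) is alive on
#' `[depth(parent), depth(child))`.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @return a data frame with columns `start`, `end`, `n_alive`, and a list
#'   column `alive` of lineage names (edge child labels) per interval.
#' @export
time_segments <- function(tree) {
  tree <- validate_tree(tree)
  di <- depth_intervals(tree)
  nseg <- length(di$bp) - 1L
  nms <- lineage_names(tree)
  alive <- vector("list", max(nseg, 0L))
  for (iv in seq_len(nseg)) {
    alive[[iv]] <- nms[di$pdi <= iv & di$cdi >= iv + 1L]
  }
  out <- data.frame(start = di$bp[seq_len(nseg)],
                    end = di$bp[seq_len(nseg) + 1L],
                    n_alive = vapply(alive, length, integer(1)))
  out$alive <- alive
  out
}

#' Evolve an alignment along a tree with recombination
#'
#' Runs the forward-time simulation described in the package vignette:
#' substitutions pick a site with probability proportional to its
#' codon-position rate and mutate the current base (transition with
#' probability `kappa / (kappa + 2)`, each transversion with probability
#' `1 / (kappa + 2)`); recombination events pick a uniform tract start, a
#' geometric tract length with mean `delta` (truncated at the sequence end),
#' and a donor uniformly among the other lineages alive in the same time
#' segment, then overwrite the recipient's tract with the donor's copy.
#' Events of all contemporaneous lineages are applied in one globally
#' shuffled order.  An event drawn when no donor is alive is discarded and
#' not counted.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `sim_result`: a list with `alignment` (leaf
#'   character matrix), `events` (one row per recombination event: `depth`,
#'   `donor`, `recipient`, `start`, `tract_length`, `alleles_transferred`),
#'   `m_realized`, `ti_realized` (transitions among the applied
#'   substitutions), `n_events`, `r_total`, `tract_bp` (sum of realized tract
#'   lengths), `nu`, `rm`, `rho_m`, and the echoed `config`.
#' @export
evolve <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be created by `sim_config()`", call. = FALSE)
  }
  with_seed(config$seed, evolve_impl(config))
}

evolve_impl <- function(config) {
  tree <- config$tree
  L <- config$params$length
  gc <- config$params$gc
  kappa <- config$params$kappa
  rho <- config$rho
  delta <- config$delta
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  nedge <- nrow(edge)
  root <- ntip + 1L

  w <- rep_len(config$params$codon_rates, L)
  p_ti <- kappa / (kappa + 2)

  di <- depth_intervals(tree)
  bp <- di$bp; pdi <- di$pdi; cdi <- di$cdi
  nms <- lineage_names(tree)

  # children edges of each internal node, and a preorder rank so that chains
  # of zero-length edges propagate parent-first
  kids <- split(seq_len(nedge), edge[, 1])
  pre <- ape::reorder.phylo(tree, "cladewise")$edge[, 2]
  pre_rank <- integer(ntip + tree$Nnode)
  pre_rank[pre] <- seq_along(pre)
  pre_rank[root] <- 0L

  seqmat <- matrix(0L, L, nedge)
  leaf_seq <- matrix(0L, L, ntip)
  rootseq <- root_sequence_int(L, gc)
  for (e in kids[[as.character(root)]]) seqmat[, e] <- rootseq

  m_real <- 0
  ti_real <- 0
  n_ev <- 0
  r_total <- 0
  tract_bp <- 0
  ev_chunks <- list()

  propagate <- function(bpi) {
    ending <- which(cdi == bpi)
    for (e in ending[order(pre_rank[edge[ending, 2]])]) {
      ch <- edge[e, 2]
      if (ch <= ntip) {
        leaf_seq[, ch] <<- seqmat[, e]
      } else {
        for (f in kids[[as.character(ch)]]) seqmat[, f] <<- seqmat[, e]
      }
    }
  }

  propagate(1L)   # zero-length edges hanging directly off the root
  for (iv in seq_len(length(bp) - 1L)) {
    len <- bp[iv + 1L] - bp[iv]
    alive <- which(pdi <= iv & cdi >= iv + 1L)
    na <- length(alive)
    nsub <- rpois(na, len * L)
    nrec <- if (rho > 0) rpois(na, rho * len * L) else integer(na)
    tot_s <- sum(nsub); tot_r <- sum(nrec)
    if (tot_s + tot_r > 0) {
      ev_lin <- c(rep(alive, nsub), rep(alive, nrec))
      lin_pos <- c(rep(seq_len(na), nsub), rep(seq_len(na), nrec))
      ord <- sample.int(tot_s + tot_r)
      s_site <- if (tot_s) sample.int(L, tot_s, replace = TRUE, prob = w)
                else integer()
      s_isti <- runif(tot_s) < p_ti
      s_tv <- if (tot_s) sample.int(2L, tot_s, replace = TRUE) else integer()
      r_start <- if (tot_r) sample.int(L, tot_r, replace = TRUE) else integer()
      r_len <- if (tot_r) 1L + rgeom(tot_r, 1 / delta) else integer()
      r_u <- runif(tot_r)
      if (tot_r) {
        e_donor <- character(tot_r); e_recip <- character(tot_r)
        e_start <- integer(tot_r); e_tlen <- integer(tot_r)
        e_alle <- integer(tot_r)
        kept <- logical(tot_r)
      }
      for (k in ord) {
        lin <- ev_lin[k]
        if (k <= tot_s) {
          site <- s_site[k]
          old <- seqmat[site, lin]
          if (s_isti[k]) {
            seqmat[site, lin] <- TI_PARTNER[old]
            ti_real <- ti_real + 1
          } else {
            seqmat[site, lin] <- TV_PARTNER[old, s_tv[k]]
          }
          m_real <- m_real + 1
        } else {
          if (na < 2L) next                   # no possible donor: discard
          j <- k - tot_s
          di_ <- 1L + floor(r_u[j] * (na - 1L))
          if (di_ >= lin_pos[k]) di_ <- di_ + 1L
          donor <- alive[di_]
          a <- r_start[j]
          b <- min(L, a + r_len[j] - 1L)
          dseg <- seqmat[a:b, donor]
          nd <- sum(dseg != seqmat[a:b, lin])
          if (nd > 0) seqmat[a:b, lin] <- dseg
          kept[j] <- TRUE
          e_donor[j] <- nms[donor]; e_recip[j] <- nms[lin]
          e_start[j] <- a; e_tlen[j] <- b - a + 1L; e_alle[j] <- nd
          n_ev <- n_ev + 1
          r_total <- r_total + nd
          tract_bp <- tract_bp + (b - a + 1L)
        }
      }
      if (tot_r && any(kept)) {
        ev_chunks[[length(ev_chunks) + 1L]] <- data.frame(
          depth = bp[iv], donor = e_donor[kept], recipient = e_recip[kept],
          start = e_start[kept], tract_length = e_tlen[kept],
          alleles_transferred = e_alle[kept], stringsAsFactors = FALSE)
      }
    }
    propagate(iv + 1L)
  }

  aln <- matrix(DNA_CHR[t(leaf_seq)], ntip, L,
                dimnames = list(tree$tip.label, NULL))
  events <- if (length(ev_chunks)) do.call(rbind, ev_chunks) else
    data.frame(depth = numeric(), donor = character(),
               recipient = character(), start = integer(),
               tract_length = integer(), alleles_transferred = integer(),
               stringsAsFactors = FALSE)
  structure(list(
    alignment = aln, events = events,
    m_realized = m_real, ti_realized = ti_real,
    n_events = n_ev, r_total = r_total,
    tract_bp = tract_bp,
    nu = if (tract_bp > 0) r_total / tract_bp else 0,
    rm = if (m_real > 0) r_total / m_real else 0,
    rho_m = if (m_real > 0) n_ev / m_real else 0,
    config = config), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "sim_result: %d taxa x %d sites | m = %d substitutions, %d recombination events\n",
    nrow(x$alignment), ncol(x$alignment), x$m_realized, x$n_events))
  cat(sprintf("  r = %d alleles transferred, nu = %.4f, r/m = %.4f, rho/m = %.4f\n",
              x$r_total, x$nu, x$rm, x$rho_m))
  invisible(x)
}

#' Effective recombination rate of a simulation
#'
#' Summarizes the event bookkeeping of a [evolve()] run: `rm = r / m` (alleles
#' transferred by recombination per substitution), the per-site tract
#' polymorphism density `nu`, the realized event rate `rho_m = events / m`,
#' and the mean realized tract length.  By construction
#' `rm = rho_m * delta_realized * nu`.
#'
#' @param result a `sim_result`.
#' @return a list with `rm`, `nu`, `rho_m`, `delta_realized`.
#' @export
measure_rm <- function(result) {
  if (!inherits(result, "sim_result")) stop("`result` must be a `sim_result`",
                                            call. = FALSE)
  if (result$m_realized <= 0) {
    stop("no substitutions realized; r/m is undefined", call. = FALSE)
  }
  list(rm = result$rm, nu = result$nu, rho_m = result$rho_m,
       delta_realized = if (result$n_events > 0)
         result$tract_bp / result$n_events else NA_real_)
}
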