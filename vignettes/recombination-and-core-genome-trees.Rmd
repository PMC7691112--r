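---
title: "Simulating the impact of homologous recombination on core-genome phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the impact of homologous recombination on core-genome trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recomphy)
```

## The question

Intraspecies phylogenies of bacteria and archaea are routinely built from
core-genome alignments: hundreds of shared genes concatenated into one long
matrix.  Prokaryotes, however, exchange chromosomal segments by homologous
recombination (gene conversion), at rates that range from essentially clonal
to near-panmictic.  Every imported tract stamps the donor's genealogy onto
part of the recipient's genome, so individual alignment columns can disagree
with — be *incongruent* with — the clonal genealogy of the strains.  The
package provides the machinery to ask, with simulations: how much
recombination can a core genome absorb before the tree inferred from it stops
being the true tree, and what makes some datasets more fragile than others?

## The simulation model

`evolve()` runs a forward-in-time branching process along a user-supplied
tree whose branch lengths are expected substitutions per site.

* **Root genome.** An i.i.d. random sequence of length $L$ with a specified
  GC-content (`root_sequence()`).  The default $L$ is 100 kb.
* **Time axis.** Cumulative branch length from the root doubles as time.
  All branches are cut into segments at every distinct node depth
  (`time_segments()`), so within a segment the set of lineages alive is
  constant.  The tree need not be ultrametric; a lineage whose tip is
  shallow simply stops being available as a donor after its endpoint.
* **Substitutions.** On a lineage segment of length $\ell$ the substitution
  count is Poisson with mean $\ell L$.  Each substitution picks a site with
  probability proportional to its codon-position rate $(r_1, r_2, r_3)$
  (normalized to mean 1, so the overall rate per branch is preserved) and
  mutates the current base: a transition with probability
  $\kappa/(\kappa+2)$, each transversion with probability $1/(\kappa+2)$.
  This is the K80 convention: $\kappa$ is the ratio of the transition rate
  to each single transversion rate, so the *observed* pairwise
  transition:transversion count ratio at low divergence is $\approx
  \kappa/2$.  `estimate_kappa()` returns the raw observed count ratio;
  recovering the simulator's $\kappa$ from data means doubling it, and the
  parameter-recovery tests are calibrated that way.
* **Recombination.** On the same segment each lineage draws a Poisson number
  of recombination events with mean $\rho\,\ell L$, i.e. $\rho$ events per
  expected substitution.  An event picks a uniform tract start, a tract
  length from a geometric law with mean $\delta$ (support $\ge 1$ bp;
  default $\delta = 100$ bp, in the middle of the 50–500 bp range reported
  for bacterial gene conversion), and a donor uniformly among the *other*
  lineages alive in the segment.  The donor's current tract overwrites the
  recipient's; tracts overrunning the sequence end are truncated (linear
  concatenates, no circular wrap) and the realized length is recorded.  An
  event drawn while no other lineage is alive is discarded and not counted.
* **Interleaving.** All events of all lineages alive in a segment are pooled
  and applied in one globally shuffled order, so a recipient can import
  alleles that the donor itself acquired moments earlier — mutation and
  recombination act simultaneously, not branch by branch.

Every event is logged.  With $r$ the total number of sites actually changed
by recombination (donor differed from recipient) and $m$ the number of
substitutions applied, the *effective recombination rate* is

$$ r/m \;=\; \rho_m \,\cdot\, \delta_{\mathrm{realized}} \,\cdot\, \nu, $$

where $\rho_m$ is the realized event-per-substitution rate,
$\delta_{\mathrm{realized}}$ the mean realized tract length and $\nu$ the
per-site density of transferred polymorphisms within tracts
(`measure_rm()`).  The identity holds exactly, by construction of the
bookkeeping; it is asserted to $10^{-6}$ relative error in the tests.  Note
that $\nu$ is a *per-site* density: only then is the product
$\rho\,\delta\,\nu$ dimensionally an alleles-per-substitution rate.

### What the model deliberately leaves out

Indels, gene gain/loss, donors from outside the tree, recombination
hotspots, circular chromosomes, and selection.  GC-content enters only
through the root sequence; the substitution process is base-symmetric, so
GC erodes toward 0.5 over long trees.  At the intra-species divergences the
generator targets (mean root-to-tip depth 0.005–0.05 substitutions/site)
that erosion is negligible, which is why `estimate_gc()` recovers the root
GC to ±0.02.  dN/dS is carried as an input covariate only — the simulator is
neutral, and any association between selection and tree robustness is a
property of real data that these simulations do not generate.

## Scoring trees and sites

* **Tree topology score.** `tts(reference, test)` is the percentage of the
  reference tree's nontrivial bipartitions (unrooted splits with both sides
  $\ge 2$) present in the test tree.  Unrooted bipartitions make the score
  invariant to arbitrary rooting; for binary trees the score is symmetric in
  its arguments, and for an $n$-leaf binary reference the denominator is
  $n-3$.  Unresolved test trees are scored conservatively: only exact split
  matches count, the denominator stays the reference's.  The chance baseline
  is `random_topology()`, a uniform draw over unrooted binary labeled
  topologies by sequential leaf insertion; against a fixed 30-leaf tree its
  expected score is a few percent.
* **Site congruence.** `site_is_congruent()` asks whether all allele classes
  of a column can simultaneously be connected subtrees of the tree: for
  biallelic columns, whether the split is an edge of the tree (or trivial).
  Multi-allelic columns use the exact convexity criterion, implemented as
  pairwise vertex-disjointness of the classes' Steiner subtrees, which also
  covers multifurcating trees and missing data.  Monomorphic and
  singleton-only columns are congruent by convention: they cannot conflict
  with any topology.

## The one-event-per-site experiment

`run_incongruence_experiment()` reproduces the proof-of-concept at desk
scale: evolve clonally ($\rho = 0$), then in the resulting alignment visit
every informative site (two alleles each carried by $\ge 2$ strains), pick
one strain uniformly and reassign it to another allele present at the site
(`inject_one_event_per_site()`) — exactly one cell changes per informative
site.  The strain is drawn among *all* carriers at the site; the headline
outcome is insensitive to that choice, since any single reassignment almost
always breaks the split.  On a well-resolved 20-taxon tree with a 200 kb
genome, roughly 95% of informative sites become incongruent with the true
tree, yet the re-inferred topology still matches it perfectly: each
perturbed column loses one strain's worth of signal but keeps the rest, and
the sum over $10^4$–$10^5$ columns overwhelms the noise.  (The package
default for this experiment is 200 kb; 2 Mb runs are a parameter away but
add nothing qualitative.)

## Tree inference

The default builder is `build_bionj()`: pairwise p-distances with pairwise
deletion, Jukes–Cantor corrected ($d = -\tfrac{3}{4}\ln(1 - \tfrac{4p}{3})$)
— the minimal multiple-hit correction consistent with the simulator's
base-symmetric model — followed by BIONJ agglomeration.  Saturated pairs
($p > 0.74$) are capped at the $p = 0.74$ distance with a warning rather
than erroring: trees at such recombination rates are garbage either way, but
the pipeline keeps running.  Negative branch lengths are clamped to zero.
BIONJ is consistent on additive matrices; the tests verify exact recovery on
hand-solved 4- and 5-taxon matrices and on all 15 unrooted 5-taxon
topologies.

`bootstrap_supports()` resamples columns with replacement to the original
length, rebuilds, and scores each nontrivial bipartition of the point tree
by its replicate frequency; the replicate RNG stream is indexed by replicate
number, so supports do not depend on taxon order.  The mean support over
internal bipartitions is the "average bootstrap" used in the robustness
analyses.

Maximum-likelihood inference is an adapter (`external_ml_adapter()`), not a
re-implementation: it shells out to a GTR+Gamma ML program (FastTree's
command-line dialect) and parses the Newick it returns.  When no backend is
on the PATH the error has class `ml_backend_unavailable`, so pipelines can
fall back to the distance builder explicitly.  All analyses run with either
builder.

## The robustness sweep and correlations

`run_grid()` runs simulate→infer→score across a grid of $\rho$ values
(the full published design is $\rho = 0$ to $10$ in steps of $0.1$; note
that this is 101 points even though it is usually described as 100
simulations per species) and records both the configured $\rho$ and the
realized $r/m$ per cell, so degradation curves can be drawn against either
axis.  Failed cells become `NA` rows, never imputed.
`correlate_robustness()` then computes Spearman correlations of the mean
topology score against per-species covariates (mean bootstrap of the true
tree, mean branch length, dN/dS, GC, number of taxa), skipping absent or
constant columns.  The mean over a species' grid weights all grid points
equally.

The statistical wrappers are deliberately small: `spearman()` uses average
ranks with the exact permutation p-value for $n \le 9$ (t-approximation
otherwise), and `wilcoxon_signed_rank()` drops zero differences and uses the
exact signed-rank null for up to 25 pairs — computed by convolution over the
doubled average ranks, so tied $|d|$ are handled exactly — with a
continuity-corrected normal approximation beyond.  Both are checked against
full enumeration (all permutations; all $2^n$ sign assignments) in the test
suite.

## The synthetic species generator

`random_species()` fixes the study conditions for everything above: a
pure-birth (Yule) topology rescaled so the mean root-to-tip depth hits a
target divergence, with defaults drawn once per species —

| parameter  | default draw          | why |
|------------|-----------------------|-----|
| $n$        | uniform 13–55         | the strain-count range of small bacterial core-genome panels |
| GC         | uniform 0.25–0.70     | span of bacterial genomic GC |
| $\kappa$   | uniform 1–4           | typical observed ti/tv pressure |
| divergence | log-uniform 0.005–0.05 | intra-species core divergences; log scale because rates vary multiplicatively |
| codon rates| $r_3 > r_1 \ge r_2$   | third positions are least constrained in coding sequence |
| dN/dS      | log-uniform 0.04–0.4  | genome-wide purifying-selection range; a covariate label only |

`fixture_panel()` places a small panel across these ranges with a Latin
hypercube so even 5–10 species exercise the extremes;
`unresolved_variant()` shrinks a chosen fraction of internal branches to a
small $\epsilon$ to create the poorly-resolved regime in which bootstrap
supports collapse.

Alignment lengths in the tests are 20–200 kb rather than the 0.9–9.2 Mb of
real core genomes: at these divergences a 100 kb genome already yields
$10^3$–$10^4$ informative sites, which is what the statistics consume, and
the simulation-scale choice matches the 100 kb genomes used in the original
simulation design.  What desk-scale synthetic data cannot show: effects that
live in real data's heterogeneity (rate variation across genes, biased —
selection-filtered — transfer routes, population structure).  Conclusions
about *those* require the empirical datasets; the package's tests establish
the mechanics, not the biology.

## Numerical choices

* Node depths are clustered with a relative tolerance of $10^{-9}$ before
  segmenting, so floating-point noise cannot split a polytomy-like depth tie
  into spurious intervals; chains of zero-length edges propagate sequences
  parent-first.
* Geometric tract lengths use success probability $1/\delta$ on support
  $\{1, 2, \dots\}$; $\delta = 1$ degenerates cleanly to single-site
  conversion.
* Recombination event counts use the *expected* substitution mean
  ($\rho\,\ell L$), not the realized Poisson draw, keeping the two processes
  independent given the tree.
* Bipartitions are canonicalized as 0/1 membership strings against the
  sorted label set, with the side not containing the first label; the
  root's two-child split is deduplicated.
* All stochastic entry points take one integer seed; derived streams
  (grid cells, bootstrap replicates, the shuffle) use a fixed integer
  derivation that stays within 32-bit range, and the caller's RNG state is
  always restored.

## Limitations

The generator's trees are ultrametric (pure birth); real trees are not, and
the simulator supports that, but the bundled study conditions do not
exercise strongly non-ultrametric donors.  The ML path depends on an
external binary and is therefore exercised opportunistically.  And because
the simulator is neutral, the selection–robustness association can only be
*tested for* on constructed fixtures here, not generated mechanistically.
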