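---
title: "Methods: from lek genotypes to a prioritized genetic network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from lek genotypes to a prioritized genetic network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`leknet` estimates a *conditional genetic covariance network* (a population
graph) among clusters of leks. The premise: gene flow in a lek-breeding
species leaves a signature in the covariance of allele frequencies among
local breeding units. Two units that exchange migrants directly covary even
after accounting for every other unit; two units connected only through
intermediaries do not. A Gaussian graphical model separates these cases:
the partial correlation between nodes i and j given all others is zero
exactly when their covariance is fully explained by the rest of the
network.

The estimator, step by step:

1. Each individual becomes a vector with one entry per observed
   (locus, allele): heterozygotes contribute 0.5 to two entries,
   homozygotes 1.0 to one, so each locus block is a composition summing
   to 1. Missing loci are imputed with the individual's node
   allele-frequency vector (global frequencies if the node has no call at
   that locus), which preserves the block sum and keeps the ≥ 4
   individuals-per-node floor intact — deleting individuals instead would
   silently drop nodes.
2. Node mean vectors give a squared Euclidean distance matrix `D`;
   Gower double-centering `C = -1/2 J D J`, `J = I - 11'/k` converts it to
   an among-node covariance, rescaled to a correlation `R`.
3. `R` is inverted (see *Numerical choices*); partial correlations
   `rho_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)` are tested with the
   edge-exclusion deviance `-n_eff * ln(1 - rho^2)` against the
   chi-squared(1) critical value at `alpha`, with a minimum-magnitude
   `tolerance` guard. Surviving edges get weight
   `sqrt(C_ii + C_jj - 2 C_ij)` — the Gower distance between the connected
   nodes.

Assumptions worth stating: loci are selectively neutral and unlinked
(covariance reflects demography, not selection); node membership is
correct (leks within the dispersal cut form one breeding unit); and
within-node sampling is exchangeable (the node mean is an unbiased
frequency estimate). Violations bias edges locally, not globally.

## Edge weight semantics

The weight stored on every edge is the Gower *distance* between its
endpoints — small weight = strong genetic covariance. All shortest-path
quantities (betweenness, closeness, conditional genetic distance, MST)
treat it as a length, so the MST is simultaneously the minimum-length and
maximum-covariance spanning tree. Strength sums these weights; comparisons
of raw weights across datasets with different allele counts are
meaningless (the scale depends on the encoding), so all ranking is done
within a network.

## Numerical choices

**Singular covariance.** Gower centering forces `C`'s rows to sum to zero,
so `R` is *exactly* singular — ridge regularization alone cannot fix this:
for any small lambda, `(R + lambda I)^-1` is dominated by the centering
null direction and every partial correlation collapses to ±1 (we verified
this; the fitted graph is then always complete). `fit_conditional_graph`
therefore eigendecomposes `R`, drops eigenvalues below `eig_tol` (1e-10)
times the largest — the centering constraint plus any compositional
redundancy of the encoding — and inverts on the retained spectrum, with a
ridge escalation (0, 1e-8, 1e-6, ...) applied only if that spectrum is
itself ill-conditioned. The used lambda and retained rank are recorded on
the fitted object.

**Null offset.** Pseudo-inverting around the centering constraint shifts
every null partial correlation to a common positive value of `1/(k-1)`
(measured empirically: mean 0.0905 at k = 12). The deviance test is applied
to partials re-centered by that offset, `rho* = (rho - 1/(k-1))/(1 -
1/(k-1))`; a full-rank input `R` (no dropped null space) gets no
correction. Without it, the fraction of retained edges under panmixia is
~2.5x the nominal alpha.

**Effective sample size.** The deviance needs an `n`. The among-node
covariance is an outer product over encoding columns, so the columns are
the observations — but they are correlated and wildly unequal-variance, so
their raw count overstates the information. `build_popgraph`'s default
`n_eff = "auto"` uses the Satterthwaite effective count
`(sum v_c)^2 / sum v_c^2` of the column variances across node means, minus
the `k - 1` parameters absorbed by conditioning. This is the convention
under which the deviance is approximately chi-squared(1) under panmixia
(empirically: effective count 80.4 vs a measured null dof of 78; retained
edge fraction 0.053 at alpha = 0.05 — the package's calibration test
recomputes this). The value is logged on every fit and can be overridden;
`fit_conditional_graph` called directly defaults to the node count, a
deliberately conservative floor.

**Ties and degeneracies.** Top-hub lists take `ceiling(fraction * k)` nodes
and include all boundary ties (flagged). Bootstrap resample size rounds
half *down* (75% of 458 nodes is 343, matching published usage; R's
banker's rounding would give 344). Keystone triggers are skipped when an
attribute is constant (its percentile is undefined). Monomorphic loci give
`He = 0` and `F_IS = NA` and are excluded from across-locus summaries.
Zero-variance nodes (indistinguishable from the centroid) abort the Gower
step with the node named. Duplicate-genotype clusters keep the member with
the fewest missing loci, ties broken lexicographically.

**Two path-length conventions.** Characteristic path length uses
*unweighted hops* (how many edges separate two nodes — the scale on which
random-graph comparisons are defined), while closeness and betweenness use
*weighted* distances (who channels covariance). Closeness is the
reciprocal of the summed weighted distances to all reachable nodes, so
larger = more central; on a disconnected graph it is computed within
components and flagged — a small component inflates its members' closeness,
which is why the warning matters.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `cut_km` | 15 | km | median breeding dispersal distance among leks |
| `min_node_size` | 4 | individuals | minimum for within-node variance estimation |
| `linkage` | complete | — | guarantees within-node lek diameter ≤ `cut_km`; the cut is a dispersal bound, so the guarantee is the point |
| `radius_km` | 6378.388 | km | sphere radius of the classic geographic-distance routines, for numerical comparability |
| `max_failed_loci` | 5 (of 15) | loci | failure at one-third of the panel |
| `max_mismatch_loci` | 0 | loci | exact duplicate matching; raise for error-tolerant matching |
| `alpha` | 0.05 | — | edge-exclusion significance |
| `tolerance` | 1e-4 | partial r | numerical floor under the deviance test |
| `n_eff` | "auto" | — | see above |
| `null_B`, `bootstrap_B` | 1000 | replicates | permutation resolution 1/(B+1) |
| `bootstrap_f` | 0.75 | — | node fraction per bootstrap replicate |
| `top_fraction` | 0.01 | — | per-index hub screen |
| `cross_percentile` | 0.5 | — | cross-index hub screen (all six indices at once) |
| `cent_pct`, `attr_pct` | 0.90, 0.50 | — | keystone rule (below) |

## Design decisions where the design was open

- **Cross-index hubs** are the *conjunction*: at or above the percentile in
  every index simultaneously. With six partly negatively correlated
  indices this is a demanding screen (independent indices would pass
  `k/2^6`), which is exactly what makes the survivors interesting.
- **Keystone rule.** "Outliers of a centrality-vs-abundance plot" is a
  visual judgment; the package uses a reproducible percentile conjunction —
  centrality at/above `cent_pct` within its index AND (count at/below
  `attr_pct` OR range distance at/above `1 - attr_pct`) — and emits the
  per-index regressions with studentized residuals so an analyst can apply
  the visual criterion too. Counts of keystones are therefore
  rule-dependent and should be read as such.
- **Peak-count aggregation.** Default is the flat mean over all
  (lek, year) records in a node; `per_lek = TRUE` averages within lek
  first (equal lek weighting regardless of years counted). Both are
  emitted by the pipeline; the flat mean is the default because a node's
  attendance is a property of its lek-years, not of its lek roster.
- **F_IS estimator**: `1 - Ho/He` per locus then averaged, plus a
  multilocus ratio-of-means variant (`Fis_multi`) — both are reported
  because the per-locus/multilocus choice is not standardized.
- **He** is the uncorrected gene diversity `1 - sum p^2`; the
  `2n/(2n-1)` unbiased version is a flag, off by default.
- **Structure classification** order: constant degree ≥ 2 → regular
  (constant degree 0/1 is merely sparse); elevated clustering with short
  paths (observed CPL ≤ null 97.5th percentile × `path_factor`, default
  2) → small_world, refined to scale_free only if a discrete power-law
  fit to the degrees is not rejected; no deviation in clustering or degree
  distribution → random. Every sub-decision is returned in the evidence
  record. The degree-distribution comparison is operationalized as a
  leave-one-out Kolmogorov–Smirnov permutation scheme: observed statistic
  KS(observed degrees, pooled null degrees) against the distribution of
  KS(replicate, pooled rest).

## What the simulator emulates — and what it does not

`simulate_stepping_stone` produces: deme allele frequencies drifting under
Wright–Fisher resampling (2N gene copies, N = 50 by default) with symmetric
nearest-neighbour lattice migration (total emigration 0.1/generation split
among neighbours, 100 generations), optional planted hub demes with extra
long-range connections (boosted migration to a chosen set), Hardy–Weinberg
individuals (~12 per deme by default, near the median node size of real
range-wide studies), leks jittered < 5 km around deme centres (below half
the 15 km cut, so clustering provably recovers demes), 2% missing calls,
and negative-binomial per-lek yearly peak male counts (mean 20, dispersion
5, 2005–2015, 70% coverage) with an optional per-deme abundance multiplier
so a genetic hub can be given low attendance (keystone recovery is testable
by construction). Under these defaults expected heterozygosity (~0.75) and
retained-edge density (~0.14) land close to published range-wide values.

Not emulated: linkage and genotyping error (loci are independent and
error-free beyond missingness), habitat/resistance heterogeneity
(migration depends only on lattice adjacency), overlapping generations,
sex-biased dispersal, and temporal sampling spread. A green pipeline test
on synthetic data therefore establishes that the estimator recovers the
structure *this* model family generates — isolation by distance plus
planted hubs — not that it is robust to every field complication.

Small worlds at small k: a 6–12 node graph cannot exhibit statistically
detectable small-world structure, and conditional graphs at that size are
often forests. The package treats components correctly throughout
(closeness per component, CPL over connected pairs, spanning forests), and
the classification test for small-worldness is exercised on synthetic
Watts–Strogatz graphs of 100 nodes instead.

## Known limitations

- The deviance calibration (`n_eff = "auto"`) is an approximation justified
  empirically under panmixia and drift-migration worlds; heavy LD or very
  uneven node sizes could shift it. It is a single logged number — audit it.
- Betweenness with real-valued weights effectively assumes unique shortest
  paths; exact ties (possible with duplicated weights) are resolved by
  path counting in both implementation and oracle, but real data rarely
  tie.
- The keystone count is sensitive to `cent_pct`/`attr_pct`; there is no
  "true" number of keystones.
- Raw edge weights are not comparable across panels or encodings; use
  ranks.
- The QC stage replaces dedicated genotyping-error software with
  transparent exact/near matching; it will not detect allelic dropout
  patterns that such tools model explicitly.
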