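---
title: "Density-sweep graph analysis of functional connectivity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-sweep graph analysis of functional connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis this package implements

Resting-state fMRI studies of training-induced plasticity commonly compare
the topology of whole-brain functional networks between a trained group and
matched controls. The chain implemented here is the standard one for binary
undirected networks built from region-of-interest (ROI) time series:

1. **Connectivity.** For each subject, the pairwise Pearson correlation
   between the time courses of all ROIs (90 cerebral parcels in the default
   configuration, after the convention of the AAL atlas), with two-sided
   p-values from the exact t transform `t = r sqrt((n-2)/(1-r^2))`. The
   diagonal is set to zero.
2. **Density thresholding.** A connection density `d` retains the
   `round(d * n(n-1)/2)` strongest edges, producing a binary undirected
   network whose edge count — not its correlation cutoff — is fixed across
   subjects. Because any single density is arbitrary, networks are built
   over a sweep (default 24.5 % to 30 % in steps of 0.5 %, i.e. 12 grids).
3. **Sweep endpoints from data.** Two rules anchor the sweep when it is not
   fixed a priori: the lower endpoint is the smallest grid density at which
   *every* subject's network is a single connected component; the upper
   endpoint is the largest fraction of node pairs that survives a
   Benjamini–Hochberg correction (q = 0.05) of each subject's correlation
   p-values, minimized across subjects, so every retained edge is
   FDR-significant for every subject.
4. **Graph metrics.** Nodal degree; nodal clustering coefficient (fraction
   of neighbor pairs that are connected); global clustering `C` (mean over
   all nodes, zeros included); characteristic path length `L` (mean BFS
   distance over node pairs); and nodal local efficiency — the mean inverse
   shortest-path distance among a node's neighbors, with distances measured
   *inside* the neighbor-induced subgraph.
5. **Null normalization.** `C` and `L` are divided by their means over 1000
   degree-matched random networks generated by Maslov–Sneppen double-edge
   swaps, yielding `C_nor` and `L_nor` (values near or above 1 with `L_nor`
   near 1 indicate small-world organization).
6. **AUC and inference.** Each metric's curve over the density grid is
   summarized by its trapezoidal area under the curve (AUC) per subject.
   Groups are compared per node by a permutation test (10 000 relabelings
   of subjects into groups of the original sizes; two-tailed p from the
   percentile position of the observed mean difference, add-one estimator),
   corrected across the nodes of each metric by Benjamini–Hochberg FDR at
   q = 0.05. Nodal AUCs are related to a behavioral score by Pearson
   correlation within each group separately, reported uncorrected at
   p < 0.05.

```{r}
library(netsweep)
spec   <- cohort_spec(seed = 1)              # 2 x 72 subjects, 90 regions
cohort <- generate_cohort(spec)
result <- analyze_cohort(cohort, analysis_config(seed = 1))
report_summary(result)
```

## The synthetic cohort generator

Designs of this kind rarely come with public neuroimaging data, so the
package ships a generator that emulates the *statistical* structure the
inference chain needs, not fMRI signals:

- Each subject's time series is `n_timepoints = 175` i.i.d. draws (180
  scans minus 5 discarded dummies) from a multivariate normal with unit
  variances and a block-modular correlation matrix: `rho_within = 0.22`
  inside modules, `rho_between = 0.12` elsewhere.
- One module of `planted_size = 8` regions (comparable to the handful of
  visually-related parcels such designs report) receives an increment
  `delta = 0.05` on its within-pairs in the trained group only.
- Behavioral scores match the printed math-test summaries (trained
  56.97 ± 8.01, control 48.16 ± 8.30, 72 per group) and, in the trained
  group, couple linearly to the subject's *realized* mean within-planted
  correlation (z-scored across the group) with slope
  `behavior_coupling = 7.5` score units per SD; residual noise is scaled so
  the marginal SD is preserved.

### Why these defaults

`delta` has no empirical anchor (published group comparisons of this kind
report significance maps, not per-region effect sizes), so it was fixed
once by a design simulation at the validation scale
(30 regions, 72 per group): the density cutoff falls inside the
within-module correlation distribution, so the planted increment shifts
edge-inclusion probabilities enough for essentially every planted node to
clear FDR, while the displacement it causes elsewhere (a fixed edge budget
means extra planted edges crowd out marginal edges at other nodes) stays
below the correction threshold at typical draws. Larger increments
saturate the planted module — every planted edge always survives
thresholding, metric variance collapses, and the behavior coupling becomes
unrecoverable — which is why the planted block sits deliberately near the
cutoff. The coupling slope corresponds to a score–connectivity correlation
of about 0.9, which after attenuation through thresholding noise yields
metric-level correlations near 0.6, comfortably detectable at n = 72.

### What the generator does not emulate

No hemodynamics, no temporal autocorrelation, no motion or physiological
artifacts, no negative-correlation structure, and no image space. The
i.i.d.-across-time choice is deliberate: the FDR endpoint rule consumes the
exact t-distribution p-values of Pearson r, which are valid only for
independent samples, so the rule is exercised under its own assumptions.
Consequences worth knowing:

- Real fMRI autocorrelation inflates correlation p-values; on real data the
  FDR endpoint would sit at a different density than on these cohorts.
- On the synthetic default cohort the two endpoint rules *conflict*: the
  minimum connected density (~0.165 at 90 regions) exceeds the
  FDR-supported ceiling once the per-subject minimum is taken (the
  between-module correlation of 0.12 at 175 timepoints is mostly
  non-significant). `analyze_cohort(sweep_mode = "auto")` reports this
  explicitly rather than inventing a range; the default configuration uses
  the conventional fixed sweep 0.245–0.300.
- Passing tests on these cohorts demonstrates the correctness and
  calibration of the chain, not its behavior under realistic noise.

## Numerical choices

- **Edge budget rounding** is round-half-away-from-zero of
  `d * n(n-1)/2` (981 edges at d = 0.245 and 1202 at d = 0.300 for 90
  nodes). Base R's banker's rounding would make budgets depend on parity.
- **Edge ranking** uses signed r (strongest positive correlations first):
  after global-signal regression negative correlations exist, and this
  literature retains strong positive edges. `rank = "absolute"` is
  available.
- **Ties** at the cutoff break by ascending (row, column) order — measure
  zero on real data, but it makes thresholding deterministic.
- **Local efficiency** is the harmonic (Latora–Marchiori) form
  `sum(1/d)/(k(k-1))` with `1/Inf = 0`: it is defined even when the
  neighbor subgraph is disconnected, which happens routinely at these
  densities. The literal reading "inverse of the average neighbor path
  length" (`1/mean(d)`, zero when any pair is unreachable) is available as
  `variant = "inverse_mean"`. Distances never leave the neighbor-induced
  subgraph; note that igraph's `local_efficiency()` allows paths through
  the rest of the graph and therefore disagrees with this definition, which
  is why the package computes its own.
- **Disconnected graphs**: `L` falls back to the mean over reachable pairs
  with a warning and a per-subject flag, rather than an error, so
  exploratory densities below the connectedness threshold do not crash a
  sweep. Rewired ensemble members are not forced to stay connected
  (enforcement would bias the null); disconnected members are tallied.
- **Permutation p** uses the add-one estimator
  `(1 + #{|null| >= |obs|})/(1 + n_perm)`, so p is never exactly zero and
  matches percentile-position semantics to within `1/(n_perm + 1)`.
- **FDR families**: degree and local efficiency are corrected as separate
  families of `n_regions` nodes each (nodal results are conventionally
  reported per metric; a single joint family is the main alternative).
- **FDR endpoint aggregation**: the per-subject significant fraction is
  aggregated by the *minimum* across subjects — the only aggregation under
  which every retained edge is FDR-significant for every subject, which is
  what "all remaining correlations significantly strong" requires. Mean or
  other aggregations are not offered because they silently break that
  guarantee.
- **Positive definiteness** of the generator's block correlation matrix is
  established by Cholesky factorization; a failing parameter combination is
  rejected with the offending minimum eigenvalue reported.
- **Seeds** are explicit everywhere; stage seeds derive from the root seed
  by fixed offsets so the permutation stage can be rerun independently of
  the ensemble stage.

## Validation scales

The shipped tests validate the chain at sizes chosen to keep the full suite
in the minutes range while leaving the statistics meaningful: type-I
calibration uses 200 null cohorts of 2 × 20 subjects × 30 regions with
1000 permutations (12 000 node-level tests; empirical rejection at
α = 0.05 lands near 0.05); planted-effect recovery uses 15 cohorts of
2 × 72 subjects × 30 regions (8 planted + 22 background nodes). Oracle
equivalence (metrics vs Floyd–Warshall and triangle enumeration, BH vs the
literal step-up rule, sampled permutation p vs exhaustive enumeration,
trapezoid AUC vs fine-grid refinement) runs on hundreds of small random
instances. `scripts/acceptance.R` recomputes the headline numbers from
scratch at the same scales.

## Known limitations

- The mean-difference permutation statistic is the conventional default; a
  t-statistic variant is not currently exposed.
- With a fixed edge budget, a planted within-module increase necessarily
  perturbs the rest of the network (edge displacement). This is a property
  of density thresholding itself; expect occasional FDR flags outside a
  genuine effect's locus at high power.
- Pearson-correlation p-values for metric–behavior relations are slightly
  anticonservative here because AUC metrics are not Gaussian at n = 72
  (observed null r SD ≈ 0.15 vs 0.118 theoretical); the field's
  uncorrected p < 0.05 convention for these correlations is mirrored
  regardless.
- Exact numerical parity with any specific published local-efficiency
  implementation cannot be claimed for disconnected neighbor subgraphs,
  since published descriptions typically leave that case unstated.
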