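# netsweep

Graph-theoretical group analysis of resting-state functional brain
networks, for researchers comparing network topology between a trained (or
patient) group and matched controls from region-of-interest (ROI) time
series. The package covers the full inferential chain used in
density-thresholded binary network studies, plus a synthetic cohort
generator that makes every stage testable without neuroimaging data.

## The method

For each subject with ROI time series `X` (regions × timepoints):

- **Connectivity**: Pearson `r_ij` between all region pairs, p-values from
  `t = r√((n−2)/(1−r²))` on `n−2` df; diagonal set to 0.
- **Thresholding**: at connection density `d`, keep the
  `round(d·n(n−1)/2)` strongest edges → binary undirected network. Sweep
  `d = 0.245, 0.250, …, 0.300` (12 networks). Data-driven endpoint rules
  are provided: the smallest density at which every subject's network is
  connected, and the largest density at which every retained edge survives
  per-subject Benjamini–Hochberg FDR (q = 0.05) on the correlation
  p-values.
- **Metrics**: nodal degree `k_i`; clustering coefficient
  `C_i = 2t_i/(k_i(k_i−1))` and its mean `C`; characteristic path length
  `L` (mean shortest-path distance); nodal local efficiency
  `E_loc(i) = (1/(k_i(k_i−1))) Σ_{j≠h∈N(i)} 1/d_{N(i)}(j,h)`, distances
  confined to the neighbor-induced subgraph.
- **Normalization**: `C_nor = C/⟨C_rand⟩`, `L_nor = L/⟨L_rand⟩` over 1000
  Maslov–Sneppen degree-preserving rewirings.
- **Inference**: per-subject trapezoidal AUC of each metric over the sweep;
  group differences in mean AUC tested by permutation (10 000 relabelings,
  two-tailed add-one p), FDR-corrected across nodes per metric (q = 0.05);
  Pearson correlation of nodal AUCs with a behavioral score within each
  group.

The synthetic generator draws i.i.d. multivariate-normal time series with
block-modular correlations, plants a within-module correlation increase in
one group, and couples behavioral scores (means/SDs 56.97 ± 8.01 vs
48.16 ± 8.30, 72 per group) to the realized planted connectivity in the
trained group only. See the methods vignette
(`vignettes/network-sweep-analysis.Rmd`) for every default and its
rationale.

## Worked example

```r
library(netsweep)

spec   <- cohort_spec(n_regions = 30, n_per_group = 36, planted_size = 8, seed = 7)
cohort <- generate_cohort(spec)
cfg    <- analysis_config(n_perm = 2000, ensemble_size = 0, seed = 7)
res    <- analyze_cohort(cohort, cfg)
report_summary(res)
```

prints (abridged):

```
Density sweep: 0.245..0.300 step 0.005 (12 densities)

Global metrics (AUC over sweep):
  C      trained 0.0279 +/- 0.0028 | control 0.02528 +/- 0.0025 | perm p = 0.0009995
  L      trained 0.1121 +/- 0.0068 | control 0.1087 +/- 0.0065 | perm p = 0.03698

Nodal local_efficiency: FDR-significant nodes (q = 0.05):
  R002   diff = +0.01802, p = 0.0004998 | trained behavior r = 0.45 (p = 0.00593)
  R007   diff = +0.01534, p = 0.0004998 | trained behavior r = 0.49 (p = 0.0025)
  R008   diff = +0.01387, p = 0.0004998 | trained behavior r = 0.03 (p = 0.877)
  ...
  R004   diff = +0.01038, p = 0.005497 | trained behavior r = 0.37 (p = 0.028)
```

All eight planted nodes (R001–R008) are flagged for local efficiency with
positive differences (trained > control), and the trained group's scores
correlate with local-efficiency AUC at most planted nodes while the control
group's do not. `diff` is the difference in group mean AUC; `perm p` is the
permutation p-value. With `ensemble_size > 0` the summary additionally
reports `C_nor` and `L_nor`. The warning about subjects disconnected within
the sweep is expected at this reduced network size (30 regions); the
90-region default cohort is connected throughout the sweep.

A YAML-driven command line (`simulate` / `analyze` / `report`) is installed
at `inst/cli/netsweep.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/netsweep.R", package="netsweep"))')" \
    simulate --config run.yaml
```

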