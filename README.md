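# microMEN

Molecular ecological network (MEN) analysis of microbiome count data in
R, for microbial ecologists comparing an exposed and a control
population — e.g. the oral microbiota of residents around a mining area
versus a clean reference area, with blood heavy-metal concentrations as
sample covariates.

Sequencing counts are compositional: per-sample totals are arbitrary,
so correlations computed on raw proportions are spurious. microMEN
implements the full MEN chain on top of that constraint:

- **SparCC** basis correlations from log-ratio variances
  `T_ij = var log(x_i/x_j)` under a sparsity assumption, with Dirichlet
  resampling (+1 pseudocount, median over 20 resamples) and iterative
  exclusion of pairs violating sparsity (|r| > 0.8, 10 rounds);
- **permutation significance** from per-taxon sample shuffles, pooled
  across pairs, with Benjamini–Hochberg FDR control;
- **RMT threshold selection**: the smallest correlation cut-off at which
  the thresholded matrix's eigenvalue nearest-neighbour spacing
  distribution is closer (chi-square) to Poisson `exp(-s)` than to
  Wigner–Dyson `(pi s/2) exp(-pi s^2/4)`;
- **signed networks** with edges requiring both `|r| >= s_t` and
  `q < 0.05`;
- **topology suite** (avgK, avgCC, GD, geodesic efficiency and harmonic
  distance, Freeman centralizations incl. stress, density, transitivity,
  Krackhardt connectedness/efficiency/hierarchy/LUBness, power-law R²)
  against **Maslov–Sneppen** degree-preserving null ensembles
  (mean ± SD over 100 rewired networks);
- **Clauset–Newman–Moore greedy modularity**, **Zi–Pi** keystone-taxon
  classification (module hubs Zi > 2.5, connectors Pi > 0.62), and
  **module eigengenes** (first principal axis of the standardized member
  submatrix) correlated with metal concentrations;
- alpha diversity (Sobs, Shannon, Simpson, Chao1, ACE), Bray–Curtis and
  weighted/unweighted UniFrac, PCoA, ANOSIM, Wilcoxon + FDR group tests,
  Spearman genus–metal correlations;
- a **synthetic-data generator** that plants correlation modules, group
  effects and metal couplings with known ground truth, so every stage
  has a recovery test.

Data live in an `OtuExperiment` (a `SummarizedExperiment`: `counts`
assay, taxonomy lineages in `rowData`, group labels and metals in
`colData`).

## Worked example

A synthetic two-group study (120 taxa, four planted modules, 40 + 35
samples, Pb loaded on module 2), through the complete chain:

```r
library(microMEN)

model <- plantNetwork(120, 4, intraDensity = 1, negativeFraction = 0.1,
                      seed = 42, backgroundFraction = 0.5,
                      nSamplesPerGroup = c(exposure = 40L, control = 35L),
                      metalLoadings = data.frame(metal = "Pb", module = 2L,
                                                 coefficient = 2,
                                                 noiseSd = 0.5))
x  <- simulateCounts(model, depth = 3000, seed = 43)
x  <- simulateMetadata(model, x, seed = 44)
x  <- rarefyCounts(x, depth = "min", seed = 45)
xf <- prevalenceFilter(x, 0.10)

fit  <- sparcc(xf, seed = 46)
fit  <- sparccPvalues(xf, fit, nPermutations = 100, seed = 47)
scan <- rmtSelectCutoff(fit)
net  <- buildNetwork(fit, scan, taxonomy = taxonomy(xf))
net
#> MicrobialNetwork: 65 nodes, 400 edges ( 354 positive / 46 negative )
#>   |r| >= 0.31 , q < 0.05

part <- greedyModularity(net)
part
#> ModulePartition: 5 modules, Q = 0.7329 ; 4 modules with >4 nodes
round(topologyIndices(net, part)[c("N", "L", "avgK", "avgCC", "GD",
                                   "D", "Trans", "Q")], 3)
#>       N       L    avgK   avgCC      GD       D   Trans       Q
#>  65.000 400.000  12.308   0.867   2.278   0.192   0.934   0.733

table(ziPi(net, part)$role)
#> peripheral
#>         65

eig <- moduleEigengenes(xf, part)
emc <- eigengeneMetalCorrelation(eig, x)
head(emc[order(emc$p), ], 3)
#>  module metal  n           r            p
#>      M2    Pb 75  0.94546229 2.699185e-37
#>      M3    Pb 75 -0.33954923 2.879877e-03
#>      M5    Pb 75 -0.09683342 4.085423e-01
```

The RMT scan lands at 0.31; the network recovers the planted modules as
near-cliques (hence the high transitivity and Q), every node is
peripheral in this dense-block regime, and the Pb–module-2 eigengene
correlation recovers the planted positive coupling (r = 0.95) while the
other modules stay near zero.

`runPipeline(pipelineConfig(...))` chains all of the above (rarefaction,
diversity, per-group networks, null ensembles, roles, eigengenes) and
writes TSV/GraphML/JSON artifacts plus a manifest; `summarizeRun()`
prints a human-readable report.

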