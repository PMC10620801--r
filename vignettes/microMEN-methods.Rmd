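---
title: "Molecular ecological networks from OTU tables: models and methods"
author: "microMEN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular ecological networks from OTU tables: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microMEN)
```

## The problem

16S rRNA amplicon surveys yield an OTU count table: sequence reads per
operational taxonomic unit per sample. Two questions recur when such
tables come from an exposed and a control population — here, residents of
a heavy-metal-contaminated mining area versus a clean area, sampled at
the buccal mucosa with blood metal concentrations for a subset:

1. Does exposure shift diversity and composition? (alpha/beta diversity,
   ordination, rank-sum tests, genus-metal correlations)
2. Does exposure rewire the *co-occurrence structure* of the community?
   (correlation networks, topology versus null models, modules, keystone
   taxa, module-covariate coupling)

The second question is the package's core. Sequencing counts are
compositional: per-sample totals are arbitrary, so correlations computed
on proportions are systematically biased. The pipeline therefore follows
the molecular-ecological-network (MEN) recipe: SparCC basis correlations,
a random-matrix-theory (RMT) cut-off, FDR-filtered signed edges, topology
indices referenced to degree-preserving null ensembles, greedy modularity,
Zi-Pi keystone classification, and module eigengenes correlated with
covariates.

## SparCC

For taxa $i, j$ with basis (absolute) abundances $w_i$, SparCC works from
the log-ratio variation $T_{ij} = \mathrm{var}\,\log(x_i/x_j)$, which is
invariant to per-sample closure. Writing
$T_{ij} = \omega_i^2 + \omega_j^2 - 2\rho_{ij}\omega_i\omega_j$ and
assuming the correlation matrix is sparse, the row sums
$t_i = \sum_j T_{ij}$ give the linear system
$[(p-2)I + J]\,\omega^2 = t$ for the basis variances, and then
$\rho_{ij} = (\omega_i^2 + \omega_j^2 - T_{ij}) / (2\omega_i\omega_j)$,
clipped to $[-1, 1]$. Pairs whose estimated $|\rho|$ exceeds an exclusion
threshold (default 0.8) violate the sparsity assumption; the strongest
such pair is removed from the system and the variances re-solved, up to
10 rounds. Counts are converted to fractions by Dirichlet resampling with
a $+1$ pseudocount prior; the final estimate is the element-wise median
over 20 resamples. These settings are the method's canonical defaults.

Two numerical choices are worth noting:

- A taxon whose solved basis variance is non-positive has an essentially
  constant log fraction (typically an OTU observed in almost no sample);
  its correlations are uninformative, and the implementation reports them
  as 0 rather than letting the formula clip them to $\pm 1$. In practice
  the 10% occupancy filter removes such taxa before SparCC runs.
- Compositional invariance (scaling any sample's counts) holds exactly
  for $T$ and up to pseudocount/resampling noise end to end; a property
  test asserts it numerically.

## Permutation significance

The null is per-taxon independent shuffling of samples, which destroys
associations while preserving marginal abundance distributions; each
permuted table is re-fit with the SparCC point estimate. With $p$ taxa
there are $p(p-1)/2$ pairs (tens of thousands at study scale) but a
p-value floor of $1/(n_{perm}+1)$ per pair: at the default 100
permutations, per-pair p-values can never survive Benjamini-Hochberg
adjustment across that many tests. The implementation therefore pools the
null $|\rho|$ values across pairs — exchangeable under this null — giving
p-value resolution of order $1/(n_{perm} \cdot \#pairs)$. A per-pair mode
remains available (`pool = FALSE`) for small problems. Two-sided p-values
use the $(\#\{|\rho_{null}| \ge |\rho_{obs}|\} + 1)/(N + 1)$ estimator;
BH runs over the upper triangle.

## RMT cut-off

A correlation matrix dominated by sampling noise has eigenvalue
nearest-neighbour spacings following the Wigner-Dyson (GOE) law
$(\pi s/2)e^{-\pi s^2/4}$; modular signal gives Poisson spacings
$e^{-s}$. For each candidate cut-off (grid 0.30-0.95, step 0.01),
sub-threshold entries are zeroed, degenerate eigenvalues collapsed, the
spectrum unfolded through a degree-9 polynomial fit of the cumulative
spectral density, and the spacing histogram compared to both laws by
chi-square distance. The selected cut-off $s_t$ is the smallest grid
point where Poisson is closer. A pinned cut-off (`pinCutoff(0.45)`)
reproduces runs whose threshold is already known. Edges require both
$|\rho| \ge s_t$ and $q < 0.05$.

## Topology and null ensembles

All indices are computed on the unweighted, sign-stripped graph (edge
signs are bookkeeping only); this matches the integer-like behaviour of
published MEN index tables (reciprocity 1, hierarchy 0). Conventions:

- `GD` averages geodesics over connected pairs only, while geodesic
  efficiency `E` uses $1/\infty = 0$ over all pairs and `HD` $= 1/E$;
  this is what reconciles a finite `GD` with connectedness $< 1$.
- Centralizations (degree, betweenness, stress, eigenvector, closeness)
  use Freeman's formula normalized by the same centrality evaluated on
  the star graph of equal order. Closeness is harmonic (defined on
  disconnected graphs); stress counts shortest paths through a node.
- Krackhardt's four dimensions: connectedness (reachable pair fraction),
  efficiency (surplus edges beyond a spanning forest, scaled), hierarchy
  (0 for any undirected graph — symmetric reachability), and LUBness
  (1 for any undirected graph: within a component every pair has a least
  upper bound). The latter two are therefore constants here; they are
  retained for completeness of the index panel.

Null ensembles use Maslov-Sneppen double-edge swaps (igraph's
degree-preserving rewiring, 100 swap attempts per edge), k = 100
networks, each re-partitioned by greedy modularity; an empirical index is
flagged nonrandom outside the null mean ± 2 SD. Degree-forced indices
(N, L, avgK, density, degree centralization) have ensemble SD exactly 0,
which doubles as a correctness check.

## Modules, Zi-Pi, eigengenes

Greedy modularity is the agglomerative Clauset-Newman-Moore algorithm
with deterministic tie-breaking (smallest module-id pair; module id = the
smallest member node index). Greedy agglomeration is a heuristic: on
small random graphs it occasionally misses the exhaustive-search optimum,
as any CNM implementation does; the test suite verifies the reported Q
against a direct $\sum_m (e_{mm} - a_m^2)$ evaluation on every graph and
against the exhaustive maximum on structured modular graphs.

Zi (within-module degree z-score) uses the sd of within-module degrees
over the node's own module, with Zi = 0 for modules of constant degree;
Pi $= 1 - \sum_m (k_{i,m}/k_i)^2$. Role thresholds are strict:
module hub Zi > 2.5, connector Pi > 0.62, network hub both, else
peripheral — the convention of the Zi-Pi framework (published tables
print the boundary inequalities inconsistently). Module hubs and
connectors are the keystone taxa.

Module eigengenes are computed on relative abundances standardized per
OTU across samples (the abundance transform is exposed because published
pipelines rarely state it; standardization makes the eigengene
scale-free). The eigengene is the first right singular vector of the
member-by-sample matrix, unit variance, signed to correlate positively
with the module's mean standardized member profile; variance explained is
the leading singular value's share. Eigengene-metal association is plain
Pearson correlation, with modules clustered on $1 - r$ into supergroups.

## The synthetic generator

`plantNetwork()` defines the ground truth: taxa are split into modules;
within a module a one-factor construction places pairwise log-scale
correlations of magnitude 0.65-0.85 (rank-1 + diagonal, PSD by
construction), with a fraction of taxa on the negative pole so that a
requested fraction of planted pairs is negative (necessarily $\le 0.5$
for a one-factor block; denser negative structure fails loudly). With
`intraDensity < 1`, deleted entries trigger a nearest-PSD repair
(`Matrix::nearPD`), after which planted values are re-read from the
repaired matrix and the call fails if any fell below 0.45 or flipped
sign. `simulateCounts()` draws log-normal basis abundances (group
log-fold-changes added to exposure means only, leaving covariance — and
hence network structure — untouched), closes to proportions, and draws
multinomial counts, the compositional model under which SparCC's estimand
is well defined. `simulateMetadata()` makes each metal a linear function
of its module's mean standardized abundance plus Gaussian noise, over a
baseline keeping concentrations positive. `simulateTree()` provides a
random rooted bifurcating tree for UniFrac.

Default design sizes emulate the study this pipeline reproduces: 92
exposure + 45 control samples, rarefaction depth 28,367, blood metals on
a 79-sample subset. Module taxa draw their log-mean abundance from a
moderately abundant stratum (N(1.5, 1) versus N(0, 1.5) for background):
a co-occurrence network is by construction built over detectable taxa —
the 10% occupancy filter guarantees it on real data — and correlations
planted on taxa near the detection limit are unrecoverable from counts by
any estimator, so planting them would only test the sequencer's shot
noise. One master seed is split deterministically per stage, so identical
seeds give byte-identical tables, metadata, trees and manifests.

What the generator does *not* emulate: sequencing error and chimeras,
overdispersion beyond the log-normal, phylogenetic signal in the
covariance, and metal-abundance coupling beyond linear-in-module-mean.
Passing recovery tests therefore certify the estimator chain, not
robustness to artefacts upstream of the OTU table.

## Test and recovery problem sizes

The recovery suite uses 300 taxa (six 15-taxon modules + 210 background),
60 + 60 samples at depth 5,000, 20 replicates — large enough that SparCC's
sparsity assumption holds and planted blocks are identifiable, small
enough to iterate on routinely. At these conditions the pipeline attains
edge precision ~0.99, recall ~0.92, and adjusted Rand index ~0.98 against
the planted modules. Statistical calibration uses 250-500 null replicates
(Wilcoxon/ANOSIM type-I error within ±2 percentage points of the nominal
5%), and the eigengene-metal sign test uses 100 replicates at 79 samples,
coefficient 1, noise sd 1.

## Known limitations

- Shannon's log base (natural) and the normalized weighted UniFrac
  variant are conventions, exposed as options; published values computed
  under other conventions will differ.
- The 10% occupancy filter is applied per group by default (each network
  sees its own samples); a global mode exists because published methods
  rarely state the choice.
- Indirect-edge removal (conditioning an edge on the remaining network)
  is not implemented; the config flag reserves the stage and logs that it
  is skipped.
- Greedy modularity is deterministic but heuristic (see above); Louvain
  or exact methods may give higher Q on adversarial graphs.
- The RMT scan needs enough non-degenerate eigenvalues after
  thresholding; very small matrices (fewer than ~30 informative taxa)
  should pin the cut-off instead.
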