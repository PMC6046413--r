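---
title: "Methods: co-occurrence network analysis of vector and host microbiomes"
author: "micronet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence network analysis of vector and host microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micronet)
```

# Scope and data model

`micronet` analyzes sample-by-taxon read-count tables from amplicon surveys
of two carriers (an arthropod vector such as *Ixodes* ticks and a
vertebrate host such as bank voles) sampled in two habitat strata (forest
and ecotone). The central container, `ReadMatrix`, extends
`SummarizedExperiment`: taxa in rows, individual carriers in columns, with
`carrier`, `biotope` and optional `sex` covariates in `colData`. Upstream
bioinformatics — contig assembly, OTU clustering, chimera removal,
taxonomic classification — is out of scope; the package starts from the
resulting OTU- or genus-level count table (an `aggregateTaxa` utility maps
OTUs to genera with a two-column table).

# Replicate merging and filtering

Paired PCR replicates guard against cross-contamination and tag-jumping:
a sample counts as positive for a taxon only when **both** replicates are
positive, and consistent detections are combined by adding the replicate
read numbers (`mergeReplicates`). Merging operates at whatever rank the
input tables carry; when OTU tables are supplied it should be run before
genus aggregation, which is the order the consistency argument is usually
made at.

Three filters then clean the matrix (`applyFilters`, in this fixed order):

1. `dropUnassigned` — taxa without a genus-level assignment are discarded.
2. `dropSingletons` — taxa with nonzero reads in exactly one sample of the
   whole set are removed.
3. `lowReadCutoff` — for each taxon, occurrences strictly below the 10th
   percentile of that taxon's **nonzero** read counts are zeroed, giving
   each microorganism its individual cutoff level.

Numerical choices worth stating, because a percentile rule admits several
readings:

- The percentile estimator is linear interpolation between order
  statistics (`quantile(..., type = 7)`, R's default). Zeros are excluded
  from the distribution: a zero is a non-detection, not a low read.
- Occurrences *equal* to the cutoff are retained ("below" is strict).
- A taxon's cutoff is **established once**, when the filter first sees its
  read distribution, and is recorded in the filter report
  (`filterReport`). Re-applying the filter reuses the established cutoffs.
  Re-deriving the percentile from the already-censored distribution would
  shift it above the new minimum on every pass and keep eroding the lower
  tail; establishing the cutoff once makes the operation idempotent, which
  is also what "establishing an individual cut-off level for each
  microorganism" should mean operationally.
- Singleton status is *not* re-evaluated after the cutoff step (the cutoff
  can create new effective singletons). `applyFilters(iterate = TRUE)`
  repeats the singleton + cutoff pair to a fixed point for users who want
  the stricter variant; the default is the literal three-step sequence.

# Genus co-occurrence networks

Within one carrier-by-biotope stratum, two genera are linked when they are
detected together in at least one sample; the edge weight is the number of
samples carrying both (`buildCooccurrenceNetwork`, computed as the
off-diagonal of `P P^T` over the binary presence matrix). Genera present
in the stratum but never co-detected stay as degree-0 nodes; genera absent
from the stratum are excluded. No association-significance filtering
(SparCC-style) is applied: the framework deliberately works on raw
co-detection counts.

Node indexes (`computeNodeMetrics`):

- **WD**, weighted degree — the sum of incident edge weights; the basic
  measure of how embedded a genus is in the co-occurrence structure.
- **BNC**, betweenness centrality — Brandes' exact algorithm. Default:
  unweighted shortest paths, unnormalized, i.e. the purely topological
  variant classic GUI network tools compute; `weighted = TRUE` switches to
  shortest paths under distance `1/weight` for sensitivity analysis.
- **CC**, local clustering coefficient — `2 e_N / (k (k - 1))` on the
  binarized graph; nodes of degree < 2 score 0.
- **PR**, PageRank — damped random walk with transition probabilities
  proportional to edge weights; damping 0.85 (the standard default; the
  statistic is reported without a habitat-specific justification since
  none exists). Isolated nodes hold teleport-only mass; the vector is
  normalized to sum exactly to 1.
- **Communities** — modularity maximization on edge weights. "Newman
  communities" is implemented as the Louvain multi-level heuristic (the
  algorithm behind the common GUI tools' modularity button), with
  Clauset–Newman–Moore greedy agglomeration available via
  `method = "greedy"`. The heuristic runs under a caller-supplied RNG
  seed, and labels are deterministically renumbered 0..k−1 by decreasing
  community size, ties broken by the smallest member name — so a seed plus
  a matrix fully determines the output.

The scale-free question is answered by `fitPowerLaw` on the WD values:
continuous maximum likelihood `gamma = 1 + n / sum log(x_i/xmin)` with
`xmin` chosen by Kolmogorov–Smirnov minimization (the
Clauset–Shalizi–Newman procedure, via igraph's `plfit`). A log–log
regression slope on the empirical survival function is reported alongside
because older network literature often quotes the regression exponent;
the MLE is the defensible estimator and is the one tested. Degenerate
input (all values equal) is an error, and a selected tail of fewer than
10 points falls back, with a warning, to a fit over the full data.

# Phylogenetic statistics

Trees enter as Newick (`readNewick`) or are built from a square distance
matrix by Saitou–Nei neighbor joining (`njTree`, via `ape::nj`). On
additive matrices NJ reproduces the input path lengths exactly (this is a
test invariant); on noisy matrices NJ can emit negative branch lengths,
which are clamped to zero with the deficit moved to the adjacent branch —
standard practice — and counted in `attr(tree, "n_clamped")`.

**Faith's PD** (`faithPD`) is the sum of branch lengths of the minimal
subtree connecting the selected tips *and the root*. The rooted convention
matters only for small sets (a singleton scores its root-to-tip path); it
is the classic definition and is fixed and documented rather than
configurable, since community-level PD values cannot adjudicate between
conventions.

**Pagel's λ** (`pagelsLambda`) measures the phylogenetic signal of a
continuous tip trait — here genus prevalence per stratum, or any of the
node indexes. The model is Brownian motion whose tip covariance has its
off-diagonal entries (shared root-to-ancestor path lengths) multiplied by
λ ∈ [0, 1]. At each λ the root state and rate σ² are profiled analytically
by GLS through a Cholesky factorization; λ is then optimized by bounded
scalar search on [0, 1] with tolerance 1e-6, and the boundary likelihoods
at 0 and 1 are always evaluated so a boundary maximum is never missed (the
returned fit records all three). Indexes are used untransformed by
default, mirroring common practice; a log1p transform can be applied by
the caller for heavy-tailed indexes. A star tree makes λ unidentifiable
(all shared paths are zero, the likelihood is flat), and the fit refuses
with an explicit error instead of returning an arbitrary interior point.
A likelihood-ratio convenience test against λ = 0 is provided
(`lambdaLRT`) but no significance claim is attached by default.

`accumulationCurve` supports the depth-saturation check on individual
samples: the expected number of distinct taxa at subsampled depth *d* is
computed analytically from the hypergeometric expectation
`E[S(d)] = sum_g (1 - C(N - n_g, d) / C(N, d))`; Monte-Carlo subsampling
is retained as a cross-checking mode.

# Host specificity

`specificityTable` contrasts, per biotope, each genus's mean reads in one
carrier against the other on the `log10(0.1 + x)` scale (so a genus absent
from a carrier maps to −1, not −∞). The mean is taken over *all* samples
of a carrier in the biotope, zeros included — an "average number of
reads" — with `positiveOnly = TRUE` as the alternative reading. The raw
ratio of summed reads is reported alongside (infinite when one carrier
never shows the genus), together with the genus's WD in the
biotope-pooled co-occurrence network; pooling both carriers is the default
because the score is about the biotope's network context, with
carrier-specific networks available by passing `network =`. The log base
only rescales scores and changes no ranking. Records are ranked by
|log score|; the procedure is a descriptive ranking, deliberately not a
statistical test.

# Carrier similarity networks and community summaries

`buildCarrierNetwork` links individual samples of a biotope by the number
of bacterial genera they share; ticks and voles are kept in **one** joint
graph, so any separation of the two species into different communities is
an outcome of modularity maximization, not an assumption. No edge-weight
threshold is applied by default (`minShared` exposes one).
`summarizeCommunities` reports, per community, the percent of each
carrier's individuals, the genus union size, Faith's PD of that union and
— because "community diversity" is sometimes read as an average — the
mean pairwise phylogenetic distance; neither statistic is silently
preferred.

`pdConcentration` quantifies the Pareto-style concentration of diversity:
the largest community (by share of individuals) versus all others, with
the minor communities' PDs **summed** ("accumulated"). Summation is the
reading consistent with an accumulated value exceeding what any single
community could carry; the PD of the pooled minor genus union is also
reported (`minor_pooled_pd`) since the pooled reading is equally sensible.

# The synthetic-data generator

`simulateReadMatrix` generates data with the structure the analysis
assumes — microorganisms circulating together in packets:

- Genera are partitioned into `n_packets` packets of near-equal size
  (mean `packet_size_mean`); leftover genera become rare background taxa.
- Packets and background genera are allocated to the two biotopes with a
  `biotope_overlap` shared fraction, and within each biotope to the two
  carriers with a `carrier_overlap` shared fraction. A group's pool is the
  union of its packets' genera plus its background genera, and the
  returned ground truth (`group_pools`, `packet_assignment`) makes every
  downstream stage checkable.
- Each sample draws 1–k packets uniformly from its group pool, adds
  Poisson(`noise_genus_rate`) extra pool genera, and gives every present
  genus a negative-binomial read count (mean `nb_mean`, dispersion
  `nb_dispersion`) truncated below at 1 — a present genus must be
  observable, which is what detection semantics require.

The defaults mirror the study design the framework targets: 228/73 ticks
and 177/92 voles in forest/ecotone, 126 genera, 16 packets of mean size
7.5, 1–2 packets per sample plus Poisson(2.2) noise genera — expected
richness 1.5 × 7.5 + 2.2 ≈ 13.45 genera per sample, matching the observed
≈ 13.4 in both carriers — and NB reads with mean 610 and dispersion 0.5,
so a typical sample carries on the order of 8,000 reads. Overlap defaults
(`biotope_overlap = 0.25`, `carrier_overlap = 0.6`) encode
biotope-specific pools with limited cross-biotope sharing and substantial
carrier sharing. These are pool-construction fractions, not observed-set
similarities: because each group's detected genus set saturates its pool
as samples accumulate, observed Sørensen values between groups come out
higher than the raw fractions. No attempt is made to reproduce any
field-data similarity value exactly.

What the generator does *not* emulate: read-depth/richness correlation,
sequencing error and chimeras, within-packet abundance correlation,
habitat gradients, and any phylogenetic structure in packet membership —
packets are assembled independently of the simulated Yule tree, so λ of
prevalence is expected to be near 0 on synthetic data. Passing tests on
synthetic data therefore demonstrate algorithmic correctness and
recoverability of planted structure, not that real tick/vole data meet the
model's assumptions.

`simulateYuleTree` provides the genus tree (pure birth, unit birth rate):
only tree shape and branch lengths matter downstream, so no
sequence-level simulation is attempted. `simulateBMTrait` draws one
multivariate-normal trait with the λ-scaled Brownian covariance and is the
generative counterpart used in the λ-recovery experiments.

# Determinism, degenerate inputs, problem sizes

Every stochastic step (simulation, Louvain, Monte-Carlo subsampling)
takes an explicit integer seed; identical seeds give bit-identical
output, and the pipeline writes its parameters and seeds into a manifest
so a rerun reproduces every file byte-for-byte. Degenerate inputs are
errors with explicit messages rather than silent defaults: empty strata,
matrices without both carriers where two are required, star trees for λ,
all-equal values for the power-law fit, taxa missing from the tree.

The test suite checks each statistic against an independent brute-force
oracle on exhaustively enumerable instances (pair enumeration for edge
weights, shortest-path and triangle enumeration for BNC/CC, a linear
solve for PageRank, full partition search over 8-node graphs for
modularity, union-of-root-paths for PD, hand-solved path equations for
NJ) and runs parameter-recovery experiments at moderate sizes chosen for
tight sampling error at interactive runtimes: λ ∈ {0, 1} recovered within
0.1 on a 200-tip tree over 50 trait replicates, the power-law exponent
2.5 recovered within 0.1 at n = 10,000 over 20 seeds, and planted packets
recovered exactly at zero noise. Reference implementations (`picante::pd`,
`phytools::phylosig`) serve as additional cross-checks, never as the
implementation.

# Known limitations

- Co-occurrence counts are not interaction estimates; the framework
  intentionally stops short of association inference and the networks
  inherit any compositional or depth biases present after filtering.
- The 10%-cutoff, unweighted-BNC and Louvain choices are documented
  interpretations of under-specified conventions in the field; the config
  flags (`percentile`, `weighted`, `method`, `resolution`) exist precisely
  to probe sensitivity to them.
- λ is fit by maximum likelihood on [0, 1]; values are not comparable
  across trees of very different depth scales, and the LRT p-value is
  approximate at the λ = 0 boundary.
- The two-carrier × two-biotope overlap model of the generator does not
  extend beyond two levels per factor; the analysis functions themselves
  have no such limit.
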