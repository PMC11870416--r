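---
title: "Brownian-motion dispersal inference on ancestral recombination graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brownian-motion dispersal inference on ancestral recombination graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(argspace)
```

## The model

`argspace` treats the movement of genetic lineages through continuous space
as Brownian motion run forward in time down an ancestral recombination graph
(ARG).  The displacement along an edge from node $i$ to node $j$ is
$D_{i,j} \sim \mathcal{N}(0, \sigma^2 t_{i,j})$ per coordinate dimension,
where $t_{i,j}$ is the edge length in generations and $\sigma^2$ the
dispersal rate (a $2\times2$ matrix $\Sigma$ in two dimensions).  On a tree
this is the classic phylogeographic model: the covariance of two sample
locations is $\sigma^2$ times their shared time.

Recombination changes two things.  First, a sample below a recombination
node has several *paths* to the root, so covariances must be organised by
path rather than by sample: with $n_p$ sample paths, the path-tip locations
are
$$\vec{L}_p \sim \mathcal{N}(R\vec\mu,\; \sigma^2 S_p),$$
where $S_p$ is the matrix of pairwise shared times between paths (the *path
matrix*), $R$ assigns each path to its root, and $\vec\mu$ holds the root
locations.  Second, the two parental lineages of a recombination node must
*meet* there, so displacements around each loop are constrained to agree.
Conditioning all paths of a sample to end at one point converts the path
matrix into the covariance structure of the samples themselves, the *sample
matrix*
$$S = (P^\top S_p^- P)^{-1},$$
with $P$ the path–sample incidence matrix and $S_p^-$ a Moore–Penrose
pseudoinverse (path bases are generally redundant).  Around a loop the
conditioned process behaves as a Brownian bridge: a symmetric loop with time
$t$ on each side leaves variance $\sigma^2 t/2$ at the recombination node —
half the single-lineage value.  This clustering cascades to every node and
sample below a loop, and is the mechanism behind the dispersal-estimation
bias the package is designed to expose (see *What the simulations show*).

Estimation is closed-form generalized least squares on the minimal path
basis:
$$\hat{\vec\mu} = (R^\top S_p^- R)^{-1} R^\top S_p^- P \vec\ell^*, \qquad
\hat{\sigma}^2 = \frac{(P\vec\ell^* - R\hat{\vec\mu})^\top S_p^-
(P\vec\ell^* - R\hat{\vec\mu})}{n_s},$$
and any ancestor $a$ (a node, or a point part-way along an edge) has the
conditional Gaussian location
$$\mathbb{E}[L_a] = \hat\mu_{r_a} + \vec{s}_a^\top S_p^-(P\vec\ell^* -
R\hat{\vec\mu}), \qquad \operatorname{Var}[L_a] = \hat\sigma^2 V,$$
$$V = \underbrace{t_a - \vec{s}_a^\top S_p^- \vec{s}_a}_{\text{Brownian motion}}
 + \underbrace{(\vec{e}_{r_a} - R^\top S_p^- \vec{s}_a)^\top (R^\top S_p^- R)^{-1}
   (\vec{e}_{r_a} - R^\top S_p^- \vec{s}_a)}_{\text{root uncertainty}},$$
where $\vec{s}_a$ holds the shared times between one (arbitrary) path from
$a$ to a root and the minimal sample paths, and $t_a$ is the time from $a$
to that root.  The $n_s$ denominator is the maximum-likelihood estimator; as
the root locations are estimated, its expectation is
$\sigma^2 (n_s - n_r)/n_s$, and `fitArg(..., reml = TRUE)` applies the
degrees-of-freedom-corrected $n_s - n_r$ denominator instead.

Because the estimator is a linear-Gaussian plug-in, the pivotal quantity
$(L_a - \mathbb{E}[L_a])/\sqrt{\sigma^2 V}$ is exactly standard normal under
the model when $\sigma^2$ is known, so nominal confidence intervals from
`confidenceRegion()` are exactly calibrated on model-simulated data — the
package's acceptance script measures precisely this.

## Why (and how) the graph is chopped

Deep in the past, lineages are spatially well mixed and Brownian motion over
a bounded habitat is a poor description, so analyses usually *chop* the ARG
at a cutoff time: every edge crossing the cutoff is truncated there and
capped with a fresh root node, yielding $n_r \ge 1$ roots.  Roots are
treated as fixed, independent, and unknown; `addRootVariance()` relaxes the
zero-variance assumption by adding a shared (or per-root) variance between
paths from the same root.  A recombination node whose loop top is removed by
the chop leaves an *open* loop: its two parent lineages reach distinct roots
and contribute no meeting constraint.  `findLoops()` reports such nodes in
`attr(, "openLoops")`, and the shared-time machinery handles them without
special cases (the paths simply share the edges below the node).

## Minimal path basis

All sample paths can be exponentially many, but the induced sample matrix
only needs a linearly sufficient basis of $n_s + (\text{number of
recombination nodes})$ paths.  `minimalPaths()` builds one in a single
tip-to-root traversal: live lineages carry their paths up the graph; at a
recombination node, one lineage (the one carrying the lowest-numbered path)
is duplicated and routed up both parents; everywhere else all lineages
follow the smaller parent id.  All tie-breaks are by node id, so output is
deterministic.  The property suite asserts the basis is exactly equivalent
to the full enumeration ($S$ agrees to $10^{-10}$), which is the only
property the basis must have — the particular choice of retained paths is
basis-irrelevant.

## Model variants and baselines

* **Midpoint model** (`fitArg(variant = "midpoint")`,
  `midpointSharedTimes()`): the two parents of a recombination node may end
  anywhere and the node sits at their unweighted average.  Each node's
  location becomes a fixed weighted sum of root locations and edge
  displacements; covariances follow by propagating weights from the roots
  down.  The recombination node's variance is still halved
  ($\operatorname{Var}[\tfrac12(X_1+X_2)] = \sigma^2 t/2$ for a symmetric
  loop), but on-loop parents and lineages branching off the loop keep their
  full variance.
* **Per-tree composite likelihood** (`treeCompositeFit()`): the tree model
  fitted to every marginal tree separately, averaging the dispersal
  estimates — no cross-tree information, no loops.
* **Averaging-up** (`averagingUp()`): each node at the unweighted mean of
  its children's locations, branch lengths ignored, computed on the
  simplified graph.  Point estimates only.

## Exact reference computations

`buildJoint()`/`conditionOnLoops()` construct the dense joint Gaussian over
node locations (one coordinate per node, recombination nodes duplicated into
left/right copies) and condition exactly on every copy pair coinciding.
This $O(n^3)$ oracle exists for verification, not speed (capped at 200 node
copies by default): the test suite checks the sample matrix, the ancestor
means and the Brownian variance components against it to $10^{-8}$, and
checks the full $V$ against the oracle-computed mean-squared error of the
plug-in GLS predictor (the root-uncertainty term is exactly the GLS
prediction penalty).  The same machinery gives `simulateLocations()` exact
draws from the loop-conditioned model, which is how the calibration and
parameter-recovery experiments generate truth.

The path-space likelihood (`spatialLogLik()`) is the density of the path
tips under $\mathcal{N}(R\vec\mu, \sigma^2 S_p)$.  It differs from the
conditional density of the $n_s$ sample locations by the density of the
meeting contrasts at zero — a factor independent of the data whenever all
loops close below the cutoff — and the tests assert that exact
decomposition.  Likelihood *ratios* across parameter values, and hence all
inference, agree between the two formulations.

## The simulators

Two fidelity levels:

1. **Model-exact** (`simulateModelArg()` + `simulateLocations()`): random
   ARG topologies from an event-driven coalescent-with-recombination in
   which recombination competes with coalescence at fixed odds
   $c = r/(n_s - n_r + r)$ for a target of $r$ recombination events — the
   event-count identity `#coalescences = ns - rootCount + #recombinations`
   then makes the expected recombination count *exactly* $r$.  Locations are
   drawn exactly from the conditioned Gaussian.  These data satisfy every
   model assumption, so estimator calibration can be tested sharply.
2. **Individual-based** (`simulateIbd()`): hermaphroditic diploids in a
   rectangular habitat with discrete non-overlapping generations.  Each
   individual mothers one brood: a mate is drawn by a Gaussian kernel
   (variance $\sigma_m^2$) within $3\sigma_m$ (no selfing; no mate in range
   means no offspring); brood size is Poisson with mean $2/(1+C)$ where $C$
   sums Gaussian competition strengths (variance $\sigma_c^2$) over
   neighbours within $3\sigma_c$; offspring are displaced from the mother by
   per-dimension $\mathcal{N}(0, \sigma_d^2)$ offsets, reflected off the
   habitat boundary; gametes recombine with Poisson crossovers.  The full
   ARG of a terminal sample is extracted backward through the recorded
   pedigree and crossover mosaics, retaining coalescent and recombination
   nodes of the sample lineages and dropping pass-through chains; a
   recombination whose branches rejoin the *same* genome before meeting any
   other lineage is invisible in such a simplified graph and is merged
   silently, as in simplified tree sequences.  The effective dispersal rate
   is $\sigma_d^2 + \sigma_m^2/2$ (inheritance is equally likely via either
   parent, and only the maternal side carries the mating displacement);
   reflecting boundaries can only lower the realized rate, which
   `realizedDispersal()` measures from the recorded edges.

Interaction radii are truncated at three kernel *standard deviations*
($3\sigma_m$, $3\sigma_c$), the conventional Gaussian truncation.

### Parameter choices

Defaults are desk-scale and chosen to be self-consistent: $n_0 = 400$
founders in a $25\times25$ habitat with $\sigma_c^2 = 0.25$ put the
competition-set carrying capacity ($\lambda = 1$ at $C = 1$, i.e. density
$1/(2\pi\sigma_c^2) \approx 0.64$) at about 400 individuals, so the
population neither crashes nor explodes; $\sigma_d^2 = \sigma_m^2 = 0.25$
give an effective dispersal rate of 0.375 square units per generation, small
against the habitat so that isolation by distance develops; a
$10^5$-bp genome at a crossover rate of $10^{-7}$ per bp yields on the order
of 20–100 marginal trees in a 150–300-generation ARG of a few dozen samples
— enough trees for the tree-count experiments while keeping every fit
dense-algebra cheap.  A cluster-scale configuration (10,000 individuals,
$100\times100$ habitat, 1 Mb at $10^{-8}$, 2,000 generations) ships as
`inst/extdata/ibd-full-scale.yaml` for use with the `simulate` subcommand.

## What the simulations show

On model-exact data everything is calibrated: bias-corrected dispersal
estimates $\hat\sigma^2 n_s/(n_s-n_r)$ recover the truth to within a few
percent over hundreds of replicates, and nominal 95% ancestor intervals
cover at 95%.  On individual-based data the meeting constraint is wrong at
recombination events — real parents mate at a distance — and the signature
documented by the test suite appears: the whole-ARG dispersal estimate
*rises steadily as more trees (hence more loops) are included*, while the
per-tree composite average stabilizes, and the midpoint variant rises more
slowly because only its recombination nodes, not its loop flanks, are
over-clustered.  The package reproduces this qualitative pattern at desk
scale (three replicates of the individual-based simulation, first 15 trees);
it does not attempt to reproduce cluster-scale quantitative values.

## Numerical choices, degenerate inputs, limitations

* Pseudoinverse truncation: eigenvalues below
  $10^{-10}\times\text{dim}\times\max|\lambda|$ are treated as zero
  (configurable via `rtol`).  Singular $S_p$ likelihoods use the
  pseudo-determinant on the support and return $-\infty$ with a diagnostic
  attribute if the data violate a meeting constraint.
* Rank-deficient $R^\top S_p^- R$ (non-identifiable roots) falls back to the
  minimum-norm GLS solution with a warning; `ancestorVariance()` clips
  Brownian components in $[-10^{-8}, 0)$ to zero and errors on anything more
  negative, which signals a basis/shared-time mismatch.
* All tie-breaks (canonical upward paths, duplicated lineages, new root ids
  after chopping) are by smallest node id; outputs are deterministic, and
  ancestor moments are provably path-choice-invariant (asserted numerically).
* Two-dimensional likelihoods use the Kronecker factorization across
  coordinates; no $2n_p \times 2n_p$ matrix is formed.
* Edges between the same parent-child pair over several genome intervals are
  one line of inheritance (one displacement); distinct lineages between the
  same node pair cannot be represented, matching tree-sequence conventions.
* Times equal to a node's time in `locateAncestor()` resolve to the node;
  strictly interior times interpolate shared times linearly along the edge.
* Not covered: ARG inference from sequence data (true graphs are assumed),
  mutation, non-Gaussian dispersal kernels, habitat-boundary likelihood
  corrections, importance sampling over graph posteriors, and joint
  distributions across several ancestors (the oracle computes pairwise
  covariances, but the user API returns one ancestor at a time).

## Problem sizes used by the test and acceptance suites

Oracle-equivalence sweeps use 50+ random graphs with 3–8 samples and 0–4
loops; interval calibration uses ≥2,000 (acceptance script: ≥5,000)
node-by-replicate draws on graphs with 5–20 samples; parameter recovery uses
300 replicates of 20-sample graphs; the bias experiment runs three
individual-based replicates with $n_0 = 250$ in a $35\times35$ habitat for
150 generations, 30 sampled individuals, first 15 trees.  These sizes are
the package's defaults for its own verification and complete in a few
minutes on a single core.
```
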