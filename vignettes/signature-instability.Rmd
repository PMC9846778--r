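---
title: "Quantifying instability in mutational-signature extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying instability in mutational-signature extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigarchetypes)
```

## The problem

Somatic single-base substitutions are conventionally classified into 96
categories: the six pyrimidine-strand changes (C>A, C>G, C>T, T>A, T>C,
T>G) crossed with the 16 combinations of 5' and 3' flanking bases. A
*mutational signature* is a probability distribution over these 96
contexts, attributed to one mutagenic process; a tumour's *mutational
catalogue* is a 96 × samples table of observed counts, modelled as a
non-negative mixture of signatures weighted by per-sample *exposures*.

Modern reference catalogues contain many signatures that are mutually very
similar, and several that are nearly featureless ("flat"). Both properties
make the inverse problem — de novo extraction of signatures from counts by
non-negative matrix factorisation (NMF) — unstable: similar or flat latent
components are easily merged, split, or swapped, and the number of samples
needed for reliable recovery grows quickly. This package provides the
machinery to measure that instability and to compress a redundant signature
catalogue into a smaller set of extreme profiles by archetypal analysis.

## Similarity and flatness

Two profiles are compared by cosine similarity,
$\cos(s_i, s_j) = s_i \cdot s_j / (\lVert s_i\rVert\,\lVert s_j\rVert)$,
which is scale-invariant and lies in [0, 1] for non-negative profiles
(`cosine_similarity()`, `pairwise_similarity()`). Following the same
geometry, the *flatness* of a profile is its cosine similarity to the
uniform distribution over the 96 contexts (`flatness()`). Flatness ranges
from $1/\sqrt{96} \approx 0.102$ for a one-hot profile to exactly 1 for a
uniform one, and these closed forms anchor the unit tests.

Groups of mutually similar signatures are found by average-linkage
hierarchical clustering of the cosine distance matrix $D = 1 - S$
(`build_cluster_map()`), with groups read off by cutting the tree; the cut
defaults to cosine similarity 0.8, the conventional criterion for calling
two profiles "the same signature", and is exposed as a parameter.
`scenario_summary()` reports the median pairwise similarity over the strict
upper triangle (each unordered pair counted once — one of several
reasonable conventions; ties in the maximum pair are broken by name order)
together with the median flatness.

## Simulating catalogues

`simulate_catalogue()` emulates the standard simulation protocol for
benchmarking extraction tools. For each sample:

* an exposure vector is drawn by taking independent Uniform(0, 1) weights
  for the k signatures and normalising them to sum to 1. This is the
  normalised-uniform construction, deliberately not Dirichlet(1, ..., 1);
  a flat-Dirichlet option is available in `sample_exposures()`;
* mutation counts are one multinomial draw of `mutations_per_sample`
  mutations from the mixed profile — equivalent to sampling each
  mutation's context independently.

Defaults are 5,000 mutations per sample (the median whole-genome mutation
burden of the pan-cancer cohorts these benchmarks emulate) and 10
replicate catalogues per scenario to expose run-to-run fluctuation.
Replicate r derives its seed as `seed + r`, so a scenario regenerates
bit-identically from its configuration. What the simulator does *not*
emulate: realistic per-cancer-type exposure distributions, inter-sample
burden variation, or sequencing artefacts — so passing benchmarks here
demonstrates algorithmic correctness under the stated generative model,
not performance on real tumours.

`generate_synthetic_signatures()` produces signature sets with controlled
flatness and pairwise similarity, so every downstream stage is testable
without reference downloads: each profile mixes a sparse random profile
with the uniform profile, and the mixing weight is tuned by bisection
until the achieved flatness is within ±0.02 of target (the mapping from
weight to flatness is continuous and increasing, so bisection is exact up
to tolerance). Pairwise-similarity bounds are enforced by bounded
rejection over fresh sparse supports; infeasible combinations error with
the best achieved values.

## De novo extraction and its stability

`run_nmf_once()` factorises a catalogue by multiplicative updates under
the generalised Kullback–Leibler divergence — the Poisson-likelihood
objective natural for count data and the one used by the SigProfiler
lineage of extractors; a Frobenius option is provided. The paper-level
protocol is consensus extraction (`repeat_nmf()` +
`consensus_partition()`): N independent factorisations (optionally each on
a Poisson-bootstrap perturbation of the counts — on by default, off for
deterministic tests), whose N·k signatures are partitioned into k clusters
by iterating minimum-cost bipartite (Hungarian) assignment of each run's
signatures to the current centroids. Cluster coherence is scored by
silhouette coefficients under cosine distance: per-cluster means $C_k$,
their average $C_{mean}$ and minimum $C_{min}$. Singleton clusters,
single-cluster partitions and all-zero distances score 0 by the standard
convention. Because every cluster receives exactly one signature per run,
the mean silhouette over all run-signatures coincides with the mean of the
per-cluster means.

`select_rank()` chooses the number of signatures with a deliberately
simple, fully transparent surrogate for the reference tool's internal
heuristics: among ranks with $C_{min} \ge 0.7$, take the largest whose
reconstruction error still improves on the previous rank by more than 1%
relative; if none qualifies, return the most stable rank flagged as
unstable. All per-rank diagnostics are returned so users can apply their
own rule.

Evaluation metrics (`evaluate_scenario()`):

* **F** — the fraction of replicates where the extractor found the right
  number of signatures and every extracted profile matched a distinct true
  one at cosine ≥ 0.8 (the matching is an optimal one-to-one assignment;
  the 0.8 threshold mirrors the similarity convention above and is a
  parameter, since "correctly identified" has no unique formalisation);
* **MSE** — the mean squared elementwise difference between the simulated
  catalogue and its reconstruction from the consensus signatures with
  NNLS-refit exposures, on raw counts, reported as median and IQR across
  replicates;
* **C_mean, C_min** — the stability scores of the chosen rank.

`refit_exposures()` fits each sample by non-negative least squares against
a fixed signature set and reports per-sample reconstruction cosine and
mean absolute error — the standard refitting validation.

## Archetypal analysis

Archetypal analysis represents each signature as a convex combination of
r *archetypes* that are themselves convex combinations of the observed
signatures: minimise $\lVert X - \alpha Z\rVert_F^2$ with $Z = \beta X$,
rows of $\alpha$ (p × r) and $\beta$ (r × p) on the probability simplex.
The constraints pin the archetypes to the convex hull of the data, so they
capture *extreme* rather than average profiles — exactly the profiles
whose redundancy one wants to expose in an over-complete catalogue.

`fit_archetypes()` alternates two blocks of simplex-constrained least
squares, each solved by projected gradient with a Lipschitz step size
(step = 1/L with L the spectral bound of the block's Hessian). This choice
guarantees two invariants the tests assert directly: the SSE trace is
non-increasing at every alternating iteration, and α and β are feasible to
machine tolerance at every step. Initialisation uses furthest-sum seeding
(greedily spread data points, re-picking the arbitrary first choice); when
r ≥ p the exact solution (each row its own archetype) is used as the
start. Multiple random restarts (default 5) guard against local minima in
`explained_variance_curve()`.

Open choices, decided as follows:

* **Explained variance** is 1 − SSE/TSS with TSS the total squared
  deviation of X about its mean profile; the zero-baseline alternative
  (TSS about the origin) is available via `ev_baseline = "zero"` because
  the definition used by existing AA software is not standardised. The
  number of archetypes is the smallest r reaching 95% explained variance
  (`select_num_archetypes()`).
* **Orientation**: archetypes are rows of Z (r × 96), consistent with
  signatures-as-rows everywhere else in the package.
* **Degenerate r ≥ p** is allowed, giving duplicate archetypes and zero
  residual rather than an error.

`reconstruction_report()` scores per-signature reconstruction cosines and
archetype–signature correspondence (an archetype "corresponds" to a
signature at cosine ≥ 0.97 by default). `alpha_grouping()` clusters
signatures on their full α rows (cosine distance, average linkage) to find
groups reconstructed by the same archetypes — the redundancy structure —
and masks coefficients below 0.2 for display only. On a 60-signature
reference catalogue this analysis identifies the subset of profiles that
are genuine extremes and the groups of signatures that are near-convex
combinations of them; reproducing those catalogue-specific counts requires
the reference signature file as input (`read_signature_table()` +
`filter_artefact_signatures()`), which this package does not bundle.

## Numerical and testing choices

* Context order is fixed once in `sbs96_contexts()` (substitution class,
  then 5' and 3' flank alphabetically); all readers reorder to it.
* Profiles are renormalised on read rather than rejected, because
  published signature files vary between probabilities and percentages.
* The bundled artefact list (19 names) is reconstructed from the COSMIC
  v3.3 annotations — user-overridable, since different catalogue versions
  flag different signatures.
* The Hungarian assignment solver is the O(n³) potentials /
  shortest-augmenting-path formulation, validated in the tests against
  exhaustive permutation search up to k = 6.
* Silhouettes are computed directly from their definition and
  cross-checked against `cluster::silhouette` on random instances.
* Test and example problem sizes are kept small by design — catalogues of
  tens to hundreds of samples, 2–5 signatures, a few NMF repetitions —
  which is sufficient for every oracle and invariant; the same functions
  scale to full-size analyses (30 repetitions, rank ranges to 25, 60 × 96
  catalogues) unchanged.

## Limitations

* The extractor is a transparent reference implementation of
  repeated-NMF-plus-consensus, not a clone of any production tool; its
  rank-selection rule is intentionally simple, and published performance
  numbers from specific tools should be compared only in a loose,
  stochastic sense.
* The simulator's uniform-exposure model overstates how evenly processes
  contribute to real tumours.
* Archetypal analysis is run on probability-normalised profiles; raw-count
  archetypes would weight high-burden contexts differently.
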