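---
title: "Scoring missing links with a simplified quantum walk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring missing links with a simplified quantum walk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sqwalk)
```

## The problem

Link prediction asks: given an observed undirected network — protein–protein
interactions, a metabolic map, a social graph — which unobserved node pairs
are most likely to be true but missing edges? The standard benchmark
protocol removes a random fraction of the edges, scores every candidate
pair on the remaining *training* graph, and asks how well the scores
recover the held-out *probe* edges.

`sqwalk` implements a discrete-time quantum-walk scorer whose state space
is deliberately small — dimension 2N for an N-node graph — alongside
fourteen classical similarity indices and the evaluation harness needed to
compare them.

## The walk model

Each node carries two coin directions: |0⟩, a self-loop, and |1⟩, a hop to
its whole neighbourhood treated as a single unit. The state is a real
vector of length 2N, written as two N-blocks `c(psi0, psi1)`.

Three operators define one step on the training graph with adjacency A,
degrees d and common-neighbour counts Γ(j,k) = |N(j) ∩ N(k)|:

* **Coin** (Grover-style diffusion, N×N):
  `G[j,k] = -A[j,k] + 2 Γ(j,k)`, so the diagonal is `2 d_j`. No
  normalising denominator is applied; the model intentionally drops the
  unitarity constraint so that amplitudes track raw similarity instead of
  a probability distribution.
* **Shift** (2N×2N, block diagonal): identity on the |0⟩ block — a
  self-loop on every node, which damps *traceback*, the oscillation of
  amplitude back and forth across a single edge — and the row-normalised
  adjacency `D⁻¹A` on the |1⟩ block. A degree-0 (dangling) node gets an
  all-zero row there: its |1⟩ amplitude simply exits rather than raising
  an error.
* **Evolution**: `U = S · blockdiag(G, G)`, i.e. `[G, 0; 0, (D⁻¹A)G]`.
  Because U is block diagonal, the two coin sectors evolve independently
  and everything stays real: no complex amplitudes ever arise.

The walk starts in the uniform superposition with every amplitude equal to
`α = 1/√N`. After `t` steps (default `t = 2` — long enough for the coin to
propagate common-neighbour structure, short enough to keep traceback from
accumulating) the ordered score of a candidate pair (j, k) is the observed
amplitude at j weighted by the pair's common-neighbour ratio:

```
score(j → k) = (Γ(j,k) / |E_T|) · (psi0(t)[j] + psi1(t)[j])
```

where |E_T| is the number of training edges. The score is zero whenever
the pair has no common neighbour, exactly like the local baseline indices.

```{r walk-example}
path <- linkNet(rbind(c("0", "1"), c("1", "2")))
buildCoin(path)
scoreLink(path, "0", "2", trainingEdgeCount = 2)   # 9 / sqrt(3)
```

### Design choices in the walk

Several points were genuinely open and are fixed here as package policy:

* **Initial amplitude.** Both `1/√N` (default, the equal-superposition
  convention) and `1/N` are available via `amplitude =`. Every score is
  linear in α, so switching conventions rescales all scores by a common
  factor and leaves every ranking — hence AUC and precision — unchanged;
  the test suite asserts this equivariance.
* **Symmetrisation.** The ordered score reads the amplitude at j only, so
  `score(j → k) ≠ score(k → j)` in general. The stored pair score is
  their mean by default (`symmetrization = "mean"`); `"sum"` scales
  everything by 2 (ranking-identical), `"none"` exposes the raw ordered
  matrix for inspection.
* **Γ(j,j) = d_j** by literal set-intersection semantics; the diagonal is
  masked to zero in every score matrix anyway.
* **Step counting.** "Apply U for a t-step walk" is implemented as exactly
  t multiplications by U, with t = 2 the operating point.

## Baseline indices

`similarityScores(net, method)` dispatches over fifteen methods
(`linkPredMethods()`): the walk model plus

| family | indices | notes |
|---|---|---|
| local | CN, Salton, Jaccard, Sorenson, HPI, HDI, PA, AA, RA | set arithmetic on neighbourhoods; ratio indices return 0 on zero denominators; AA uses the natural log |
| path | LP (`A² + αA³`, α = 0.001), Katz (`(I−αA)⁻¹ − I`) | Katz damping defaults to `min(0.01, 0.85/λ_max)` and convergence `α λ_max < 1` is enforced |
| Laplacian | ACT, Cos+ | both via the Moore–Penrose pseudoinverse L⁺ of D − A; ACT is the *reciprocal* commute distance `1/(l⁺_jj + l⁺_kk − 2 l⁺_jk)` so that, like every other index, larger means more similar; cross-component pairs score 0 |
| local walk | NC | three-step horizon; weight `w_j = Σ_{z∈N(j)} d_z / (d_max · 2M)`, transition probabilities from `D⁻¹A` |

The NC weight normalisation admits alternative readings that differ only
by per-node constant factors; the form above is the one implemented, and
it is a documented decision rather than an inference.

## Evaluation protocol

`splitEdges(net, eta, seed)` draws a uniform partition with
`|E_T| = round(η·M)`; no connectivity repair is attempted, so probe
endpoints may become isolated in the training graph (they then score 0
under every common-neighbour-family index — a property of the protocol,
not a bug).

* **Sampled AUC** draws `nSamples` independent (probe, nonexistent) pairs
  *with replacement*; strict wins count 1, ties within an absolute
  tolerance of 1e−12 count 0.5. The "nonexistent" pool is every unordered
  pair outside the full edge set E (training *and* probe edges excluded).
  The default `nSamples = 672400` bounds the Monte-Carlo standard error
  by `0.5/√672400 ≈ 6.1e−4`, i.e. below 1e−3 for any score matrix.
  `aucExhaustive()` enumerates all probe × nonexistent comparisons and is
  the oracle the sampler is validated against.
* **Precision@L** ranks only non-training pairs (ranking training edges
  would trivially flood the top of the list), breaks score ties
  lexicographically by label pair for reproducibility, and defaults to
  `L = floor(|E_T|/3)`.
* **`benchmarkLinkPrediction()`** repeats split → score → evaluate for
  several methods and reports per-method mean ± sd; per-repetition seeds
  are derived from the benchmark seed, so reports are byte-reproducible
  from (network, configuration, seed).

## Synthetic networks and what the tests do (not) show

`samplePlantedPartition()` is the workhorse fixture: its defaults
(120 nodes, 4 blocks, within-block edge probability 0.4, between-block
0.02) produce a strongly modular graph in which removed within-block edges
retain many common neighbours — precisely the signal that
common-neighbour predictors, the walk model included, exploit — while
keeping a full 15-method benchmark in the seconds range. Erdős–Rényi and
Watts–Strogatz generators cover the unstructured and small-world regimes,
and the packaged 34-node Zachary karate-club graph (78 edges, mean degree
4.588, max degree 17, diameter 5, transitivity ≈ 0.256, assortativity
≈ −0.476) is the canonical small real network.

These fixtures emulate controllable common-neighbour structure and degree
heterogeneity. They do **not** emulate the fat-tailed degree
distributions, core–periphery structure or thousands-of-nodes scale of
real interactomes and airline networks, so a passing suite demonstrates
correctness of the operators and protocol and qualitative predictive
power on modular graphs — not performance rankings on any particular real
network.

The test suite runs its heavier statistical checks at these sizes: the
sampler-accuracy and random-scorer checks use the default planted graph
(N = 120, ≈ 800 edges) with the full 672,400-sample AUC, operator-oracle
checks sweep 50 random graphs of up to 8 nodes, and baseline-oracle
checks 50 graphs of up to 12 nodes — sizes chosen so each property is
checked in seconds while the enumeration oracles stay exact.

## Numerical choices and edge cases

* Tie detection in AUC uses absolute tolerance 1e−12: exact-arithmetic
  ties (e.g. integer CN scores) are recognised, accidental
  floating-point near-ties are not inflated.
* `round(η·M)` is clamped to keep at least one edge on each side of the
  split at extreme η.
* Regular graphs have undefined degree assortativity; `networkStats()`
  warns and reports 0. Diameter of a disconnected graph is that of its
  largest component.
* Multi-edges and self-loops in input edge lists are collapsed/dropped
  (with a warning), since the model assumes a simple graph.
* Dense base-R matrices throughout: the 2N-dimensional walk space keeps
  networks of a few thousand nodes comfortably in memory; sparsity would
  be an optimisation, not a contract.

## Limitations

* Complex amplitudes, unitary walks and Szegedy/Fourier variants are out
  of scope; the model is deliberately non-unitary and real-valued.
* Only undirected, unweighted simple graphs are supported.
* The AUC sampler's with-replacement draws mean repeated runs at the same
  seed count are i.i.d. estimates of the same population AUC; exhaustive
  enumeration is available whenever the probe × nonexistent product is
  below 10⁷.
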