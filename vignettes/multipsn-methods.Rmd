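---
title: "Methods: multiplex similarity-network phylogenetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplex similarity-network phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multipsn)
```

## The model

multipsn infers relationships among organisms from protein similarity
networks (PSNs). The input is one square percent-identity matrix $W$ per
ortholog: $w_{ij} \in [0, 100]$ is the percentage of identical amino acids
between the aligned sequences of organisms $i$ and $j$, relative to the
total alignment length. Asymmetric inputs are symmetrized by the arithmetic
mean, $w_{ij} \leftarrow (w_{ij} + w_{ji})/2$. An organism missing from an
ortholog is kept as an isolated node with all-zero identities, so every
layer spans the same organism set.

Each layer is binarized by a threshold $\sigma_{th}$:

$$A(\sigma_{th})_{ij} = \begin{cases}1 & w_{ij} \ge \sigma_{th}\\
0 & \text{otherwise,}\end{cases}$$

giving a family of 101 nested networks per layer on the integer grid
$\sigma \in [0, 100]$. The thresholded layers are assembled into a
multiplex: organism $i$ in layer $\alpha$ is global node
$(\alpha - 1)n + i$, and the $L$ replicas of each organism are joined by an
unweighted inter-layer clique ($L(L-1)/2$ couplings per organism).
Communities are then found divisively: the intra-layer edge with the
highest shortest-path edge betweenness — computed on the full global graph,
so that a removal in one layer reroutes paths through the others — is
removed, betweenness is recomputed, and the process repeats until no
intra-layer edge remains. Because couplings are never removed, connectivity
projects cleanly onto organisms, and the ordered split events form an
organism-level dendrogram.

## Threshold selection

Thresholds are chosen per layer at peaks of a network dissimilarity
profile. For consecutive thresholds $\sigma$ and $\sigma + \Delta\sigma$ we
compare the two thresholded networks through their neighborhood-order
(shortest-path) matrices:

$$\delta(\sigma, \sigma + \Delta\sigma) = \frac{1}{n(n-1)}
\sum_{i \ne j} \left| d^{(\sigma)}_{ij} - d^{(\sigma + \Delta\sigma)}_{ij}
\right|,$$

with disconnected pairs capped at $\Lambda = n$. The cap is what makes the
profile spike when a threshold increment splits a component: all pairs that
lose contact jump to $\Lambda$ at once. The literature on network
comparison offers several related distances (including higher-order
neighborhood variants); we use the plain shortest-path form because the
peaks it produces sit exactly at the component-splitting transitions the
thresholds are meant to capture, and the dissimilarity function is a small,
isolated component that can be swapped without touching peak detection.
Peak positions under variant measures can shift by a grid step or two,
which is why reported per-layer thresholds should be read with that
tolerance.

Peaks are strict local maxima on the grid interior; a plateau counts once,
at its smallest $\sigma$ (deterministic and reproducible). Three selection
modes are provided:

* `split_guided` (default): the largest peak at which a probe subset —
  typically the eukaryote/mitochondrial sequences — is still connected to
  the rest of its component. This is "the point immediately preceding the
  split" of the probe: the chosen network still contains the inter-group
  edges whose removal order the analysis is about.
* `max_peak`: the global maximum of $\delta$.
* `manual`: a user-supplied value, since practitioners often choose
  thresholds by inspection.

A single multiplex-wide threshold (rather than per-layer values) is a
known alternative but is deliberately out of scope.

## Modularity

Partition quality along the removal trace is tracked with the multilayer
modularity

$$Q = \frac{1}{2\mu}\left[\sum_{\alpha}\sum_{ij}
\left(A^{\alpha}_{ij} - \gamma\,\frac{k^{\alpha}_i k^{\alpha}_j}
{2m_\alpha}\right)\delta(g_i, g_j) + \omega\, n\, L(L-1)\right],$$

with resolution $\gamma = 1$ and coupling weight $\omega = 1$ by default
(both exposed); $2\mu$ is the total strength including couplings. Because
partitions are organism-level, the coupling term is saturated and constant;
it still matters through the normalization. At $L = 1$ and $\gamma = 1$
this reduces (to machine precision) to the single-layer form
$Q = \frac{1}{2m}\sum_{ij} (A_{ij} - k_i k_j / 2m)\,\delta(C_i, C_j)$,
which is also exported separately. Two conventions required a decision:

* $Q$ is evaluated for the *current partition on the original thresholded
  multiplex*, the classical divisive-algorithm convention; evaluating on
  the pruned graph would drive $Q$ to zero trivially.
* The sum runs over all ordered pairs including $i = j$, so the
  one-community partition of any graph scores exactly 0 — a property the
  test suite asserts on random graphs.

The headline partition of an analysis ("immediately before the divergence
within the large community") is operationalized as the partition
established at the event where the probe group fully branches out — no
community mixes probe and non-probe members — available as the
`"group_split"` strategy; `max_Q`, `before_event(k)` and
`at_community_count(c)` cover the other selection conventions.

## Numerical choices

* **Tie-breaking.** Equal maximal betweenness (within a relative tolerance
  of $10^{-9}$, to absorb floating-point summation order) is resolved
  lexicographically on (layer index, smaller endpoint, larger endpoint).
  Removal traces are therefore bit-reproducible.
* **Recomputation schedule.** Betweenness is recomputed after every single
  removal (the classical schedule; complexity $O(m^2 n)$). The scorer only
  recomputes the connected component touched by the last removal —
  betweenness is component-local, so this is exact, and it makes the long
  fragmentation tail cheap. The removal loop is compiled (Rcpp) for the
  same reason; an igraph-based implementation serves as the independent
  cross-check in the tests, never as the implementation.
* **Degenerate inputs.** Edgeless graphs have modularity 0 by convention;
  an edgeless multiplex cannot be traced (error). Absent organisms carry a
  zero diagonal so presence is recoverable from the matrix alone.
* **Gap convention.** Percent identity counts a column as a match only
  when both sequences carry the same non-gap residue; the denominator is
  the full alignment length by default ("relative to the total alignment
  length"), with a both-ungapped (`pairwise`) denominator available
  because aligner conventions differ.
* **Inclusive threshold.** $w_{ij} \ge \sigma$ places an edge, so
  $w = 64$ survives $\sigma = 64$ and a zero-identity pair is still
  connected at $\sigma = 0$.

## Bootstrap

Support values resample identity scores, not alignment columns: each
$w_{ij}$ of one randomly chosen layer is replaced by
$k \cdot 100 / Y$ with $k \sim \mathrm{Binomial}(Y, w_{ij}/100)$, where
$Y$ is the layer's alignment length; one draw per unordered pair keeps the
matrix symmetric. All other layers are untouched, the original per-layer
thresholds are reused, and the detection is rerun; support for a named
group is the percentage of replicates in which it is recovered. Recovery
defaults to the exact-community criterion (the group's members share one
label and nobody else carries it) — the strictest reproducible reading of
"manual inspection of members in each module" — with a containment variant
available. The resampling variance $100^2\,p(1-p)/Y$ vanishes toward both
identity bounds, mirroring the behavior of strongly similar sequence pairs
under traditional bootstrapping. A single seeded RNG stream drives layer
choice and all draws in documented order, so a fixed seed makes the whole
run reproducible. An `all_layers` mode (every layer perturbed per
replicate) is provided for sensitivity analysis; the literal
one-layer-per-replicate scheme is the default.

## The synthetic benchmark

Real deposited identity matrices cannot be shipped with the package, so
every stage is exercised on generated fixtures. `planted_spec()` +
`generate_planted()` draw symmetric matrices with diagonal 100 from
truncated (clamped) normal distributions per block pair — a deliberately
simple noise model: controllable, deterministic per seed, and sufficient
to create the block structure, threshold transitions and missing-organism
patterns the pipeline consumes. It does *not* simulate sequence evolution,
rate heterogeneity, compositional bias, or the correlations between layers
that shared evolutionary history induces, so passing recovery tests shows
algorithmic correctness, not robustness to real-data artifacts.

`mito_fixture()` is a labelled convenience wrapper emulating the shape of
the mitochondrial-origin dataset: 6 eukaryotes, 72 Alphaproteobacteria
(17 of them a Rickettsiales-like sub-block), 4 + 4 Beta-/Gammaproteobacteria
outgroups, 8 ortholog layers, and 4 organisms isolated in every layer. The
identity levels (percent, sd 3–4) were fixed once at values a practitioner
would call realistic for conserved mitochondrial orthologs and their
bacterial homologs:

| pair | mean |
|---|---|
| within eukaryotes | 72 |
| within alpha (non-Rickettsiales) | 66 |
| within Rickettsiales-like block | 61 |
| Rickettsiales-like to other alpha | 60 |
| eukaryote to alpha | 52 |
| alpha to outgroups | 45 |
| within beta / within gamma | 70 |
| beta to gamma | 60 |
| eukaryote to outgroups | 40 |
| isolated organisms to anyone | 25 |

These levels put the eukaryote–alpha attachment just below the
Rickettsiales crossing, so `split_guided` selection lands around
$\sigma_{th} \approx 60$, the eukaryotes remain attached by a handful of
bridges, and the outgroups and isolates are already separate — the
structure the selection strategy is designed to find. The
Rickettsiales-like members are the most weakly attached alpha members, so
they depart earliest in the removal trace.

## Problem sizes

The removal loop is $O(m^2 n)$, so full traces to exhaustion are run at
reduced, proportionally shaped sizes: the 20-seed planted-recovery study
uses 4 blocks of 4/24/3/3 organisms over 8 layers, and trace-depth
analyses (early-departure ranking) use a 27-organism mito-shaped fixture.
Full-scale runs (86 organisms, 8 layers) are used wherever the trace can
stop at the probe's branch-out — threshold selection, the headline
partition and modularity, and the 100-replicate bootstrap — because only
the few bridge edges need removing there.

## Limitations

* The dissimilarity measure is one member of a family; thresholds under
  variant measures can differ by a few grid units.
* $\gamma$ and $\omega$ default to 1; reported modularity values are tied
  to that convention (and to evaluating on the thresholded, unweighted
  layers).
* The bootstrap perturbs one layer per replicate by design; correlated
  errors across orthologs are not modeled.
* Betweenness uses the classical exact recomputation schedule; faster
  approximations (e.g. Brandes-style sampling) are left as future work
  behind the pluggable scorer.
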