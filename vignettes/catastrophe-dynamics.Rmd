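---
title: "Catastrophe dynamics: modelling cascading disasters as absorbing Markov chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catastrophe dynamics: modelling cascading disasters as absorbing Markov chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascadyn)
```

## The model

cascadyn treats a catastrophe as a finite chain-of-events over a fixed
catalogue of peril classes: an earthquake triggers a tsunami, the tsunami
knocks out a power plant, the outage interrupts business, and so on until
the cascade dies off. The machinery is a discrete absorbing Markov chain:

* A **reduced adjacency matrix** $\bar{A}$ holds the one-step conditional
  probabilities $p_{ij}$ that an event of peril class $i$ triggers an
  event of class $j$. Rows are substochastic (they may sum to less than
  1); the residual mass $1 - \sum_j p_{ij}$ is the probability that the
  cascade stops at that event.
* `to_full()` appends an **outflow state** receiving that residual mass.
  The outflow row is the unit vector on itself, making it absorbing:
  every chain-of-events terminates with probability 1 whenever the
  spectral radius of $\bar{A}$ is below 1.
* The **fundamental matrix** $N = (I - \bar{A})^{-1}$ gives in entry
  $n_{ij}$ the expected number of visits to peril $j$ in a cascade
  triggered by peril $i$, counting the initial occupancy (diagonal
  $\ge 1$). The **interaction matrix** $M = N - I =
  \sum_{\tau \ge 1} \bar{A}^\tau$ removes the step-0 self-occupancy and
  is the object the analysis reads:
  * **expansion** — pairs with $m_{ij} > 0$ but $p_{ij} = 0$ are
    *emergent*: $j$ is reachable from $i$ only through intermediary
    events (`emergent_pairs()`);
  * **amplification** — pairs with $m_{ij} > p$ exceed what a single
    direct trigger contributes, the signature of feedback loops
    ($p_{ii} > 0$ or longer cycles) or of several converging paths
    (`amplified_pairs()`).

All closed-form computation operates on the reduced matrix: with the
absorbing state included, $I - A$ is singular by construction, so the
full matrix exists for simulation and conservation checks only.

Two routes to $M$ are provided. `interaction_matrix_truncated()` sums
$\bar{A} + \bar{A}^2 + \dots + \bar{A}^{\tau_{\max}}$, which mirrors a
cascade bounded at $\tau_{\max}$ steps and works for any substochastic
matrix, including ones at the row-sum boundary. `interaction_matrix_closed()`
solves the linear system $(I - \bar{A})N = I$ (no explicit inverse) after
a spectral-radius precheck at threshold $1 - 10^{-9}$; truncated entries
converge to it monotonically from below with geometric tail
$\max_{ij} |m^{\text{closed}}_{ij} - m^{(T)}_{ij}| \le s^{T+1}/(1-s)$
for row sums bounded by $s < 1$.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `p` | 0.1 | Ad-hoc one-step probability placed on every observed/declared edge (binary encoding). Dimensionless; also the amplification threshold. |
| `tau_max` | 10 (topology lab), 3 (historical) | Truncation depth in chain steps. Depth 10 is where the idealized 10-node patterns have stabilized; depth 3 matches the historical readout of secondary/tertiary effects. |
| random family `density` | 0.2 | Per-cell edge probability of the random topology family; produces the merging of several explored subspaces without saturating rows. |
| `max_steps` | 10 000 | Simulator guard; with row sums well below 1 a chain this long is astronomically unlikely, so hitting the cap signals a modelling error, not bad luck. |
| row-sum tolerance | 1e-9 | Validation slack for substochasticity; inputs are products of decimal fractions that do not round-trip exactly in binary floating point. |

The amplification threshold is **strict** ($m_{ij} > p$): a pair whose
only contribution is its single one-step path has $m_{ij} = p$ exactly
and is classed as plain expansion. This keeps "amplified" synonymous with
"something beyond the direct trigger is at work".

## The peril taxonomy and the historical encoding

The packaged taxonomy (`load_taxonomy()`) catalogues 19 peril classes —
11 natural (geological/geomorphological, hydrological, meteorological,
biophysical/ecological, extraterrestrial origins) followed by 8
anthropogenic (technological, economical, social). Catalogue order fixes
matrix indices, so outputs are comparable across runs and datasets. The
taxonomy ships as a data file so users can extend it; any extension is
flagged non-canonical and opts out of the 19-peril checks.

The packaged case list transcribes 29 historical cascading catastrophes
(1783 Laki through 2020 COVID-19) as ordered lists of directed peril
pairs. The transcription is literal: raw token strings are kept in the
data file and all normalization happens at parse time — uppercasing,
tolerance for `,`/`;` separators, and the `ES -> EC` alias (the
economic-crisis peril appears under both spellings in the source
records; the `(BI, ES)` pairs always follow GDP/financial-crisis
narratives, so we read `ES` as a typographical alias of `EC` rather than
an unlisted peril, and warn on first use). The flood self-loop in the
2008 Wenchuan record encodes landslide lakes causing downstream
flooding.

`build_empirical_adjacency()` is deliberately **binary**: an edge gets
probability `p` whether it was observed once or in ten cases. Historical
records are far too sparse to estimate $p_{ij}$ per pair, and an
unweighted union keeps rare-but-real interactions visible. The citing
cases per edge are retained in a provenance attribute, and a singular
rare edge (landslide-to-disease, observed once in 1994 Northridge) can
be dropped with `exclude_edges = "MS>DI"`. We keep it by default: it
does not cascade further, so it does not affect the headline readouts.

## Graph centralities

Cascade roles are read off the unweighted support graph of $\bar{A}$
(edge iff $p_{ij} > 0$), since the binary encoding carries no weight
information: sinks have high in-degree, sources high out-degree and
closeness, catalysts high betweenness. Two conventions are pinned down
so results are reproducible bit-for-bit:

* **Closeness** is the harmonic out-variant,
  $c(i) = \frac{1}{n-1}\sum_{j \ne i} 1/d(i,j)$ with $1/\infty = 0$. The
  empirical graph is not strongly connected (nothing triggers the
  extraterrestrial perils), so a plain average path length is undefined;
  the harmonic form degrades gracefully and preserves the
  source-ranking interpretation.
* **Betweenness** uses fractional shortest-path counts
  $\sum_{s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}$, endpoints excluded,
  self-loops ignored, unnormalized. Tied shortest paths split their
  credit; this is the standard resolution of the ambiguity in a pure
  path-count definition.
* Self-loops count once in in-degree and once in out-degree (a flag
  excludes them).

Centralities are standard graph operations and are delegated to igraph;
the test suite cross-checks them against exhaustive simple-path
enumeration on random graphs with up to six nodes.

## The topology laboratory

`topology_preset()` instantiates 24 named 10×10 configurations ordered
by pattern complexity: self-loops only; a single trigger row (1-to-n)
and single triggered column (n-to-1), each with and without self-loops;
two trigger rows and two triggered columns, with explicit gap-removal
variants; a row–column cross; forward chains, cycles, converging-path
diamonds and a relay band; an acyclic upper-triangular pattern; two
seeded random patterns at density 0.2; and near-full/full matrices. The
reference patterns these families follow were published only as figures,
so the preset implements their construction logic rather than any exact
pixel mask — an arbitrary `edges` mask entry point lets users reproduce
any specific pattern. The preset is about structure and count, and no
cell-for-cell claim is made for the figure-only patterns.

Useful exact facts the lab exposes (and the tests pin): a single trigger
row admits no second step, so $M = \bar{A}$ and nothing is emergent or
amplified; a pure self-loop topology amplifies every diagonal cell to
the geometric value $p/(1-p) > p$; any acyclic pattern is nilpotent, so
the truncated series stabilizes exactly by depth $n - 1$.

## The chain simulator as synthetic-data generator and oracle

`sample_chain()` draws chains state-by-state from the full matrix rows;
`mc_expected_visits()` vectorizes this over many chains and estimates
visit counts with standard errors, providing a Monte Carlo check of the
fundamental matrix that shares no code with the linear-algebra path.
Visit counting includes the initial occupancy, so the estimate targets
$N$ directly; comparisons with $M$ subtract the identity.

`generate_catalogue()` emulates the statistical structure the encoding
pipeline assumes: each synthetic catastrophe is one sampled chain,
recorded as its consecutive real-peril pairs in the same tabular dialect
the historical parser reads. Triggers cycle round-robin over the perils
with outgoing edges (or uniformly at random). Chains absorbed at step 1
are retained and flagged pair-less, mirroring single-event catastrophes.
Soundness is exact by construction — a sampled chain can only traverse
true edges — so recovered support is always a subset of the generating
support, and with high edge probabilities and a few hundred cases it
recovers the reachable support exactly.

What the generator does **not** emulate: reporting bias (real case lists
over-represent famous disasters), interpretation noise in encoding
narratives into pairs, non-stationarity of interactions over a century
of cases, and multi-variate preconditions (wind amplifying fire). A
green synthetic pipeline therefore demonstrates correctness of the
encoding machinery, not completeness of any historical catalogue.

## Numerical choices and degenerate inputs

* Row sums may equal 1 exactly (the full 10×10 pattern at $p = 0.1$);
  the truncated route handles this, the closed form refuses with a
  pointer to it.
* A 1×1 matrix `[1.0]` never reaches absorption; the spectral precheck
  rejects it.
* Ties in top-$k$ centrality lists break by catalogue order, making
  reports deterministic.
* Emergence uses $m_{ij} > 0$ exactly: truncated entries are sums of
  products of non-negative probabilities, so no positive path mass can
  cancel to a false zero.
* All stochastic entry points take an explicit integer seed and record
  it in their output; the random topology family is reproducible from
  its spec seed alone.

## Problem sizes used by the shipped checks

The test suite verifies the series/closed-form agreement at depth 50 on
the 19-peril empirical matrix and on 100 random mask matrices (density
0.2, rows capped at nine edges); the Monte Carlo oracle runs 100 000
chains per start state on the 2-cycle, self-loop, and 3-chain fixtures
(agreement within three standard errors); the geometric chain-length law
is checked on 100 000 chains; support recovery uses a 3-chain truth at
edge probability 0.9 with 500 synthetic cases. These sizes make every
stochastic check tight while the whole suite runs in seconds.

## Known limitations

* The one-step probability is a single ad-hoc constant; the binary
  encoding measures the *topology* of possibility, not calibrated risk.
* Only one-to-one triggering is modelled: no multi-variate interactions,
  no underlying-condition amplifiers, no inhibiting interactions, no
  time-dependence of the transition structure, and no loss/severity
  accumulation along chains.
* The discrete step index is causal order, not physical time: recovering
  a continuous-time rate description from the one-step matrix is out of
  scope.
* Conclusions drawn from the packaged 29-case list inherit its
  incompleteness; every interaction observed is real, but absence of an
  edge is weak evidence of impossibility.
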