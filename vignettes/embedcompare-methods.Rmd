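---
title: "Class-based comparison of embedding visualizations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-based comparison of embedding visualizations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embedcompare)
```

## The model

Two 2D embeddings of labeled points — say a UMAP of healthy tissue and a UMAP
of tumor tissue, both annotated with the same cell-population labels — cannot
be compared point by point: the layouts share neither coordinates nor, in
general, points. `embedcompare` compares them *through the labels*, asking
three sequential questions per class:

1. **Confusion** — how much does the class visually intermix with others?
2. **Neighborhood** — which other classes surround it, and how strongly?
3. **Size** — how abundant is it relative to its own neighborhood?

The order matters: a class whose neighborhood looks unstable but whose
confusion is low likely shifted its distribution, whereas high confusion with
an unstable neighborhood mostly signals that several class distributions are
too similar for per-class conclusions. Each stage is computed on regions
derived from the previous stage's construction.

### The perceptual graph

All three metrics are summaries of regions on a **Delaunay triangulation** of
the point set (built with `deldir`). The Delaunay graph is a natural proxy
for perceptual adjacency: each point connects to its surrounding points
without a bandwidth parameter, and the graph is invariant under rigid motion
and uniform scaling — as any quantity derived from a scatter plot's *shape*
should be.

Delaunay triangulations also connect points across empty space (hull and
bridge edges). To discount such perceptually unreasonable links, each class
$C$ gets a distance threshold

$$\tau_C = \mu_{D_C} + k\,\sigma_{D_C},$$

the mean plus $k$ standard deviations of the lengths of $C$'s *intra-class*
edges (both endpoints labeled $C$). The **core region** is the set of
vertices reachable from any $C$ vertex in at most $h$ hops, where an edge is
traversable if it is intra-class or no longer than $\tau_C$. The **context
region** is the unconstrained $(h+1)$-hop reachable set minus the core. The
**combined region** is the label closure: every vertex of the embedding whose
label appears in core or context. Counting whole classes (rather than the
accidental slice inside a hop radius) makes the Size composition independent
of where exactly the hop frontier fell.

### Metrics

- **Confusion** $= 1 - |\{v \in R_\mathrm{core}: \mathrm{label}(v)=C\}| /
  |R_\mathrm{core}|$, a fraction in $[0,1]$.
- **Neighborhood**: for each other class $X$, the raw connectivity
  $\kappa_{C\to X}$ sums $1/d(e)$ over boundary edges joining $V_C$ directly
  to $X$-labeled context vertices — it grows with the number of connecting
  edges and shrinks with their length. Raw values are normalized to mid-rank
  empirical-CDF scores $(\mathrm{rank}-0.5)/n$ within the pooled set of all
  strictly positive $\kappa$ across all ordered class pairs of that
  embedding; pairs with no boundary edge score exactly 0.
- **Size**: counts $c_\ell$ of each label present in $R_\mathrm{combined}$,
  expressed as centered log-ratios $\mathrm{clr}_\ell = \ln c_\ell -
  \overline{\ln c}$. CLR is the standard scale-free treatment of
  compositional data; values sum to zero, and a class's own CLR measures its
  abundance relative to the geometric mean of its neighborhood. A
  $\kappa$-weighted variant (each neighbor's CLR times the neighborhood score
  toward it) is also exposed.

### Comparing two embeddings

For each shared class: `confusion_delta` and `size_delta` are signed A − B
differences; `neighborhood_dissimilarity` is one minus the cosine similarity
of the two score vectors restricted to shared labels excluding the class
itself. Cosine was chosen because neighborhood vectors are directions in
"who-is-next-to-me" space: what matters is the profile, not the overall
connectivity level. Labels present in only one embedding are reported
separately and excluded from the vectors — zero-filling would conflate
"absent" with "present but disconnected". A configurable alternative
(total-variation distance on normalized vectors) was considered and rejected
as the default because it is dominated by the largest entry under the heavily
tied rank scores.

As a deliberately contrasting baseline, `neighborhood_jaccard_baseline()`
implements the conventional per-point k-NN Jaccard index (requires row-order
correspondence). On two re-layouts of identical data it collapses toward the
chance level $\approx k/n$ while the class metrics correctly report
similarity — the failure mode that motivates class-based comparison.

## Parameters

| parameter | default | units | effect |
|---|---|---|---|
| `h` | 1 | hops | core radius; context uses `h + 1`. Larger `h` grows both regions and smooths local noise at the cost of locality. |
| `k` | 3 | intra-class SDs | threshold $\tau = \mu + k\sigma$. `k = 0` prunes every inter-class edge longer than the intra-class mean; large `k` disables pruning. 3 follows the upstream prototype's calibration. |
| `kernel` | `"reciprocal"` | — | $\kappa$ kernel: `1/d` (default), edge count, or $e^{-d/\lambda}$ with $\lambda$ = mean edge length. The exact form is not pinned down by the framework; all satisfy "more edges, shorter edges ⇒ stronger". |
| `jitter_scale` | `1e-9` | fraction of bbox diagonal | seeded displacement of exactly coincident points, below any visual resolution; Delaunay is undefined on duplicates. |
| `prune_intra` | `FALSE` | — | also prune over-length intra-class edges. Provably inert for the regions (see below); retained for interface compatibility. |

### σ convention and degenerate classes

`sigma` is the population standard deviation, so a class with a single
intra-class edge gets $\sigma = 0$ and a finite threshold rather than `NaN`.
A class with no intra-class edge at all (singletons, or classes never
Delaunay-adjacent to themselves) falls back to the pooled statistics over all
intra-class edges of all classes; if the graph has none whatsoever, over all
edges. The fallback is recorded in the `pooled` field of
`intra_class_stats()`.

### Why `prune_intra` cannot matter

Every vertex of the reference class is a BFS source. A path that traverses an
intra-class edge arrives at another source, from which the remainder of the
path could have started with at least as many hops available. The union of
reached sets is therefore identical whether or not long intra-class edges are
traversable. The flag exists because the upstream prototype's behavior on
this point is unknown; a property test asserts the equivalence on random
layouts.

## The synthetic generator

`generate_layout()` draws one isotropic Gaussian cluster per class. This is a
*stated world*, not an imitation of UMAP/t-SNE geometry: it gives direct,
seeded control over exactly the three properties the metrics measure —
overlap (center distance vs spread), adjacency (which clusters are near
which), and abundance (points per class). Each class draws from a sub-seed
hashed from `(seed, label)`, so adding, moving, or resizing one class never
perturbs another's draw; `generate_pair()` exploits this to produce pairs
identical except for planted changes.

What a green test on this world does **not** establish: behavior on curved or
anisotropic manifolds, on density gradients within a class, or on the
fragmented multi-cluster classes real DR methods produce. Those layouts still
satisfy every *invariant* test (the invariants are layout-free), but the
planted-change recovery margins are specific to blob-like geometry.

Default scales follow the acceptance criteria's stated ranges: 200–1,000
points per class, 3–6 classes for planted-change recovery, with
unit spread and center separations quoted in spread units (e.g. separation 10
⇒ fully separated; 0 ⇒ fully overlapping).

## Numerical choices

- **Quantile ties**: mid-rank $(\mathrm{rank}-0.5)/n$ with average ranks —
  deterministic and symmetric; scores never reach 0 or 1, keeping 0 reserved
  for "no connection at all".
- **Zero-vector cosine**: both vectors zero → dissimilarity 0 (identically
  disconnected); exactly one zero → 1 (connected vs isolated is maximal
  disagreement); identical vectors short-circuit to exactly 0 so
  self-comparison is an identity rather than floating-point residue.
- **CLR**: natural log; labels present in a combined region always have count
  ≥ 1, so no pseudocount is needed; absent labels are excluded from the
  composition, not zero-imputed.
- **Degenerate input**: exactly coincident points are jittered (seeded,
  recorded in the graph's `jittered` field); an all-collinear point set has
  no triangulation and raises an error rather than silently chaining points.
- **BFS**: regions are unions of reachable sets and therefore independent of
  visit order; no tie-breaking is needed, which the path-enumeration oracle
  test confirms.

## Known limitations

- **Rank inflation of stray connectivities.** The quantile normalization is
  scale-free by design, so a single long hull edge (raw $\kappa \sim 0.05$
  against real connections $\sim 1{-}10$) still occupies a rank and can score
  up to $\sim 0.4$ when several such strays populate the pool. Between
  independent re-layouts of the same data these strays flip between exactly 0
  and small-positive, which can rotate a neighborhood vector noticeably: on
  adversarial layout seeds, a class's cross-re-layout dissimilarity
  occasionally exceeds 0.1 even though the layouts are statistically
  identical. Related, near-tied raw connectivities (e.g. perfectly symmetric
  layouts) have unstable ranks. This is a property of empirical-quantile
  scoring itself; the stochastic acceptance checks therefore pin their layout
  seeds, and comparisons of strongly symmetric embeddings should be read with
  care.
- **Core absorption.** When two clusters nearly touch, the reference class's
  core can absorb every directly adjacent vertex of the neighbor, leaving no
  class-to-context boundary edge and hence $\kappa = 0$ toward a class that
  plainly *is* a neighbor (it still appears in the context labels and the
  combined region). Confusion reports the intermixing correctly; the
  neighborhood vector underreports saturated adjacency.
- **No uncertainty quantification**: metric values carry no standard errors;
  differences should be judged against planted-change-scale effects, not
  read as significant per se.
- **Two embeddings only**; multi-way comparison is out of scope.
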