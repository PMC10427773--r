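---
title: "Trophic metanetworks: models, layouts and indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trophic metanetworks: models, layouts and indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the data model,
the algorithms, the parameters that matter and why their defaults are
what they are, what the synthetic generators do and do not emulate, and
the numerical choices made where the design was genuinely open.

## The data model

A **metaweb** `G*` is the directed network of all potential trophic
interactions in a regional pool. Edges point **resource → consumer**
(the direction of energy flow), so basal resources — detritus,
phytoplankton, plants — have in-degree 0. The metaweb must be weakly
connected; `build_metanet()` rejects a disconnected one and names the
components, because the trophic-level anchor (below) and the diffusion
kernel both assume a single component at the regional scale. Edge
weights, where present, are interaction probabilities or diet fractions
`π_kk'` and must be non-negative; self-loops and duplicate edges are
rejected (duplicate *file rows* are collapsed by summing, with a
warning, since edge-list dialects differ).

A **community matrix** `P` holds one row per local community (site or
date) of non-negative abundances over the metaweb nodes. Rows are
rescaled to sum to 1 on ingestion — the aggregation and diversity
formulas are stated on relative abundances — and the raw totals are
kept as metadata. Each row induces a **local network**: the
vertex-induced metaweb subgraph on the species with `p_k > 0`. Local
networks may be disconnected; that is a routine outcome of sampling,
not an error.

A **trophic table** maps each node to group labels at one or more
coarser resolutions, ordered fine to coarse. Partitions must be nested
(each group has exactly one parent); `trophic_table_tree()` validates
this and returns the containment forest. Node-name matching is exact
and case-sensitive everywhere — silent fuzzy matching is how community
matrices get corrupted.

## Trophic levels

Levels solve the linear system `L x = v` with `L = D − A − Aᵀ` the
Laplacian of the symmetrised web and `v = indegree − outdegree`. `L` is
symmetric positive semi-definite with zero row sums, so on a connected
component the solution is unique up to translation. Two conventions
fix it:

* **Solve.** The minimum-norm least-squares solution (`MASS::ginv`),
  which is well defined for every component size including isolated
  nodes. The equivalent reduced-system route (pin one coordinate,
  solve the nonsingular remainder) is used as an independent oracle in
  the tests; both agree to ~1e−7 on webs up to 200 nodes, and the
  residual `‖Lx − v‖∞` is checked below 1e−8 on every solve.
* **Anchor.** On the metaweb the minimum is set to 0 (basal species).
  Each weakly connected component of a local network is solved
  independently and translated so that its minimal-level node takes
  that node's *metaweb* level — all networks of a metanetwork share one
  trophic axis, and an isolated top predator keeps its metaweb height
  rather than collapsing to 0. If several nodes tie for the component
  minimum (within 1e−10), the anchor is the one with the smallest
  metaweb level, ties broken by node name: the output is deterministic;
  the choice is otherwise immaterial because tied nodes are translated
  identically.

Degrees are **binary** by default even on weighted webs (the imbalance
vector is a degree difference; a message notes when weights are being
ignored); `weighted = TRUE` switches `A`, `D` and `v` to edge-weighted
versions consistently. Useful identities, all tested: a chain solves to
(0, 1, …); reversing every edge maps `x` to `max(x) − x` (`v` changes
sign, `L` does not); self-loops cancel out of both `L` and `v`, which
is what lets aggregated webs (whose groups may feed on themselves)
reuse the same machinery.

## The diffusion kernel

`K = exp(−β L)` is computed through the eigendecomposition of `L` —
`K = U exp(−βΛ) Uᵀ` — then symmetrised against rounding
(`(K + Kᵀ)/2`). Because `L` has zero row sums, `K` is row-stochastic;
because the metaweb is connected, all entries are strictly positive;
and `K(β₁)K(β₂) = K(β₁+β₂)` (tested against an independent
scaling-and-squaring matrix exponential). Ecologically, `K_ij` is the
similarity of nodes `i` and `j` under a diffusion of organic matter
along the web: paths of *all* lengths contribute, which is what makes
the downstream layout robust to single-edge errors and sensitive to
energetic channels. β sets the diffusion extent: β → 0 gives the
identity (no structure), β → ∞ the uniform matrix `1/n` (all structure
diffused away). Overflowing β is rejected with a suggestion to lower
it.

## TL-tsne

The layout pins `x` to the trophic levels and embeds `y` by minimising
`KL(P ‖ Q)` with gradient descent on `y` only.

* **High-dimensional affinities** `P` are the kernel itself: zero the
  diagonal, clip rounding negatives, normalise globally to sum 1. No
  perplexity calibration — the kernel is already a symmetric,
  row-stochastic similarity, so recalibrating it through Gaussians
  would discard exactly the β-controlled structure the method is
  built on. A numerically identity kernel (β ≈ 0) has no off-diagonal
  mass and is rejected as degenerate.
* **Low-dimensional similarities** `Q` are the standard Student-t
  kernel `(1 + ‖(x_i,y_i) − (x_j,y_j)‖²)⁻¹`, zero diagonal, normalised
  over pairs. The pinned `x` enters the distances, so the optimiser
  accounts for trophic structure it cannot change.

Configuration (`layout_config()`), with defaults and rationale:

| parameter | default | why |
|---|---|---|
| `beta` | — (required) | diffusion extent; explore a grid (see below) |
| `max_iter` | 1000 | standard t-SNE budget; runs in seconds at food-web sizes |
| `learning_rate` | `max(2, n/exaggeration)` | size-adaptive; see below |
| `momentum` | 0.5 → 0.8 at iter 250 | standard two-phase momentum |
| `exaggeration` | ×4, first 100 iters | standard early exaggeration |
| `init_scale` | 1e−4 | y starts as N(0, 1e−4²): structure comes from the gradient, not the draw |
| `seed` | 1 | part of the configuration; identical config ⇒ bit-identical layout |
| `tol` | 0 (off) | see below |

Two defaults deviate from the classic fixed recipe, for measured
reasons:

* **Learning rate.** The classic fixed rate of 200 was tuned for
  embeddings of thousands of points initialised at a common origin.
  Food webs have tens to hundreds of nodes and a pinned, spread-out
  x-axis; at that size a 200-step makes `y` overshoot to coordinates of
  order 10² during exaggeration, from which the Student-t attraction
  (which decays with distance) cannot recover — the run ends *above*
  its starting KL. The size-adaptive `n/exaggeration` (floored at 2)
  descends reliably from 10 to 100 nodes across β from 0.01 to 1.
* **Stopping.** A per-iteration `|ΔKL| < tol` rule is available but
  off by default. The symmetric start `y ≈ 0` is a critical point of
  the objective: KL traces show it stationary to 1e−16 for on the
  order of a hundred iterations before the seeded asymmetry grows
  enough to escape, so any ΔKL threshold fires there, freezing an
  unformed layout. When a user sets `tol > 0` the check only begins
  after the momentum switch; the default simply runs `max_iter`, which
  is cheap at these sizes and never stops on a saddle.

Degenerate and awkward cases: with `n = 2`, pairwise normalisation
forces `P = Q = {½, ½}`, the KL is identically 0 and its gradient
vanishes, so the seeded (centred) initialisation is returned unchanged.
Disconnected networks are embedded **one component at a time**
(`attach_layout()` does this): the kernel of a disconnected graph is
block-diagonal, cross-component affinities are exactly zero, and a
joint embed would place components relative to each other arbitrarily;
per-component embedding makes the arbitrariness explicit while the
metaweb-anchored trophic levels keep a shared x-axis. Single-node
components get `y = 0`.

Layouts are stored under the key (network, resolution, β); several β
values coexist and re-attaching a key overwrites it with a message.

## Choosing β: the extended Moran index

`extended_moran()` scores a layout by the spatial autocorrelation of
the *embedded* coordinate over the symmetrised adjacency
`w = A + Aᵀ`:

`I = n/Σw · Σ w_ij (y_i − ȳ)(y_j − ȳ) / Σ (y_i − ȳ)²`.

Only `y` enters — `x` is pinned, so its autocorrelation says nothing
about the optimisation. This is one reasonable member of the family of
modified Moran statistics; it is deliberately isolated in a single
exported function so an alternative weighting can be swapped in.
`select_beta()` embeds a grid under one seed, scores each layout, and
returns the profile plus the argmax (ties to the smallest β; failures
recorded as `NA`, not fatal). Two caveats worth knowing: on webs with
an exact layer symmetry (the pyramid fixture) the index vanishes
identically — every edge joins layers whose centred y-sums cancel — so
the profile is uninformative there; and a high index at *every* β
(common on small webs) means all layouts are locally consistent and the
choice should fall back on how much channel separation is wanted.
Exploring several β values visually is encouraged; separation grows
gradually with β.

## group-TL-tsne

For webs beyond a few hundred nodes, the quadratic embed is spent on
the aggregated network instead: (1) TL-tsne on the Q group nodes of the
chosen resolution; (2) inside each group, a seeded
Fruchterman–Reingold placement of the group's vertex-induced subgraph,
centred so the member centroid equals the group's embedded coordinate
and rescaled so no member lies farther than `group_diameter/2` from it.
Any deterministic force-directed spread satisfies this contract; FR is
used because igraph provides it and only local, seeded spread is
needed. Diameters are in layout coordinate units (scalar or per-group).
Singleton groups sit exactly at their group coordinate. By default the
group centre carries the aggregated trophic level and members spread
around it in both dimensions; `strict_x = TRUE` re-pins every node to
its own trophic level after centring, for readers who want per-node
trophic alignment at the cost of the circular group shape. The layout
object records `tsne_n`, the node count the expensive stage actually
embedded, which the tests use to assert the claimed scaling.

## Aggregation

Group abundances and interaction probabilities are the
abundance-weighted lump:

`p̃_q = Σ_{k∈C_q} p_k`,
`π̃_ql = Σ_{k∈C_q, k'∈C_l} π_kk' p_k p_k' / (p̃_q p̃_l)`.

An aggregated edge exists iff `π̃_ql > 0`; within-group feeding becomes
a self-loop. Abundance is conserved exactly under any partition, the
identity partition returns the input, and nested aggregation is
associative on abundances — all tested. A group whose members all have
zero abundance is absent from the aggregated local network. The metaweb
itself carries no abundances; its aggregation uses uniform
`p_k = 1/n`, the least-informative choice, reported by a message —
aggregated *local* networks always use the real abundances, so only
the group-level backbone rests on this convention.
`append_agg_nets()` recomputes from the finest level on every call and
is therefore idempotent.

## Metrics, diversity, dissimilarity

`compute_metrics()` reports mean and max trophic level and the mean
directed shortest path per network at every resolution present.
Unreachable ordered pairs are excluded from the mean (local webs are
often disconnected); a single-node network reports `NA`. Paths are
unweighted — the metric describes web topology, not flux.

Node diversity is the Hill number
`(Σ p_k^q)^{1/(1−q)}` (`exp` of Shannon entropy at `q = 1`): `q = 0`
richness, `q = 1` exponential Shannon, `q = 2` inverse Simpson. Link
diversity is the Hill number of the normalised link distribution
`L_kl ∝ π_kl p_k p_l` over edges — the effective number of trophic
links. Diversity is non-increasing in `q`, and lumping can only lower
it (both tested).

Pairwise dissimilarity decomposes gamma over alpha with two equally
weighted networks: `D_β = D_γ / D_α ∈ [1, 2]`, where `D_γ` is the
diversity of the half-half mixture and `D_α` the generalised mean of
the within-network diversities at order `q`. `D_β` is mapped onto
[0, 1] by `ln D_β / ln 2` at `q = 1` and `(D_β^{1−q} − 1)/(2^{1−q} − 1)`
otherwise — both send identical networks to 0 and disjoint
equally-weighted ones to 1 at every `q`. Computed on node abundances
and on link distributions (over the metaweb's edge set, absent edges
weighing 0). The dissimilarity is **not** guaranteed to satisfy the
triangle inequality; treat the matrices as dissimilarities, not
distances.

Difference networks (`diff_networks()`) are the metaweb subgraph
induced by `V₁ ∪ V₂` with signed per-node `Δp` (absent = 0), a
presence category, and signed per-edge `Δw` (an edge counts 0 in a
network missing either endpoint). The difference is antisymmetric by
construction.

## Synthetic generators, and what passing tests do not show

* `make_pyramid(layer_sizes)` — an idealised, maximally hierarchical
  web: complete feeding between consecutive layers. Its trophic levels
  are the layer indices, which pins the Laplacian solver, and its
  symmetry is a known blind spot of the Moran score (above).
* `make_two_branch(chain_length)` — one basal resource feeding two
  disjoint chains that rejoin at one apex: the minimal web with two
  energetic channels. The channel-separation checks use chains of
  length 7 because the claim "larger β separates channels" holds in
  the *growth regime* of diffusion; on very short chains the kernel
  homogenises before β reaches 1 and the contrast peaks inside the
  test grid {0.01, 0.1, 0.5, 1}. Length 7 keeps the whole grid in the
  regime at both the kernel and the layout level.
* `make_random_metanetwork()` — a random DAG at a target connectance
  (rejection-resampled to weak connectivity), Dirichlet abundances
  with random absences, optionally a random nested trophic table.

These fixtures emulate hierarchy, channels, sampling-induced absences
and nestedness. They do **not** emulate trophic loops and cannibalism,
empirical degree distributions, body-size-structured diets, or
spatially correlated sampling. Green tests therefore certify the
algebra and the algorithms — exact identities, conservation laws,
descent, determinism, regime-level separation — not that any particular
empirical web will show clean channels; that judgement stays with the
β exploration on real data.

Problem sizes exercised by the checks, chosen to keep the full suite in
seconds while covering the regimes that matter: Laplacian solves on
random webs up to 200 nodes, kernels and semigroup checks up to ~25
nodes, embeddings from 2 to 100 nodes, aggregation sweeps over 100
random partitions.

## Known limitations

* Dense linear algebra throughout: eigendecomposition and the per-pair
  gradient are O(n³)/O(n²), comfortable to a few hundred nodes; beyond
  that, `group_tl_tsne()` *is* the intended path, not an optimisation.
* Directed, unipartite food webs only; no bipartite or mutualistic
  semantics.
* The metaweb is taken as given — no interaction inference from
  occurrence data.
* One trophic-level definition (the Laplacian system); flow-based or
  prey-averaged variants are out of scope.
* The extended Moran variant is one defensible choice among several;
  it is isolated so it can be replaced.
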