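---
title: "Edit-cost learning for GED-based virtual screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edit-cost learning for GED-based virtual screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergged)
```

## The screening model

Ligand-based virtual screening asks whether an untested molecule is likely
to bind a receptor, judging only by similarity to molecules whose activity
is known. `ergged` works on *extended reduced graphs* (ErGs): a molecule is
collapsed into a small attributed graph whose nodes are pharmacophoric
features — hydrogen-bond donors `[0]` and acceptors `[1]`, charges `[2]`
and `[3]`, hydrophobic groups `[4]`, aromatic ring systems `[5]`, carbon
and non-carbon link nodes `[6]`/`[7]`, and seven composite features such as
`[0,1]` — and whose edges carry the bond order (`-`, `=`, `≡`). Composite
labels are atomic symbols: any affinity between `[0]` and `[0,1]` is
expressed through the cost table, never through set-overlap logic.

The dissimilarity between two ErGs $G_a$ and $G_b$ is the normalised Graph
Edit Distance

$$
\mathrm{GED}(G_a, G_b, C_1,\dots,C_n) \;=\;
\min_{\{N_t\}} \frac{C_1 N_1 + \dots + C_n N_n}{L},
$$

where the minimum runs over edit scripts (node and edge insertions,
deletions, substitutions) transforming $G_a$ into $G_b$, $N_t$ counts the
applications of operation kind $t$, $C_t$ is its penalty, and
$L = |G_a| + |G_b|$ is the summed node count, which makes the distance
size-independent. A query molecule is classified *active* or *inactive* by
the class of its nearest neighbour; equidistant references are resolved to
the lowest input index so that every computation in this package is
deterministic and reproducible.

## The cost model: 126 parameters

With 15 node labels and 3 edge labels, and with substitutions unordered,
insert/delete tied, and identity substitutions structurally fixed at zero,
the model has

$$\binom{15}{2} + 15 + \binom{3}{2} + 3 = 105 + 15 + 3 + 3 = 126$$

free parameters. The unordered-pair, tied-indel parameterisation is what
makes the distance symmetric, and it matches the symmetric published
tables with identical insert and delete rows and zero diagonals.
`harper_costs()` ships the expert defaults (related features substitute for
1, unrelated for 2, anything involving the non-carbon link node for 3; link
nodes insert for 1, features for 2; single bonds insert free, others for 1;
bond-order changes cost 3). `learned_costs()` ships the cost table reported
from training on the six public screening benchmarks; it is provided as
published and is *not* reproduced by this package's tests, because those
benchmarks are external data.

## Distance engines

`exact_ged()` enumerates injective node mappings (deletion allowed,
leftover targets inserted) depth-first with branch-and-bound pruning; edge
operations are induced by the mapping. It is exponential and refuses pairs
above 14 total nodes by default — enough for oracle duty on small graphs.
Among equal-cost mappings the lexicographically smallest is kept.

`bipartite_ged()` is the polynomial approximation used for real work: a
$(n_1+n_2)\times(n_1+n_2)$ assignment matrix whose substitution cells hold
the node substitution cost plus an optimal assignment between the two
incident-edge label multisets (unmatched edges paying their indel cost),
and whose deletion/insertion cells charge the node indel plus all incident
edge indels at full cost. The matrix is solved exactly (Hungarian method,
`clue::solve_LSAP`), and the *induced edit path* — a valid transformation —
is scored. The result is therefore always an upper bound on the exact
distance; the test suite asserts this on hundreds of seeded random pairs.
Because the induced path depends on the direction in which the matrix is
built, the engine canonicalises the pair order internally and inverts the
mapping when needed, making `bipartite_ged(a, b)` and `bipartite_ged(b, a)`
identical by construction (a reversed path costs the same: indels are tied
and substitutions unordered).

Degenerate inputs follow fixed conventions: the distance between a graph
and the empty graph is the sum of its node and edge indel costs divided by
its order; two empty graphs are at distance zero; a zero cost table makes
every distance zero.

## Learning the costs

The learning loop repairs one molecule per iteration. For a training
molecule $G_j$ misclassified under the current costs, let $D$ be its
nearest different-class distance and $D' > D$ its nearest same-class
distance, with realizing edit paths held fixed (operation counts $N_t$,
$N_t'$, normalisers $L$, $L'$). The update chooses increments that would
swap the two path costs:

$$
\alpha_t = \frac{(D'-D)\,L}{m\,N_t} \ (N_t>0), \qquad
\alpha_t' = \frac{(D-D')\,L'}{m'\,N_t'} \ (N_t'>0),
$$

with $m$, $m'$ the number of distinct operation kinds on each path. Kinds
appearing on both paths receive the average $(\alpha_t+\alpha_t')/2$; all
others their single increment; untouched kinds keep their value. Per
iteration the molecule minimising the gap $D'-D$ is selected — the cheapest
repair, to perturb the solution as little as possible. The reconstruction
identities $\sum_t \alpha_t N_t / L = D'-D$ and
$\sum_t \alpha_t' N_t' / L' = D-D'$ hold exactly, and when the two paths
share no operation kind the updated fixed-path distances swap exactly; the
test suite asserts both.

Decisions this package had to make where the procedure was open:

* **Reference set during learning.** Each training molecule is classified
  against all other training molecules (leave-one-out), the natural reading
  of "classify all molecules" over the learning set.
* **Operation counts.** $N_t$ come from the edit path returned by the
  configured engine (bipartite by default) and are held fixed for the
  update; paths are not re-optimised mid-update.
* **Identity substitutions** are excluded from counts and from $m$, $m'$,
  and their cost is pinned at zero — mirroring the zero diagonals of every
  published table, before and after learning.
* **Clamping.** An update can drive a cost negative; since costs are
  penalties and all published values are non-negative, results are clamped
  at 0 (with a warning; `clamp = FALSE` disables it).
* **Degenerate paths.** A misclassified molecule whose realizing path has
  no costed operations ($m = 0$) cannot drive an update; it is skipped with
  a warning and the next-smallest gap is taken.
* **Termination.** The loop runs to `max_iter` (default 50, the reference
  protocol) but stops early when nothing is misclassified — the loop has no
  defined action in that state. Convergence is *not* guaranteed in general;
  the returned `learning_trace` keeps per-iteration selections, distances,
  accuracies and cost snapshots so oscillation is visible rather than
  hidden.

## The experiment protocol

`run_experiment()` reproduces the benchmark protocol shape: each target is
capped at its first 100 actives and equally many inactives (all actives and
as many inactives when fewer than 100 exist), costs are learned per target
on the train half, averaged into a per-dataset table and then across
datasets into one global mean table, and every target's test half is scored
against its train half under that mean table. Averaging is unweighted at
both levels, matching the one-number-per-dataset reporting convention.
"Mean of the learned costs over all databases" is resolved as averaging the
per-dataset tables (not all per-target tables directly); per-target tables
are first averaged within their dataset because class labels are only
meaningful within a target. A diagnostic flag (`per_target_costs = TRUE`)
evaluates each target under its own learned table instead.

## What the synthetic generator emulates — and what it does not

Because the six public benchmarks cannot be redistributed, all tests run on
generated two-class populations (`make_two_class_dataset()`). Each class
descends from a prototype graph; the class signal is carried by label
composition (actives biased towards `[5]`, `[4]`, `[6]`; inactives towards
`[0]`, `[1]`, `[2]`), echoing the pharmacophoric premise that bioactivity
similarity lives in feature content. Molecules are prototypes perturbed by
a known number of edit operations, and the applied script is returned, so
every perturbed pair doubles as an oracle: the script's cost certifies an
upper bound on the exact GED.

Two regimes are used, fixed once:

* **Separated** (default: 10 molecules per class, 8-node prototypes drawn
  independently per class, 1 perturbation op): nearest-neighbour accuracy
  under the expert costs is essentially perfect; used to test classifier
  plumbing.
* **Planted overlap** (`proto_divergence = 2`, `perturb_ops = 3`): the
  inactive prototype is the active one with exactly 2 node labels
  resampled, and 3 perturbation ops per molecule are enough for a
  label-blind (all-ones) cost table to misclassify part of the training
  set; used to exercise the learner, which must raise the discriminating
  substitution costs relative to the noise.

These fixtures do **not** emulate real chemistry: no valence constraints,
no realistic ring statistics, no decoy property matching, and graph sizes
(≤ 10 nodes) are at the small end of real ErGs. A green test suite
therefore certifies the algorithmic contracts — bounds, identities,
determinism, invariant preservation, accuracy improvement on planted
structure — not screening performance on real benchmarks.

## Numerical and scale choices

All ties (nearest neighbour, molecule selection, equal-cost mappings) break
by lowest index, making every result a pure function of its inputs. Exact
floating-point equality is asserted only where the arithmetic is exact
(zero diagonals, distance = raw/L); derived identities use 1e-9 or
tighter. Problem sizes in the tests — random pairs of ≤ 6 total nodes for
oracle comparisons, 500 pairs for the bound property, 10 training molecules
for the 50-iteration learning run — were chosen so the full suite completes
in about a minute while still exercising every code path; the learning
dynamics do not change qualitatively with larger populations, only slower.

## Known limitations

* The exact engine is exponential; it exists as an oracle, not for
  screening-scale graphs.
* The bipartite engine is an upper bound with no approximation guarantee;
  its tightness on random small graphs is asserted only as a bound.
* Learned costs depend strongly on initialisation (the optimisation surface
  is highly non-convex); initialising from the expert table is recommended
  over all-ones.
* The learning loop can oscillate; inspect the trace, and prefer the
  averaged cross-dataset table for deployment.
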