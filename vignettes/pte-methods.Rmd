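---
title: "Methods: network-based theme elicitation from card sorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based theme elicitation from card sorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pte)
```

## The procedure and its assumptions

Participatory theme elicitation replaces analyst-led coding with an
independent sorting exercise: each analyst partitions the same set of
quote cards into at least two labelled piles of their own devising, with
no "miscellaneous" pile allowed. The computational task is to combine
these independent partitions into quote groupings that reflect shared
sorting structure, and to quantify how well the themes the analysts later
articulate line up with those groupings and with each other.

The model makes three assumptions worth stating explicitly:

1. **Co-placement is the only signal.** Two quotes are related exactly to
   the extent that analysts put them in the same pile. Pile labels are
   opaque and never compared across analysts (each analyst chooses their
   own criteria), so a pile called "3" by one analyst and "barriers" by
   another contribute identically.
2. **Agreement is additive.** The edge weight between two quotes is the
   *count* of co-placing analysts. Weights are never normalized by the
   analyst count: three-of-four analysts agreeing is a materially
   stronger tie than one-of-four, and the optimization should see that.
3. **Groupings are a partition.** Every quote receives exactly one
   grouping label, including quotes nobody co-placed with anything
   (isolated nodes become singleton groupings). Human themes, by
   contrast, may overlap and need not cover all quotes — the congruence
   statistics accept that asymmetry rather than forcing themes into a
   partition.

## Community detection

Groupings maximize weighted Newman–Girvan modularity with a resolution
parameter,

$$Q = \frac{1}{2m}\sum_{ij}\Big[w_{ij} - \gamma\frac{k_ik_j}{2m}\Big]
\delta(c_i,c_j),$$

optimized by the Louvain heuristic implemented in this package:
repeated seeded sweeps over nodes, each node moving to the neighbouring
community with the largest positive gain; aggregation of communities
into super-nodes; repetition until a level produces no move; and a final
*refinement* sweep of single-node moves over the original graph starting
from the multi-level result. The refinement pass never decreases
modularity and measurably raises the rate at which the heuristic attains
the true maximum on small graphs, which we can verify exactly: the
package ships an exhaustive set-partition oracle (guarded to 10 nodes,
Bell(10) = 115,975 partitions) used throughout the test suite as the
independent standard.

Numerical and tie-break choices:

* **Gain tolerance 1e-12** — a move must improve modularity by more than
  this to be accepted, preventing cycling on floating-point noise.
* **Node order** — a fresh seeded shuffle per sweep (`seed` argument,
  default 0). Louvain output is order-dependent; fixing the seed makes
  every run reproducible, and the seed is logged by the CLI.
* **Resolution `γ = 1`** by default. Small `γ` collapses the partition
  toward one community, large `γ` shatters it toward singletons (both
  limits are exercised in the tests at `γ = 0.01` and `γ = 100`); the
  parameter is exposed but untuned because the method's typical use is
  the classic `γ = 1` optimum.
* **Weighted by default** — edge weights carry the analyst-agreement
  signal (assumption 2). `weighted = FALSE` is available for comparing
  against a purely topological reading of the network.
* **Canonical labels** — communities are relabelled `1..K` by descending
  size, ties broken by smallest member quote. Groupings from different
  runs, seeds or analyst groups are thereby directly comparable.
* **Edgeless networks** — modularity is undefined (division by `2m`);
  scoring raises an error while detection returns all-singletons with a
  warning, so a degenerate input still yields a usable (if vacuous)
  grouping.
* **Exhaustive-oracle ties** — among partitions within tolerance of the
  maximal modularity the oracle returns the one with fewest communities,
  then the lexicographically smallest labelling, making the oracle
  deterministic without a seed.

## Congruence statistics

`dominant_grouping()` tallies the grouping labels within a theme. The
percentage is kept at full precision internally; presentation rounding is
a separate, explicit policy (`integer`, `one_decimal`, or `full`) because
published PTE tables have used both integer and one-decimal renderings.
A tie for the modal label means *no dominant grouping*: the percentage is
undefined (`N/A`) and the full breakdown is reported
(`"4 green; 4 pink; 3 blue"`, descending count then label) rather than
silently picking a winner. Inputs are never reconciled against their
stated summaries: if a theme's quote list cannot produce a claimed
breakdown, the discrepancy surfaces in the output.

`adjusted_rand_index()` is computed from the pair-count contingency table
under the permutation model. The degenerate case where both groupings
are trivial *and* identical (expected index equals maximal index) returns
1 by convention; a non-trivial grouping scored against the
all-one-community grouping comes out 0 without special-casing.

`match_theme_sets()` reports the full Jaccard matrix and a *greedy*
best-match pairing (largest Jaccard first, each theme used once, zero
overlap never matched, ties to the earlier theme index). Greedy rather
than optimal assignment is a deliberate choice: it mirrors the informal
side-by-side comparison a joint workshop actually performs, and every
step is explainable to a non-technical co-analyst. It is documented as a
heuristic; an adversarial Jaccard matrix can make it globally
sub-optimal.

## The synthetic generator

`generate_study()` emulates the sorting exercise: `K` latent themes over
`N` quotes are the planted ground truth; each analyst starts from the
planted partition as piles and independently applies

1. one pile **split** with probability `p_split` (a random bisection),
2. one pile **merge** with probability `p_merge` (skipped when only two
   piles remain, preserving the two-pile rule),
3. independent per-quote **moves** with probability `p_move` each, to a
   uniformly chosen different pile. A move that would empty one of only
   two piles is rejected (any alternative target would empty the same
   source pile, so the quote simply stays put); with more piles, a pile
   emptied by a move just disappears.

Defaults are `N = 89` quotes, `R = 4` analysts and `K = 4` themes —
the size of the study design this generator emulates — with
`p_move = p_split = p_merge = 0.1` as an illustrative mild-disagreement
level; realistic human sorting-noise rates are unknown, which is exactly
why the rates are parameters. Noise is independent across analysts
(sorting is done in isolation). Randomness is one stream per study with
per-analyst sub-streams derived by fixed offsets, so a study is fully
reproducible from its seed and pile labels are emitted in a form that
lets moved quotes be identified when split/merge noise is off.

What the generator does **not** model: quote semantics (no notion of two
themes being conceptually adjacent), correlated errors across analysts,
analyst fatigue or ordering effects, and overlapping ground-truth themes.
Passing recovery tests therefore show that the pipeline recovers *planted
partition structure under independent random noise* — they do not show
that human sorts at a given disagreement level are this well-behaved.

## Experiment sizes

The test suite and the acceptance script run the pipeline at the emulated
study size (N = 89, R = 4) with 20 replicates per condition, a 20-seed
sweep over K = 2..6 for the zero-noise exactness check, 50 random ≤8-node
graphs for the Louvain-vs-exhaustive comparison and 100 random studies
for the handshake-conservation check; these sizes give stable estimates
(the noisy-recovery mean ARI varies by well under 0.01 across master
seeds) while keeping a full run in seconds.

## Known limitations

* Modularity maximization has a resolution limit; very small true themes
  embedded in a large quote set can be absorbed into neighbours at
  `γ = 1`. The resolution flag exists for exploring this, not to tune
  results post hoc.
* Louvain is a heuristic: on small graphs it attains the exhaustive
  maximum in most but not all instances (the suite checks ≥ 90% with the
  refinement pass, and that it never exceeds it).
* The grouping a given real-world PTE web tool produced may differ in
  unknowable details (variant, weighting, seed policy); this package
  fixes and documents every such choice, which guarantees
  reproducibility of *its own* outputs rather than bit-identity with any
  particular historical run.
* The two bundled per-quote colour assignments are synthetic stand-ins
  consistent with the published theme tables, present so the congruence
  statistics can be exercised end-to-end; conclusions about the original
  study's data cannot be drawn from them.
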