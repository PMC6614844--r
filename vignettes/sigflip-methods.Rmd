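---
title: "Predicting signalling drivers of cell-state transitions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting signalling drivers of cell-state transitions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigflip)
```

## The problem

Given expression profiles of a cell in an *initial* state and in a
*desired* state (two differentiation stages, a diseased versus a healthy
tissue, a resting versus an activated cell), which signalling molecules
should be activated or inhibited to push the cell from one to the other?
sigflip answers this by coupling three layers — expression, transcription
and signalling — around the transcription factors (TFs) that sit at their
junction.

## Booleanization of expression

Two routes convert continuous measurements into per-gene Boolean states
(1 = expressed) plus an expression probability in $[0,1]$:

**Barcode mixture.** Normalised log2 values of a non-expressed gene follow
$N(\mu, \sigma)$; expressed values follow $U(\mu, \text{upper})$ with a
fixed upper bound (default 15, log2 units). With equal mixture weights the
expression probability of value $x$ is

$$p(x) = \frac{\tfrac12 f_e(x)}{\tfrac12 f_e(x) + \tfrac12 f_n(x)},$$

where $f_e$, $f_n$ are the uniform and Gaussian densities. We read
$U(\mu, 15)$ as having support $[\mu, 15]$ — on log2 arrays expressed
values lie above the non-expressed mode, so values below $\mu$ get
probability 0. Per gene, the probability is the **maximum across
replicates**, and the state is 1 iff it *strictly* exceeds the cutoff
(default 0.95, i.e. < 0.05 probability of belonging to the non-expressed
component). The boundary is strict by that reading; the detection-call
route below is inclusive by its own wording — the two conventions are
deliberate and tested.

**Detection calls.** Probability $= 1 - p$ from a detection-call p-value;
expressed iff probability $\ge$ 0.94 (MAS5-style 'marginal'/'present').

Missing values are treated as non-expressed with probability 0. When both
routes are available the caller must choose one per run; they are never
mixed.

## The transition GRN

TFs whose Boolean state differs between the two conditions are wired into
a Boolean network using the transcriptional prior (mechanisms
*Transcriptional regulation*, *Influence on Expression*, *Regulation*).
Updates are synchronous majority (threshold) logic: with $a$ activating
and $i$ inhibiting regulators currently on, a TF switches to 1 if
$a - i > 0$, to 0 if $a - i < 0$, and **keeps its state on a tie or
without regulators**. The tie/no-input rule is a design choice the source
description leaves open; keeping state makes every state of an edgeless
network a fixed point, which guarantees the pruning step below always has
a feasible solution. Unspecified-sign regulatory edges carry no Boolean
semantics (excluded from the majority sum) but count as connectivity.

Both Booleanized states must be *point attractors*. Because the
fixed-point condition of a node involves only its own in-edges, the
pruning problem decomposes node-wise: for every TF we keep the
maximum-cardinality subset of incoming signed edges consistent with both
states (exact subset search up to in-degree 20, a documented greedy repair
above that; ties resolved by preferring activating edges, then canonical
order). Maximum cardinality per node implies global
restoration-maximality: putting back any removed edge breaks an attractor,
which the test suite checks exhaustively. GRNs with fewer than 10
connected TFs are flagged (`grn_too_small`): such transitions tend to
reflect non-signalling biology.

## Interface TFs and in-silico perturbation

*Interface TFs* regulate GRN-TFs, are expressed initially, and are
reachable from a 0-indegree source of the signalling network through a
path whose every node is expressed initially (unmeasured nodes are treated
as expressed — absence of evidence is not evidence of absence here).

All combinations of up to 4 interface TFs are clamped exhaustively. A TF
that is itself differential is clamped only to its final state (its
required direction is known); all others are tried in both states, since
expression does not reveal activity. Non-perturbed interface TFs are held
at their initial Boolean expression state throughout the simulation: they
are expressed molecules whose activity is not being perturbed, and
dropping them entirely would silently remove their constitutive influence.
Simulation runs to a fixed point; revisited states (oscillations) mark the
combination non-convergent and exclude it, rather than guessing a score.

The **flipping score** is the number of GRN-TFs changed relative to the
initial attractor. Combinations within the three best distinct scores
(ties included) are kept; those whose flips equal the union of their
singletons' flips are removed (no synergy). Note the rule's exact shape:
combinations whose flips are a *strict subset* of the union (one clamp
suppressing another's effect) are not removed — we keep the stated rule
rather than a stricter variant, and the synthetic tests cover this case
explicitly. If the best score covers less than 40% of the GRN-TFs the run
is flagged (`low_flip`). Pair frequencies across the best-performing
combinations, normalised to one, give the distribution $Q$ over
(interface TF, state) pairs.

## Path scoring and ranking

For molecule $x$ and interface TF $y$ the *most probably expressed path*
maximises the product of the expression probabilities of the
**intermediate** nodes (source and target contribute 1) over all simple
directed paths. Two variants:

* **correlation** — an edge $(u,v)$ whose expression correlation satisfies
  $|r| > 0.7$ with sign matching the interaction gets contribution
  $\max(p(v), |r|)$. The boost magnitude is not pinned down by the source
  description ("increased the probability"); $\max$ is monotone in both
  arguments, bounded by 1, and reduces to the base case without data.
* **length** — the plain product times $e^{-n}$ for $n$ edges, penalising
  the crosstalk risk of long routes.

Maximisation is a shortest-path problem under additive $-\log$ costs
(+1 per edge in log space for the length variant); all costs are
non-negative, so optima are simple paths. Unspecified-sign edges are
removed before the search, making the path sign (product of edge signs)
always $\pm 1$. Nodes with probability exactly 0 are excluded from the
graph; unmeasured nodes default to probability 0.5 (configurable). Ties
are broken deterministically — fewer edges, lexicographic node sequence,
positive sign — and an opposite-sign tie is reported (`sign_ambiguous`),
since equally probable paths of opposite sign are a genuine failure mode
of sign prediction.

$P_{x,y} = M_{x,y} / \sum_i M_{x,i}$ over reachable interface TFs. The
activation profile assigns TF $y$ state 1 when the path sign is positive;
the inhibition profile flips every assignment, so each molecule appears
twice in the ranking. Profiles are compared to $Q$ by Jensen–Shannon
divergence (natural log; the base cancels in ranking), with support-union
zero padding, so JSD is finite and bounded by $\ln 2$. Per variant,
molecules are competition-ranked by ascending JSD (ties share the minimum
rank); $R$ is the minimum over the two variants, falling back to the only
available variant for molecules reachable in one. Candidates satisfy
$R < 0.06 \cdot \max R$ (strictly below; the fraction is configurable,
1–10% being the sensible range). Success against known targets is judged
by molecule identity (direction matching is available), and the chance
level is the one-sided hypergeometric probability of hitting at least one
target in a random same-size selection; the universe counts molecules, not
(molecule, direction) entries, configurable via `success_universe`.

## What the synthetic generator emulates

`generate_case()` builds a fully ground-truthed world: a layered
signalling DAG with labelled sources; a planted molecule `X` fanning out
through disjoint branches (signs forced to a $+1$ product) to one *driver*
interface TF per GRN chain; a GRN of independent chains whose heads are
balanced between an inhibiting driver and an activating helper, so that
clamping a driver to 0 releases its chain and the flip cascades; junk
interface TFs and cross edges providing a graded ranking background; and
expression values drawn inside the barcode mixture components so that
Booleanization recovers the intended states exactly at noise 0.

Defaults (60 general molecules, 3 sources, 3 chains × (2 backbone + 2
leaf) TFs = 12 GRN-TFs, 3-edge branches, 4 junk TFs, 2 replicates per
state) are chosen once from the method's own constraints — the GRN must
clear the 10-connected-TF filter, drivers must fit within size-4
combinations — and scaled so the full multi-seed acceptance run stays
within minutes on one CPU. Noise flips the expression of a fraction of
non-GRN genes in both states, degrading interface-TF identification and
path probabilities while leaving the GRN ground truth intact.

What a green planted-recovery test does **not** establish: realistic
MetaCore topology (hubs, complexes, dense crosstalk), CMap-scale
correlation structure, probe-level artefacts, or the behaviour of the
attractor assumption on real, noisy Booleanizations. The generator's
chains are deliberately modular; real GRNs are not, and anti-synergistic
clamp interactions (see above) will be more tangled there.

## Numerical choices and degenerate inputs

* All path products are sums of logs; probability ties use a relative
  tolerance of 1e−12, matching the oracle-equivalence tolerance.
* $Q$ and every $P_x$ sum to 1 within 1e−12 by construction; `jsd()`
  validates its inputs to 1e−9.
* Empty edge sets, edgeless GRNs, molecules reaching no interface TF,
  empty BPC sets after filtering, and disconnected endpoints all yield
  labelled errors or documented empty results, never silent zeros.
* The ranking pipeline is seed-free and byte-deterministic; only the
  random-path sampler, Monte-Carlo permutation test and the fixture
  generator consume seeds.
* Configuration files are JSON (not YAML): no YAML parser is part of the
  package's dependency footprint, and `jsonlite` round-trips the
  provenance record losslessly.

## Known limitations

* The random simple-path sampler (randomized DFS with rejection) is biased
  towards short paths; the phospho-enrichment comparison inherits that
  bias, which is documented rather than corrected.
* The per-node exact pruning search is exponential in in-degree (guarded
  at 20 with a greedy fallback that sacrifices maximality).
* Complexes and functional groups are ordinary nodes; their expression
  probability defaults to 0.5 unless measured.
* The exhaustive size-4 enumeration is $O(I^4 2^4)$ in the number of
  interface TFs $I$; beyond roughly $I = 40$, lower `max_combo_size`.
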