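---
title: "Equal-weights parsimony for morphological matrices: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equal-weights parsimony for morphological matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpclad)
```

## The problem

`mpclad` reanalyses discrete morphological character matrices under
equal-weights maximum parsimony, the optimality criterion of classical
cladistics: the preferred tree is the one minimising the total number of
character-state changes (the tree length *L*). The motivating dataset is a
43-taxon × 72-character matrix for *Isodacrys* weevils and their tanymecine
outgroups, rooted on *Megalostylus albicans*; the package reproduces the
whole analytical chain that such a study runs in TNT/WINCLADA — tree
search, consensus, branch support, character optimization and homoplasy
accounting — as tested, scriptable R.

## The data model

A cell of a matrix is a *state set*, not a number:

* determinate — one state code in 0–9;
* polymorphic (`[01]`) — two or more observed states;
* missing (`?`) and inapplicable (`–`) — empty sentinels.

Missing and inapplicable cells are kept distinct in the data model (they
mean different things: ignorance vs. logical absence under reductive
coding), but both are *scored* as the full set of states observed in the
column. That is the TNT/WINCLADA default, and for the motivating matrix it
is the treatment that reconciles the published per-character statistics
(e.g. character 1's star-tree length of 19 requires the `[01]` cell to
cost nothing against either candidate ancestral state). Restricting the
state universe of blank cells to the column's *observed* states prevents
phantom states from inflating the maximum-steps bound *g*.

Characters carry an `ordered` (additive) flag — changes between states
`i` and `j` cost `|i − j|` — and an `active` flag. Five characters of the
motivating matrix are additive (3, 15, 28, 29, 34); everything without a
declaration defaults to non-additive, cost 1 per change.

## Length and optimization

Two routes compute character length on a tree:

* a vectorised **Fitch** pass (bitmask intersections/unions across all
  unordered characters simultaneously), exact on binary trees with
  set-valued terminals;
* a generalised **Sankoff** dynamic program with the unit or linear cost
  regime, used for additive characters and for polytomous trees, which it
  scores natively (each child contributes its own minimised cost vector —
  no soft/hard polytomy distinction beyond this).

The two routes are cross-checked against each other, against brute-force
enumeration of ancestral assignments at small *n*, and against
`phangorn`'s Sankoff implementation in the test suite.

Ancestral states are summarised as **MPR sets** (every state a node takes
in at least one minimum-length reconstruction, from the down-pass plus an
up-pass over cost vectors) and resolved to single states by **ACCTRAN**
(prefer, among cost-optimal choices, the child state farthest from the
parent: changes are pulled rootward and later reversed) or **DELTRAN**
(prefer the nearest: changes are pushed tipward as parallelisms). Ties
beyond that preference break to the lowest state code; the root takes the
lowest member of its MPR set. Under either mode the implied changes of a
character sum exactly to its length *s* — an invariant the tests enforce.
A transformation is flagged non-homoplastic iff its derived state arises
exactly once on the tree and never reverses.

## Homoplasy indices and truncation

Per character: *m* (minimum conceivable steps: one less than the number of
states forced by determinate cells, or the forced range for additive
characters), *g* (star-tree length: best single ancestral state against
every cell's cheapest member), and on a given tree *s*; then
`ci = m/s`, `ri = (g−s)/(g−m)`, `rc = ci·ri`. Ensemble values sum the
components over all active characters, including parsimony-uninformative
ones (the TNT convention). Two-decimal renderings are produced by
**truncation toward zero**, not rounding, using exact integer arithmetic
(`2/7 → "0.28"`, `12/17 → "0.70"`): truncation is the only rendering
consistent with the published per-character values, and it is what
reconciles printed two-decimal indices with exact fractions.

## Search

The heuristic search is the classical protocol: per replicate, a Wagner
starting tree from a random addition sequence (greedy insertion at the
cheapest edge, ties to the lowest edge index), then tree bisection and
reconnection (TBR) swapping — every edge bisected, every edge pair of the
two fragments reconnected, so the SPR neighbourhood is contained. Equal
length trees are buffered up to `hold`; strictly better trees restart
swapping; the pooled optima are collapsed and deduplicated by unrooted
split signature. All randomness flows from one master seed through a
deterministic splitting scheme, so runs are reproducible bit for bit; the
published protocol's "random seed = 1" is TNT-internal and not portable,
which is why reproduction targets the result (length, tree count), not
the replicate trajectory. The default replicate count is 50 (the study
used 300; convergence at this matrix size is rapid, and 300 remains one
keystroke away).

An exhaustive enumerator (with optional branch-and-bound pruning, which
provably cannot change the result because adding a taxon never shortens a
tree) serves as the exact oracle up to 9 taxa.

**Zero-length branch collapsing.** The default rule is `min_zero`:
collapse a branch whose minimum length over all most-parsimonious
reconstructions is zero (TNT-style). Branches are collapsed *one at a
time with recomputation*: contracting a single min-zero branch preserves
every character's length, whereas contracting several at once can
lengthen the tree, because different characters may need different
reconstructions to zero out different branches. The published tree count
(2 MPTs) is sensitive to this rule, so it is exposed as a switch
(`min_zero`, `max_zero`, `none`).

## Support

*Strict consensus* keeps exactly the splits common to all trees.
*Bremer* values come from one suboptimal-retaining search (bound 15,
buffer 10,000 under the published protocol) filtered by length: a node's
decay is the smallest excess at which some retained tree lacks it; nodes
surviving to the bound are reported as `≥ bound`. *Jackknife* replicates
deactivate each character independently with probability 0.36 (the
`e⁻¹`-style convention; the study states 1,000 replicates and a 63%
display cutoff but not the deletion probability) and summarise absolute
split frequencies. Inside replicates the search is deliberately reduced
(default 5 addition sequences) as a fidelity/runtime trade-off; for eight
or fewer taxa the package instead enumerates all topologies once,
precomputes the topology × character length matrix (lengths do not depend
on which characters a replicate keeps) and reads each replicate's *full*
optimal set from it — faster and free of search noise. Jackknife and
Bremer figures for the motivating study are published only as figure
annotations, so they are validated by properties (analytic deletion
expectation, monotonicity, reproducibility), not against printed numbers.

## The synthetic world

`simulate_tree()` draws uniform unrooted binary topologies (sequential
addition to a uniformly chosen edge). `simulate_matrix()` evolves each
character root-to-tip with a per-branch Bernoulli change probability —
not a continuous-time Mk process, deliberately, so step-count
expectations stay analytic — uniform among alternative states (±1 with
reflection for additive characters). Defaults emulate the motivating
matrix's shape: ~74% binary characters, a multistate minority of which
~26% are additive, change rate 0.05 (appreciable but unsaturated
homoplasy at this tree size), missing rate 0.01 and polymorphism rate
0.0013 (about one cell in 774, matching the single `[01]` cell of the
printed block), and a controller→dependents inapplicability rule
mirroring reductive coding (e.g. "epistome indistinct ⇒ epistome
characters inapplicable"). What a green synthetic test establishes is
internal correctness of the machinery under this generative model; it
does not establish that the model captures real morphological evolution
(no rate heterogeneity, no character correlation, no ascertainment bias —
all out of scope).

One consequence worth stating plainly: even at a "low" change rate the
generating tree is not almost-surely the most parsimonious one. A
character that happens to change on two branches can outvote a true
branch that happens to carry no change, so perfect topology recovery at,
say, rate 0.02 with 100 characters on 8 taxa plateaus around 75% of
seeds — with the search verifiably exact (it matches exhaustive
enumeration in every miss). The recovery acceptance test keeps its
stated ≥90% threshold and is allowed to stay red rather than having the
world tuned to it; the provable form of the property (a matrix
homoplasy-free on its generating tree makes that tree globally optimal,
because `sum(m)` is a tree-independent lower bound) is what the unit
suite asserts.

## What cannot be reproduced here, and why

Only characters 1–18 of the 43×72 matrix are available in print; the full
deposited file is not shipped. The package therefore ships the printed
18-character block verbatim (`builtin_fixture("table2_cols1_18")`) and
the published per-character statistics table
(`published_character_stats()`) as *inputs*. The headline reproduction
tests (L = 242, two MPTs, CI 0.39/RI 0.70, consensus L = 244, the 57/6/9
ambiguity partition) are implemented end-to-end against a
`supplementary_full` fixture slot and fail with an explicit message until
the deposited Nexus file is supplied; they are not weakened or skipped.
Two strong internal checks *are* possible from print alone: the published
per-character lengths sum to exactly 242, and the per-character minima
implied by the printed consistency indices sum to 95 — the unique integer
consistent with the truncated ensemble CI at both L = 242 ("0.39") and
L = 244 ("0.38"); `min_steps()` reproduces those minima on all 18 printed
columns.

## Numerical and degenerate-input choices

* State codes are capped at 0–9 (the data use 0–4).
* A wholly blank column scores 0 steps with one dummy state; `ri` is
  undefined (rendered blank) whenever `g = m`.
* Sankoff "infinite" terminal costs use a large finite constant; all
  index arithmetic that reaches output goes through exact integers.
* TNT `ccode` indices are 0-based, NEXUS `TYPESET` indices 1-based, as in
  the respective programs; taxon-name whitespace becomes underscores on
  write for Newick/NEXUS compatibility.
* Root state ties and traceback ties resolve to the lowest state code, so
  every reported reconstruction is deterministic.

## Known limitations

No implied or successive weighting, no user step matrices beyond
ordered/unordered, no ratchet/drift/sectorial search, no branch lengths
or time calibration, and pure-R performance: the 43-taxon TBR
neighbourhood is minutes-scale, which is adequate for the study-size
matrix but not for hundreds of taxa.
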