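---
title: "Recombination-aware alignment of sequences to variation graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recombination-aware alignment of sequences to variation graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recombalign)
```

## The problem

Bacterial genes are frequently mosaics: homologous recombination replaces a
segment of a gene with the corresponding segment from another lineage, which
is how much antigenic variation and antibiotic resistance spreads.  A
pangenome of known strains can be stored as a *variation graph* — a
vertex-labelled directed acyclic graph whose distinguished source-to-sink
paths spell the known haplotypes.  Aligning a new sequence to such a graph
with a standard sequence-to-graph aligner either forces the query onto a
single path (missing the mosaic structure) or lets it wander freely across
bubbles (implying arbitrarily many unpenalized recombinations).

`recombalign` implements the middle ground: an exact global alignment of a
query against the distinguished paths that allows *at most one*
recombination — a switch from one path to another at a pair of
recombination vertices, possibly through a "virtual" arc absent from the
graph — and prices that switch with an explicit, displacement-dependent
penalty.  A high-scoring alignment that uses the virtual arc is direct
evidence that the graph lacks a path consistent with the query, i.e. that
the query is a recombinant of two stored haplotypes.

## The model

Throughout, the graph is *canonical*: every vertex carries a single
character (the package converts arbitrary GFA segments into chains of
single-character vertices and keeps an origin map back to the input
segments).  An alignment of a query `s` to a path `p` is the usual sequence
of ordered column pairs; its value is the sum of per-column substitution
scores (`match` for equal characters, `-mismatch` otherwise) plus `-gap`
per gap column (linear gap model).

**Forward pass.** For every path `p`, vertex `v` on `p`, and prefix length
`i`, `M[v, i, p]` is the optimal value of a global alignment between the
portion of `p` ending at `v` and the prefix `s[1..i]`.  Because a vertex
occurs at most once per path, `M` is realized as one dense
`(|p|+1) x (n+1)` table per path, and each table is exactly a
Needleman–Wunsch matrix of the query against the path's spelling.  The
per-row recurrence is vectorised: with linear gaps the serial horizontal
dependency collapses into a running maximum,
`M[r, i] = cummax(c(M[r, 0], cand + gap*i))[i+1] - gap*i`, which keeps the
whole pass in vectorised arithmetic on integer-valued doubles (exact, so
oracle comparisons can use strict equality).

**Backward pass.** `R[v, i, p]` is the optimal value of aligning the
suffix starting after position `i` against the portion of `p` starting at
`v`; it is computed by running the forward recurrence on the reversed path
and reversed query and flipping indices.

**Recombination.** A recombination is a quadruple `(p1, p2, rho, psi)` of
two *different* paths and a recombination vertex on each.  Its
*displacement* anchors the junction to the smallest bubble containing it:
with `alpha` the deepest vertex shared by both paths strictly preceding
`rho` on `p1` and `psi` on `p2`, and `beta` the shallowest shared vertex
strictly following both, the displacement is

```
d = | |a1| - |a2| + 1 | + | |b1| - |b2| - 1 |
```

where `a1` (`a2`) is the subpath from `alpha` to `rho` (`psi`) and `b1`
(`b2`) from `rho` (`psi`) to `beta`, vertex counts inclusive of both ends.
The recombination penalty is affine: `rec_open + rec_ext * d`.  Balanced
junctions (e.g. switching between the two branches of a SNP bubble at
corresponding positions) cost only `rec_open`; junctions that imply a large
insertion or deletion relative to the bubble structure pay proportionally
more.  Displacements for all path pairs are tabulated once per graph by a
parallel scan over each pair's shared vertices (shared vertices appear in
the same relative order on both paths because the graph is acyclic), after
which any query is answered in constant time.

**Combination.** The reported score is the maximum of

* (a) the best no-recombination alignment, `max_p M[sink, n, p]`, and
* (b) `M[v, j, p] + R[w, j+1, q] - rec_open - rec_ext * d(p, q, v, w)`
  over all ordered pairs of distinct paths `(p, q)`, all labelled vertices
  `v` on `p` and `w` on `q`, and all breakpoints `j` inside the breakpoint
  window.

On a tie the no-recombination alignment wins; within case (b) ties are
broken by smallest breakpoint, then smallest `(v, w)` in topological
order, then lexicographically smallest `(p, q)` — output is fully
deterministic.

### Why the search iterates over all path pairs

A tempting shortcut considers, at each `(v, j)`, only the path maximizing
`M[v, j, ·]` (and symmetrically for `R`): any other path gives a smaller
alignment contribution.  That argument is sound only when the penalty is
the same for every pair, which the displacement term breaks: the pair
maximizing `M + R` is not always the pair maximizing
`M + R - rec_ext * d`, because `d` depends on which pair is switched
between.  Since path sets of gene-scale graphs are small, the package
evaluates case (b) per ordered pair with a precomputed displacement matrix
and fully vectorised `(v, w)` sweeps per breakpoint; this restores exact
optimality (and exact agreement with the brute-force oracle) at a cost of
`O(|P|^2)` vectorised passes instead of one.  The best/second-best path
summaries (`dp_state()`, `enforce_distinct_paths()`) are still provided:
they implement the distinct-path constraint for the shortcut formulation
and are useful for screening.

### The `rho == psi` case

The two half-alignments both consume the shared vertex's label when
`rho == psi` (the prefix matrix ends *at* `v`, the suffix matrix starts
*at* `w`).  The definitions of a mosaic alignment and of the combined
recurrence genuinely disagree here about whether that label is used once
or twice; we resolve it on the side of the recurrence's arithmetic: the
emitted walk contains the shared vertex twice (a degenerate virtual
self-arc) and both columns are kept, so the re-scored value of the emitted
columns minus the recombination penalty always equals the reported score
exactly.  `rescore_alignment()` performs precisely that check and the test
suite applies it to every traceback.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `match` | 2 | score per matching column |
| `mismatch` | 4 | penalty magnitude per mismatching column |
| `gap` | 4 | penalty magnitude per gap column (linear) |
| `rec_open` | 4 | recombination opening penalty |
| `rec_ext` | 0.1 | penalty per displacement unit (may be fractional) |
| `window` | 0.95 | fraction of the query where a breakpoint may sit |

Penalties are magnitudes and are subtracted, so a command line stating
"mismatch penalty: 4" maps directly onto `mismatch = 4`.  The window
fraction `f` maps to breakpoints `j` in
`[ceil(n(1-f)/2), floor(n(1+f)/2)]`, clamped to `[1, n]` (a recombination
needs a nonempty prefix); `f = 0.95` restricts recombinations to the
middle 95% of the query, which suppresses junctions placed near the ends
where too few variants distinguish the candidate parents, and `f = 1`
lifts the restriction.  Raising `rec_open` (e.g. from 4 to 28) trades
sensitivity for specificity; the count of reported recombinations on a
fixed query set is non-increasing in `rec_open`, which the tests verify.
All scores are kept as doubles; with integer match/mismatch/gap values the
matrices are exact integers, and only the `rec_ext * d` term is
fractional, so equality comparisons against the oracles are exact.

## The synthetic generator

`make_graph()` emulates the structure of gene-scale bacterial pangenome
graphs: a random backbone with `n_variant_sites` planted bubbles, each a
SNP (two parallel single-base branches) or a short (1–4 bp) indel, and
`n_paths` haplotype paths assigned one allele per site, with both alleles
of every site forced into use.  The graph is the union of the path walks,
so the distinguished paths cover every arc.  `select_edge_cover_paths()`
reproduces the hold-out construction used to define ground truth: paths
are iteratively dropped (in name order) while they cover no arc uniquely,
leaving a minimal edge-cover set `K` of "known strains".
`simulate_recombinant()` cuts two parents at a shared-vertex-anchored
coordinate with the breakpoint restricted to the middle 10–90% of the
sequence, so the truth is an exact two-subpath mosaic walk;
`mutate_query()` adds substitution-only noise at a fixed per-base rate
(0–10% in the tests).

What the generator does *not* emulate: the topology of real
graph-construction pipelines (nested or overlapping bubbles, long
repeats), indel errors in queries, and site-specific mutation-rate
variation.  Passing the recovery tests therefore demonstrates correctness
of the algorithm under its own model assumptions — clean mosaics of known
haplotypes with moderate point noise — not robustness to arbitrary real
data.

Two details of the recovery experiments are deliberate:

* *Identifiability conditioning.*  A reported breakpoint is only defined
  up to the variant-free window around the cut (every position in that
  window yields the same mosaic sequence), and the parent pair is only
  recoverable when no third path matches the query prefix or suffix over
  that whole window.  With `require_identifiable = TRUE` the simulator
  redraws anchors until both conditions hold, making "correct pair,
  breakpoint inside the window, Jaccard 1" a well-posed target that the
  aligner then meets in 100/100 cases.
* *Controls are structurally clean.*  A control query spelling an existing
  path scores `2n` without a recombination, while any case-(b) candidate
  scores at most `2n - rec_open`; with `rec_open > 0` controls can never
  report a recombination, and the 20/20 specificity the tests observe is
  exact rather than statistical.

## Problem sizes and runtime

The test and acceptance workloads use graphs well inside the guards of the
brute-force oracles: per-path oracle equivalence on 200 graphs of 2–8
paths (~40–75 canonical vertices, queries to ~75 bp), recombination oracle
equivalence on 100 graphs of 3–6 paths (~30–45 vertices, queries to
~45 bp), exhaustive displacement checks on 100 small graphs (all
`(p1, p2, rho, psi)` combinations, ~135 000 queries), and recovery on 100
mutation-free recombinants plus 20 controls at 150 bp / 10 sites / 5
paths.  These sizes keep the full exhaustive enumerations tractable while
exercising every code path; the aligner itself handles multi-kilobase
queries, with case (b) costing `O(|P|^2 |V'|^2 n)` vectorised operations
in the worst case (`|V'|` = vertices per path).

## Limitations

At most one recombination per alignment is modelled; mosaic genes with
multiple donors need repeated application or a future multi-switch
extension.  Gaps are linear (no affine gap model).  Queries are aligned
globally on the forward strand only; semi-global alignment and
reverse-complement handling are out of scope.  Graphs must be acyclic
with forward-oriented links, and GFA W-lines/GFA2 are not read.
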