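---
title: "Methods: interval discretization and parsimony analysis for transitional hadrosauroids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interval discretization and parsimony analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hadromosaic)
```

`hadromosaic` implements two complementary quantitative procedures for
placing a fossil taxon relative to the basal-hadrosauroid / hadrosaurid
split: model-based discretization of continuous measurement attributes,
and equally weighted maximum-parsimony analysis of a morphological
character–taxon matrix.  This vignette records the models, the numerical
choices, and the reasoning behind the design decisions that the interface
documentation does not have room for.

## The mixture model behind the interval standards

Each measurement attribute is a one-dimensional variable — a dimensionless
ratio or an angle in degrees — observed for most known hadrosauroid
species plus a few closely related iguanodontians.  Multiple specimens of
one species are first collapsed to the species mean; the focal taxon under
evaluation is always excluded from model fitting and only enters at the
classification step, so the standards are never contaminated by the
specimen they are meant to judge.

The per-species values \(x_1,\dots,x_n\) are modeled as a finite Gaussian
mixture

\[
  f(x) \;=\; \sum_{g=1}^{G} \pi_g\, \mathcal N(x \mid \mu_g, \sigma^2_g),
  \qquad \sum_g \pi_g = 1 ,
\]

fitted by EM in two families: *equal variance* (\(\sigma^2_g \equiv
\sigma^2\), df \(= 2G\)) and *free variance* (df \(= 3G - 1\)).  Models
are compared by BIC in the maximize-is-better convention \(2\ell -
\mathrm{df}\,\log n\), over \(G = 1,\dots,9\) by default — the univariate
families and a component range wide enough that the argmax is always
interior for datasets of this size (a few dozen species).  Ties break
toward smaller \(G\), then toward equal variance: the more parsimonious
description wins.

Numerical choices:

* **Initialization** is deterministic: the sorted values are cut into
  `G` contiguous blocks of near-equal size.  This makes every fit
  reproducible without storing a random state.  An agglomerative
  alternative (Ward linkage) is available behind `init = "hclust"`; on
  one-dimensional data the two almost always converge to the same
  optimum, and the quantile cut is cheaper and has no library
  dependency.
* **Variance floor**: \(10^{-6}\times\operatorname{var}(x)\) (absolute
  \(10^{-12}\) for constant data) prevents a component from collapsing
  onto a single observation and sending the likelihood to infinity.
* **Degeneracy**: if a component's weight collapses the fit is retried
  from shifted deterministic cuts (three attempts) and then fails with an
  informative error; nothing silently falls back.
* **Convergence**: relative log-likelihood change below `1e-8`, with the
  full per-iteration trace stored so monotonicity is checkable on every
  fit.

### From partition to decision standard

The MAP assignment under the selected model partitions the species into
components, relabeled `C01`, `C02`, … in increasing value order and
summarized by closed intervals \([\min, \max]\) of their assigned values.
Components are ordered by interval lower bound; this equals ordering by
mean whenever the MAP regions are contiguous (always the case in the
equal-variance family) and keeps the interval ordering well defined in
the rare free-variance fit whose broad component catches both tails.

Each component is then mapped to the side — *basal* (basal hadrosauroids
plus basal iguanodontians) or *hadrosaurid* (hadrosaurines plus
lambeosaurines) — holding the majority of its species, and contiguous
same-side components are merged (the standard for an attribute whose
derived side splits into two adjacent components is their union).  The
**boundary** between the adjacent opposite-side intervals is the mean of
the lower interval's maximum and the upper interval's minimum.  It is
kept unrounded internally; reports may round to printed precision (two
decimals for ratios, whole degrees for angles), but the package never
feeds a rounded boundary back into computation.

A standard is **diagnostic** when the arrangement along the value axis is
exactly one basal run and one hadrosaurid run, and its **alignment
score** — the fraction of species whose component side matches their
taxonomic side — reaches 0.9 by default.  The threshold is a design
choice: the procedure is only described as "generally aligned" with the
taxonomy, and 0.9 keeps an attribute with one or two strays while
rejecting anything close to label-shuffled noise (whose expected
alignment is 0.5).  Interleaved arrangements (basal / hadrosaurid /
basal) are flagged non-diagnostic rather than patched, since a boundary
is then not meaningful.

Classification of a focal value uses interval membership first; a value
falling in the gap between the two sides is split at the boundary with
the inclusive "up to \(b\)" convention (\(\le b\) goes to the low-value
side).  This makes classification monotone in the value, which the test
suite asserts.  The per-attribute sides are tallied into a mosaic
summary; a taxon whose counts are split across both sides *straddles*
the two interval combinations — the quantitative signature of a
transitional form.

For two of the six published attributes the printed thresholds (10° and
15°) do not equal the footnote rule applied to the printed intervals (11°
and 15.5°); the published rounding or adjustment is not stated.  The
shipped fixture therefore carries the printed boundaries verbatim, and
the exact-arithmetic check is pinned only on the attribute where the rule
and the printed value agree exactly (the scapular-neck ratio, boundary
0.59).  Classification is unaffected: all six published focal values land
inside intervals, not in gaps.

## The parsimony engine

Characters are unordered (nonadditive) and equally weighted; cells are
state *sets* — a fixed state, a polymorphism (any-of semantics), or
missing, which behaves as the full state universe.  Tree length is the
Fitch count summed over characters, computed bit-parallel across
characters with state-set bitmasks; the length of an unordered character
is invariant under re-rooting, which the engine exploits by always
scoring the tree rooted on its first tip's pendant edge.

Per-character step bounds are computed directly from the cells, with
set-valued cells free to adopt any of their states:

* minimum steps \(m_i\): size of the smallest state set intersecting
  every non-missing cell, minus one (exhaustive cover search over the
  observed universe, which is at most a handful of states);
* maximum steps \(g_i\): number of constraining cells minus the largest
  achievable single-state frequency.

These feed the ensemble indices \(CI = \sum m_i / L\) and
\(RI = (\sum g_i - L)/(\sum g_i - \sum m_i)\).  All characters are
included by default; a flag excludes the characters that cannot show
homoplasy on any tree (\(g_i = m_i\)), since whether published values
include uninformative characters is often unstated — both variants are
one call apart.

**Search.**  Starting trees come from random-addition Wagner
construction: taxa are inserted in seeded random order, each on the edge
minimizing total length, ties broken uniformly.  TBR branch swapping then
bisects every edge of every held tree and reconnects every pair of
branches of the two fragments, accepting topologies within the
suboptimal bound of the best length seen, until no held tree yields a
new acceptable topology.  Bisection is applied to terminal edges too
(giving single-leaf SPR moves as a subset); this is a strict superset of
internal-edge-only TBR and can only improve the optimum found.
Duplicate topologies are recognized by canonical bipartition signatures.
The defaults mirror the published protocol's memory settings (hold 1000
trees per replicate, 10000 trees overall); replicate counts are chosen
per run.  Replicate \(r\) uses RNG stream `seed + r`, so results are
reproducible and adding replicates never changes the earlier ones —
which also makes "more replicates never lengthen the best tree" a
testable monotonicity property.

**Consensus and support.**  Strict and majority-rule consensus are
computed from bipartition counts (the majority rule keeps splits with
frequency strictly above the threshold, which guarantees pairwise
compatibility for thresholds ≥ 0.5) and rebuilt into trees from the
nested cluster hierarchy; frequencies ride along as node labels.
Bootstrap support resamples characters with replacement to the original
count, runs a reduced search per replicate (five random-addition
replicates with modest holds by default — per-replicate search depth is
a cost/precision dial, and published support values from deeper searches
are matched only qualitatively), and reports the plain percentage of
replicates whose best-tree strict consensus contains each bipartition.
Failed replicates are excluded from the denominator with a warning.

**Bremer decay** is computed from pooled suboptimal sweeps: one TBR
sweep from the MPT set accepting trees up to \(k_{\max}\) extra steps,
then for each clade of the MPT strict consensus the decay is the
smallest extra-step value at which a pooled tree lacking it exists.
Because the sweep may not enumerate every suboptimal tree, a reported
decay can only *overestimate* the truth; raising the sweep's hold
tightens it.  This trades exactness for reuse of the single search
engine, and the toy cases with enumerable tree spaces confirm exact
values there.

**Unambiguous synapomorphies.**  Rather than running accelerated and
delayed optimizations separately, the engine uses their common core: a
character change is unambiguous on a branch precisely when forcing the
branch's two ends to share a state costs extra steps, i.e.
\(\min_s\,[\mathrm{up}(v,s) + \mathrm{down}(v,s)] > L\) with the up/down
conditional costs from a two-pass dynamic program over the tree rooted
on the outgroup.  Any reconstruction-specific optimization places a
change on such a branch, so the report is exactly the set of changes
present under both ACCTRAN and DELTRAN (and every other MPR); the test
suite verifies this against brute-force enumeration of all minimum-cost
reconstructions on small trees.

## What the generators emulate — and what they do not

`gen_two_group_measurements()` draws a true value per species from its
side's Gaussian and specimen observations around it.  The defaults are a
ratio attribute of the scapular-neck kind: twenty species per side,
side means 0.48 and 0.68 with between-species sd 0.04 (five pooled sd of
separation — cleanly detached intervals, matching the regime in which
the published attributes were selected as diagnostic), one to three
specimens per species with within-species sd 0.01.  At exactly five sd
of separation roughly one species in two hundred is expected to cross
the component boundary, so end-to-end recovery is asserted as alignment
≥ 0.95 (perfect alignment is asserted in the ten-sd regime).

`evolve_characters()` evolves unordered characters down a known tree
with a per-edge change probability (to a uniformly chosen different
state) and applies a missingness mask, either independent per cell or in
per-taxon blocks that mimic specimens missing whole anatomical regions.
A per-edge change probability, rather than continuous-time rates, is
deliberate: only parsimony consumes the output, and parsimony sees
changes, not branch lengths.

Neither generator attempts morphological realism: characters are
independent, states are unordered, rates are homogeneous, and
measurement attributes are uncorrelated.  Passing recovery tests on this
synthetic structure shows the machinery is correct under the model's own
assumptions; it does not certify behavior on real matrices with
correlated characters or systematically biased missingness.

## Scale of the shipped checks

The test suite exercises the oracles at sizes where exhaustive truth is
computable: all 10,395 eight-leaf topologies for search optimality (50
seeded matrices), all 105 six-leaf topologies for the step bounds,
uniform-cost Sankoff dynamic programming on 1,000 random instances for
scoring equivalence, and brute-force enumeration of minimum
reconstructions for the synapomorphy criterion.  The mixture stage is
checked against an independent reference implementation's BIC ranking on
20 seeded datasets and a 100-run recovery study at five-sd separation.
The full 61-taxon, 346-character reproduction (best length 1004, CI
0.495, RI 0.863) is implemented end-to-end and runs whenever a
plain-text transcription of the original supplementary matrix is placed
at `inst/extdata/published_hadrosauroid_matrix.nex`; the original is distributed
only as a word-processor document, which this package deliberately does
not parse.

## Known limitations

* Pure-R search: comfortable to a few dozen taxa with desk-scale
  replicate counts; a 61-taxon, thousand-replicate protocol is hours of
  compute, not minutes.
* Bremer values are upper bounds under limited sweep effort (see above).
* Bootstrap percentages depend on per-replicate search depth; only their
  qualitative pattern is stable across depths.
* Majority-rule consensus requires thresholds ≥ 0.5; arbitrary-threshold
  compatibility resolution is out of scope.
* The NEXUS reader covers the DATA/CHARACTERS–MATRIX subset used for
  morphological matrices (SYMBOLS, MISSING, GAP, bracketed state
  groups), not the full NEXUS grammar.
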