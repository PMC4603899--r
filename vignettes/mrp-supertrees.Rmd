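---
title: "Building MRP supertrees: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building MRP supertrees: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrptree)
```

## The problem

Published phylogenies of a clade rarely share a common taxon sample: one
study resolves a handful of genera from morphology, another sequences a
different (partially overlapping) species set for one or two genes.  A
*supertree* synthesises such a corpus of rooted source trees into a single
inclusive phylogeny.  Because each source tree was inferred by its authors
with methods appropriate to its data, the synthesis works on topologies
alone.  This package implements a complete, repeatable construction
protocol — the kind used for species-level supertrees of groups such as
spiny and slipper lobsters — from raw source-tree curation through to
per-node support, with every decision logged.

## The protocol

### Curation

Raw source trees carry nomenclature noise that would fragment the taxon
set if left alone.  Curation applies four rules, in order:

1. **Synonym standardisation** (`standardize_names()`).  Every leaf label
   is mapped to its accepted name through a user-supplied synonym table
   (in practice derived from a taxonomic database such as WoRMS; here a
   local, editable CSV so runs are reproducible offline).  When two leaves
   of one tree collapse to the same accepted name they are merged; the
   retained leaf is the first in a pre-order traversal, a deterministic
   choice since no published convention exists.
2. **Higher-taxon substitution** (`substitute_higher_taxa()`).  A leaf
   labelled with a higher taxon (e.g. a family used as a placeholder) is
   replaced by a polytomy of those of its constituent species that occur
   in the *other* source trees.  Using only species found elsewhere avoids
   inflating the taxon set with names no other tree can corroborate.  A
   single constituent renames the leaf; none deletes it.
3. **Independence** (`apply_independence()`).  Two source trees are
   non-independent when they derive from identical data (same character
   types, same taxa) or when one matrix nests inside another.  Identical
   groups of size $k$ are down-weighted to $1/k$ each, so a replicated
   analysis never counts more than once; nested records lose the less
   inclusive tree, but only within a study — across studies a nesting is
   flagged for the analyst rather than removed, since true matrix identity
   cannot be verified from meta-data alone.  Removal runs before
   weighting, so a removed record takes no share of a group's weight.
4. **Overlap** (`check_overlap()`).  Supertree methods need topological
   glue: every source tree must share at least two taxa with some other
   tree, and the pairwise-overlap graph must be connected.  A disconnected
   dataset halts the pipeline (or, optionally, drops the records outside
   the largest component).

### Matrix representation with parsimony

`encode_brs()` applies Baum–Ragan coding: each nontrivial, non-root clade
of each source tree becomes one binary character — members scored 1, the
tree's other taxa 0, taxa absent from that tree `?` — and the matrix is
rooted by a hypothetical outgroup scored 0 throughout.  The root node of a
source tree yields no character: against the all-zero outgroup it would be
uninformative.  Characters inherit their record's weight, kept as an exact
rational (`1/k`) so that length comparisons during search never depend on
floating-point rounding; weights are scaled to integers by their least
common denominator only at TNT serialisation.

For a single binary source tree on $n$ taxa the matrix has $n-2$
characters and is *compatible*: its minimum parsimony length equals the
character count, with the source tree among the optima.  This property
anchors several tests.

### Parsimony search

`fitch_length()` scores a binary tree by the Fitch set-intersection pass,
with `?` carrying the full state set $\{0,1\}$; the result is invariant to
rerooting, which lets the search treat trees as effectively unrooted and
root the results on the synthetic outgroup afterwards.

`heuristic_search()` mirrors standard parsimony practice: each replicate
builds a starting tree by stepwise addition in random taxon order (greedy
best insertion), then swaps branches — SPR first, then TBR (SPR with
rerooting of the pruned subtree) — accepting the first strict improvement
until a local optimum.  Optima are pooled across replicates and the pool
is optionally expanded with equally parsimonious SPR neighbours up to
`maxtrees`.  Replicate $i$ seeds the generator with `seed + i`, so results
are reproducible and the best length is non-increasing in the replicate
count.  Library defaults (20 replicates, 1000 stored trees) are desk-scale
choices; production analyses of published matrices would raise both, and
stored-tree counts should always be read as cap-dependent.

`branch_and_bound()` provides the exact optimum for small matrices by
stepwise taxon insertion with partial-length pruning (a partial tree's
Fitch length never decreases as taxa are added), and
`exhaustive_search()` scores every unrooted topology outright; both exist
mainly to referee the heuristic.

### Consensus and MAST

With many equally parsimonious trees, `strict_consensus()` keeps exactly
the clades common to all.  The maximum agreement subtree (`mast_pair()`,
`mast_k()`) instead finds the largest leaf set on which all trees agree
completely — useful when a few unstable taxa dissolve the consensus.  The
pairwise MAST is the exact dynamic programme over node pairs; for more
than two trees the exact answer (descending-size subset search) is
exponential and is attempted only up to `exact_limit` leaves (default 8).
Above that a heuristic folds `mast_pair()` across the trees in input
order, then *verifies* that the final leaf set is a genuine agreement set
for every input — an invalid set raises an internal error rather than
returning silently.  Equal-size ties resolve to the lexicographically
smallest name set, making outputs deterministic.  Tree sets beyond a cap
are subsampled reproducibly with a logged seed, since the fold is
quadratic in the tree count.  The outgroup is dropped before any
consensus, and ingroup counts never include it.

### Node support: V and V+

Each supertree clade is scored against each source tree.  With
$A$ = clade members present in the source tree and $B$ = the source tree's
other taxa: the source tree is **irrelevant** if $|A| < 2$ or $|B| < 1$;
it **supports** the clade if $A$ is one of its clades; it **conflicts** if
one of its clades straddles $A$ (nonempty intersection and differences
both ways); otherwise it **permits** the clade (compatible, e.g. through a
polytomy).  Counting source trees in each class,

$$V = \frac{s - q}{s + q}, \qquad
  V^{+} = \frac{s + p - q}{s + p + q},$$

both in $[-1, 1]$ with $V^{+} \ge V$ whenever both are defined.  $V = 1$
means every relevant source tree contains the node; negative values flag
nodes contradicted more often than corroborated.  Two conventions are
deliberate and documented rather than inherited: counts are *unweighted*
(independence weights shape the search, not the support audit), and nodes
with $s + q = 0$ are reported as undefined (`NA`), never as 0 — a balance
of evidence and an absence of evidence are different findings.  A clade
with $s = 0$ that at least one source tree could evaluate
($q + p \ge 1$) is a **novel clade**, the classic MRP artefact; clades no
source tree can evaluate are listed separately as unevaluable.

## The synthetic generator

`synthetic_truth()` + `sample_source_trees()` + `inject_noise()` emulate
the raw material of a supertree study with known truth.  The model tree
grows under a Yule (equal-rates) process — the standard null model; at
$n = 4$ its labelled-topology distribution (balanced trees $1/9$ each,
caterpillars $1/18$ each) is exact and testable.  Source trees are
restrictions of the model tree to uniform subsamples, optionally degraded
by random rooted NNI moves (analytical error) and random polytomy
formation (soft resolution), with meta-data drawn from fixed pools.
Overlap connectivity is enforced by rejection sampling so subsamples stay
uniform conditional on acceptance.  Noise injection renames a fraction of
taxa to pseudo-synonyms and replaces a fraction with invented higher-taxon
labels defined as the smallest model-tree clade containing the replaced
taxon; the emitted synonym/taxonomy key is exactly what curation needs to
undo the damage (exactly for synonyms; up to local polytomies for
higher-taxon expansion).

The default study conditions — 20 model taxa, 10 source trees of 8–12
taxa, no perturbation — give a compact experiment in which every stage is
exercised in seconds.  What the generator does *not* emulate matters for
interpretation: real source trees are not clean restrictions of one true
tree (estimation error is correlated with data type and age), real
synonymy is not a bijection, and real taxon sampling is phylogenetically
biased rather than uniform.  Passing recovery tests therefore shows the
machinery is sound, not that MRP recovers truth on real corpora.

## Identifiability and what "recovery" means

With zero perturbation the MRP matrix is compatible, the optimum equals
the character count, and the true tree is always among the optima.  It is
*not* guaranteed to be the only optimum: whether the sampled clades pin
every branch of the model tree depends on the draw.  When they do not,
the strict consensus is under-resolved relative to the truth (never
contradicting it — support stays at $V = 1$ and no novel clades appear),
and the Robinson–Foulds distance to the model tree counts those missing
resolutions.  The end-to-end tests therefore fix the generator seed; the
acceptance script reports the measured distance for whatever seed it is
given.

## Numerical and degenerate-case choices

* All tree output is canonical (children ordered by smallest subtended
  leaf label), so identical topologies serialise to identical bytes and
  reruns of the pipeline are byte-identical.
* Search arithmetic is integer throughout (weights scaled by their least
  common denominator); no tolerance parameters exist anywhere in the
  length comparisons.
* Duplicate leaf labels are a parse-time error; only curation may merge
  leaves, explicitly and logged.
* A dataset whose trees are all stars encodes to an empty matrix, which is
  an error rather than an empty search.
* Trees reduced below two leaves by curation drop their record with a log
  entry.
* `mast_k`'s heuristic path never trusts itself: the returned leaf set is
  re-verified against every input tree.

## Limitations

* The heuristic search is a faithful open implementation of
  random-addition + SPR/TBR, not a reimplementation of any particular
  proprietary strategy; on large, conflict-rich matrices its plateau
  exploration is cap-limited, so stored MPT counts (and anything computed
  from them) are cap-dependent.
* Exact multi-tree MAST is exponential and gated to small leaf sets; the
  heuristic is verified but can undershoot the optimum.
* Rooted-tree semantics only: unrooted source trees must be rooted before
  import, and branch lengths are deliberately discarded.

## A minimal worked run

```{r example, eval = FALSE}
truth <- synthetic_truth(n_taxa = 20, k_trees = 10,
                         subsample_min = 8, subsample_max = 12, seed = 1)
ds <- sample_source_trees(truth)
res <- run_pipeline(ds, pipeline_config(out_dir = "run1", seed = 1,
                                        replicates = 5))
res$search$best_length          # equals ncol(res$matrix$mat): compatible
rf_distance(res$consensus,
            restrict_tree(truth$model_tree, res$consensus$tip.label))
head(res$support)
```
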