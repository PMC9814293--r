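---
title: "Designing DNA-encoded libraries by combinatorial enumeration and heavy-atom convolution"
author: "deldesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing DNA-encoded libraries by combinatorial enumeration and heavy-atom convolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A DNA-encoded library (DEL) is built in a few synthesis cycles: each cycle
attaches one building block (BB) to a growing molecule tethered to a DNA
tag, using a reaction compatible with the presence of DNA.  With hundreds
of usable reactions and 10^5-scale BB collections, the number of possible
*library designs* is combinatorial, and each design can hold 10^6-10^9
products.  Exhaustive enumeration of products is impossible; yet a
practitioner must decide which handful of designs to actually synthesize,
balancing library size, molecular-size distribution, and structural novelty
relative to existing screening decks.

`deldesign` implements a staged answer: (1) enumerate *designs*
exhaustively at the level of reactivity classes, never molecules; (2) size
each candidate library by integer histogram convolution of building-block
heavy-atom distributions, which is exact and cheap; (3) enumerate only
small random samples of the few surviving designs for property and
diversity profiling.

## Objects

**Functional groups (FGs).**  An FG here is not the organic-chemistry
notion but *a handle usable by a DNA-compatible reaction*, or a protected
precursor of one.  The ontology is hierarchical (amine > aliphatic amine >
primary aliphatic amine) and every FG carries a SMARTS pattern.  Leaf
resolution is per matched site: when a pattern and its descendant match the
same site only the most specific FG is kept, while two different amines on
one molecule are both retained.  The implementation resolves this by
match-count arithmetic (a parent's resolved count is its raw count minus
its direct children's counts), which is exact under the ontology contract
that every child match site is also a parent match site.  The shipped
patterns obey this contract; users adding FGs must preserve it.

**Building-block types (BBTs).**  A BBT is a canonical triple of distinct
FG ids padded with the null FG (id 0); BBs with the same FG combination
react identically and are interchangeable at design time.  The enumerated
BBT space is the set of 3-subsets of the FG list with the null treated as
an ordinary element: pairs of reactive FGs plus the null (bifunctional) and
triples of reactive FGs (trifunctional), `choose(n, 3)` combinations for
an n-FG ontology.  Monofunctional BBTs ((fg, 0, 0)) arise through BB
assignment rather than enumeration; `enumerate_bbt_space()` has an
`include_monofunctional` switch for the wider space.  Pairs of strong
electrophiles and/or strong nucleophiles are declared incompatible (class
tags expanded to pairs at load time) and every BBT containing such a pair
is pruned; pruning is pairwise only — no triple-wise rules — because
nothing in the underlying procedure requires more.

**Reactions.**  Connecting reactions consume (design FG, BB FG) and may
emit FGs (SNAr on a dichlorotriazine leaves a monochlorotriazine);
deprotections rewrite one design FG, optionally adding scaffold atoms
(cyanuric chloride capping: primary amine to dichlorotriazine).  Each
reaction carries a reaction-SMARTS `transform` used at enumeration time,
and three heavy-atom parameters: `design_side_atom_delta`,
`bb_side_atom_delta` and `scaffold_atoms`.  Splitting the atom delta per
side makes *effective heavy atoms* (atoms a BB actually contributes to the
product) well defined per BB.  The shipped values were verified by running
each transform on a worked molecule and counting product atoms, e.g.
amidation costs the acid side 1 atom (the hydroxyl), Boc removal costs 7,
and triazine capping adds 8 (the C3N3 ring plus the two chlorines that
later leave at -1 per SNAr step).  Reactions that can be pooled in one
experimental step (amidation of primary and secondary amines) share an
`enum_index`.

## Design growth

Designs grow cycle by cycle from a DNA headpiece carrying one FG.  Per
cycle, the engine branches over {no deprotection} plus every applicable
deprotection, then over every applicable (connecting reaction x BBT) pair;
exactly one BBT joins per cycle.  Chained deprotections within one cycle
are not attempted — the procedure is "a deprotection or scaffold addition
followed by a connection", and allowing chains would multiply the space
with routes of doubtful practicality.  Reaction-FG incompatibility is
checked on both sides of the DNA: a live FG on the design may veto a
reaction (on-DNA) independently of the same FG arriving on a BB (off-DNA).
A design's identity is its replay trace (headpiece, per-cycle deprotection,
reaction, BBT); growth output order is fixed (designs in list order,
reactions by id, BBTs canonical), so runs are byte-reproducible.  After
the last cycle, designs with disallowed live FGs (e.g. sulfonyl chloride)
are removed.  A configurable cap (default 10^8) aborts pathological
systems cleanly.

## libDESIGNs and convolution sizing

Designs that share topology (headpiece, cycle count) and per-cycle enum
indices — of the connection and, separately, of the deprotection or its
absence — merge into one libDESIGN whose nodes hold BBT sets.  The heavy
atoms of a product decompose exactly as

    HA(product) = headpiece_atoms + sum_j eff(bb_j) + sum_j delta_design_j

so the distribution of HA over the whole library is the discrete
convolution across cycles of the per-node effective-heavy-atom histograms,
shifted by the headpiece and design-side constants.  The convolution total
equals the product of per-node BB counts: library size and size
distribution come without enumerating one molecule.  This identity is not
an approximation; the test suite verifies, per sampled product, that the
RDKit-synthesized structure has exactly the predicted atom count.

**Size maximization.**  Production practice wants the largest library
whose product median heavy atoms stays at a target (default 29, matching a
screening-collection mean of ~25 atoms plus the 4-atom headpiece).  The
knob is a per-node heavy-atom cap: BBs above the cap are dropped.  Caps
are the right parameterization because any optimal median-constrained
selection closed under replacing a BB by a lighter one is representable by
caps.  The median is the lower median of the integer histogram (smallest
value whose cumulative count reaches half the total), and the constraint
direction is `median <= target` since BB collections skew heavy.  When the
lattice of distinct per-node sizes has at most 10^5 points the search is
exhaustive, hence exact; beyond that a coordinate descent lowers, at each
step, the cap whose single-step reduction preserves the largest library,
which is approximate and documented as such (tests bound its gap on
reference instances).  Sizing uses only the "internal" BB source,
mirroring the practice of guaranteeing library size from in-house stock;
enumeration and profiling may use all sources.

## Sampling and profiling

A selected libDESIGN is translated into a self-contained enumeration
config: per cycle, the cap-compliant BB list of every node BBT with the
transform that consumes it, plus a headpiece surrogate fragment (default
surrogates carry exactly the 4 accounted heavy atoms; the DNA itself is
not modeled).  Sampling draws provenance tuples uniformly *without
replacement* from the Cartesian product of BB lists: indices are drawn by
`sample.int` when the library size fits an integer, otherwise by rejection
on 53-bit uniforms, and decoded in mixed radix.  Products are then built
by replaying the reaction SMARTS with RDKit in one batched call.  When a
transform matches several sites, the product with the lexicographically
smallest canonical SMILES is kept and the multiplicity recorded —
regiochemistry is out of scope, determinism is not.  Transform failures
are logged; a failure rate above 5% is an error.

The default profiling sample is 10,000 compounds per library.  The
motivating behavior — 10,000-compound samples reproduce whole-library
property distributions while 1,000-compound samples drift visibly — is
reproduced in the test suite on a ~10^5-product fixture library, where
heavy-atom means from 10,000-samples sit within 3 sigma of the exact
full-library mean (finite-population corrected) and 1,000-samples show
more than twice the average drift.

Properties per compound: heavy atoms, cLogP, fraction Csp3, TPSA,
rotatable bonds (Open Babel descriptors and SMARTS counts).  Diversity
uses Open Babel FP2 fingerprints — hashed linear paths up to seven atoms,
1024 bits — as the package's path-based fingerprint; parameters are fixed
and recorded so reported distances are comparable only within a
fingerprint setting.  Two library-level measures are exposed and each
report records which one it used: the mean over all cross-set pairs of
(1 - Tanimoto), and the mean nearest-neighbor distance of a library's
compounds to a reference set.  Spread design ranks libraries greedily by
the second measure: pick the library farthest from the reference union,
add its compounds to the reference, repeat; ties break by larger library,
then id.  With no reference sets the first pick maximizes distance to the
union of the other libraries.  The conventional flagging thresholds (0.25
"adequate", 0.2 "sufficiently different") are report annotations, never
filters.

## The synthetic study system

Real DEL inputs (vendor catalogs, corporate collections, screening decks)
are proprietary, so the package generates its own, with ground truth
recorded in a manifest.  BBs are assembled from vetted FG substituent
templates on branched-alkane skeletons — branching (methyls) absorbs atoms
without adding rotatable bonds, so generated BBs pass curation filters —
and the intended BBT is recovered by annotation for 100% of generated
structures (a tested invariant).  Heavy atoms are drawn from truncated
normal distributions: the empirical shapes being emulated are unimodal
size histograms in the 5-25 atom range with the internal source skewed
heavier than the external one.  Defaults: internal monofunctional BBs mean
14 (sd 4), external mean 12 (sd 4), bifunctional/trifunctional slightly
heavier; reference decks mean 25 atoms (screening-deck-like) and 30 atoms
(prior-DEL-like).  Two scales are shipped: `small` (1 headpiece, 3
reactions, ~30 BBs over 4 BBTs) is fully checkable by brute-force
recursion; `medium` (the full default ontology, ~20 reactions, ~370 BBs
over 18 BBTs, two sources, two reference decks) exercises every stage
end-to-end, including the triazine and SNAr/benzimidazole routes.

What the generator does *not* emulate — and hence what green tests do not
show about real data: real catalogs' scaffold diversity and correlated FG
co-occurrence, stereochemistry, tautomerism, protonation equilibria,
reagent quality, and the long tails of real size distributions.  The
combinatorial machinery is agnostic to these; the chemistry-facing steps
(standardization, annotation) would meet harder inputs in production use.

## Numerical and degenerate-input choices

* Lower median on integer histograms: deterministic, no interpolation.
* Exact cap search below 10^5 lattice points; greedy coordinate descent
  above, preferring the largest surviving library at each step and
  stopping at the first feasible point.
* Duplicate BBs after standardization: deduplicated keeping the
  lexicographically first id, with a merge record (actionable curation
  reports need the mapping).
* A BB whose FGs exceed three, carry an incompatible pair, or vanish
  entirely is rejected with a named reason; all failing filter rules are
  listed, the first is primary.
* Empty node BB lists make convolution return an empty flagged histogram
  and make config writing an error naming the cycle.
* All randomness flows from one integer seed; sub-seeds are derived by a
  fixed linear-congruential step, and every generator and the sampler are
  byte-reproducible under it.

## Problem sizes used by the checks

The bundled verification uses the small system for oracle equality
(brute-force recursion, exhaustive convolution and cap lattices), the
medium system for end-to-end and scope-nesting checks, a ~10^5-product
fixture for the sampling-fidelity study, and 1,000-compound X-Sets over
the top 3 libraries in the reproduction script — sizes chosen so a
complete from-scratch run stays comfortable on one CPU while every claim
remains at the scale where it is provable.

## Known limitations

* FG incompatibility is pairwise; if a production rule set needs
  triple-wise exclusions it cannot be expressed yet.
* The 43-FG production ontology and its incompatibility tables are not
  public; the shipped ontology is a representative ~25-FG subset and the
  ontology file format accepts a full replacement.
* Hierarchy resolution relies on the child-implies-parent site contract
  rather than explicit atom-map bookkeeping.
* FP2 is a stand-in for proprietary path fingerprints; absolute distance
  values are fingerprint-specific.
* The greedy cap descent is approximate on very large lattices.
* Site-ambiguous transforms pick a deterministic representative rather
  than enumerating regiochemistry.
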