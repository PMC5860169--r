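---
title: "Genome-distance phylogeny and classification of prokaryotic viruses: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-distance phylogeny and classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes, which
choices were open, and what the bundled simulations do and do not
demonstrate.

## The distance model

The unit of information is the high-scoring segment pair (HSP): one local
alignment between two genomes with coordinates, score, identities and an
e-value. HSPs come from the built-in aligner or from an external tool's
12-column tabular output; the distance method itself is agnostic to the
aligner behind the HSP list.

**Built-in aligner.** Ungapped seed-and-extend: every exact word match
(word length 11 for DNA, 3 for proteins) is extended in both directions
under an X-drop rule. Nucleotide scoring is +2/−3, protein scoring
BLOSUM62; seeds on the reverse strand are found on the reverse complement
and reported in forward coordinates with strand "−". In amino-acid mode
every protein of one genome is aligned against every protein of the other,
with coordinates in per-protein space. E-values follow the Karlin–Altschul
form `K·m·n·exp(−λ·S)` with `λ` solved by bisection (to 1e-9) from the
scoring scheme and background frequencies (uniform for DNA,
Robinson–Robinson for proteins) and `K` fixed at 0.1. These e-values are an
internally consistent filter quantity — their relative ordering is what the
e-value threshold acts on — and are not claimed to match any external
tool's statistics. Gapped alignments enter only via the tabular reader.

**Paralogy filters.** Two algorithms reduce the HSP list before distances
are computed:

* *Greedy trimming*: HSPs are accepted in decreasing raw score (ties:
  longer first, then input order). A candidate overlapping
  already-accepted matches is shortened by `t = max(overlap_q, overlap_s)`
  columns. The removal is split between the candidate's two ends: the side
  with the larger overlap contributes its contiguous covered run at the
  left end, the remainder comes off the right end, and the removal is
  mirrored strand-aware onto the other genome. This shortening repeats
  until the candidate no longer overlaps occupied positions — iterating to
  that fixpoint is what makes the filter idempotent (a single pass is not,
  when an accepted interval lies strictly inside a later candidate's
  subject interval). Identities are scaled proportionally
  (`id·len'/len`) and kept real-valued to avoid rounding-order artifacts.
  Candidates trimmed to nothing are dropped.
* *Coverage*: per-position interval unions; matched positions are counted
  once, and identities accrue per HSP in score order in proportion to its
  newly covered query positions.

The exact trimming rule (which end loses columns, how ties break) is this
package's normative definition; the original implementations are cited by
name in the literature but not restated there, so bit-for-bit parity with
them is explicitly not claimed. The position-level brute force in the test
suite defines correctness.

**Formulas.** With `A` = matched positions summed over both genomes, `C` =
retained columns, `I` = retained identities:
`d0 = 1 − A/(L_A+L_B)`, `d4 = 1 − I/C` (1 when `C = 0`),
`d6 = 1 − 2I/(L_A+L_B)`, clamped to [0, 1]. `d0` sees gene content, `d4`
sequence identity only — which makes it robust to incomplete genomes, since
missing sequence removes columns and matched positions in equal measure —
and `d6` both. Each genome pair is scored in both search directions and the
two direction distances averaged, which enforces symmetry regardless of
aligner asymmetries. The remaining seven slots of the ten-formula grid are
registry placeholders (min/max-length denominator variants, off by
default): their originals are defined in the earlier genome-distance
literature, not here, and inventing them silently would be worse than
stubbing them visibly.

**Pseudo-bootstrap.** Replicate `r` of a pair resamples each direction's
retained HSP list with replacement (same count) and recomputes the formula
from the resampled summary *without re-filtering* — replicates must reflect
the retained-HSP composition the point estimate used. Resampling happens
after filtering for the same reason. The RNG stream is keyed by (seed,
unordered pair, replicate index), so a matrix is reproducible regardless of
the order in which pairs are computed. For `d6`/`d0` the replicate summary
adds duplicated HSPs' columns and identities while matched positions are
union-based; for the coverage algorithm the per-position accumulation is
re-run on the multiset.

## Trees and taxon support

Neighbour-joining (via ape, negative branch estimates clamped to 0) is the
built-in tree method; distance matrices and trees are exchanged in relaxed
PHYLIP and Newick, so an external balanced-minimum-evolution tool can be
substituted by the user without touching the rest of the pipeline. Trees
are midpoint-rooted: the root bisects the longest leaf-to-leaf path, with
ties broken by the lexicographically smallest leaf pair and the degenerate
all-zero-lengths case rooted on the pendant edge of the smallest leaf.
Branch support is the rounded percentage of replicate trees whose unrooted
bipartition set contains the branch's bipartition; trivial bipartitions
(and hence the root) count 100 by convention, and rounding to integer
percent happens exactly once, there.

A taxon is monophyletic when its members form a clade. Otherwise a
minimum-change reconstruction of the binary membership character decides
between paraphyly (some most-parsimonious reconstruction makes the taxon's
MRCA a member; computed exactly with a two-pass Sankoff dynamic program)
and polyphyly. The signed support of a non-trivial taxon is its clade's
branch support if monophyletic, else minus the maximum support among clades
that cross it (share members and non-members and miss members). Conflict is
assessed against clades of the *rooted* tree — the natural reading of
support "in the rooted phylogeny" — and a non-monophyletic taxon crossed by
no clade (possible in unresolved regions) scores 0. The overall taxon
support at a rank is the signed sum over the absolute sum (0 if the
denominator is 0), hence in [−1, 1].

## Clustering

Threshold clustering links pairs at distance ≤ T and merges, from
singletons, the cluster pair with the highest linked fraction
`f = links/(|P||Q|)` subject to `f ≥ F` and at least one link; ties prefer
the smallest minimum inter-cluster distance, then the smallest labels.
`F = 0` reproduces connected components, `F = 1` complete-linkage cliques;
the default `F = 0.5` is the value reported to give the most consistent
clusterings in earlier genome-distance work. Because the agreement index is
piecewise constant in T, the optimiser scans the midpoints between
consecutive distinct off-diagonal distances plus one candidate below the
minimum and one above the maximum — this covers every attainable
clustering, unlike a fixed grid. Ties take the smallest T. When all
distances are zero the below-minimum candidate is (slightly) negative so
that the all-singletons clustering remains attainable.

The agreement index ("MRI") is realised as the Hubert–Arabie adjusted Rand
index: the cited index is constrained to equal 1 exactly on identical
partitions and to fall with disagreement, ARI satisfies both and is the
field's standard chance-corrected choice; whether the original is
numerically identical everywhere cannot be settled from the description
alone, and the identity-partition property is the one the acceptance
target asserts. Degenerate contingency tables (both partitions trivial)
return 1, which only occurs for identical partitions.

Per-rank runs drop genomes with an empty value at that rank before
optimising (e.g. species without a genus assignment when clustering at the
genus rank). Published per-rank thresholds for the optimal settings ship as
defaults for fixed-threshold classification of new genomes.

## Settings grid and selection

The grid enumerates sequence type × e-value filter {10, 1, 1e-1, 1e-2,
1e-3, 1e-8} × algorithm × formula in deterministic order: 72 points with
the three normative formulas, 240 with the full registry. Grid evaluation
computes HSPs once per sequence type at the most permissive e-value and
re-filters per point, and reuses resampled summaries across formulas (the
resample is formula-independent), which keeps the 72-point grid tractable
at desk scale. Selection is two-step and per sequence type: Pareto
frontier on the three per-rank taxon-support objectives, then, within the
survivors, on the three per-rank MRI objectives. The order matters and is
deliberate: phylogenetic support is the primary criterion, agreement the
secondary. Host specificity is `m/N` per cluster over genomes with a
non-empty host annotation; modal ties report the count (the index is
unaffected) and the lexicographically smallest modal host name, and the
genus rank compares first name tokens only.

## The simulator, and what the tests do and do not show

`simulate_dataset()` evolves a uniform-random root genome along a known
tree: substitutions are Poisson(rate × branch length × length) random site
replacements with one of the three other bases (a Jukes–Cantor-like model,
no rate heterogeneity, no codon structure), with optional block deletions
and inversions (geometric block lengths, mean 200 nt) and truncation of
designated leaves to emulate incomplete genome sequences. Branch lengths
are `0.002 + Exp(mean 0.018)` in substitutions/site — the floor guarantees
distinct taxa so that topology recovery is well-posed. Taxonomy ranks are
assigned to consecutive leaf blocks (which coincide with clades on
balanced trees and on the hand-built fixtures); hosts share a genus token
within a genus block. Proteomes are fixed-length translated blocks of the
genome (300 aa) — this exercises the amino-acid pipeline without gene
finding.

The defaults are the simulation's study conditions, chosen once: 20-kb
genomes (small-phage scale), divergences up to ~10–15% across an 8-taxon
tree (strong but unsaturated signal for an 11-mer seed aligner).
Real phage data differ in ways the simulator deliberately omits — mosaicism
and horizontal transfer, compositional bias, rate heterogeneity,
annotation errors. Passing tests therefore demonstrate that the
implementation computes its definitions correctly and that the method
recovers structure under its own model's assumptions; they are not
evidence about classification accuracy on real viral genomes.

Problem sizes used by the test and acceptance suites (the package's own
choice of desk scale): exhaustive oracles at ≤ 6 HSPs / ≤ 8 taxa /
partitions of ≤ 6 elements; property suites on 2–12 genomes of 2–5 kb; the
stochastic end-to-end experiment runs 20 seeded simulations of 8 × 20 kb
genomes and requires ≥ 90% exact unrooted-topology recovery, plus full
agreement (MRI = 1) on a hand-built three-species fixture with
well-separated within/between rates.

## Numerical choices and degenerate inputs

* PHYLIP matrices use a relaxed dialect (full-length labels); write/read
  round-trips are exact to 1e-9, asymmetry beyond 1e-9 is rejected.
* Newick support values are integer node labels; malformed parentheses are
  reported with a character offset.
* Distance matrices must be symmetric with a zero diagonal and entries in
  [0, 1]; identical genomes are at distance 0 with all replicates 0.
* Fewer than three taxa yield the trivial two-leaf tree with the distance
  split evenly; an all-zero matrix yields all-zero branch lengths.
* λ-bisection brackets away from the trivial root at 0 and requires a
  negative expected score.
* Duplicate genomes are collapsed by MD5 of the concatenated upper-cased
  nucleotide sequence, keeping the version with most proteins (ties: the
  smallest id).
* Trimming of gapped external HSPs treats interval positions and columns
  interchangeably (exact for the built-in ungapped aligner, approximate
  for gapped hits).

## Known limitations

The built-in aligner is ungapped and unoptimised for speed beyond hashing
and diagonal pruning; for large studies an external aligner's tabular
output is the intended input. NJ is the built-in tree method — balanced
minimum evolution with SPR refinement typically yields slightly better
topologies and can be slotted in via Newick round-tripping. The formula
registry implements the three normative formulas only. Host-name handling
validates format but performs no nomenclature reconciliation.
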