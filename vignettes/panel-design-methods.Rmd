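---
title: "Designing degenerate primer panels by greedy agglomeration"
author: "PrimerPanels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing degenerate primer panels by greedy agglomeration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PrimerPanels)
```

## The problem

A degenerate primer written in IUPAC ambiguity codes stands for a pool
of plain oligonucleotides; its *degeneracy* is the pool size. Pools
beyond a few hundred variants dilute each individual primer below
useful concentration, so practical designs cap both degeneracy and the
number of ambiguous positions. For a marker gene as diverse as the
family-B DNA polymerase of giant viruses, no single pair under such
caps can bind the whole family: the sequence space must be *covered*
by many pairs, each responsible for a cluster of mutually similar
genes. The design question is therefore a greedy set cover: how few
clusters — each admitting a constrained degenerate pair on its
consensus — are needed so that every collection member is amplified by
at least one pair?

## The design loop

`designPanel()` implements an abundance-seeded, similarity-guided
agglomeration over a `TargetCollection` (CDS sequences + protein
master alignment + abundance weights + outgroup flags):

1. **Seeding.** The most abundant remaining sequence seeds a cluster
   (ties broken by id, so reruns are reproducible). Abundance here
   means mapped reads divided by gene length; when unknown, every
   weight is 1 and seeding falls back to id order.
2. **Guide order.** Remaining sequences are offered in ascending
   protein p-distance to the seed — the fraction of mismatched
   residues over mutually non-gap alignment columns — with ties broken
   by descending abundance, then id. Pairs sharing no non-gap column
   get distance 1.
3. **Consensus and candidate test.** The cluster's nucleotide rows
   (codon-threaded from the protein alignment, see below) are
   collapsed column-wise to the minimal IUPAC code covering the
   observed bases; all-gap columns are dropped and a column map
   retained. `enumerateCandidates()` then searches the consensus for
   a pair satisfying every constraint. A candidate sequence joins the
   cluster only if at least one pair survives its inclusion;
   otherwise it is rejected but remains in the collection and may
   seed or join a later cluster. Each remaining sequence is tested
   once per cluster, in guide order; the consensus a later candidate
   sees includes all earlier acceptances.
4. **Emission and sweep.** The lowest-penalty pair of the final
   successful design is stored as `PP1`, `PP2`, ... Cluster members
   and every other remaining sequence the pair amplifies at zero
   mismatches (with a product-size-valid amplicon; set
   `sweepRequireProduct = FALSE` for a sites-only sweep) are removed.
   The loop repeats until the collection is empty. A seed whose own
   consensus admits no pair is recorded as *undesignable* — reported,
   never silently dropped.

Because removal is tied to strict amplification, the panel's
zero-mismatch coverage of the non-undesignable collection is exactly
100% *by construction*; the test suite asserts this as an invariant
rather than measuring it as an outcome.

### Codon threading and one deliberate deviation

Cluster consensus sequences are built on nucleotide alignments derived
by *threading* each CDS through the protein master alignment: every
residue becomes its source codon, every gap `---`. Threading validates
that each CDS translates residue-for-residue to its aligned protein
(one terminal stop codon is tolerated; `X` is a wildcard) and fails
loudly otherwise. The original protocol this package systematizes
realigned every cluster with an external aligner at each agglomeration
step; `designPanel()` instead subsets one master alignment computed up
front. This trades per-cluster realignment fidelity for determinism,
speed and independence from an external aligner; whenever the master
alignment is consistent with the per-cluster alignments the results
coincide, and the deviation is confined to gap placement in indel-rich
regions.

## Primer constraints and their defaults

`primerConstraints()` collects the tunables; defaults encode a
protocol for a highly diverse protein-coding marker:

| parameter | default | meaning |
|---|---|---|
| `tmOpt`, `tmMin`, `tmMax` | 52, 47, 57 °C | melting-temperature optimum and acceptance band |
| `lenOpt`, `lenMin`, `lenMax` | 20, 18, 27 nt | primer length optimum and band |
| `maxDegeneratePositions` | 8 | ambiguous positions per primer |
| `maxDegeneracy` | 256 | variants per primer pool |
| `targetWindow` | [105, 214) | region every product must contain |
| `windowUnits` | `"nt"` | window coordinate units (see below) |
| `productMin`, `productMax` | 200, 600 nt | product-size bounds |
| `pairTmMaxDiff` | 5 °C | max midpoint-Tm difference within a pair |
| `saltMolar`, `oligoMolar` | 0.05 M, 50 nM | Tm model conditions |

Melting temperatures use nearest-neighbor thermodynamics (SantaLucia
1998 unified ΔH/ΔS, entropy salt correction
ΔS' = ΔS + 0.368·(N−1)·ln[Na⁺], Tm = ΔH/(ΔS' + R·ln(C/4)) − 273.15).
A degenerate primer's Tm is the exact min–max range over its full
expansion — cheap under the 256-variant cap — and a primer passes when
that range intersects the acceptance band. Candidate pairs are ranked
by `|len−lenOpt|` summed over both primers plus `|midTm−tmOpt|` summed
over both, ties broken by coordinates, so ranking is deterministic.
Auxiliary primer-design heuristics found in general-purpose tools
(hairpin and self-dimer thermodynamics, GC clamps) are deliberately
not part of the acceptance predicate: the constraint set above *is*
the method. A coarse self-complementarity flag
(`screenSelfStructure()`) is available as an optional post-filter, off
by default.

**Window units.** Whether a published "alignment position" window
refers to nucleotide or amino-acid columns is often ambiguous — for
this package's default (105–214) both readings are defensible. The
default treats it as consensus nucleotide columns (`windowUnits =
"nt"`); `"aa"` multiplies by three. Note the window is interpreted on
each cluster's consensus after all-gap-column removal, so in indel-rich
alignments the window drifts with the cluster; the column map returned
by `alignmentConsensus()` makes the correspondence explicit.

## In silico PCR

`findSites()` / `amplifyPair()` / `panelCoverage()` implement
degenerate-primer matching with intersection semantics: a primer base
matches a template base when their IUPAC sets share a member (for
plain templates this is ordinary degenerate matching). The mismatch
allowance is `floor(fraction × primer length)` — 0 reproduces the
strict sweep of the design loop, 0.10 the conventional relaxed screen.
No indels are modelled in primer binding, matching the behavior of the
standard screening tools; overhanging (partially off-template) sites
are excluded; overlapping forward/reverse sites never form a product;
both template strands are searched. Coverage is monotone in the
mismatch fraction, which the tests assert. Matching is delegated to
`Biostrings::matchPattern(fixed = FALSE)`, whose ambiguity semantics
are exactly the intersection rule; the test suite checks it against an
independent brute-force oracle (expand the primer, Hamming-scan every
offset) on a thousand randomized instances.

## The synthetic family generator

Real reference collections for this kind of assay mix curated genomes
with metagenome-assembled genes; neither is redistributable here, and
desk-scale validation wants known ground truth anyway.
`simulateFamily()` emulates the *structure* such collections exhibit:

* one ancestral CDS of sense codons; per-clade consensi derived by
  substitution at rate `pVarBetween` (default 0.15) outside conserved
  windows and `pCons` (default 0.01) inside; members derived from
  their clade consensus at `pVarWithin` (default 0.02) / `pCons`;
* substitutions are codon-aware — draws creating stop codons are
  redrawn — so every simulated CDS translates cleanly and threading
  preconditions always hold;
* one conserved 40-codon window (codons 35–75 by default) plays the
  role of the conserved core the target window sits in;
* abundances are log-normal (meanlog 0, sdlog 1.5), mimicking the
  heavy-tailed read-recruitment weights of environmental gene
  collections;
* optional outgroup sequences are distant mutants of the ancestor
  (rate 0.3 everywhere), exercising `pruneOutgroupOnlyPairs()` — the
  rule that drops a pair whose strict amplification set is non-empty
  and entirely outgroup, without renumbering survivors.

What the generator does *not* emulate: indels (the trivial columnwise
alignment is therefore exact — deliberate, since alignment building is
an input, not part of this method), rate heterogeneity across sites
beyond the window dichotomy, codon-usage bias, and sequencing error.
Passing tests on simulated families therefore validate the algorithmic
machinery — constraint satisfaction, set-cover bookkeeping,
determinism, coverage invariants — not robustness to alignment error
in real data.

`simulateIncompatibleClades()` is a separate deterministic
construction for cluster-recovery tests: each clade gets a base-4
digit pair indexing per-position base patterns (a permutation of
A/C/G/T per position, stop-codon-free), so any two clades differ at
*every* position of the forward or of the reverse half. A merged
consensus then exceeds the degenerate-position cap in every candidate
window, and no primer can cross clades at zero mismatches — the
designed panel must contain exactly one pair per clade, which the
tests assert for k ∈ {1, 2, 5, 10}. A stochastic divergence model
cannot guarantee this; the construction does.

## Numerical and edge-case choices

* IUPAC algebra runs on 4-bit base masks; degeneracy products are
  computed in log space and rounded (exact below the 2¹⁶ ceiling the
  caps imply).
* Ambiguity in *templates* is honored by the same intersection rule
  (a member `N` forces a consensus `N`, preserving the
  consensus-covers-members invariant).
* Gaps are illegal inside primers; in consensus building gaps are
  ignored unless a column is all-gap, in which case it is dropped and
  recorded in the column map.
* All orderings (seeding, guide order, tie-breaks) use C-locale radix
  sorting, making results independent of platform locale and of input
  record order; two runs on the same inputs are byte-identical, which
  an end-to-end test verifies.
* Problem sizes in the test suite: the study-scale check designs a
  panel over 200 sequences in 12 clades of 400-codon genes (one
  conserved 120-nt core, log-normal abundances, fixed seed); oracle
  checks use 1000 randomized site-finding instances and 500 threading
  fixtures; cluster recovery uses k up to 10. These sizes keep the
  whole suite within a few minutes while still exercising every code
  path at realistic diversity.

## Known limitations

* Primer–template binding is sequence-combinatorial, not
  thermodynamic: no ΔG of mispriming, no 3'-end weighting (a config
  flag can forbid a degenerate 3' terminus), no amplification
  efficiency — panel PCR of this kind is presence/absence, not
  quantitative.
* The master-alignment subsetting deviation above means indel-rich
  families may cluster slightly differently than under per-step
  realignment.
* `enumerateCandidates()` is exhaustive within the window/length
  bands; for consensus sequences much longer than a few kilobases the
  candidate space grows quadratically and the designer, while still
  correct, slows accordingly.
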