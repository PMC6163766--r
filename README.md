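# PrimerPanels

Degenerate PCR primers let one oligonucleotide pool bind a family of
related sequences, but for highly diverse protein-coding marker genes —
the *polB* genes of giant viruses being the motivating case — no single
degenerate pair can span the whole family: the consensus of distant
clades degenerates past any usable bound. **PrimerPanels** takes the
opposite route: it designs a *panel* of degenerate primer pairs that
jointly amplify an entire collection of homologous coding sequences,
in silico, by construction. It is aimed at people building multi-pair
meta-barcoding assays from reference-plus-metagenome gene collections.

## The algorithm

Inputs are a collection of CDS sequences, a protein multiple alignment
covering them, and optional per-sequence abundance weights (mapped
reads / gene length) and outgroup flags. The design loop is a greedy,
abundance-seeded, similarity-guided agglomeration:

1. **Seed** — pick the most abundant remaining sequence.
2. **Grow** — offer every other remaining sequence in order of protein
   p-distance to the seed. A candidate joins the cluster if the
   cluster's codon-threaded nucleotide alignment, collapsed to an
   IUPAC consensus, still admits at least one primer pair under the
   constraints; otherwise it is rejected (and stays in the
   collection).
3. **Store** — the best pair of the final successful design becomes
   `PPn`. Constraints: melting temperature optimum 52 °C (band
   47–57 °C, nearest-neighbor thermodynamics over the full expansion
   of each degenerate primer), length optimum 20 nt (18–27), at most 8
   degenerate positions and degeneracy ≤ 256 per primer, and a product
   of 200–600 nt that fully contains the target window (consensus
   positions 105–214 by default).
4. **Sweep** — remove the cluster members *and* every other remaining
   sequence the pair amplifies at zero mismatches (valid product
   required). Repeat from 1 until the collection is empty.

Every target outside the (reported) undesignable set is therefore
amplified by at least one pair at zero mismatches — coverage is an
invariant of the construction, not an aspiration. Around the designer
the package provides degenerate in silico PCR with a mismatch-percent
tolerance, specificity screening against decoy sequences, per-sample
genotype censuses, outgroup-only pair pruning, abundance-weighted
coverage, and a codon-aware synthetic gene-family simulator used as
the test substrate.

## Worked example

```r
library(PrimerPanels)

# a synthetic family: 3 clades, 18 sequences, 150-codon genes
fam   <- simulateFamily(nClades = 3, nSequences = 18, geneLen = 150, seed = 5)
panel <- designPanel(fam$collection)
panel
#> PrimerPanel with 1 primer pairs
#>   covered targets (0-mismatch): 18; undesignable: 0
#>   degeneracy: fwd 36-36, rev 96-96; product 310-310 nt

panelPairs(panel)[, c("pair_id", "fwd_seq", "rev_seq", "product_len")]
#>   pair_id               fwd_seq              rev_seq product_len
#> 1     PP1 TBKTCTCGTAAMCAGBCTGAG TAGGKTTADYCGCAYTWCGY         310

abundanceWeightedCoverage(panel, fam$collection)
#> [1] 1
```

At this family's default divergence the clades still share enough of
the conserved core for a single degenerate pair (degeneracy 36
forward, 96 reverse — both under the 256 cap) to cover all 18
targets: the greedy sweep removed everything after one iteration. On
a collection of mutually incompatible clades the cover must split —
one pair per clade:

```r
ic    <- simulateIncompatibleClades(5, membersPerClade = 3, seed = 2)
panel <- designPanel(ic$collection)
panel
#> PrimerPanel with 5 primer pairs
#>   covered targets (0-mismatch): 15; undesignable: 0
#>   degeneracy: fwd 1-1, rev 1-1; product 266-320 nt
```

`panelPairs()` gives the primer table (IUPAC sequences, 0-based
consensus coordinates, per-primer Tm range over expansions, degeneracy
counts, penalty); `designLog()` records each iteration's seed,
accepted and rejected members, and sweep. `attachOverhangs()` prepends
constant 5' adapters for synthesis. A thin command-line front end with
`simulate` / `design` / `amplify` subcommands is in
`inst/scripts/primerpanel.R`.

(The primer sequences shown above are representative output for that
seed; rerunning the snippet reproduces them exactly — the whole
pipeline is deterministic given the seed.)

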