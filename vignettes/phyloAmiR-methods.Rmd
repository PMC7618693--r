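---
title: "Phylogeny-guided multi-target amiRNA design: models and methods"
author: "phyloAmiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-guided multi-target amiRNA design: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plant gene families are rife with functional redundancy: knocking out a
single transporter gene often produces no phenotype because close paralogs
cover for it. Artificial microRNAs (amiRNAs) offer a way out — a 21-nt
guide engineered into an endogenous miRNA precursor can silence several
transcripts at once, provided those transcripts share a sufficiently
complementary target site. The catch is choosing *which* subsets of a
family to co-target and *which* 21-mers to use, at the scale of hundreds of
families, while keeping each guide effective, specific, and synthesizable
as part of a pooled oligo library.

phyloAmiR implements a phylogeny-guided answer. The gene tree of each
family organizes paralogs by relatedness, so each internal node delimits a
subfamily of genes that plausibly share function. The design walks those
nodes, derives candidate guides from conserved coding-sequence windows,
scores them with a duplex hybridization-energy model, and fills a fixed
per-node budget top-down so that effort concentrates on coherent clades
rather than arbitrary gene subsets.

## Candidate generation

For a subfamily at an internal node, every 21-nt window of every member CDS
is reverse-complemented into a candidate guide; the guide's 5'-terminal
base is then forced to T (the canonical 5'U of plant miRNAs, which biases
AGO1 loading), recorded implicitly as an engineered mismatch at position 1
when the source window did not already end in A. Window-derived candidates
guarantee at least one near-perfect target site; the package deliberately
performs no free sequence optimization beyond the position-1 edit.
Candidates with GC content outside 30–70% or a homopolymer run of six or
more bases are discarded, as are candidates with any admissible hit at or
above the energy-fraction threshold against a user-supplied background
transcriptome (when no background is given, off-target screening is
skipped with a prominent warning). Node-phase generation is attempted only
for subfamilies of 2–11 genes; larger subfamilies are skipped and logged —
guides broad enough to cover them tend to be unachievable and the node
budget is better spent deeper in the tree.

## The duplex energy model

Guide efficacy is judged by the *energy fraction*
$$
\Omega_{\text{site}} \;=\; \frac{\Delta G(\text{guide},\text{site})}
                                {\Delta G(\text{guide},\text{perfect
                                complement})},
$$
clipped to [0, 1], so 1 means a perfect duplex and the default threshold
0.75 admits sites whose predicted pairing retains at least three quarters
of the perfect-match stability. Rather than a full secondary-structure
engine, the package uses a transparent nearest-neighbor model:
$\Delta G = \Delta G_{\text{init}} + \sum \text{stacks} + \text{penalties}$,
where stacking free energies for the 16 Watson–Crick dinucleotide stacks
are published RNA/RNA values at 37&nbsp;°C (Xia et al. 1998, as tabulated
in the Turner 2004 parameter set; shipped as a data table, never
hard-coded), a stack contributes only when both of its positions are
Watson–Crick paired, and flat penalties are added per internal mismatch
(0.25 kcal/mol) and per G:U wobble (0.10 kcal/mol). With these defaults a
single internal mismatch costs roughly 10–12% of a typical perfect-match
energy (the two lost stacks dominate; the flat penalty only separates
mismatches from wobbles), so the 0.75 threshold tolerates about two
mismatches — the intended behavior. Dangling ends and terminal-mismatch
corrections are second-order relative to this threshold and are omitted.
All constants are user-overridable.

Energy alone does not guarantee silencing: the mismatch *pattern* matters.
A best site is *admissible* when, counting 1-based from the guide 5' end,
positions 10–11 (the cleavage site) carry no mismatch or wobble, positions
2–9 (the seed-proximal pairing region) carry at most one mismatch,
positions 12–21 at most three, and the weighted total (a G:U counts 0.5,
summed and rounded up) is at most four. These bounds live in the
configuration, not in code. A gene is an *effective target* of a guide
when its best sense-strand window (ties broken toward the smallest start
coordinate) is admissible and at or above the threshold. Only the sense
strand is scanned: amiRNAs silence mRNA.

## Selection

Candidates at a node keep only those with between 2 and 8 effective
targets; two is the point of multi-targeting, and eight is the design
cut-off at the upper end of the observed target range (very broad guides
are, in practice, low-quality compromises). Node-phase effective targets
are counted within the origin subfamily; family-wide target sets belong to
the MRCA phase below. Candidates are ranked by target count, then by score
$$
s \;=\; w_f \cdot \overline{\Omega}_{\text{targets}}
      \;-\; w_o \cdot n_{\text{off}}
      \;-\; w_c \cdot \lvert \text{GC} - 0.5 \rvert,
$$
with unit default weights, then lexicographically by sequence so the
ordering is fully deterministic.

Selection proceeds root-to-leaves (pre-order; children in stable node-ID
order, itself a pure function of topology and leaf labels via canonical
post-order numbering) admitting ranked candidates until a node holds
$x = 8$ guides. A candidate is admitted if (a) it differs by at least
$m = 2$ substitutions from every guide already chosen at the node or any
ancestor, or (b) it fails (a) but strictly out-scores every such similar
pick. Rule (b) follows the literal "added if better" reading; a
`replace_similar` switch implements the alternative reading in which the
similar picks are displaced, and `rule_b = FALSE` disables the exception
entirely.

Nodes still under budget after the node phase are topped up by an MRCA
phase: candidates are regenerated family-wide with a minimum of two
effective targets, each ascribed to the most recent common ancestor of its
target set, and admitted under the same rules — but only when the
monophyletic clusters of its targets (maximal blocks that are exact
subtree leaf sets; the coarsest such partition is unique because clades
are laminar) are pairwise within 3 internal nodes of each other.
Leaf-to-leaf distance counts every internal node on the connecting path
including the MRCA, so siblings are at distance 1 — the smallest sensible
positive value; this convention is isolated behind one function so it can
be flipped. The distance cap keeps MRCA-phase guides from pairing genes so
distantly related that shared function is implausible.

Two additional global rules keep the library usable as a pooled,
sequencing-verified resource. First, a mature sequence is selected at most
once across the entire run: the 21-mer is the member's identity in
downstream amplicon counting, and duplicates would make reads permanently
ambiguous. Second, a candidate is rejected when its 21-mer (in either
orientation) would occur inside an already-chosen member's assembled
oligo, or vice versa — without this, overlapping windows from the same
conserved region produce members whose reads cannot be told apart (the
forced 5' T makes every star arm end in A, so such collisions at arm/flank
junctions are systematic, not rare). Both rules are configuration-visible
and on by default.

After selection, matures found in a user-supplied blacklist (e.g. guides
already present in an earlier library) are removed.

## Assembly and restriction screening

Each selected guide is paired with a star (passenger) strand — by default
the plain reverse complement; star mismatch positions can be specified —
and both arms are substituted into a precursor backbone template carrying
`{MATURE}` and `{STAR}` placeholders. The default template is a synthetic
stand-in for the miR159a scaffold: the true arm positions, loop, and star
mismatch pattern are vendor/supplementary data, so the packaged default is
a placeholder (flagged as such) and real deployments should supply their
own template in the configuration. Class-specific forward/reverse adaptors
are attached so that each of the eight functional sub-libraries (CP, APC,
MFS, DMT, MATE, ABC, PA, UF) can be amplified exclusively from the pooled
synthesis; the adaptor table is validated at load so no adaptor is a
substring of another class's adaptor or of the backbone.

The full concatenated oligo — adaptors, backbone, both arms — is screened
for Golden Gate BsaI recognition sites (GGTCTC and its reverse complement
GAGACC, both held in configuration with reverse complements added
automatically): an internal site would be cut during one-step cloning.
Entries carrying a site anywhere in the oligo are removed and logged.
Cloning-flank BsaI sites needed for Golden Gate are assumed to live
outside the modeled oligo and are not generated. An optional back-fill
pass (`backfill = TRUE`, default off since the removal rate is small)
re-opens selection for affected families with the removed matures
excluded.

## Sequencing QC

To verify that a synthesized and cloned library actually contains its
members at usable abundance, amplicon reads are assigned to members by
exact containment of the member's identifying 21-mer (the antisense arm by
default) in either orientation; reads matching zero or two-plus members
are counted as unassigned. Exact matching is appropriate because
amplicons are short and the identifying 21-mer is designed unique (see
the identifiability rule above); a Hamming-distance-1 rescue exists behind
a flag for error-prone data. Quality values are ignored — this is
counting, not variant calling.

*Coverage* is the percentage of members detected with at least one read.
*Skew* summarizes unevenness as the adjusted Fisher–Pearson sample
skewness of per-member read fractions; the statistic is scale-free, zero
for a perfectly uniform pool (the zero-variance case is defined as exactly
0), and positive when a minority of members soak up reads. There is no
community-standard formula behind the word "skew" in library QC reports,
so only the sign/zero behavior of this statistic — not any particular
reported value — should be treated as comparable across tools. Summary tables (targets per amiRNA, amiRNAs per
internal node including zero-count nodes when trees are given, amiRNAs
per gene, per-class totals) are emitted as TSV.

## The synthetic data generator

`simulateFamily` emulates the one thing the design actually consumes:
families of paralogs whose similarity is graded by a known tree. A root
CDS is drawn uniformly over the 61 sense codons and evolved down the tree
with independent per-site substitutions (default 0.01 per site per branch,
uniform over the three alternative bases, no indels — keeping windows
alignable and the brute-force oracles simple). At that rate siblings
differ by ~2% of sites and share abundant exact 21-nt windows, which is
the regime in which multi-target design is meaningful; a warning fires
when the rate is so high that siblings are not expected to share a single
window. Random topologies come from recursive random bifurcation of the
leaf set. `simulateReads` emits each member's full oligo as its amplicon
at uniform, lognormal, or user-specified depths. Everything is a pure
function of its arguments and a seed.

What the generator does *not* emulate — codon usage and selection,
indels, real paralog age structure, sequencing errors, PCR bias — bounds
what passing tests show: they validate the algorithmic pipeline under its
stated model, not performance on any particular genome's transporter
complement, whose families, trees and database annotations are inputs the
user must supply.

## Numerical and design choices

* **Determinism.** The design path uses no random numbers; every ordering
  (node traversal, candidate ranking, tie-breaks) is fully specified, so
  two runs on identical inputs are byte-identical. Seeds affect only the
  simulators.
* **Standard problem sizes.** The validation suite exercises a five-family
  panel of 8–16 paralogs with 600-nt CDSs (base seed 42) for end-to-end
  constraint checks, families of up to 4 genes with ~200-nt CDSs for
  exhaustive selection-oracle comparisons, and 500-nt transcripts for
  per-window scan oracles. Tree oracles run exhaustively over all 105
  rooted 5-leaf topologies plus random 6–8-leaf trees (the rooted 8-leaf
  topology count, 135,135, makes full enumeration pointless).
* **Clipping.** Energy fractions are clipped to [0, 1]; clip events are
  logged. A non-negative perfect-match energy (pathological composition)
  is an error rather than a silent zero.
* **Degenerate inputs.** Trees may be multifurcating (each node still
  induces one subfamily; partial child groups are not monophyletic) and
  may carry branch lengths, which are ignored — all distances are node
  counts. An unrooted basal trifurcation is accepted with the basal node
  treated as the root; the package otherwise accepts the rooting as given
  (midpoint rooting, if desired, is the user's pre-processing step).
* **Coordinates and alphabet.** Everything internal is uppercase DNA
  (T, not U) with 0-based half-open coordinates on the CDS sense strand;
  the RNA spelling of each mature appears only in exports.
* **Interfaces.** The R functions are the primary interface; a thin
  command-line wrapper (`inst/scripts/phyloamir.R`) exposes `design`,
  `qc`, `simulate` and `simulate-reads` subcommands for shell pipelines,
  with assembly running inside `design`.

## Known limitations

The duplex model is a deliberate simplification — no target-site
accessibility, no precursor secondary-structure verification, no
dangling-end corrections — and its absolute energies should not be
over-interpreted; only the fraction relative to a perfect match is used.
Off-target screening is exact-window scanning of a supplied transcriptome,
not a genome-scale index. The blacklist is a user-supplied file of
21-mers. The default backbone and adaptors are placeholders suitable for
algorithmic work and testing, not for ordering oligos.
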