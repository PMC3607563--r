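---
title: "Methods: in-silico OLTA zinc-finger nuclease construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico OLTA zinc-finger nuclease construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olta)
```

## The problem

A zinc-finger nuclease (ZFN) is a chimeric protein: an array of 4-6 C2H2
zinc fingers, each recognising one DNA triplet through a 7-residue
recognition helix, fused to the FokI nuclease domain. Two ZFN monomers bind
half-sites on opposite strands, separated by a 5-6 bp spacer in which FokI
dimerises and cuts; error-prone repair of the break leaves small
substitutions, deletions and insertions.

OLTA (OverLap extension PCR and TA cloning) is a construction strategy in
which the finger array is not assembled from a module library but amplified
from a single two-helix *template* with short (≤ 29 nt) primers whose 21
codon positions encode the desired recognition helix. Each first-PCR
fragment runs from one helix to the next; because consecutive fragments end
and begin with the *same* helix codons, a primer-free second PCR joins them
by overlap extension, a third PCR amplifies the chains, and the product is
TA-cloned into a platform vector carrying the promoter, tags and FokI
domain. This package implements every dry-lab step of that workflow —
target-site discovery, primer design, assembly simulation, cloning and
orientation screening, and genotyping — so that designs can be checked
end-to-end before any oligo is ordered.

## The helix registry

`helix_registry()` ships the 21 published triplet → helix → primer entries.
Sequences are stored uppercase; the published mixed-case typography
(lowercase marking mismatches to the template) is retained in
`fwd_printed` / `rev_printed` for provenance. Three published reverse
primers encode a residue that conflicts with their annotated helix (GAT,
GCC, GTT); they are kept verbatim, because they are internally consistent
with their own published mismatch counts, and the disagreement is surfaced
in the `note` column. One reverse primer (GTC) is shipped with a
single-nucleotide correction (flagged `corrected`): the published string
contradicts its own count, its own lowercase mask and the annotated helix,
and all three are restored by the one-letter change.

`validate_registry()` recomputes every mismatch annotation as a
positionwise Hamming distance against the template references. 38 of the
42 published integers are reproduced exactly; the remaining four (GAC and
GCA reverse, GCC and ATG forward) are miscounts in the published
annotation — each lowercase mask misses exactly one true mismatch, and no
synonymous codon choice can produce the published integer from the
published sequence. The validator reports these as discrepancies rather
than silently rewriting the data.

## The template model

`build_template()` reconstructs the template from its two cloning primers:

* `fwd_ref` (29 nt) — 21 nt of helix-1 codons plus the constant 8-nt tail
  `CATATCCG` shared by all forward primers;
* `rev_ref` (29 nt) — `"GG"` prepended to the 27-nt reverse cloning primer.
  This 29-mer is itself a reverse primer with zero mismatches to the
  template, which is why mismatch counting over all 29 positions reproduces
  the published annotations. On the primer strand its codon region is
  positions 2-22 (`"G"` + reverse-complemented codons + the constant
  `ACTGAAG` anchor).

The interior of the template is not published, so the packaged fixture
(`make_fixture_template()`) uses a synthetic 48-nt internal framework,
chosen once so that the 63 framework nucleotides between the two helix
slots back-translate the canonical C2H2 inter-finger linker
`HIRIHTGQKPFQCRICMRNFS`. The resulting template is 106 nt primer-to-primer
and the helix-to-helix repeat is the canonical 84 nt. The 84-nt repeat is
deliberate: the nominal figure of 104 bp for the template insert would give
an 82-nt repeat, which is not a multiple of three and would put every
second finger out of frame — incompatible with the requirement that the
assembled array translate as helices joined by invariant framework
residues. The framework can be overridden with any user sequence (for
example the true template interior) via `build_template()`.

## Primer design

`design_primer_pair()` back-translates a 7-residue helix by choosing one
synonymous codon per residue (standard genetic code; no organism-specific
codon-usage weighting). The objective is the **joint** mismatch total of
the codon against the helix-1 slot and the helix-2 slot references. Two
observations force the joint objective rather than per-primer minimisation:

1. every published primer pair encodes the *same* codons in its forward and
   reverse primer — necessary, because the helix codons are the overlap by
   which fragments join, so the reverse primer of fragment *i* and the
   forward primer of fragment *i+1* must agree letter-for-letter; and
2. the published per-primer counts follow from it. The template's own
   helix-1 (`RSDALTR`) designs with 0 forward mismatches but 4 reverse
   mismatches, exactly as published, whereas independent per-slot
   minimisation would give 3.

Per-residue independence makes the per-position greedy choice globally
optimal; the test suite checks it against an oracle that enumerates every
codon combination. Ties are broken deterministically: fewer forward-slot
mismatches first, then the alphabetically first codon. Because published
designs may sit on other members of a tie class, agreement with the
published table is asserted on mismatch *counts*, never on sequence
identity.

Design constraints follow the published feasibility envelope: at most 11
mismatches per primer (`max_mismatch`, configurable; violations raise a
condition carrying the best achievable design), an exact 8-nt 3' tail on
forward primers and an exact 7-nt 3' anchor on reverse primers. The
published rule of thumb says 8 bp of complementary 3' end for both, but two
published reverse primers (GAT, GTT) carry a mismatch at the eighth
position from the 3' end, so the guaranteed reverse anchor is 7 nt; both
lengths are parameters of `check_three_prime_anchor()`.

## Target-site scanning

`scan_zfn_sites()` reports every arrangement
`revcomp(left) + spacer + right` in which both half-sites decompose fully
into registry triplets and the spacer is 5-6 nt (defaults; configurable via
`scan_params()`). Conventions:

* coordinates are 0-based, half-open, on the input plus strand; half-site
  sequences are reported 5'→3' on their own strands;
* ZF1 binds the 3'-most triplet, so `finger_order()` reverses the triplet
  reading order;
* asymmetric pairs (e.g. 6+4 fingers) are allowed;
* all overlapping or nested candidates are reported without suppression.
  In particular, any sub-array of a valid half-site that still decomposes
  into registry triplets is itself a candidate, so a planted 6+4 site also
  yields its 4+4 and 5+4 sub-candidates. Site choice was a manual step in
  the original workflow; the optional `rank_gnn = TRUE` ordering (fraction
  of GNN triplets, which have the best-characterised helices) is exposed
  but has no published validation;
* a pair and its mirror image on the reverse complement are one physical
  site; results are reported once in plus-strand coordinates, with "left"
  being the minus-strand half-site whose footprint lies upstream.

## Assembly simulation

`plan_reactions()` emits, for an n-finger array, the n−1 first-PCR
reactions (forward primer of finger *i*, reverse primer of finger *i+1*),
the published second-PCR mixing recipe (flanking fragments 0.5 µl, central
fragments 1.5 µl; advisory text, not simulated volumetrically) and the
third-PCR end primers.

`simulate_overlap_assembly()` joins fragments wherever a 3' suffix equals a
5' prefix exactly over at least `min_overlap = 21` nt — the helix length;
designed fragments sharing a helix in fact overlap over 22 nt because the
framework nucleotide after every helix is constant. PCR thermodynamics are
not modelled anywhere: annealing is exact string matching (anchor-based for
primers), which is the same abstraction the design constraints encode. All
maximal simple chains of the overlap graph are enumerated; with distinct
helices there is exactly one and it is on-pathway, while a repeated helix
creates branch points and multiple flagged chains — reproducing, quantity
aside, the misassembled ZF orders observed among sequenced clones.
`simulate_third_pcr()` retains chains whose ends carry the constant
tail/anchor (hence the ladder of bands) and marks the intended product.

Exact intended band sizes are not published; predicted lengths are
validated only relative to the template length (a k-fragment chain is
`106 + 84·(k−1)` nt with the packaged template).

## Cloning and orientation screening

`platform_vector()` models a circular vector with single PvuII
(`CAG^CTG`) and BstZ17I (`GTA^TAC`) blunt sites; `digest_and_tail()` drops
the stuffer between them and marks both backbone ends 3'-T-tailed
(terminal transferase + ddTTP). `ta_clone()` returns both insert
orientations — each junction contributes one A:T pair, so the forward
construct is `backbone + T + insert + A` circularised.
`colony_pcr_check()` screens orientation exactly as on the bench: the
T3-promoter primer converges with the third-PCR reverse primer only when
the insert is in the forward orientation; the reverse orientation yields no
product (`NA`).

The full platform vector is user-supplied in practice;
`make_fixture_vector()` ships a clearly synthetic miniature with T3
promoter, FLAG + SV40 NLS, the cassette, a short FokI-like stub and an XhoI
site, with the reading frame arranged so that a TA-cloned insert of any
finger count translates in frame from the ATG through the array into the
stub (the insert repeat of 84 nt plus the two junction scar bases keeps any
insert length ≡ 0 mod 3). KK/EL obligate-heterodimer FokI variants are
metadata tags: left arrays go to KK, right arrays to EL.

## Genotyping

`align_pair()` performs global affine-gap alignment (Needleman-Wunsch via
Biostrings) with defaults match +1, mismatch −1, gap open 4, gap extension
0.5. The strongly asymmetric open/extension pair makes a contiguous
deletion — the dominant repair outcome — align as a single gap instead of
scattered gaps; an independent dynamic-programming oracle checks the scores
in the tests. `classify_edits()` counts alignment columns (substituted,
deleted, inserted bases); the canonical label lists non-zero counts with
deletions first (`"3 D, 2 S"`), the convention of the published mutation
tables, or `"WT"`. Reads are compared case-insensitively; published
mixed-case/hyphen typography is display only and is never parsed. Complex
reads combining insertions with substitutions are reported with full
(S, D, I) counts; no attempt is made to reproduce single-label
simplifications of mixed events.

`t7e1_predict()` places the heteroduplex cut at the first divergent
alignment column, so a lesion at 0-based offset *p* in an *n*-nt amplicon
yields fragments (*p*, *n−p*), which always sum to *n*.

`tally_calls()` reproduces the structure of the published mutation
summaries (examined / mutated / per-genotype multiplicities) from any set
of calls. The biological quantities in those summaries — mutation rates,
embryo development rates — depend on injection, repair and development and
are out of scope; only fixture data feed the tally in the tests.

## Synthetic fixtures and what the tests show

`make_planted_genome()` draws a uniform random background and plants
non-overlapping `revcomp(L) + spacer + R` arrangements built from registry
triplets, returning truth coordinates; `make_mutant_reads()` applies one
contiguous event per edit type at a known anchor. All randomness flows
through a single integer seed and fixtures are byte-identical across
calls.

These fixtures emulate the *combinatorics* of the problem — triplet
decomposition, spacer geometry, contiguous NHEJ-like edits — not the
statistics of real data: background composition is uniform (real genomes
are not), reads are error-free full-length amplicons (no chromatogram
noise, no heterozygous mixtures, no mosaicism), and edits are single
contiguous events. Passing tests therefore demonstrate correctness of the
algorithms under those assumptions, not calling performance on noisy
traces.

Problem sizes used by the test-suite and the acceptance script: planted
genomes of 400-1000 nt with 1-2 sites over a handful of seeds, 10 random
helices for the designer-optimality check alongside all 21 registry
helices (the codon-combination oracle enumerates up to 6^7 combinations
per helix), and 4-6 finger arrays for assembly. These sizes exercise every
code path; the algorithms themselves are linear or near-linear in sequence
length and have no practical limit at amplicon/locus scale.

## Known limitations

* No melting-temperature or secondary-structure screening of primers; the
  published workflow uses fixed cycling conditions and the mismatch-count
  envelope stands in for annealing quality.
* No genome-scale off-target search and no affinity/specificity scoring of
  helices; the registry maps triplets to helices but does not predict new
  helices.
* The template interior and the platform vector are synthetic stand-ins,
  correct in structure (lengths, frames, sites) but not in sequence.
* Four published mismatch annotations and a handful of published primer
  letters are internally inconsistent, as detailed above; the package
  reproduces everything that is arithmetically reproducible and flags the
  rest.
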