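# olta

In-silico design and simulation of zinc-finger nuclease (ZFN) construction
by **OLTA** — OverLap extension PCR followed by TA cloning.

## What problem this solves, and for whom

A ZFN is an array of 4–6 C2H2 zinc fingers fused to the FokI nuclease
domain; each finger reads one DNA triplet through a 7-residue recognition
helix, and a ZFN *pair* binds two half-sites on opposite strands separated
by a 5–6 bp spacer where FokI dimerises and cuts. In the OLTA workflow the
finger array is amplified from a single two-helix template using ≤ 29-nt
primers of the form

```
forward:  [21 nt = codons of the recognition helix][CATATCCG]      (8-nt common tail)
reverse:  [G][reverse-complemented helix codons][ACTGAAG]          (7-nt constant anchor)
```

so a primer pair per triplet, reusable at any finger position, replaces a
module library. Fragment *i* runs from helix *i* to helix *i+1*; because
consecutive fragments share the helix codons, a primer-free overlap-extension
PCR joins them, a third PCR amplifies the chains, and the product is TA-cloned
into a platform vector (T3 promoter – FLAG/NLS – array – FokI).

This package is for anyone designing such constructs or analysing their
outcomes: it finds candidate paired half-sites, designs the primers by
synonymous-codon search minimising mismatches to the template (the design
envelope is ≤ 11 mismatches per primer with an exact 3' anchor), simulates
the three-step assembly including the misassembly mode caused by repeated
helices, models digestion/TA-cloning/orientation screening, and classifies
sequenced reads against the wild type into substitution/deletion/insertion
calls with T7 endonuclease I fragment prediction.

The core optimisation is exact: for helix residues *r₁…r₇* the designer
chooses codons *c₁…c₇* minimising

```
Σᵢ  [ d(cᵢ, fᵢ) + d(cᵢ, gᵢ) ]
```

where *d* is Hamming distance and *fᵢ*, *gᵢ* are the template's helix-1 and
helix-2 slot codons — jointly over both slots because one codon choice per
helix is shared by the forward and reverse primers (that sharing is what
makes the overlaps exact). Per-residue independence makes the per-position
minimum global; tests verify it against exhaustive enumeration of all codon
combinations.

## Worked example

Design a left-ZFN against a target amplicon, end to end:

```r
library(olta)

wt <- "AGGCCCACAGCTCTACGGCGACTGAGAGGAAG"
pairs <- scan_zfn_sites(wt)
pairs[, c("start", "end", "left_site", "right_site", "spacer_len")]
#>   start end    left_site   right_site spacer_len
#> 1     1  31 GAGCTGTGGGCC GACTGAGAGGAA          6

finger_order(pairs$left_site)   # ZF1 binds the 3'-most triplet
#> [1] "GCC" "TGG" "CTG" "GAG"

plan <- plan_reactions(finger_order(pairs$left_site))
plan
#> <reaction_plan> 4-finger array: GCC TGG CTG GAG
#> 1st PCR (3 reactions):
#>  fragment fwd_name rev_name
#>   ZF1-ZF2   GCC-Fw   TGG-Rv
#>   ZF2-ZF3   TGG-Fw   CTG-Rv
#>   ZF3-ZF4   CTG-Fw   GAG-Rv
#> 2nd PCR mix:
#>  fragment volume_ul
#>   ZF1-ZF2       0.5
#>   ZF2-ZF3       1.5
#>   ZF3-ZF4       0.5
#> 3rd PCR end primers: GCC-Fw + GAG-Rv
```

One candidate pair is found: the left half-site `GAGCTGTGGGCC` (minus
strand), spacer, then `GACTGAGAGGAA` (plus strand). The 4-finger array
needs three first-PCR fragments, mixed 0.5/1.5/0.5 µl for the overlap
extension, then amplified with the ZF1 forward and ZF4 reverse primers.

```r
tm <- make_fixture_template()
hx <- plan$helices
frags <- mapply(function(a, b) synthesize_fragment(tm, a, b),
                hx[-4], hx[-1], SIMPLIFY = FALSE)
prods <- simulate_overlap_assembly(frags)
prods
#> <assembly_products> 1 maximal chain(s)
#>   chain 1->2->3  274 nt  DCRDLAR|RSDHLTT|RNDALTE|RSDNLAR  (on pathway)

cons <- ta_clone(prods[[1]]$seq, digest_and_tail(make_fixture_vector("KK")))
colony_pcr_check(cons$forward, plan$third_pcr$primer[2])
#> [1] 354
colony_pcr_check(cons$reverse, plan$third_pcr$primer[2])
#> [1] NA
```

All three fragments chain into a single on-pathway 274-nt product
(4 fingers × 84-nt repeat + the trailing helix), and the colony-PCR screen
returns a 354-nt product only for the forward-orientation clone — the
wrong orientation gives no band.

Genotyping a sequenced read against the wild type:

```r
classify_edits(align_pair(wt, "AGGCCCACAGCTCTCGGCGACTGAGAGGAAG"))
#> <edit_call> 1 D
t7e1_predict(wt, "AGGCCCACAGCTCTCGGCGACTGAGAGGAAG")
#> [1] 14 18
```

The read carries a one-base deletion 14 nt into the amplicon; a T7
endonuclease I assay on the wild-type/mutant heteroduplex would cut into
14-nt and 18-nt fragments.

## Package layout

| Area | Functions |
|---|---|
| Registry | `helix_registry()`, `lookup_helix()`, `registry_size()`, `validate_registry()` |
| Template & primers | `build_template()`, `design_primer_pair()`, `count_mismatches()`, `check_three_prime_anchor()`, `primer_order_sheet()` |
| Site scanning | `scan_params()`, `scan_zfn_sites()`, `finger_order()`, `write_site_bed()` |
| Assembly | `plan_reactions()`, `synthesize_fragment()`, `simulate_overlap_assembly()`, `simulate_third_pcr()` |
| Cloning | `platform_vector()`, `digest_and_tail()`, `ta_clone()`, `colony_pcr_check()` |
| Genotyping | `align_pair()`, `classify_edits()`, `genotype_reads()`, `tally_calls()`, `t7e1_predict()` |
| Fixtures & I/O | `make_fixture_template()`, `make_fixture_vector()`, `make_planted_genome()`, `make_mutant_reads()`, `read_fasta_dna()`, `read_reads()` |

The methods vignette (`vignettes/olta-methods.Rmd`) documents the models,
conventions, parameter choices and known limitations, including the
handful of internally inconsistent annotations in the published primer
table and how the package handles them.
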