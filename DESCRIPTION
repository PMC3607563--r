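Package: olta
Title: Zinc-Finger Nuclease Construction by Overlap-Extension PCR and TA
    Cloning, In Silico
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and simulation toolkit for the OLTA workflow of building
    zinc-finger nuclease (ZFN) expression vectors: scanning DNA for paired
    ZFN half-sites, back-translating 7-residue DNA-recognition helices into
    first-round PCR primers by synonymous-codon search that minimises
    mismatches against a common zinc-finger template, simulating the
    three-step overlap-extension PCR assembly of 4-6 finger arrays,
    modelling blunt-cut/TA cloning into a platform vector with orientation
    screening by colony PCR, and classifying sequenced reads against a
    wild-type amplicon into substitution, deletion and insertion calls with
    T7 endonuclease I fragment prediction. Ships the validated registry of
    21 published triplet-to-helix-to-primer entries and deterministic
    synthetic fixture generators for self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
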