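# Shared fixtures and independent oracles used across the test files.

the_template <- make_fixture_template()
the_registry <- helix_registry()

# Wild-type amplicons around the four published target loci, with the
# published half-site pairs used as ground truth by the scanner tests.
wt_amplicons <- list(
  Gli3   = "AGGCCCACAGCTCTACGGCGACTGAGAGGAAG",
  Rosa26 = "CTGCAACTCCAGTCTTTCTAGAAGATGGGCGGGAGTCT",
  Il2rg  = "ACCAACCTCACGCTGCACTATAGGTATGAGAAGGGGGA",
  Cdkn1b = "GGTCCACACCCGCCCGAGGAGGAAGATGTCA"
)
known_pairs <- list(
  Gli3   = list(left = "GAGCTGTGGGCC", right = "GACTGAGAGGAA"),
  Rosa26 = list(left = "AGAAAGACTGGAGTTGCA", right = "TGGGCGGGAGTC"),
  Il2rg  = list(left = "GCAGCGTGAGGTTGG", right = "GGTATGAGAAGGGGG"),
  Cdkn1b = list(left = "GCGGGTGTGGAC", right = "GAGGAAGATGTC")
)

ham_str <- function(a, b) {
  sum(strsplit(toupper(a), "")[[1]] != strsplit(toupper(b), "")[[1]])
}

# Exhaustive synonymous-codon oracle: enumerates every codon combination for
# a 7-residue helix and returns the minimal total mismatch count against the
# two slot references (and the minimal forward-only count).  Enumeration is
# by accumulated outer sums, i.e. every one of the up-to-6^7 combinations is
# represented individually.
brute_force_design <- function(helix, template) {
  gc <- Biostrings::GENETIC_CODE
  residues <- strsplit(toupper(helix), "")[[1]]
  fcod <- split_codons(substr(template$fwd_ref, 1, 21))
  rcod <- split_codons(substr(revcomp(template$rev_ref), 8, 28))
  tot <- 0; fwd <- 0
  for (i in seq_along(residues)) {
    cand <- sort(names(gc)[gc == residues[i]])
    cf <- vapply(cand, ham_str, numeric(1), b = fcod[i])
    cr <- vapply(cand, ham_str, numeric(1), b = rcod[i])
    tot <- as.vector(outer(tot, cf + cr, "+"))
    fwd <- as.vector(outer(fwd, cf, "+"))
  }
  list(min_total = min(tot), min_fwd = min(fwd), n_combos = length(tot))
}

random_helix <- function() {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"), 7, replace = TRUE),
        collapse = "")
}

# Independent affine-gap global alignment score by full dynamic programming
# (Gotoh three-matrix recursion); gap of length L costs open + L * extend.
dp_align_score <- function(a, b, match = 1, mismatch = -1, open = 4, extend = 0.5) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1); Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * extend)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * extend)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE), collapse = "")

# fragments for an array of triplets, via the designer
fragments_for <- function(triplets, template = the_template) {
  hx <- vapply(triplets, function(t) lookup_helix(t, the_registry)$helix, character(1))
  mapply(function(a, b) synthesize_fragment(template, a, b),
         hx[-length(hx)], hx[-1], SIMPLIFY = FALSE)
}
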