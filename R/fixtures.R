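# Deterministic synthetic fixtures: the packaged template, a synthetic
# platform vector, planted-site genomes and mutant reads.  Everything is
# generated in code; random fixtures are reproducible from a seed.

# 48-nt synthetic internal framework.  Together with the constant 8-nt tail
# and the 7-nt upstream framework it back-translates the canonical C2H2
# inter-finger linker HIRIHTGQKPFQCRICMRNFS, so that the helix-to-helix
# repeat is the canonical 84 nt and assembled arrays stay in frame.  This is
# a synthetic stand-in for the real template interior, which is not
# reproduced here; any user template can be supplied via build_template().
olta_internal_framework <- function() {
  paste0(
    "C",                                              # completes the Arg codon after the tail
    "ATCCACACCGGCCAGAAACCGTTCCAGTGCCGTATTTGTATGCGT",  # IHTGQKPFQCRICMR
    "AA"                                              # with the next C: Asn before Phe-Ser
  )
}

#' Packaged fixture template
#'
#' The two-helix-slot template reconstructed from the published cloning
#' primers, with the packaged synthetic internal framework.  Its ends equal
#' the cloning primers; the framework between the helix slots translates to
#' the canonical C2H2 linker residues HIRIHTGQKPFQCRICMRNFS, giving an
#' 84-nt finger repeat so that assembled arrays translate in frame.
#' Deterministic: repeated calls return identical objects.
#'
#' @return A [build_template()] model (106 nt).
#' @export
make_fixture_template <- function() {
  build_template(OLTA_FWD_CLONING_PRIMER, OLTA_REV_CLONING_PRIMER,
                 olta_internal_framework())
}

#' Synthetic platform vector for testing
#'
#' A miniature circular platform vector with the elements the cloning and
#' screening operations need: T3 promoter, an open reading frame start
#' (FLAG tag + SV40 nuclear localisation signal) running into the PvuII
#' half of the cloning cassette, a stuffer, the BstZ17I half running into a
#' short FokI-like stub with stop codon, and an XhoI linearisation site.
#' The reading frame across the cassette is arranged so that a TA-cloned
#' OLTA insert of any finger count translates in frame from the ATG through
#' the zinc-finger array into the stub.  Synthetic: not any published vector
#' sequence.
#'
#' @param variant `"KK"` or `"EL"` FokI variant tag.
#' @return A [platform_vector()].
#' @export
make_fixture_vector <- function(variant = c("KK", "EL")) {
  variant <- match.arg(variant)
  up_filler <- "GCGCTTAATGCGCCGCTACAGGGCGCGTC"
  t3 <- T3_PROMOTER
  utr <- "AGAAAC"
  flag <- "GATTACAAGGATGACGACGATAAG"        # DYKDDDDK
  nls <- "CCAAAAAAGAAGAGAAAGGTA"            # PKKKRKV
  linker <- "GC"                            # puts the PvuII CAG in frame A-S at the junction
  stuffer <- "TTAGACGTCCTGAATTGGCATCACGGTCAATTCTGAGGACCTAAGGCATT"
  # FokI-like stub, QLVKSELEEKKSELRHKLKYV + stop, offset one nt after the
  # BstZ17I TAC so the fusion frame runs H-T-(stub) across the junction
  stub <- paste0("G",
                 "CAACTGGTGAAAAGCGAACTGGAAGAGAAGAAATCCGAACTGCGCCACAAACTGAAATATGTG",
                 "TGA")
  down_filler <- "GGATCCTCTAGAGTCGACGCATGCAAGCTTGGCACTGGCCGTCG"
  seqv <- paste0(up_filler, t3, utr, "ATG", flag, nls, linker,
                 PVUII_SITE, stuffer, BSTZ17I_SITE, stub, XHOI_SITE, down_filler)
  platform_vector(seqv, variant = variant)
}

#' Fixture specification for synthetic genomes and reads
#'
#' @param seed Integer seed; all fixture randomness flows through it.
#' @param genome_length Length of the random background sequence.
#' @param n_planted_sites Number of non-overlapping ZFN site pairs to plant.
#' @param finger_range,spacer_range Integer length-2 vectors for the planted
#'   half-site finger counts and spacer lengths.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, genome_length = 1000L, n_planted_sites = 1L,
                         finger_range = c(4L, 6L), spacer_range = c(5L, 6L)) {
  stopifnot(genome_length > 0L, n_planted_sites >= 0L,
            finger_range[1] <= finger_range[2], spacer_range[1] <= spacer_range[2])
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 n_planted_sites = as.integer(n_planted_sites),
                 finger_range = as.integer(finger_range),
                 spacer_range = as.integer(spacer_range)),
            class = "fixture_spec")
}

#' Generate a random genome with planted ZFN site pairs
#'
#' Draws a uniform random background sequence and plants
#' `revcomp(left) + spacer + right` arrangements whose half-sites are random
#' concatenations of registry triplets, recording the truth coordinates.
#' Planting is non-overlapping; deterministic for a fixed spec.
#'
#' @param spec A [fixture_spec()].
#' @param registry A [helix_registry()].
#' @return List with `seq` and `truth` (data frame: 0-based `start`, `end`,
#'   `left_site`, `right_site`, `spacer_len`).
#' @export
make_planted_genome <- function(spec = fixture_spec(), registry = helix_registry()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$genome_length
  genome <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  truth <- data.frame(start = integer(0), end = integer(0),
                      left_site = character(0), right_site = character(0),
                      spacer_len = integer(0), stringsAsFactors = FALSE)
  occupied <- rep(FALSE, n)
  # sample() treats a length-1 vector as 1:x; resample() avoids that
  resample <- function(x) x[sample.int(length(x), 1L)]
  for (i in seq_len(spec$n_planted_sites)) {
    kl <- resample(spec$finger_range[1]:spec$finger_range[2])
    kr <- resample(spec$finger_range[1]:spec$finger_range[2])
    sp <- resample(spec$spacer_range[1]:spec$spacer_range[2])
    left <- paste(sample(registry$triplet, kl, replace = TRUE), collapse = "")
    right <- paste(sample(registry$triplet, kr, replace = TRUE), collapse = "")
    spacer <- paste(sample(c("A", "C", "G", "T"), sp, replace = TRUE), collapse = "")
    site <- paste0(revcomp(left), spacer, right)
    L <- nchar(site)
    placed <- FALSE
    for (attempt in seq_len(200L)) {
      pos <- sample.int(n - L + 1L, 1L)  # 1-based start
      if (!any(occupied[pos:(pos + L - 1L)])) {
        genome <- paste0(substr(genome, 1L, pos - 1L), site,
                         substr(genome, pos + L, n))
        occupied[pos:(pos + L - 1L)] <- TRUE
        truth <- rbind(truth, data.frame(
          start = pos - 1L, end = pos + L - 1L,
          left_site = left, right_site = right, spacer_len = sp,
          stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place planted site ", i, " without overlap")
  }
  list(seq = genome, truth = truth)
}

#' Generate mutant reads with known edits
#'
#' Applies one contiguous event per requested edit type to the wild-type
#' sequence: `n_sub` substituted bases starting at `pos` (each base replaced
#' by a different one), or `n_del` deleted bases, or `n_ins` inserted bases.
#' Events are applied in the order substitution, deletion, insertion at the
#' same anchor position; the truth call is returned with each read.
#'
#' @param wt Wild-type sequence.
#' @param edit_specs A list of lists with elements `n_sub`, `n_del`, `n_ins`
#'   (defaults 0) and `pos` (1-based anchor, default midpoint).
#' @param seed Seed used to draw substituted/inserted bases.
#' @return Data frame with `read`, `n_sub`, `n_del`, `n_ins`, `label`.
#' @export
make_mutant_reads <- function(wt, edit_specs, seed = 1L) {
  wt <- check_dna(wt, "wild-type sequence")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  one <- function(es) {
    n_sub <- es$n_sub %||% 0L
    n_del <- es$n_del %||% 0L
    n_ins <- es$n_ins %||% 0L
    pos <- es$pos %||% max(1L, nchar(wt) %/% 2L)
    if (pos < 1L || pos + n_sub + n_del - 1L > nchar(wt)) {
      stop("edit at position ", pos, " runs outside the sequence")
    }
    read <- wt
    if (n_sub > 0L) {
      for (k in seq_len(n_sub)) {
        old <- substr(read, pos + k - 1L, pos + k - 1L)
        new <- sample(setdiff(bases, old), 1L)
        substr(read, pos + k - 1L, pos + k - 1L) <- new
      }
    }
    if (n_del > 0L) {
      at <- pos + n_sub
      read <- paste0(substr(read, 1L, at - 1L), substr(read, at + n_del, nchar(read)))
    }
    if (n_ins > 0L) {
      at <- pos + n_sub
      ins <- paste(sample(bases, n_ins, replace = TRUE), collapse = "")
      read <- paste0(substr(read, 1L, at - 1L), ins, substr(read, at, nchar(read)))
    }
    data.frame(read = read, n_sub = n_sub, n_del = n_del, n_ins = n_ins,
               label = edit_call(n_sub, n_del, n_ins)$label,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(edit_specs, one))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
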