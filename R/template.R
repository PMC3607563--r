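# Model of the two-helix-slot zinc-finger template and the mismatch-minimising
# primer designer.
#
# The template is the stretch of a C2H2 zinc-finger domain running from the
# first DNA-recognition helix to one nucleotide past the second.  Its two ends
# are fixed by the cloning primers used to amplify it:
#
#   fwd_ref  (29 nt)  = 21 nt of helix-1 codons + the 8-nt common tail
#   rev_ref  (29 nt)  = reverse-complement view of 1 framework nt +
#                       21 nt of helix-2 codons + 7 nt constant anchor,
#                       i.e. "GG" prepended to the 27-nt reverse cloning primer
#
# A first-PCR primer for an arbitrary 7-residue helix keeps the constant
# framework positions and substitutes the 21 codon positions, choosing one
# synonymous codon per residue so that the total number of mismatches against
# the template (forward slot plus reverse slot jointly) is minimal.  Sharing
# one codon choice per helix between the forward and reverse primers is what
# makes overlap-extension fragments carrying the same helix overlap exactly.

#' Default cloning primers that define the packaged template ends
#' @name template_constants
#' @keywords internal
NULL

OLTA_FWD_CLONING_PRIMER <- "CGCTCGGATGCGCTTACCCGCCATATCCG"
OLTA_REV_CLONING_PRIMER <- "CGGGCAAGATTATCCGAGCGACTGAAG"
OLTA_FWD_TAIL <- "CATATCCG"   # 8-nt common tail, 3' anchor of all forward primers
OLTA_REV_ANCHOR <- "ACTGAAG"  # 7-nt constant anchor, 3' anchor of all reverse primers

#' Build a zinc-finger template model
#'
#' Constructs the template used for first-PCR primer design and fragment
#' synthesis from the two cloning primers that define its ends, plus an
#' internal framework sequence joining the helix-1 tail to the helix-2
#' upstream framework.
#'
#' The reverse annealing reference `rev_ref` is the 29-mer obtained by
#' prepending `"GG"` to the 27-nt reverse cloning primer: that 29-mer is
#' itself a valid reverse primer with zero mismatches to the template, and
#' mismatch counting over all 29 positions reproduces the published primer
#' annotations.
#'
#' @param fwd_cloning_primer 29-nt forward cloning primer (helix-1 slot plus
#'   common tail).
#' @param rev_cloning_primer 27-nt reverse cloning primer.
#' @param internal_framework DNA string between the two annealing regions.
#'   Defaults to the packaged 48-nt synthetic framework, a back-translation of
#'   the canonical C2H2 inter-helix linker (see [make_fixture_template()]).
#' @return An object of class `zf_template`: a list with elements `fwd_ref`,
#'   `rev_ref`, `internal_framework`, `seq` (the full coding strand),
#'   `total_length`, and the per-slot reference codons `fwd_slot_codons`,
#'   `rev_slot_codons`.
#' @examples
#' tm <- build_template()
#' tm$total_length
#' translate_dna(substr(tm$fwd_ref, 1, 21))
#' @export
build_template <- function(fwd_cloning_primer = OLTA_FWD_CLONING_PRIMER,
                           rev_cloning_primer = OLTA_REV_CLONING_PRIMER,
                           internal_framework = NULL) {
  fwd_ref <- check_dna(fwd_cloning_primer, "forward cloning primer", len = 29L)
  rev27 <- check_dna(rev_cloning_primer, "reverse cloning primer", len = 27L)
  rev_ref <- paste0("GG", rev27)
  if (is.null(internal_framework)) {
    internal_framework <- olta_internal_framework()
  }
  internal_framework <- check_dna(internal_framework, "internal framework")

  helix1 <- translate_dna(substr(fwd_ref, 1L, 21L))
  if (grepl("\\*", helix1)) {
    stop("forward reference does not encode a valid helix: ", helix1)
  }
  # coding strand: helix-1 slot, common tail, framework, 7-nt upstream
  # framework, helix-2 slot, one trailing framework nt
  seq <- paste0(fwd_ref, internal_framework, revcomp(rev_ref))
  structure(
    list(
      fwd_ref = fwd_ref,
      rev_ref = rev_ref,
      internal_framework = internal_framework,
      seq = seq,
      total_length = nchar(seq),
      fwd_slot_codons = split_codons(substr(fwd_ref, 1L, 21L)),
      rev_slot_codons = split_codons(substr(revcomp(rev_ref), 8L, 28L)),
      helix1 = helix1,
      helix2 = translate_dna(substr(revcomp(rev_ref), 8L, 28L))
    ),
    class = "zf_template"
  )
}

#' @export
print.zf_template <- function(x, ...) {
  cat("<zf_template> ", x$total_length, " nt\n", sep = "")
  cat("  helix-1 slot: ", x$helix1, "  (", substr(x$fwd_ref, 1, 21), ")\n", sep = "")
  cat("  helix-2 slot: ", x$helix2, "\n", sep = "")
  cat("  forward tail: ", substr(x$fwd_ref, 22, 29),
      "   reverse anchor: ", substr(x$rev_ref, 23, 29), "\n", sep = "")
  invisible(x)
}

#' Positionwise mismatch count between two equal-length sequences
#'
#' Case-insensitive Hamming distance; the published primer tables annotate
#' each primer with this count against the template references.
#'
#' @param a,b DNA strings of equal length.
#' @return Integer number of differing positions.
#' @examples
#' count_mismatches("CGCTCGGATaatCTTgCCCGCCATATCCG", "CGCTCGGATGCGCTTACCCGCCATATCCG")
#' @export
count_mismatches <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L || length(b) != 1L) {
    stop("count_mismatches expects two single strings")
  }
  if (nchar(a) != nchar(b)) {
    stop("sequences have unequal lengths (", nchar(a), " vs ", nchar(b), ")")
  }
  sum(strsplit(toupper(a), "")[[1]] != strsplit(toupper(b), "")[[1]])
}

#' Check the 3'-terminal anchor of a primer
#'
#' A primer is considered to anneal productively only when its 3'-terminal
#' `k` positions match the reference exactly: 8 nt for forward primers (the
#' common tail) and 7 nt for reverse primers (the constant anchor).
#'
#' @param primer,reference Equal-length DNA strings.
#' @param k Number of 3'-terminal positions that must be identical.
#' @return `TRUE` if the last `k` positions agree.
#' @export
check_three_prime_anchor <- function(primer, reference, k = 7L) {
  n <- nchar(primer)
  if (n != nchar(reference)) stop("primer and reference lengths differ")
  if (k > n) return(FALSE)
  toupper(substr(primer, n - k + 1L, n)) == toupper(substr(reference, n - k + 1L, n))
}

# Choose one codon per helix residue minimising the joint mismatch total
# against the forward- and reverse-slot reference codons.  Ties are broken
# deterministically: first prefer fewer forward-slot mismatches, then the
# alphabetically first codon.  Per-residue independence makes the greedy
# per-position choice globally optimal.
choose_helix_codons <- function(helix, template) {
  helix <- check_aa(helix)
  residues <- strsplit(helix, "")[[1]]
  ham3 <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  codons <- character(7L)
  fwd_mm <- integer(7L)
  rev_mm <- integer(7L)
  for (i in seq_len(7L)) {
    cand <- synonymous_codons(residues[i])
    cf <- vapply(cand, ham3, integer(1), b = template$fwd_slot_codons[i])
    cr <- vapply(cand, ham3, integer(1), b = template$rev_slot_codons[i])
    tot <- cf + cr
    keep <- which(tot == min(tot))
    keep <- keep[order(cf[keep], cand[keep])][1L]
    codons[i] <- cand[keep]
    fwd_mm[i] <- cf[keep]
    rev_mm[i] <- cr[keep]
  }
  list(codons = codons, fwd_ndn = sum(fwd_mm), rev_ndn = sum(rev_mm))
}

#' Design the first-PCR primer pair for a DNA-recognition helix
#'
#' Back-translates a 7-residue recognition helix into the 21 codon positions
#' of the forward and reverse first-PCR primers, selecting synonymous codons
#' to minimise the total number of mismatches against the template's two
#' helix slots.  One codon choice is shared by both primers of a helix so
#' that overlap-extension fragments carrying the same helix share an exact
#' overlap.
#'
#' The forward primer is the 21 chosen codon nucleotides followed by the
#' constant 8-nt tail.  The reverse primer is the reverse complement of
#' (1 framework nt + 21 codon nt + 7 framework nt) read off the template with
#' the helix-2 slot substituted; its 3' end therefore lies in constant
#' framework.
#'
#' @param helix 7-residue helix in one-letter code.
#' @param template A [build_template()] model.
#' @param max_mismatch Maximum tolerated mismatch count per primer
#'   (default 11, the largest count among the published primer sets).
#' @return An object of class `designed_primers`: list with `helix`,
#'   `codons`, `fwd_primer`, `rev_primer`, `fwd_ndn`, `rev_ndn`,
#'   `fwd_anchor_ok`, `rev_anchor_ok`.
#' @examples
#' tm <- build_template()
#' design_primer_pair("RSDNLAR", tm)
#' @export
design_primer_pair <- function(helix, template, max_mismatch = 11L) {
  stopifnot(inherits(template, "zf_template"))
  sel <- choose_helix_codons(helix, template)
  codons21 <- paste(sel$codons, collapse = "")
  fwd <- paste0(codons21, substr(template$fwd_ref, 22L, 29L))
  # reverse primer covers (on the coding strand) the 7-nt upstream framework,
  # the helix codons, and one trailing framework nt
  rc_rev_ref <- revcomp(template$rev_ref)
  coding <- paste0(substr(rc_rev_ref, 1L, 7L), codons21, substr(rc_rev_ref, 29L, 29L))
  rev <- revcomp(coding)
  out <- structure(
    list(
      helix = toupper(helix),
      codons = sel$codons,
      fwd_primer = fwd,
      rev_primer = rev,
      fwd_ndn = sel$fwd_ndn,
      rev_ndn = sel$rev_ndn,
      fwd_anchor_ok = check_three_prime_anchor(fwd, template$fwd_ref, 8L),
      rev_anchor_ok = check_three_prime_anchor(rev, template$rev_ref, 7L)
    ),
    class = "designed_primers"
  )
  if (sel$fwd_ndn > max_mismatch || sel$rev_ndn > max_mismatch) {
    cond <- structure(
      class = c("olta_design_error", "error", "condition"),
      list(
        message = sprintf(
          "helix %s needs %d (forward) / %d (reverse) mismatches; cap is %d",
          out$helix, sel$fwd_ndn, sel$rev_ndn, max_mismatch),
        call = sys.call(-1),
        best_design = out
      )
    )
    stop(cond)
  }
  out
}

#' @rdname design_primer_pair
#' @export
design_forward_primer <- function(helix, template, max_mismatch = 11L) {
  design_primer_pair(helix, template, max_mismatch)
}

#' @rdname design_primer_pair
#' @export
design_reverse_primer <- function(helix, template, max_mismatch = 11L) {
  design_primer_pair(helix, template, max_mismatch)
}

#' @export
print.designed_primers <- function(x, ...) {
  cat("<designed_primers> helix ", x$helix, "\n", sep = "")
  cat(sprintf("  Fw %s (%d mismatches, anchor %s)\n",
              x$fwd_primer, x$fwd_ndn, if (x$fwd_anchor_ok) "ok" else "BROKEN"))
  cat(sprintf("  Rv %s (%d mismatches, anchor %s)\n",
              x$rev_primer, x$rev_ndn, if (x$rev_anchor_ok) "ok" else "BROKEN"))
  invisible(x)
}

#' Export designed primers as a data frame
#'
#' @param designs A list of `designed_primers` objects.
#' @return A data frame with one row per primer, ready to write as TSV
#'   (name, sequence, mismatch count, anchor flag).
#' @export
primer_order_sheet <- function(designs) {
  if (inherits(designs, "designed_primers")) designs <- list(designs)
  rows <- lapply(designs, function(d) {
    data.frame(
      name = paste0(d$helix, c("-Fw", "-Rv")),
      sequence = c(d$fwd_primer, d$rev_primer),
      mismatches = c(d$fwd_ndn, d$rev_ndn),
      anchor_ok = c(d$fwd_anchor_ok, d$rev_anchor_ok),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
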