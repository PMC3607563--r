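# Platform-vector model: blunt double digestion, 3'-T tailing, TA cloning in
# both orientations, and the colony-PCR orientation screen.
#
# The platform vector carries (clockwise): a T3 promoter, the start of the
# ZFN open reading frame (FLAG tag + nuclear localisation signal), a cloning
# cassette bounded by single PvuII (CAG^CTG) and BstZ17I (GTA^TAC) blunt
# sites around a stuffer, the FokI nuclease domain, a stop codon, and the
# XhoI site used to linearise for in vitro transcription.  KK and EL are the
# obligate-heterodimer FokI variants: left-side arrays go into the KK vector,
# right-side arrays into the EL vector.

PVUII_SITE <- "CAGCTG"    # cuts CAG^CTG, blunt
BSTZ17I_SITE <- "GTATAC"  # cuts GTA^TAC, blunt
XHOI_SITE <- "CTCGAG"
T3_PROMOTER <- "AATTAACCCTCACTAAAGGG"

#' Construct a platform-vector model
#'
#' @param seq Circular vector sequence (plus strand). Typically the
#'   user-supplied full vector; [make_fixture_vector()] builds a synthetic
#'   test vector.
#' @param variant `"KK"` (left-ZFN) or `"EL"` (right-ZFN) FokI
#'   obligate-heterodimer variant; metadata only.
#' @param t3_primer Sequence used to locate the T3 promoter.
#' @return An object of class `platform_vector`: list with `seq`, `variant`,
#'   `length`, 0-based positions `t3_start`, `pvuii_cut`, `bstz17i_cut`,
#'   `xhoi_start`.
#' @export
platform_vector <- function(seq, variant = c("KK", "EL"), t3_primer = T3_PROMOTER) {
  variant <- match.arg(variant)
  seq <- check_dna(seq, "vector sequence")
  find_all <- function(site) {
    # circular search: scan the doubled sequence, keep starts in [0, n)
    hits <- gregexpr(site, paste0(seq, substr(seq, 1L, nchar(site) - 1L)),
                     fixed = TRUE)[[1]]
    if (hits[1] == -1L) integer(0) else as.integer(hits[hits <= nchar(seq)]) - 1L
  }
  pv <- find_all(PVUII_SITE)
  bs <- find_all(BSTZ17I_SITE)
  t3 <- find_all(t3_primer)
  xh <- find_all(XHOI_SITE)
  if (length(pv) != 1L) {
    stop("expected exactly one PvuII site, found ", length(pv),
         if (length(pv)) paste0(" at ", paste(pv, collapse = ", ")))
  }
  if (length(bs) != 1L) {
    stop("expected exactly one BstZ17I site, found ", length(bs),
         if (length(bs)) paste0(" at ", paste(bs, collapse = ", ")))
  }
  if (length(t3) != 1L) stop("expected exactly one T3 promoter match")
  structure(
    list(seq = seq, variant = variant, length = nchar(seq),
         t3_start = t3, t3_primer = toupper(t3_primer),
         pvuii_cut = (pv + 3L) %% nchar(seq),    # CAG^CTG
         bstz17i_cut = (bs + 3L) %% nchar(seq),  # GTA^TAC
         xhoi_start = if (length(xh)) xh[1] else NA_integer_),
    class = "platform_vector"
  )
}

#' @export
print.platform_vector <- function(x, ...) {
  cat("<platform_vector> ", x$length, " bp circular, FokI variant ", x$variant, "\n",
      "  T3 promoter at ", x$t3_start, "; PvuII cut ", x$pvuii_cut,
      "; BstZ17I cut ", x$bstz17i_cut, "\n", sep = "")
  invisible(x)
}

# rotate a circular sequence so that 0-based position `pos` becomes first
rotate_seq <- function(seq, pos) {
  n <- nchar(seq)
  pos <- pos %% n
  if (pos == 0L) return(seq)
  paste0(substr(seq, pos + 1L, n), substr(seq, 1L, pos))
}

#' Digest the platform vector and add 3'-T overhangs
#'
#' Blunt-cuts at the single PvuII and BstZ17I sites, discards the stuffer
#' (the arc that does not contain the T3 promoter) and marks both backbone
#' ends as carrying the single 3' T added by terminal transferase (ddTTP).
#' Digesting an already-linearised backbone is an error because the enzymes'
#' sites are destroyed by the cut-and-tail.
#'
#' @param vector A [platform_vector()].
#' @return An object of class `linearized_vector`: list with `seq` (plus
#'   strand of the backbone, running from the BstZ17I cut round through the
#'   T3 promoter to the PvuII cut), `t_tailed = TRUE`, `variant`,
#'   `t3_offset` (0-based position of the T3 promoter within the backbone),
#'   `stuffer` (the dropped arc).
#' @export
digest_and_tail <- function(vector) {
  stopifnot(inherits(vector, "platform_vector"))
  n <- vector$length
  # arc from BstZ17I cut forward to PvuII cut (may wrap)
  arc_len <- (vector$pvuii_cut - vector$bstz17i_cut) %% n
  arc1 <- substr(rotate_seq(vector$seq, vector$bstz17i_cut), 1L, arc_len)
  arc2 <- substr(rotate_seq(vector$seq, vector$pvuii_cut), 1L, n - arc_len)
  t3_in_arc1 <- ((vector$t3_start - vector$bstz17i_cut) %% n) < arc_len
  backbone <- if (t3_in_arc1) arc1 else arc2
  stuffer <- if (t3_in_arc1) arc2 else arc1
  t3_offset <- if (t3_in_arc1) {
    (vector$t3_start - vector$bstz17i_cut) %% n
  } else {
    (vector$t3_start - vector$pvuii_cut) %% n
  }
  structure(
    list(seq = backbone, t_tailed = TRUE, variant = vector$variant,
         t3_offset = t3_offset, t3_primer = vector$t3_primer,
         stuffer = stuffer),
    class = "linearized_vector"
  )
}

#' TA-clone an insert into the linearised backbone
#'
#' Joins an A-tailed insert to the T-tailed backbone.  TA ligation is not
#' directional, so both orientations are returned; each junction contributes
#' one A:T base pair, so the circular product is
#' backbone + T + insert + A (forward) or backbone + T + revcomp(insert) + A.
#'
#' @param insert Insert sequence (plus strand, without the terminal A
#'   overhangs).
#' @param backbone A [digest_and_tail()] result.
#' @param a_tailed Whether the insert carries 3' A overhangs; a plain blunt
#'   product triggers a warning (ligation would be inefficient) but both
#'   orientations are still modelled.
#' @return List of two `cloned_construct` objects (`forward`, `reverse`),
#'   each with the circular `seq`, `orientation`, `insert`, `variant`,
#'   `t3_offset`.
#' @export
ta_clone <- function(insert, backbone, a_tailed = TRUE) {
  stopifnot(inherits(backbone, "linearized_vector"))
  insert <- check_dna(insert, "insert")
  if (nchar(insert) == 0L) stop("empty insert")
  if (!isTRUE(a_tailed)) {
    warning("insert is not A-tailed; TA ligation would be inefficient")
  }
  mk <- function(ins, orientation) {
    structure(
      list(seq = paste0(backbone$seq, "T", ins, "A"),
           orientation = orientation, insert = ins,
           variant = backbone$variant,
           t3_offset = backbone$t3_offset,
           t3_primer = backbone$t3_primer),
      class = "cloned_construct"
    )
  }
  list(forward = mk(insert, "forward"),
       reverse = mk(revcomp(insert), "reverse"))
}

#' @export
print.cloned_construct <- function(x, ...) {
  cat("<cloned_construct> ", nchar(x$seq), " bp circular, insert ",
      nchar(x$insert), " nt, ", x$orientation, " orientation, variant ",
      x$variant, "\n", sep = "")
  invisible(x)
}

#' Colony-PCR orientation screen
#'
#' Simulates colony PCR with the T3-promoter primer as forward primer and a
#' reverse primer (typically the third-PCR reverse primer).  A product is
#' predicted only when the reverse primer's annealing site (the reverse
#' complement of the primer on the plus strand) lies downstream of the T3
#' primer within `max_product` nt -- i.e. the two primers converge.  A
#' reverse-orientation insert presents the primer sequence itself instead of
#' its reverse complement, so no product is predicted.
#'
#' @param construct A `cloned_construct` (or a `linearized_vector` re-ligated
#'   empty, passed as a construct with zero-length insert).
#' @param rev_primer Reverse primer sequence.
#' @param t3_primer Forward primer (defaults to the construct's T3 promoter).
#' @param max_product Maximum plausible product size in nt.
#' @return Predicted product length (integer, from the 5' end of the T3
#'   primer to the 3' end of the reverse-primer site), or `NA_integer_` when
#'   no convergent product forms.
#' @export
colony_pcr_check <- function(construct, rev_primer, t3_primer = NULL,
                             max_product = 5000L) {
  stopifnot(inherits(construct, "cloned_construct"))
  rev_primer <- check_dna(rev_primer, "reverse primer")
  if (is.null(t3_primer)) t3_primer <- construct$t3_primer
  t3_primer <- check_dna(t3_primer, "T3 primer")
  # linearise with the T3 primer at the origin so "downstream" is well defined
  lin <- rotate_seq(construct$seq, construct$t3_offset)
  if (substr(lin, 1L, nchar(t3_primer)) != t3_primer) {
    stop("T3 primer does not match the promoter position")
  }
  site <- revcomp(rev_primer)
  hit <- regexpr(site, lin, fixed = TRUE)[1]
  if (hit == -1L) return(NA_integer_)
  len <- hit - 1L + nchar(site)
  if (len > max_product) return(NA_integer_)
  as.integer(len)
}
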