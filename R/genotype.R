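# Genotyping of sequenced reads against a wild-type amplicon.
#
# Non-homologous end joining after a ZFN double-strand break leaves small
# substitutions, deletions and insertions around the cut site.  Reads are
# globally aligned to the wild type with affine gap penalties chosen so that
# a contiguous deletion -- the dominant repair outcome -- aligns as a single
# gap, then each alignment column is classified.

#' Alignment parameters
#'
#' Affine-gap global alignment scores.  Defaults: match +1, mismatch -1,
#' gap open 4, gap extension 0.5 (penalties are positive; a gap of length L
#' costs open + L * extension).
#'
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Positive gap penalties, `gap_open > gap_extend >= 0`.
#' @return An `alignment_params` list.
#' @export
alignment_params <- function(match = 1, mismatch = -1, gap_open = 4, gap_extend = 0.5) {
  stopifnot(gap_open > gap_extend, gap_extend >= 0, match > mismatch)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

#' Globally align a read against the wild-type sequence
#'
#' Needleman-Wunsch with affine gaps (via Biostrings).  Tie-breaking among
#' equal-scoring alignments is deterministic.
#'
#' @param wt Wild-type amplicon sequence.
#' @param read Read sequence.
#' @param params An [alignment_params()].
#' @return An object of class `wt_alignment`: list with the gapped strings
#'   `wt_aln`, `read_aln`, and `score`.
#' @export
align_pair <- function(wt, read, params = alignment_params()) {
  wt <- check_dna(wt, "wild-type sequence")
  read <- check_dna(read, "read")
  if (nchar(wt) == 0L || nchar(read) == 0L) stop("empty sequence")
  stopifnot(inherits(params, "alignment_params"))
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(wt), Biostrings::DNAString(read),
    substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    type = "global")
  structure(
    list(wt_aln = as.character(Biostrings::alignedPattern(pa)),
         read_aln = as.character(Biostrings::alignedSubject(pa)),
         score = Biostrings::score(pa)),
    class = "wt_alignment"
  )
}

#' @export
print.wt_alignment <- function(x, ...) {
  cat("<wt_alignment> score ", x$score, "\n  wt   ", x$wt_aln,
      "\n  read ", x$read_aln, "\n", sep = "")
  invisible(x)
}

#' Classify an alignment into substitution/deletion/insertion counts
#'
#' Counts aligned columns: a mismatch between two bases is a substitution, a
#' wild-type base opposite a gap is a deleted base, a read base opposite a
#' gap is an inserted base.  The canonical label lists the non-zero counts
#' as `"<n> D, <n> S, <n> I"` (deletions first, matching the convention of
#' published mutation tables) or `"WT"` when all are zero.
#'
#' @param alignment An [align_pair()] result.
#' @return An object of class `edit_call`: list with `n_sub`, `n_del`,
#'   `n_ins`, `label`.
#' @examples
#' wt <- "GGTCCACACCCGCCCGAGGAGGAAGATGTCA"
#' classify_edits(align_pair(wt, "GGTCCACACCCACCGGAGGAGGAAGATGTCA"))
#' @export
classify_edits <- function(alignment) {
  stopifnot(inherits(alignment, "wt_alignment"))
  a <- strsplit(alignment$wt_aln, "")[[1]]
  b <- strsplit(alignment$read_aln, "")[[1]]
  stopifnot(length(a) == length(b))
  n_del <- sum(b == "-" & a != "-")
  n_ins <- sum(a == "-" & b != "-")
  n_sub <- sum(a != "-" & b != "-" & a != b)
  edit_call(n_sub, n_del, n_ins)
}

edit_call <- function(n_sub, n_del, n_ins) {
  parts <- c(
    if (n_del > 0) paste(n_del, "D"),
    if (n_sub > 0) paste(n_sub, "S"),
    if (n_ins > 0) paste(n_ins, "I")
  )
  structure(
    list(n_sub = as.integer(n_sub), n_del = as.integer(n_del),
         n_ins = as.integer(n_ins),
         label = if (length(parts)) paste(parts, collapse = ", ") else "WT"),
    class = "edit_call"
  )
}

#' @export
print.edit_call <- function(x, ...) {
  cat("<edit_call> ", x$label, "\n", sep = "")
  invisible(x)
}

#' Genotype a set of reads against a wild-type amplicon
#'
#' @param wt Wild-type amplicon.
#' @param reads Character vector of reads (names used as read ids).
#' @param params An [alignment_params()].
#' @return Data frame with one row per read: `read_id`, `n_sub`, `n_del`,
#'   `n_ins`, `label`.
#' @export
genotype_reads <- function(wt, reads, params = alignment_params()) {
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  rows <- lapply(seq_along(reads), function(i) {
    call <- classify_edits(align_pair(wt, reads[[i]], params))
    data.frame(read_id = ids[i], n_sub = call$n_sub, n_del = call$n_del,
               n_ins = call$n_ins, label = call$label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tally edit calls into a summary table
#'
#' @param calls A list of `edit_call` objects or a [genotype_reads()] data
#'   frame.
#' @return List with `examined`, `mutated`, and `genotypes` (a data frame of
#'   distinct labels with multiplicities, wild type first).
#' @export
tally_calls <- function(calls) {
  if (is.data.frame(calls)) {
    labels <- calls$label
  } else {
    labels <- vapply(calls, function(x) x$label, character(1))
  }
  examined <- length(labels)
  mutated <- sum(labels != "WT")
  if (examined == 0L) {
    return(list(examined = 0L, mutated = 0L,
                genotypes = data.frame(label = character(0), n = integer(0))))
  }
  tab <- as.data.frame(table(label = labels), stringsAsFactors = FALSE)
  names(tab)[2] <- "n"
  tab <- tab[order(tab$label != "WT", tab$label), , drop = FALSE]
  rownames(tab) <- NULL
  list(examined = examined, mutated = mutated, genotypes = tab)
}

#' Predict T7 endonuclease I heteroduplex cleavage fragments
#'
#' When a wild-type strand re-anneals with a mutant strand, the mismatch or
#' indel bubble is cleaved by T7 endonuclease I.  The cut is placed at the
#' first non-matching column of the wild-type/mutant alignment; the two
#' fragment lengths are reported on the wild-type amplicon and always sum to
#' its length.
#'
#' @param wt_amplicon,mutant_amplicon Amplicon sequences sharing flanking
#'   primer regions.
#' @param params An [alignment_params()].
#' @return Integer vector of the two fragment lengths, or `NULL` for
#'   identical sequences.
#' @export
t7e1_predict <- function(wt_amplicon, mutant_amplicon, params = alignment_params()) {
  wt_amplicon <- check_dna(wt_amplicon, "wild-type amplicon")
  mutant_amplicon <- check_dna(mutant_amplicon, "mutant amplicon")
  if (wt_amplicon == mutant_amplicon) return(NULL)
  aln <- align_pair(wt_amplicon, mutant_amplicon, params)
  a <- strsplit(aln$wt_aln, "")[[1]]
  b <- strsplit(aln$read_aln, "")[[1]]
  bad <- which(a != b)
  first <- bad[1]
  # cut position on the wild-type amplicon: number of wt bases strictly
  # before the first divergent column, so a lesion at 0-based offset p gives
  # fragments (p, n - p)
  cut <- sum(a[seq_len(first - 1L)] != "-")
  n <- nchar(wt_amplicon)
  c(cut, n - cut)
}
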