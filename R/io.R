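# Small I/O wrappers around Biostrings for the formats the tools consume.

#' Read DNA sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta_dna <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write DNA sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta_dna <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(toupper(unlist(seqs)))
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read sequencing reads from FASTA or one-sequence-per-line text
#'
#' @param path Input file; format auto-detected from the first character
#'   (`>` means FASTA).
#' @return Named character vector of reads.
#' @export
read_reads <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, ">")) {
    return(read_fasta_dna(path))
  }
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  stats::setNames(toupper(lines), paste0("read", seq_along(lines)))
}
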