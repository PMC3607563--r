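# Low-level sequence helpers. All user-facing sequences are plain uppercase
# character strings; Biostrings does the heavy lifting underneath.

#' Reverse complement of a DNA string
#'
#' @param x A DNA string (A/C/G/T, optionally N).
#' @return The reverse complement, uppercase.
#' @examples
#' revcomp("GAGCTGTGGGCC")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

#' Translate a DNA string under the standard genetic code
#'
#' @param x A DNA string whose length is a multiple of 3.
#' @return Amino-acid string in one-letter code.
#' @export
translate_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) %% 3L != 0L) {
    stop("sequence length ", nchar(x), " is not a multiple of 3")
  }
  as.character(Biostrings::translate(Biostrings::DNAString(toupper(x))))
}

# Validate an uppercase ACGT string (N optionally allowed); returns it normalised.
check_dna <- function(x, what = "sequence", allow_n = FALSE, len = NULL) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string")
  }
  x <- toupper(x)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  if (!grepl(paste0("^[", alphabet, "]*$"), x)) {
    stop(what, " contains characters outside [", alphabet, "]")
  }
  if (!is.null(len) && nchar(x) != len) {
    stop(what, " must be ", len, " nt, got ", nchar(x))
  }
  x
}

check_aa <- function(x, what = "helix", len = 7L) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string")
  }
  x <- toupper(x)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]*$", x)) {
    stop(what, " contains invalid amino-acid letters: ", x)
  }
  if (!is.null(len) && nchar(x) != len) {
    stop(what, " must be ", len, " residues, got ", nchar(x))
  }
  x
}

# Split a DNA string into consecutive codons.
split_codons <- function(x) {
  n <- nchar(x)
  stopifnot(n %% 3L == 0L)
  substring(x, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
}

# Synonymous codons for one amino acid, standard code, sorted for determinism.
synonymous_codons <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  out <- sort(names(gc)[gc == aa])
  if (length(out) == 0L) stop("no codon for residue '", aa, "'")
  out
}
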