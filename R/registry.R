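# Packaged registry of triplet -> DNA-recognition-helix -> first-PCR-primer
# entries, transcribed from the published primer table of the OLTA method.
#
# Each entry carries the 3-nt target triplet (half-site strand, read 5'->3'),
# the 7-residue recognition helix, the forward and reverse first-PCR primers
# and their published mismatch counts ("NDN") against the zinc-finger
# template.  Sequences are stored uppercase; the published mixed-case form
# (lowercase = mismatch to the template) is kept alongside as provenance.
# One reverse primer (GTC) ships with a single-nucleotide correction, flagged
# in the `corrected` column: the published string disagrees with its own
# mismatch count, its own lowercase mask, and the annotated helix, all three
# of which the one-letter correction restores.  Four published counts are
# annotation miscounts (off by one against any recomputation from the
# published sequences); they are packaged verbatim and surfaced by
# `validate_registry()`.

registry_path <- function() {
  system.file("extdata", "helix_registry.tsv", package = "olta", mustWork = TRUE)
}

load_registry_tsv <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("triplet", "helix", "fwd_printed", "fwd_ndn", "rev_printed", "rev_ndn")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) stop("registry file lacks columns: ", paste(missing, collapse = ", "))
  if (!"rev_seq_corrected" %in% names(raw)) raw$rev_seq_corrected <- "."
  if (!"note" %in% names(raw)) raw$note <- "."
  corrected <- raw$rev_seq_corrected != "."
  df <- data.frame(
    triplet = toupper(raw$triplet),
    helix = toupper(raw$helix),
    fwd_primer = toupper(raw$fwd_printed),
    rev_primer = toupper(ifelse(corrected, raw$rev_seq_corrected, raw$rev_printed)),
    fwd_ndn = as.integer(raw$fwd_ndn),
    rev_ndn = as.integer(raw$rev_ndn),
    fwd_printed = raw$fwd_printed,
    rev_printed = raw$rev_printed,
    corrected = corrected,
    note = ifelse(raw$note == ".", "", raw$note),
    stringsAsFactors = FALSE
  )
  validate_entry_fields(df)
  df
}

validate_entry_fields <- function(df) {
  stopifnot(!anyDuplicated(df$triplet))
  for (i in seq_len(nrow(df))) {
    check_dna(df$triplet[i], "triplet", len = 3L)
    check_aa(df$helix[i], "helix", len = 7L)
    check_dna(df$fwd_primer[i], "forward primer")
    check_dna(df$rev_primer[i], "reverse primer")
    if (nchar(df$fwd_primer[i]) > 29L || nchar(df$rev_primer[i]) > 29L) {
      stop("primer for ", df$triplet[i], " exceeds 29 nt")
    }
    tr <- translate_dna(substr(df$fwd_primer[i], 1L, 21L))
    if (tr != df$helix[i]) {
      stop("forward primer for ", df$triplet[i], " encodes ", tr,
           " but helix is annotated ", df$helix[i])
    }
    if (!endsWith(df$fwd_primer[i], OLTA_FWD_TAIL)) {
      stop("forward primer for ", df$triplet[i], " lacks the common tail ", OLTA_FWD_TAIL)
    }
    if (!endsWith(df$rev_primer[i], OLTA_REV_ANCHOR)) {
      stop("reverse primer for ", df$triplet[i], " lacks the constant anchor ", OLTA_REV_ANCHOR)
    }
    if (df$fwd_ndn[i] < 0L || df$fwd_ndn[i] > 11L || df$rev_ndn[i] < 0L || df$rev_ndn[i] > 11L) {
      stop("mismatch count for ", df$triplet[i], " outside [0, 11]")
    }
  }
  invisible(df)
}

#' Load the helix registry
#'
#' Returns the packaged registry of 21 triplet/helix/primer entries,
#' optionally overlaid with user entries supplied in the same TSV dialect
#' (columns `triplet`, `helix`, `fwd_printed`, `fwd_ndn`, `rev_printed`,
#' `rev_ndn`).  User entries must pass the same structural invariants as
#' packaged ones (primer length, helix translation, constant 3' regions,
#' mismatch cap) and may not redefine a packaged triplet.
#'
#' @param user_tsv Optional path to a user overlay TSV.
#' @return An object of class `helix_registry` (a data frame).
#' @examples
#' reg <- helix_registry()
#' registry_size(reg)
#' @export
helix_registry <- function(user_tsv = NULL) {
  df <- load_registry_tsv(registry_path())
  df$source <- "packaged"
  if (!is.null(user_tsv)) {
    user <- load_registry_tsv(user_tsv)
    clash <- intersect(user$triplet, df$triplet)
    if (length(clash)) {
      stop("user overlay redefines packaged triplet(s): ", paste(clash, collapse = ", "))
    }
    user$source <- "user"
    df <- rbind(df, user)
  }
  class(df) <- c("helix_registry", "data.frame")
  df
}

#' @export
print.helix_registry <- function(x, ...) {
  cat("<helix_registry> ", nrow(x), " entries (",
      sum(x$source == "packaged"), " packaged)\n", sep = "")
  print.data.frame(x[, c("triplet", "helix", "fwd_ndn", "rev_ndn")], row.names = FALSE)
  invisible(x)
}

#' Number of entries in a registry
#' @param registry A [helix_registry()].
#' @return Integer count.
#' @export
registry_size <- function(registry = helix_registry()) {
  stopifnot(inherits(registry, "helix_registry"))
  nrow(registry)
}

#' Look up the registry entry for a DNA triplet
#'
#' @param triplet 3-nt DNA triplet on the half-site strand, read 5'->3'.
#' @param registry A [helix_registry()].
#' @return A one-row list with fields `triplet`, `helix`, `fwd_primer`,
#'   `rev_primer`, `fwd_ndn`, `rev_ndn`.
#' @examples
#' lookup_helix("GAG")$helix
#' @export
lookup_helix <- function(triplet, registry = helix_registry()) {
  triplet <- check_dna(triplet, "triplet", len = 3L)
  stopifnot(inherits(registry, "helix_registry"))
  i <- match(triplet, registry$triplet)
  if (is.na(i)) {
    stop("no helix available for triplet ", triplet)
  }
  as.list(registry[i, c("triplet", "helix", "fwd_primer", "rev_primer",
                        "fwd_ndn", "rev_ndn", "fwd_printed", "rev_printed",
                        "corrected", "note")])
}

#' Recompute and check all registry mismatch counts against a template
#'
#' For every entry the forward and reverse primer mismatch counts are
#' recomputed as the positionwise distance against the template's annealing
#' references and compared with the packaged annotations.  Discrepancies are
#' reported, not raised: four published annotations are known miscounts
#' (see the `note` column).
#'
#' @param registry A [helix_registry()].
#' @param template A [build_template()] model.
#' @return An object of class `registry_validation`: data frame with one row
#'   per entry and columns `fwd_recomputed`, `rev_recomputed`, `fwd_match`,
#'   `rev_match`, plus helper columns carried over from the registry.
#' @examples
#' rep <- validate_registry()
#' sum(rep$fwd_match) + sum(rep$rev_match)
#' @export
validate_registry <- function(registry = helix_registry(), template = build_template()) {
  stopifnot(inherits(registry, "helix_registry"), inherits(template, "zf_template"))
  fwd_re <- vapply(registry$fwd_primer, count_mismatches, integer(1),
                   b = template$fwd_ref)
  rev_re <- vapply(registry$rev_primer, count_mismatches, integer(1),
                   b = template$rev_ref)
  out <- data.frame(
    triplet = registry$triplet,
    helix = registry$helix,
    fwd_ndn = registry$fwd_ndn,
    fwd_recomputed = as.integer(fwd_re),
    fwd_match = as.integer(fwd_re) == registry$fwd_ndn,
    rev_ndn = registry$rev_ndn,
    rev_recomputed = as.integer(rev_re),
    rev_match = as.integer(rev_re) == registry$rev_ndn,
    fwd_anchor_ok = vapply(registry$fwd_primer, check_three_prime_anchor,
                           logical(1), reference = template$fwd_ref, k = 8L),
    rev_anchor_ok = vapply(registry$rev_primer, check_three_prime_anchor,
                           logical(1), reference = template$rev_ref, k = 7L),
    note = registry$note,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("registry_validation", "data.frame")
  out
}

#' @export
print.registry_validation <- function(x, ...) {
  ok <- sum(x$fwd_match) + sum(x$rev_match)
  cat("<registry_validation> ", ok, "/", 2L * nrow(x),
      " mismatch counts confirmed\n", sep = "")
  bad <- x[!x$fwd_match | !x$rev_match, , drop = FALSE]
  if (nrow(bad)) {
    cat("discrepant entries:\n")
    print.data.frame(bad[, c("triplet", "fwd_ndn", "fwd_recomputed",
                             "rev_ndn", "rev_recomputed")], row.names = FALSE)
  }
  invisible(x)
}
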