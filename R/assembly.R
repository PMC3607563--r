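# Three-step overlap-extension assembly of zinc-finger arrays.
#
# 1st PCR: for an n-finger array, n-1 partial fragments are amplified from
# the two-helix template, each running from the codons of helix i to one
# framework nucleotide past the codons of helix i+1 (primer pair: forward
# primer of finger i, reverse primer of finger i+1).
#
# 2nd PCR: the fragments are combined without primers; shared helix codons
# at fragment ends act as the overlap regions.
#
# 3rd PCR: end primers (ZF1 forward, ZFn reverse) amplify the assembled
# chains; gel ladders arise because every chain whose ends carry the common
# tail/anchor amplifies.

#' Plan the OLTA reactions for a finger array
#'
#' @param array Character vector of DNA triplets in finger order (ZF1 first),
#'   or of 7-residue helices when `by = "helix"`.
#' @param registry A [helix_registry()] (used to resolve triplets).
#' @param min_fingers,max_fingers Allowed array sizes (default 4-6).
#' @param by Whether `array` lists triplets (default) or helices.
#' @return An object of class `reaction_plan`: list with `fragments` (data
#'   frame of first-PCR reactions: fragment name, forward/reverse primer
#'   names and sequences), `second_pcr` (data frame of the mixing recipe:
#'   fragment and volume in ul), and `third_pcr` (end primer names and
#'   sequences).
#' @examples
#' plan_reactions(c("GCC", "TGG", "CTG", "GAG"))
#' @export
plan_reactions <- function(array, registry = helix_registry(),
                           min_fingers = 4L, max_fingers = 6L,
                           by = c("triplet", "helix")) {
  by <- match.arg(by)
  n <- length(array)
  if (n < min_fingers || n > max_fingers) {
    stop("array has ", n, " fingers; allowed range is [",
         min_fingers, ", ", max_fingers, "]")
  }
  if (by == "triplet") {
    entries <- lapply(array, lookup_helix, registry = registry)
    labels <- toupper(array)
    fwd <- vapply(entries, `[[`, character(1), "fwd_primer")
    rev <- vapply(entries, `[[`, character(1), "rev_primer")
    helices <- vapply(entries, `[[`, character(1), "helix")
  } else {
    labels <- toupper(array)
    helices <- labels
    fwd <- rev <- rep(NA_character_, n)
  }
  frag <- data.frame(
    fragment = paste0("ZF", seq_len(n - 1L), "-ZF", seq_len(n - 1L) + 1L),
    fwd_name = paste0(labels[-n], "-Fw"),
    rev_name = paste0(labels[-1L], "-Rv"),
    fwd_primer = fwd[-n],
    rev_primer = rev[-1L],
    stringsAsFactors = FALSE
  )
  # published second-PCR mixing recipe: flanking fragments at 0.5 ul,
  # central fragment(s) at 1.5 ul
  vol <- switch(as.character(n),
    "4" = c(0.5, 1.5, 0.5),
    "5" = c(0.5, 1.5, 1.5, 0.5),
    "6" = c(0.5, 0.5, 1.5, 0.5, 0.5),
    rep(0.5, n - 1L)
  )
  structure(
    list(
      array = labels,
      helices = helices,
      fragments = frag,
      second_pcr = data.frame(fragment = frag$fragment, volume_ul = vol,
                              stringsAsFactors = FALSE),
      third_pcr = data.frame(
        role = c("forward", "reverse"),
        name = c(paste0(labels[1L], "-Fw"), paste0(labels[n], "-Rv")),
        primer = c(fwd[1L], rev[n]),
        stringsAsFactors = FALSE
      )
    ),
    class = "reaction_plan"
  )
}

#' @export
print.reaction_plan <- function(x, ...) {
  cat("<reaction_plan> ", length(x$array), "-finger array: ",
      paste(x$array, collapse = " "), "\n", sep = "")
  cat("1st PCR (", nrow(x$fragments), " reactions):\n", sep = "")
  print.data.frame(x$fragments[, c("fragment", "fwd_name", "rev_name")],
                   row.names = FALSE)
  cat("2nd PCR mix:\n")
  print.data.frame(x$second_pcr, row.names = FALSE)
  cat("3rd PCR end primers: ", paste(x$third_pcr$name, collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' Simulate a first-PCR partial fragment
#'
#' Builds the amplicon produced from the template by the forward primer of
#' `helix_i` and the reverse primer of `helix_j`: the designed codons of
#' helix i, the constant tail, the internal framework, the upstream
#' framework, the designed codons of helix j, and one trailing framework
#' nucleotide.  The fragment length always equals the template length.
#'
#' @param template A [build_template()] model.
#' @param helix_i,helix_j 7-residue helices (5' and 3' fingers of the
#'   fragment).
#' @param max_mismatch Designer cap passed to [design_primer_pair()].
#' @return An object of class `partial_fragment`: list with `seq`, `helix_i`,
#'   `helix_j`, `fwd_primer`, `rev_primer`, `length`.
#' @export
synthesize_fragment <- function(template, helix_i, helix_j, max_mismatch = 11L) {
  stopifnot(inherits(template, "zf_template"))
  di <- design_primer_pair(helix_i, template, max_mismatch)
  dj <- design_primer_pair(helix_j, template, max_mismatch)
  seq <- paste0(di$fwd_primer, template$internal_framework, revcomp(dj$rev_primer))
  structure(
    list(seq = seq, helix_i = di$helix, helix_j = dj$helix,
         fwd_primer = di$fwd_primer, rev_primer = dj$rev_primer,
         length = nchar(seq)),
    class = "partial_fragment"
  )
}

# longest exact suffix(a)/prefix(b) agreement, capped at the shorter sequence
suffix_prefix_overlap <- function(a, b) {
  kmax <- min(nchar(a), nchar(b))
  for (k in kmax:1) {
    if (substr(a, nchar(a) - k + 1L, nchar(a)) == substr(b, 1L, k)) return(k)
  }
  0L
}

#' Simulate overlap-extension joining of partial fragments
#'
#' Builds a directed graph with an edge i -> j whenever the 3' suffix of
#' fragment i exactly equals the 5' prefix of fragment j over at least
#' `min_overlap` nt, then enumerates every maximal simple chain (a chain not
#' extendable at either end without reusing a fragment).  Arrays whose
#' helices are all distinct yield exactly one chain; a repeated helix creates
#' branch points and therefore multiple, possibly mis-ordered, products --
#' the misassembly mode observed on gels as extra ladder bands.
#'
#' @param fragments List of [synthesize_fragment()] results (length >= 1).
#' @param min_overlap Minimum exact overlap in nt (default 21, the helix
#'   length; designed fragments sharing a helix overlap over 22 nt because
#'   the framework nucleotide after every helix is the same).
#' @param intended Optional character vector: the helix sequence of the
#'   intended array (ZF1 first) used to set `on_pathway`.  Defaults to the
#'   chain implied by the fragment list order.
#' @return An object of class `assembly_products`: list of products, each
#'   with `chain` (fragment indices), `seq`, `helices`, `on_pathway`,
#'   `length`; plus attribute `ambiguous` (TRUE when more than one maximal
#'   chain exists).
#' @export
simulate_overlap_assembly <- function(fragments, min_overlap = 21L, intended = NULL) {
  if (inherits(fragments, "partial_fragment")) fragments <- list(fragments)
  stopifnot(length(fragments) >= 1L)
  n <- length(fragments)
  fragments <- unname(fragments)
  if (is.null(intended)) {
    intended <- c(unname(vapply(fragments, `[[`, character(1), "helix_i")),
                  fragments[[n]]$helix_j)
  } else {
    intended <- unname(toupper(intended))
  }
  if (n == 1L) {
    prod <- list(chain = 1L, seq = fragments[[1L]]$seq,
                 helices = c(fragments[[1L]]$helix_i, fragments[[1L]]$helix_j),
                 on_pathway = identical(
                   c(fragments[[1L]]$helix_i, fragments[[1L]]$helix_j), intended),
                 length = fragments[[1L]]$length)
    out <- structure(list(prod), class = "assembly_products",
                     ambiguous = FALSE, intended = intended)
    return(out)
  }
  ov <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) ov[i, j] <- suffix_prefix_overlap(fragments[[i]]$seq, fragments[[j]]$seq)
  }
  edge <- ov >= min_overlap

  # enumerate maximal simple paths by DFS from every node
  paths <- list()
  extend <- function(path) {
    last <- path[length(path)]
    nxt <- which(edge[last, ] & !(seq_len(n) %in% path))
    if (!length(nxt)) {
      # maximal to the right; maximal to the left iff no unused predecessor
      first <- path[1L]
      preds <- which(edge[, first] & !(seq_len(n) %in% path))
      if (!length(preds)) paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (j in nxt) extend(c(path, j))
  }
  for (s in seq_len(n)) extend(s)
  paths <- unique(paths)
  # drop paths that are sub-paths of longer reported paths
  is_subchain <- function(p, q) {
    if (length(p) >= length(q)) return(FALSE)
    for (off in 0:(length(q) - length(p))) {
      if (identical(q[off + seq_along(p)], p)) return(TRUE)
    }
    FALSE
  }
  keep <- vapply(paths, function(p) !any(vapply(paths, function(q) is_subchain(p, q),
                                                logical(1))), logical(1))
  paths <- paths[keep]

  products <- lapply(paths, function(p) {
    seq <- fragments[[p[1L]]]$seq
    helices <- c(fragments[[p[1L]]]$helix_i, fragments[[p[1L]]]$helix_j)
    for (k in seq_along(p)[-1L]) {
      o <- ov[p[k - 1L], p[k]]
      seq <- paste0(seq, substr(fragments[[p[k]]]$seq, o + 1L, nchar(fragments[[p[k]]]$seq)))
      helices <- c(helices, fragments[[p[k]]]$helix_j)
    }
    list(chain = p, seq = seq, helices = helices,
         on_pathway = identical(helices, intended), length = nchar(seq))
  })
  structure(products, class = "assembly_products",
            ambiguous = length(products) > 1L, intended = intended)
}

#' @export
print.assembly_products <- function(x, ...) {
  cat("<assembly_products> ", length(x), " maximal chain(s)",
      if (attr(x, "ambiguous")) " [AMBIGUOUS]", "\n", sep = "")
  for (p in x) {
    cat(sprintf("  chain %s  %d nt  %s%s\n",
                paste(p$chain, collapse = "->"), p$length,
                paste(p$helices, collapse = "|"),
                if (p$on_pathway) "  (on pathway)" else ""))
  }
  invisible(x)
}

#' Simulate the third PCR: end-primer amplification and the band ladder
#'
#' Retains every assembly product to which both end primers can anneal,
#' modelling annealing as an exact match of the primer's 3'-terminal anchor
#' at the corresponding position of the product end (8 nt for the forward
#' primer's common tail, 7 nt for the reverse primer's constant anchor).
#' Because those anchors are shared by all fragments, every chain amplifies
#' and the predicted band lengths form the ladder seen on gels; the band
#' whose product is on-pathway is marked as the intended one.  Amplified
#' products are flagged `a_tailed`: a non-proofreading polymerase leaves a
#' single 3' A overhang used later for TA cloning.
#'
#' @param products An [simulate_overlap_assembly()] result.
#' @param end_fwd_primer,end_rev_primer End primer sequences (ZF1 forward,
#'   ZFn reverse).
#' @param fwd_anchor,rev_anchor Anchor lengths (default 8 and 7).
#' @return Data frame with one row per retained product: `length`,
#'   `on_pathway`, `intended`, `a_tailed`, and the product index.
#' @export
simulate_third_pcr <- function(products, end_fwd_primer, end_rev_primer,
                               fwd_anchor = 8L, rev_anchor = 7L) {
  stopifnot(inherits(products, "assembly_products"))
  end_fwd_primer <- check_dna(end_fwd_primer, "forward end primer")
  end_rev_primer <- check_dna(end_rev_primer, "reverse end primer")
  nf <- nchar(end_fwd_primer)
  fa <- substr(end_fwd_primer, nf - fwd_anchor + 1L, nf)
  nr <- nchar(end_rev_primer)
  ra <- substr(end_rev_primer, nr - rev_anchor + 1L, nr)
  rows <- list()
  for (i in seq_along(products)) {
    p <- products[[i]]
    if (nchar(p$seq) < max(nf, nr)) next
    # forward primer 3' anchor sits at positions [nf - anchor, nf) of the product
    fwd_ok <- substr(p$seq, nf - fwd_anchor + 1L, nf) == fa
    # reverse primer anneals to the 3' end of the plus strand
    tail_rc <- revcomp(substr(p$seq, nchar(p$seq) - nr + 1L, nchar(p$seq)))
    rev_ok <- substr(tail_rc, nr - rev_anchor + 1L, nr) == ra
    if (fwd_ok && rev_ok) {
      rows[[length(rows) + 1L]] <- data.frame(
        product = i, length = p$length, on_pathway = p$on_pathway,
        a_tailed = TRUE, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(product = integer(0), length = integer(0),
                      on_pathway = logical(0), a_tailed = logical(0),
                      intended = logical(0)))
  }
  out <- do.call(rbind, rows)
  out$intended <- out$on_pathway
  out[order(out$length), , drop = FALSE]
}
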