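# Paired ZFN half-site scanner.
#
# A ZFN pair binds two half-sites on opposite strands separated by a 5-6 bp
# spacer in which the FokI domains dimerise and cut.  On the plus strand the
# arrangement is
#
#     5'- ... [revcomp(left half-site)] [spacer] [right half-site] ... -3'
#
# with the left half-site read 5'->3' on the minus strand.  A half-site is
# usable only when every one of its 3-bp triplets has a recognition helix in
# the registry.  Within each half-site the N-terminal finger (ZF1) binds the
# 3'-most triplet, so finger order is the reverse of the triplet reading
# order.

#' Scan parameters
#'
#' @param min_fingers,max_fingers Allowed fingers per half-site (default 4-6).
#' @param spacer_min,spacer_max Allowed spacer length in nt (default 5-6).
#' @param registry A [helix_registry()].
#' @return A `scan_params` list.
#' @export
scan_params <- function(min_fingers = 4L, max_fingers = 6L,
                        spacer_min = 5L, spacer_max = 6L,
                        registry = helix_registry()) {
  stopifnot(
    min_fingers >= 3L, min_fingers <= max_fingers,
    spacer_min > 0L, spacer_min <= spacer_max,
    inherits(registry, "helix_registry")
  )
  structure(
    list(min_fingers = as.integer(min_fingers), max_fingers = as.integer(max_fingers),
         spacer_min = as.integer(spacer_min), spacer_max = as.integer(spacer_max),
         registry = registry),
    class = "scan_params"
  )
}

#' Finger-order assignment for a half-site
#'
#' Splits a half-site (read 5'->3' on its own strand) into triplets and
#' returns them in finger order: ZF1, the N-terminal finger, binds the
#' 3'-most triplet.
#'
#' @param site_seq Half-site DNA, length a multiple of 3.
#' @return Character vector of triplets, ZF1 first.
#' @examples
#' finger_order("AGAAAGACTGGAGTTGCA")
#' @export
finger_order <- function(site_seq) {
  site_seq <- check_dna(site_seq, "half-site")
  if (nchar(site_seq) %% 3L != 0L) {
    stop("half-site length ", nchar(site_seq), " is not a multiple of 3")
  }
  rev(split_codons(site_seq))
}

# registry membership of every triplet starting position, plus strand and
# (reverse-complemented) minus strand
triplet_masks <- function(seq, registry) {
  n <- nchar(seq)
  if (n < 3L) return(list(plus = logical(0), minus = logical(0)))
  starts <- seq_len(n - 2L)
  tr <- substring(seq, starts, starts + 2L)
  comp <- chartr("ACGT", "TGCA", tr)
  rc3 <- vapply(strsplit(comp, ""), function(x) paste(rev(x), collapse = ""), character(1))
  list(plus = tr %in% registry$triplet, minus = rc3 %in% registry$triplet)
}

#' Scan a sequence for paired ZFN half-sites
#'
#' Reports every arrangement revcomp(left) + spacer + right on the plus
#' strand where both half-sites decompose fully into registry triplets and
#' the spacer length is within range.  A half-site pair and its mirror image
#' found on the reverse complement describe the same physical site; results
#' are reported once, in plus-strand coordinates, with the left half-site
#' being the minus-strand half-site whose footprint lies upstream.
#' Overlapping and nested candidate pairs are all reported, sorted by
#' position; no greedy suppression is applied.  Setting `rank_gnn = TRUE`
#' additionally orders pairs by their fraction of GNN triplets (descending),
#' reflecting the practice of preferring GNN triplets when choosing sites.
#'
#' @param seq DNA string (N allowed; windows containing N are skipped).
#' @param params A [scan_params()] object.
#' @param rank_gnn Rank pairs by GNN-triplet fraction instead of position.
#' @return A data frame of class `zfn_site_pairs`; one row per pair with
#'   0-based half-open plus-strand coordinates (`start`, `end`), half-site
#'   sequences read 5'->3' on their own strands, triplet and finger-order
#'   strings (";"-separated), spacer sequence and length, finger counts and
#'   GNN fraction.
#' @examples
#' pairs <- scan_zfn_sites("AGGCCCACAGCTCTACGGCGACTGAGAGGAAG")
#' pairs$left_site
#' @export
scan_zfn_sites <- function(seq, params = scan_params(), rank_gnn = FALSE) {
  seq <- check_dna(seq, "sequence", allow_n = TRUE)
  stopifnot(inherits(params, "scan_params"))
  n <- nchar(seq)
  rows <- list()
  masks <- triplet_masks(seq, params$registry)
  fingers <- params$min_fingers:params$max_fingers
  for (kl in fingers) {
    for (kr in fingers) {
      for (sp in params$spacer_min:params$spacer_max) {
        span <- 3L * kl + sp + 3L * kr
        if (span > n) next
        for (t in seq_len(n - span + 1L)) {
          lpos <- t + 3L * (0:(kl - 1L))
          rstart <- t + 3L * kl + sp
          rpos <- rstart + 3L * (0:(kr - 1L))
          if (all(masks$minus[lpos]) && all(masks$plus[rpos])) {
            left_plus <- substr(seq, t, t + 3L * kl - 1L)
            right <- substr(seq, rstart, rstart + 3L * kr - 1L)
            left <- revcomp(left_plus)
            rows[[length(rows) + 1L]] <- data.frame(
              start = t - 1L,
              end = rstart + 3L * kr - 1L,
              left_start = t - 1L, left_end = t + 3L * kl - 1L,
              right_start = rstart - 1L, right_end = rstart + 3L * kr - 1L,
              left_site = left, right_site = right,
              left_fingers = kl, right_fingers = kr,
              spacer_seq = substr(seq, t + 3L * kl, rstart - 1L),
              spacer_len = sp,
              left_triplets = paste(split_codons(left), collapse = ";"),
              right_triplets = paste(split_codons(right), collapse = ";"),
              left_zf_order = paste(finger_order(left), collapse = ";"),
              right_zf_order = paste(finger_order(right), collapse = ";"),
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(
      start = integer(0), end = integer(0),
      left_start = integer(0), left_end = integer(0),
      right_start = integer(0), right_end = integer(0),
      left_site = character(0), right_site = character(0),
      left_fingers = integer(0), right_fingers = integer(0),
      spacer_seq = character(0), spacer_len = integer(0),
      left_triplets = character(0), right_triplets = character(0),
      left_zf_order = character(0), right_zf_order = character(0),
      stringsAsFactors = FALSE
    )
  } else {
    out <- do.call(rbind, rows)
    out <- out[!duplicated(out[, c("start", "end", "left_end", "right_start")]), ]
  }
  gnn <- function(tr) {
    t3 <- strsplit(tr, ";", fixed = TRUE)[[1]]
    mean(substr(t3, 1L, 1L) == "G")
  }
  out$gnn_fraction <- if (nrow(out)) {
    vapply(paste(out$left_triplets, out$right_triplets, sep = ";"), gnn, numeric(1),
           USE.NAMES = FALSE)
  } else numeric(0)
  ord <- if (rank_gnn) {
    order(-out$gnn_fraction, out$start, out$end)
  } else {
    order(out$start, out$end, out$left_end)
  }
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("zfn_site_pairs", "data.frame")
  out
}

#' Write scan results as a BED-like TSV
#'
#' Emits one line per half-site (two per pair): chrom, 0-based start, end,
#' name, fingers, strand, plus spacer length.
#'
#' @param pairs Result of [scan_zfn_sites()].
#' @param file Output path or connection.
#' @param chrom Chromosome/record name to use.
#' @export
write_site_bed <- function(pairs, file, chrom = "seq") {
  stopifnot(inherits(pairs, "zfn_site_pairs"))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    data.frame(
      chrom = chrom,
      start = c(p$left_start, p$right_start),
      end = c(p$left_end, p$right_end),
      name = c(paste0("pair", i, "_L:", p$left_site),
               paste0("pair", i, "_R:", p$right_site)),
      score = c(p$left_fingers, p$right_fingers),
      strand = c("-", "+"),
      spacer = p$spacer_len,
      stringsAsFactors = FALSE
    )
  })
  bed <- do.call(rbind, rows)
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bed)
}
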