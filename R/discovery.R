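# Stage 1 of the pipeline: identify TE-junction reads in every accession
# against the non-redundant end library, map the genomic flank of each
# junction read uniquely to the reference, pool the implied breakpoints
# across accessions, cluster them into the population locus set, and
# classify each locus as present in (Ref) or absent from (nonRef) the
# reference assembly.
#
# Breakpoints are stored as the 0-based insertion offset b: the TE sits
# between reference bases b-1 and b. `te_dir` records on which side of
# the insertion point the TE body lies in the reference frame (+1 right,
# -1 left); together with the element end side this fixes the insertion
# strand.

default_scoring <- function() list(match = 1, mismatch = -2, gap_open = -4,
                                   gap_extend = -1)

#' Find TE-junction reads in one accession
#'
#' A read qualifies iff a local alignment to some library end covers at
#' least `min_te_match` read bases at identity >= `min_ident`, reaches
#' the junction-forming terminus of that end (within `slack` bases), and
#' leaves >= `min_flank` unaligned contiguous bases on exactly the flank
#' side. Both read orientations are searched; the best-scoring end wins,
#' ties broken by library order.
#'
#' @param reads character vector of read sequences (names = read ids).
#' @param library end-library data.frame from [build_end_library()].
#' @param min_te_match minimum TE bases on the read (default 20).
#' @param min_flank minimum flank length in bp (default 30).
#' @param min_ident minimum alignment identity (default 0.95).
#' @param slack tolerated distance from the end terminus (default 2).
#' @param k seed k-mer size (default 15).
#' @return data.frame of junction reads: `read_id`, `end_id`, `te_id`,
#'   `family`, `superfamily`, `side` (element end side), `orient`,
#'   `te_start`/`te_end` (0-based span on the oriented read), `flank`.
#' @export
find_junction_reads <- function(reads, library, min_te_match = 20,
                                min_flank = 30, min_ident = 0.95, slack = 2,
                                k = 15) {
  if (!nrow(library)) stopf("empty end library")
  hits <- cpp_scan_junctions(unname(reads), library$sequence, library$side,
                             k, min_te_match, min_flank, min_ident, slack)
  if (!nrow(hits)) {
    return(data.frame(read_id = character(), end_id = character(),
                      te_id = character(), family = character(),
                      superfamily = character(), side = character(),
                      orient = character(), te_start = integer(),
                      te_end = integer(), flank = character(),
                      stringsAsFactors = FALSE))
  }
  rid <- names(reads) %||% as.character(seq_along(reads))
  oriented <- ifelse(hits$orient == "+", reads[hits$read],
                     unname(revcomp(reads[hits$read])))
  flank <- ifelse(hits$side == "L",
                  substr(oriented, 1, hits$te_start),
                  substr(oriented, hits$te_end + 1, nchar(oriented)))
  data.frame(read_id = rid[hits$read], end_id = library$end_id[hits$end],
             te_id = library$te_id[hits$end],
             family = library$family[hits$end],
             superfamily = library$superfamily[hits$end],
             side = hits$side, orient = hits$orient,
             te_start = hits$te_start, te_end = hits$te_end,
             flank = unname(flank), stringsAsFactors = FALSE)
}

#' Map flanks uniquely to the reference
#'
#' Exact-seed (`k`-mer) and ungapped score-maximising extension search of
#' both strands. A flank maps iff exactly one location attains the best
#' score and no second seeded location scores within `second_frac` of
#' it; otherwise it is discarded as non-unique.
#'
#' @param flanks character vector of flank sequences.
#' @param reference named character vector of reference sequences.
#' @param min_ident minimum identity over the aligned segment (default 0.95).
#' @param min_len minimum aligned segment length (default 30).
#' @param k seed size (default 15).
#' @param second_frac uniqueness threshold (default 0.95).
#' @return data.frame with one row per flank: `found`, `chrom`, `strand`,
#'   `ref_start`, `ref_end`, `f_start`, `f_end` (segment on the strand-
#'   oriented flank), `score`, `matches`.
#' @export
map_flanks <- function(flanks, reference, min_ident = 0.95, min_len = 30,
                       k = 15, second_frac = 0.95) {
  res <- cpp_map_flanks(unname(flanks), unname(reference), k, min_len,
                        min_ident, second_frac)
  res$chrom <- ifelse(res$found, names(reference)[res$rid], NA_character_)
  res$rid <- NULL
  res
}

#' @rdname map_flanks
#' @param flank a single flank sequence.
#' @return `map_flank()`: a one-row data.frame, or `NULL` when the flank
#'   has no unique placement.
#' @export
map_flank <- function(flank, reference, min_ident = 0.95, min_len = 30,
                      k = 15, second_frac = 0.95) {
  r <- map_flanks(flank, reference, min_ident, min_len, k, second_frac)
  if (!r$found[1]) NULL else r[1, , drop = FALSE]
}

# Convert mapped junction reads into candidate breakpoints.
# For an element-L junction the flank precedes the TE in read
# orientation, so the insertion offset is the reference coordinate of
# the flank's 3' end; mirrored for element-R junctions. A clip of more
# than `slack` bases at the flank's junction end invalidates the read.
junctions_to_candidates <- function(junc, mapped, accession, slack = 2) {
  keep <- mapped$found
  b <- integer(nrow(junc)); te_dir <- integer(nrow(junc))
  flen <- nchar(junc$flank)
  for (i in which(keep)) {
    plus <- mapped$strand[i] == "+"
    if (junc$side[i] == "L") {
      clip <- if (plus) flen[i] - mapped$f_end[i] else mapped$f_start[i]
      b[i] <- if (plus) mapped$ref_end[i] else mapped$ref_start[i]
      te_dir[i] <- if (plus) 1L else -1L
    } else {
      clip <- if (plus) mapped$f_start[i] else flen[i] - mapped$f_end[i]
      b[i] <- if (plus) mapped$ref_start[i] else mapped$ref_end[i]
      te_dir[i] <- if (plus) -1L else 1L
    }
    if (clip > slack) keep[i] <- FALSE
  }
  data.frame(accession = accession[keep], chrom = mapped$chrom[keep],
             pos = b[keep], te_id = junc$te_id[keep],
             family = junc$family[keep], superfamily = junc$superfamily[keep],
             side = junc$side[keep], te_dir = te_dir[keep],
             stringsAsFactors = FALSE)[order(b[keep]), , drop = FALSE]
}

#' Cluster candidate breakpoints into the population locus set
#'
#' Single-linkage clustering of candidates pooled over all accessions
#' that share (chrom, te_id, element end side, TE direction), linking
#' candidates whose positions differ by at most `window` bp. The locus
#' position is the median of member positions (the lower of the two
#' middle values for even clusters).
#'
#' @param candidates data.frame of candidate breakpoints (columns
#'   `accession`, `chrom`, `pos`, `te_id`, `family`, `superfamily`,
#'   `side`, `te_dir`).
#' @param window linkage window in bp (default 15).
#' @return data.frame of TE loci with `end_support = "single"` and
#'   per-locus total read `support`.
#' @export
cluster_breakpoints <- function(candidates, window = 15) {
  if (!nrow(candidates)) {
    return(data.frame(locus_id = character(), chrom = character(),
                      pos = integer(), te_id = character(),
                      family = character(), superfamily = character(),
                      side = character(), te_dir = integer(),
                      end_support = character(), ref_status = character(),
                      span_start = integer(), span_end = integer(),
                      support = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(candidates$chrom, candidates$te_id, candidates$side,
               candidates$te_dir, sep = "\r")
  out <- list()
  for (kk in unique(key)) {
    cc <- candidates[key == kk, , drop = FALSE]
    p <- sort(cc$pos)
    brk <- c(0L, which(diff(p) > window), length(p))
    for (g in seq_len(length(brk) - 1)) {
      v <- p[(brk[g] + 1):brk[g + 1]]
      out[[length(out) + 1]] <- data.frame(
        chrom = cc$chrom[1], pos = v[ceiling(length(v) / 2)],
        te_id = cc$te_id[1], family = cc$family[1],
        superfamily = cc$superfamily[1], side = cc$side[1],
        te_dir = cc$te_dir[1], end_support = "single",
        ref_status = NA_character_, span_start = NA_integer_,
        span_end = NA_integer_, support = length(v),
        stringsAsFactors = FALSE)
    }
  }
  loci <- do.call(rbind, out)
  loci <- loci[order(loci$chrom, loci$pos, loci$te_id, loci$side), , drop = FALSE]
  loci <- cbind(locus_id = sprintf("TEL%05d", seq_len(nrow(loci))), loci,
                stringsAsFactors = FALSE)
  rownames(loci) <- NULL
  loci
}

# Terminal end_len bases of an element, oriented so that the sequence
# runs away from the junction: side L as-is, side R reverse-complemented.
oriented_terminus <- function(seq, side, end_len = 150) {
  n <- nchar(seq)
  if (side == "L") substr(seq, 1, min(end_len, n))
  else unname(revcomp(substr(seq, max(1, n - end_len + 1), n)))
}

#' Classify loci as reference (Ref) or non-reference (nonRef)
#'
#' A locus is Ref iff the reference sequence adjacent to the breakpoint,
#' on the TE side of the insertion point, aligns to the corresponding TE
#' terminus at identity >= `min_ident` over >= `min_len` aligned bases.
#' For Ref loci the reference TE span is delimited by locating the
#' opposite terminus within twice the element length.
#'
#' @param loci locus data.frame from [cluster_breakpoints()].
#' @param reference named character vector of reference sequences.
#' @param elements TE element table ([te_elements()]).
#' @param min_len minimum aligned length (default 50).
#' @param min_ident minimum identity (default 0.90).
#' @param end_len terminus length used for comparison (default 150).
#' @return `loci` with `ref_status`, `span_start`, `span_end` filled in.
#' @export
classify_ref_status <- function(loci, reference, elements, min_len = 50,
                                min_ident = 0.90, end_len = 150) {
  sc <- default_scoring()
  for (i in seq_len(nrow(loci))) {
    elem <- elements$sequence[match(loci$te_id[i], elements$te_id)]
    len_e <- nchar(elem)
    ref <- reference[[loci$chrom[i]]]
    L <- nchar(ref); b <- loci$pos[i]; dir <- loci$te_dir[i]
    wl <- min(2L * end_len, if (dir == 1L) L - b else b)
    win <- if (dir == 1L) substr(ref, b + 1, b + wl)
           else unname(revcomp(substr(ref, b - wl + 1, b)))
    eseq <- oriented_terminus(elem, loci$side[i], end_len)
    is_ref <- FALSE
    if (nchar(win) >= min_len) {
      al <- cpp_sw_align(win, eseq, sc$match, sc$mismatch, sc$gap_open,
                         sc$gap_extend)
      is_ref <- al$aligned_len >= min_len &&
        al$matches / al$aligned_len >= min_ident &&
        al$a_start <= 10 && al$b_start <= 10
    }
    loci$ref_status[i] <- if (is_ref) "Ref" else "nonRef"
    if (is_ref) {
      # locate the far terminus to delimit the reference TE span
      far_side <- if (loci$side[i] == "L") "R" else "L"
      span_w <- min(2L * len_e, if (dir == 1L) L - b else b)
      if (dir == 1L) {
        wseq <- substr(ref, b + 1, b + span_w)
        tfar <- oriented_terminus(elem, far_side, end_len)
        # far terminus oriented away from junction; flip to genome frame
        al <- cpp_sw_align(wseq, unname(revcomp(tfar)), sc$match, sc$mismatch,
                           sc$gap_open, sc$gap_extend)
        if (al$aligned_len >= min_len && al$matches / al$aligned_len >= min_ident) {
          loci$span_start[i] <- b
          loci$span_end[i] <- b + al$a_end
        }
      } else {
        w0 <- b - span_w
        wseq <- substr(ref, w0 + 1, b)
        tfar <- oriented_terminus(elem, far_side, end_len)
        al <- cpp_sw_align(wseq, tfar, sc$match, sc$mismatch,
                           sc$gap_open, sc$gap_extend)
        if (al$aligned_len >= min_len && al$matches / al$aligned_len >= min_ident) {
          loci$span_start[i] <- w0 + al$a_start
          loci$span_end[i] <- b
        }
      }
    }
  }
  loci
}

#' Discover TE loci across a cohort
#'
#' Runs junction-read detection in every accession, maps all flanks to
#' the reference, pools candidate breakpoints, clusters them into the
#' non-redundant population locus set and classifies Ref/nonRef status.
#' The result is invariant to read input order.
#'
#' @param reads_by_accession named list of read vectors (one per
#'   accession; names = accession ids).
#' @param library end library ([build_end_library()]).
#' @param reference named character vector of reference sequences.
#' @param elements TE element table (for Ref classification).
#' @param params parameter list; see [pipeline_params()].
#' @return locus data.frame; attribute `"candidates"` holds the pooled
#'   per-accession candidate breakpoints.
#' @export
discover_loci <- function(reads_by_accession, library, reference, elements,
                          params = pipeline_params()) {
  p <- params$discover
  junc_all <- list(); acc_all <- list()
  for (acc in names(reads_by_accession)) {
    junc <- find_junction_reads(reads_by_accession[[acc]], library,
                                p$min_te_match, p$min_flank, p$min_ident,
                                p$slack, p$k)
    if (nrow(junc)) { junc_all[[acc]] <- junc; acc_all[[acc]] <- acc }
  }
  if (!length(junc_all)) {
    loci <- cluster_breakpoints(data.frame())
    attr(loci, "candidates") <- data.frame()
    return(loci)
  }
  junc <- do.call(rbind, junc_all)
  accession <- rep(names(junc_all), vapply(junc_all, nrow, 0L))
  mapped <- map_flanks(junc$flank, reference, p$flank_min_ident,
                       p$min_flank, p$k, p$second_frac)
  candidates <- junctions_to_candidates(junc, mapped, accession, p$slack)
  candidates <- candidates[order(candidates$chrom, candidates$pos,
                                 candidates$te_id, candidates$side,
                                 candidates$accession), , drop = FALSE]
  loci <- cluster_breakpoints(candidates, p$window)
  loci <- classify_ref_status(loci, reference, elements, p$ref_min_len,
                              p$ref_min_ident, params$endlib$end_len)
  attr(loci, "candidates") <- candidates
  loci
}
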