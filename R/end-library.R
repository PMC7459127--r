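# TE end-sequence library: extract terminal segments of curated TE
# elements and collapse them into the non-redundant library used for
# junction-read search. Redundancy is decided by an explicit
# identity/length criterion (>= 90% identity over an alignment of >= 75
# bp) applied via exact Smith-Waterman on both strands, rather than a
# BLAST e-value heuristic.

TE_TAXONOMY <- list(
  DNA = list(TIR = c("Pong", "CACTA", "Tc1/Mariner", "hAT", "Mutator",
                     "PIF/Harbinger", "Stowaway", "Tourist"),
             Helitron = "Helitron"),
  Retro = list(LTR = c("Copia", "Gypsy", "Unclassified"),
               SINE = c("tRNA", "Unclassified"),
               LINE = "L1")
)

#' Construct a TE element table
#'
#' Validates the class/order/superfamily taxonomy and the sequences of a
#' curated TE set.
#'
#' @param te_id,class_,order_,superfamily,family character vectors.
#' @param sequence DNA sequences (length >= 50).
#' @return data.frame of TE elements.
#' @export
te_elements <- function(te_id, class_, order_, superfamily, family, sequence) {
  sequence <- toupper(sequence)
  validate_dna(sequence, "TE element")
  if (any(nchar(sequence) < 50)) stopf("TE element shorter than 50 bp")
  for (i in seq_along(te_id)) {
    cl <- TE_TAXONOMY[[class_[i]]]
    if (is.null(cl)) stopf("unknown TE class '%s'", class_[i])
    sf <- cl[[order_[i]]]
    if (is.null(sf)) stopf("order '%s' invalid for class '%s'", order_[i], class_[i])
    if (!superfamily[i] %in% sf)
      stopf("superfamily '%s' invalid for order '%s'", superfamily[i], order_[i])
  }
  data.frame(te_id = te_id, class_ = class_, order_ = order_,
             superfamily = superfamily, family = family, sequence = sequence,
             stringsAsFactors = FALSE)
}

#' Extract TE end sequences
#'
#' Takes the terminal `end_len` bases from both ends of every element.
#' Elements no longer than `end_len` contribute a single `whole` end;
#' elements shorter than `2 * end_len` yield two overlapping ends.
#'
#' @param elements data.frame from [te_elements()].
#' @param end_len end length in bp (default 150).
#' @return data.frame with columns `end_id`, `te_id`, `side`
#'   (`L`/`R`/`whole`), `sequence`.
#' @export
extract_ends <- function(elements, end_len = 150) {
  if (!nrow(elements)) stopf("empty element set")
  out <- list()
  for (i in seq_len(nrow(elements))) {
    s <- elements$sequence[i]; id <- elements$te_id[i]; n <- nchar(s)
    if (n <= end_len) {
      out[[length(out) + 1]] <- data.frame(
        te_id = id, side = "whole", sequence = s, stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1]] <- data.frame(
        te_id = id, side = c("L", "R"),
        sequence = c(substr(s, 1, end_len), substr(s, n - end_len + 1, n)),
        stringsAsFactors = FALSE)
    }
  }
  ends <- do.call(rbind, out)
  ends$end_id <- paste(ends$te_id, ends$side, sep = "|")
  ends[, c("end_id", "te_id", "side", "sequence")]
}

#' Optimal local alignment of two DNA sequences
#'
#' Exact Smith-Waterman with affine gaps under a BLASTN-like scheme
#' (match +1, mismatch -2, gap open -4, gap extend -1 by default). Ties
#' between equally scoring alignments are broken deterministically
#' towards the lowest end coordinates. `N` never counts as a match.
#'
#' @param a,b DNA strings.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return list with `score`, `identity` (matches / aligned columns),
#'   `aligned_len`, `matches`, and 0-based half-open spans `a_start`,
#'   `a_end`, `b_start`, `b_end`.
#' @export
local_align <- function(a, b, match = 1, mismatch = -2, gap_open = -4,
                        gap_extend = -1) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == 0 || nchar(b) == 0) stopf("sequences must be non-empty")
  r <- cpp_sw_align(a, b, match, mismatch, gap_open, gap_extend)
  r$identity <- if (r$aligned_len > 0) r$matches / r$aligned_len else 0
  r
}

ends_redundant <- function(sa, sb, min_len, min_ident, both_strands = TRUE,
                           scoring = list()) {
  sc <- utils::modifyList(list(match = 1, mismatch = -2, gap_open = -4,
                               gap_extend = -1), scoring)
  cand <- c(sb, if (both_strands) unname(revcomp(sb)))
  for (s in cand) {
    al <- cpp_sw_align(sa, s, sc$match, sc$mismatch, sc$gap_open, sc$gap_extend)
    if (al$aligned_len >= min_len && al$matches / al$aligned_len >= min_ident)
      return(TRUE)
  }
  FALSE
}

#' Collapse redundant TE ends into a non-redundant library
#'
#' Greedy representative selection: ends are visited sorted by (length
#' descending, `te_id`, `side`); a candidate is kept unless it aligns to
#' an already kept representative with aligned length >= `min_len` and
#' identity >= `min_ident` (both strands tested when `both_strands`).
#' The result is independent of the input order.
#'
#' @param ends data.frame from [extract_ends()].
#' @param min_len minimum alignment length in bp (default 75).
#' @param min_ident minimum identity (default 0.90).
#' @param both_strands also test the reverse complement (default TRUE).
#' @return `ends` restricted to representatives, with an attribute
#'   `"mapping"`: data.frame `end_id` -> `representative` for every
#'   dropped end.
#' @export
collapse_redundancy <- function(ends, min_len = 75, min_ident = 0.90,
                                both_strands = TRUE) {
  o <- order(-nchar(ends$sequence), ends$te_id, ends$side)
  ends <- ends[o, , drop = FALSE]
  keep <- integer(0)
  dropped <- character(0); reps_of <- character(0)
  for (i in seq_len(nrow(ends))) {
    rep_hit <- NA_integer_
    for (j in keep) {
      if (ends_redundant(ends$sequence[i], ends$sequence[j], min_len,
                         min_ident, both_strands)) { rep_hit <- j; break }
    }
    if (is.na(rep_hit)) keep <- c(keep, i)
    else { dropped <- c(dropped, ends$end_id[i]); reps_of <- c(reps_of, ends$end_id[rep_hit]) }
  }
  out <- ends[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mapping") <- data.frame(end_id = dropped, representative = reps_of,
                                     stringsAsFactors = FALSE)
  out
}

#' Build the non-redundant end library from TE elements
#'
#' Convenience wrapper: [extract_ends()] followed by
#' [collapse_redundancy()], with family/superfamily annotation carried
#' onto the representative ends.
#'
#' @inheritParams extract_ends
#' @inheritParams collapse_redundancy
#' @return data.frame of representative ends with `family` and
#'   `superfamily` columns; attribute `"mapping"` as in
#'   [collapse_redundancy()].
#' @export
build_end_library <- function(elements, end_len = 150, min_len = 75,
                              min_ident = 0.90, both_strands = TRUE) {
  ends <- extract_ends(elements, end_len)
  lib <- collapse_redundancy(ends, min_len, min_ident, both_strands)
  idx <- match(lib$te_id, elements$te_id)
  lib$family <- elements$family[idx]
  lib$superfamily <- elements$superfamily[idx]
  lib
}
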