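# The four-rule locus filter cascade applied to the raw mobilome
# profile, in order: (1) excessive missingness, (2) excessive
# heterozygosity, (3) poorly supported singletons, (4) merging of locus
# pairs predicted independently from the two ends of one insertion.
# All thresholds use the strict inequalities they are stated with
# (missing fraction > 0.5, heterozygosity > 0.41, < 3 reads).

subset_profile <- function(profile, keep) {
  mobilome_profile(profile$loci[keep, , drop = FALSE], profile$accessions,
                   profile$calls[keep, , drop = FALSE],
                   profile$presence[keep, , drop = FALSE],
                   profile$absence[keep, , drop = FALSE])
}

#' Drop loci with too many missing calls
#'
#' Removes loci whose fraction of missing (`M`) calls exceeds
#' `max_missing` (strictly).
#'
#' @param profile a [mobilome_profile()].
#' @param max_missing maximum tolerated missing fraction (default 0.5).
#' @return filtered profile; attribute `"removed"` holds the dropped
#'   locus ids.
#' @export
filter_missing <- function(profile, max_missing = 0.5) {
  m <- rowMeans(profile$calls == "M")
  keep <- m <= max_missing
  out <- subset_profile(profile, keep)
  attr(out, "removed") <- profile$loci$locus_id[!keep]
  out
}

#' Drop loci with excessive heterozygosity
#'
#' Removes loci whose heterozygous fraction among non-missing calls,
#' `#H / (#P + #A + #H)`, exceeds `max_het` (strictly). The threshold
#' default of 0.41 reflects cohorts of near-homozygous inbred
#' accessions, where frequent `H` calls signal artifacts.
#'
#' @inheritParams filter_missing
#' @param max_het maximum heterozygous fraction (default 0.41).
#' @export
filter_heterozygosity <- function(profile, max_het = 0.41) {
  h <- rowSums(profile$calls == "H")
  called <- rowSums(profile$calls != "M")
  keep <- called == 0 | h / pmax(called, 1) <= max_het
  out <- subset_profile(profile, keep)
  attr(out, "removed") <- profile$loci$locus_id[!keep]
  out
}

#' Drop poorly supported singleton loci
#'
#' Removes loci carried (`P` or `H`) by exactly one accession whose
#' single carrier has fewer than `min_reads` presence-supporting reads.
#' Loci with two or more carriers are never touched by this rule.
#'
#' @inheritParams filter_missing
#' @param min_reads minimum presence reads for a singleton (default 3).
#' @export
filter_singleton_support <- function(profile, min_reads = 3) {
  carrier <- profile$calls %in% c("P", "H")
  dim(carrier) <- dim(profile$calls)
  n_car <- rowSums(carrier)
  drop <- rep(FALSE, nrow(profile$loci))
  for (i in which(n_car == 1)) {
    j <- which(carrier[i, ])
    drop[i] <- profile$presence[i, j] < min_reads
  }
  out <- subset_profile(profile, !drop)
  attr(out, "removed") <- profile$loci$locus_id[drop]
  out
}

join_calls <- function(a, b) {
  out <- character(length(a))
  for (i in seq_along(a)) {
    x <- a[i]; y <- b[i]
    out[i] <- if (x == "H" || y == "H") "H"
      else if (x == "M") y
      else if (y == "M") x
      else if (x == y) x
      else "M" # P/A conflict across ends: artifact signal, not heterozygosity
  }
  out
}

#' Merge locus pairs predicted from the two ends of one insertion
#'
#' Two loci merge iff they come from the same TE family on the same
#' chromosome with opposite element end sides and opposite TE
#' directions, and either (nonRef) their breakpoints differ by at most
#' `pair_window` bp - the two sides of one insertion are separated by
#' the target-site duplication only - or (Ref) they flank the same
#' reference TE span, each breakpoint within `pair_window` of its span
#' end. The merged locus keeps the leftmost position, is flagged
#' `end_support = "pair"`, and joins the per-accession genotypes:
#' agreeing calls stand, `H` dominates, a missing call defers to the
#' other end, and a P/A conflict becomes missing with its read counts
#' zeroed. Read counts are summed otherwise. When more than two loci are
#' mergeable the closest pair is merged and the rest left, with a
#' warning.
#'
#' @inheritParams filter_missing
#' @param pair_window breakpoint tolerance in bp (default 25).
#' @return profile with merged pair loci; attribute `"n_merged"` gives
#'   the number of merged pairs.
#' @export
merge_end_pairs <- function(profile, pair_window = 25) {
  loci <- profile$loci
  n <- nrow(loci)
  eligible <- list()
  for (grp in split(seq_len(n), paste(loci$chrom, loci$family, sep = "\r"))) {
    if (length(grp) < 2) next
    for (ii in seq_along(grp)) for (jj in seq_along(grp)) {
      if (ii >= jj) next
      i <- grp[ii]; j <- grp[jj]
      if (loci$side[i] == loci$side[j]) next
      if (loci$te_dir[i] == loci$te_dir[j]) next
      if (loci$ref_status[i] != loci$ref_status[j]) next
      ok <- if (loci$ref_status[i] == "nonRef") {
        abs(loci$pos[i] - loci$pos[j]) <= pair_window
      } else {
        !is.na(loci$span_start[i]) && !is.na(loci$span_start[j]) &&
          abs(loci$span_start[i] - loci$span_start[j]) <= pair_window &&
          abs(loci$span_end[i] - loci$span_end[j]) <= pair_window
      }
      if (ok) eligible[[length(eligible) + 1]] <-
          c(i, j, abs(loci$pos[i] - loci$pos[j]))
    }
  }
  if (!length(eligible)) {
    out <- profile
    attr(out, "n_merged") <- 0L
    return(out)
  }
  el <- do.call(rbind, eligible)
  if (any(table(c(el[, 1], el[, 2])) > 1))
    warnf("more than two mergeable loci in a group; merging closest pairs only")
  el <- el[order(el[, 3], el[, 1]), , drop = FALSE]
  used <- rep(FALSE, n)
  calls <- profile$calls; pres <- profile$presence; abs_ <- profile$absence
  drop <- rep(FALSE, n); n_merged <- 0L
  for (r in seq_len(nrow(el))) {
    i <- el[r, 1]; j <- el[r, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    n_merged <- n_merged + 1L
    keep_i <- loci$pos[i] <= loci$pos[j]
    a <- if (keep_i) i else j; b <- if (keep_i) j else i
    merged <- join_calls(calls[a, ], calls[b, ])
    p_sum <- pres[a, ] + pres[b, ]; a_sum <- abs_[a, ] + abs_[b, ]
    conflict <- merged == "M" & (calls[a, ] != "M" | calls[b, ] != "M")
    p_sum[conflict] <- 0L; a_sum[conflict] <- 0L
    calls[a, ] <- merged; pres[a, ] <- p_sum; abs_[a, ] <- a_sum
    loci$end_support[a] <- "pair"
    drop[b] <- TRUE
  }
  keep <- !drop
  out <- mobilome_profile(loci[keep, , drop = FALSE], profile$accessions,
                          calls[keep, , drop = FALSE],
                          pres[keep, , drop = FALSE],
                          abs_[keep, , drop = FALSE])
  attr(out, "n_merged") <- n_merged
  out
}

#' Construct a filter accounting report
#'
#' The accounting identity `final = initial - removed_missing -
#' removed_het - removed_low_support_singleton - merged_pairs` holds by
#' construction.
#'
#' @param initial_loci,removed_missing,removed_het,removed_low_support_singleton,merged_pairs
#'   counts.
#' @return object of class `filter_report`.
#' @export
filter_report <- function(initial_loci, removed_missing, removed_het,
                          removed_low_support_singleton, merged_pairs) {
  r <- list(initial_loci = initial_loci, removed_missing = removed_missing,
            removed_het = removed_het,
            removed_low_support_singleton = removed_low_support_singleton,
            merged_pairs = merged_pairs,
            final_loci = initial_loci - removed_missing - removed_het -
              removed_low_support_singleton - merged_pairs)
  structure(r, class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("filter_report: %d initial - %d missing - %d het - ",
                     "%d singleton - %d pair-merged = %d final\n"),
              x$initial_loci, x$removed_missing, x$removed_het,
              x$removed_low_support_singleton, x$merged_pairs, x$final_loci))
  invisible(x)
}

#' Apply the full filter cascade
#'
#' Filters in order: missingness, heterozygosity, singleton support,
#' end-pair merging; returns the filtered profile and the exact
#' accounting report.
#'
#' @inheritParams filter_missing
#' @param max_het,min_reads,pair_window see the individual filters.
#' @return list with elements `profile` and `report`
#'   ([filter_report()]).
#' @export
apply_filters <- function(profile, max_missing = 0.5, max_het = 0.41,
                          min_reads = 3, pair_window = 25) {
  n0 <- nrow(profile$loci)
  p1 <- filter_missing(profile, max_missing)
  p2 <- filter_heterozygosity(p1, max_het)
  p3 <- filter_singleton_support(p2, min_reads)
  p4 <- merge_end_pairs(p3, pair_window)
  rep <- filter_report(n0,
                       n0 - nrow(p1$loci),
                       nrow(p1$loci) - nrow(p2$loci),
                       nrow(p2$loci) - nrow(p3$loci),
                       attr(p4, "n_merged"))
  stopifnot(rep$final_loci == nrow(p4$loci))
  list(profile = p4, report = rep)
}

#' Quality-control summaries of a profile
#'
#' Computes the overall detection rate (non-missing fraction of the call
#' matrix), the supporting-read distribution over non-missing calls
#' (mean and the fraction of calls with at least three reads), and -
#' when run on a pre-merge profile - the per-accession genotype
#' concordance of locus pairs predicted from the two ends of the same
#' insertion.
#'
#' @inheritParams filter_missing
#' @param pair_window window used to identify end pairs (default 25).
#' @return list with `detection_rate`, `support_mean`,
#'   `support_ge3_fraction`, `support_hist` (table), `pair_concordance`
#'   (NA when the profile has no end pairs).
#' @export
qc_summaries <- function(profile, pair_window = 25) {
  calls <- profile$calls
  total <- length(calls)
  det <- if (total) sum(calls != "M") / total else NA_real_
  supp <- (profile$presence + profile$absence)[calls != "M"]
  conc <- NA_real_
  merged <- merge_end_pairs(profile, pair_window)
  if (attr(merged, "n_merged") > 0) {
    # recover the pairs to compare raw calls end-by-end
    loci <- profile$loci
    agree <- 0L; tot <- 0L
    pair_ids <- merged$loci$locus_id[merged$loci$end_support == "pair" &
                                       merged$loci$locus_id %in% loci$locus_id]
    for (lid in pair_ids) {
      a <- which(loci$locus_id == lid)
      ch <- loci$chrom[a]; fam <- loci$family[a]
      cand <- which(loci$chrom == ch & loci$family == fam &
                      loci$side != loci$side[a] & loci$te_dir != loci$te_dir[a])
      cand <- cand[abs(loci$pos[cand] - loci$pos[a]) <= pair_window |
                     (!is.na(loci$span_start[cand]) & !is.na(loci$span_start[a]) &
                        abs(loci$span_start[cand] - loci$span_start[a]) <= pair_window)]
      if (!length(cand)) next
      b <- cand[which.min(abs(loci$pos[cand] - loci$pos[a]))]
      both <- calls[a, ] != "M" & calls[b, ] != "M"
      agree <- agree + sum(calls[a, both] == calls[b, both])
      tot <- tot + sum(both)
    }
    if (tot > 0) conc <- agree / tot
  }
  list(detection_rate = det,
       support_mean = if (length(supp)) mean(supp) else NA_real_,
       support_ge3_fraction = if (length(supp)) mean(supp >= 3) else NA_real_,
       support_hist = table(supp),
       pair_concordance = conc)
}
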