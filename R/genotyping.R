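# Stage 2 of the pipeline: presence/absence calling at every discovered
# locus in every accession from breakpoint-spanning (chimeric) reads.
# For each locus a presence template (genomic flank joined to the TE
# terminus) and, where possible, an absence template (the contiguous
# sequence across the empty site) are built; a read supports an allele
# iff it aligns across that allele's junction with at least min_overlap
# matched bases on both sides.

#' Build allele templates for discovered loci
#'
#' For nonRef loci the presence template joins `flank_len` reference
#' bases to the TE terminus on the insertion side, and the absence
#' template is the contiguous reference across the empty site. For Ref
#' loci the presence template is read directly from the reference
#' junction; the absence template is the excision joint, removing the
#' reference TE span plus one copy of the target-site duplication
#' (detected by comparing the sequence flanking the span, up to
#' `max_tsd` bp). Ref loci whose span could not be delimited get no
#' absence template and are genotyped presence-vs-missing only.
#'
#' @param loci locus data.frame from [discover_loci()].
#' @param reference named character vector of reference sequences.
#' @param elements TE element table.
#' @param flank_len genomic flank length per template side (default 150).
#' @param min_overlap minimum junction overlap the templates must be
#'   able to host on each side (default 20); a template truncated below
#'   this by a contig edge is an error.
#' @param max_tsd maximum target-site duplication length probed (default 20).
#' @return data.frame of templates: `locus_id`, `allele`
#'   (`presence`/`absence`), `sequence`, `junction` (0-based offset of
#'   the breakpoint within the template).
#' @export
build_templates <- function(loci, reference, elements, flank_len = 150,
                            min_overlap = 20, max_tsd = 20) {
  out <- list()
  add <- function(locus_id, allele, left, right) {
    if (nchar(left) < min_overlap || nchar(right) < min_overlap)
      stopf("locus %s: template truncated below %d bp at a contig edge",
            locus_id, min_overlap)
    out[[length(out) + 1]] <<- data.frame(
      locus_id = locus_id, allele = allele,
      sequence = paste0(left, right), junction = nchar(left),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(loci))) {
    ref <- reference[[loci$chrom[i]]]
    L <- nchar(ref); b <- loci$pos[i]; dir <- loci$te_dir[i]
    lid <- loci$locus_id[i]
    elem <- elements$sequence[match(loci$te_id[i], elements$te_id)]
    term <- oriented_terminus(elem, loci$side[i], flank_len)
    if (loci$ref_status[i] == "nonRef") {
      if (dir == 1L) {
        add(lid, "presence", substr(ref, max(1, b - flank_len + 1), b), term)
      } else {
        add(lid, "presence", unname(revcomp(term)),
            substr(ref, b + 1, min(L, b + flank_len)))
      }
      add(lid, "absence", substr(ref, max(1, b - flank_len + 1), b),
          substr(ref, b + 1, min(L, b + flank_len)))
    } else {
      # presence junction exists verbatim in the reference
      add(lid, "presence", substr(ref, max(1, b - flank_len + 1), b),
          substr(ref, b + 1, min(L, b + flank_len)))
      s <- loci$span_start[i]; e <- loci$span_end[i]
      if (!is.na(s) && !is.na(e)) {
        tsd <- 0L
        tmax <- min(max_tsd, s, L - e)
        if (tmax >= 1) {
          for (t in tmax:1) {
            if (substr(ref, s - t + 1, s) == substr(ref, e + 1, e + t)) {
              tsd <- t; break
            }
          }
        }
        add(lid, "absence", substr(ref, max(1, s - flank_len + 1), s),
            substr(ref, e + tsd + 1, min(L, e + tsd + flank_len)))
      }
    }
  }
  do.call(rbind, out)
}

#' Collect breakpoint-spanning read evidence for one accession
#'
#' A read supports an allele iff it aligns to that allele's template
#' crossing the junction with >= `min_overlap` matched bases on both
#' sides at >= `min_ident` identity (both orientations searched). Reads
#' supporting both alleles of the same locus are discarded as
#' uninformative.
#'
#' @param reads character vector of read sequences.
#' @param templates template data.frame from [build_templates()].
#' @param min_overlap minimum matched bases on each side (default 20).
#' @param min_ident minimum alignment identity (default 0.95).
#' @param k seed k-mer size (default 15).
#' @return data.frame per locus: `locus_id`, `presence_reads`,
#'   `absence_reads`.
#' @export
collect_evidence <- function(reads, templates, min_overlap = 20,
                             min_ident = 0.95, k = 15) {
  loci <- unique(templates$locus_id)
  res <- data.frame(locus_id = loci, presence_reads = 0L, absence_reads = 0L,
                    stringsAsFactors = FALSE)
  if (!length(reads)) return(res)
  hits <- cpp_collect_evidence(unname(reads), templates$sequence,
                               templates$junction, k, min_overlap, min_ident)
  if (!nrow(hits)) return(res)
  hit_locus <- templates$locus_id[hits$template]
  hit_allele <- templates$allele[hits$template]
  # discard reads supporting both alleles at one locus
  key <- paste(hits$read, hit_locus, sep = "\r")
  both <- tapply(hit_allele, key, function(a) length(unique(a)) > 1)
  drop <- both[key]
  hit_locus <- hit_locus[!drop]; hit_allele <- hit_allele[!drop]
  tp <- table(factor(hit_locus[hit_allele == "presence"], levels = loci))
  ta <- table(factor(hit_locus[hit_allele == "absence"], levels = loci))
  res$presence_reads <- as.integer(tp)
  res$absence_reads <- as.integer(ta)
  res
}

#' Call a genotype from supporting-read counts
#'
#' `(0,0)` is missing (`M`), presence-only reads give `P`, absence-only
#' give `A`, and reads on both alleles give a heterozygous call `H`.
#' Vectorised over loci.
#'
#' @param presence_reads,absence_reads non-negative integer vectors.
#' @return character vector over `P/A/H/M`.
#' @export
call_genotype <- function(presence_reads, absence_reads) {
  stopifnot(all(presence_reads >= 0), all(absence_reads >= 0))
  ifelse(presence_reads > 0 & absence_reads > 0, "H",
         ifelse(presence_reads > 0, "P",
                ifelse(absence_reads > 0, "A", "M")))
}

#' Genotype every accession at every discovered locus
#'
#' Builds allele templates once, then collects evidence and calls
#' genotypes per accession, producing the complete mobilome profile with
#' per-call supporting-read counts retained for filtering and QC.
#'
#' @param loci locus data.frame from [discover_loci()].
#' @param reads_by_accession named list of read vectors.
#' @param accessions data.frame with `accession` and `morphotype`
#'   columns (order defines profile column order).
#' @param reference named character vector of reference sequences.
#' @param elements TE element table.
#' @param params parameter list; see [pipeline_params()].
#' @return a [mobilome_profile()].
#' @export
genotype_population <- function(loci, reads_by_accession, accessions,
                                reference, elements,
                                params = pipeline_params()) {
  p <- params$genotype
  templates <- build_templates(loci, reference, elements, p$flank_len,
                               p$min_overlap, p$max_tsd)
  n <- nrow(loci); m <- nrow(accessions)
  calls <- matrix("M", n, m)
  pres <- matrix(0L, n, m); abs_ <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    acc <- accessions$accession[j]
    reads <- reads_by_accession[[acc]]
    if (is.null(reads) || !length(reads)) {
      warnf("accession '%s' has no reads; all calls set to missing", acc)
      next
    }
    ev <- collect_evidence(reads, templates, p$min_overlap, p$min_ident, p$k)
    idx <- match(loci$locus_id, ev$locus_id)
    pres[, j] <- ev$presence_reads[idx]
    abs_[, j] <- ev$absence_reads[idx]
    calls[, j] <- call_genotype(pres[, j], abs_[, j])
  }
  keep <- setdiff(names(loci), "support")
  mobilome_profile(loci[, keep, drop = FALSE], accessions, calls, pres, abs_)
}
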