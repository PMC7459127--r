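# Population-frequency analytics on the filtered profile: per-locus and
# per-morphotype carrier frequencies, frequency classes, differential
# fixation between morphotypes, group-specific/shared and singleton
# accounting, gene-proximity annotation, and subgenome statistics.
#
# A heterozygous call counts as a carrier (carrier frequency, not allele
# frequency). Frequency classes use the integer-percent bins low
# (0-30%], median (30-70%], high (70-100%) and fixed (exactly 100%).

#' Per-locus population frequencies and classes
#'
#' Carrier frequency = (#P + #H) / (#P + #A + #H) per locus, classified
#' as `fixed` (freq == 1), `high` (0.70 < freq < 1), `median`
#' (0.30 < freq <= 0.70) or `low` (freq <= 0.30).
#'
#' @param profile a [mobilome_profile()] (post-filter, so every locus
#'   has at least one non-missing call).
#' @return data.frame with `locus_id`, `n_carrier`, `n_called`, `freq`,
#'   `class_`.
#' @export
locus_frequencies <- function(profile) {
  calls <- profile$calls
  n_car <- rowSums(calls == "P" | calls == "H")
  n_cal <- rowSums(calls != "M")
  if (any(n_cal == 0)) stopf("locus with zero called accessions; run filter_missing first")
  freq <- n_car / n_cal
  data.frame(locus_id = profile$loci$locus_id, n_carrier = n_car,
             n_called = n_cal, freq = freq,
             class_ = classify_frequency(freq), stringsAsFactors = FALSE)
}

#' @rdname locus_frequencies
#' @param freq numeric vector of carrier frequencies in \[0, 1\].
#' @export
classify_frequency <- function(freq) {
  ifelse(freq == 1, "fixed",
         ifelse(freq > 0.70, "high",
                ifelse(freq > 0.30, "median", "low")))
}

#' Per-morphotype carrier frequencies
#'
#' Carrier frequency of every locus within every morphotype group, over
#' that group's called accessions. Loci with no called accession in a
#' group get `freq = NA` (flagged undefined).
#'
#' @param profile a [mobilome_profile()]; groups are taken from the
#'   `morphotype` column of its accession table.
#' @param groups optional character vector of group labels per accession
#'   (overrides the morphotype column).
#' @return data.frame with `locus_id`, `group`, `freq`, `n_called`.
#' @export
group_frequencies <- function(profile, groups = NULL) {
  groups <- groups %||% profile$accessions$morphotype
  stopifnot(length(groups) == nrow(profile$accessions))
  if (any(table(groups) == 0)) stopf("empty morphotype group")
  out <- list()
  for (g in unique(groups)) {
    calls <- profile$calls[, groups == g, drop = FALSE]
    n_car <- rowSums(calls == "P" | calls == "H")
    n_cal <- rowSums(calls != "M")
    out[[g]] <- data.frame(locus_id = profile$loci$locus_id, group = g,
                           freq = ifelse(n_cal > 0, n_car / n_cal, NA_real_),
                           n_called = n_cal, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Morphotype-differential fixed loci
#'
#' A locus qualifies for the ordered group pair (g1, g2) iff its carrier
#' frequency is at least `hi` in g1 and at most `lo` in g2 (both
#' frequencies defined).
#'
#' @param groupfreqs data.frame from [group_frequencies()].
#' @param hi,lo fixation thresholds (defaults 0.90 / 0.10).
#' @return data.frame with `locus_id`, `high_group`, `low_group`; the
#'   attribute `"pair_counts"` tabulates loci per ordered pair.
#' @export
differential_fixed <- function(groupfreqs, hi = 0.90, lo = 0.10) {
  w <- stats::reshape(groupfreqs[, c("locus_id", "group", "freq")],
                      idvar = "locus_id", timevar = "group",
                      direction = "wide")
  gs <- sub("^freq\\.", "", names(w)[-1])
  out <- list()
  for (g1 in gs) for (g2 in gs) {
    if (g1 == g2) next
    f1 <- w[[paste0("freq.", g1)]]; f2 <- w[[paste0("freq.", g2)]]
    hit <- !is.na(f1) & !is.na(f2) & f1 >= hi & f2 <= lo
    if (any(hit)) out[[length(out) + 1]] <- data.frame(
      locus_id = w$locus_id[hit], high_group = g1, low_group = g2,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(locus_id = character(), high_group = character(),
               low_group = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "pair_counts") <- table(high = res$high_group, low = res$low_group)
  res
}

#' Loci with large between-morphotype frequency differences
#'
#' Returns the loci whose maximum pairwise difference in group carrier
#' frequency exceeds `delta` (strictly). Every differential-fixed locus
#' at the default 0.9/0.1 thresholds is necessarily heterogeneous at
#' `delta = 0.5`.
#'
#' @inheritParams differential_fixed
#' @param delta difference threshold (default 0.5).
#' @return character vector of locus ids.
#' @export
heterogeneous_loci <- function(groupfreqs, delta = 0.5) {
  sp <- split(groupfreqs$freq, groupfreqs$locus_id)
  rng <- vapply(sp, function(f) {
    f <- f[!is.na(f)]
    if (length(f) < 2) 0 else max(f) - min(f)
  }, numeric(1))
  names(rng)[rng > delta]
}

#' Shared, group-specific and singleton locus accounting
#'
#' A locus is "present in a group" iff it has at least one carrier
#' there. Reports loci shared by all groups, loci specific to exactly
#' one group, and the singleton table: loci carried by exactly one
#' accession overall, per morphotype, with the per-accession average
#' rounded to one decimal (half-up).
#'
#' @inheritParams group_frequencies
#' @return list with `shared_by_all`, `group_specific` (named counts),
#'   and `singletons` (data.frame with a `Total` row).
#' @export
venn_and_singletons <- function(profile, groups = NULL) {
  groups <- groups %||% profile$accessions$morphotype
  carrier <- profile$calls == "P" | profile$calls == "H"
  gs <- unique(groups)
  pres <- vapply(gs, function(g)
    rowSums(carrier[, groups == g, drop = FALSE]) > 0, logical(nrow(carrier)))
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = 1, dimnames = list(NULL, gs))
  n_groups_present <- rowSums(pres)
  shared <- sum(n_groups_present == length(gs))
  spec <- colSums(pres & n_groups_present == 1)
  one_carrier <- rowSums(carrier) == 1
  carrier_group <- rep(NA_character_, nrow(carrier))
  if (any(one_carrier)) {
    j <- apply(carrier[one_carrier, , drop = FALSE], 1, which)
    carrier_group[one_carrier] <- groups[j]
  }
  sing <- data.frame(
    morphotype = gs,
    n_accessions = as.integer(table(factor(groups, levels = gs))),
    n_singletons = as.integer(table(factor(carrier_group, levels = gs))),
    stringsAsFactors = FALSE)
  sing <- rbind(sing, data.frame(morphotype = "Total",
                                 n_accessions = length(groups),
                                 n_singletons = sum(sing$n_singletons)))
  sing$average <- round_half_up(sing$n_singletons / sing$n_accessions, 1)
  list(shared_by_all = shared, group_specific = spec, singletons = sing)
}

#' Singleton-table arithmetic
#'
#' Given singleton and accession counts per morphotype, reproduces the
#' per-accession averages (one decimal, half-up) and the total row.
#'
#' @param n_accessions,n_singletons integer vectors per morphotype.
#' @return data.frame with per-group and total averages.
#' @export
singleton_averages <- function(n_accessions, n_singletons) {
  data.frame(n_accessions = c(n_accessions, sum(n_accessions)),
             n_singletons = c(n_singletons, sum(n_singletons)),
             average = round_half_up(
               c(n_singletons, sum(n_singletons)) /
                 c(n_accessions, sum(n_accessions)), 1))
}

# point-in-interval semantics for a breakpoint: the insertion at offset
# p (between bases p-1 and p) disrupts the 0-based half-open interval
# [a, b) iff a < p < b.
point_in <- function(p, a, b) a < p & p < b

#' Annotate loci relative to gene models
#'
#' Assigns each breakpoint exactly one category by the precedence CDS >
#' intron > upstream > downstream > intergenic. Upstream/downstream are
#' strand-aware windows of `window` bp adjacent to the gene span
#' (inclusive at the window edge). When several genes compete within
#' one precedence level the nearest gene wins.
#'
#' @param loci locus data.frame (columns `locus_id`, `chrom`, `pos`).
#' @param gene_models a `gene_models` object ([read_gene_models()]).
#' @param window upstream/downstream window in bp (default 500).
#' @return data.frame with `locus_id`, `category`, `gene_id`.
#' @export
annotate_loci <- function(loci, gene_models, window = 500) {
  genes <- gene_models$genes
  prec <- c(CDS = 1, intron = 2, upstream = 3, downstream = 4, intergenic = 5)
  cat_out <- rep("intergenic", nrow(loci))
  gene_out <- rep(NA_character_, nrow(loci))
  for (i in seq_len(nrow(loci))) {
    p <- loci$pos[i]
    gsel <- which(genes$chrom == loci$chrom[i])
    best <- c(prec = 5, dist = Inf); best_gene <- NA_character_; best_cat <- "intergenic"
    for (k in gsel) {
      gid <- genes$gene_id[k]
      s <- genes$start[k]; e <- genes$end[k]; plus <- genes$strand[k] == "+"
      cds <- gene_models$cds[gene_models$cds$gene_id == gid, , drop = FALSE]
      intr <- gene_models$introns[gene_models$introns$gene_id == gid, , drop = FALSE]
      cat_k <- NULL
      if (nrow(cds) && any(point_in(p, cds$start, cds$end))) cat_k <- "CDS"
      else if (nrow(intr) && any(point_in(p, intr$start, intr$end))) cat_k <- "intron"
      else if (if (plus) p <= s && s - p <= window else p >= e && p - e <= window)
        cat_k <- "upstream"
      else if (if (plus) p >= e && p - e <= window else p <= s && s - p <= window)
        cat_k <- "downstream"
      if (is.null(cat_k)) next
      d <- if (p < s) s - p else if (p > e) p - e else 0
      if (prec[cat_k] < best["prec"] ||
          (prec[cat_k] == best["prec"] && d < best["dist"])) {
        best <- c(prec = prec[[cat_k]], dist = d)
        best_gene <- gid; best_cat <- cat_k
      }
    }
    cat_out[i] <- best_cat; gene_out[i] <- best_gene
  }
  data.frame(locus_id = loci$locus_id, category = cat_out, gene_id = gene_out,
             stringsAsFactors = FALSE)
}

#' Subgenome locus counts and densities
#'
#' Assigns each locus to the subgenome block containing the base
#' immediately left of its breakpoint, and reports per-subgenome locus
#' count, block size, and density in loci/Mb rounded to the nearest
#' integer.
#'
#' @param loci locus data.frame (`chrom`, `pos`).
#' @param blocks block data.frame ([read_subgenome_blocks()]).
#' @return data.frame per subgenome label with `n_loci`, `size_mb`,
#'   `density`; attribute `"unassigned"` counts loci outside all blocks.
#' @export
subgenome_stats <- function(loci, blocks) {
  check_blocks(blocks)
  labels <- c("LF", "MF1", "MF2")
  assign <- rep(NA_character_, nrow(loci))
  for (k in seq_len(nrow(blocks))) {
    hit <- loci$chrom == blocks$chrom[k] &
      loci$pos > blocks$start[k] & loci$pos <= blocks$end[k]
    assign[hit] <- blocks$label[k]
  }
  size <- vapply(labels, function(l)
    sum(blocks$end[blocks$label == l] - blocks$start[blocks$label == l]) / 1e6,
    numeric(1))
  n <- vapply(labels, function(l) sum(assign == l, na.rm = TRUE), numeric(1))
  out <- data.frame(subgenome = labels, n_loci = as.integer(n),
                    size_mb = size,
                    density = ifelse(size > 0,
                                     as.integer(round_half_up(n / size, 0)), 0L),
                    stringsAsFactors = FALSE)
  attr(out, "unassigned") <- sum(is.na(assign))
  attr(out, "assignment") <- assign
  out
}

#' Frequency-class by gene-category cross-table
#'
#' Counts loci per frequency class and gene-proximity category and the
#' row percentages relative to the total loci of each class (one
#' decimal, half-up), in the layout of a class x {CDS, intron, upstream,
#' downstream, total gene-associated} report table.
#'
#' @param freqs data.frame from [locus_frequencies()].
#' @param annotations data.frame from [annotate_loci()] (same loci).
#' @return list with `counts` (classes+Total x categories+Total matrix),
#'   `percent` (same shape, percentages of class locus totals) and
#'   `class_totals`.
#' @export
class_by_category_table <- function(freqs, annotations) {
  stopifnot(nrow(freqs) == nrow(annotations))
  classes <- c("low", "median", "high", "fixed")
  cats <- c("CDS", "intron", "upstream", "downstream")
  cls <- factor(freqs$class_, levels = classes)
  ann <- annotations$category[match(freqs$locus_id, annotations$locus_id)]
  tab <- table(cls, factor(ann, levels = cats))
  counts <- cbind(tab, Total = rowSums(tab))
  counts <- rbind(counts, Total = colSums(counts))
  class_totals <- c(table(cls), Total = length(cls))
  percent <- round_half_up(100 * counts / as.numeric(class_totals), 1)
  list(counts = counts, percent = percent, class_totals = class_totals)
}

#' Homogeneity test of frequency classes across superfamilies
#'
#' Pearson chi-square test on the superfamily x frequency-class
#' contingency table (no continuity correction). Rows or columns with a
#' zero marginal are dropped with a warning.
#'
#' @param freqs data.frame from [locus_frequencies()].
#' @param loci locus data.frame providing `superfamily` per locus.
#' @return list with `statistic`, `df`, `p_value`, `table`.
#' @export
class_by_superfamily_chisq <- function(freqs, loci) {
  sf <- loci$superfamily[match(freqs$locus_id, loci$locus_id)]
  tab <- table(sf, factor(freqs$class_, levels = c("low", "median", "high", "fixed")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warnf("dropping empty rows/columns from the contingency table")
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) stopf("need at least 2 superfamilies and 2 classes")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, table = tab)
}
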