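# Frequency classes, group frequencies, differential fixation,
# singleton/venn accounting, gene-proximity annotation (with a
# brute-force oracle) and subgenome statistics.

test_that("frequency classes use the printed integer-percent bins", {
  expect_equal(classify_frequency(c(1, 0.99, 0.71, 0.70, 0.31, 0.30, 0)),
               c("fixed", "high", "high", "median", "median", "low", "low"))
  prof <- make_profile(rbind(rep("P", 10),
                             rep(c("P", "A"), c(3, 7))))
  fr <- locus_frequencies(prof)
  expect_equal(fr$class_, c("fixed", "low"))
  expect_equal(fr$freq, c(1, 0.3))
  expect_equal(fr$n_carrier, c(10L, 3L))
})

test_that("heterozygous calls count as carriers", {
  prof <- make_profile(rbind(c("H", "H", "A", "A")))
  expect_equal(locus_frequencies(prof)$freq, 0.5)
})

test_that("group frequencies are computed over called accessions per group", {
  calls <- rbind(c("P", "P", "A", "A"),
                 c("P", "M", "M", "M"),
                 c("M", "M", "A", "A"))
  prof <- make_profile(calls, morphotype = c("cabbage", "cabbage",
                                             "broccoli", "broccoli"))
  gf <- group_frequencies(prof)
  cab <- gf[gf$group == "cabbage", ]
  bro <- gf[gf$group == "broccoli", ]
  expect_equal(cab$freq, c(1, 1, NA))
  expect_equal(bro$freq, c(0, NA, 0))
  expect_equal(cab$n_called, c(2L, 1L, 0L))
})

test_that("differential fixation uses inclusive 0.9/0.1 thresholds", {
  gf <- data.frame(locus_id = rep(c("l1", "l2", "l3"), each = 2),
                   group = rep(c("g1", "g2"), 3),
                   freq = c(0.92, 0.05, 0.89, 0.05, 0.90, 0.10),
                   n_called = 5L, stringsAsFactors = FALSE)
  dfx <- differential_fixed(gf)
  expect_setequal(dfx$locus_id, c("l1", "l3"))
  expect_true(all(dfx$high_group == "g1"))
})

test_that("heterogeneous loci require a strict > 0.5 frequency difference", {
  gf <- data.frame(locus_id = rep(c("l1", "l2"), each = 2),
                   group = rep(c("g1", "g2"), 2),
                   freq = c(0.9, 0.3, 0.6, 0.4), n_called = 5L)
  expect_equal(heterogeneous_loci(gf), "l1")
  # every differential-fixed locus is heterogeneous by implication
  run <- small_run()
  gf2 <- group_frequencies(run$profile)
  dfx <- differential_fixed(gf2)
  expect_true(all(dfx$locus_id %in% heterogeneous_loci(gf2)))
})

test_that("venn and singleton accounting matches construction", {
  calls <- rbind(c("P", "P", "P", "P"),   # shared by both groups
                 c("P", "P", "A", "A"),   # specific to group 1 (2 carriers)
                 c("P", "A", "A", "A"),   # singleton in group 1
                 c("A", "A", "A", "P"))   # singleton in group 2
  prof <- make_profile(calls, morphotype = c("cabbage", "cabbage",
                                             "broccoli", "broccoli"))
  v <- venn_and_singletons(prof)
  expect_equal(v$shared_by_all, 1)
  expect_equal(unname(v$group_specific), c(2, 1))
  expect_equal(v$singletons$n_singletons, c(1L, 1L, 2L))
})

test_that("singleton-table averages reproduce the published arithmetic", {
  tab <- singleton_averages(
    n_accessions = c(46L, 19L, 20L, 23L, 13L),
    n_singletons = c(704L, 411L, 367L, 87L, 932L))
  expect_equal(tab$average, c(15.3, 21.6, 18.4, 3.8, 71.7, 20.7))
  expect_equal(tab$n_singletons[6], 2501L)
  expect_equal(tab$n_accessions[6], 121L)
})

simple_models <- function() {
  genes <- data.frame(
    gene_id = c("g1", "g2"), chrom = "chr1", strand = c("+", "-"),
    start = c(2000L, 10000L), end = c(4000L, 12000L), stringsAsFactors = FALSE)
  exons <- mobiscan:::interval_df(c("g1", "g1", "g2"),
                                  c(2000L, 3000L, 10000L),
                                  c(2500L, 4000L, 12000L))
  cds <- exons
  introns <- mobiscan:::interval_df("g1", 2500L, 3000L)
  mobiscan:::new_gene_models(genes, exons, cds, introns)
}

test_that("annotation precedence and strand-aware windows", {
  gm <- simple_models()
  loci <- make_loci(6, pos = c(2100L,   # inside CDS of g1
                               2700L,   # inside intron of g1
                               1500L,   # 500 bp before g1 start: upstream
                               4400L,   # 400 bp past g1 end: downstream
                               12100L,  # 100 bp past minus-strand g2 end: upstream
                               7000L))  # far from both: intergenic
  ann <- annotate_loci(loci, gm)
  expect_equal(ann$category, c("CDS", "intron", "upstream", "downstream",
                               "upstream", "intergenic"))
  expect_equal(ann$gene_id[1:5], c("g1", "g1", "g1", "g1", "g2"))
})

test_that("annotation agrees with a brute-force interval oracle", {
  gm <- simple_models()
  set.seed(50)
  loci <- make_loci(300, pos = sample(0:14000, 300))
  ann <- annotate_loci(loci, gm)
  oracle <- vapply(loci$pos, function(p) {
    cats <- character(0)
    for (k in seq_len(nrow(gm$genes))) {
      g <- gm$genes[k, ]
      cds <- gm$cds[gm$cds$gene_id == g$gene_id, ]
      intr <- gm$introns[gm$introns$gene_id == g$gene_id, ]
      if (any(cds$start < p & p < cds$end)) cats <- c(cats, "CDS")
      else if (nrow(intr) && any(intr$start < p & p < intr$end))
        cats <- c(cats, "intron")
      else {
        before <- p <= g$start && g$start - p <= 500
        after <- p >= g$end && p - g$end <= 500
        if (g$strand == "+") {
          if (before) cats <- c(cats, "upstream")
          if (after) cats <- c(cats, "downstream")
        } else {
          if (after) cats <- c(cats, "upstream")
          if (before) cats <- c(cats, "downstream")
        }
      }
    }
    prec <- c("CDS", "intron", "upstream", "downstream")
    hit <- prec[prec %in% cats]
    if (length(hit)) hit[1] else "intergenic"
  }, character(1))
  expect_equal(ann$category, oracle)
})

test_that("subgenome densities reproduce the published rounding", {
  blocks <- data.frame(chrom = c("c1", "c2", "c3"), start = 0L,
                       end = c(178L, 129L, 98L) * 1000000L,
                       label = c("LF", "MF1", "MF2"), stringsAsFactors = FALSE)
  loci <- data.frame(
    locus_id = "x",
    chrom = rep(c("c1", "c2", "c3"), c(17402L, 12634L, 9890L)),
    pos = c(seq_len(17402L) * 10L, seq_len(12634L) * 10L, seq_len(9890L) * 10L))
  st <- subgenome_stats(loci, blocks)
  expect_equal(st$n_loci, c(17402L, 12634L, 9890L))
  expect_equal(st$density, c(98L, 98L, 101L))
  # an empty subgenome has density zero
  st2 <- subgenome_stats(loci[0, ], blocks)
  expect_equal(st2$density, c(0L, 0L, 0L))
})

test_that("class-by-category table reproduces the published percentages", {
  counts <- rbind(low = c(422, 1247, 2306, 1766),
                  median = c(80, 429, 976, 813),
                  high = c(16, 207, 553, 416),
                  fixed = c(24, 510, 1045, 835))
  class_n <- c(low = 18575, median = 8591, high = 5029, fixed = 13542)
  cls <- rep(rownames(counts), class_n)
  cats <- unlist(lapply(rownames(counts), function(cl) {
    n_gene <- counts[cl, ]
    rep(c("CDS", "intron", "upstream", "downstream", "intergenic"),
        c(n_gene, class_n[cl] - sum(n_gene)))
  }))
  freqs <- data.frame(locus_id = sprintf("l%05d", seq_along(cls)),
                      class_ = cls, stringsAsFactors = FALSE)
  ann <- data.frame(locus_id = freqs$locus_id, category = cats,
                    stringsAsFactors = FALSE)
  tab <- class_by_category_table(freqs, ann)
  expect_equal(unname(tab$counts["low", "Total"]), 5741)
  expect_equal(unname(tab$counts["Total", "Total"]), 11645)
  expect_equal(unname(tab$percent["low", "Total"]), 30.9)
  expect_equal(unname(tab$percent["median", "Total"]), 26.7)
  expect_equal(unname(tab$percent["high", "Total"]), 23.7)
  expect_equal(unname(tab$percent["fixed", "Total"]), 17.8)
  expect_equal(unname(tab$percent["Total", "CDS"]), 1.2)
  expect_equal(unname(tab$percent["Total", "upstream"]), 10.7)
})

test_that("chi-square homogeneity test matches hand computation", {
  freqs <- data.frame(locus_id = sprintf("l%02d", 1:40),
                      class_ = rep(c("low", "fixed"), each = 20),
                      stringsAsFactors = FALSE)
  loci <- data.frame(locus_id = freqs$locus_id,
                     superfamily = rep(c("A", "B", "A", "B"), each = 10),
                     stringsAsFactors = FALSE)
  # A: 10 low / 10 fixed; B: 10 low / 10 fixed -> homogeneous
  res <- suppressWarnings(class_by_superfamily_chisq(freqs, loci))
  expect_equal(res$statistic, 0)
  expect_equal(res$df, 1)
  # complete separation: chi-square = n
  loci2 <- data.frame(locus_id = freqs$locus_id,
                      superfamily = rep(c("A", "B"), each = 20),
                      stringsAsFactors = FALSE)
  res2 <- suppressWarnings(class_by_superfamily_chisq(freqs, loci2))
  expect_equal(res2$statistic, 40)
  expect_equal(res2$df, 1)
})

test_that("chi-square p-values are uniform under homogeneity", {
  set.seed(60)
  pv <- replicate(200, {
    cls <- sample(c("low", "median", "high", "fixed"), 400, TRUE,
                  prob = c(.3, .3, .2, .2))
    sf <- sample(c("A", "B", "C", "D"), 400, TRUE)
    freqs <- data.frame(locus_id = as.character(1:400), class_ = cls)
    loci <- data.frame(locus_id = freqs$locus_id, superfamily = sf)
    suppressWarnings(class_by_superfamily_chisq(freqs, loci))$p_value
  })
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})
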