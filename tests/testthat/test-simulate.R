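# The cohort simulator: determinism, genome construction guarantees,
# read sampling properties, genotype sampling, and truth-table I/O.

tiny_cfg <- function(seed = 5, ...) {
  sim_config(seed = seed, chrom_lengths = c(chr1 = 12000L),
             n_accessions = c(cabbage = 2L, broccoli = 2L),
             locus_spec = list(list(n = 3L, freq = 0.5,
                                    ref_status = "nonRef",
                                    sampling = "binomial")),
             error_rate = 0, het_rate = 0, dropout_rate = 0, n_genes = 3L,
             ...)
}

test_that("the simulator is fully deterministic under the seed", {
  a <- simulate_cohort(tiny_cfg())
  b <- simulate_cohort(tiny_cfg())
  expect_identical(a$reference, b$reference)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth$genotypes, b$truth$genotypes)
  c_ <- simulate_cohort(tiny_cfg(seed = 6))
  expect_false(identical(a$reference, c_$reference))
})

test_that("the backbone has the configured shape and unique 15-mers", {
  cfg <- tiny_cfg()
  bb <- build_genome(cfg)
  expect_equal(names(bb), "chr1")
  expect_equal(nchar(bb), c(chr1 = 12000L))
  km <- substring(bb, 1:(12000 - 14), 15:12000)
  expect_false(any(duplicated(km)))
})

test_that("the TE library honours the family spec and divergence", {
  cfg <- tiny_cfg()
  tl <- build_te_library(cfg)
  fam <- cfg$te_families
  expect_equal(nrow(tl), sum(fam$copies))
  expect_equal(as.integer(table(tl$family)[fam$family]), fam$copies)
  # within-family copies are ~divergence apart
  cop <- tl$sequence[tl$family == fam$family[1]]
  mism <- mapply(function(a, b) {
    mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, cop[1], cop[2])
  expect_lt(mism, 4 * cfg$divergence)
  expect_error(sim_config(te_families = mobiscan:::default_te_families()[0, ]),
               "at least one family")
})

test_that("target frequencies are realized within binomial bounds", {
  cfg <- sim_config(seed = 30, chrom_lengths = c(chr1 = 60000L, chr2 = 60000L),
                    n_accessions = c(g1 = 40L, g2 = 40L),
                    locus_spec = list(list(n = 60L, freq = 0.5,
                                           ref_status = "nonRef",
                                           sampling = "binomial")),
                    het_rate = 0, dropout_rate = 0, n_genes = 0L)
  bb <- build_genome(cfg)
  tl <- build_te_library(cfg)
  pl <- plant_population(cfg, bb, tl)
  gf <- pl$truth$group_freq
  sigma <- sqrt(0.5 * 0.5 / 40)
  within <- abs(gf - 0.5) <= 3 * sigma
  expect_gte(mean(within), 0.99)
  # degenerate targets
  cfg2 <- tiny_cfg()
  cfg2$locus_spec <- list(list(n = 2L, freq = 1.0, ref_status = "nonRef",
                               sampling = "exact"),
                          list(n = 2L, freq = 0.0, ref_status = "nonRef",
                               sampling = "exact"))
  pl2 <- plant_population(cfg2, build_genome(cfg2), build_te_library(cfg2))
  gf2 <- pl2$truth$group_freq
  tgt <- pl2$truth$target_freq
  expect_true(all(gf2[tgt[, 1] == 1, ] == 1))
  expect_true(all(gf2[tgt[, 1] == 0, ] == 0))
})

test_that("read counts follow the coverage formula and are error-free substrings", {
  cfg <- tiny_cfg()
  cfg$locus_spec <- list(list(n = 1L, freq = 0.0, ref_status = "nonRef",
                              sampling = "exact"))
  co <- simulate_cohort(cfg)
  r1 <- co$reads[[1]]
  expect_equal(length(r1), round(10 * 12000 / 100))
  expect_true(all(nchar(r1) == 100))
  genome <- co$reference[[1]]
  idx <- sample(length(r1), 40)
  hit <- vapply(r1[idx], function(rd)
    grepl(rd, genome, fixed = TRUE) ||
      grepl(unname(revcomp(rd)), genome, fixed = TRUE), logical(1))
  expect_true(all(hit))
})

test_that("empirical depth approximates the target coverage", {
  cfg <- tiny_cfg()
  cfg$locus_spec <- list(list(n = 1L, freq = 0.0, ref_status = "nonRef",
                              sampling = "exact"))
  co <- simulate_cohort(cfg)
  r1 <- co$reads[[1]]
  src <- attr(r1, "source")
  # per-base depth over the (insertion-free) genome
  cov_vec <- integer(12000)
  for (s in src$start) {
    idx <- (s + 1):(s + 100)
    cov_vec[idx] <- cov_vec[idx] + 1L
  }
  inner <- cov_vec[100:11900]  # away from the uncovered chromosome tips
  expect_lt(abs(mean(inner) - 10) / 10, 0.05)
})

test_that("TSDs duplicate the target site around planted insertions", {
  co <- small_sim()
  tr <- co$truth$loci
  ref_loci <- tr[tr$ref_status == "Ref" & tr$tsd_len > 0, ]
  for (i in seq_len(nrow(ref_loci))) {
    s <- ref_loci$span_start[i]; e <- ref_loci$span_end[i]
    t <- ref_loci$tsd_len[i]
    ref <- co$reference[[ref_loci$chrom[i]]]
    expect_equal(substr(ref, s - t + 1, s), substr(ref, e + 1, e + t))
  }
})

test_that("planted presence junctions occur verbatim in carrier genomes", {
  co <- small_sim()
  tr <- co$truth$loci
  # locus table in truth coordinates with the planted donor copy
  loci <- data.frame(locus_id = tr$locus_id, chrom = tr$chrom,
                     pos = tr$pos_left, te_id = tr$te_id, family = tr$family,
                     superfamily = tr$superfamily,
                     side = ifelse(tr$strand == "+", "L", "R"),
                     te_dir = 1L,  # at the left junction the TE lies rightward
                     end_support = "single", ref_status = tr$ref_status,
                     span_start = tr$span_start, span_end = tr$span_end,
                     stringsAsFactors = FALSE)
  tp <- build_templates(loci, co$reference, co$elements)
  pres <- tp[tp$allele == "presence", ]
  for (i in seq_len(nrow(pres))) {
    li <- which(tr$locus_id == pres$locus_id[i])
    carriers <- which(co$truth$genotypes[li, ] == "P")
    if (!length(carriers)) next
    haps <- mobiscan:::accession_haplotypes(co$config, co$backbone,
                                            co$elements, tr,
                                            co$truth$genotypes[, carriers[1]])
    hap <- haps[[1]]$seqs[[tr$chrom[li]]]
    expect_true(grepl(pres$sequence[i], hap, fixed = TRUE) ||
                  grepl(unname(revcomp(pres$sequence[i])), hap, fixed = TRUE),
                info = pres$locus_id[i])
  }
})

test_that("truth tables roundtrip exactly", {
  co <- small_sim()
  d <- withr::local_tempdir()
  write_truth(co$truth, d)
  back <- read_truth(d)
  expect_equal(back$loci, co$truth$loci)
  expect_equal(back$genotypes, co$truth$genotypes)
  expect_equal(back$dropout, co$truth$dropout)
  expect_equal(back$group_freq, co$truth$group_freq, tolerance = 1e-12)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(error_rate = 1.2), "error_rate")
  expect_error(sim_config(chrom_lengths = c(chr1 = 100L)), "too short")
  expect_error(sim_config(coverage = 0), "coverage")
})
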