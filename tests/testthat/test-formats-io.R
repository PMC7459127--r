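# Readers/writers: FASTA/FASTQ, GFF3 gene models, profile tables,
# subgenome blocks and newick, including exact roundtrips on random
# data.

test_that("FASTA parsing handles minimal and wrapped records and maps case", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT"), f)
  expect_equal(read_sequences(f, "fasta"),
               data.frame(id = "a", sequence = "ACGT", stringsAsFactors = FALSE))
  writeLines(c(">a", "AC", "GT", ">b", "acgtn"), f)
  df <- read_sequences(f, "fasta")
  expect_equal(df$sequence, c("ACGT", "ACGTN"))
})

test_that("invalid FASTA records are rejected with the record index", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">b", "ACRT"), f)
  expect_error(read_sequences(f, "fasta"), "record 2")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), f)
  expect_error(read_sequences(f, "fasta"), "duplicate")
})

test_that("sequence roundtrip through FASTA and FASTQ is exact", {
  set.seed(42)
  df <- data.frame(id = sprintf("seq%03d", 1:100),
                   sequence = vapply(sample(30:120, 100, TRUE), rand_dna, ""),
                   stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".fa")
  write_sequences(df, f, "fasta")
  expect_equal(read_sequences(f, "fasta"), df)

  df$qualities <- vapply(nchar(df$sequence), function(n)
    paste(rep("I", n), collapse = ""), "")
  df$mate <- "unpaired"
  fq <- withr::local_tempfile(fileext = ".fq")
  write_sequences(df, fq, "fastq")
  expect_equal(read_sequences(fq, "fastq"), df)
})

test_that("FASTQ mate suffixes are parsed", {
  fq <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1/1", "ACGT", "+", "IIII", "@r1/2", "ACGT", "+", "IIII",
               "@r2", "ACGT", "+", "IIII"), fq)
  expect_equal(read_sequences(fq, "fastq")$mate, c("1", "2", "unpaired"))
})

gff_text <- function(...) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", ...), f)
  f
}

test_that("gene models derive introns as gaps between exons", {
  f <- gff_text(
    "chr1\tsrc\tgene\t1\t300\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tID=e1;Parent=g1.t1",
    "chr1\tsrc\texon\t201\t300\t.\t+\t.\tID=e2;Parent=g1.t1")
  gm <- read_gene_models(f)
  expect_equal(gm$genes$start, 0L)
  expect_equal(gm$genes$end, 300L)
  expect_equal(gm$introns$start, 100L)   # gap [100, 200) in 0-based coords
  expect_equal(gm$introns$end, 200L)

  f2 <- gff_text(
    "chr1\tsrc\tgene\t1\t100\t.\t-\t.\tID=g1",
    "chr1\tsrc\texon\t1\t100\t.\t-\t.\tID=e1;Parent=g1")
  expect_equal(nrow(read_gene_models(f2)$introns), 0L)
})

test_that("gene model errors: exon outside span, unknown strand", {
  f <- gff_text(
    "chr1\tsrc\tgene\t50\t100\t.\t+\t.\tID=g1",
    "chr1\tsrc\texon\t10\t100\t.\t+\t.\tID=e1;Parent=g1")
  expect_error(read_gene_models(f), "outside span")
  f2 <- gff_text("chr1\tsrc\tgene\t50\t100\t.\t.\t.\tID=g1")
  expect_error(read_gene_models(f2), "strand")
})

test_that("gene models roundtrip through GFF3 exactly", {
  set.seed(7)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:8),
                      chrom = rep(c("chr1", "chr2"), 4),
                      strand = sample(c("+", "-"), 8, TRUE),
                      start = seq(0L, by = 5000L, length.out = 8),
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + 2000L
  exons <- do.call(rbind, lapply(1:8, function(i) {
    b <- sort(sample(seq(genes$start[i] + 100, genes$end[i] - 100, 10), 2))
    data.frame(gene_id = genes$gene_id[i],
               start = c(genes$start[i], b[2]), end = c(b[1], genes$end[i]))
  }))
  gm <- mobiscan:::new_gene_models(genes[order(genes$chrom, genes$start), ],
                                   exons, exons, mobiscan:::interval_df())
  gm$introns <- read_gene_models(write_gene_models(gm, tempfile()))$introns
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(gm, f)
  back <- read_gene_models(f)
  expect_equal(back$genes$gene_id, gm$genes$gene_id)
  expect_equal(back$genes$start, gm$genes$start)
  expect_equal(back$genes$end, gm$genes$end)
  expect_equal(back$exons[order(back$exons$gene_id, back$exons$start), ],
               gm$exons[order(gm$exons$gene_id, gm$exons$start), ],
               ignore_attr = TRUE)
})

test_that("profile roundtrip is exact, including the empty profile", {
  d0 <- withr::local_tempdir()
  p0 <- make_profile(matrix(character(0), 0, 3,
                            dimnames = list(NULL, c("a", "b", "c"))),
                     loci = make_loci(0))
  write_profile(p0, d0)
  b0 <- read_profile(d0)
  expect_equal(nrow(b0$loci), 0L)
  expect_equal(b0$accessions, p0$accessions)

  set.seed(1)
  for (dims in list(c(3, 2), c(1000, 50))) {
    calls <- matrix(sample(c("P", "A", "H", "M"), prod(dims), TRUE,
                           prob = c(.5, .3, .1, .1)), dims[1], dims[2])
    prof <- make_profile(calls)
    d <- withr::local_tempdir()
    write_profile(prof, d)
    back <- read_profile(d)
    expect_equal(back$loci, prof$loci)
    expect_equal(back$calls, prof$calls)
    expect_equal(back$presence, prof$presence)
    expect_equal(back$absence, prof$absence)
    expect_equal(back$accessions, prof$accessions)
  }
})

test_that("unknown genotype symbols are rejected on read", {
  prof <- make_profile(matrix(c("P", "A"), 2, 1))
  d <- withr::local_tempdir()
  write_profile(prof, d)
  g <- readLines(file.path(d, "genotypes.tsv"))
  g[2] <- sub("\tP", "\tX", g[2])
  writeLines(g, file.path(d, "genotypes.tsv"))
  expect_error(read_profile(d), "genotype symbol")
})

test_that("newick serialisation validates and roundtrips", {
  t2 <- read_newick(text = "(A:1.5,B:2.25);")
  expect_match(write_newick(t2), "^\\(A:1\\.5,B:2\\.25\\);$")
  t3 <- read_newick(text = "(A:1,B:2,C:3);")
  expect_equal(ape::Ntip(t3), 3L)
  expect_equal(t3$Nnode, 1L)

  dup <- t2; dup$tip.label <- c("A", "A")
  expect_error(write_newick(dup), "duplicate")

  set.seed(5)
  tr <- ape::rtree(20)
  back <- read_newick(text = write_newick(tr))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back))[1], 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-8)
})

test_that("subgenome blocks roundtrip and reject overlap", {
  blocks <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                       start = c(0L, 500L, 0L), end = c(500L, 900L, 400L),
                       label = c("LF", "MF1", "MF2"), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_subgenome_blocks(blocks, f)
  expect_equal(read_subgenome_blocks(f), blocks)
  bad <- blocks; bad$start[2] <- 400L
  expect_error(mobiscan:::check_blocks(bad), "overlap")
})
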