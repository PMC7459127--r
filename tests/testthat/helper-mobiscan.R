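# Shared test utilities: an independent pure-R affine-gap Smith-Waterman
# (the oracle for the compiled aligner), a quick profile builder, and a
# memoised small simulated cohort reused across test files.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Independent affine-gap local alignment by dynamic programming with the
# same conventions as the package aligner: first gap base costs
# gap_open, later ones gap_extend; N never matches; optimum at the
# lowest (a_end, b_end); traceback prefers diagonal, then vertical, then
# horizontal.
r_sw <- function(a, b, match = 1, mismatch = -2, gap_open = -4, gap_extend = -1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b); NEG <- -1e9
  H <- matrix(0, n + 1, m + 1); E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0; bi <- 0; bj <- 0
  for (i in 1:n) for (j in 1:m) {
    E[i + 1, j + 1] <- max(H[i + 1, j] + gap_open, E[i + 1, j] + gap_extend)
    F[i + 1, j + 1] <- max(H[i, j + 1] + gap_open, F[i, j + 1] + gap_extend)
    s <- if (a[i] == b[j] && a[i] != "N") match else mismatch
    h <- max(0, H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
    H[i + 1, j + 1] <- h
    if (h > best) { best <- h; bi <- i; bj <- j }
  }
  if (best == 0)
    return(list(score = 0, matches = 0, aligned_len = 0, identity = 0))
  i <- bi; j <- bj; layer <- "H"; matches <- 0; cols <- 0
  while (i > 0 && j > 0) {
    if (layer == "H") {
      h <- H[i + 1, j + 1]
      if (h == 0) break
      is_m <- a[i] == b[j] && a[i] != "N"
      d <- H[i, j] + (if (is_m) match else mismatch)
      if (h == d) {
        matches <- matches + is_m; cols <- cols + 1; i <- i - 1; j <- j - 1
      } else if (h == F[i + 1, j + 1]) layer <- "F" else layer <- "E"
    } else if (layer == "F") {
      cols <- cols + 1
      if (F[i + 1, j + 1] == H[i, j + 1] + gap_open) layer <- "H"
      i <- i - 1
    } else {
      cols <- cols + 1
      if (E[i + 1, j + 1] == H[i + 1, j] + gap_open) layer <- "H"
      j <- j - 1
    }
  }
  list(score = best, matches = matches, aligned_len = cols,
       identity = matches / cols, a_start = i, a_end = bi,
       b_start = j, b_end = bj)
}

# The oracle redundancy relation: does any (strand) alignment reach the
# length/identity criterion?
r_redundant <- function(sa, sb, min_len, min_ident, both_strands = TRUE) {
  for (s in c(sb, if (both_strands) unname(mobiscan::revcomp(sb)))) {
    al <- r_sw(sa, s)
    if (al$aligned_len >= min_len && al$identity >= min_ident) return(TRUE)
  }
  FALSE
}

# Minimal locus table for constructed profiles.
make_loci <- function(n, family = rep("famA", n), side = rep("L", n),
                      te_dir = rep(1L, n), pos = seq(1000, by = 1000,
                                                     length.out = n),
                      ref_status = rep("nonRef", n), chrom = rep("chr1", n),
                      span_start = rep(NA_integer_, n),
                      span_end = rep(NA_integer_, n)) {
  data.frame(locus_id = sprintf("L%03d", seq_len(n)), chrom = chrom,
             pos = as.integer(pos), te_id = paste0(family, rep("_c1", n)),
             family = family, superfamily = family, side = side,
             te_dir = te_dir, end_support = rep("single", n),
             ref_status = ref_status,
             span_start = span_start, span_end = span_end,
             stringsAsFactors = FALSE)
}

# Build a profile from a call matrix; read counts consistent with calls
# unless given explicitly.
make_profile <- function(calls, loci = NULL, morphotype = NULL,
                         presence = NULL, absence = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); m <- ncol(calls)
  loci <- loci %||% make_loci(n)
  acc <- data.frame(accession = colnames(calls) %||% sprintf("acc%02d", seq_len(m)),
                    morphotype = morphotype %||% rep("cabbage", m),
                    stringsAsFactors = FALSE)
  colnames(calls) <- acc$accession
  if (is.null(presence)) {
    presence <- matrix(0L, n, m)
    presence[calls == "P"] <- 5L
    presence[calls == "H"] <- 3L
  }
  if (is.null(absence)) {
    absence <- matrix(0L, n, m)
    absence[calls == "A"] <- 5L
    absence[calls == "H"] <- 3L
  }
  mobilome_profile(loci, acc, calls, presence, absence)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Memoised small simulated cohort shared across test files.
.sim_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.sim_cache$small)) {
    cfg <- sim_config(
      seed = 11, chrom_lengths = c(chr1 = 30000L),
      n_accessions = c(cabbage = 4L, broccoli = 4L),
      locus_spec = list(
        list(n = 4L, freq = 1.0, ref_status = "Ref", sampling = "exact"),
        list(n = 5L, freq = 0.5, ref_status = "nonRef", sampling = "binomial"),
        list(n = 3L, freq = c(high = 0.95, low = 0.05), differential = TRUE,
             ref_status = "nonRef", sampling = "exact")),
      coverage = 10, error_rate = 0, het_rate = 0, dropout_rate = 0,
      n_genes = 8L)
    .sim_cache$small <- simulate_cohort(cfg)
  }
  .sim_cache$small
}

small_run <- function() {
  if (is.null(.sim_cache$run)) {
    co <- small_sim()
    lib <- build_end_library(co$elements)
    loci <- discover_loci(co$reads, lib, co$reference, co$elements)
    prof <- genotype_population(loci, co$reads, co$accessions, co$reference,
                                co$elements)
    fl <- apply_filters(prof)
    .sim_cache$run <- list(cohort = co, library = lib, loci = loci,
                           raw = prof, profile = fl$profile,
                           report = fl$report)
  }
  .sim_cache$run
}

# Match called loci to planted truth within a breakpoint window of
# either junction; returns the truth row index per called locus (NA
# when unmatched).
match_truth <- function(called_loci, truth_loci, window = 15) {
  vapply(seq_len(nrow(called_loci)), function(i) {
    ok <- truth_loci$chrom == called_loci$chrom[i] &
      (abs(truth_loci$pos_left - called_loci$pos[i]) <= window |
         abs(truth_loci$pos_right - called_loci$pos[i]) <= window)
    if (any(ok)) which(ok)[1] else NA_integer_
  }, integer(1))
}
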