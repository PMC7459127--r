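# Deterministic mobilome cohort simulator: a uniform-random reference
# backbone with globally unique 15-mers at planted flanks, a TE library
# spanning the major superfamilies with diverged within-family copies,
# a structured population of mostly-homozygous accessions carrying
# TSD-flanked insertions at configured per-morphotype frequencies
# (including planted differential-fixed loci), uniform-coverage reads
# with a configurable substitution error rate, and full truth tables.
#
# Every stage draws from its own RNG stream derived from the master
# seed, so outputs are reproducible and stages are independent.

default_te_families <- function() {
  data.frame(
    family = c("Pong-1", "CACTA-1", "Heli-1", "Copia-1", "Gypsy-1",
               "SINE-1", "L1-1"),
    superfamily = c("Pong", "CACTA", "Helitron", "Copia", "Gypsy",
                    "tRNA", "L1"),
    class_ = c("DNA", "DNA", "DNA", "Retro", "Retro", "Retro", "Retro"),
    order_ = c("TIR", "TIR", "Helitron", "LTR", "LTR", "SINE", "LINE"),
    length = c(400L, 500L, 450L, 600L, 600L, 200L, 500L),
    copies = c(4L, 4L, 4L, 4L, 3L, 3L, 2L),
    tsd = c(5L, 3L, 0L, 5L, 5L, 8L, 10L),
    stringsAsFactors = FALSE)
}

default_locus_spec <- function() {
  list(
    list(n = 10L, freq = 1.00, ref_status = "Ref",    sampling = "exact"),
    list(n = 12L, freq = 0.15, ref_status = "nonRef", sampling = "binomial"),
    list(n = 12L, freq = 0.50, ref_status = "nonRef", sampling = "binomial"),
    list(n = 8L,  freq = 0.85, ref_status = "nonRef", sampling = "binomial"),
    list(n = 8L,  freq = c(high = 0.95, low = 0.05), differential = TRUE,
         ref_status = "nonRef", sampling = "exact"))
}

#' Simulation configuration
#'
#' Bundles and validates all generator parameters. The defaults define
#' a desk-scale cohort: 20 accessions across four morphotypes, a 100-kb
#' two-chromosome genome, a 24-element TE library over seven
#' superfamilies (within-family copies diverged by 2%), 50 planted loci
#' spanning the low/median/high/fixed frequency classes plus eight
#' differential-fixed loci (0.95 vs 0.05 between morphotypes), 10-fold
#' uniform coverage of 100-bp reads with a 1% substitution error rate,
#' occasional heterozygotes (5% of carrier calls) and rare coverage
#' dropout (2% of accession-locus pairs).
#'
#' @param seed master seed; fully determines all outputs.
#' @param chrom_lengths named integer vector of backbone lengths.
#' @param te_families data.frame (`family`, `superfamily`, `class_`,
#'   `order_`, `length`, `copies`, `tsd`).
#' @param divergence within-family copy divergence (substitution
#'   fraction).
#' @param n_accessions named integer vector: accessions per morphotype.
#' @param locus_spec list of entries `list(n, freq, ref_status,
#'   sampling, differential, het_rate)`; `freq` is a scalar, a named
#'   per-group vector, or `c(high=, low=)` with `differential = TRUE`
#'   (the high group rotates across morphotypes).
#' @param coverage target fold coverage per accession.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error rate.
#' @param het_rate probability that a carrier accession is heterozygous
#'   at a locus.
#' @param dropout_rate probability that an accession-locus pair loses
#'   its junction-spanning coverage (emulates missing calls).
#' @param min_spacing minimum distance between planted loci.
#' @param n_genes number of toy gene models placed on the backbone.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 50000L, chr2 = 50000L),
                       te_families = default_te_families(),
                       divergence = 0.02,
                       n_accessions = c(cabbage = 5L, kohlrabi = 5L,
                                        cauliflower = 5L, broccoli = 5L),
                       locus_spec = default_locus_spec(),
                       coverage = 10, read_length = 100L, error_rate = 0.01,
                       het_rate = 0.05, dropout_rate = 0.02,
                       min_spacing = NULL, n_genes = 40L) {
  if (!nrow(te_families)) stopf("te_families must contain at least one family")
  stopifnot(all(te_families$copies >= 1), all(te_families$length >= 50),
            all(te_families$tsd >= 0))
  stopifnot(coverage > 0, read_length >= 30, error_rate >= 0, error_rate < 1,
            het_rate >= 0, het_rate <= 1, dropout_rate >= 0, dropout_rate < 1)
  if (any(chrom_lengths < 4 * read_length)) stopf("chromosomes too short")
  for (e in locus_spec) {
    stopifnot(e$n >= 0, all(e$freq >= 0), all(e$freq <= 1),
              e$ref_status %in% c("Ref", "nonRef"))
  }
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 te_families = te_families, divergence = divergence,
                 n_accessions = n_accessions, locus_spec = locus_spec,
                 coverage = coverage, read_length = as.integer(read_length),
                 error_rate = error_rate, het_rate = het_rate,
                 dropout_rate = dropout_rate,
                 min_spacing = as.integer(min_spacing %||% (2L * read_length)),
                 n_genes = as.integer(n_genes)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: seed %d, %d chrom (%d bp), %d accessions, ",
                     "%d loci, %gx coverage, %g%% error\n"),
              x$seed, length(x$chrom_lengths), sum(x$chrom_lengths),
              sum(x$n_accessions), sum(vapply(x$locus_spec, `[[`, 0L, "n")),
              x$coverage, 100 * x$error_rate))
  invisible(x)
}

# Mutate single bases until no 15-mer occurs twice genome-wide, which
# guarantees that every planted flank maps uniquely.
enforce_unique_kmers <- function(seqs, k = 15, max_iter = 50) {
  for (iter in seq_len(max_iter)) {
    km <- lapply(seqs, function(s) {
      n <- nchar(s)
      if (n < k) character(0) else
        substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
    })
    all_km <- unlist(km, use.names = FALSE)
    dup <- unique(all_km[duplicated(all_km)])
    if (!length(dup)) return(seqs)
    for (d in dup) {
      for (ci in seq_along(seqs)) {
        hit <- which(km[[ci]] == d)
        if (length(hit)) {
          p <- hit[length(hit)] + sample.int(k, 1) - 1L
          old <- substr(seqs[[ci]], p, p)
          substr(seqs[[ci]], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
          break
        }
      }
    }
  }
  stopf("could not make genome %d-mers unique after %d rounds", k, max_iter)
}

#' Generate the reference backbone
#'
#' I.i.d. uniform ACGT sequence per chromosome, post-processed so that
#' no 15-mer occurs twice genome-wide (single-base resampling), which
#' guarantees unique flank mapping for any planted locus. Deterministic
#' under the config seed.
#'
#' @param config a [sim_config()].
#' @return named character vector of chromosome sequences.
#' @export
build_genome <- function(config) {
  set.seed(stage_seed(config$seed, "genome"))
  seqs <- vapply(config$chrom_lengths, random_dna, character(1))
  unlist(enforce_unique_kmers(as.list(seqs)))
}

#' Generate the TE element library
#'
#' One random consensus per family; within-family copies are
#' independently diverged from the consensus by the configured
#' substitution fraction.
#'
#' @param config a [sim_config()].
#' @return TE element table ([te_elements()]).
#' @export
build_te_library <- function(config) {
  set.seed(stage_seed(config$seed, "telib"))
  fam <- config$te_families
  rows <- list()
  for (i in seq_len(nrow(fam))) {
    consensus <- random_dna(fam$length[i])
    for (cpy in seq_len(fam$copies[i])) {
      rows[[length(rows) + 1]] <- data.frame(
        te_id = sprintf("%s_c%d", fam$family[i], cpy),
        class_ = fam$class_[i], order_ = fam$order_[i],
        superfamily = fam$superfamily[i], family = fam$family[i],
        sequence = mutate_dna(consensus, config$divergence),
        stringsAsFactors = FALSE)
    }
  }
  el <- do.call(rbind, rows)
  te_elements(el$te_id, el$class_, el$order_, el$superfamily, el$family,
              el$sequence)
}

# Expand the locus spec into per-locus target frequencies per group.
expand_locus_spec <- function(config) {
  groups <- names(config$n_accessions)
  rows <- list()
  for (e in config$locus_spec) {
    if (e$n == 0) next
    for (i in seq_len(e$n)) {
      if (isTRUE(e$differential)) {
        hi_g <- groups[(i - 1) %% length(groups) + 1]
        f <- setNames(rep(e$freq[["low"]], length(groups)), groups)
        f[hi_g] <- e$freq[["high"]]
      } else if (!is.null(names(e$freq)) && length(e$freq) > 1) {
        f <- e$freq[groups]
      } else {
        f <- setNames(rep(unname(e$freq)[1], length(groups)), groups)
      }
      rows[[length(rows) + 1]] <- list(freq = f, ref_status = e$ref_status,
                                       sampling = e$sampling %||% "binomial",
                                       het_rate = e$het_rate %||% config$het_rate)
    }
  }
  rows
}

# Choose spaced insertion positions per chromosome.
choose_positions <- function(config, n_loci) {
  lens <- config$chrom_lengths
  margin <- 2L * config$read_length + 200L
  alloc <- floor(n_loci * lens / sum(lens))
  rem <- n_loci - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
  gap <- config$min_spacing + 800L  # room for the TE body plus templates
  out <- list()
  for (ci in seq_along(lens)) {
    k <- alloc[ci]
    if (k == 0) next
    lo <- margin; hi <- lens[ci] - margin
    slack <- (hi - lo) - (k - 1L) * gap
    if (slack < k) stopf("cannot place %d loci on %s with the required spacing",
                         k, names(lens)[ci])
    p <- lo + sort(sample.int(slack, k)) + (seq_len(k) - 1L) * gap
    out[[names(lens)[ci]]] <- p
  }
  out
}

#' Plant a structured population of TE insertions
#'
#' Assigns each configured locus a position, a donor TE copy, a strand
#' and the family's target-site duplication length; samples per-group
#' genotypes (binomially or by exact carrier counts, heterozygous with
#' the configured rate among carriers); inserts Ref loci into the
#' emitted reference; and records the full truth (positions in both
#' backbone and reference coordinates, true genotypes, dropout mask,
#' realized group frequencies).
#'
#' @param config a [sim_config()].
#' @param backbone named character vector from [build_genome()].
#' @param telib TE element table from [build_te_library()].
#' @return list with `reference` (named character vector), `accessions`
#'   (data.frame), and `truth` (list: `loci`, `genotypes`, `dropout`,
#'   `group_freq`).
#' @export
plant_population <- function(config, backbone, telib) {
  set.seed(stage_seed(config$seed, "plant"))
  spec <- expand_locus_spec(config)
  n_loci <- length(spec)
  groups <- names(config$n_accessions)
  acc <- data.frame(
    accession = unlist(lapply(groups, function(g)
      sprintf("%s_%02d", g, seq_len(config$n_accessions[[g]])))),
    morphotype = rep(groups, config$n_accessions),
    stringsAsFactors = FALSE)
  m <- nrow(acc)

  pos_by_chrom <- choose_positions(config, n_loci)
  fam <- config$te_families
  loci <- data.frame(
    locus_id = sprintf("SIM%03d", seq_len(n_loci)),
    chrom = rep(names(pos_by_chrom), lengths(pos_by_chrom)),
    backbone_pos = unlist(pos_by_chrom, use.names = FALSE),
    stringsAsFactors = FALSE)
  ord <- sample.int(n_loci)  # decouple spec order from genome order
  loci$ref_status <- vapply(spec, `[[`, "", "ref_status")[ord]
  loci$sampling <- vapply(spec, `[[`, "", "sampling")[ord]
  loci$het_rate <- vapply(spec, function(e) e$het_rate, 0)[ord]
  target <- do.call(rbind, lapply(spec, `[[`, "freq"))[ord, , drop = FALSE]
  colnames(target) <- groups

  pick <- sample.int(nrow(telib), n_loci, replace = TRUE)
  loci$te_id <- telib$te_id[pick]
  loci$family <- telib$family[pick]
  loci$superfamily <- telib$superfamily[pick]
  loci$te_len <- nchar(telib$sequence)[pick]
  loci$strand <- sample(c("+", "-"), n_loci, replace = TRUE)
  loci$tsd_len <- fam$tsd[match(loci$family, fam$family)]

  # genotypes: loci x accessions over P/H/A
  geno <- matrix("A", n_loci, m, dimnames = list(loci$locus_id, acc$accession))
  for (l in seq_len(n_loci)) {
    for (g in groups) {
      cols <- which(acc$morphotype == g)
      f <- target[l, g]
      carrier <- if (loci$sampling[l] == "exact") {
        k <- round(f * length(cols))
        seq_along(cols) %in% sample(seq_along(cols), k)
      } else {
        runif(length(cols)) < f
      }
      st <- ifelse(carrier,
                   ifelse(runif(length(cols)) < loci$het_rate[l], "H", "P"), "A")
      geno[l, cols] <- st
    }
  }
  dropout <- matrix(runif(n_loci * m) < config$dropout_rate, n_loci, m,
                    dimnames = dimnames(geno))

  # reference: backbone plus Ref insertions; track coordinate shifts
  ref_idx <- which(loci$ref_status == "Ref")
  reference <- backbone
  loci$span_start <- NA_integer_; loci$span_end <- NA_integer_
  loci$pos_left <- NA_integer_; loci$pos_right <- NA_integer_
  for (ch in names(backbone)) {
    on_ch <- which(loci$chrom == ch)
    ins <- intersect(on_ch, ref_idx)
    ins <- ins[order(loci$backbone_pos[ins])]
    shift <- 0L
    shifts <- integer(0)
    for (i in ins) {
      shifts <- c(shifts, shift)
      shift <- shift + loci$te_len[i] + loci$tsd_len[i]
    }
    # reference-coordinate positions for all loci on this chromosome
    for (i in on_ch) {
      p <- loci$backbone_pos[i]
      sh <- 0L
      for (kk in seq_along(ins)) {
        if (loci$backbone_pos[ins[kk]] < p) sh <- shifts[kk] +
            loci$te_len[ins[kk]] + loci$tsd_len[ins[kk]]
      }
      if (loci$ref_status[i] == "Ref") {
        s <- p + sh + loci$tsd_len[i]
        loci$span_start[i] <- s
        loci$span_end[i] <- s + loci$te_len[i]
        loci$pos_left[i] <- s
        loci$pos_right[i] <- s + loci$te_len[i]
      } else {
        loci$pos_left[i] <- p + sh + loci$tsd_len[i]
        loci$pos_right[i] <- p + sh
      }
    }
    if (length(ins)) {
      seqs <- telib$sequence[match(loci$te_id[ins], telib$te_id)]
      seqs <- ifelse(loci$strand[ins] == "+", seqs, unname(revcomp(seqs)))
      reference[[ch]] <- build_haplotype(backbone[[ch]],
                                         loci$backbone_pos[ins],
                                         loci$tsd_len[ins], seqs)$seq
    }
  }
  loci$pos <- pmin(loci$pos_left, loci$pos_right)

  group_freq <- t(apply(geno, 1, function(g) {
    vapply(groups, function(gr)
      mean(g[acc$morphotype == gr] %in% c("P", "H")), numeric(1))
  }))
  colnames(group_freq) <- groups
  list(reference = reference, accessions = acc,
       truth = list(loci = loci, genotypes = geno, dropout = dropout,
                    group_freq = group_freq, target_freq = target))
}

# Insert TE copies (with their TSD duplications) into one backbone
# chromosome; positions are 0-based insertion offsets, sorted.
build_haplotype <- function(chrom_seq, pos, tsd_len, seqs) {
  o <- order(pos)
  pos <- pos[o]; tsd_len <- tsd_len[o]; seqs <- seqs[o]
  parts <- character(0); last <- 0L
  starts <- integer(length(pos)); shift <- 0L
  for (i in seq_along(pos)) {
    parts <- c(parts, substr(chrom_seq, last + 1, pos[i] + tsd_len[i]))
    starts[i] <- pos[i] + tsd_len[i] + shift
    parts <- c(parts, seqs[i])
    shift <- shift + nchar(seqs[i]) + tsd_len[i]
    last <- pos[i]
  }
  parts <- c(parts, substr(chrom_seq, last + 1, nchar(chrom_seq)))
  list(seq = paste(parts, collapse = ""), te_starts = starts,
       te_ends = starts + nchar(seqs))
}

# Build both haplotypes of an accession and the junction coordinates of
# every locus in haplotype coordinates (for dropout masking).
accession_haplotypes <- function(config, backbone, telib, loci, geno_col) {
  haps <- list()
  for (h in 1:2) {
    carried <- geno_col == "P" | (geno_col == "H" & h == 1)
    seqs_all <- list(); junctions <- list()
    for (ch in names(backbone)) {
      on_ch <- which(loci$chrom == ch)
      ins <- on_ch[carried[on_ch]]
      ins <- ins[order(loci$backbone_pos[ins])]
      tseq <- telib$sequence[match(loci$te_id[ins], telib$te_id)]
      tseq <- ifelse(loci$strand[ins] == "+", tseq, unname(revcomp(tseq)))
      hb <- build_haplotype(backbone[[ch]], loci$backbone_pos[ins],
                            loci$tsd_len[ins], tseq)
      seqs_all[[ch]] <- hb$seq
      # junction points per locus on this chromosome, hap coordinates
      jx <- vector("list", length(on_ch)); names(jx) <- loci$locus_id[on_ch]
      cum <- function(p) { # shift from carried insertions left of p
        sh <- 0L
        for (k in seq_along(ins))
          if (loci$backbone_pos[ins[k]] < p)
            sh <- sh + loci$te_len[ins[k]] + loci$tsd_len[ins[k]]
        sh
      }
      for (i in on_ch) {
        p <- loci$backbone_pos[i]
        if (i %in% ins) {
          k <- which(ins == i)
          jx[[loci$locus_id[i]]] <- c(hb$te_starts[k], hb$te_ends[k])
        } else {
          jx[[loci$locus_id[i]]] <- p + cum(p)
        }
      }
      junctions[[ch]] <- jx
    }
    haps[[h]] <- list(seqs = seqs_all, junctions = junctions)
  }
  haps
}

# Uniform read sampling from a haplotype set with substitution errors.
sample_reads <- function(seq_list, n_reads, read_length, error_rate, prefix) {
  lens <- vapply(seq_list, nchar, 0L)
  if (any(lens < read_length)) stopf("read length exceeds a sequence length")
  pick <- sample.int(length(seq_list), n_reads, replace = TRUE,
                     prob = lens / sum(lens))
  starts <- integer(n_reads)
  for (ci in seq_along(seq_list)) {
    idx <- which(pick == ci)
    starts[idx] <- sample.int(lens[ci] - read_length + 1L, length(idx),
                              replace = TRUE)
  }
  reads <- substring(unlist(seq_list)[pick], starts, starts + read_length - 1L)
  rc <- runif(n_reads) < 0.5
  reads[rc] <- unname(revcomp(reads[rc]))
  if (error_rate > 0) {
    long <- paste(reads, collapse = "")
    bases <- strsplit(long, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(bases)) < error_rate)
    if (length(hit)) {
      bases[hit] <- vapply(bases[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      long <- paste(bases, collapse = "")
      reads <- substring(long, seq(1, by = read_length, length.out = n_reads),
                         seq(read_length, by = read_length, length.out = n_reads))
    }
  }
  names(reads) <- sprintf("%s_r%06d", prefix, seq_len(n_reads))
  attr(reads, "source") <- data.frame(seq = pick, start = starts - 1L,
                                      revcomp = rc)
  reads
}

#' Simulate reads for every accession
#'
#' Draws fixed-length reads with i.i.d. uniform start positions from
#' both haplotypes of each accession (expected depth = `coverage`),
#' random strand, and per-base substitution errors. Reads overlapping
#' the junctions of a dropped-out accession-locus pair are removed to
#' emulate missing calls. Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @param backbone backbone from [build_genome()].
#' @param telib TE library.
#' @param planted result of [plant_population()].
#' @return named list (per accession) of named read vectors.
#' @export
simulate_reads <- function(config, backbone, telib, planted) {
  loci <- planted$truth$loci
  acc <- planted$accessions
  out <- list()
  for (j in seq_len(nrow(acc))) {
    set.seed(stage_seed(config$seed, "reads", j))
    haps <- accession_haplotypes(config, backbone, telib, loci,
                                 planted$truth$genotypes[, j])
    seq_list <- c(haps[[1]]$seqs, haps[[2]]$seqs)
    names(seq_list) <- paste0(rep(names(backbone), 2), "_h", rep(1:2, each = length(backbone)))
    total_len <- sum(vapply(seq_list, nchar, 0L))
    n_reads <- round(config$coverage * total_len / (2 * config$read_length))
    reads <- sample_reads(seq_list, n_reads, config$read_length,
                          config$error_rate, acc$accession[j])
    dropped <- which(planted$truth$dropout[, j])
    if (length(dropped)) {
      src <- attr(reads, "source")
      kill <- rep(FALSE, length(reads))
      for (l in dropped) {
        ch <- loci$chrom[l]; lid <- loci$locus_id[l]
        for (h in 1:2) {
          jx <- haps[[h]]$junctions[[ch]][[lid]]
          sidx <- match(paste0(ch, "_h", h), names(seq_list))
          for (jp in jx) {
            kill <- kill | (src$seq == sidx & src$start < jp &
                              src$start + config$read_length > jp)
          }
        }
      }
      reads <- reads[!kill]
    }
    out[[acc$accession[j]]] <- reads
  }
  out
}

#' Run the full simulator
#'
#' Backbone, TE library, planted population, reference, reads, gene
#' models and subgenome blocks, all deterministic under the config
#' seed.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `backbone`, `reference`, `elements`,
#'   `accessions`, `reads`, `truth`, `gene_models`, `blocks`.
#' @export
simulate_cohort <- function(config) {
  backbone <- build_genome(config)
  telib <- build_te_library(config)
  planted <- plant_population(config, backbone, telib)
  reads <- simulate_reads(config, backbone, telib, planted)
  genes <- simulate_gene_models(config, planted)
  blocks <- simulate_blocks(config, planted)
  list(config = config, backbone = backbone, reference = planted$reference,
       elements = telib, accessions = planted$accessions, reads = reads,
       truth = planted$truth, gene_models = genes, blocks = blocks)
}

# Toy gene models on the reference, placed clear of planted loci.
simulate_gene_models <- function(config, planted) {
  set.seed(stage_seed(config$seed, "genes"))
  loci <- planted$truth$loci
  ref_lens <- vapply(planted$reference, nchar, 0L)
  genes <- list(); exons <- list(); cds <- list()
  gi <- 0L
  for (attempt in seq_len(config$n_genes * 20)) {
    if (gi >= config$n_genes) break
    ch <- sample(names(ref_lens), 1)
    glen <- sample(900:1500, 1)
    if (ref_lens[[ch]] < glen + 200) next
    s <- sample.int(ref_lens[[ch]] - glen - 100, 1) + 50L
    e <- s + glen
    # keep clear of TE loci and of genes already placed
    near <- loci$chrom == ch & loci$pos > s - 600 & loci$pos < e + 600
    if (any(near)) next
    clash <- vapply(genes, function(g)
      g$chrom == ch && s < g$end + 100 && e > g$start - 100, logical(1))
    if (any(clash)) next
    gi <- gi + 1L
    gid <- sprintf("gene%03d", gi)
    n_ex <- sample(1:3, 1)
    bounds <- sort(sample(seq(s + 100, e - 100, by = 10), 2 * (n_ex - 1)))
    ex_s <- c(s, bounds[seq_along(bounds) %% 2 == 0])
    ex_e <- c(bounds[seq_along(bounds) %% 2 == 1], e)
    genes[[gi]] <- list(gene_id = gid, chrom = ch,
                        strand = sample(c("+", "-"), 1), start = s, end = e)
    exons[[gi]] <- interval_df(gid, ex_s, ex_e)
    cds[[gi]] <- interval_df(gid, ex_s, ex_e)
  }
  gdf <- do.call(rbind, lapply(genes, as.data.frame))
  if (is.null(gdf)) gdf <- data.frame(gene_id = character(), chrom = character(),
                                      strand = character(), start = integer(),
                                      end = integer())
  exdf <- do.call(rbind, exons) %||% interval_df()
  cddf <- do.call(rbind, cds) %||% interval_df()
  introns <- interval_df()
  for (k in seq_len(nrow(gdf))) {
    ex <- exdf[exdf$gene_id == gdf$gene_id[k], , drop = FALSE]
    if (nrow(ex) > 1) {
      m <- merge_intervals(ex$start, ex$end)
      if (length(m$start) > 1)
        introns <- rbind(introns, interval_df(gdf$gene_id[k],
                                              m$end[-length(m$end)], m$start[-1]))
    }
  }
  o <- order(gdf$chrom, gdf$start)
  new_gene_models(gdf[o, , drop = FALSE], exdf, cddf, introns)
}

# Partition each reference chromosome into LF/MF1/MF2 blocks.
simulate_blocks <- function(config, planted) {
  set.seed(stage_seed(config$seed, "blocks"))
  labels <- c("LF", "MF1", "MF2")
  out <- list()
  for (ci in seq_along(planted$reference)) {
    ch <- names(planted$reference)[ci]
    L <- nchar(planted$reference[[ci]])
    cuts <- sort(sample.int(L - 2, 2))
    lab <- labels[((ci - 1 + 0:2) %% 3) + 1]
    out[[ci]] <- data.frame(chrom = ch, start = c(0L, cuts),
                            end = c(cuts, L), label = lab,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write / read simulator truth tables
#'
#' Emits `truth_loci.tsv` (1-based positions), `truth_genotypes.tsv`,
#' `truth_dropout.tsv` and `truth_group_freq.tsv` under `dir`;
#' `read_truth()` is the exact inverse.
#'
#' @param truth the `truth` element of [simulate_cohort()].
#' @param dir output directory.
#' @return `dir` invisibly; `read_truth()` returns the truth list.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # pos columns are already the 1-based index of the base left of the
  # insertion point; only the half-open span start needs shifting
  tab <- truth$loci
  tab$span_start <- tab$span_start + 1L
  write.table(tab, file.path(dir, "truth_loci.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_matrix_tsv(truth$genotypes, rownames(truth$genotypes),
                   file.path(dir, "truth_genotypes.tsv"))
  write_matrix_tsv(ifelse(truth$dropout, "1", "0"), rownames(truth$dropout),
                   file.path(dir, "truth_dropout.tsv"))
  gf <- data.frame(locus_id = rownames(truth$group_freq),
                   truth$group_freq, check.names = FALSE)
  write.table(gf, file.path(dir, "truth_group_freq.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  loci <- read.delim(file.path(dir, "truth_loci.tsv"), stringsAsFactors = FALSE,
                     colClasses = c(locus_id = "character", chrom = "character",
                                    te_id = "character"))
  loci$span_start <- as.integer(loci$span_start) - 1L
  loci$het_rate <- as.numeric(loci$het_rate)
  geno <- read_matrix_tsv(file.path(dir, "truth_genotypes.tsv"), "character")
  drp <- read_matrix_tsv(file.path(dir, "truth_dropout.tsv"), "character") == "1"
  gf <- read.delim(file.path(dir, "truth_group_freq.tsv"),
                   stringsAsFactors = FALSE, check.names = FALSE)
  gfm <- as.matrix(gf[, -1, drop = FALSE])
  rownames(gfm) <- gf$locus_id
  list(loci = loci, genotypes = geno, dropout = drp, group_freq = gfm)
}
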