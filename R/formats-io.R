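# Readers and writers for the standard formats the pipeline touches
# (FASTA/FASTQ via Biostrings, GFF3 via rtracklayer, newick via ape) and
# for the pipeline's own tabular artifacts (locus tables, genotype and
# support-count matrices, subgenome blocks). All emitted tables use
# 1-based inclusive coordinates; everything internal is 0-based half-open.

#' Read sequences from FASTA or FASTQ
#'
#' Returns one row per record, in file order. Lowercase bases are mapped
#' to uppercase; line-wrapped FASTA records are concatenated. Characters
#' outside `{A,C,G,T,N}` are rejected. For FASTQ, a `/1` or `/2` suffix on
#' the read id is parsed into the `mate` column (`1`, `2` or `unpaired`);
#' qualities are carried verbatim but are not used anywhere in scoring
#' (all downstream calling is count-based).
#'
#' @param path file path.
#' @param format `"fasta"` or `"fastq"`.
#' @return data.frame with columns `id`, `sequence` and, for FASTQ,
#'   `qualities` and `mate`.
#' @export
read_sequences <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file does not exist: %s", path)
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                    error = function(e) stopf("malformed FASTA '%s': %s",
                                              path, conditionMessage(e)))
    df <- data.frame(id = names(set),
                     sequence = toupper(as.character(set)),
                     stringsAsFactors = FALSE)
  } else {
    set <- tryCatch(Biostrings::readBStringSet(path, format = "fastq",
                                               with.qualities = TRUE),
                    error = function(e) stopf("malformed FASTQ '%s': %s",
                                              path, conditionMessage(e)))
    quals <- as.character(S4Vectors::mcols(set)$qualities)
    seqs <- toupper(as.character(set))
    bad <- nchar(quals) != nchar(seqs)
    if (any(bad))
      stopf("record %d: quality length differs from sequence length",
            which(bad)[1])
    ids <- names(set)
    mate <- rep("unpaired", length(ids))
    mate[grepl("/1$", ids)] <- "1"
    mate[grepl("/2$", ids)] <- "2"
    df <- data.frame(id = ids, sequence = seqs, qualities = quals,
                     mate = mate, stringsAsFactors = FALSE)
  }
  rownames(df) <- NULL
  if (nrow(df)) {
    if (any(df$id == "")) stopf("record %d has an empty id", which(df$id == "")[1])
    if (anyDuplicated(df$id))
      stopf("duplicate id '%s'", df$id[duplicated(df$id)][1])
    if (any(nchar(df$sequence) == 0))
      stopf("record %d has an empty sequence", which(nchar(df$sequence) == 0)[1])
    bad <- grepl("[^ACGTN]", df$sequence)
    if (any(bad))
      stopf("record %d contains characters outside {A,C,G,T,N}", which(bad)[1])
  }
  df
}

#' Write sequences to FASTA or FASTQ
#'
#' @param x data.frame as returned by [read_sequences()], or a named
#'   character vector of sequences (FASTA only).
#' @param path output file path.
#' @param format `"fasta"` or `"fastq"` (FASTQ requires a `qualities`
#'   column).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (is.character(x)) {
    x <- data.frame(id = names(x) %||% as.character(seq_along(x)),
                    sequence = unname(x), stringsAsFactors = FALSE)
  }
  set <- Biostrings::BStringSet(setNames(x$sequence, x$id))
  if (format == "fasta") {
    Biostrings::writeXStringSet(set, path, format = "fasta")
  } else {
    if (is.null(x$qualities)) stopf("FASTQ output requires a 'qualities' column")
    Biostrings::writeXStringSet(set, path, format = "fastq",
                                qualities = Biostrings::BStringSet(x$qualities))
  }
  invisible(path)
}

# ---- gene models (GFF3) ----------------------------------------------------

new_gene_models <- function(genes, exons, cds, introns) {
  structure(list(genes = genes, exons = exons, cds = cds, introns = introns),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons, %d CDS segments\n",
              nrow(x$genes), nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

interval_df <- function(gene_id = character(), start = integer(),
                        end = integer()) {
  data.frame(gene_id = gene_id, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

# Merge overlapping/adjacent sorted intervals of one gene.
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]; out_s <- integer(); out_e <- integer()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- start[i]; me <- end[i] }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

#' Read gene models from GFF3
#'
#' Parses `gene`/`mRNA`/`exon`/`CDS` features, resolves `Parent`
#' attributes up to the enclosing gene, converts the GFF3 1-based
#' inclusive coordinates to the internal 0-based half-open convention,
#' and derives introns deterministically as the gaps between the merged
#' exon intervals within the gene span.
#'
#' @param path GFF3 file.
#' @return a `gene_models` object: list of data.frames `genes`
#'   (`gene_id`, `chrom`, `strand`, `start`, `end`), `exons`, `cds` and
#'   `introns` (`gene_id`, `start`, `end`).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stopf("file does not exist: %s", path)
  g <- as.data.frame(rtracklayer::readGFF(path))
  g$ID <- as.character(g$ID)
  parent <- vapply(g$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
                   character(1))
  id2row <- setNames(seq_len(nrow(g)), g$ID)

  resolve_gene <- function(i) {
    depth <- 0
    while (!is.na(i) && g$type[i] != "gene" && depth < 10) {
      p <- parent[i]
      i <- if (!is.na(p) && p %in% names(id2row)) id2row[[p]] else NA_integer_
      depth <- depth + 1
    }
    i
  }

  gi <- which(g$type == "gene")
  strands <- as.character(g$strand[gi])
  if (any(!strands %in% c("+", "-")))
    stopf("gene '%s' has unknown strand", g$ID[gi[!strands %in% c("+", "-")][1]])
  genes <- data.frame(gene_id = g$ID[gi], chrom = as.character(g$seqid[gi]),
                      strand = strands, start = g$start[gi] - 1L,
                      end = as.integer(g$end[gi]), stringsAsFactors = FALSE)

  collect <- function(type) {
    fi <- which(g$type == type)
    if (!length(fi)) return(interval_df())
    owner <- vapply(fi, function(i) {
      j <- resolve_gene(i)
      if (is.na(j)) NA_character_ else g$ID[j]
    }, character(1))
    if (any(is.na(owner))) stopf("%s feature without a resolvable gene parent", type)
    interval_df(owner, g$start[fi] - 1L, g$end[fi])
  }
  exons <- collect("exon")
  cds <- collect("CDS")

  introns <- interval_df()
  for (k in seq_len(nrow(genes))) {
    gid <- genes$gene_id[k]
    ex <- exons[exons$gene_id == gid, , drop = FALSE]
    if (!nrow(ex)) next
    if (any(ex$start < genes$start[k] | ex$end > genes$end[k]))
      stopf("exon outside span of gene '%s'", gid)
    m <- merge_intervals(ex$start, ex$end)
    if (length(m$start) > 1) {
      introns <- rbind(introns,
                       interval_df(gid, m$end[-length(m$end)], m$start[-1]))
    }
  }
  o <- order(genes$chrom, genes$start)
  new_gene_models(genes[o, , drop = FALSE], exons, cds, introns)
}

#' Write gene models to GFF3
#'
#' Emits one `gene` feature plus a single `mRNA` with `exon` and `CDS`
#' children per gene, converting back to 1-based inclusive coordinates.
#' `read_gene_models(write_gene_models(x))` reproduces `x` exactly.
#'
#' @param models a `gene_models` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  rows <- list()
  add <- function(chrom, type, start, end, strand, attrs) {
    rows[[length(rows) + 1]] <<- sprintf("%s\tmobiscan\t%s\t%d\t%d\t.\t%s\t.\t%s",
                                         chrom, type, start + 1L, end, strand, attrs)
  }
  gs <- models$genes
  for (k in seq_len(nrow(gs))) {
    gid <- gs$gene_id[k]
    add(gs$chrom[k], "gene", gs$start[k], gs$end[k], gs$strand[k],
        sprintf("ID=%s", gid))
    mid <- paste0(gid, ".t1")
    add(gs$chrom[k], "mRNA", gs$start[k], gs$end[k], gs$strand[k],
        sprintf("ID=%s;Parent=%s", mid, gid))
    ex <- models$exons[models$exons$gene_id == gid, , drop = FALSE]
    for (i in seq_len(nrow(ex)))
      add(gs$chrom[k], "exon", ex$start[i], ex$end[i], gs$strand[k],
          sprintf("ID=%s.exon%d;Parent=%s", mid, i, mid))
    cd <- models$cds[models$cds$gene_id == gid, , drop = FALSE]
    for (i in seq_len(nrow(cd)))
      add(gs$chrom[k], "CDS", cd$start[i], cd$end[i], gs$strand[k],
          sprintf("ID=%s.cds%d;Parent=%s", mid, i, mid))
  }
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}

# ---- subgenome blocks ------------------------------------------------------

#' Read subgenome block assignments
#'
#' BED-like 4-column TSV with header `chrom  start  end  label`, `start`
#' 1-based inclusive. Labels are the triplicated-subgenome classes
#' `LF`, `MF1`, `MF2`. Blocks on one chromosome must not overlap.
#'
#' @param path TSV file.
#' @return data.frame with internal 0-based half-open `start`/`end`.
#' @export
read_subgenome_blocks <- function(path) {
  b <- read.delim(path, stringsAsFactors = FALSE)
  b$start <- as.integer(b$start) - 1L
  b$end <- as.integer(b$end)
  if (any(!b$label %in% c("LF", "MF1", "MF2")))
    stopf("unknown subgenome label '%s'", setdiff(b$label, c("LF", "MF1", "MF2"))[1])
  check_blocks(b)
  b
}

check_blocks <- function(b) {
  for (ch in unique(b$chrom)) {
    x <- b[b$chrom == ch, , drop = FALSE]
    x <- x[order(x$start), , drop = FALSE]
    if (nrow(x) > 1 && any(x$start[-1] < x$end[-nrow(x)]))
      stopf("overlapping subgenome blocks on %s", ch)
  }
  invisible(TRUE)
}

#' @rdname read_subgenome_blocks
#' @param blocks data.frame of blocks (internal coordinates).
#' @export
write_subgenome_blocks <- function(blocks, path) {
  out <- data.frame(chrom = blocks$chrom, start = blocks$start + 1L,
                    end = blocks$end, label = blocks$label)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- mobilome profile ------------------------------------------------------

GENOTYPE_SYMBOLS <- c("P", "A", "H", "M")

#' Construct a mobilome profile
#'
#' The central container of the pipeline: a complete loci x accessions
#' genotype matrix with per-call supporting-read counts. Genotype symbols
#' are `P` (insertion present), `A` (absent), `H` (heterozygous: reads
#' supporting both alleles) and `M` (missing: no informative reads).
#'
#' @param loci data.frame with columns `locus_id`, `chrom`, `pos`
#'   (0-based insertion offset), `te_id`, `family`, `superfamily`,
#'   `side`, `end_support`, `ref_status`, `span_start`, `span_end`.
#' @param accessions data.frame with columns `accession`, `morphotype`.
#' @param calls character matrix (loci x accessions) over `P/A/H/M`.
#' @param presence,absence integer matrices of supporting-read counts,
#'   same shape as `calls`.
#' @return object of class `mobilome_profile`.
#' @export
mobilome_profile <- function(loci, accessions, calls, presence, absence) {
  stopifnot(is.data.frame(loci), is.data.frame(accessions))
  n <- nrow(loci); m <- nrow(accessions)
  for (mt in list(calls, presence, absence))
    if (!all(dim(mt) == c(n, m))) stopf("matrix dimensions do not match loci x accessions")
  if (n && any(!calls %in% GENOTYPE_SYMBOLS))
    stopf("unknown genotype symbol '%s'", setdiff(unique(c(calls)), GENOTYPE_SYMBOLS)[1])
  bad <- calls == "M" & (presence > 0 | absence > 0)
  if (any(bad)) stopf("M call with nonzero supporting reads")
  dimnames(calls) <- dimnames(presence) <- dimnames(absence) <-
    list(loci$locus_id, accessions$accession)
  structure(list(loci = loci, accessions = accessions, calls = calls,
                 presence = presence, absence = absence),
            class = "mobilome_profile")
}

#' @export
print.mobilome_profile <- function(x, ...) {
  cat(sprintf("mobilome_profile: %d loci x %d accessions\n",
              nrow(x$loci), nrow(x$accessions)))
  if (nrow(x$loci)) {
    tab <- table(factor(x$calls, levels = GENOTYPE_SYMBOLS))
    cat(sprintf("  calls: P=%d A=%d H=%d M=%d\n", tab["P"], tab["A"], tab["H"], tab["M"]))
  }
  invisible(x)
}

#' @export
dim.mobilome_profile <- function(x) c(nrow(x$loci), nrow(x$accessions))

empty_matrix <- function(mode, n, m, loci_ids, acc) {
  matrix(vector(mode, 0), nrow = n, ncol = m, dimnames = list(loci_ids, acc))
}

loci_to_table <- function(loci) {
  data.frame(locus_id = loci$locus_id, chrom = loci$chrom,
             pos = loci$pos,  # 1-based index of the base left of the insertion
             te_id = loci$te_id, family = loci$family,
             superfamily = loci$superfamily, side = loci$side,
             te_dir = loci$te_dir,
             end_support = loci$end_support, ref_status = loci$ref_status,
             span_start = ifelse(is.na(loci$span_start), NA, loci$span_start + 1L),
             span_end = loci$span_end, stringsAsFactors = FALSE)
}

table_to_loci <- function(tab) {
  tab$pos <- as.integer(tab$pos)
  tab$te_dir <- as.integer(tab$te_dir)
  tab$span_start <- ifelse(is.na(tab$span_start), NA_integer_,
                           as.integer(tab$span_start) - 1L)
  tab$span_end <- as.integer(tab$span_end)
  tab
}

write_matrix_tsv <- function(mat, locus_ids, path) {
  df <- data.frame(locus_id = locus_ids, stringsAsFactors = FALSE)
  if (ncol(mat)) df <- cbind(df, as.data.frame(mat, stringsAsFactors = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path, mode) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (mode == "integer") storage.mode(m) <- "integer"
  rownames(m) <- df$locus_id
  m
}

#' Write / read a mobilome profile as TSV tables
#'
#' `write_profile()` emits five TSV files under `dir`: `loci.tsv` (1-based
#' positions), `accessions.tsv`, `genotypes.tsv` and the parallel
#' supporting-read count matrices `presence_reads.tsv` /
#' `absence_reads.tsv`. `read_profile()` is its exact inverse.
#'
#' @param profile a `mobilome_profile`.
#' @param dir output directory (created if needed).
#' @return `write_profile()`: `dir`, invisibly. `read_profile()`: a
#'   `mobilome_profile`.
#' @export
write_profile <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(loci_to_table(profile$loci), file.path(dir, "loci.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(profile$accessions, file.path(dir, "accessions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(profile$calls, profile$loci$locus_id,
                   file.path(dir, "genotypes.tsv"))
  write_matrix_tsv(profile$presence, profile$loci$locus_id,
                   file.path(dir, "presence_reads.tsv"))
  write_matrix_tsv(profile$absence, profile$loci$locus_id,
                   file.path(dir, "absence_reads.tsv"))
  invisible(dir)
}

#' @rdname write_profile
#' @export
read_profile <- function(dir) {
  loci <- table_to_loci(read.delim(file.path(dir, "loci.tsv"),
                                   stringsAsFactors = FALSE,
                                   colClasses = c(locus_id = "character",
                                                  te_id = "character",
                                                  chrom = "character")))
  acc <- read.delim(file.path(dir, "accessions.tsv"), stringsAsFactors = FALSE,
                    colClasses = "character")
  if (nrow(loci) == 0) {
    n <- 0L; m <- nrow(acc)
    mk <- function(mode, fill) matrix(vector(mode, 0), 0, m,
                                      dimnames = list(NULL, acc$accession))
    return(mobilome_profile(loci, acc, mk("character"), mk("integer"), mk("integer")))
  }
  calls <- read_matrix_tsv(file.path(dir, "genotypes.tsv"), "character")
  pres <- read_matrix_tsv(file.path(dir, "presence_reads.tsv"), "integer")
  abs_ <- read_matrix_tsv(file.path(dir, "absence_reads.tsv"), "integer")
  mobilome_profile(loci, acc, calls, pres, abs_)
}

# ---- newick ----------------------------------------------------------------

#' Serialise / parse trees in newick format
#'
#' Thin validation wrappers around [ape::write.tree()] and
#' [ape::read.tree()]; branch lengths are printed with 10 significant
#' digits so a re-parse reproduces topology and lengths.
#'
#' @param tree an [ape::phylo] tree with unique leaf labels.
#' @param path optional file; when `NULL` the newick string is returned.
#' @return newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stopf("duplicate leaf label '%s'", tree$tip.label[duplicated(tree$tip.label)][1])
  s <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' @rdname write_newick
#' @param text newick string (alternative to `path`).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
}
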