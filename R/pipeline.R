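# Orchestration: a single parameter registry with the defaults of every
# stage, and run_all(), which wires simulate (optional) -> end library
# -> discovery -> genotyping -> filtering -> population frequency ->
# population genetics, writing all tabular artifacts.

#' Pipeline parameter registry
#'
#' Returns the full nested list of stage parameters with their
#' defaults; `overrides` (a nested list with the same shape) replaces
#' individual values. Unknown keys are rejected.
#'
#' @param overrides nested list of overrides, e.g.
#'   `list(discover = list(window = 10))`.
#' @return nested parameter list.
#' @export
pipeline_params <- function(overrides = NULL) {
  p <- list(
    endlib = list(end_len = 150L, min_len = 75L, min_ident = 0.90,
                  both_strands = TRUE),
    discover = list(min_te_match = 20L, min_flank = 30L, min_ident = 0.95,
                    flank_min_ident = 0.95, slack = 2L, k = 15L,
                    window = 15L, second_frac = 0.95, ref_min_len = 50L,
                    ref_min_ident = 0.90),
    genotype = list(flank_len = 150L, min_overlap = 20L, min_ident = 0.95,
                    k = 15L, max_tsd = 20L),
    filter = list(max_missing = 0.5, max_het = 0.41, min_reads = 3L,
                  pair_window = 25L),
    popfreq = list(gene_window = 500L, hi = 0.90, lo = 0.10, delta = 0.5),
    popgen = list(lo = 0.2, hi = 0.8))
  if (!is.null(overrides)) {
    for (stage in names(overrides)) {
      if (!stage %in% names(p)) stopf("unknown parameter stage '%s'", stage)
      for (key in names(overrides[[stage]])) {
        if (!key %in% names(p[[stage]]))
          stopf("unknown parameter '%s' in stage '%s'", key, stage)
        p[[stage]][[key]] <- overrides[[stage]][[key]]
      }
    }
  }
  p
}

write_tsv <- function(df, path, digits = 6) {
  for (cc in names(df)) if (is.double(df[[cc]])) df[[cc]] <- signif(df[[cc]], digits)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[mobiscan] ", fmt), ...))
}

load_cohort_inputs <- function(inputs) {
  for (key in c("reference", "te_fasta", "te_table", "reads_manifest")) {
    if (is.null(inputs[[key]])) stopf("input '%s' is required", key)
    if (!file.exists(inputs[[key]])) stopf("input '%s' not found: %s", key, inputs[[key]])
  }
  ref_df <- read_sequences(inputs$reference, "fasta")
  reference <- setNames(ref_df$sequence, ref_df$id)
  te_seq <- read_sequences(inputs$te_fasta, "fasta")
  te_tab <- read.delim(inputs$te_table, stringsAsFactors = FALSE)
  elements <- te_elements(te_tab$te_id, te_tab$class_, te_tab$order_,
                          te_tab$superfamily, te_tab$family,
                          te_seq$sequence[match(te_tab$te_id, te_seq$id)])
  man <- read.delim(inputs$reads_manifest, stringsAsFactors = FALSE)
  reads <- lapply(seq_len(nrow(man)), function(i) {
    r <- read_sequences(man$fastq[i], "fastq")
    setNames(r$sequence, r$id)
  })
  names(reads) <- man$accession
  accessions <- data.frame(accession = man$accession,
                           morphotype = man$morphotype, stringsAsFactors = FALSE)
  genes <- if (!is.null(inputs$genes_gff)) read_gene_models(inputs$genes_gff)
  blocks <- if (!is.null(inputs$blocks)) read_subgenome_blocks(inputs$blocks)
  list(reference = reference, elements = elements, reads = reads,
       accessions = accessions, gene_models = genes, blocks = blocks)
}

#' Run the complete pipeline
#'
#' Executes every stage in order - simulate (when `sim` is given) or
#' load inputs, build the end library, discover loci, genotype the
#' population, filter, and compute the population-frequency and
#' population-genetics outputs - writing all artifacts under `out`.
#' Outputs are identical for identical config and seed; floating-point
#' table values are rounded to 6 significant digits at I/O.
#'
#' @param config a list (or path to a YAML file) with elements `seed`
#'   (integer), `out` (output directory), and either `sim` (a list of
#'   [sim_config()] overrides) or `inputs` (paths: `reference`,
#'   `te_fasta`, `te_table`, `reads_manifest`, optional `genes_gff`,
#'   `blocks`); optional `params` ([pipeline_params()] overrides).
#' @param verbose log stage progress to stderr (default TRUE).
#' @return invisible list with all in-memory artifacts (`cohort`,
#'   `library`, `loci`, `raw_profile`, `profile`, `report`, `freqs`,
#'   `groupfreqs`, `popgen`, ...).
#' @export
run_all <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "out", "sim", "inputs", "params")
  if (length(setdiff(names(config), known)))
    stopf("unknown config key '%s'", setdiff(names(config), known)[1])
  seed <- as.integer(config$seed %||% 1L)
  out <- config$out %||% stopf("config must name an output directory 'out'")
  params <- pipeline_params(config$params)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  if (!is.null(config$sim)) {
    sim_args <- config$sim
    # YAML deserialises named vectors as lists; normalise
    for (key in c("chrom_lengths", "n_accessions"))
      if (is.list(sim_args[[key]])) sim_args[[key]] <- unlist(sim_args[[key]])
    if (!is.null(sim_args$locus_spec))
      sim_args$locus_spec <- lapply(sim_args$locus_spec, function(e) {
        if (is.list(e$freq)) e$freq <- unlist(e$freq)
        e
      })
    sim_args$seed <- sim_args$seed %||% seed
    cfg <- do.call(sim_config, sim_args)
    stage_log(verbose, "simulate: %d accessions, %d bp genome",
              sum(cfg$n_accessions), sum(cfg$chrom_lengths))
    cohort <- simulate_cohort(cfg)
    write_truth(cohort$truth, file.path(out, "truth"))
  } else {
    stage_log(verbose, "loading inputs")
    cohort <- load_cohort_inputs(config$inputs)
  }

  stage_log(verbose, "end library: %d elements", nrow(cohort$elements))
  lib <- build_end_library(cohort$elements, params$endlib$end_len,
                           params$endlib$min_len, params$endlib$min_ident,
                           params$endlib$both_strands)
  write_sequences(setNames(lib$sequence, lib$end_id),
                  file.path(out, "end_library.fasta"))

  stage_log(verbose, "discovery across %d accessions", length(cohort$reads))
  loci <- discover_loci(cohort$reads, lib, cohort$reference, cohort$elements,
                        params)
  stage_log(verbose, "discovered %d loci", nrow(loci))

  stage_log(verbose, "genotyping")
  raw <- genotype_population(loci, cohort$reads, cohort$accessions,
                             cohort$reference, cohort$elements, params)
  write_profile(raw, file.path(out, "profile_raw"))

  stage_log(verbose, "filtering")
  fl <- apply_filters(raw, params$filter$max_missing, params$filter$max_het,
                      params$filter$min_reads, params$filter$pair_window)
  profile <- fl$profile
  write_profile(profile, file.path(out, "profile_filtered"))
  rep_df <- data.frame(metric = names(unclass(fl$report)),
                       value = unlist(unclass(fl$report)))
  write_tsv(rep_df, file.path(out, "filter_report.tsv"))
  qc <- qc_summaries(raw, params$filter$pair_window)

  stage_log(verbose, "population frequencies")
  freqs <- locus_frequencies(profile)
  write_tsv(freqs, file.path(out, "frequencies.tsv"))
  gf <- group_frequencies(profile)
  write_tsv(gf, file.path(out, "group_frequencies.tsv"))
  dfx <- differential_fixed(gf, params$popfreq$hi, params$popfreq$lo)
  write_tsv(dfx, file.path(out, "differential_fixed.tsv"))
  het <- heterogeneous_loci(gf, params$popfreq$delta)
  venn <- venn_and_singletons(profile)
  ann <- sub_stats <- NULL
  if (!is.null(cohort$gene_models) && nrow(cohort$gene_models$genes)) {
    ann <- annotate_loci(profile$loci, cohort$gene_models,
                         params$popfreq$gene_window)
    write_tsv(ann, file.path(out, "annotations.tsv"))
  }
  if (!is.null(cohort$blocks)) {
    sub_stats <- subgenome_stats(profile$loci, cohort$blocks)
    write_tsv(sub_stats, file.path(out, "subgenome_stats.tsv"))
  }

  stage_log(verbose, "population genetics")
  popgen <- NULL
  bm <- tryCatch(select_informative(profile, params$popgen$lo, params$popgen$hi),
                 error = function(e) NULL)
  if (!is.null(bm) && ncol(bm) >= 2 && nrow(bm) >= 3) {
    d <- mean_difference_distance(bm)
    tree <- nj_tree(d)
    write_newick(tree, file.path(out, "nj_tree.nwk"))
    pc <- pca_profile(bm)
    coords <- data.frame(accession = rownames(pc$coordinates),
                         pc$coordinates[, 1:min(5, ncol(pc$coordinates))])
    write_tsv(coords, file.path(out, "pca_coordinates.tsv"))
    write_tsv(data.frame(component = seq_along(pc$eigenvalues),
                         eigenvalue = pc$eigenvalues,
                         percent = pc$percent_variance),
              file.path(out, "pca_eigenvalues.tsv"))
    fst <- pairwise_fst(profile, params$popgen$lo, params$popgen$hi)
    write_tsv(fst, file.path(out, "pairwise_fst.tsv"))
    popgen <- list(distance = d, tree = tree, pca = pc, fst = fst)
  } else {
    stage_log(verbose, "too few informative loci for population genetics")
  }

  stage_log(verbose, "done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  invisible(list(cohort = cohort, library = lib, loci = loci,
                 raw_profile = raw, profile = profile, report = fl$report,
                 qc = qc, freqs = freqs, groupfreqs = gf,
                 differential_fixed = dfx, heterogeneous = het, venn = venn,
                 annotations = ann, subgenome = sub_stats, popgen = popgen))
}
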