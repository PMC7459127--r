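# Internal helpers shared across modules.
#
# Coordinate convention: all internal positions are 0-based half-open.
# Conversion to the 1-based inclusive convention of emitted tables and of
# GFF3 happens exactly once, inside the formats-io layer. An insertion
# breakpoint is stored as the 0-based offset b such that the sequence left
# of the insertion point is ref[0, b); in emitted tables the `pos` column
# is therefore the 1-based index of the last reference base before the
# insertion point (i.e. the integer b itself).

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

validate_dna <- function(seqs, what = "sequence") {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("%s %d contains characters outside {A,C,G,T,N}", what, i),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over plain `ACGTN` character strings.
#' Any character outside the alphabet becomes `N`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length (names preserved).
#' @export
revcomp <- function(x) {
  cpp_revcomp(toupper(as.character(x)))
}

# Round half away from zero to `digits` decimals, matching how the
# report tables print averages and percentages.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a per-stage RNG seed from the master seed so that changing one
# stage's parameters does not perturb another stage's draws. Kept within
# 32-bit integer range.
stage_seed <- function(seed, stage, index = 0L) {
  offsets <- c(genome = 11L, telib = 23L, plant = 37L, reads = 53L,
               genes = 71L, blocks = 83L, misc = 97L)
  off <- offsets[[stage]]
  as.integer((as.double(seed) * 1009 + off * 131 + index) %% 2147483647)
}

# Random DNA of length n from the current RNG stream.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Apply substitutions to a DNA string at per-base rate `rate`; substituted
# bases are drawn uniformly from the three alternatives.
mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(bases)) < rate)
  if (length(hit)) {
    alt <- vapply(bases[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    bases[hit] <- alt
  }
  paste(bases, collapse = "")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
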