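# Binary-marker population genetics on the filtered profile:
# informative-locus selection (0.2 <= freq <= 0.8), mean pairwise
# character-difference distances that adjust for missing calls, a
# Saitou-Nei neighbor-joining tree, SNP-style PCA of the genetic
# covariance matrix, and the Weir & Cockerham (1984) FST estimator with
# presence/absence calls diploidised as allele dosages (P=2, H=1, A=0).

#' Encode a profile as a binary marker matrix
#'
#' Accessions x loci matrix with 1 = insertion present (heterozygous
#' calls count as carriers), 0 = absent, `NA` = missing.
#'
#' @param profile a [mobilome_profile()].
#' @param loci optional locus-id subset.
#' @return integer matrix (accessions x loci).
#' @export
binary_matrix <- function(profile, loci = NULL) {
  calls <- profile$calls
  if (!is.null(loci)) calls <- calls[match(loci, profile$loci$locus_id), , drop = FALSE]
  m <- matrix(NA_integer_, ncol(calls), nrow(calls),
              dimnames = list(colnames(calls), rownames(calls)))
  m[t(calls == "P" | calls == "H")] <- 1L
  m[t(calls == "A")] <- 0L
  m
}

#' Diploid allele-dosage matrix
#'
#' Presence-allele dosage per accession and locus: `P` = 2, `H` = 1,
#' `A` = 0, missing = `NA`.
#'
#' @inheritParams binary_matrix
#' @return integer matrix (accessions x loci).
#' @export
dosage_matrix <- function(profile, loci = NULL) {
  calls <- profile$calls
  if (!is.null(loci)) calls <- calls[match(loci, profile$loci$locus_id), , drop = FALSE]
  m <- matrix(NA_integer_, ncol(calls), nrow(calls),
              dimnames = list(colnames(calls), rownames(calls)))
  m[t(calls == "P")] <- 2L
  m[t(calls == "H")] <- 1L
  m[t(calls == "A")] <- 0L
  m
}

#' Select informative loci and encode the binary matrix
#'
#' Retains loci with population carrier frequency in `[lo, hi]`
#' (inclusive) - the proper-frequency band for marker-based analyses -
#' and encodes them as a binary matrix.
#'
#' @inheritParams binary_matrix
#' @param lo,hi inclusive frequency bounds (defaults 0.2 and 0.8).
#' @return integer matrix (accessions x loci); attribute `"loci"` holds
#'   the retained locus ids.
#' @export
select_informative <- function(profile, lo = 0.2, hi = 0.8) {
  fr <- locus_frequencies(profile)
  keep <- fr$freq >= lo & fr$freq <= hi
  if (!any(keep)) stopf("no locus within the frequency band [%g, %g]", lo, hi)
  m <- binary_matrix(profile, fr$locus_id[keep])
  if (any(rowSums(!is.na(m)) == 0))
    stopf("accession '%s' has no called informative locus",
          rownames(m)[rowSums(!is.na(m)) == 0][1])
  attr(m, "loci") <- fr$locus_id[keep]
  m
}

#' Mean pairwise character-difference distance
#'
#' `d(i, j)` is the fraction of loci at which both accessions are
#' called and their binary states differ, computed over the mutually
#' non-missing loci of each pair (the "mean model", which adjusts for
#' missing calls).
#'
#' @param m binary matrix from [select_informative()] /
#'   [binary_matrix()].
#' @return symmetric distance matrix with zero diagonal.
#' @export
mean_difference_distance <- function(m) {
  called <- !is.na(m) + 0
  x <- m; x[is.na(x)] <- 0L
  shared <- tcrossprod(called)
  if (any(shared[upper.tri(shared)] == 0)) {
    idx <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)[1, ]
    stopf("accessions '%s' and '%s' share no called locus",
          rownames(m)[idx[1]], rownames(m)[idx[2]])
  }
  unequal <- tcrossprod(x, called) + tcrossprod(called, x) - 2 * tcrossprod(x)
  d <- unequal / shared
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q criterion and
#' branch-length formulas. Ties in Q are broken towards the
#' lexicographically smallest label pair (each internal node is
#' labelled by its smallest member tip). Negative branch lengths are
#' clamped to zero with the deficit moved to the sister branch.
#'
#' @param d symmetric distance matrix with unique row/column names.
#' @return an unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stopf("distance matrix is not symmetric")
  n <- nrow(d)
  if (n < 3) stopf("need at least 3 taxa")
  labels <- rownames(d) %||% as.character(seq_len(n))
  nwk <- labels          # newick fragment per active node
  key <- labels          # tie-break label (smallest member tip)
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(d) > 3) {
    nn <- nrow(d)
    r <- rowSums(d)
    q <- (nn - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    ties <- which(q - qmin < 1e-12 & upper.tri(q), arr.ind = TRUE)
    pair_key <- apply(ties, 1, function(ij) {
      ks <- sort(c(key[ij[1]], key[ij[2]]))
      paste(ks, collapse = "\r")
    })
    sel <- ties[order(pair_key)[1], ]
    i <- sel[1]; j <- sel[2]
    vi <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (nn - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(vi), nwk[j], fmt(vj))
    new_key <- min(key[i], key[j])
    dk <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(nn), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    key <- c(key[keep], new_key)
    d <- d2
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  v <- c(v1, v2, v3)
  for (i in which(v < 0)) {
    k <- which.max(v)
    v[k] <- v[k] + v[i]; v[i] <- 0
  }
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(v[1]), nwk[2], fmt(v[2]),
                 nwk[3], fmt(v[3]))
  ape::read.tree(text = txt)
}

#' PCA of the genetic covariance matrix
#'
#' Missing cells are imputed by the locus mean, loci are centred and
#' scaled by `sqrt(p * (1 - p))` (the SNP-style normalisation, `p` the
#' locus mean); the accession x accession covariance matrix is
#' eigen-decomposed. Component signs are fixed by making the
#' largest-magnitude loading of each component positive.
#'
#' @param m binary matrix (accessions x loci).
#' @param scale scale by `sqrt(p(1-p))` (default TRUE).
#' @return list with `eigenvalues`, `coordinates` (accessions x
#'   components), `percent_variance`.
#' @export
pca_profile <- function(m, scale = TRUE) {
  if (nrow(m) < 2 || ncol(m) < 2) stopf("need at least 2 accessions and 2 loci")
  p <- colMeans(m, na.rm = TRUE)
  x <- m
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- p[j]
  x <- sweep(x, 2, p)
  if (scale) {
    s <- sqrt(p * (1 - p))
    s[s == 0] <- 1
    x <- sweep(x, 2, s, "/")
  }
  cov_acc <- tcrossprod(x) / ncol(x)
  if (all(abs(cov_acc) < 1e-12)) stopf("zero-variance matrix")
  eg <- eigen(cov_acc, symmetric = TRUE)
  vec <- eg$vectors
  for (k in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, k]))
    if (vec[i, k] < 0) vec[, k] <- -vec[, k]
  }
  rownames(vec) <- rownames(m)
  pos <- pmax(eg$values, 0)
  list(eigenvalues = eg$values, coordinates = vec,
       percent_variance = 100 * pos / sum(pos))
}

# Weir & Cockerham (1984) variance components for one biallelic locus
# over r populations; inputs per population: sample size (individuals),
# presence-allele frequency, observed heterozygote proportion.
wc84_components <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  c(a = a, b = b, c = c_)
}

#' Weir & Cockerham (1984) FST between two groups
#'
#' Each accession is treated as a diploid genotype at a biallelic locus
#' (presence dosage 2/1/0; missing excluded). The among-population (a),
#' among-individuals-within-population (b) and within-individual (c)
#' variance components are computed per locus with observed
#' heterozygosity, and FST is the ratio of sums `sum(a) / sum(a+b+c)`
#' over loci with a defined denominator.
#'
#' @param dosage dosage matrix (accessions x loci) from
#'   [dosage_matrix()].
#' @param group_a,group_b accession names (row names) of the two
#'   groups; each locus needs at least two called accessions per group
#'   to contribute.
#' @return list with `fst`, `n_loci` used, and the per-locus component
#'   data.frame `components`.
#' @export
fst_wc84 <- function(dosage, group_a, group_b) {
  ga <- dosage[group_a, , drop = FALSE]
  gb <- dosage[group_b, , drop = FALSE]
  comp <- matrix(NA_real_, ncol(dosage), 3,
                 dimnames = list(colnames(dosage), c("a", "b", "c")))
  for (l in seq_len(ncol(dosage))) {
    xa <- ga[, l]; xa <- xa[!is.na(xa)]
    xb <- gb[, l]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2 || length(xb) < 2) next
    n <- c(length(xa), length(xb))
    p <- c(mean(xa) / 2, mean(xb) / 2)
    h <- c(mean(xa == 1), mean(xb == 1))
    comp[l, ] <- wc84_components(n, p, h)
  }
  ok <- !is.na(comp[, 1])
  denom <- sum(comp[ok, ], na.rm = TRUE)
  if (!any(ok) || denom == 0)
    stopf("FST undefined: no polymorphic locus with sufficient calls")
  list(fst = sum(comp[ok, "a"]) / denom, n_loci = sum(ok),
       components = as.data.frame(comp))
}

#' Pairwise FST between all morphotype groups
#'
#' Convenience wrapper: selects informative loci (`lo`-`hi` frequency
#' band), builds the dosage matrix and computes [fst_wc84()] for every
#' unordered pair of morphotypes.
#'
#' @inheritParams select_informative
#' @return data.frame with `group1`, `group2`, `fst`, `n_loci`.
#' @export
pairwise_fst <- function(profile, lo = 0.2, hi = 0.8) {
  m <- select_informative(profile, lo, hi)
  dos <- dosage_matrix(profile, attr(m, "loci"))
  groups <- profile$accessions$morphotype
  gs <- unique(groups)
  out <- list()
  for (i in seq_along(gs)) for (j in seq_along(gs)) {
    if (i >= j) next
    acc_a <- profile$accessions$accession[groups == gs[i]]
    acc_b <- profile$accessions$accession[groups == gs[j]]
    f <- fst_wc84(dos, acc_a, acc_b)
    out[[length(out) + 1]] <- data.frame(group1 = gs[i], group2 = gs[j],
                                         fst = f$fst, n_loci = f$n_loci,
                                         stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
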