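# Binary-marker population genetics: informative-locus selection,
# mean-difference distances (with a brute-force oracle), neighbor
# joining (closed-form and additive-matrix recovery), PCA identities,
# and the Weir & Cockerham FST estimator against hand computation.

test_that("informative-locus selection uses an inclusive 0.2-0.8 band", {
  calls <- rbind(rep(c("P", "A"), c(2, 8)),   # 0.2: retained
                 rep(c("P", "A"), c(8, 2)),   # 0.8: retained
                 rep(c("P", "A"), c(9, 1)),   # 0.9: dropped
                 rep(c("P", "A"), c(1, 9)))   # 0.1: dropped
  prof <- make_profile(calls)
  m <- select_informative(prof)
  expect_equal(attr(m, "loci"), c("L001", "L002"))
  expect_equal(dim(m), c(10L, 2L))
  expect_error(select_informative(prof, lo = 0.95, hi = 0.99), "no locus")
})

test_that("binary encoding maps H to carrier and M to missing", {
  prof <- make_profile(rbind(c("P", "A", "H", "M")))
  m <- binary_matrix(prof)
  expect_equal(unname(m[, 1]), c(1L, 0L, 1L, NA))
  d <- dosage_matrix(prof)
  expect_equal(unname(d[, 1]), c(2L, 0L, 1L, NA))
})

test_that("mean-difference distance handles identity, complement and missing", {
  m <- rbind(a = c(1L, 0L, 1L, 0L), b = c(1L, 0L, 1L, 0L),
             c = c(0L, 1L, 0L, 1L))
  d <- mean_difference_distance(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)
  set.seed(70)
  mm <- matrix(sample(c(0L, 1L, NA), 200, TRUE, prob = c(.4, .4, .2)), 10, 20)
  rownames(mm) <- letters[1:10]
  dd <- mean_difference_distance(mm)
  for (i in 1:9) for (j in (i + 1):10) {
    both <- !is.na(mm[i, ]) & !is.na(mm[j, ])
    expect_equal(dd[i, j], mean(mm[i, both] != mm[j, both]))
    expect_equal(dd[i, j], dd[j, i])
  }
  m2 <- rbind(a = c(1L, NA), b = c(NA, 0L))
  expect_error(mean_difference_distance(m2), "share no called locus")
})

test_that("three-taxon NJ matches the closed-form branch lengths", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  cd <- ape::cophenetic.phylo(tr)
  expect_equal(cd[c("A", "B", "C"), c("A", "B", "C")], d, tolerance = 1e-9)
  # closed form: vA = (dAB + dAC - dBC) / 2 = 2
  edge_a <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "A")]
  expect_equal(edge_a, 2)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ recovers additive five-taxon matrices exactly", {
  tr0 <- ape::read.tree(text = "((A:2,B:3):1,(C:4,D:1):2,E:5);")
  d <- ape::cophenetic.phylo(tr0)
  tr <- nj_tree(d)
  expect_equal(ape::dist.topo(ape::unroot(tr0), tr)[1], 0)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
})

test_that("NJ recovers random additive matrices (n <= 12) and matches ape", {
  set.seed(80)
  for (n in c(6, 9, 12)) {
    for (rep_ in 1:3) {
      tr0 <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
      d <- ape::cophenetic.phylo(tr0)
      d <- d[order(rownames(d)), order(colnames(d))]
      tr <- nj_tree(d)
      expect_equal(ape::dist.topo(ape::unroot(tr0), tr)[1], 0)
      expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
                   tolerance = 1e-8)
      expect_equal(ape::dist.topo(ape::nj(as.dist(d)), tr)[1], 0)
    }
  }
})

test_that("PCA separates clusters and reconstructs the covariance", {
  m <- rbind(matrix(rep(c(1L, 1L, 1L, 0L, 0L, 0L), 4), 4, 6, byrow = TRUE),
             matrix(rep(c(0L, 0L, 0L, 1L, 1L, 1L), 4), 4, 6, byrow = TRUE))
  rownames(m) <- letters[1:8]
  pc <- pca_profile(m, scale = FALSE)
  expect_true(all(sign(pc$coordinates[1:4, 1]) != sign(pc$coordinates[5:8, 1])))
  expect_lt(abs(pc$eigenvalues[2]), 1e-10)  # rank-1 structure
  expect_equal(sum(pc$percent_variance), 100)

  set.seed(90)
  mr <- matrix(sample(0:1, 120, TRUE), 8, 15)
  rownames(mr) <- letters[1:8]
  pcr <- pca_profile(mr)
  p <- colMeans(mr)
  x <- sweep(mr, 2, p); x <- sweep(x, 2, sqrt(p * (1 - p)), "/")
  cov_acc <- tcrossprod(x) / ncol(x)
  rec <- pcr$coordinates %*% diag(pcr$eigenvalues) %*% t(pcr$coordinates)
  expect_equal(unname(rec), unname(cov_acc), tolerance = 1e-8)
})

test_that("fixed differences give FST = 1 and null cohorts give ~0", {
  dos <- rbind(matrix(2L, 5, 10), matrix(0L, 5, 10))
  rownames(dos) <- c(paste0("a", 1:5), paste0("b", 1:5))
  colnames(dos) <- paste0("l", 1:10)
  f <- fst_wc84(dos, paste0("a", 1:5), paste0("b", 1:5))
  expect_equal(f$fst, 1)

  set.seed(100)
  dos2 <- matrix(rbinom(200 * 50, 2, 0.5), 200, 50)
  rownames(dos2) <- paste0("x", 1:200)
  colnames(dos2) <- paste0("l", 1:50)
  f2 <- fst_wc84(dos2, paste0("x", 1:100), paste0("x", 101:200))
  expect_lt(abs(f2$fst), 0.02)
})

test_that("single-locus components match the published formulas by hand", {
  # pop1: 4 individuals with dosages 2,2,1,0; pop2: 5 individuals 0,0,1,0,0
  dos <- matrix(c(2L, 2L, 1L, 0L, 0L, 0L, 1L, 0L, 0L), ncol = 1,
                dimnames = list(c(paste0("a", 1:4), paste0("b", 1:5)), "l1"))
  f <- fst_wc84(dos, paste0("a", 1:4), paste0("b", 1:5))
  # independent hand computation of Weir & Cockerham (1984) a, b, c
  n <- c(4, 5); r <- 2
  p <- c(mean(c(2, 2, 1, 0)) / 2, mean(c(0, 0, 1, 0, 0)) / 2)
  h <- c(1 / 4, 1 / 5)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  expect_equal(unlist(f$components["l1", ]), c(a = a, b = b, c = cc))
  expect_equal(f$fst, a / (a + b + cc))
})

test_that("FST increases with between-group frequency divergence", {
  set.seed(110)
  fst_at <- function(delta) {
    p1 <- 0.5 + delta / 2; p2 <- 0.5 - delta / 2
    dos <- rbind(matrix(rbinom(50 * 30, 2, p1), 50, 30),
                 matrix(rbinom(50 * 30, 2, p2), 50, 30))
    rownames(dos) <- paste0("x", 1:100)
    colnames(dos) <- paste0("l", 1:30)
    fst_wc84(dos, paste0("x", 1:50), paste0("x", 51:100))$fst
  }
  fsts <- vapply(c(0, 0.3, 0.6, 0.9), fst_at, numeric(1))
  expect_true(all(diff(fsts) > 0))
  expect_true(all(fsts <= 1 & fsts > -0.05))
})

test_that("monophyletic morphotype groups emerge from the simulated cohort", {
  run <- small_run()
  prof <- run$profile
  m <- select_informative(prof)
  d <- mean_difference_distance(m)
  tr <- nj_tree(d)
  groups <- setNames(prof$accessions$morphotype, prof$accessions$accession)
  # within-group mean distance below between-group mean distance
  same <- outer(groups[rownames(d)], groups[colnames(d)], "==")
  diag(same) <- NA
  expect_lt(mean(d[same & upper.tri(d)]), mean(d[!same & upper.tri(d)]))
})
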