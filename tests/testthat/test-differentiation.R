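test_that("Euclidean distances match hand computation and handle missingness", {
  gp <- toyPanel(rbind(a = c(0L, 0L), b = c(2L, 2L), c = c(0L, 0L)))
  d <- euclideanDistance(gp, normalize = "none")
  expect_equal(d["a", "b"], sqrt(8))
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))
  expect_equal(diag(d), setNames(rep(0, 3), c("a", "b", "c")))

  dn <- euclideanDistance(gp, normalize = "loci")
  expect_equal(dn["a", "b"], sqrt(8 / 2))

  # pair with missing overlap at one locus uses the shared locus only
  gm <- toyPanel(rbind(a = c(0L, NA, 2L), b = c(2L, 2L, NA)))
  dm <- euclideanDistance(gm, normalize = "none")
  expect_equal(dm["a", "b"], 2)  # only locus 1 shared

  gz <- toyPanel(rbind(a = c(0L, NA), b = c(NA, 2L)))
  expect_error(euclideanDistance(gz), "zero shared loci")
})

test_that("group mean distances agree with brute-force enumeration", {
  set.seed(12)
  calls <- matrix(sample(c(0L, 2L), 8 * 25, TRUE), 8, 25)
  groups <- factor(rep(c("A", "B"), each = 4))
  gp <- toyPanel(calls, groups = groups)
  d <- euclideanDistance(gp)
  gm <- groupMeanDistance(d, groups)
  cross <- outer(1:4, 5:8, Vectorize(function(i, j) d[i, j]))
  expect_equal(gm["A", "B"], mean(cross))
  within <- combn(1:4, 2, function(p) d[p[1], p[2]])
  expect_equal(gm["A", "A"], mean(within))

  # permuting individuals leaves group means unchanged
  perm <- sample(8)
  gm2 <- groupMeanDistance(d[perm, perm], groups[perm])
  expect_equal(gm2, gm)

  # singleton group: within-group mean undefined
  g3 <- factor(c("A", rep("B", 7)))
  expect_true(is.na(groupMeanDistance(d, g3)["A", "A"]))
})

test_that("UPGMA first merge and ultrametric exactness hold", {
  d <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  phy <- upgma(d)
  coph <- ape::cophenetic.phylo(phy)
  # first merge {A,B} at height 0.5: cophenetic distance 1
  expect_equal(coph["A", "B"], 1)
  expect_equal(coph["A", "C"], 4)
  # ultrametric input reproduced exactly
  expect_equal(coph[rownames(d), colnames(d)], d)

  dNaN <- d; dNaN[1, 2] <- dNaN[2, 1] <- NaN
  expect_error(upgma(dNaN), "NaN")
})

test_that("UPGMA agrees with an independent naive implementation on random
           4-taxon matrices", {
  set.seed(13)
  for (rep in 1:10) {
    m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    v <- runif(6, 0.5, 3)
    m[lower.tri(m)] <- v
    m <- m + t(m)
    phy <- upgma(m)
    coph <- ape::cophenetic.phylo(phy)[letters[1:4], letters[1:4]]
    expect_equal(coph, oracleUpgmaCophenetic(m), tolerance = 1e-12)
  }
})

test_that("Newick output round-trips through the reader", {
  set.seed(14)
  calls <- matrix(sample(c(0L, 2L), 6 * 30, TRUE), 6, 30)
  gp <- toyPanel(calls)
  phy <- upgma(euclideanDistance(gp))
  p <- file.path(tempdir(), "t.nwk")
  ape::write.tree(phy, p)
  back <- ape::read.tree(p)
  expect_setequal(back$tip.label, individualIds(gp))
  expect_equal(ape::cophenetic.phylo(back)[individualIds(gp), individualIds(gp)],
               ape::cophenetic.phylo(phy)[individualIds(gp), individualIds(gp)],
               tolerance = 1e-8)
})

test_that("Weir-Cockerham theta is 1 at a fixed difference and <= 0 without
           among-group variance", {
  fixed <- toyPanel(matrix(c(rep(0L, 4), rep(2L, 4)), ncol = 1),
                    groups = rep(c("A", "B"), each = 4))
  f <- weirCockerhamFst(fixed, c("A", "B"))
  expect_equal(f$theta, 1)

  same <- toyPanel(matrix(rep(c(0L, 0L, 2L, 2L), 2), ncol = 1),
                   groups = rep(c("A", "B"), each = 4))
  f2 <- weirCockerhamFst(same, c("A", "B"))
  expect_lte(f2$theta, 0)
})

test_that("per-locus components agree with the nested-ANOVA oracle", {
  # deterministic toy: p1 = 0.75, p2 = 0.25, all homozygotes
  g1 <- c(2L, 2L, 2L, 0L)
  g2 <- c(0L, 0L, 0L, 2L)
  gp <- toyPanel(matrix(c(g1, g2), ncol = 1),
                 groups = rep(c("A", "B"), each = 4))
  f <- weirCockerhamFst(gp, c("A", "B"))
  expect_equal(f$theta, oracleWcTheta(g1, g2), tolerance = 1e-12)

  # randomized cases with heterozygotes and unequal sizes
  set.seed(15)
  for (rep in 1:8) {
    c1 <- sample(0:2, 7, TRUE)
    c2 <- sample(0:2, 12, TRUE)
    if (length(unique(c(c1, c2))) == 1) next
    gpR <- toyPanel(matrix(c(c1, c2), ncol = 1),
                    groups = rep(c("A", "B"), c(7, 12)))
    fR <- weirCockerhamFst(gpR, c("A", "B"), min_group_n = 2)
    if (!is.na(fR$theta)) {
      expect_equal(fR$theta, oracleWcTheta(c1, c2), tolerance = 1e-12)
    }
  }
})

test_that("multi-locus theta is the ratio of summed components", {
  set.seed(16)
  calls <- matrix(sample(c(0L, 2L), 20 * 30, TRUE,
                         prob = c(0.6, 0.4)), 20, 30)
  gp <- toyPanel(calls, groups = rep(c("A", "B"), each = 10))
  f <- weirCockerhamFst(gp, c("A", "B"))
  u <- f$used
  expect_equal(attr(f, "theta_multilocus"),
               sum(f$a[u]) / sum((f$a + f$b + f$cc)[u]))
})

test_that("theta of a random split of one homogeneous population is near 0", {
  sim <- buildPanel(miniConfig(seed = 17, n_markers_per_chrom = 300,
                               c0_size = 60, maintenance_size = 60,
                               n_cycles = 1, cycle_pop_size = 10,
                               n_dh_per_group = c(60, 1, 1)))
  c0 <- sim$panel[panelGroups(sim$panel) == "C0_DHL", ]
  set.seed(17)
  thetas <- replicate(20, {
    split <- factor(ifelse(seq_len(60) %in% sample(60, 30), "X", "Y"))
    attr(weirCockerhamFst(c0, c("X", "Y"), groups = split),
         "theta_multilocus")
  })
  expect_true(all(abs(thetas) < 0.02))
})

test_that("F_ST scan orders loci and flags the top percent deterministically", {
  set.seed(18)
  calls <- matrix(sample(c(0L, 2L), 16 * 100, TRUE), 16, 100)
  gp <- toyPanel(calls, groups = rep(c("A", "B"), each = 8))
  f <- weirCockerhamFst(gp, c("A", "B"))
  scan <- fstScanTable(f, markerMap(gp))
  expect_identical(sum(scan$outlier), 1L)  # ceiling(1% of 100)
  expect_true(!is.unsorted(scan$bp))

  # flags invariant to the order loci arrive in the per-locus table
  perm <- sample(100)
  scanP <- fstScanTable(f[perm, ], markerMap(gp))
  expect_identical(scanP$marker[scanP$outlier], scan$marker[scan$outlier])

  # all-equal thetas: quota still ceiling(1%), resolved by map order
  fT <- f
  fT$theta <- rep(0.5, 100)
  scanT <- fstScanTable(fT, markerMap(gp))
  expect_identical(sum(scanT$outlier), 1L)
  expect_identical(which(scanT$outlier), 1L)  # earliest position wins
})
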