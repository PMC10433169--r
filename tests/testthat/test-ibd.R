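test_that("map interpolation is linear between reference points with
           rate-continued extrapolation", {
  ref <- data.frame(chrom = 1, bp = c(1e6, 2e6, 3e6), cM = c(10, 12, 20))
  map <- data.frame(marker = paste0("m", 1:4), chrom = 1,
                    bp = c(1e6, 1.5e6, 2.5e6, 3.2e6), cM = NA)
  out <- interpolateMap(map, ref)
  expect_equal(out$cM, c(10, 11, 16, 21.6))  # midpoints + end-rate 8 cM/Mb

  # constant-rate reference: cM = bp / 1,385,600 everywhere
  ref2 <- data.frame(chrom = 1, bp = c(0, 3e8), cM = c(0, 3e8 / 1385600))
  map2 <- data.frame(marker = paste0("x", 1:3), chrom = 1,
                     bp = c(1385600, 13856000, 277120000), cM = NA)
  out2 <- interpolateMap(map2, ref2)
  expect_equal(out2$cM, map2$bp / 1385600, tolerance = 1e-12)

  far <- data.frame(marker = "y", chrom = 1, bp = 6e8, cM = NA)
  expect_error(interpolateMap(far, ref2), "beyond reference span")
})

test_that("forward-backward posteriors match exhaustive path enumeration", {
  set.seed(40)
  L <- 10
  for (rep in 1:5) {
    e0 <- runif(L, 0.1, 1)
    e1 <- runif(L, 0.1, 1)
    stay0 <- runif(L - 1, 0.5, 0.99)
    stay1 <- runif(L - 1, 0.5, 0.99)
    prior <- runif(1, 0.05, 0.5)
    fb <- dhpanel:::ibd_forward_backward(e0, e1, stay0, stay1, prior)
    expect_equal(fb, oraclePathPosteriors(e0, e1, stay0, stay1, prior),
                 tolerance = 1e-10)
    expect_true(all(fb >= 0 & fb <= 1))
  }
})

test_that("identical inbred genome pairs get high IBD posteriors and opposite
           pairs get low ones", {
  set.seed(41)
  nm <- 120
  map <- data.frame(marker = paste0("m", 1:nm), chrom = 1,
                    bp = seq(1e5, by = 4e5, length.out = nm),
                    cM = seq(0.25, by = 0.4, length.out = nm))
  freqs <- runif(nm, 0.1, 0.9)
  x <- ifelse(runif(nm) < freqs, 2L, 0L)
  post <- pairIbdPosteriors(x, x, map, freqs)
  expect_gt(min(post[10:(nm - 10)]), 0.99)

  post2 <- pairIbdPosteriors(x, 2L - x, map, freqs)
  expect_lt(max(post2), 0.01)
})

test_that("segment calling applies the posterior, marker-count and length
           filters", {
  params <- ibdHmmParams()
  mkMap <- function(bp) data.frame(marker = paste0("m", seq_along(bp)),
                                   chrom = 1, bp = bp,
                                   cM = bp / 1385600)
  # 9 markers spanning 300 kb: fails both the >10-SNP and 350-kb rules
  map9 <- mkMap(seq(1e5, 4e5, length.out = 9))
  segs <- callSegments(rep(0.95, 9), map9, params)
  expect_identical(nrow(segs), 0L)

  # 15 markers spanning 500 kb, all posteriors 0.95: one segment
  map15 <- mkMap(seq(1e5, 6e5, length.out = 15))
  segs15 <- callSegments(rep(0.95, 15), map15, params)
  expect_identical(nrow(segs15), 1L)
  expect_identical(segs15$n_snps, 15L)
  expect_equal(segs15$start_bp, 1e5)
  expect_equal(segs15$end_bp, 6e5)
  expect_gt(segs15$mean_posterior, params$posterior_threshold)

  # a single low marker splits a 12-marker run into two rejected candidates
  map12 <- mkMap(seq(1e5, 5e5, length.out = 12))
  post12 <- rep(0.95, 12); post12[6] <- 0.65
  expect_identical(nrow(callSegments(post12, map12, params)), 0L)

  # posterior exactly at the threshold is not "above 70%"
  expect_identical(nrow(callSegments(rep(0.70, 15), map15, params)), 0L)
})

test_that("contribution accounting credits covered markers and preserves the
           100% identity", {
  sim <- buildPanel(miniConfig(seed = 44, n_markers_per_chrom = 100,
                               n_chromosomes = 1, n_cycles = 2,
                               n_progenitors = 2,
                               n_dh_per_group = c(2, 2, 2)))
  panel <- sim$panel
  nm <- ncol(genotypeCalls(panel))
  map <- markerMap(panel)
  lines <- individualIds(panel)[panelGroups(panel) != "progenitors"]
  seg <- function(line, prog, from, to, post) {
    data.frame(line_id = line, progenitor_id = prog, chrom = 1,
               start_bp = map$bp[from], end_bp = map$bp[to],
               start_cM = map$cM[from], end_cM = map$cM[to],
               n_snps = to - from + 1L, mean_posterior = post,
               start_idx = from, end_idx = to)
  }
  half <- nm %/% 2
  # every marker of line 1 covered by P01 -> 100% / non-IBD 0 for its group
  segs <- rbind(seg(lines[1], "P01", 1, nm, 0.99),
                seg(lines[2], "P01", 1, nm, 0.99),
                # line 3: half covered; line 4: overlap resolved by posterior
                seg(lines[3], "P01", 1, half, 0.99),
                seg(lines[4], "P01", 1, half, 0.99),
                seg(lines[4], "P02", 1, half, 0.80),
                seg(lines[4], "P02", half + 1L, nm, 0.95))
  co <- ibdContribution(segs, panel)
  expect_equal(unname(co$contribution["P01", "C0_DHL"]), 100)
  expect_equal(unname(co$non_ibd["C0_DHL"]), 0)
  # group with half/overlapping coverage: P01 gets the contested first half
  # of line 4 (higher posterior), P02 the second half
  h <- 100 * half / nm
  expect_equal(unname(co$contribution["P01", "C0/C17_DHL"]), h)
  expect_equal(unname(co$contribution["P02", "C0/C17_DHL"]), (100 - h) / 2)
  expect_equal(unname(co$non_ibd["C0/C17_DHL"]), 100 - h - (100 - h) / 2)
  # percentages always account for all markers
  expect_equal(unname(colSums(co$contribution) + co$non_ibd),
               rep(100, 3))

  # invariant to the order progenitors/segments are processed
  co2 <- ibdContribution(segs[sample(nrow(segs)), ], panel)
  expect_equal(co2$contribution, co$contribution)
})

test_that("mode imputation fills missing calls with the locus mode and leaves
           observed calls untouched", {
  calls <- rbind(c(0L, 0L, 2L), c(0L, 2L, 2L), c(2L, NA, 2L), c(NA, 2L, 2L))
  gp <- toyPanel(calls)
  imp <- modeImpute(gp)
  ci <- genotypeCalls(imp)
  expect_identical(ci[4, 1], 0L)   # mode of {0,0,2}
  expect_identical(ci[3, 2], 2L)   # mode of {0,2,2}
  expect_identical(ci[!is.na(calls)], calls[!is.na(calls)])
  expect_identical(attr(imp, "n_imputed"), 2L)
  # identity on complete data
  full <- toyPanel(calls[, 3, drop = FALSE])
  expect_identical(genotypeCalls(modeImpute(full)),
                   genotypeCalls(full))
})
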