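#' Pairwise Euclidean genetic distance
#'
#' Distances are computed over dosage vectors using the loci non-missing in
#' both individuals of a pair. With `normalize = "loci"` (default) the
#' per-locus root-mean-square form sqrt(SSQ / L) is returned, which makes
#' pairs with different missingness patterns comparable; `"none"` returns the
#' raw Euclidean distance sqrt(SSQ).
#'
#' @param panel a [GenotypePanel-class] (>= 2 individuals).
#' @param normalize "loci" or "none".
#' @return symmetric distance matrix with individual ids; attribute
#'   `shared_loci` holds the per-pair locus counts.
#' @examples
#' gp <- GenotypePanel(rbind(a = c(0, 0), b = c(2, 2)),
#'                     data.frame(marker = c("m1", "m2"), chrom = 1,
#'                                bp = 1:2, cM = c(0.1, 0.2)))
#' euclideanDistance(gp, normalize = "none")  # sqrt(8)
#' @export
euclideanDistance <- function(panel, normalize = c("loci", "none")) {
  normalize <- match.arg(normalize)
  calls <- genotypeCalls(panel)
  if (nrow(calls) < 2L) stop("need at least 2 individuals")
  M <- !is.na(calls)
  Z <- calls
  Z[!M] <- 0L
  storage.mode(Z) <- "double"
  storage.mode(M) <- "double"
  S1 <- (Z^2) %*% t(M)
  ssq <- S1 + t(S1) - 2 * Z %*% t(Z)
  ssq[ssq < 0] <- 0  # numerical guard
  L <- M %*% t(M)
  offdiag <- row(L) != col(L)
  if (any(L[offdiag] == 0)) stop("pair(s) with zero shared loci")
  d <- if (normalize == "loci") sqrt(ssq / L) else sqrt(ssq)
  diag(d) <- 0
  dimnames(d) <- list(rownames(calls), rownames(calls))
  attr(d, "shared_loci") <- L
  attr(d, "normalize") <- normalize
  d
}

#' Mean genetic distance within and between groups
#'
#' Between-group entries are means over all cross-group pairs; diagonal
#' entries are means over distinct within-group pairs (NA for singleton
#' groups).
#'
#' @param d symmetric distance matrix (from [euclideanDistance()]).
#' @param groups factor of group labels aligned to the matrix ids.
#' @return symmetric group x group matrix of mean distances.
#' @export
groupMeanDistance <- function(d, groups) {
  g <- levels(groups)
  out <- matrix(NA_real_, length(g), length(g), dimnames = list(g, g))
  for (i in seq_along(g)) {
    for (j in seq_len(i)) {
      ri <- which(groups == g[i])
      rj <- which(groups == g[j])
      sub <- d[ri, rj, drop = FALSE]
      if (i == j) {
        if (length(ri) < 2L) next
        out[i, j] <- mean(sub[lower.tri(sub)])
      } else {
        out[i, j] <- out[j, i] <- mean(sub)
      }
    }
  }
  out
}

#' UPGMA dendrogram from a distance matrix
#'
#' Standard unweighted pair-group method with arithmetic averaging
#' (size-weighted cluster means), returned as a rooted ultrametric `phylo`
#' tree with branch lengths; node heights are half the merge distances, so
#' cophenetic distances reproduce the input exactly on ultrametric data.
#'
#' @param d symmetric distance matrix with ids, no NA/NaN.
#' @return an [ape::as.phylo()] tree; serialize with [ape::write.tree()].
#' @export
upgma <- function(d) {
  if (any(!is.finite(as.matrix(d)))) stop("distance matrix contains NaN/NA")
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  phy <- ape::as.phylo(hc)
  phy
}

#' Per-locus and multi-locus Weir-Cockerham F_ST for a group pair
#'
#' Implements the two-population variance-component estimator: per locus,
#' among-population (a), among-individual-within-population (b) and
#' within-individual (c) components are computed from sample sizes, allele
#' frequencies and observed heterozygote proportions, with
#' theta = a / (a + b + c). The multi-locus estimate is the ratio of summed
#' components (not the mean of ratios). Negative per-locus estimates are
#' retained. Loci monomorphic across both groups, or with fewer than
#' `min_group_n` genotyped individuals in either group, are excluded from
#' the sums and reported.
#'
#' @param panel a [GenotypePanel-class]
#' @param pair character vector of two group labels.
#' @param groups factor overriding `panelGroups(panel)`.
#' @param min_group_n minimum genotyped individuals per group per locus
#'   (default 2).
#' @param outlier_quantile fraction of loci flagged as high-F_ST outliers
#'   (default 0.01; ceiling of the count, earlier map position wins at ties).
#' @return data.frame per locus (`marker`, `n1`, `n2`, `p1`, `p2`, `a`, `b`,
#'   `cc`, `theta`, `used`, `outlier`) with attribute `theta_multilocus`.
#' @examples
#' calls <- rbind(matrix(0L, 4, 1), matrix(2L, 4, 1))
#' gp <- GenotypePanel(calls, data.frame(marker = "m1", chrom = 1, bp = 1,
#'                                       cM = 0), groups = rep(c("A", "B"),
#'                                                             each = 4))
#' f <- weirCockerhamFst(gp, c("A", "B"))
#' f$theta  # 1 at a fixed difference
#' @export
weirCockerhamFst <- function(panel, pair, groups = panelGroups(panel),
                             min_group_n = 2L, outlier_quantile = 0.01) {
  stopifnot(length(pair) == 2L)
  calls <- genotypeCalls(panel)
  g1 <- calls[groups == pair[1], , drop = FALSE]
  g2 <- calls[groups == pair[2], , drop = FALSE]
  n1 <- colSums(!is.na(g1))
  n2 <- colSums(!is.na(g2))
  p1 <- ifelse(n1 > 0, colSums(g1, na.rm = TRUE) / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, colSums(g2, na.rm = TRUE) / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, colSums(g1 == 1L, na.rm = TRUE) / n1, NA_real_)
  h2 <- ifelse(n2 > 0, colSums(g2 == 1L, na.rm = TRUE) / n2, NA_real_)

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (2 * nbar - 1) / (4 * nbar) *
       hbar)
  cc <- hbar / 2

  mono <- pbar %in% c(0, 1)
  used <- n1 >= min_group_n & n2 >= min_group_n & !is.na(pbar) & !mono
  theta <- ifelse(used & (a + b + cc) != 0, a / (a + b + cc), NA_real_)

  L <- sum(used & !is.na(theta))
  outlier <- rep(FALSE, length(theta))
  if (L > 0) {
    k <- ceiling(outlier_quantile * L)
    ord <- order(-theta, seq_along(theta), na.last = TRUE)
    outlier[ord[seq_len(k)]] <- TRUE
  }

  out <- data.frame(marker = colnames(calls), n1 = n1, n2 = n2,
                    p1 = p1, p2 = p2, a = a, b = b, cc = cc,
                    theta = theta, used = used, outlier = outlier,
                    row.names = NULL)
  denom <- sum((a + b + cc)[used], na.rm = TRUE)
  attr(out, "theta_multilocus") <-
    if (denom != 0) sum(a[used], na.rm = TRUE) / denom else NA_real_
  attr(out, "n_excluded_monomorphic") <- sum(mono, na.rm = TRUE)
  attr(out, "pair") <- pair
  out
}

#' Multi-locus Weir-Cockerham F_ST for every group pair
#'
#' @param panel a [GenotypePanel-class]
#' @param groups factor overriding the panel groups.
#' @return symmetric group x group matrix of multi-locus theta estimates.
#' @export
pairwiseFstMatrix <- function(panel, groups = panelGroups(panel)) {
  g <- levels(droplevels(groups))
  out <- matrix(NA_real_, length(g), length(g), dimnames = list(g, g))
  for (i in seq_along(g)) {
    for (j in seq_len(i - 1L)) {
      f <- weirCockerhamFst(panel, c(g[i], g[j]), groups = groups)
      out[i, j] <- out[j, i] <- attr(f, "theta_multilocus")
    }
  }
  out
}

#' Genome-ordered F_ST scan table
#'
#' Joins per-locus F_ST estimates with the marker map and orders loci by
#' chromosome and physical position for Manhattan-style inspection. Outlier
#' flags (top fraction of per-locus theta) are recomputed on the ordered
#' table with a deterministic tie-break: at equal theta the earlier map
#' position is flagged first, so the largest-bp locus is excluded when the
#' quota is exceeded.
#'
#' @param fst per-locus table from [weirCockerhamFst()].
#' @param map marker map data.frame covering the loci.
#' @param outlier_quantile top fraction flagged (default 0.01).
#' @return data.frame ordered by chromosome and bp with columns from `fst`
#'   plus `chrom`, `bp`, `cM`.
#' @export
fstScanTable <- function(fst, map, outlier_quantile = 0.01) {
  m <- match(fst$marker, map$marker)
  if (anyNA(m)) stop("map does not cover all F_ST loci")
  tab <- cbind(fst, map[m, c("chrom", "bp", "cM")])
  tab <- tab[order(tab$chrom, tab$bp), , drop = FALSE]
  rownames(tab) <- NULL
  ok <- which(!is.na(tab$theta))
  tab$outlier <- FALSE
  if (length(ok)) {
    k <- ceiling(outlier_quantile * length(ok))
    ord <- ok[order(-tab$theta[ok], seq_along(ok))]
    tab$outlier[ord[seq_len(k)]] <- TRUE
  }
  tab
}
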