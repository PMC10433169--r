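#' Pairwise r-squared within a chromosome
#'
#' Composite LD from dosages: for every marker pair within the chromosome
#' (optionally capped by distance or subsampled to `max_pairs`), the squared
#' Pearson correlation of dosage vectors over pairwise-complete calls. DH
#' lines are (near-)homozygous, so composite and haplotypic LD coincide up
#' to rare heterozygous calls. A two-sided Fisher exact p-value is computed
#' from the 2x2 table of homozygous classes at the two loci.
#'
#' @param panel a [GenotypePanel-class]
#' @param chrom chromosome label to analyse.
#' @param max_dist_bp only pairs closer than this (default Inf).
#' @param max_pairs subsample to at most this many pairs (default Inf; uses
#'   the current RNG stream).
#' @param fisher_p compute Fisher exact p-values (default TRUE; the slowest
#'   part on large tables).
#' @return data.frame: `m1`, `m2`, `dist_bp`, `dist_cM`, `r2`, `p`, `n`
#'   (individuals used), with subsampling metadata as attributes.
#' @export
pairwiseR2 <- function(panel, chrom, max_dist_bp = Inf, max_pairs = Inf,
                       fisher_p = TRUE) {
  calls <- genotypeCalls(panel)
  map <- markerMap(panel)
  j <- which(map$chrom == chrom)
  sub <- calls[, j, drop = FALSE]
  poly <- apply(sub, 2L, function(x) {
    v <- x[!is.na(x)]
    length(unique(v)) > 1L
  })
  nSkipped <- sum(!poly)
  j <- j[poly]
  if (length(j) < 2L) stop("fewer than 2 polymorphic markers on chromosome ", chrom)
  bp <- map$bp[j]
  cm <- map$cM[j]
  pr <- which(upper.tri(matrix(0, length(j), length(j))), arr.ind = TRUE)
  d <- bp[pr[, 2]] - bp[pr[, 1]]
  keep <- d <= max_dist_bp
  pr <- pr[keep, , drop = FALSE]
  if (nrow(pr) > max_pairs) {
    ## systematic thinning along the distance axis: preserves the pair
    ## distance distribution, so the decay fit is stable under subsampling
    ord <- order(bp[pr[, 2]] - bp[pr[, 1]])
    sel <- ord[round(seq(1, length(ord), length.out = max_pairs))]
    pr <- pr[sel, , drop = FALSE]
  }
  X <- calls[, j, drop = FALSE]
  r2 <- numeric(nrow(pr)); pv <- rep(NA_real_, nrow(pr)); nn <- integer(nrow(pr))
  for (k in seq_len(nrow(pr))) {
    x <- X[, pr[k, 1]]; y <- X[, pr[k, 2]]
    ok <- !is.na(x) & !is.na(y)
    nn[k] <- sum(ok)
    r <- suppressWarnings(cor(x[ok], y[ok]))
    r2[k] <- if (is.na(r)) NA_real_ else r^2
    if (fisher_p) {
      hom <- ok & x != 1L & y != 1L
      if (sum(hom) > 1L) {
        tb <- table(factor(X[hom, pr[k, 1]], levels = c(0L, 2L)),
                    factor(X[hom, pr[k, 2]], levels = c(0L, 2L)))
        pv[k] <- stats::fisher.test(tb)$p.value
      }
    }
  }
  out <- data.frame(m1 = map$marker[j][pr[, 1]], m2 = map$marker[j][pr[, 2]],
                    dist_bp = bp[pr[, 2]] - bp[pr[, 1]],
                    dist_cM = cm[pr[, 2]] - cm[pr[, 1]],
                    r2 = r2, p = pv, n = nn)
  attr(out, "n_monomorphic_skipped") <- nSkipped
  attr(out, "subsampled") <- is.finite(max_pairs)
  out
}

## Hill-Weir expectation of r2 at recombination scale C = rho * distance,
## for sample size n (chromosomes sampled as n lines)
hillWeirExpectation <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the Hill-Weir expected-r2 decay curve
#'
#' Nonlinear least squares of the drift-equilibrium expectation of r2 as a
#' function of C = rho * distance with sample size n:
#' E(r2) = ((10+C) / ((2+C)(11+C))) (1 + ((3+C)(12+12C+C^2)) / (n(2+C)(11+C))).
#' The single free parameter rho (per bp) is estimated from the pair table;
#' fitting restarts from three fixed initial values (1e-4, 1e-6, 1e-8 per bp)
#' before failing.
#'
#' @param pairs pair table from [pairwiseR2()] (needs `dist_bp`, `r2`).
#' @param n sample size entering the expectation (number of lines).
#' @param distance use `"bp"` (default) or `"cM"` distances.
#' @return object of class `ldFit`: list with `rho` (C per distance unit),
#'   `n`, `distance`, `rss` and `curve` (function of distance).
#' @export
fitHillWeir <- function(pairs, n, distance = c("bp", "cM")) {
  distance <- match.arg(distance)
  d <- if (distance == "bp") pairs$dist_bp else pairs$dist_cM
  ok <- is.finite(d) & is.finite(pairs$r2) & d >= 0
  d <- d[ok]; r2 <- pairs$r2[ok]
  if (length(d) < 10L || length(unique(d)) < 2L) {
    stop("need >= 10 pairs spanning >= 2 distinct distances")
  }
  dat <- data.frame(d = d, r2 = r2)
  starts <- if (distance == "bp") c(1e-4, 1e-6, 1e-8) else c(1, 1e-2, 1e-4)
  fit <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(r2 ~ hillWeirExpectation(rho * d, n), data = dat,
                        start = list(rho = s),
                        lower = .Machine$double.xmin,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("Hill-Weir fit failed from all restarts")
  rho <- coef(fit)[["rho"]]
  structure(list(rho = rho, n = n, distance = distance,
                 rss = sum(residuals(fit)^2),
                 curve = function(dd) hillWeirExpectation(rho * dd, n)),
            class = "ldFit")
}

#' @export
print.ldFit <- function(x, ...) {
  cat(sprintf("ldFit: rho = %.4g per %s, n = %d\n", x$rho, x$distance, x$n))
  invisible(x)
}

#' LD decay distance at an r2 threshold
#'
#' Smallest distance at which the fitted Hill-Weir curve drops to the
#' threshold, solved by bisection to 1 bp resolution. The curve is strictly
#' decreasing, so the crossing is unique. Returns 0 when the curve starts at
#' or below the threshold and NA (with attribute `beyond_range = TRUE`) when
#' the curve never crosses within `max_dist`.
#'
#' @param fit an `ldFit` from [fitHillWeir()].
#' @param threshold r2 level defining "decayed" (default 0.1).
#' @param max_dist search limit (default 1e4x the scale 1/rho; the curve
#'   approaches its 1/n asymptote slowly, so a generous range is needed for
#'   thresholds near the asymptote).
#' @return distance in the fit's units (bp by default).
#' @export
decayDistance <- function(fit, threshold = 0.1, max_dist = NULL) {
  f <- fit$curve
  if (is.null(max_dist)) max_dist <- 1e4 / fit$rho
  if (f(0) <= threshold) return(0)
  if (f(max_dist) > threshold) {
    out <- NA_real_
    attr(out, "beyond_range") <- TRUE
    return(out)
  }
  lo <- 0; hi <- max_dist
  while (hi - lo > 1) {
    mid <- (lo + hi) / 2
    if (f(mid) > threshold) lo <- mid else hi <- mid
  }
  ceiling(hi)
}

#' Per-chromosome LD decay distances for each group
#'
#' Convenience wrapper: for each requested group and chromosome, computes the
#' pair table within the group's lines, fits the Hill-Weir curve with n =
#' group size, and reports the decay distance at the threshold.
#'
#' @param panel a [GenotypePanel-class]
#' @param groups group labels to analyse (default all panel groups).
#' @param chroms chromosomes (default all).
#' @param threshold r2 threshold (default 0.1).
#' @param max_pairs per-chromosome pair cap passed to [pairwiseR2()].
#' @return data.frame: `group`, `chrom`, `n_pairs`, `rho`, `decay_bp`.
#' @export
ldDecayByGroup <- function(panel, groups = levels(panelGroups(panel)),
                           chroms = unique(markerMap(panel)$chrom),
                           threshold = 0.1, max_pairs = 20000L) {
  lab <- panelGroups(panel)
  rows <- list()
  for (g in groups) {
    sub <- panel[lab == g, ]
    for (ch in chroms) {
      row <- tryCatch({
        pairs <- pairwiseR2(sub, ch, max_pairs = max_pairs, fisher_p = FALSE)
        fit <- fitHillWeir(pairs, n = sum(lab == g))
        data.frame(group = g, chrom = as.character(ch),
                   n_pairs = nrow(pairs), rho = fit$rho,
                   decay_bp = as.numeric(decayDistance(fit, threshold)))
      }, error = function(e) {
        data.frame(group = g, chrom = as.character(ch), n_pairs = 0L,
                   rho = NA_real_, decay_bp = NA_real_)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
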