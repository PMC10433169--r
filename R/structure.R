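## shared helper: per-locus mean imputation + column centering
.centeredZ <- function(calls) {
  mu <- colMeans(calls, na.rm = TRUE)
  Z <- sweep(calls, 2L, mu)
  Z[is.na(Z)] <- 0  # mean imputation == zero after centering
  storage.mode(Z) <- "double"
  attr(Z, "mu") <- mu
  Z
}

#' Centered-IBS kinship matrix
#'
#' Genomic relationship matrix from column-centered dosages: K = Z Z' / s,
#' where Z subtracts the per-locus mean dosage and s is the summed observed
#' per-locus variance, so the average self-kinship is exactly 1. Missing
#' calls are mean-imputed per locus for this computation only. Rows sum to
#' ~0 by the centering identity; negative entries are meaningful (two lines
#' less related than random panel members).
#'
#' @param panel a [GenotypePanel-class] (>= 2 individuals).
#' @return symmetric kinship matrix; the scaling constant is attached as
#'   attribute `scaling`.
#' @export
centeredIbsKinship <- function(panel) {
  calls <- genotypeCalls(panel)
  if (nrow(calls) < 2L) stop("need at least 2 individuals")
  Z <- .centeredZ(calls)
  s <- sum(colSums(Z^2) / nrow(Z))
  if (s == 0) stop("zero-variance panel: no polymorphic markers")
  K <- tcrossprod(Z) / s
  dimnames(K) <- list(rownames(calls), rownames(calls))
  attr(K, "scaling") <- s
  K
}

#' Bin the off-diagonal kinship distribution
#'
#' Off-diagonal upper-triangle coefficients are binned; the "= 0" bin uses a
#' tolerance (default |k| <= 0.005, i.e. values that round to 0.0 at
#' one-decimal reporting precision), the remaining coefficients fall into
#' `(0, breaks[1]]`, ... interval bins, with negatives below the tolerance
#' reported separately.
#'
#' @param K kinship matrix.
#' @param breaks increasing positive break points (default c(0.4, 0.5)).
#' @param zero_tol half-width of the "equal to 0" bin.
#' @return named numeric vector of fractions (sums to 1): `negative`,
#'   `zero`, one per interval, and `gt_<last break>`.
#' @examples
#' K <- diag(3); K[upper.tri(K)] <- c(0, 0.2, 0.6); K[lower.tri(K)] <- 0
#' K <- K + t(K) - diag(diag(K))
#' kinshipDistribution(K)
#' @export
kinshipDistribution <- function(K, breaks = c(0.4, 0.5), zero_tol = 0.005) {
  v <- K[upper.tri(K)]
  n <- length(v)
  zero <- abs(v) <= zero_tol
  neg <- v < -zero_tol
  rest <- v[!zero & !neg]
  edges <- c(zero_tol, breaks, Inf)
  counts <- table(cut(rest, edges, right = TRUE))
  labs <- c(sprintf("(0,%g]", breaks[1]),
            if (length(breaks) > 1)
              sprintf("(%g,%g]", breaks[-length(breaks)], breaks[-1]),
            sprintf("gt_%g", breaks[length(breaks)]))
  out <- c(negative = sum(neg), zero = sum(zero),
           setNames(as.integer(counts), labs)) / n
  out
}

#' Principal component analysis with BIC model-size selection
#'
#' Eigen-decomposes the individual-space cross-product of the centered
#' (optionally unit-variance standardized) dosage matrix; scores are the
#' classical PC projections. The number of informative components is chosen
#' by a profile-likelihood BIC: for each candidate k, retained eigenvalues
#' keep their values and the residual spectrum is pooled into an isotropic
#' variance; the parameter count is k (d_eff + 1) - k(k-1)/2 with d_eff
#' capped at the matrix rank. The k minimizing BIC is selected.
#'
#' @param panel a [GenotypePanel-class] (>= 3 individuals).
#' @param max_pcs maximum candidate number of components (default 10,
#'   truncated with a warning at the rank of the matrix).
#' @param scale standardize loci to unit variance before decomposition
#'   (default FALSE).
#' @return object of class `pcaResult`: list with `eigenvalues`, `scores`
#'   (individuals x PCs), `percent_var`, `bic` (data.frame `k`, `bic`),
#'   `chosen_k`, and `groups`.
#' @export
pcaPanel <- function(panel, max_pcs = 10L, scale = FALSE) {
  calls <- genotypeCalls(panel)
  n <- nrow(calls)
  if (n < 3L) stop("need at least 3 individuals")
  Z <- .centeredZ(calls)
  if (scale) {
    sdv <- sqrt(colSums(Z^2) / (n - 1))
    keep <- sdv > 0
    Z <- sweep(Z[, keep, drop = FALSE], 2L, sdv[keep], "/")
  }
  E <- eigen(tcrossprod(Z), symmetric = TRUE)
  lam <- pmax(E$values, 0)
  rank <- sum(lam > max(lam) * 1e-10)
  m <- min(rank, n - 1L)
  if (max_pcs > m) {
    warning("max_pcs exceeds matrix rank; truncated to ", m)
    max_pcs <- m
  }
  lam <- lam[seq_len(m)]
  scores <- E$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(lam), m)
  dimnames(scores) <- list(rownames(calls), paste0("PC", seq_len(m)))
  pct <- 100 * lam / sum(lam)

  d_eff <- min(ncol(calls), m)
  bic <- vapply(seq_len(max_pcs), function(k) {
    ## saturated case k = m: no residual spectrum to pool
    sig2 <- if (k < m) mean(lam[(k + 1L):m]) else NA_real_
    ll <- -(n / 2) * (sum(log(lam[seq_len(k)])) +
                        if (k < m) (m - k) * log(sig2) else 0)
    pk <- k * (d_eff + 1) - k * (k - 1) / 2
    -2 * ll + pk * log(n)
  }, numeric(1))
  chosen <- which.min(bic)

  structure(list(eigenvalues = lam, scores = scores, percent_var = pct,
                 bic = data.frame(k = seq_len(max_pcs), bic = bic),
                 chosen_k = chosen, groups = panelGroups(panel)),
            class = "pcaResult")
}

#' @export
print.pcaResult <- function(x, ...) {
  cat(sprintf("pcaResult: %d individuals, %d components\n",
              nrow(x$scores), length(x$eigenvalues)))
  cat(sprintf("PC1-2 explain %.1f%% of variation; BIC selects k = %d\n",
              sum(x$percent_var[1:2]), x$chosen_k))
  invisible(x)
}
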