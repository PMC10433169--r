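# shared fixture builders and independent oracles used across test files

# minimal panel from a dosage matrix; map spacing defaults to 100 kb / 0.1 cM
toyPanel <- function(calls, groups = "panel", chrom = 1, bp = NULL,
                     cM = NULL) {
  nm <- ncol(calls)
  if (is.null(bp)) bp <- seq(1e5, by = 1e5, length.out = nm)
  if (is.null(cM)) cM <- seq(0.1, by = 0.1, length.out = nm)
  map <- data.frame(marker = sprintf("m%02d", seq_len(nm)),
                    chrom = chrom, bp = bp, cM = cM)
  GenotypePanel(calls, map, groups = groups)
}

# small simulation scenario used by several tests (study conditions scaled
# to two chromosomes so a replicate runs in ~1 s)
miniConfig <- function(seed = NULL, ...) {
  args <- utils::modifyList(
    list(n_markers_per_chrom = 200, n_chromosomes = 2, chrom_length_cM = 120,
         c0_size = 40, maintenance_generations = 2, maintenance_size = 40,
         n_cycles = 17, cycle_pop_size = 40, selection_fraction = 0.25,
         n_dh_per_group = c(20, 20, 20), seed = seed),
    list(...))
  do.call(simConfig, args)
}

# --- independent oracles ---------------------------------------------------

# Weir-Cockerham theta via the nested allele-indicator ANOVA mean squares:
# c = MS within individuals, b = (MS_ind - MS_within)/2,
# a = (MS_pop - MS_ind)/(2 n_c)
oracleWcTheta <- function(calls1, calls2) {
  mkAlleles <- function(calls) t(vapply(calls, function(d) {
    if (is.na(d)) c(NA, NA) else c(as.integer(d >= 1), as.integer(d == 2))
  }, integer(2)))
  a1 <- mkAlleles(calls1); a2 <- mkAlleles(calls2)
  y <- c(t(a1), t(a2))
  ind <- rep(seq_len(length(calls1) + length(calls2)), each = 2)
  pop <- rep(c(1, 2), times = 2 * c(length(calls1), length(calls2)))
  ok <- !is.na(y)
  y <- y[ok]; ind <- ind[ok]; pop <- pop[ok]
  n_i <- c(length(unique(ind[pop == 1])), length(unique(ind[pop == 2])))
  grand <- mean(y)
  popMeans <- tapply(y, pop, mean)
  indMeans <- tapply(y, ind, mean)
  ssPop <- sum(2 * n_i * (popMeans - grand)^2)
  ssInd <- sum(2 * (indMeans - popMeans[as.character(pop[!duplicated(ind)])])^2)
  ssGam <- sum((y - indMeans[as.character(ind)])^2)
  msPop <- ssPop / (2 - 1)
  msInd <- ssInd / (sum(n_i) - 2)
  msGam <- ssGam / sum(n_i)
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (2 - 1)
  cc <- msGam
  b <- (msInd - msGam) / 2
  a <- (msPop - msInd) / (2 * nc)
  a / (a + b + cc)
}

# naive UPGMA (size-weighted averaging) returning the cophenetic matrix
oracleUpgmaCophenetic <- function(d) {
  n <- nrow(d)
  labs <- rownames(d)
  clusters <- as.list(seq_len(n))
  dm <- d
  coph <- matrix(0, n, n)
  active <- seq_len(n)
  while (length(active) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_len(ii - 1)) {
        dd <- dm[active[ii], active[jj]]
        if (dd < bestd) { bestd <- dd; best <- c(active[ii], active[jj]) }
      }
    }
    i <- best[1]; j <- best[2]
    mi <- clusters[[i]]; mj <- clusters[[j]]
    coph[mi, mj] <- bestd; coph[mj, mi] <- bestd
    ni <- length(mi); nj <- length(mj)
    for (k in setdiff(active, c(i, j))) {
      dm[i, k] <- dm[k, i] <- (ni * dm[i, k] + nj * dm[j, k]) / (ni + nj)
    }
    clusters[[i]] <- c(mi, mj)
    active <- setdiff(active, j)
  }
  dimnames(coph) <- list(labs, labs)
  coph
}

# exhaustive 2-state HMM posteriors over all state paths (tiny L only)
oraclePathPosteriors <- function(e0, e1, stay0, stay1, prior1) {
  L <- length(e0)
  paths <- as.matrix(expand.grid(rep(list(0:1), L)))
  probs <- apply(paths, 1, function(s) {
    p <- if (s[1] == 1) prior1 * e1[1] else (1 - prior1) * e0[1]
    for (t in 2:L) {
      tr <- if (s[t - 1] == 0) {
        if (s[t] == 0) stay0[t - 1] else 1 - stay0[t - 1]
      } else {
        if (s[t] == 1) stay1[t - 1] else 1 - stay1[t - 1]
      }
      p <- p * tr * (if (s[t] == 1) e1[t] else e0[t])
    }
    p
  })
  unname(colSums(paths * probs) / sum(probs))
}
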