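#' Per-locus minor allele frequency
#'
#' Allele copies are counted from dosages: a call of dosage d contributes d
#' copies of the counted allele and 2 - d of the other; missing calls are
#' skipped. The MAF is the lesser of the two allele frequencies.
#'
#' @param calls numeric vector of dosages (0/1/2/NA) at one locus, or a
#'   [GenotypePanel-class] (then a per-marker vector is returned).
#' @return frequency in [0, 0.5]; NA (with a warning) for an all-missing
#'   locus.
#' @examples
#' locusMaf(c(0, 1, 2, 2))  # 5 of 8 copies -> minor freq 0.375
#' @export
locusMaf <- function(calls) {
  if (is(calls, "GenotypePanel")) calls <- genotypeCalls(calls)
  if (is.matrix(calls)) {
    cnt <- colSums(calls, na.rm = TRUE)
    tot <- 2 * colSums(!is.na(calls))
    p <- cnt / tot
    if (any(tot == 0L)) warning("all-missing loci yield NA MAF")
    return(pmin(p, 1 - p))
  }
  tot <- 2 * sum(!is.na(calls))
  if (tot == 0L) {
    warning("all calls missing at locus")
    return(NA_real_)
  }
  p <- sum(calls, na.rm = TRUE) / tot
  min(p, 1 - p)
}

#' Per-locus unbiased expected heterozygosity
#'
#' Nei's gene diversity with the small-sample correction,
#' \deqn{H_{exp} = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right),}
#' where n is the number of non-missing gene copies observed at the locus
#' (2 x non-missing individuals) and p_i the sample allele frequencies.
#'
#' @inheritParams locusMaf
#' @return H_exp per locus; NA (flagged by warning) when fewer than 2 gene
#'   copies are observed.
#' @examples
#' locusHexp(c(0, 1))       # n = 4 copies, p = 0.125
#' locusHexp(c(1))          # n = 2 copies, one of each allele -> 1
#' @export
locusHexp <- function(calls) {
  if (is(calls, "GenotypePanel")) calls <- genotypeCalls(calls)
  hexp1 <- function(n, p) {
    if (n < 2) return(NA_real_)
    (n / (n - 1)) * (1 - (p^2 + (1 - p)^2))
  }
  if (is.matrix(calls)) {
    n <- 2 * colSums(!is.na(calls))
    p <- ifelse(n > 0, colSums(calls, na.rm = TRUE) / n, NA_real_)
    if (any(n < 2)) warning("loci with < 2 gene copies yield NA H_exp")
    out <- ifelse(n >= 2, (n / pmax(n - 1, 1)) * (1 - (p^2 + (1 - p)^2)),
                  NA_real_)
    return(as.numeric(out))
  }
  n <- 2 * sum(!is.na(calls))
  if (n < 2) {
    warning("fewer than 2 gene copies at locus")
    return(NA_real_)
  }
  hexp1(n, sum(calls, na.rm = TRUE) / n)
}

#' Per-group diversity summary (MAF and expected heterozygosity)
#'
#' Allele frequencies are re-estimated within each group, so the minor allele
#' is re-oriented per group (guaranteeing group MAF <= 0.5) unless
#' `reorient = FALSE`, in which case the panel-wide counted-allele frequency
#' is averaged instead. Loci monomorphic within a group contribute 0 to both
#' statistics. Standard errors are over loci.
#'
#' @param panel a [GenotypePanel-class]
#' @param groups optional factor overriding `panelGroups(panel)`.
#' @param reorient re-orient the minor allele within each group (default TRUE).
#' @return data.frame with one row per group: `group`, `n_individuals`,
#'   `mean_maf`, `se_maf`, `mean_hexp`, `se_hexp`.
#' @examples
#' sim <- buildPanel(simConfig(n_markers_per_chrom = 80, n_chromosomes = 2,
#'                             c0_size = 20, maintenance_generations = 0,
#'                             n_cycles = 3, cycle_pop_size = 20,
#'                             n_dh_per_group = c(10, 10, 10), seed = 2))
#' groupDiversity(sim$panel)
#' @export
groupDiversity <- function(panel, groups = panelGroups(panel),
                           reorient = TRUE) {
  calls <- genotypeCalls(panel)
  se <- function(x) sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  rows <- lapply(levels(groups), function(g) {
    sub <- calls[groups == g, , drop = FALSE]
    n <- 2 * colSums(!is.na(sub))
    p <- ifelse(n > 0, colSums(sub, na.rm = TRUE) / n, NA_real_)
    maf <- if (reorient) pmin(p, 1 - p) else p
    hexp <- ifelse(n >= 2, (n / pmax(n - 1, 1)) * (1 - (p^2 + (1 - p)^2)),
                   NA_real_)
    data.frame(group = g, n_individuals = nrow(sub),
               mean_maf = mean(maf, na.rm = TRUE), se_maf = se(maf),
               mean_hexp = mean(hexp, na.rm = TRUE), se_hexp = se(hexp))
  })
  do.call(rbind, rows)
}
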