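#' Configuration for the breeding-scheme simulator
#'
#' Bundles and validates all parameters of the forward-in-time simulation of a
#' synthetic maize population: a set of inbred founders intermated into a base
#' synthetic (C0), a configurable number of maintenance generations of random
#' mating, repeated cycles of truncation selection on an additive trait (or
#' pure drift when `selection_fraction = 1`), an intermated C0 x C17 cross,
#' and doubled-haploid (DH) derivation with residual heterozygosity injected
#' as per-call genotyping error.
#'
#' Defaults emulate the Iowa Stiff Stalk Synthetic setting: 16 founders, ten
#' chromosomes of 150 cM (roughly 1,500 cM genome-wide), a physical scale of
#' about 1385.6 kb per cM, 17 selection cycles, panel sizes of 15 progenitors
#' and 132/170/185 DH lines, and a 1.3% per-call error rate producing the
#' residual heterozygosity observed in DH lines.
#'
#' @param n_founders number of fully inbred founder lines (default 16).
#' @param n_markers_per_chrom markers simulated per chromosome.
#' @param n_chromosomes number of chromosomes (default 10).
#' @param chrom_length_cM genetic length of each chromosome in cM (scalar or
#'   vector of length `n_chromosomes`).
#' @param cM_per_Mb genetic-to-physical conversion; the default corresponds to
#'   1385.6 kb per cM.
#' @param c0_size individuals in the intermated base population.
#' @param maintenance_generations random-mating generations between founding
#'   and sampling, modeling unrecorded seed maintenance (default 5).
#' @param maintenance_size population size during maintenance (default 200).
#' @param n_cycles recurrent-selection cycles from C0 to the advanced cycle
#'   population (default 17).
#' @param cycle_pop_size individuals evaluated per cycle.
#' @param selection_fraction proportion advanced each cycle; 1 = pure drift.
#'   The default 0.05 of 200 evaluated individuals recombines ~10 selected
#'   parents per cycle, the order of the historical program, and reproduces
#'   a comparable diversity loss over 17 cycles.
#' @param trait_n_qtl markers recruited as additive QTL for the selected trait.
#' @param trait_h2 narrow-sense heritability of the selected trait.
#' @param n_progenitors founders retained in the panel's progenitor group
#'   (default 15: one founder is dropped, mirroring QC exclusion of one line).
#' @param n_dh_per_group DH lines per group, named or ordered as
#'   (C0_DHL, C0/C17_DHL, C17_DHL); default c(132, 170, 185).
#' @param genotyping_error_rate per-call probability that a homozygous DH call
#'   is read as heterozygous (default 0.013, giving ~1.3% residual
#'   heterozygosity).
#' @param private_allele_fraction fraction of founder markers whose minor
#'   allele is carried by a single founder.
#' @param seed optional RNG seed applied by [buildPanel()].
#' @return A validated list of class `simConfig`.
#' @examples
#' cfg <- simConfig(n_markers_per_chrom = 100, n_chromosomes = 2,
#'                  c0_size = 30, cycle_pop_size = 30,
#'                  n_dh_per_group = c(10, 10, 10), seed = 1)
#' str(cfg[c("n_founders", "n_cycles")])
#' @export
simConfig <- function(n_founders = 16,
                      n_markers_per_chrom = 2489,
                      n_chromosomes = 10,
                      chrom_length_cM = 150,
                      cM_per_Mb = 1000 / 1385.6,
                      c0_size = 200,
                      maintenance_generations = 5,
                      maintenance_size = 200,
                      n_cycles = 17,
                      cycle_pop_size = 200,
                      selection_fraction = 0.05,
                      trait_n_qtl = 100,
                      trait_h2 = 0.3,
                      n_progenitors = 15,
                      n_dh_per_group = c(132, 170, 185),
                      genotyping_error_rate = 0.013,
                      private_allele_fraction = 0.15,
                      seed = NULL) {
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_markers_per_chrom = as.integer(n_markers_per_chrom),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_cM = rep(as.numeric(chrom_length_cM),
                          length.out = as.integer(n_chromosomes)),
    cM_per_Mb = as.numeric(cM_per_Mb),
    c0_size = as.integer(c0_size),
    maintenance_generations = as.integer(maintenance_generations),
    maintenance_size = as.integer(maintenance_size),
    n_cycles = as.integer(n_cycles),
    cycle_pop_size = as.integer(cycle_pop_size),
    selection_fraction = as.numeric(selection_fraction),
    trait_n_qtl = as.integer(trait_n_qtl),
    trait_h2 = as.numeric(trait_h2),
    n_progenitors = as.integer(n_progenitors),
    n_dh_per_group = as.integer(rep(n_dh_per_group, length.out = 3)),
    genotyping_error_rate = as.numeric(genotyping_error_rate),
    private_allele_fraction = as.numeric(private_allele_fraction),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  counts <- c("n_founders", "n_markers_per_chrom", "n_chromosomes", "c0_size",
              "maintenance_size", "cycle_pop_size", "trait_n_qtl",
              "n_progenitors")
  for (nm in counts) {
    if (cfg[[nm]] < 1L) stop(nm, " must be >= 1")
  }
  if (any(cfg$n_dh_per_group < 1L)) stop("n_dh_per_group entries must be >= 1")
  if (cfg$n_cycles < 0L) stop("n_cycles must be >= 0")
  if (cfg$maintenance_generations < 0L) stop("maintenance_generations must be >= 0")
  if (cfg$selection_fraction <= 0 || cfg$selection_fraction > 1) {
    stop("selection_fraction must be in (0, 1]")
  }
  if (cfg$genotyping_error_rate < 0 || cfg$genotyping_error_rate >= 1) {
    stop("genotyping_error_rate must be in [0, 1)")
  }
  if (cfg$trait_h2 <= 0 || cfg$trait_h2 > 1) stop("trait_h2 must be in (0, 1]")
  if (any(cfg$chrom_length_cM <= 0)) stop("chrom_length_cM must be positive")
  if (cfg$n_progenitors > cfg$n_founders) {
    stop("n_progenitors cannot exceed n_founders")
  }
  class(cfg) <- "simConfig"
  cfg
}

## --- internal haplotype population representation --------------------------
## hapA/hapB: individuals x markers 0/1 allele matrices (two gametes each);
## orgA/orgB: founder-of-origin index per allele; map: marker map data.frame.

newHaploPop <- function(hapA, hapB, orgA, orgB, map) {
  structure(list(hapA = hapA, hapB = hapB, orgA = orgA, orgB = orgB, map = map),
            class = "haploPop")
}

#' @export
print.haploPop <- function(x, ...) {
  cat(sprintf("haploPop: %d individuals x %d markers (%d chromosomes)\n",
              nrow(x$hapA), ncol(x$hapA), length(unique(x$map$chrom))))
  invisible(x)
}

nIndividuals <- function(pop) nrow(pop$hapA)

## map split by chromosome, cached structure for meiosis
splitMapIdx <- function(map) {
  idx <- split(seq_len(nrow(map)), map$chrom)
  lapply(idx, function(i) list(idx = i, cM = map$cM[i]))
}

## one recombinant gamete (allele vector + origin vector) from individual i
sampleGamete <- function(pop, i, chromSplit) {
  nm <- ncol(pop$hapA)
  allele <- integer(nm)
  origin <- integer(nm)
  hapA <- pop$hapA[i, ]
  hapB <- pop$hapB[i, ]
  orgA <- pop$orgA[i, ]
  orgB <- pop$orgB[i, ]
  for (cs in chromSplit) {
    cm <- cs$cM
    L <- cm[length(cm)] - cm[1]
    k <- rpois(1L, L / 100)
    phase <- sample.int(2L, 1L) - 1L            # 0 = start on hapA
    if (k > 0L) {
      xo <- sort(runif(k, min = cm[1], max = cm[1] + L))
      phase <- (phase + findInterval(cm, xo)) %% 2L
    } else {
      phase <- rep.int(phase, length(cm))
    }
    j <- cs$idx
    useB <- phase == 1L
    allele[j] <- ifelse(useB, hapB[j], hapA[j])
    origin[j] <- ifelse(useB, orgB[j], orgA[j])
  }
  list(allele = allele, origin = origin)
}

#' Simulate a set of inbred founder lines
#'
#' Draws fully homozygous founder genotypes at polymorphic biallelic markers
#' on a genetic map. Allele configurations follow a 1/j-weighted frequency
#' spectrum over the number of founders carrying the minor allele, with a
#' configurable fraction of markers whose minor allele is private to a single
#' founder (frequency 1/n_founders in the founder pool, ~6.2% with 16
#' founders). Physical bp positions are derived from cM positions at the
#' constant `cM_per_Mb` rate.
#'
#' @param config a [simConfig()] object.
#' @return list with `pop` (internal haplotype population), `panel`
#'   (a [GenotypePanel-class] of the founders) and `map` (marker map).
#' @examples
#' set.seed(1)
#' f <- makeFounders(simConfig(n_markers_per_chrom = 50, n_chromosomes = 2))
#' f$panel
#' @export
makeFounders <- function(config) {
  nf <- config$n_founders
  nmc <- config$n_markers_per_chrom
  nc <- config$n_chromosomes
  maps <- vector("list", nc)
  for (ch in seq_len(nc)) {
    L <- config$chrom_length_cM[ch]
    cm <- sort(runif(nmc, min = 0, max = L))
    bp <- round(cm / config$cM_per_Mb * 1e6)
    ## enforce strictly increasing bp (cM ties at bp resolution)
    bp <- bp + seq_len(nmc) - 1L
    maps[[ch]] <- data.frame(
      marker = sprintf("chr%d_%07d", ch, seq_len(nmc)),
      chrom = ch, bp = bp, cM = cm
    )
  }
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  nm <- nrow(map)

  ## minor-allele carrier count per marker: private with stated probability,
  ## otherwise 1/j-weighted among 2..floor(nf/2) carriers
  jmax <- max(2L, nf %/% 2L)
  wts <- 1 / (2:jmax)
  carriers <- ifelse(
    runif(nm) < config$private_allele_fraction, 1L,
    sample(2:jmax, nm, replace = TRUE, prob = wts)
  )
  hap <- matrix(0L, nrow = nf, ncol = nm)
  for (m in seq_len(nm)) {
    hap[sample.int(nf, carriers[m]), m] <- 1L
  }
  poly <- colSums(hap) > 0L & colSums(hap) < nf
  if (!any(poly)) stop("no polymorphic markers after founder draw")
  hap <- hap[, poly, drop = FALSE]
  map <- map[poly, , drop = FALSE]
  rownames(hap) <- sprintf("P%02d", seq_len(nf))
  colnames(hap) <- map$marker
  org <- matrix(rep(seq_len(nf), ncol(hap)), nrow = nf,
                dimnames = dimnames(hap))
  pop <- newHaploPop(hap, hap, org, org, map)
  panel <- GenotypePanel(hap + hap, map, groups = "founders")
  list(pop = pop, panel = panel, map = map)
}

#' Intermate a population by random pairing and meiosis
#'
#' Offspring are produced by drawing two distinct parents uniformly at random
#' and sampling one recombinant gamete from each. Crossovers follow the
#' Haldane model: per chromosome, crossover count is Poisson with mean equal
#' to map length / 100, positions uniform on the cM scale, no interference.
#' Founder-of-origin labels are carried through recombination.
#'
#' @param pop internal haplotype population (from [makeFounders()] or a
#'   previous simulation step).
#' @param n_offspring number of offspring to produce.
#' @return a haplotype population of the offspring.
#' @export
intermate <- function(pop, n_offspring) {
  n <- nIndividuals(pop)
  if (n < 2L) stop("intermating requires at least 2 parents (no selfing)")
  nm <- ncol(pop$hapA)
  chromSplit <- splitMapIdx(pop$map)
  hapA <- matrix(0L, n_offspring, nm)
  hapB <- matrix(0L, n_offspring, nm)
  orgA <- matrix(0L, n_offspring, nm)
  orgB <- matrix(0L, n_offspring, nm)
  for (o in seq_len(n_offspring)) {
    pr <- sample.int(n, 2L, replace = FALSE)
    g1 <- sampleGamete(pop, pr[1], chromSplit)
    g2 <- sampleGamete(pop, pr[2], chromSplit)
    hapA[o, ] <- g1$allele; orgA[o, ] <- g1$origin
    hapB[o, ] <- g2$allele; orgB[o, ] <- g2$origin
  }
  colnames(hapA) <- colnames(hapB) <- colnames(orgA) <- colnames(orgB) <-
    pop$map$marker
  newHaploPop(hapA, hapB, orgA, orgB, pop$map)
}

## cross two populations: each offspring takes one gamete from each
crossPops <- function(popA, popB, n_offspring) {
  chromSplit <- splitMapIdx(popA$map)
  nm <- ncol(popA$hapA)
  hapA <- matrix(0L, n_offspring, nm); hapB <- matrix(0L, n_offspring, nm)
  orgA <- matrix(0L, n_offspring, nm); orgB <- matrix(0L, n_offspring, nm)
  for (o in seq_len(n_offspring)) {
    g1 <- sampleGamete(popA, sample.int(nIndividuals(popA), 1L), chromSplit)
    g2 <- sampleGamete(popB, sample.int(nIndividuals(popB), 1L), chromSplit)
    hapA[o, ] <- g1$allele; orgA[o, ] <- g1$origin
    hapB[o, ] <- g2$allele; orgB[o, ] <- g2$origin
  }
  newHaploPop(hapA, hapB, orgA, orgB, popA$map)
}

#' Run recurrent-selection (or drift) cycles
#'
#' Each cycle optionally applies truncation selection on a simulated additive
#' trait — QTL effects are drawn once, phenotypes add Gaussian noise scaled to
#' the requested heritability, and the top `selection_fraction` of individuals
#' are advanced — then intermates the survivors to `cycle_pop_size`. With
#' `selection_fraction = 1` the process is pure genetic drift.
#'
#' @param c0 haplotype population to start from.
#' @param config a [simConfig()]; `n_cycles`, `cycle_pop_size`,
#'   `selection_fraction`, `trait_n_qtl`, `trait_h2` are used.
#' @param keep_all if TRUE return every intermediate cycle, else only the
#'   final one.
#' @return list with `cycles` (list of populations; `cycles[[1]]` is the
#'   input) and `qtl` (data.frame of QTL marker indices and effects).
#' @export
runCycles <- function(c0, config, keep_all = FALSE) {
  nm <- ncol(c0$hapA)
  nq <- min(config$trait_n_qtl, nm)
  qtlIdx <- sample.int(nm, nq)
  effects <- rnorm(nq)
  pop <- c0
  cycles <- list(pop)
  for (cyc in seq_len(config$n_cycles)) {
    if (config$selection_fraction < 1) {
      g <- (pop$hapA[, qtlIdx, drop = FALSE] +
            pop$hapB[, qtlIdx, drop = FALSE]) %*% effects
      vg <- var(as.vector(g))
      ve <- if (vg > 0) vg * (1 - config$trait_h2) / config$trait_h2 else 1
      pheno <- as.vector(g) + rnorm(length(g), sd = sqrt(ve))
      nsel <- max(2L, ceiling(config$selection_fraction * nIndividuals(pop)))
      keep <- order(pheno, decreasing = TRUE)[seq_len(nsel)]
      if (length(keep) < 2L) stop("selection left fewer than 2 parents")
      sel <- newHaploPop(pop$hapA[keep, , drop = FALSE],
                         pop$hapB[keep, , drop = FALSE],
                         pop$orgA[keep, , drop = FALSE],
                         pop$orgB[keep, , drop = FALSE], pop$map)
    } else {
      sel <- pop
    }
    pop <- intermate(sel, config$cycle_pop_size)
    if (keep_all) cycles[[cyc + 1L]] <- pop
  }
  if (!keep_all) cycles <- list(cycles[[1]], pop)
  list(cycles = cycles, qtl = data.frame(idx = qtlIdx, effect = effects))
}

#' Derive doubled-haploid lines from a population
#'
#' Each DH line fixes one recombinant gamete sampled from a random individual
#' (every locus homozygous), after which per-call genotyping error converts a
#' homozygous call to a heterozygous one with probability `error_rate`,
#' producing the residual heterozygosity observed in real DH data.
#'
#' @param pop haplotype population to sample gametes from.
#' @param n_dh number of DH lines.
#' @param error_rate per-call heterozygous-error probability.
#' @param prefix id prefix for the lines.
#' @return list with `calls` (lines x markers dosage matrix, errors applied),
#'   `origin` (lines x markers founder-of-origin index of the fixed gamete)
#'   and `map`.
#' @export
deriveDH <- function(pop, n_dh, error_rate = 0, prefix = "DHL") {
  if (nIndividuals(pop) < 1L) stop("empty population")
  chromSplit <- splitMapIdx(pop$map)
  nm <- ncol(pop$hapA)
  calls <- matrix(0L, n_dh, nm)
  origin <- matrix(0L, n_dh, nm)
  for (d in seq_len(n_dh)) {
    g <- sampleGamete(pop, sample.int(nIndividuals(pop), 1L), chromSplit)
    calls[d, ] <- 2L * g$allele
    origin[d, ] <- g$origin
  }
  if (error_rate > 0) {
    err <- matrix(runif(length(calls)) < error_rate, nrow = n_dh)
    calls[err] <- 1L
  }
  rownames(calls) <- rownames(origin) <- sprintf("%s%03d", prefix, seq_len(n_dh))
  colnames(calls) <- colnames(origin) <- pop$map$marker
  list(calls = calls, origin = origin, map = pop$map)
}

#' Simulate the full DH panel of a recurrent-selection study
#'
#' Runs the complete scheme: founders are intermated into a base synthetic
#' (C0) and random-mated through maintenance generations; recurrent selection
#' produces the advanced cycle population (C17); a C0 x C17 cross is
#' intermated once; DH lines are derived from C0, the cross, and C17; and the
#' panel combines the retained progenitors with the three DH groups. Dosages
#' are oriented to the panel-wide minor allele.
#'
#' @param config a [simConfig()].
#' @return list with components:
#'   \describe{
#'     \item{panel}{[GenotypePanel-class] with groups `progenitors`,
#'       `C0_DHL`, `C0/C17_DHL`, `C17_DHL`.}
#'     \item{truth}{list: `origin` (founder-of-origin index per individual and
#'       marker; progenitors carry their own index), `true_contribution`
#'       (founders x groups matrix of genome proportions, columns sum to 1).}
#'     \item{populations}{internal haplotype populations (`founders`, `c0`,
#'       `c17`, `c0c17`) for downstream experimentation.}
#'   }
#' @examples
#' sim <- buildPanel(simConfig(n_markers_per_chrom = 60, n_chromosomes = 2,
#'                             c0_size = 25, maintenance_generations = 1,
#'                             maintenance_size = 25, n_cycles = 4,
#'                             cycle_pop_size = 25,
#'                             n_dh_per_group = c(8, 8, 8), seed = 7))
#' sim$panel
#' @export
buildPanel <- function(config = simConfig()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  fnd <- makeFounders(config)
  c0 <- intermate(fnd$pop, config$c0_size)
  for (g in seq_len(config$maintenance_generations)) {
    c0 <- intermate(c0, config$maintenance_size)
  }
  adv <- runCycles(c0, config)
  c17 <- adv$cycles[[length(adv$cycles)]]
  f1 <- crossPops(c0, c17, config$cycle_pop_size)
  c0c17 <- intermate(f1, config$cycle_pop_size)

  er <- config$genotyping_error_rate
  dh0 <- deriveDH(c0, config$n_dh_per_group[1], er, prefix = "C0_DHL")
  dhx <- deriveDH(c0c17, config$n_dh_per_group[2], er, prefix = "C0C17_DHL")
  dh17 <- deriveDH(c17, config$n_dh_per_group[3], er, prefix = "C17_DHL")

  keepP <- seq_len(config$n_progenitors)
  progCalls <- fnd$pop$hapA[keepP, , drop = FALSE] +
    fnd$pop$hapB[keepP, , drop = FALSE]
  progOrigin <- fnd$pop$orgA[keepP, , drop = FALSE]

  calls <- rbind(progCalls, dh0$calls, dhx$calls, dh17$calls)
  origin <- rbind(progOrigin, dh0$origin, dhx$origin, dh17$origin)
  groups <- factor(rep(c("progenitors", "C0_DHL", "C0/C17_DHL", "C17_DHL"),
                       times = c(config$n_progenitors, config$n_dh_per_group)),
                   levels = c("progenitors", "C0_DHL", "C0/C17_DHL", "C17_DHL"))
  panel <- orientMinor(GenotypePanel(calls, fnd$map, groups = groups))

  contrib <- sapply(split(seq_len(nrow(origin)), groups), function(rows) {
    tab <- tabulate(origin[rows, , drop = FALSE], nbins = config$n_founders)
    tab / sum(tab)
  })
  rownames(contrib) <- sprintf("P%02d", seq_len(config$n_founders))

  list(panel = panel,
       truth = list(origin = origin, true_contribution = contrib),
       populations = list(founders = fnd$pop, c0 = c0, c17 = c17,
                          c0c17 = c0c17),
       qtl = adv$qtl,
       config = config)
}

## expected heterozygosity from a haplotype population (per-locus, unbiased)
popHexp <- function(pop) {
  al <- rbind(pop$hapA, pop$hapB)
  n <- nrow(al)
  p <- colMeans(al)
  mean((n / (n - 1)) * (1 - (p^2 + (1 - p)^2)))
}
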