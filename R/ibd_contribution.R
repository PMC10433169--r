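#' Interpolate genetic positions from a reference map
#'
#' Fills per-marker cM coordinates by linear interpolation between flanking
#' reference points (per chromosome); markers beyond the reference span are
#' extrapolated at the nearest interval's local rate. A marker further beyond
#' the span than 10% of the reference chromosome length is an error.
#'
#' @param map marker map (`marker`, `chrom`, `bp`, `cM`; cM may be NA).
#' @param reference_map reference data.frame (`chrom`, `bp`, `cM`), monotone
#'   in bp within chromosome.
#' @return `map` with the `cM` column replaced by interpolated values.
#' @export
interpolateMap <- function(map, reference_map) {
  out <- map
  for (ch in unique(map$chrom)) {
    ref <- reference_map[reference_map$chrom == ch, , drop = FALSE]
    if (nrow(ref) < 2L) stop("reference map needs >= 2 points on chromosome ", ch)
    ref <- ref[order(ref$bp), , drop = FALSE]
    if (is.unsorted(ref$cM)) stop("reference cM not monotone on chromosome ", ch)
    i <- which(map$chrom == ch)
    bp <- map$bp[i]
    span <- diff(range(ref$bp))
    over <- pmax(ref$bp[1] - bp, bp - ref$bp[nrow(ref)], 0)
    if (any(over > 0.1 * span)) {
      stop("marker(s) beyond reference span by > 10% of chromosome length")
    }
    cm <- stats::approx(ref$bp, ref$cM, xout = bp, rule = 1)$y
    ## extrapolate ends at the nearest interval's rate
    lowRate <- (ref$cM[2] - ref$cM[1]) / (ref$bp[2] - ref$bp[1])
    nR <- nrow(ref)
    hiRate <- (ref$cM[nR] - ref$cM[nR - 1]) / (ref$bp[nR] - ref$bp[nR - 1])
    lo <- bp < ref$bp[1]
    hi <- bp > ref$bp[nR]
    cm[lo] <- ref$cM[1] + (bp[lo] - ref$bp[1]) * lowRate
    cm[hi] <- ref$cM[nR] + (bp[hi] - ref$bp[nR]) * hiRate
    out$cM[i] <- cm
  }
  out
}

#' Parameters of the two-state IBD hidden Markov model
#'
#' @param expected_segment_cM mean IBD-segment length in cM, governing the
#'   IBD-to-nonIBD transition rate (default 5).
#' @param expected_gap_cM mean nonIBD tract length in cM, governing the
#'   nonIBD-to-IBD rate (default 50).
#' @param genotyping_error per-call error rate absorbed by the emission model
#'   (default 0.01).
#' @param prior_ibd initial IBD probability; defaults to the stationary value
#'   segment / (segment + gap).
#' @param posterior_threshold minimum per-marker posterior inside a segment
#'   (strictly above; default 0.70).
#' @param min_segment_bp minimum physical segment length (default 350,000).
#' @param min_segment_snps minimum markers per segment (default 11, i.e.
#'   "more than 10").
#' @return validated list of class `ibdHmmParams`.
#' @export
ibdHmmParams <- function(expected_segment_cM = 5, expected_gap_cM = 50,
                         genotyping_error = 0.01, prior_ibd = NULL,
                         posterior_threshold = 0.70,
                         min_segment_bp = 350000L, min_segment_snps = 11L) {
  if (is.null(prior_ibd)) {
    prior_ibd <- expected_segment_cM / (expected_segment_cM + expected_gap_cM)
  }
  p <- list(expected_segment_cM = expected_segment_cM,
            expected_gap_cM = expected_gap_cM,
            genotyping_error = genotyping_error, prior_ibd = prior_ibd,
            posterior_threshold = posterior_threshold,
            min_segment_bp = as.numeric(min_segment_bp),
            min_segment_snps = as.integer(min_segment_snps))
  stopifnot(p$expected_segment_cM > 0, p$expected_gap_cM > 0,
            p$genotyping_error > 0, p$genotyping_error < 1,
            p$prior_ibd > 0, p$prior_ibd < 1,
            p$posterior_threshold > 0, p$posterior_threshold < 1,
            p$min_segment_bp > 0, p$min_segment_snps >= 1L)
  class(p) <- "ibdHmmParams"
  p
}

## emission likelihoods for one pair of (near-homozygous) genotype vectors.
## Calls are reduced to allele classes: dosage 0 -> ref allele, 2 -> counted
## allele, het/missing -> uninformative (likelihood 1 under both states).
.ibdEmissions <- function(x, y, p, e) {
  q <- p * (1 - e) + (1 - p) * e          # marginal prob of observing "2"
  cx <- ifelse(is.na(x) | x == 1L, NA_integer_, as.integer(x == 2L))
  cy <- ifelse(is.na(y) | y == 1L, NA_integer_, as.integer(y == 2L))
  e0 <- rep(1, length(x))
  e1 <- rep(1, length(x))
  inf <- !is.na(cx) & !is.na(cy)
  bb <- inf & cx == 1L & cy == 1L
  aa <- inf & cx == 0L & cy == 0L
  mm <- inf & cx != cy
  e0[bb] <- q[bb]^2
  e0[aa] <- (1 - q[aa])^2
  e0[mm] <- q[mm] * (1 - q[mm])
  e1[bb] <- p[bb] * (1 - e)^2 + (1 - p[bb]) * e^2
  e1[aa] <- (1 - p[aa]) * (1 - e)^2 + p[aa] * e^2
  e1[mm] <- e * (1 - e)
  list(e0 = e0, e1 = e1)
}

#' Per-marker IBD posteriors for one pair of individuals
#'
#' Runs the scaled forward-backward algorithm of a two-state (IBD / nonIBD)
#' hidden Markov chain along each chromosome. Transitions between
#' consecutive markers leave a state with probability 1 - exp(-d_cM / L),
#' where L is the state's expected tract length; emissions compare the two
#' (near-homozygous) genotype calls — under nonIBD the two allele classes
#' are independent draws at the panel allele frequency, under IBD they share
#' one allele lineage with the genotyping-error rate absorbing mismatches.
#' Heterozygous and missing calls are uninformative. Zero-frequency loci are
#' skipped with a warning.
#'
#' @param x,y dosage vectors of the two individuals (aligned to `map`).
#' @param map marker map with cM filled.
#' @param freqs per-locus frequency of the counted allele (estimated from
#'   the combined panel).
#' @param params an [ibdHmmParams()].
#' @return numeric vector of per-marker IBD posteriors (NA at skipped loci).
#' @export
pairIbdPosteriors <- function(x, y, map, freqs, params = ibdHmmParams()) {
  stopifnot(length(x) == nrow(map), length(y) == nrow(map),
            length(freqs) == nrow(map))
  bad <- !is.na(freqs) & (freqs <= 0 | freqs >= 1)
  if (any(bad)) warning(sum(bad), " zero-frequency loci skipped")
  post <- rep(NA_real_, nrow(map))
  e <- params$genotyping_error
  for (ch in unique(map$chrom)) {
    i <- which(map$chrom == ch & !bad & !is.na(freqs))
    if (length(i) == 0L) next
    em <- .ibdEmissions(x[i], y[i], freqs[i], e)
    if (length(i) == 1L) {
      num <- params$prior_ibd * em$e1
      post[i] <- num / (num + (1 - params$prior_ibd) * em$e0)
      next
    }
    d <- diff(map$cM[i])
    d[d < 0] <- 0
    stay1 <- exp(-d / params$expected_segment_cM)
    stay0 <- exp(-d / params$expected_gap_cM)
    post[i] <- ibd_forward_backward(em$e0, em$e1, stay0, stay1,
                                    params$prior_ibd)
  }
  post
}

#' Call filtered IBD segments from per-marker posteriors
#'
#' Maximal runs of consecutive markers (within chromosome) with posterior
#' strictly above the threshold become candidate segments; candidates
#' shorter than `min_segment_bp` (first to last marker) or with fewer than
#' `min_segment_snps` markers are discarded, which suppresses spurious
#' segments created by occasional genotyping errors.
#'
#' @param posteriors per-marker IBD posteriors (from [pairIbdPosteriors()]).
#' @param map aligned marker map.
#' @param params an [ibdHmmParams()].
#' @return data.frame of segments: `chrom`, `start_bp`, `end_bp`, `start_cM`,
#'   `end_cM`, `n_snps`, `mean_posterior`, `start_idx`, `end_idx` (marker
#'   indices into `map`).
#' @export
callSegments <- function(posteriors, map, params = ibdHmmParams()) {
  segs <- list()
  for (ch in unique(map$chrom)) {
    i <- which(map$chrom == ch)
    above <- !is.na(posteriors[i]) & posteriors[i] > params$posterior_threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- i[starts[k]:ends[k]]
      lenBp <- map$bp[idx[length(idx)]] - map$bp[idx[1]]
      if (length(idx) < params$min_segment_snps) next
      if (lenBp < params$min_segment_bp) next
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start_bp = map$bp[idx[1]],
        end_bp = map$bp[idx[length(idx)]],
        start_cM = map$cM[idx[1]], end_cM = map$cM[idx[length(idx)]],
        n_snps = length(idx),
        mean_posterior = mean(posteriors[idx]),
        start_idx = idx[1], end_idx = idx[length(idx)])
    }
  }
  if (!length(segs)) {
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), start_cM = numeric(),
                      end_cM = numeric(), n_snps = integer(),
                      mean_posterior = numeric(), start_idx = integer(),
                      end_idx = integer()))
  }
  do.call(rbind, segs)
}

#' IBD segments between every DH line and every progenitor
#'
#' Allele frequencies for the emission model are estimated once from the
#' whole panel; each line x progenitor pair is run through the HMM and
#' segment filter.
#'
#' @param panel a [GenotypePanel-class]
#' @param line_ids,progenitor_ids individual ids to pair (defaults: all
#'   non-progenitor lines vs the `progenitors` group).
#' @param params an [ibdHmmParams()].
#' @return data.frame of segments with `line_id` and `progenitor_id` columns
#'   prepended to the [callSegments()] columns.
#' @export
ibdScan <- function(panel, line_ids = NULL, progenitor_ids = NULL,
                    params = ibdHmmParams()) {
  calls <- genotypeCalls(panel)
  map <- markerMap(panel)
  groups <- panelGroups(panel)
  if (is.null(progenitor_ids)) {
    progenitor_ids <- rownames(calls)[groups == "progenitors"]
  }
  if (is.null(line_ids)) {
    line_ids <- setdiff(rownames(calls), progenitor_ids)
  }
  freqs <- colMeans(calls, na.rm = TRUE) / 2
  out <- list()
  for (ln in line_ids) {
    x <- calls[ln, ]
    for (pg in progenitor_ids) {
      post <- suppressWarnings(
        pairIbdPosteriors(x, calls[pg, ], map, freqs, params))
      segs <- callSegments(post, map, params)
      if (nrow(segs)) {
        out[[length(out) + 1L]] <-
          cbind(line_id = ln, progenitor_id = pg, segs)
      }
    }
  }
  if (!length(out)) {
    return(cbind(data.frame(line_id = character(), progenitor_id = character()),
                 callSegments(numeric(), map[0, ], params)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Founder genetic contributions from IBD segments
#'
#' For each DH line, every marker inside any of its IBD segments is credited
#' to the segment's progenitor; where segments from several progenitors
#' overlap a marker, the progenitor whose covering segment has the highest
#' mean posterior wins, and exact ties are split equally. Markers covered by
#' no segment are non-IBD. Group values are means over the group's lines of
#' (credited markers / total markers). A segment-length histogram with
#' configurable bins is included.
#'
#' @param segments segment table from [ibdScan()].
#' @param panel the [GenotypePanel-class] the segments refer to.
#' @param groups factor overriding the panel groups.
#' @param length_breaks_mb histogram bin edges in Mb
#'   (default c(0.35, 1.2, 2.4, 4.1, 8.1, Inf)).
#' @return list with `contribution` (progenitor x group percent matrix),
#'   `non_ibd` (named per-group percent), and `length_histogram`
#'   (data.frame of bin counts).
#' @export
ibdContribution <- function(segments, panel, groups = panelGroups(panel),
                            length_breaks_mb = c(0.35, 1.2, 2.4, 4.1, 8.1,
                                                 Inf)) {
  calls <- genotypeCalls(panel)
  nm <- ncol(calls)
  lineGroups <- setNames(as.character(groups), rownames(calls))
  progs <- sort(union(rownames(calls)[as.character(groups) == "progenitors"],
                      as.character(segments$progenitor_id)))
  dhGroups <- setdiff(levels(groups), "progenitors")
  lines <- rownames(calls)[as.character(groups) %in% dhGroups]

  credit <- matrix(0, nrow = length(progs), ncol = length(lines),
                   dimnames = list(progs, lines))
  segsByLine <- split(segments, segments$line_id)
  for (ln in intersect(lines, names(segsByLine))) {
    s <- segsByLine[[ln]]
    best <- rep(-Inf, nm)
    for (k in seq_len(nrow(s))) {
      idx <- s$start_idx[k]:s$end_idx[k]
      best[idx] <- pmax(best[idx], s$mean_posterior[k])
    }
    nbest <- rep(0L, nm)
    for (k in seq_len(nrow(s))) {
      idx <- s$start_idx[k]:s$end_idx[k]
      nbest[idx] <- nbest[idx] + (s$mean_posterior[k] == best[idx])
    }
    for (k in seq_len(nrow(s))) {
      idx <- s$start_idx[k]:s$end_idx[k]
      w <- (s$mean_posterior[k] == best[idx]) / nbest[idx]
      credit[as.character(s$progenitor_id[k]), ln] <-
        credit[as.character(s$progenitor_id[k]), ln] + sum(w)
    }
  }
  credit <- credit / nm * 100

  contrib <- sapply(dhGroups, function(g) {
    rowMeans(credit[, lineGroups[lines] == g, drop = FALSE])
  })
  contrib <- matrix(contrib, nrow = length(progs),
                    dimnames = list(progs, dhGroups))
  nonIbd <- 100 - colSums(contrib)

  lenMb <- (segments$end_bp - segments$start_bp) / 1e6
  hist <- as.data.frame(table(cut(lenMb, c(0, length_breaks_mb))),
                        stringsAsFactors = FALSE)
  names(hist) <- c("bin_mb", "count")

  list(contribution = contrib, non_ibd = nonIbd, length_histogram = hist)
}

#' Modal-dosage imputation of missing calls
#'
#' Replaces each missing call by the per-locus modal dosage (ties resolved
#' toward the smaller dosage). Non-missing calls are never changed. A simple
#' stand-in where complete genotypes are required.
#'
#' @param panel a [GenotypePanel-class]
#' @return a `GenotypePanel` with attribute `n_imputed`.
#' @export
modeImpute <- function(panel) {
  calls <- genotypeCalls(panel)
  nimp <- 0L
  for (j in which(colSums(is.na(calls)) > 0L)) {
    x <- calls[, j]
    tab <- tabulate(x[!is.na(x)] + 1L, nbins = 3L)
    mode <- which.max(tab) - 1L
    nimp <- nimp + sum(is.na(x))
    calls[is.na(x), j] <- mode
  }
  out <- initialize(panel, calls = calls)
  attr(out, "n_imputed") <- nimp
  out
}
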