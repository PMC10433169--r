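#' Read genotypes and a marker map from standard formats
#'
#' Supports VCF 4.2 (GT field, diploid), HapMap-style 11-column TSV, and a
#' plain dosage matrix TSV (rows = individuals, columns = markers, values
#' 0/1/2, "." missing). Only biallelic SNPs are kept; multi-allelic VCF
#' records are dropped with a reported count. Dosages are oriented to the
#' panel-wide minor allele; at a frequency tie the alphabetically first
#' allele is treated as minor (for the dosage-matrix format, where allele
#' identities are unknown, the written coding is kept at ties).
#'
#' @param path input file.
#' @param format one of "vcf", "hapmap", "matrix". Guessed from the file
#'   extension when missing.
#' @param map optional marker map data.frame (`marker`, `chrom`, `bp`, `cM`)
#'   or path to a map TSV; required for the matrix format, used to fill cM
#'   for VCF/HapMap input.
#' @return a [GenotypePanel-class]; the number of dropped multi-allelic
#'   records is attached as attribute `n_multiallelic_dropped`.
#' @seealso [writeGenotypes()], [readMarkerMap()]
#' @export
readGenotypes <- function(path, format = c("vcf", "hapmap", "matrix"),
                          map = NULL) {
  if (length(format) > 1L) {
    format <- switch(tolower(tools::file_ext(path)),
                     vcf = "vcf", hmp = "hapmap", hapmap = "hapmap", "matrix")
  }
  format <- match.arg(format)
  if (is.character(map)) map <- readMarkerMap(map)
  out <- switch(format,
                vcf = .readVcf(path),
                hapmap = .readHapmap(path),
                matrix = .readDosageMatrix(path, map))
  if (!is.null(map) && format != "matrix") {
    m <- match(out$map$marker, map$marker)
    if (!anyNA(m)) out$map$cM <- map$cM[m]
  }
  panel <- GenotypePanel(out$calls, out$map, groups = "panel")
  attr(panel, "n_multiallelic_dropped") <- out$dropped
  panel
}

.orientLetters <- function(dos, a1, a2) {
  ## dos counts a2; orient each column so the minor allele is counted,
  ## alphabetical tie-break
  n2 <- colSums(dos, na.rm = TRUE)
  ntot <- 2 * colSums(!is.na(dos))
  f2 <- ifelse(ntot > 0, n2 / ntot, 0)
  flip <- f2 > 0.5 | (f2 == 0.5 & a1 < a2)
  flip[is.na(flip)] <- FALSE
  dos[, flip] <- 2L - dos[, flip, drop = FALSE]
  dos
}

.readVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- grepl(",", alt) | nchar(ref) != 1L | (nchar(alt) != 1L & !is.na(alt))
  dropped <- sum(multi)
  gtRaw <- vcfR::extract.gt(v, element = "GT")
  keep <- which(!multi)
  gtRaw <- gtRaw[keep, , drop = FALSE]
  gt <- gsub("\\|", "/", gtRaw)
  bad <- !is.na(gt) & !gt %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("unsupported GT '%s' at record %d (ploidy != 2?)",
                 gt[bad][1], i[1]))
  }
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt == "0/0"] <- 0L
  dos[gt %in% c("0/1", "1/0")] <- 1L
  dos[gt == "1/1"] <- 2L
  dos <- t(dos)  # individuals x markers
  dos <- .orientLetters(dos, ref[keep], alt[keep])
  map <- data.frame(marker = fix[keep, "ID"],
                    chrom = fix[keep, "CHROM"],
                    bp = as.numeric(fix[keep, "POS"]),
                    cM = NA_real_)
  noid <- is.na(map$marker) | map$marker == "."
  map$marker[noid] <- paste0(map$chrom[noid], "_", map$bp[noid])
  colnames(dos) <- map$marker
  list(calls = dos, map = map, dropped = dropped)
}

.readHapmap <- function(path) {
  h <- read.table(path, header = TRUE, sep = "\t", comment.char = "",
                  check.names = FALSE, stringsAsFactors = FALSE)
  metaCols <- 11L
  gcols <- (metaCols + 1L):ncol(h)
  alleles <- strsplit(h[[2]], "/", fixed = TRUE)
  multi <- lengths(alleles) != 2L
  dropped <- sum(multi)
  h <- h[!multi, , drop = FALSE]
  alleles <- alleles[!multi]
  a1 <- vapply(alleles, `[`, "", 1L)
  a2 <- vapply(alleles, `[`, "", 2L)
  gt <- as.matrix(h[, gcols, drop = FALSE])
  nmk <- nrow(h)
  dos <- matrix(NA_integer_, length(gcols), nmk,
                dimnames = list(colnames(h)[gcols], h[[1]]))
  for (m in seq_len(nmk)) {
    g <- gt[m, ]
    c1 <- substr(g, 1L, 1L)
    c2 <- substr(g, 2L, 2L)
    d <- (c1 == a2[m]) + (c2 == a2[m])
    d[c1 == "N" | c2 == "N" | g == "NA" | is.na(g)] <- NA_integer_
    valid <- c1 %in% c(a1[m], a2[m], "N") & c2 %in% c(a1[m], a2[m], "N")
    d[!valid] <- NA_integer_
    dos[, m] <- d
  }
  dos <- .orientLetters(dos, a1, a2)
  map <- data.frame(marker = h[[1]], chrom = h[[3]], bp = as.numeric(h[[4]]),
                    cM = NA_real_)
  list(calls = dos, map = map, dropped = dropped)
}

.readDosageMatrix <- function(path, map) {
  m <- read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                  na.strings = ".", check.names = FALSE)
  calls <- as.matrix(m)
  if (is.null(map)) {
    map <- data.frame(marker = colnames(calls),
                      chrom = 1L, bp = seq_len(ncol(calls)), cM = NA_real_)
  } else {
    map <- map[match(colnames(calls), map$marker), , drop = FALSE]
  }
  freq <- colMeans(calls, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  calls[, flip] <- 2L - calls[, flip, drop = FALSE]
  list(calls = calls, map = map, dropped = 0L)
}

#' Write genotypes in a supported format
#'
#' The VCF writer emits the counted (minor) allele as ALT "A" against
#' reference allele "C" with unphased diploid GT; the HapMap writer uses the
#' same two allele letters; the matrix writer emits the dosage TSV with "."
#' for missing. A seed/provenance comment line is included in VCF headers.
#'
#' @param panel a [GenotypePanel-class]
#' @param path output file
#' @param format "vcf", "hapmap" or "matrix"
#' @param seed optional integer stamped into the VCF header
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(panel, path, format = c("vcf", "hapmap", "matrix"),
                           seed = NULL) {
  format <- match.arg(format)
  calls <- genotypeCalls(panel)
  map <- markerMap(panel)
  if (format == "matrix") {
    out <- as.data.frame(calls)
    out[is.na(out)] <- "."
    write.table(cbind(id = rownames(calls), out), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (format == "vcf") {
    hdr <- c("##fileformat=VCFv4.2",
             if (!is.null(seed)) sprintf("##simulation_seed=%d", seed),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(calls)), collapse = "\t"))
    gtcode <- c("0/0", "0/1", "1/1")
    body <- vapply(seq_len(ncol(calls)), function(m) {
      d <- calls[, m]
      gt <- ifelse(is.na(d), "./.", gtcode[d + 1L])
      paste(c(map$chrom[m], map$bp[m], map$marker[m], "C", "A", ".", "PASS",
              ".", "GT", gt), collapse = "\t")
    }, character(1))
    writeLines(c(hdr, body), path)
    return(invisible(path))
  }
  ## hapmap
  letters2 <- c("CC", "CA", "AA")
  gtmat <- matrix("NN", nrow = ncol(calls), ncol = nrow(calls))
  for (m in seq_len(ncol(calls))) {
    d <- calls[, m]
    gtmat[m, ] <- ifelse(is.na(d), "NN", letters2[d + 1L])
  }
  out <- data.frame(`rs#` = map$marker, alleles = "C/A", chrom = map$chrom,
                    pos = map$bp, strand = "+", `assembly#` = NA,
                    center = NA, protLSID = NA, assayLSID = NA,
                    panelLSID = NA, QCcode = NA, check.names = FALSE)
  out <- cbind(out, as.data.frame(gtmat, col.names = rownames(calls)))
  colnames(out)[12:ncol(out)] <- rownames(calls)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a 4-column marker map TSV (marker, chrom, bp, cM)
#' @param path file path
#' @return `readMarkerMap`: data.frame; `writeMarkerMap`: `path` invisibly.
#' @export
readMarkerMap <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  names(m)[1:4] <- c("marker", "chrom", "bp", "cM")
  m
}

#' @rdname readMarkerMap
#' @param map data.frame with columns marker, chrom, bp, cM
#' @export
writeMarkerMap <- function(map, path) {
  write.table(map[, c("marker", "chrom", "bp", "cM")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Marker-level quality-control filters
#'
#' Applies, in order: missing-rate filter (markers with missing fraction
#' above `max_missing` removed), monomorphic filter (only one allele observed
#' among non-missing calls), duplicate filter (identical call vector,
#' including the missing pattern, to an earlier marker), and collapse of
#' physical-position duplicates keeping the first. Filters are idempotent.
#'
#' @param panel a [GenotypePanel-class]
#' @param max_missing maximum tolerated missing fraction per marker
#'   (default 0.10).
#' @param drop_monomorphic,drop_duplicates,drop_position_duplicates logical
#'   switches for the individual filters.
#' @return list with `panel` (filtered) and `report` (named counts of removed
#'   markers per reason plus markers kept).
#' @export
filterMarkers <- function(panel, max_missing = 0.10, drop_monomorphic = TRUE,
                          drop_duplicates = TRUE,
                          drop_position_duplicates = TRUE) {
  calls <- genotypeCalls(panel)
  map <- markerMap(panel)
  nm <- ncol(calls)
  keep <- rep(TRUE, nm)
  report <- c(missing = 0L, monomorphic = 0L, duplicate = 0L,
              position_duplicate = 0L, kept = 0L)

  missRate <- colMeans(is.na(calls))
  drop <- missRate > max_missing
  report["missing"] <- sum(drop)
  keep[drop] <- FALSE

  if (drop_monomorphic) {
    cnt1 <- colSums(calls, na.rm = TRUE)          # copies of counted allele
    ntot <- 2 * colSums(!is.na(calls))
    mono <- keep & (cnt1 == 0L | cnt1 == ntot | ntot == 0L)
    report["monomorphic"] <- sum(mono)
    keep[mono] <- FALSE
  }
  if (drop_duplicates) {
    idx <- which(keep)
    if (length(idx) > 1L) {
      key <- vapply(idx, function(j) paste(calls[, j], collapse = ","),
                    character(1))
      dup <- duplicated(key)
      report["duplicate"] <- sum(dup)
      keep[idx[dup]] <- FALSE
    }
  }
  if (drop_position_duplicates) {
    idx <- which(keep)
    if (length(idx) > 1L) {
      dup <- duplicated(paste(map$chrom[idx], map$bp[idx]))
      report["position_duplicate"] <- sum(dup)
      keep[idx[dup]] <- FALSE
    }
  }
  if (!any(keep)) stop("all markers removed by filters")
  report["kept"] <- sum(keep)
  list(panel = panel[, which(keep)], report = report)
}

#' Screen lines for excess heterozygosity
#'
#' Inbred and DH lines are expected to be (near-)homozygous; lines whose
#' heterozygous-call rate among non-missing calls exceeds `max_het` are
#' flagged for exclusion. The default threshold of 8.8% reflects the level
#' at which a line is no longer credible as an inbred.
#'
#' @param panel a [GenotypePanel-class]
#' @param max_het maximum per-line heterozygosity rate (default 0.088).
#' @return list with `kept` and `flagged` id vectors and `het_rate` (named
#'   per-line rates).
#' @export
screenLines <- function(panel, max_het = 0.088) {
  calls <- genotypeCalls(panel)
  het <- rowSums(calls == 1L, na.rm = TRUE) / rowSums(!is.na(calls))
  flagged <- names(het)[het > max_het]
  list(kept = setdiff(rownames(calls), flagged), flagged = flagged,
       het_rate = het)
}

#' Per-chromosome and genome-wide panel summary
#'
#' Reports marker counts, mean heterozygous-call rate (%), covered physical
#' length (first to last marker), mean inter-marker spacing (covered length
#' over the marker gaps, in kb), and the physical-to-genetic ratio (kb per
#' cM) per chromosome and genome-wide.
#'
#' @param panel a [GenotypePanel-class]
#' @return data.frame with one row per chromosome plus a `genome` row.
#' @export
summarizePanel <- function(panel) {
  calls <- genotypeCalls(panel)
  map <- markerMap(panel)
  chroms <- unique(map$chrom)
  rows <- lapply(chroms, function(ch) {
    j <- which(map$chrom == ch)
    sub <- calls[, j, drop = FALSE]
    covered <- diff(range(map$bp[j]))
    cmspan <- diff(range(map$cM[j]))
    data.frame(chrom = as.character(ch), n_markers = length(j),
               het_pct = 100 * mean(sub == 1L, na.rm = TRUE),
               covered_bp = covered,
               spacing_kb = covered / 1000 / max(length(j) - 1L, 1L),
               kb_per_cM = if (!is.na(cmspan) && cmspan > 0)
                 covered / 1000 / cmspan else NA_real_)
  })
  tab <- do.call(rbind, rows)
  coveredAll <- sum(tab$covered_bp)
  cmAll <- sum(vapply(chroms, function(ch) {
    diff(range(map$cM[map$chrom == ch]))
  }, numeric(1)))
  genome <- data.frame(chrom = "genome", n_markers = ncol(calls),
                       het_pct = 100 * mean(calls == 1L, na.rm = TRUE),
                       covered_bp = coveredAll,
                       spacing_kb = coveredAll / 1000 /
                         max(ncol(calls) - 1L, 1L),
                       kb_per_cM = if (!is.na(cmAll) && cmAll > 0)
                         coveredAll / 1000 / cmAll else NA_real_)
  rbind(tab, genome)
}
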