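#' @import methods
#' @importFrom stats var sd cor rnorm runif rpois setNames coef residuals
#' @importFrom utils head tail write.table read.table adist
#' @useDynLib dhpanel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' GenotypePanel: dosage genotypes with a marker map and group labels
#'
#' The central data container of the package: an individuals-by-markers matrix
#' of biallelic SNP dosages (0, 1, 2 copies of the counted allele, `NA` for
#' missing), a marker map giving chromosome, physical (bp) and genetic (cM)
#' coordinates per marker, and one group label per individual (e.g.
#' progenitors, C0_DHL, C0/C17_DHL, C17_DHL).
#'
#' By convention dosages are oriented so the counted allele is the panel-wide
#' minor allele; ties are broken toward the allele observed first. Orientation
#' only affects reporting, not MAF- or variance-based statistics.
#'
#' @slot calls integer matrix, individuals x markers, values 0/1/2/NA.
#' @slot map data.frame with columns `marker`, `chrom`, `bp`, `cM`.
#' @slot groups factor of length `nrow(calls)`, one label per individual.
#'
#' @seealso [GenotypePanel()] for the user-facing constructor,
#'   [genotypeCalls()], [markerMap()], [panelGroups()] for accessors.
#' @export
setClass("GenotypePanel",
  representation(
    calls = "matrix",
    map = "data.frame",
    groups = "factor"
  )
)

setValidity("GenotypePanel", function(object) {
  msgs <- character()
  calls <- object@calls
  map <- object@map
  if (!is.numeric(calls)) {
    msgs <- c(msgs, "calls must be a numeric matrix")
  } else {
    bad <- calls[!is.na(calls)]
    if (length(bad) && !all(bad %in% c(0L, 1L, 2L))) {
      msgs <- c(msgs, "calls must be dosages in {0, 1, 2} or NA")
    }
  }
  need <- c("marker", "chrom", "bp", "cM")
  if (!all(need %in% names(map))) {
    msgs <- c(msgs, sprintf("map must have columns %s", paste(need, collapse = ", ")))
  } else {
    if (nrow(map) != ncol(calls)) {
      msgs <- c(msgs, "map rows must match number of marker columns")
    }
    if (!is.null(colnames(calls)) && !identical(as.character(map$marker), colnames(calls))) {
      msgs <- c(msgs, "map$marker must match colnames(calls)")
    }
    for (ch in unique(map$chrom)) {
      bp <- map$bp[map$chrom == ch]
      cm <- map$cM[map$chrom == ch]
      if (is.unsorted(bp, strictly = TRUE)) {
        msgs <- c(msgs, sprintf("bp positions not strictly increasing on chromosome %s", ch))
      }
      if (!anyNA(cm) && is.unsorted(cm)) {  # cM may be NA before interpolation
        msgs <- c(msgs, sprintf("cM positions decreasing on chromosome %s", ch))
      }
    }
  }
  if (length(object@groups) != nrow(calls)) {
    msgs <- c(msgs, "groups must have one label per individual")
  }
  if (anyNA(object@groups)) msgs <- c(msgs, "groups must not contain NA")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypePanel
#'
#' @param calls individuals x markers matrix of dosages (0/1/2/NA). Row names
#'   are individual ids, column names marker ids (generated when absent).
#' @param map data.frame with columns `marker`, `chrom`, `bp`, `cM` in marker
#'   (column) order.
#' @param groups character or factor of group labels, one per individual;
#'   a single value is recycled.
#' @return A [GenotypePanel-class] object.
#' @examples
#' calls <- matrix(c(0, 2, 1, 0, 2, 2), nrow = 2, byrow = TRUE)
#' map <- data.frame(marker = paste0("m", 1:3), chrom = 1,
#'                   bp = c(100, 200, 300), cM = c(0.1, 0.2, 0.3))
#' gp <- GenotypePanel(calls, map, groups = c("A", "B"))
#' gp
#' @export
GenotypePanel <- function(calls, map, groups = "panel") {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) rownames(calls) <- sprintf("ind%03d", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- as.character(map$marker)
  map <- as.data.frame(map)
  map$marker <- as.character(map$marker)
  if (length(groups) == 1L) groups <- rep(groups, nrow(calls))
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  new("GenotypePanel", calls = calls, map = map, groups = groups)
}

#' @describeIn GenotypePanel-class number of individuals and markers
#' @param x,object a `GenotypePanel`
#' @export
setMethod("dim", "GenotypePanel", function(x) dim(x@calls))

#' Accessors for GenotypePanel
#'
#' `genotypeCalls()` returns the dosage matrix, `markerMap()` the marker map,
#' `panelGroups()` the per-individual group factor, `individualIds()` and
#' `markerIds()` the id vectors.
#'
#' @param x a [GenotypePanel-class]
#' @return matrix, data.frame, factor or character vector as described.
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
genotypeCalls <- function(x) x@calls

#' @rdname panel-accessors
#' @export
markerMap <- function(x) x@map

#' @rdname panel-accessors
#' @export
panelGroups <- function(x) x@groups

#' @rdname panel-accessors
#' @export
individualIds <- function(x) rownames(x@calls)

#' @rdname panel-accessors
#' @export
markerIds <- function(x) colnames(x@calls)

#' Subset a GenotypePanel by individuals and/or markers
#'
#' @param x a `GenotypePanel`
#' @param i individual index (integer, logical or names)
#' @param j marker index
#' @param ... ignored
#' @param drop ignored; the result is always a `GenotypePanel`
#' @export
setMethod("[", "GenotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@calls))
  if (missing(j)) j <- seq_len(ncol(x@calls))
  GenotypePanel(x@calls[i, j, drop = FALSE], x@map[j, , drop = FALSE],
                groups = x@groups[i])
})

setMethod("show", "GenotypePanel", function(object) {
  d <- dim(object@calls)
  cat(sprintf("GenotypePanel: %d individuals x %d markers\n", d[1], d[2]))
  tab <- table(object@groups)
  cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("chromosomes: %s\n",
              paste(unique(object@map$chrom), collapse = ", ")))
  miss <- mean(is.na(object@calls))
  het <- mean(object@calls == 1L, na.rm = TRUE)
  cat(sprintf("missing: %.2f%%  heterozygous calls: %.2f%%\n",
              100 * miss, 100 * het))
  invisible(NULL)
})

#' Orient dosages to the panel-wide minor allele
#'
#' Flips marker columns whose counted-allele frequency exceeds 0.5 so that
#' every column counts the panel-wide minor allele. Frequency ties (exactly
#' 0.5) keep the current orientation.
#'
#' @param x a [GenotypePanel-class]
#' @return a `GenotypePanel` with re-oriented dosages.
#' @export
orientMinor <- function(x) {
  calls <- x@calls
  freq <- colMeans(calls, na.rm = TRUE) / 2
  flip <- which(!is.na(freq) & freq > 0.5)
  if (length(flip)) calls[, flip] <- 2L - calls[, flip]
  initialize(x, calls = calls)
}
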