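.pipelineDefaults <- function() {
  list(
    seed = 1L,
    out_dir = "dhpanel_run",
    stages = c("simulate", "qc", "diversity", "fst", "structure", "ld",
               "ibd"),
    genotypes = NULL,          # input file (disables the simulate stage)
    genotypes_format = "vcf",
    map = NULL,                # map TSV path for file input
    groups_file = NULL,        # two-column TSV: id, group
    scenario = list(),         # simConfig() overrides
    max_missing = 0.10,
    max_het = 0.088,
    drop_duplicates = TRUE,
    ld_threshold = 0.1,
    ld_max_pairs = 20000L,
    kinship_breaks = c(0.4, 0.5),
    kinship_zero_tol = 0.005,
    max_pcs = 10L,
    ibd = list(),              # ibdHmmParams() overrides
    log_level = "info"
  )
}

#' Validate a pipeline run configuration
#'
#' Accepts a named list or the path of a YAML / flat `key=value` file, checks
#' every key against the documented defaults (unknown keys are errors naming
#' the nearest valid key), range-checks numeric parameters, and fills
#' defaults. An empty file yields the all-defaults configuration.
#'
#' @param config named list, YAML file path, or NULL for defaults.
#' @return validated configuration list of class `runConfig`.
#' @export
validateRunConfig <- function(config = NULL) {
  defaults <- .pipelineDefaults()
  if (is.character(config)) {
    txt <- readLines(config, warn = FALSE)
    config <- if (any(grepl("=", txt) & !grepl(":", txt))) {
      kv <- strsplit(txt[nzchar(trimws(txt))], "=", fixed = TRUE)
      vals <- lapply(kv, function(x) utils::type.convert(trimws(x[2]),
                                                         as.is = TRUE))
      setNames(vals, vapply(kv, function(x) trimws(x[1]), ""))
    } else {
      yaml::yaml.load(paste(txt, collapse = "\n"))
    }
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    nearest <- vapply(unknown, function(k) {
      names(defaults)[which.min(adist(k, names(defaults)))]
    }, "")
    stop("unknown config key(s): ",
         paste(sprintf("'%s' (did you mean '%s'?)", unknown, nearest),
               collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  if (cfg$max_missing < 0 || cfg$max_missing > 1) {
    stop("max_missing must be in [0, 1]")
  }
  if (cfg$max_het < 0 || cfg$max_het > 1) stop("max_het must be in [0, 1]")
  if (cfg$ld_threshold <= 0 || cfg$ld_threshold >= 1) {
    stop("ld_threshold must be in (0, 1)")
  }
  badStages <- setdiff(cfg$stages, defaults$stages)
  if (length(badStages)) {
    stop("unknown stage(s): ", paste(badStages, collapse = ", "))
  }
  if (!is.null(cfg[["genotypes"]]) && !file.exists(cfg[["genotypes"]])) {
    stop("genotype file not found: ", cfg[["genotypes"]])
  }
  ## stage dependencies: everything downstream needs genotypes
  if (is.null(cfg[["genotypes"]]) && !"simulate" %in% cfg$stages &&
      length(setdiff(cfg$stages, "simulate"))) {
    stop("no genotype input: enable the simulate stage or set 'genotypes'")
  }
  cfg$scenario <- do.call(simConfig, cfg$scenario)
  cfg$ibd <- do.call(ibdHmmParams, cfg$ibd)
  class(cfg) <- "runConfig"
  cfg
}

.writeTsv <- function(x, path) {
  num <- vapply(x, is.numeric, TRUE)
  x[num] <- lapply(x[num], function(v) signif(v, 6))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.writeMatrixTsv <- function(m, path) {
  df <- data.frame(id = rownames(m), signif(as.data.frame(m), 6),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full characterization pipeline
#'
#' Executes the enabled stages in dependency order — simulate (or load
#' genotype files), marker/line QC, per-group diversity, pairwise
#' F_ST + distances + UPGMA trees, kinship + PCA, LD decay, IBD
#' contributions — writing every result as a TSV/Newick file under the
#' output directory plus a JSON manifest with the package version, seeds,
#' parameters and per-stage status. Identical configuration and seed give
#' byte-identical outputs. A stage failure halts the run; partial outputs
#' are kept with a `FAILED` marker file naming the stage.
#'
#' @param config a [validateRunConfig()] result, raw list, or YAML path.
#' @return the manifest list, invisibly; written as `manifest.json`.
#' @export
runPipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "runConfig")) config else validateRunConfig(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  stageSeeds <- setNames(sample.int(.Machine$integer.max, 7),
                         .pipelineDefaults()$stages)
  manifest <- list(package = "dhpanel",
                   version = as.character(utils::packageVersion("dhpanel")),
                   seed = cfg$seed, stage_seeds = as.list(stageSeeds),
                   stages = list(), files = character())
  logmsg <- function(...) {
    if (cfg$log_level != "quiet") message(sprintf(...))
  }
  addFile <- function(p) manifest$files <<- c(manifest$files, basename(p))
  stageStatus <- function(name, status, n = NULL) {
    manifest$stages[[name]] <<- list(status = status, rows = n)
  }
  out <- function(f) file.path(cfg$out_dir, f)

  runStage <- function(name, fun) {
    if (!name %in% cfg$stages) {
      stageStatus(name, "skipped")
      return(invisible(NULL))
    }
    set.seed(stageSeeds[[name]])
    logmsg("[%s] running", name)
    ok <- tryCatch({
      fun()
      TRUE
    }, error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 out("FAILED"))
      stageStatus(name, paste("failed:", conditionMessage(e)))
      FALSE
    })
    if (!ok) {
      jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                           pretty = TRUE)
      stop("stage '", name, "' failed; see ", out("FAILED"))
    }
    invisible(NULL)
  }

  env <- new.env()

  runStage("simulate", function() {
    if (!is.null(cfg[["genotypes"]])) {
      env$panel <- readGenotypes(cfg[["genotypes"]], cfg$genotypes_format,
                                 map = cfg[["map"]])
      if (!is.null(cfg[["groups_file"]])) {
        g <- read.table(cfg[["groups_file"]], header = TRUE, sep = "\t")
        lab <- setNames(as.character(g[[2]]), g[[1]])[individualIds(env$panel)]
        env$panel@groups <- factor(lab, levels = unique(lab))
      }
      stageStatus("simulate", "ok (loaded from file)", nrow(env$panel@calls))
      return()
    }
    sim <- buildPanel(cfg$scenario)
    env$panel <- sim$panel
    env$truth <- sim$truth
    addFile(writeGenotypes(sim$panel, out("genotypes.vcf"), "vcf",
                           seed = cfg$seed))
    addFile(writeMarkerMap(markerMap(sim$panel), out("map.tsv")))
    addFile(.writeMatrixTsv(sim$truth$true_contribution,
                            out("true_contribution.tsv")))
    stageStatus("simulate", "ok", nrow(genotypeCalls(sim$panel)))
  })

  runStage("qc", function() {
    fm <- filterMarkers(env$panel, max_missing = cfg$max_missing,
                        drop_duplicates = cfg$drop_duplicates)
    sl <- screenLines(fm$panel, max_het = cfg$max_het)
    keep <- match(sl$kept, individualIds(fm$panel))
    env$panel <- fm$panel[keep, ]
    qc <- c(as.list(fm$report), list(lines_flagged = sl$flagged))
    jsonlite::write_json(qc, out("qc_report.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    addFile(out("qc_report.json"))
    addFile(.writeTsv(summarizePanel(env$panel), out("panel_summary.tsv")))
    stageStatus("qc", "ok", ncol(genotypeCalls(env$panel)))
  })

  runStage("diversity", function() {
    div <- groupDiversity(env$panel)
    addFile(.writeTsv(div, out("group_diversity.tsv")))
    stageStatus("diversity", "ok", nrow(div))
  })

  runStage("fst", function() {
    d <- euclideanDistance(env$panel)
    gm <- groupMeanDistance(d, panelGroups(env$panel))
    fstM <- pairwiseFstMatrix(env$panel)
    ## Table-3 analogue: distances upper triangle, F_ST lower triangle
    tab3 <- gm
    tab3[lower.tri(tab3)] <- fstM[lower.tri(fstM)]
    addFile(.writeMatrixTsv(tab3, out("distance_fst_matrix.tsv")))
    phy <- upgma(d)
    ape::write.tree(phy, out("upgma_panel.nwk"))
    addFile(out("upgma_panel.nwk"))
    grp <- panelGroups(env$panel)
    pairs <- utils::combn(levels(grp), 2, simplify = FALSE)
    scan <- do.call(rbind, lapply(pairs, function(pp) {
      f <- weirCockerhamFst(env$panel, pp)
      s <- fstScanTable(f, markerMap(env$panel))
      cbind(pair = paste(pp, collapse = "_vs_"),
            s[, c("marker", "chrom", "bp", "theta", "outlier")])
    }))
    addFile(.writeTsv(scan, out("fst_scan.tsv")))
    stageStatus("fst", "ok", nrow(scan))
  })

  runStage("structure", function() {
    K <- centeredIbsKinship(env$panel)
    addFile(.writeMatrixTsv(K, out("kinship.tsv")))
    kd <- kinshipDistribution(K, breaks = cfg$kinship_breaks,
                              zero_tol = cfg$kinship_zero_tol)
    addFile(.writeTsv(data.frame(bin = names(kd), fraction = kd),
                      out("kinship_distribution.tsv")))
    pca <- pcaPanel(env$panel, max_pcs = cfg$max_pcs)
    sc <- data.frame(id = rownames(pca$scores),
                     group = as.character(pca$groups),
                     pca$scores[, 1:min(5, ncol(pca$scores))])
    addFile(.writeTsv(sc, out("pca_scores.tsv")))
    addFile(.writeTsv(data.frame(pc = seq_along(pca$percent_var),
                                 eigenvalue = pca$eigenvalues,
                                 percent_var = pca$percent_var),
                      out("pca_eigenvalues.tsv")))
    addFile(.writeTsv(pca$bic, out("pca_bic.tsv")))
    stageStatus("structure", "ok", nrow(sc))
  })

  runStage("ld", function() {
    ld <- ldDecayByGroup(env$panel, threshold = cfg$ld_threshold,
                         max_pairs = cfg$ld_max_pairs)
    addFile(.writeTsv(ld, out("ld_decay.tsv")))
    stageStatus("ld", "ok", nrow(ld))
  })

  runStage("ibd", function() {
    segs <- ibdScan(env$panel, params = cfg$ibd)
    if (nrow(segs)) {
      addFile(.writeTsv(segs[, c("chrom", "start_bp", "end_bp", "line_id",
                                 "progenitor_id", "n_snps",
                                 "mean_posterior")],
                        out("ibd_segments.tsv")))
      bed <- data.frame(chrom = segs$chrom, start = segs$start_bp - 1L,
                        end = segs$end_bp,
                        name = paste(segs$line_id, segs$progenitor_id,
                                     sep = "|"))
      write.table(bed, out("ibd_segments.bed"), sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
      addFile(out("ibd_segments.bed"))
      contrib <- ibdContribution(segs, env$panel)
      addFile(.writeMatrixTsv(contrib$contribution, out("contribution.tsv")))
      addFile(.writeTsv(data.frame(group = names(contrib$non_ibd),
                                   non_ibd_pct = contrib$non_ibd),
                        out("non_ibd.tsv")))
      addFile(.writeTsv(contrib$length_histogram,
                        out("segment_length_histogram.tsv")))
    }
    stageStatus("ibd", "ok", nrow(segs))
  })

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
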