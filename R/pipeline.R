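.stopUsage <- function(...) {
  stop(structure(class = c("m6Ashift_usage_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

.stopMissingInput <- function(...) {
  stop(structure(class = c("m6Ashift_missing_input", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Assemble a pipeline run configuration
#'
#' A flat key-value configuration: input paths plus the analysis
#' parameters, with the peak-filter and binning defaults used throughout
#' the package. All randomness in a run flows from `seed` via fixed
#' per-stage offsets.
#'
#' @param annotation,m6aPeaks,histonePeaks,coverage,expression Input file
#'   paths (subsets suffice for individual subcommands).
#' @param outDir Output directory.
#' @param binBp,windowBp Profile resolution and TSS window (10 / 1000).
#' @param maxFdr,minFe Peak-filter thresholds (0.01 / 1.5).
#' @param searchWindowBp Summit search window (default `windowBp`).
#' @param maxDistanceBp Per-gene summit-distance cap (2000).
#' @param reps Random-control draws (100).
#' @param seed Top-level seed (1).
#' @param simulate A [simConfig()] for the `simulate` stage (optional).
#' @return A list of class `"RunConfig"`.
#' @export
runConfig <- function(annotation = NULL, m6aPeaks = NULL,
                      histonePeaks = NULL, coverage = NULL,
                      expression = NULL, outDir = "m6Ashift_out",
                      binBp = 10, windowBp = 1000, maxFdr = 0.01,
                      minFe = 1.5, searchWindowBp = windowBp,
                      maxDistanceBp = 2000, reps = 100, seed = 1,
                      simulate = NULL) {
  structure(as.list(environment()), class = "RunConfig")
}

#' Read a flat key-value (YAML) run configuration
#'
#' Keys mirror the [runConfig()] arguments; `simulate.*` keys (dotted)
#' populate the simulation config. Unknown keys are an error so typos do
#' not silently fall back to defaults.
#'
#' @param path YAML file of flat `key: value` pairs.
#' @return A `"RunConfig"`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .stopMissingInput("config file not found: ", path)
  kv <- yaml::read_yaml(path)
  simKeys <- grepl("^simulate\\.", names(kv))
  sim <- NULL
  if (any(simKeys)) {
    simArgs <- kv[simKeys]
    names(simArgs) <- sub("^simulate\\.", "", names(simArgs))
    bad <- setdiff(names(simArgs), names(formals(simConfig)))
    if (length(bad)) .stopUsage("unknown simulate config key(s): ",
                                paste(bad, collapse = ", "))
    sim <- do.call(simConfig, simArgs)
  }
  main <- kv[!simKeys]
  bad <- setdiff(names(main), names(formals(runConfig)))
  if (length(bad)) .stopUsage("unknown config key(s): ",
                              paste(bad, collapse = ", "))
  do.call(runConfig, c(main, list(simulate = sim)))
}

.requireInputs <- function(config, fields) {
  for (f in fields) {
    p <- config[[f]]
    if (is.null(p)) .stopMissingInput("config is missing required input: ", f)
    if (!file.exists(p)) .stopMissingInput("input file not found: ", p)
  }
}

.loadInputs <- function(config, what) {
  inp <- list()
  if ("annotation" %in% what) {
    .requireInputs(config, "annotation")
    inp$catalog <- loadAnnotation(config$annotation)
  }
  if ("m6aPeaks" %in% what) {
    .requireInputs(config, "m6aPeaks")
    inp$m6a <- filterPeaks(readPeaks(config$m6aPeaks, "m6a"),
                           config$maxFdr, config$minFe)
  }
  if ("histonePeaks" %in% what) {
    .requireInputs(config, "histonePeaks")
    inp$histone <- filterPeaks(readPeaks(config$histonePeaks, "histone"),
                               config$maxFdr, config$minFe)
  }
  if ("coverage" %in% what) {
    .requireInputs(config, "coverage")
    inp$coverage <- readCoverage(config$coverage)
  }
  if ("expression" %in% what) {
    .requireInputs(config, "expression")
    inp$expression <- readExpression(config$expression)
  }
  inp
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  path
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages behind subcommands:
#' \describe{
#'   \item{simulate}{write a synthetic dataset (uses `config$simulate`)}
#'   \item{classify}{filter m6A peaks, build the gene groups, and (when
#'     histone peaks are given) compute marked-gene overlap statistics
#'     with a random-gene control}
#'   \item{metagene}{TSS-anchored and body-scaled profiles per group}
#'   \item{shift}{group summit positions and their shift (5'UTR-only vs
#'     3'UTR-only genes)}
#'   \item{correlate}{enrichment-expression and enrichment-shift
#'     correlations plus pairwise group expression tests}
#'   \item{all}{everything above in order}
#' }
#' Outputs land under `config$outDir/<stage>/`; a run manifest JSON
#' records parameters, input checksums and the package version. Outputs
#' are deterministic for a fixed config and seed (no timestamps).
#'
#' @param subcommand One of simulate, classify, metagene, shift,
#'   correlate, all.
#' @param config A [runConfig()] or path read by [readRunConfig()].
#' @return Invisibly, a list with `status` (0 on success) and the
#'   machine-readable `report` written per stage.
#' @export
runPipeline <- function(subcommand, config) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  known <- c("simulate", "classify", "metagene", "shift", "correlate", "all")
  if (length(subcommand) != 1L || !subcommand %in% known)
    .stopUsage("unknown subcommand '", paste(subcommand, collapse = " "),
               "'; usage: runPipeline(<",
               paste(known, collapse = "|"), ">, config)")
  stages <- if (subcommand == "all")
    c("simulate"[!is.null(config$simulate)], "classify", "metagene",
      "shift", "correlate")
  else subcommand

  outDir <- config$outDir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  report <- list(parameters = config[setdiff(names(config),
                                             c("simulate"))],
                 package_version = as.character(utils::packageVersion("m6Ashift")),
                 stages = list())

  for (stage in stages) {
    message("[", stage, "] starting")
    sdir <- file.path(outDir, stage)
    if (!dir.exists(sdir)) dir.create(sdir)
    report$stages[[stage]] <- switch(stage,
      simulate = {
        if (is.null(config$simulate))
          .stopMissingInput("simulate stage requires config$simulate")
        sim <- simulateDataset(config$simulate, dir = sdir)
        # downstream stages of an `all` run consume the emitted files
        for (f in c("annotation", "m6aPeaks", "histonePeaks", "coverage",
                    "expression")) {
          key <- c(annotation = "annotation", m6aPeaks = "m6a",
                   histonePeaks = "h3k4me3", coverage = "coverage",
                   expression = "expression")[[f]]
          config[[f]] <- unname(sim$files[key])
        }
        list(files = as.list(sim$files),
             planted_shift_bp = sim$manifest$planted_shift_bp)
      },
      classify = {
        inp <- .loadInputs(config, c("annotation", "m6aPeaks"))
        gt <- buildGroups(inp$m6a, inp$catalog)
        res <- list(group_sizes = as.list(groupSizes(gt)),
                    n_universe = length(geneIds(gt)),
                    groups_tsv = writeGroupTable(gt, file.path(sdir,
                                                               "groups.tsv")))
        if (!is.null(config$histonePeaks)) {
          inp2 <- .loadInputs(config, "histonePeaks")
          marked <- markedGenes(inp$catalog, inp2$histone)
          ov <- overlapStats(marked, groupGenes(gt, "G_m6A"))
          ctl <- randomControl(geneIds(gt), length(marked),
                               groupGenes(gt, "G_m6A"),
                               seed = config$seed + 101L,
                               reps = config$reps)
          res$overlap <- unclass(ov)
          res$random_control <- ctl[c("mean_pct_A_with_B", "sd_pct_A_with_B",
                                      "mean_pct_of_B_covered",
                                      "sd_pct_of_B_covered", "reps")]
        }
        .writeJson(res[setdiff(names(res), "groups_tsv")],
                   file.path(sdir, "classify.json"))
        res
      },
      metagene = {
        inp <- .loadInputs(config, c("annotation", "m6aPeaks", "coverage"))
        gt <- buildGroups(inp$m6a, inp$catalog)
        res <- list()
        for (lab in c("G_5only", "G_3only", "G_m6A")) {
          genes <- groupGenes(gt, lab)
          if (!length(genes)) next
          pt <- tssProfile(inp$coverage, genes, inp$catalog,
                           config$windowBp, config$binBp)
          writeProfile(pt, file.path(sdir, paste0("tss_", lab, ".tsv")))
          pb <- withCallingHandlers(
            bodyProfile(inp$coverage, genes, inp$catalog),
            warning = function(w) {
              message("[metagene] WARN: ", conditionMessage(w))
              invokeRestart("muffleWarning")
            })
          writeProfile(pb, file.path(sdir, paste0("body_", lab, ".tsv")))
          res[[lab]] <- list(n_genes = length(genes))
        }
        res
      },
      shift = {
        inp <- .loadInputs(config, c("annotation", "m6aPeaks", "coverage"))
        gt <- buildGroups(inp$m6a, inp$catalog)
        gA <- groupGenes(gt, "G_5only"); gB <- groupGenes(gt, "G_3only")
        if (!length(gA) || !length(gB))
          stop("shift stage: empty m6A_5-only or m6A_3-only group")
        pA <- tssProfile(inp$coverage, gA, inp$catalog, config$windowBp,
                         config$binBp)
        pB <- tssProfile(inp$coverage, gB, inp$catalog, config$windowBp,
                         config$binBp)
        sr <- groupShift(pA, pB, config$searchWindowBp,
                         c("G_5only", "G_3only"))
        writeShiftResult(sr, file.path(sdir, "shift.json"))
        list(summit_bp_A = sr@summitA, summit_bp_B = sr@summitB,
             shift_bp = sr@shift)
      },
      correlate = {
        inp <- .loadInputs(config, c("annotation", "m6aPeaks",
                                     "histonePeaks", "expression"))
        gt <- buildGroups(inp$m6a, inp$catalog)
        ce <- enrichmentExpressionCorr(gt, inp$expression)
        scatter <- enrichmentExpressionData(gt, inp$expression)
        utils::write.table(scatter,
                           file.path(sdir, "fe_expression_scatter.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        dist <- geneSummitDistance(inp$catalog, groupGenes(gt, "G_5only"),
                                   inp$histone, config$maxDistanceBp,
                                   groups = gt)
        utils::write.table(dist, file.path(sdir, "summit_distances.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        cs <- enrichmentShiftCorr(dist)
        cmp <- compareGroupExpression(gt, inp$expression)
        utils::write.table(cmp, file.path(sdir, "group_expression_tests.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        res <- list(fe_expression = unclass(ce), fe_shift = unclass(cs))
        .writeJson(res, file.path(sdir, "correlate.json"))
        res
      })
    message("[", stage, "] done")
  }

  inputs <- config[c("annotation", "m6aPeaks", "histonePeaks", "coverage",
                     "expression")]
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  report$input_md5 <- lapply(inputs, function(p)
    unname(tools::md5sum(p)))
  .writeJson(report, file.path(outDir, "run_manifest.json"))
  invisible(list(status = 0L, report = report))
}
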