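## Configuration-driven pipeline driver: simulate -> characterize ->
## decompose -> fit -> report, reproducible from (config, seed).

.log <- function(level, current, ...) {
  levels <- c(quiet = 0, info = 1, debug = 2)
  if (levels[[current]] >= levels[[level]])
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Read a pipeline configuration (YAML or JSON)
#'
#' One structured text file is the single source of truth for a pipeline
#' run; both YAML and JSON syntax are accepted (JSON is a YAML subset, so a
#' single reader suffices).
#'
#' @param path configuration file.
#' @return configuration as a named list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Run the characterization pipeline
#'
#' Executes the requested stages in their natural order:
#' \code{simulate} (synthetic inputs with ground truth),
#' \code{hya-scaling} (correlation peak, scaling, slope and Guinier
#' descriptors of the polymer solutions), \code{decompose} (bound/unbound
#' split of the mixtures), \code{fit-np} (core-shell fit of the decomposed
#' profile), \code{waxs} (crystallinity and indexing), \code{dls}
#' (autocorrelation inversion) and \code{aero} (impactor aerodynamics).
#' Every random draw is derived from \code{config$seed}, so a run is fully
#' reproducible from (config, seed). A stage failure halts the pipeline with
#' a diagnostic naming the stage.
#'
#' @param config a configuration list or the path of a YAML/JSON file.
#'   Recognized top-level fields: \code{seed}, \code{outputDir},
#'   \code{stages} (character vector), \code{logLevel} and one optional list
#'   per stage with its parameters.
#' @return invisibly, a list with \code{status} (0 on success), the
#'   \code{results} and the report file paths.
#' @examples
#' \donttest{
#' res <- runPipeline(list(seed = 7, outputDir = tempfile(),
#'                         stages = c("simulate", "decompose")))
#' res$status
#' }
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(is.list(config))
  seed <- config$seed %||% 1
  outDir <- config$outputDir %||% file.path(tempdir(), "nanoscatter-run")
  logLevel <- config$logLevel %||% "info"
  stages <- config$stages %||% character(0)
  known <- c("simulate", "hya-scaling", "decompose", "fit-np", "waxs",
             "dls", "aero")
  if (!length(stages)) {
    warning("no stages requested: nothing to do")
    return(invisible(list(status = 0, results = list(), files = character(0))))
  }
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- known[known %in% stages]

  data <- list()
  results <- list()
  runStage <- function(name, expr) {
    .log("info", logLevel, "stage ", name, " (seed ", seed, ")")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  for (stage in stages) {
    if (stage == "simulate") {
      p <- config$simulate %||% list()
      data <- runStage("simulate", {
        concs <- p$concentrations %||% c(1.4, 2.8, 5.6, 11.2)
        noiseLevel <- p$noiseLevel %||% 0.01
        nm <- function(k) NoiseModel(level = noiseLevel,
                                     seed = .childSeed(seed, k))
        water <- makeHyaWaterSeries(concs, noise = nm(1))
        pb <- makeHyaPbSeries(concs, noise = nm(2))
        np <- CoreShellParams(
          coreRadius = p$coreRadius %||% 1000,
          shellThickness = p$shellThickness %||% 15,
          sldCore = p$sldCore %||% 11.8, sldShell = p$sldShell %||% 16,
          sldSolvent = p$sldSolvent %||% 9.47,
          polydispersity = p$polydispersity %||% 0.1)
        mixture <- makeNpMixture(np, totalConc = p$totalConc %||% 20,
                                 boundFraction = p$boundFraction %||% 0.25,
                                 noise = nm(3))
        waxs <- makeWaxsPattern(concentration = 1, noise = nm(4))
        dls <- makeDlsTrace(p$dlsDiameter %||% 300,
                            viscosity = p$dlsViscosity %||% 2.5,
                            noise = nm(5))
        ngi <- if (!is.null(p$cutoffs))
          makeNgiTable(p$totalDose %||% 1000,
                       deviceFraction = p$deviceFraction %||% 0.75,
                       mmad = p$mmad %||% 3, gsd = p$gsd %||% 1.8,
                       cutoffs = p$cutoffs, noise = nm(6))
        else NULL
        list(water = water, pb = pb, np = np, mixture = mixture,
             waxs = waxs, dls = dls, ngi = ngi)
      })
      results$simulate <- list(
        groundTruth = list(water = data$water$groundTruth,
                           mixture = data$mixture$groundTruth,
                           dls = data$dls$groundTruth,
                           ngi = if (!is.null(data$ngi))
                             data$ngi$groundTruth))
    } else if (stage == "hya-scaling") {
      results$hya_scaling <- runStage("hya-scaling", {
        if (is.null(data$water)) stop("no polymer curves: run simulate first")
        summary <- polymerSolutionSummary(c(data$water$curves,
                                            data$pb$curves))
        peaks <- summary[!is.na(summary$qPeak), ]
        scaling <- if (nrow(peaks) >= 2)
          fitScaling(peaks$concentration, peaks$qPeak) else NULL
        list(summary = summary, peakScaling = scaling)
      })
      results$hya_summary_table <- results$hya_scaling$summary
    } else if (stage == "decompose") {
      results$decompose <- runStage("decompose", {
        if (is.null(data$mixture)) stop("no mixture curve: run simulate first")
        p <- config$decompose %||% list()
        mix <- data$mixture
        nominal <- mix$groundTruth$params$hyaMassFraction *
          mix$groundTruth$params$totalConc
        freeFraction(mix$curve, data$water$curves,
                     nominalHyaConc = nominal,
                     method = p$method %||% "peak_position")
      })
    } else if (stage == "fit-np") {
      results$fit_np <- runStage("fit-np", {
        if (is.null(results$decompose))
          stop("no decomposed profile: run decompose first")
        p <- config$fitNp %||% list()
        prof <- results$decompose@npProfile
        keep <- prof@intensity > 0
        prof <- ScatterCurve(prof@q[keep], prof@intensity[keep],
                             meta = prof@meta)
        init <- data$np
        init@scale <- data$mixture$groundTruth$params$np$scale
        fitCoreShell(prof, init = init,
                     multiStart = p$multiStart %||% 3,
                     maxIter = p$maxIter %||% 50)
      })
    } else if (stage == "waxs") {
      results$waxs <- runStage("waxs", {
        if (is.null(data$waxs)) stop("no WAXS pattern: run simulate first")
        analyzeWaxs(data$waxs$curve)
      })
    } else if (stage == "dls") {
      results$dls <- runStage("dls", {
        if (is.null(data$dls)) stop("no DLS trace: run simulate first")
        p <- config$dls %||% list()
        dlsAnalyze(data$dls$trace, method = p$method %||% "cumulant")
      })
    } else if (stage == "aero") {
      results$aero <- runStage("aero", {
        if (is.null(data$ngi))
          stop("no deposition table: run simulate with cutoffs first")
        aerodynamicParams(data$ngi$table)
      })
    }
  }

  files <- writeReport(results, outDir, config = config, seed = seed)
  .log("info", logLevel, "report written to ", outDir)
  invisible(list(status = 0, results = results, files = files))
}
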