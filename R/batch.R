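## Batch processing: one configuration applied to many runs, with per-run
## failure isolation and a combined summary.

#' Build and validate a run configuration
#'
#' Collects every tunable of the pipeline into one object, serializable to
#' YAML with [writeRunConfig()] and reloadable with [readRunConfig()].
#'
#' @param inputs character vector of mzML/mzXML paths.
#' @param outDir output directory (created if needed).
#' @param ms1Library path to an MS1 library CSV, or an `ms1_library`
#'   data.frame; NULL disables MS1 annotation.
#' @param msmsLibrary path to an MS/MS library CSV, or an `msms_library`;
#'   NULL disables AIF annotation.
#' @param format input format hint, see [readMsRun()].
#' @param polarity optional polarity filter applied before channel
#'   splitting.
#' @param energyCycle optional collision-energy cycle fallback, see
#'   [readMsRun()].
#' @param ppmTol,mzWindow,rtTol tolerances (ppm, Da, minutes).
#' @param minFragments fragment-count constraint, see [annotateAif()].
#' @param ppcCutoff,ppsBand score cutoffs, see [scoreVerdict()].
#' @param smoothMethod smoother for PPC, see [smoothPeak()].
#' @param seed RNG seed recorded with the config.
#' @param logLevel `"info"` or `"quiet"`.
#' @return a validated list of class `RunConfig`.
#' @export
runConfig <- function(inputs, outDir, ms1Library = NULL,
                      msmsLibrary = NULL, format = "auto",
                      polarity = NULL, energyCycle = NULL, ppmTol = 5,
                      mzWindow = 0.005, rtTol = 0.08, minFragments = 1L,
                      ppcCutoff = 0.7, ppsBand = c(0.3, 3),
                      smoothMethod = "smoothing-spline", seed = 1L,
                      logLevel = "info") {
    stopifnot(ppmTol > 0, mzWindow > 0, rtTol > 0, length(inputs) >= 1L)
    cfg <- list(inputs = inputs, outDir = outDir, ms1Library = ms1Library,
                msmsLibrary = msmsLibrary, format = format,
                polarity = polarity, energyCycle = energyCycle,
                ppmTol = ppmTol, mzWindow = mzWindow, rtTol = rtTol,
                minFragments = minFragments, ppcCutoff = ppcCutoff,
                ppsBand = ppsBand, smoothMethod = smoothMethod,
                seed = seed, logLevel = logLevel)
    class(cfg) <- "RunConfig"
    cfg
}

#' @rdname runConfig
#' @param path YAML file path.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    do.call(runConfig, y)
}

#' @rdname runConfig
#' @param config a `RunConfig`.
#' @export
writeRunConfig <- function(config, path) {
    out <- config[!vapply(config, is.null, TRUE)]
    out <- out[!vapply(out, is.data.frame, TRUE)]  # paths only in YAML
    yaml::write_yaml(unclass(out), path)
    invisible(path)
}

.resolveLibrary <- function(x, loader) {
    if (is.null(x) || is.data.frame(x)) return(x)
    loader(x)
}

.batchLog <- function(cfg, ...) {
    if (!identical(cfg$logLevel, "quiet"))
        message("[metaif] ", ...)
}

#' Process many runs with one configuration
#'
#' Each input file is processed independently: read, polarity filter,
#' collision-energy split, MS1 annotation (when an MS1 library is
#' configured) and per-energy AIF annotation plus DIA scoring (when an
#' MS/MS library is configured). Per-run CSV reports land in the output
#' directory, plus one combined summary with a `run_id` column. A failing
#' file is logged and marked in the summary without aborting the batch.
#'
#' @param config a `RunConfig` from [runConfig()] or [readRunConfig()].
#' @return the summary data.frame (`run_id`, `file`, `status`, `n_ms1`,
#'   `n_dia`, `error`), invisibly, with attribute `"exit"`: 0 when all runs
#'   succeeded, 2 when some failed, 1 when all failed.
#' @export
runBatch <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    ms1Lib <- .resolveLibrary(config$ms1Library, loadMs1Library)
    msmsLib <- .resolveLibrary(config$msmsLibrary, loadMsmsLibrary)
    summary <- list()
    for (i in seq_along(config$inputs)) {
        f <- config$inputs[i]
        runId <- sprintf("run%03d", i)
        .batchLog(config, runId, ": ", f)
        res <- tryCatch({
            scans <- readMsRun(f, format = config$format,
                               energyCycle = config$energyCycle)
            chans <- splitByEnergy(scans, polarity = config$polarity)
            if (!"0" %in% names(chans))
                stop("no energy-0 MS1 channel in ", f)
            nMs1 <- 0L; nDia <- 0L
            if (!is.null(ms1Lib)) {
                ann <- annotateMs1(chans[["0"]], ms1Lib,
                                   ppmTol = config$ppmTol,
                                   mzWindow = config$mzWindow)
                nMs1 <- nrow(ann)
                writeMs1Results(ann, file.path(
                    config$outDir, paste0(runId, "_ms1.csv")))
            }
            if (!is.null(msmsLib)) {
                msmsChans <- chans[setdiff(names(chans), "0")]
                groups <- unlist(lapply(msmsChans, function(ch)
                    annotateAif(chans[["0"]], ch, msmsLib,
                                ppmTol = config$ppmTol,
                                mzWindow = config$mzWindow,
                                rtTol = config$rtTol,
                                minFragments = config$minFragments)),
                    recursive = FALSE)
                scores <- if (length(groups))
                    scoreDia(groups, ppcCutoff = config$ppcCutoff,
                             ppsBand = config$ppsBand,
                             smoothMethod = config$smoothMethod)
                else data.frame()
                nDia <- nrow(scores)
                writeDiaResults(scores, file.path(
                    config$outDir, paste0(runId, "_dia.csv")))
            }
            data.frame(run_id = runId, file = f, status = "ok",
                       n_ms1 = nMs1, n_dia = nDia, error = "",
                       stringsAsFactors = FALSE)
        }, error = function(e) {
            .batchLog(config, runId, " FAILED: ", conditionMessage(e))
            data.frame(run_id = runId, file = f, status = "failed",
                       n_ms1 = NA_integer_, n_dia = NA_integer_,
                       error = conditionMessage(e), stringsAsFactors = FALSE)
        })
        summary[[i]] <- res
    }
    summary <- do.call(rbind, summary)
    utils::write.csv(summary, file.path(config$outDir, "summary.csv"),
                     row.names = FALSE)
    nf <- sum(summary$status == "failed")
    attr(summary, "exit") <-
        if (nf == 0L) 0L else if (nf == nrow(summary)) 1L else 2L
    invisible(summary)
}
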