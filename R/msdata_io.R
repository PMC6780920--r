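## Reading centroided mzML/mzXML runs and demultiplexing scans into
## per-collision-energy channels.

.energyLabel <- function(ce) {
    ifelse(is.na(ce), NA_character_,
           sub("\\.?0+$", "", sprintf("%.4f", as.numeric(ce))))
}

.polarityLabel <- function(p) {
    out <- rep("unknown", length(p))
    out[!is.na(p) & p > 0] <- "positive"
    out[!is.na(p) & p == 0] <- "negative"
    out
}

#' Construct a ScanSet
#'
#' Low-level constructor; most users get ScanSets from [readMsRun()] or
#' [simulateRun()].
#'
#' @param header data.frame with columns `scanId`, `rt` (minutes),
#'   `msLevel`, `energy` (character label), `polarity`.
#' @param peaks list of two-column `(mz, intensity)` matrices, one per scan,
#'   each sorted ascending by m/z.
#' @return a [ScanSet-class].
#' @export
ScanSet <- function(header, peaks) {
    rownames(header) <- NULL
    header$energy <- as.character(header$energy)
    header$msLevel <- as.integer(header$msLevel)
    peaks <- lapply(peaks, function(p) {
        p <- matrix(as.numeric(p), ncol = 2,
                    dimnames = list(NULL, c("mz", "intensity")))
        p[order(p[, 1]), , drop = FALSE]
    })
    new("ScanSet", header = header, peaks = peaks)
}

#' Read a centroided mzML/mzXML run
#'
#' Parses every spectrum of the file into a [ScanSet-class]. Retention times
#' are normalized to minutes whatever the file records. The collision-energy
#' label is taken from the per-spectrum metadata (the "collision energy"
#' cvParam in mzML, the `collisionEnergy` attribute in mzXML); when it is
#' absent, MS1 scans are labelled `"0"` and MS2 scans either follow the
#' user-supplied `energyCycle` (a vector recycled over the scan order, e.g.
#' `c(0, 5, 10, 20)`) or are labelled `"unknown"` with a warning.
#'
#' @param path path to an mzML or mzXML file.
#' @param format `"auto"` (extension-based, the parser autodetects anyway),
#'   `"mzML"` or `"mzXML"`.
#' @param energyCycle optional collision-energy cycle applied positionally
#'   to all scans (overrides recorded energies when given).
#' @param centroiding what to do with profile-mode spectra: `"reject"`
#'   (default, error) or `"local-max"` (reduce each to its intensity local
#'   maxima).
#' @return a [ScanSet-class]; scan count equals the file's spectrum count.
#' @export
readMsRun <- function(path, format = c("auto", "mzML", "mzXML"),
                      energyCycle = NULL,
                      centroiding = c("reject", "local-max")) {
    format <- match.arg(format)
    centroiding <- match.arg(centroiding)
    if (!file.exists(path)) stop("file not found: ", path)
    ms <- mzR::openMSfile(path)
    on.exit(mzR::close(ms))
    h <- mzR::header(ms)
    if (!nrow(h))
        return(ScanSet(data.frame(scanId = integer(), rt = numeric(),
                                  msLevel = integer(), energy = character(),
                                  polarity = character()), list()))
    pk <- mzR::peaks(ms)
    if (is.matrix(pk)) pk <- list(pk)
    profile <- !is.na(h$centroided) & !h$centroided
    if (any(profile)) {
        if (centroiding == "reject")
            stop(sum(profile), " profile-mode spectra found; ",
                 "set centroiding = 'local-max' to reduce them")
        pk[profile] <- lapply(pk[profile], .localMaxCentroid)
    }
    energy <- .energyLabel(h$collisionEnergy)
    if (!is.null(energyCycle)) {
        energy <- as.character(rep_len(.energyLabel(as.numeric(energyCycle)),
                                       nrow(h)))
    } else {
        energy[is.na(energy) & h$msLevel == 1L] <- "0"
        if (anyNA(energy)) {
            warning("collision-energy metadata missing for ",
                    sum(is.na(energy)),
                    " MS2 scan(s); recorded as 'unknown'")
            energy[is.na(energy)] <- "unknown"
        }
    }
    ScanSet(data.frame(scanId = h$seqNum,
                       rt = h$retentionTime / 60,
                       msLevel = h$msLevel,
                       energy = energy,
                       polarity = .polarityLabel(h$polarity),
                       stringsAsFactors = FALSE),
            pk)
}

## Profile fallback: keep intensity local maxima along the m/z axis.
.localMaxCentroid <- function(p) {
    n <- nrow(p)
    if (n < 3L) return(p)
    y <- p[, 2]
    keep <- y > 0 & y >= c(-Inf, y[-n]) & y >= c(y[-1], -Inf)
    p[keep, , drop = FALSE]
}

#' Split a run into per-collision-energy channels
#'
#' Partitions the scans of a run by collision-energy label (and polarity,
#' when several polarities survive filtering), the demultiplexing step for
#' multiplexed all-ion-fragmentation acquisitions. Every scan lands in
#' exactly one channel and within-channel retention-time order is preserved.
#' Energy `"0"` (at any recorded MS level) is the full-scan MS1 channel.
#'
#' @param x a [ScanSet-class].
#' @param polarity optional polarity filter (`"positive"`/`"negative"`)
#'   applied before splitting.
#' @return named list of [ScanChannel-class], keyed by energy label (with a
#'   polarity suffix when both polarities are present).
#' @export
#' @examples
#' run <- simulateRun(demoTruth(), seed = 1)
#' chans <- splitByEnergy(run$scans)
#' names(chans)
splitByEnergy <- function(x, polarity = NULL) {
    stopifnot(is(x, "ScanSet"))
    h <- scanHeader(x)
    pk <- scanPeaks(x)
    if (!is.null(polarity)) {
        polarity <- match.arg(polarity, c("positive", "negative"))
        keep <- h$polarity == polarity
        h <- h[keep, , drop = FALSE]
        pk <- pk[keep]
    }
    if (!nrow(h)) return(stats::setNames(list(), character()))
    onePol <- length(unique(h$polarity)) == 1L
    key <- if (onePol) h$energy else paste0(h$energy, "/", h$polarity)
    out <- lapply(split(seq_len(nrow(h)), key), function(i) {
        i <- i[order(h$rt[i])]
        hh <- h[i, , drop = FALSE]
        rownames(hh) <- NULL
        lev <- if (unique(hh$energy) == "0") 1L else max(hh$msLevel)
        new("ScanChannel", header = hh, peaks = pk[i],
            energy = unique(hh$energy), msLevel = lev,
            polarity = unique(hh$polarity))
    })
    ## natural numeric order of energy labels where possible
    ord <- order(suppressWarnings(as.numeric(sub("/.*", "", names(out)))),
                 names(out))
    out[ord]
}
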