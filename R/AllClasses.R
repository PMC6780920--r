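#' @import methods
NULL

.scanHeaderCols <- c("scanId", "rt", "msLevel", "energy", "polarity")

#' ScanSet: a centroided LC-MS run in memory
#'
#' Container for the spectra of one run. `header` holds one row per scan
#' (`scanId`, `rt` in minutes, `msLevel`, `energy` label as recorded by the
#' instrument, `polarity`); `peaks` holds one two-column matrix
#' (`mz`, `intensity`) per scan, sorted ascending by m/z.
#'
#' @slot header data.frame of per-scan metadata.
#' @slot peaks list of numeric matrices, parallel to `header` rows.
#' @aliases ScanSet-class
#' @exportClass ScanSet
setClass("ScanSet",
         representation(header = "data.frame", peaks = "list"))

setValidity("ScanSet", function(object) {
    h <- object@header
    msg <- character()
    if (!all(.scanHeaderCols %in% names(h)))
        msg <- c(msg, paste("header must contain columns:",
                            paste(.scanHeaderCols, collapse = ", ")))
    else {
        if (nrow(h) != length(object@peaks))
            msg <- c(msg, "one peaks matrix required per header row")
        if (nrow(h) && any(h$rt < 0))
            msg <- c(msg, "retention times must be >= 0")
        for (p in object@peaks) {
            if (!is.matrix(p) || ncol(p) != 2) {
                msg <- c(msg, "each peaks element must be a 2-column matrix")
                break
            }
            if (nrow(p) > 1 && is.unsorted(p[, 1])) {
                msg <- c(msg, "peak matrices must be sorted ascending by m/z")
                break
            }
            if (nrow(p) && any(p[, 2] < 0)) {
                msg <- c(msg, "intensities must be >= 0")
                break
            }
        }
    }
    if (length(msg)) msg else TRUE
})

#' ScanChannel: scans of one collision-energy channel
#'
#' A [ScanSet-class] restricted to one (collision energy, MS level, polarity)
#' combination, retention-time ordered. Produced by [splitByEnergy()].
#'
#' @slot energy collision-energy label (instrument units kept as text,
#'   e.g. `"0"`, `"5"`, `"30"`).
#' @slot msLevel 1 for the full-scan channel, 2 for fragmentation channels.
#' @slot polarity `"positive"`, `"negative"` or `"unknown"`.
#' @aliases ScanChannel-class
#' @exportClass ScanChannel
setClass("ScanChannel", contains = "ScanSet",
         representation(energy = "character", msLevel = "integer",
                        polarity = "character"))

setValidity("ScanChannel", function(object) {
    h <- object@header
    msg <- character()
    if (nrow(h)) {
        if (!all(h$energy == object@energy))
            msg <- c(msg, "all scans must share the channel energy label")
        if (is.unsorted(h$rt, strictly = TRUE))
            msg <- c(msg, "retention times must be strictly increasing")
    }
    if (length(msg)) msg else TRUE
})

#' EIC: extracted ion chromatogram
#'
#' One point per scan of the source channel: the most intense centroid within
#' the m/z tolerance window of `targetMz`, or a zero-intensity placeholder
#' when no centroid matched. `points` columns: `scanId`, `rt` (min),
#' `intensity`, `mz` (observed, NA for placeholders), `ppm` (signed deviation
#' from target, NA for placeholders).
#'
#' @slot targetMz target m/z (Da).
#' @slot ppmTol relative tolerance (ppm).
#' @slot mzWindow absolute tolerance cap (Da).
#' @slot points data.frame, RT-ordered.
#' @aliases EIC-class
#' @exportClass EIC
setClass("EIC",
         representation(targetMz = "numeric", ppmTol = "numeric",
                        mzWindow = "numeric", points = "data.frame"))

setValidity("EIC", function(object) {
    p <- object@points
    msg <- character()
    if (object@targetMz <= 0) msg <- c(msg, "targetMz must be > 0")
    if (nrow(p)) {
        if (is.unsorted(p$rt)) msg <- c(msg, "points must be RT-ordered")
        tol <- min(object@targetMz * object@ppmTol * 1e-6, object@mzWindow)
        d <- abs(p$mz - object@targetMz)
        if (any(d > tol + 1e-12, na.rm = TRUE))
            msg <- c(msg, "observed m/z outside the stated tolerance window")
    }
    if (length(msg)) msg else TRUE
})

#' EICPeak: a detected chromatographic peak
#'
#' A contiguous scan span of an [EIC-class] reported by [detectPeaks()].
#' Edges `tRi`/`tRf` and apex `tRmax` feed the asymmetry factor
#' f = (tRf - tRmax) / (tRmax - tRi), which is set to 0 for peaks with fewer
#' than 3 scans or an apex on an endpoint. `smoothed` holds spline-smoothed
#' intensities on the same RT grid once [smoothPeak()] has run (length 0
#' before that).
#'
#' @slot targetMz target m/z of the parent EIC.
#' @slot points the EIC points of the span.
#' @slot apexIdx index of the apex within `points`.
#' @slot area trapezoidal area on the raw trace (counts x min).
#' @slot f asymmetry factor.
#' @slot meanPpm mean absolute m/z deviation over matched scans (ppm).
#' @slot smoothed smoothed intensities (possibly length 0).
#' @slot smoothMethod `"none"`, `"smoothing-spline"` or `"cubic-spline"`.
#' @aliases EICPeak-class
#' @exportClass EICPeak
setClass("EICPeak",
         representation(targetMz = "numeric", points = "data.frame",
                        apexIdx = "integer", area = "numeric", f = "numeric",
                        meanPpm = "numeric", smoothed = "numeric",
                        smoothMethod = "character"))

setValidity("EICPeak", function(object) {
    p <- object@points
    msg <- character()
    if (!nrow(p)) msg <- c(msg, "peak span must be non-empty")
    else {
        a <- object@apexIdx
        if (a < 1L || a > nrow(p)) msg <- c(msg, "apexIdx out of range")
        else if (p$intensity[a] < max(p$intensity))
            msg <- c(msg, "apex must carry the maximum intensity of the span")
        if (length(object@smoothed) &&
            length(object@smoothed) != nrow(p))
            msg <- c(msg, "smoothed values must match the RT grid")
    }
    if (length(msg)) msg else TRUE
})

#' PeakGroup: an aligned precursor-fragment peak group
#'
#' One metabolite/adduct at one collision energy: the precursor peak from the
#' full-scan channel plus the fragment peaks that co-elute with it within the
#' retention-time tolerance. `fragmentInfo` columns: `fragment_mz` (library
#' value), `observed_mz`, `ppm_error`, `dRT_min` (apex-to-apex), `matched`.
#'
#' @slot metabolite metabolite name.
#' @slot adduct adduct label.
#' @slot energy collision-energy label of the fragment channel.
#' @slot precursor the precursor [EICPeak-class].
#' @slot fragments list of matched fragment [EICPeak-class] objects.
#' @slot fragmentInfo data.frame, one row per library fragment.
#' @slot nLibFragments number of fragments listed for this entry.
#' @slot nMatched number of fragments matched within tolerance.
#' @aliases PeakGroup-class
#' @exportClass PeakGroup
setClass("PeakGroup",
         representation(metabolite = "character", adduct = "character",
                        energy = "character", precursor = "EICPeak",
                        fragments = "list", fragmentInfo = "data.frame",
                        nLibFragments = "integer", nMatched = "integer"))

setValidity("PeakGroup", function(object) {
    msg <- character()
    if (object@nMatched > object@nLibFragments)
        msg <- c(msg, "nMatched cannot exceed nLibFragments")
    if (length(object@fragments) != object@nMatched)
        msg <- c(msg, "one fragment peak required per matched fragment")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ScanSet", function(object) {
    h <- object@header
    cat("ScanSet with", nrow(h), "scans\n")
    if (nrow(h)) {
        cat("  RT range:", sprintf("%.3f-%.3f min", min(h$rt), max(h$rt)), "\n")
        cat("  MS levels:", paste(sort(unique(h$msLevel)), collapse = ", "), "\n")
        cat("  energies:", paste(unique(h$energy), collapse = ", "), "\n")
        cat("  polarity:", paste(unique(h$polarity), collapse = ", "), "\n")
    }
})

setMethod("show", "ScanChannel", function(object) {
    cat(sprintf("ScanChannel [CE %s, MS%d, %s] with %d scans\n",
                object@energy, object@msLevel, object@polarity,
                nrow(object@header)))
})

setMethod("show", "EIC", function(object) {
    p <- object@points
    cat(sprintf("EIC for m/z %.4f (%g ppm / %g Da): %d scans, %d matched\n",
                object@targetMz, object@ppmTol, object@mzWindow,
                nrow(p), sum(p$intensity > 0)))
})

setMethod("show", "EICPeak", function(object) {
    cat(sprintf(
        "EICPeak m/z %.4f: apex %.3f min (I=%.3g), %d scans, f=%.2f%s\n",
        object@targetMz, rtApex(object), apexIntensity(object),
        nScans(object), object@f,
        if (length(object@smoothed)) paste0(", smoothed (",
                                            object@smoothMethod, ")") else ""))
})

setMethod("show", "PeakGroup", function(object) {
    cat(sprintf("PeakGroup %s %s @ CE %s: %d/%d fragments matched\n",
                object@metabolite, object@adduct, object@energy,
                object@nMatched, object@nLibFragments))
})
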