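#' Accessors for MS data containers
#'
#' Small accessor generics used across the package: `scanHeader()` and
#' `scanPeaks()` expose a [ScanSet-class]'s metadata table and centroid
#' matrices; `nScans()` counts scans (or the scans spanned by a peak);
#' `rtApex()`, `apexIntensity()`, `peakArea()` and `asymmetryFactor()` read
#' the derived quantities of an [EICPeak-class]; `eicPoints()` returns the
#' per-scan table of an [EIC-class] or peak span.
#'
#' @param object a ScanSet, ScanChannel, EIC or EICPeak.
#' @return the requested component.
#' @name accessors
#' @examples
#' run <- simulateRun(demoTruth(), seed = 1)
#' nScans(run$scans)
NULL

#' @rdname accessors
#' @export
setGeneric("scanHeader", function(object) standardGeneric("scanHeader"))
#' @rdname accessors
#' @export
setGeneric("scanPeaks", function(object) standardGeneric("scanPeaks"))
#' @rdname accessors
#' @export
setGeneric("nScans", function(object) standardGeneric("nScans"))
#' @rdname accessors
#' @export
setGeneric("eicPoints", function(object) standardGeneric("eicPoints"))
#' @rdname accessors
#' @export
setGeneric("rtApex", function(object) standardGeneric("rtApex"))
#' @rdname accessors
#' @export
setGeneric("apexIntensity", function(object) standardGeneric("apexIntensity"))
#' @rdname accessors
#' @export
setGeneric("peakArea", function(object) standardGeneric("peakArea"))

#' @rdname asymmetryFactor
#' @export
setGeneric("asymmetryFactor", function(object, ...)
    standardGeneric("asymmetryFactor"))

setMethod("scanHeader", "ScanSet", function(object) object@header)
setMethod("scanPeaks", "ScanSet", function(object) object@peaks)
setMethod("nScans", "ScanSet", function(object) nrow(object@header))
setMethod("nScans", "EICPeak", function(object) nrow(object@points))
setMethod("eicPoints", "EIC", function(object) object@points)
setMethod("eicPoints", "EICPeak", function(object) object@points)
setMethod("rtApex", "EICPeak", function(object)
    object@points$rt[object@apexIdx])
setMethod("apexIntensity", "EICPeak", function(object)
    object@points$intensity[object@apexIdx])
setMethod("peakArea", "EICPeak", function(object) object@area)
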