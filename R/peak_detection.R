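## Targeted EIC extraction, chromatographic peak detection, spline
## smoothing, and the asymmetry factor.

#' Extract an ion chromatogram for a target m/z
#'
#' For every scan of the channel, selects the most intense centroid within
#' the tolerance window of `targetMz` — the window is the tighter of the
#' relative (`ppmTol`) and absolute (`mzWindow`) tolerances — or records a
#' zero-intensity placeholder when no centroid matches. The per-scan signed
#' ppm deviation is kept for quality-control plotting.
#'
#' @param channel a [ScanChannel-class].
#' @param targetMz target m/z in Da.
#' @param ppmTol relative tolerance in ppm (default 5).
#' @param mzWindow absolute tolerance cap in Da (default 0.005); for m/z
#'   below 1000 the 5 ppm window is the binding constraint.
#' @return an [EIC-class] with one point per scan.
#' @export
extractEic <- function(channel, targetMz, ppmTol = 5, mzWindow = 0.005) {
    stopifnot(is(channel, "ScanSet"), targetMz > 0, ppmTol > 0, mzWindow > 0)
    tol <- min(targetMz * ppmTol * 1e-6, mzWindow)
    h <- scanHeader(channel)
    pk <- scanPeaks(channel)
    n <- nrow(h)
    int <- numeric(n); mz <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        p <- pk[[i]]
        if (!nrow(p)) next
        lo <- findInterval(targetMz - tol, p[, 1]) + 1L
        hi <- findInterval(targetMz + tol, p[, 1])
        if (hi < lo) next
        j <- lo:hi
        best <- j[which.max(p[j, 2])]
        int[i] <- p[best, 2]
        mz[i] <- p[best, 1]
    }
    new("EIC", targetMz = targetMz, ppmTol = ppmTol, mzWindow = mzWindow,
        points = data.frame(scanId = h$scanId, rt = h$rt, intensity = int,
                            mz = mz, ppm = ppmError(mz, targetMz)))
}

## Recursive valley split: cut a candidate run at its deepest interior
## minimum whenever the valley drops below valleyFraction of the smaller
## flanking maximum.
.splitAtValleys <- function(v, valleyFraction) {
    n <- length(v)
    if (n < 3L) return(list(seq_len(n)))
    interior <- 2:(n - 1L)
    mins <- interior[v[interior] <= v[interior - 1L] &
                     v[interior] <= v[interior + 1L]]
    if (length(mins)) {
        depth <- vapply(mins, function(j) {
            flank <- min(max(v[1:j]), max(v[j:n]))
            if (flank <= 0) Inf else v[j] / flank
        }, numeric(1))
        j <- mins[which.min(depth)]
        if (depth[which.min(depth)] < valleyFraction) {
            left <- .splitAtValleys(v[1:j], valleyFraction)
            right <- .splitAtValleys(v[(j + 1L):n], valleyFraction)
            return(c(left, lapply(right, `+`, j)))
        }
    }
    list(seq_len(n))
}

.trapezoid <- function(x, y) {
    if (length(x) < 2L) return(0)
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

.newPeak <- function(targetMz, pts) {
    apex <- which.max(pts$intensity)
    rownames(pts) <- NULL
    f <- .asymmetry(pts$rt[1], pts$rt[apex], pts$rt[nrow(pts)],
                    nrow(pts), apex)
    new("EICPeak", targetMz = targetMz, points = pts, apexIdx = apex,
        area = .trapezoid(pts$rt, pts$intensity), f = f,
        meanPpm = mean(abs(pts$ppm), na.rm = TRUE),
        smoothed = numeric(), smoothMethod = "none")
}

#' Detect chromatographic peaks in an EIC
#'
#' Finds maximal runs of consecutive above-threshold points and splits each
#' run at interior local minima whose depth falls below `valleyFraction` of
#' the smaller flanking apex. Each surviving segment with at least
#' `minScans` points becomes an [EICPeak-class] with apex, bounds,
#' trapezoidal area (raw trace) and asymmetry factor.
#'
#' @param eic an [EIC-class].
#' @param minScans minimum points per peak (default 3).
#' @param minIntensity intensity threshold; points at or below it do not
#'   belong to any peak (default 0, i.e. any signal).
#' @param valleyFraction valley split fraction (default 0.5).
#' @return list of [EICPeak-class], ordered by retention time.
#' @export
detectPeaks <- function(eic, minScans = 3L, minIntensity = 0,
                        valleyFraction = 0.5) {
    stopifnot(is(eic, "EIC"), minScans >= 1L)
    pts <- eicPoints(eic)
    above <- pts$intensity > max(0, minIntensity)
    if (!any(above)) return(list())
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    out <- list()
    for (k in which(r$values)) {
        idx <- starts[k]:ends[k]
        segs <- .splitAtValleys(pts$intensity[idx], valleyFraction)
        for (s in segs) {
            if (length(s) < minScans) next
            out[[length(out) + 1L]] <-
                .newPeak(eic@targetMz, pts[idx[s], , drop = FALSE])
        }
    }
    out
}

.asymmetry <- function(tRi, tRmax, tRf, n, apexIdx) {
    if (n < 3L || apexIdx == 1L || apexIdx == n) return(0)
    (tRf - tRmax) / (tRmax - tRi)
}

#' Chromatographic peak asymmetry factor
#'
#' f = (tRf - tRmax) / (tRmax - tRi), the ratio of the trailing-edge to the
#' leading-edge time distance over a detected peak's scan span: 1 for a
#' symmetric peak, > 1 for tailing, < 1 for fronting. Degenerate peaks —
#' fewer than 3 scans, or the maximum intensity on the first or last scan —
#' score 0.
#'
#' @param object an [EICPeak-class], or `tRi` (numeric) when calling the
#'   three-argument form `asymmetryFactor(tRi, tRmax, tRf)`.
#' @param ... `tRmax` and `tRf` for the numeric form.
#' @return the asymmetry factor (dimensionless).
#' @export
#' @examples
#' asymmetryFactor(1.0, 1.2, 1.5)  # 1.5
setMethod("asymmetryFactor", "EICPeak", function(object, ...) object@f)

#' @rdname asymmetryFactor
setMethod("asymmetryFactor", "numeric", function(object, ...) {
    args <- list(...)
    stopifnot(length(args) >= 2)
    tRmax <- args[[1]]; tRf <- args[[2]]
    (tRf - tRmax) / (tRmax - object)
})

#' Smooth a detected peak
#'
#' Fits a spline to the peak's raw intensities and evaluates it on the
#' original retention-time grid. `"smoothing-spline"` (default) is a
#' cross-validated [stats::smooth.spline()] fit and is what the
#' peak-correlation score uses; `"cubic-spline"` is a natural cubic
#' interpolating spline, exact at the knots, useful for resampling and
#' plotting. Negative fitted values are clamped to 0. Peaks with fewer than
#' 4 scans are passed through unsmoothed with `smoothMethod` left `"none"`.
#'
#' @param peak an [EICPeak-class].
#' @param method `"smoothing-spline"` or `"cubic-spline"`.
#' @param spar optional smoothing parameter forwarded to
#'   [stats::smooth.spline()].
#' @return the peak with the `smoothed` slot filled.
#' @export
smoothPeak <- function(peak, method = c("smoothing-spline", "cubic-spline"),
                       spar = NULL) {
    stopifnot(is(peak, "EICPeak"))
    method <- match.arg(method)
    pts <- eicPoints(peak)
    n <- nrow(pts)
    if (n < 4L) {
        peak@smoothed <- pts$intensity
        peak@smoothMethod <- "none"
        return(peak)
    }
    y <- switch(method,
        "smoothing-spline" = tryCatch({
            fit <- if (is.null(spar)) stats::smooth.spline(pts$rt, pts$intensity)
                   else stats::smooth.spline(pts$rt, pts$intensity, spar = spar)
            stats::predict(fit, pts$rt)$y
        }, error = function(e) pts$intensity),
        "cubic-spline" = stats::spline(pts$rt, pts$intensity, xout = pts$rt,
                                       method = "natural")$y)
    peak@smoothed <- pmax(y, 0)
    peak@smoothMethod <- method
    peak
}

## Smoothed intensities, smoothing on demand with the given method.
.smoothedIntensity <- function(peak, method = "smoothing-spline") {
    if (!length(peak@smoothed))
        peak <- smoothPeak(peak, method = method)
    peak@smoothed
}
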