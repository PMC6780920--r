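## Quality-control plots: EIC trace with per-scan m/z deviation, and
## precursor-fragment co-elution panels.

.openDevice <- function(file, width, height) {
    if (is.null(file)) return(FALSE)
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = width, height = height,
                                units = "in", res = 150),
           svg = grDevices::svg(file, width = width, height = height),
           stop("unsupported plot format: ", ext))
    TRUE
}

#' Plot an extracted ion chromatogram with its m/z deviation panel
#'
#' Two stacked panels: the EIC intensity trace with the apex marked, and
#' the signed per-scan m/z deviation (ppm) of the centroids forming the
#' trace — the standard QC view for judging an annotation's mass accuracy
#' scan by scan.
#'
#' @param eic an [EIC-class] (or [EICPeak-class], plotted over its span).
#' @param file optional PNG/SVG path; NULL draws on the current device.
#' @param main plot title.
#' @return NULL, invisibly.
#' @export
plotEic <- function(eic, file = NULL, main = NULL) {
    pts <- eicPoints(eic)
    target <- if (is(eic, "EIC")) eic@targetMz else eic@targetMz
    if (is.null(main)) main <- sprintf("EIC m/z %.4f", target)
    dev <- .openDevice(file, 6, 5)
    if (dev) on.exit(grDevices::dev.off())
    op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 2, 1),
                        mgp = c(2, 0.7, 0))
    on.exit(graphics::par(op), add = TRUE)
    graphics::plot(pts$rt, pts$intensity, type = "l", xlab = "",
                   ylab = "intensity", main = main)
    apex <- which.max(pts$intensity)
    graphics::points(pts$rt[apex], pts$intensity[apex], pch = 19,
                     col = "red")
    ok <- !is.na(pts$ppm)
    graphics::plot(pts$rt[ok], pts$ppm[ok], pch = 19, cex = 0.6,
                   xlab = "retention time (min)", ylab = "m/z dev (ppm)")
    graphics::abline(h = 0, lty = 2, col = "grey50")
    invisible(NULL)
}

#' Co-elution plot for a precursor-fragment peak group
#'
#' One panel per matched fragment: the precursor trace (normalized to its
#' apex) overlaid with the fragment trace, the view used to vet PPC/PPS
#' scores against the raw chromatography.
#'
#' @param group a [PeakGroup-class].
#' @param file optional PNG/SVG path.
#' @return NULL, invisibly.
#' @export
plotCoelution <- function(group, file = NULL) {
    stopifnot(is(group, "PeakGroup"))
    prec <- eicPoints(group@precursor)
    nF <- length(group@fragments)
    dev <- .openDevice(file, 6, 2 + 1.6 * nF)
    if (dev) on.exit(grDevices::dev.off())
    op <- graphics::par(mfrow = c(max(nF, 1L), 1), mar = c(2.5, 4, 2, 1),
                        mgp = c(2, 0.7, 0))
    on.exit(graphics::par(op), add = TRUE)
    fi <- group@fragmentInfo[group@fragmentInfo$matched, , drop = FALSE]
    for (k in seq_len(nF)) {
        fpts <- eicPoints(group@fragments[[k]])
        graphics::plot(prec$rt, prec$intensity / max(prec$intensity),
                       type = "l", col = "blue", ylim = c(0, 1),
                       xlab = "retention time (min)",
                       ylab = "relative intensity",
                       main = sprintf("%s CE %s: precursor %.4f / fragment %.4f",
                                      group@metabolite, group@energy,
                                      group@precursor@targetMz,
                                      fi$fragment_mz[k]))
        graphics::lines(fpts$rt, fpts$intensity / max(fpts$intensity),
                        col = "red")
    }
    invisible(NULL)
}
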