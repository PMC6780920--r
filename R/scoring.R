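## Shared scoring primitives: peak-to-peak Pearson correlation (PPC),
## peak-to-peak shape ratio (PPS) and the accept/reject verdict engine.

#' Peak-to-peak Pearson correlation
#'
#' Pearson correlation of two co-eluting peaks' intensities over their
#' shared scans, with the two-sided p-value of the fit. The score is
#' meaningful only with at least 3 shared scans; fewer return NA with a
#' reason.
#'
#' @param x,y intensity vectors at the shared scans (equal length).
#' @return list with `ppc`, `p`, `n`, and `reason` (NA when defined).
#' @export
#' @examples
#' ppcScore(c(1, 5, 9, 5, 1), c(2, 10, 18, 10, 2))  # ppc = 1
ppcScore <- function(x, y) {
    stopifnot(length(x) == length(y))
    n <- length(x)
    if (n < 3L)
        return(list(ppc = NA_real_, p = NA_real_, n = n,
                    reason = "insufficient shared scans"))
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(list(ppc = NA_real_, p = NA_real_, n = n,
                    reason = "zero variance"))
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    list(ppc = unname(ct$estimate), p = ct$p.value, n = n, reason = NA)
}

#' Peak-to-peak shape ratio
#'
#' PPS = f1 / f2, the quotient of the two peaks' asymmetry factors. NA when
#' the denominator peak is degenerate (f2 = 0).
#'
#' @param f1,f2 asymmetry factors (see [asymmetryFactor()]).
#' @return the shape ratio.
#' @export
ppsScore <- function(f1, f2) {
    ifelse(f2 == 0, NA_real_, f1 / f2)
}

#' Score-based accept/reject verdict
#'
#' The decision rule applied to every precursor-fragment (or adduct-adduct)
#' pair: accept iff PPC >= `ppcCutoff` and PPS lies inside `ppsBand`, both
#' boundaries inclusive — a pair at PPS exactly 3.00 fails only if its PPC
#' is below the cutoff. An undefined PPC (too few shared scans) yields
#' `"insufficient scans"`; an undefined PPS counts as a shape failure.
#'
#' @param ppc PPC value (may be NA).
#' @param pps PPS value (may be NA).
#' @param ppcCutoff PPC acceptance cutoff (default 0.7).
#' @param ppsBand inclusive PPS acceptance band (default `c(0.3, 3)`).
#' @return character verdict: `"accept"`, `"reject: PPC"`, `"reject: PPS"`,
#'   `"reject: PPC,PPS"` or `"insufficient scans"`. Vectorized.
#' @export
#' @examples
#' scoreVerdict(0.93, 0.22)   # "reject: PPS"
#' scoreVerdict(0.60, 3.00)   # "reject: PPC" (PPS sits on the inclusive edge)
scoreVerdict <- function(ppc, pps, ppcCutoff = 0.7, ppsBand = c(0.3, 3)) {
    stopifnot(length(ppsBand) == 2, ppsBand[1] <= ppsBand[2])
    mapply(function(a, b) {
        if (is.na(a)) return("insufficient scans")
        fails <- c(
            if (a < ppcCutoff) "PPC",
            if (is.na(b) || b < ppsBand[1] || b > ppsBand[2]) "PPS")
        if (length(fails)) paste0("reject: ", paste(fails, collapse = ","))
        else "accept"
    }, ppc, pps, USE.NAMES = FALSE)
}

## Shared-scan pairing of two peaks.
## Same channel: intersect scan ids. Different channels: nearest-RT pairing
## within half the median scan period of the second peak's grid.
.sharedScans <- function(p1, p2, sameChannel = TRUE) {
    a <- eicPoints(p1); b <- eicPoints(p2)
    if (sameChannel) {
        ids <- intersect(a$scanId, b$scanId)
        list(i = match(ids, a$scanId), j = match(ids, b$scanId))
    } else {
        halfPeriod <- stats::median(diff(b$rt)) / 2
        if (!is.finite(halfPeriod)) return(list(i = integer(), j = integer()))
        j <- vapply(a$rt, function(t) which.min(abs(b$rt - t)), 0L)
        ok <- abs(a$rt - b$rt[j]) <= halfPeriod
        i <- seq_len(nrow(a))[ok]; j <- j[ok]
        dup <- duplicated(j)
        list(i = i[!dup], j = j[!dup])
    }
}

## PPC between two peaks on smoothed intensities over shared scans.
.peakPpc <- function(p1, p2, sameChannel = TRUE,
                     smoothMethod = "smoothing-spline") {
    sh <- .sharedScans(p1, p2, sameChannel)
    if (length(sh$i) < 3L)
        return(list(ppc = NA_real_, p = NA_real_, n = length(sh$i),
                    reason = "insufficient shared scans"))
    s1 <- .smoothedIntensity(p1, smoothMethod)
    s2 <- .smoothedIntensity(p2, smoothMethod)
    ppcScore(s1[sh$i], s2[sh$j])
}
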