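## All-ion-fragmentation annotation: precursor anchoring in the MS1
## channel, fragment matching in one collision-energy channel, grouping
## across energies, and DIA-level scoring (PPC, PPS, F/P ion ratio).

#' Annotate AIF data against an MS/MS library
#'
#' For each library entry, anchors the precursor in the full-scan (energy
#' 0) channel, then searches each library fragment in the MS/MS channel
#' within the m/z tolerance; a fragment peak matches when its apex lies
#' within `rtTol` of the precursor apex (apex-to-apex). Among several
#' candidates the smallest apex distance wins, ties broken by intensity.
#' Groups with fewer matched fragments than `minFragments` are discarded
#' (`"all"` requires the complete library fragment list). The surviving
#' precursor ion inside the MS/MS channel is treated like any other library
#' fragment.
#'
#' @param ms1Channel the energy-0 [ScanChannel-class] (mandatory precursor
#'   anchor).
#' @param msmsChannel one collision-energy [ScanChannel-class].
#' @param lib an `msms_library` (see [loadMsmsLibrary()]).
#' @param ppmTol,mzWindow EIC tolerances, see [extractEic()].
#' @param rtTol precursor-fragment apex alignment tolerance in minutes
#'   (default 0.08).
#' @param minFragments minimum matched fragments to keep a group: an
#'   integer, or `"all"` for the complete fragment list.
#' @param minScans,minIntensity peak-detection settings.
#' @return list of [PeakGroup-class] objects.
#' @export
annotateAif <- function(ms1Channel, msmsChannel, lib, ppmTol = 5,
                        mzWindow = 0.005, rtTol = 0.08, minFragments = 1L,
                        minScans = 3L, minIntensity = 0) {
    if (is.null(ms1Channel))
        stop("the MS1 channel is the mandatory precursor anchor")
    stopifnot(is(ms1Channel, "ScanChannel"), is(msmsChannel, "ScanChannel"),
              ppmTol > 0, mzWindow > 0, rtTol > 0)
    requireAll <- identical(minFragments, "all")
    if (!requireAll) stopifnot(minFragments >= 1L)
    groups <- list()
    for (e in seq_len(nrow(lib))) {
        prec <- .bestPeak(detectPeaks(
            extractEic(ms1Channel, lib$precursor_mz[e], ppmTol, mzWindow),
            minScans, minIntensity))
        if (is.null(prec)) next
        fr <- lib$fragments[[e]]
        fpeaks <- list()
        info <- lapply(seq_len(nrow(fr)), function(k) {
            cand <- detectPeaks(
                extractEic(msmsChannel, fr$mz[k], ppmTol, mzWindow),
                minScans, minIntensity)
            drt <- vapply(cand, function(p)
                abs(rtApex(p) - rtApex(prec$best)), 0)
            ok <- which(drt <= rtTol)
            if (!length(ok))
                return(data.frame(fragment_mz = fr$mz[k],
                                  observed_mz = NA_real_,
                                  ppm_error = NA_real_, dRT_min = NA_real_,
                                  matched = FALSE))
            ok <- ok[order(drt[ok],
                           -vapply(cand[ok], apexIntensity, 0))]
            p <- cand[[ok[1]]]
            fpeaks[[length(fpeaks) + 1L]] <<- p
            obs <- eicPoints(p)$mz[p@apexIdx]
            data.frame(fragment_mz = fr$mz[k], observed_mz = obs,
                       ppm_error = ppmError(obs, fr$mz[k]),
                       dRT_min = abs(rtApex(p) - rtApex(prec$best)),
                       matched = TRUE)
        })
        info <- do.call(rbind, info)
        nMatched <- sum(info$matched)
        need <- if (requireAll) nrow(fr) else minFragments
        if (nMatched < need) next
        groups[[length(groups) + 1L]] <-
            new("PeakGroup", metabolite = lib$name[e],
                adduct = lib$adduct[e], energy = msmsChannel@energy,
                precursor = prec$best, fragments = fpeaks,
                fragmentInfo = info, nLibFragments = nrow(fr),
                nMatched = as.integer(nMatched))
    }
    groups
}

#' Tabulate peak groups across collision energies
#'
#' Collates [PeakGroup-class] objects from several collision-energy
#' channels into one table keyed (metabolite, adduct, energy), preserving
#' each channel's fragment inventory so per-energy comparisons (a fragment
#' present at one energy, absent at another) are direct.
#'
#' @param groups a list of [PeakGroup-class] objects (flat, or a list of
#'   per-energy lists as produced by running [annotateAif()] per channel).
#' @return data.frame with columns `metabolite`, `adduct`, `energy`,
#'   `rt_apex_min`, `n_library_fragments`, `n_matched`,
#'   `fragments_matched` (semicolon-joined m/z).
#' @export
groupAcrossEnergies <- function(groups) {
    if (length(groups) && !is(groups[[1]], "PeakGroup"))
        groups <- unlist(groups, recursive = FALSE)
    if (!length(groups))
        return(data.frame(metabolite = character(), adduct = character(),
                          energy = character(), rt_apex_min = numeric(),
                          n_library_fragments = integer(),
                          n_matched = integer(),
                          fragments_matched = character()))
    out <- do.call(rbind, lapply(groups, function(g) {
        fi <- g@fragmentInfo
        data.frame(metabolite = g@metabolite, adduct = g@adduct,
                   energy = g@energy, rt_apex_min = rtApex(g@precursor),
                   n_library_fragments = g@nLibFragments,
                   n_matched = g@nMatched,
                   fragments_matched = paste(
                       sprintf("%.4f", fi$fragment_mz[fi$matched]),
                       collapse = ";"),
                   stringsAsFactors = FALSE)
    }))
    ord <- order(out$metabolite, out$adduct,
                 suppressWarnings(as.numeric(out$energy)))
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Score a precursor-fragment peak group
#'
#' Per matched fragment: PPC of the smoothed fragment trace against the
#' smoothed precursor trace over shared scans (precursor and fragment live
#' on different channels, so scans are paired by nearest retention time
#' within half the scan period); PPS = f_fragment / f_precursor; and the
#' product/precursor ion ratio F/P = I_max,F / I_max,P on the raw apex
#' intensities, with I_max,P taken from the MS1-channel precursor. The
#' verdict accepts a fragment iff PPC >= `ppcCutoff` and PPS lies within
#' `ppsBand` (inclusive); F/P is reported without a cutoff. Fewer than 3
#' shared scans give verdict `"insufficient scans"`.
#'
#' @param group a [PeakGroup-class], or a list of them.
#' @param ppcCutoff,ppsBand verdict thresholds, see [scoreVerdict()].
#' @param smoothMethod smoother used for the PPC, see [smoothPeak()].
#' @return data.frame with one row per matched fragment: `metabolite`,
#'   `adduct`, `energy`, `precursor_mz`, `fragment_mz`, `ppm_error`,
#'   `dRT_min`, `n_shared`, `PPC`, `PPC_p`, `PPS`, `FP_ratio`, `verdict`.
#' @export
scoreDia <- function(group, ppcCutoff = 0.7, ppsBand = c(0.3, 3),
                     smoothMethod = "smoothing-spline") {
    if (is.list(group))
        return(do.call(rbind, lapply(group, scoreDia,
                                     ppcCutoff = ppcCutoff,
                                     ppsBand = ppsBand,
                                     smoothMethod = smoothMethod)))
    stopifnot(is(group, "PeakGroup"), group@nMatched >= 1L)
    prec <- group@precursor
    fi <- group@fragmentInfo[group@fragmentInfo$matched, , drop = FALSE]
    rows <- lapply(seq_along(group@fragments), function(k) {
        fp <- group@fragments[[k]]
        pc <- .peakPpc(fp, prec, sameChannel = FALSE,
                       smoothMethod = smoothMethod)
        pps <- ppsScore(asymmetryFactor(fp), asymmetryFactor(prec))
        data.frame(metabolite = group@metabolite, adduct = group@adduct,
                   energy = group@energy,
                   precursor_mz = prec@targetMz,
                   fragment_mz = fi$fragment_mz[k],
                   ppm_error = fi$ppm_error[k], dRT_min = fi$dRT_min[k],
                   n_shared = pc$n, PPC = pc$ppc, PPC_p = pc$p, PPS = pps,
                   FP_ratio = apexIntensity(fp) / apexIntensity(prec),
                   verdict = scoreVerdict(pc$ppc, pps, ppcCutoff, ppsBand),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Write DIA scoring results to CSV
#'
#' @param scores output of [scoreDia()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeDiaResults <- function(scores, path) {
    utils::write.csv(scores, path, row.names = FALSE, na = "")
    invisible(path)
}
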