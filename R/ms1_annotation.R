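## Full-scan MS1 annotation: targeted extraction against the neutral-mass
## library, grouping by metabolite, and MS1-level quality scores (IPIR,
## PPC, PPS, asymmetry factor).

.bestPeak <- function(peaks) {
    if (!length(peaks)) return(NULL)
    ord <- order(vapply(peaks, apexIntensity, 0), decreasing = TRUE)
    list(best = peaks[[ord[1]]], alternates = peaks[ord[-1]])
}

.annotationRow <- function(name, formula, adduct, iso, theoMz, peak) {
    pts <- eicPoints(peak)
    obs <- pts$mz[peak@apexIdx]
    data.frame(metabolite = name, formula = formula, adduct = adduct,
               isotopologue = iso, theoretical_mz = theoMz,
               observed_mz = obs,
               ppm_error = ppmError(obs, theoMz),
               rt_apex_min = rtApex(peak),
               apex_intensity = apexIntensity(peak),
               area = peakArea(peak), f = asymmetryFactor(peak),
               n_scans = nScans(peak), stringsAsFactors = FALSE)
}

#' Targeted MS1 annotation against a neutral-mass library
#'
#' For every library entry x adduct x isotopologue (monoisotopic and +1),
#' computes the theoretical m/z, extracts the EIC from the full-scan
#' channel, detects peaks and keeps the most intense one (alternates are
#' kept in the `"alternates"` attribute). The +1 isotopologue is only
#' reported when the monoisotopic peak was found, and must co-elute with it
#' within `isoRtTol`. When both the library and the call provide retention
#' times, annotations outside `rtTol` of the library value are dropped.
#'
#' @param channel the energy-0 MS1 [ScanChannel-class].
#' @param lib an `ms1_library` (see [loadMs1Library()]).
#' @param adducts adduct registry rows to consider (default
#'   [defaultAdducts()] restricted to the channel polarity).
#' @param ppmTol,mzWindow EIC tolerances, see [extractEic()].
#' @param rtTol optional tolerance (minutes) against the library retention
#'   time; NULL disables the retention-time constraint.
#' @param isoRtTol apex co-elution tolerance for the +1 isotopologue
#'   (minutes).
#' @param minScans,minIntensity peak-detection settings, see
#'   [detectPeaks()].
#' @return data.frame with one row per annotation (metabolite, adduct,
#'   isotopologue, theoretical/observed m/z, ppm error, apex RT, apex
#'   intensity, area, asymmetry f, n_scans) plus a `peak` list column of
#'   [EICPeak-class] objects; sorted by metabolite, adduct, isotopologue.
#' @export
annotateMs1 <- function(channel, lib, adducts = NULL, ppmTol = 5,
                        mzWindow = 0.005, rtTol = NULL, isoRtTol = 0.08,
                        minScans = 3L, minIntensity = 0) {
    stopifnot(is(channel, "ScanChannel"))
    if (is.null(adducts)) {
        adducts <- defaultAdducts()
        if (channel@polarity %in% c("positive", "negative"))
            adducts <- adducts[adducts$polarity == channel@polarity, ,
                               drop = FALSE]
    }
    if (!nrow(lib)) {
        warning("empty MS1 library; nothing to annotate")
        return(.emptyMs1Annotations())
    }
    rows <- list(); peaks <- list(); alternates <- list()
    for (e in seq_len(nrow(lib))) {
        for (a in seq_len(nrow(adducts))) {
            if (lib$polarity[e] != "any" &&
                lib$polarity[e] != adducts$polarity[a]) next
            theo0 <- adductMz(lib$neutral_mass[e], adducts$label[a], adducts)
            eic0 <- extractEic(channel, theo0, ppmTol, mzWindow)
            cand <- detectPeaks(eic0, minScans, minIntensity)
            if (!is.null(rtTol) && !is.na(lib$rt[e]))
                cand <- Filter(function(p)
                    abs(rtApex(p) - lib$rt[e]) <= rtTol, cand)
            pick <- .bestPeak(cand)
            if (is.null(pick)) next
            rows[[length(rows) + 1L]] <-
                .annotationRow(lib$name[e], lib$formula[e],
                               adducts$label[a], 0L, theo0, pick$best)
            peaks[[length(peaks) + 1L]] <- pick$best
            if (length(pick$alternates))
                alternates[[paste(lib$name[e], adducts$label[a])]] <-
                    pick$alternates
            ## +1 isotopologue, gated on the monoisotopic find
            theo1 <- isotopologueMz(theo0, 1L, abs(adducts$charge[a]))
            eic1 <- extractEic(channel, theo1, ppmTol, mzWindow)
            iso <- Filter(function(p)
                abs(rtApex(p) - rtApex(pick$best)) <= isoRtTol,
                detectPeaks(eic1, minScans, minIntensity))
            ipick <- .bestPeak(iso)
            if (!is.null(ipick)) {
                rows[[length(rows) + 1L]] <-
                    .annotationRow(lib$name[e], lib$formula[e],
                                   adducts$label[a], 1L, theo1, ipick$best)
                peaks[[length(peaks) + 1L]] <- ipick$best
            }
        }
    }
    if (!length(rows)) return(.emptyMs1Annotations())
    out <- do.call(rbind, rows)
    out$peak <- peaks
    ord <- order(out$metabolite, out$adduct, out$isotopologue)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "alternates") <- alternates
    out
}

.emptyMs1Annotations <- function() {
    out <- data.frame(metabolite = character(), formula = character(),
                      adduct = character(), isotopologue = integer(),
                      theoretical_mz = numeric(), observed_mz = numeric(),
                      ppm_error = numeric(), rt_apex_min = numeric(),
                      apex_intensity = numeric(), area = numeric(),
                      f = numeric(), n_scans = integer())
    out$peak <- list()
    out
}

#' Group MS1 annotations by metabolite
#'
#' Partitions the annotation table into one group per metabolite name and
#' records each group's apex retention-time spread.
#'
#' @param annotations output of [annotateMs1()].
#' @return named list of annotation data.frames, each carrying an
#'   `rt_spread` attribute (minutes).
#' @export
groupMs1 <- function(annotations) {
    if (!nrow(annotations)) return(stats::setNames(list(), character()))
    lapply(split(annotations, annotations$metabolite), function(g) {
        rownames(g) <- NULL
        attr(g, "rt_spread") <- diff(range(g$rt_apex_min))
        g
    })
}

#' MS1-level quality scores for a metabolite group
#'
#' Computes, for one metabolite's annotated peaks (adducts and
#' isotopologues):
#' \itemize{
#'   \item pairwise PPC over shared scans of the smoothed peaks, with the
#'     two-sided p-value, and pairwise PPS (ratio of asymmetry factors),
#'     with the accept/reject verdict of [scoreVerdict()];
#'   \item IPIR per adduct: monoisotopic over +1 apex intensity. IPIR must
#'     exceed 1 for formulas without S or Br; when the formula contains S
#'     or Br the verdict is suppressed (reported as NA).
#' }
#'
#' @param group one element of [groupMs1()] (or an annotation subset with a
#'   single metabolite).
#' @param ppcCutoff,ppsBand verdict thresholds, see [scoreVerdict()].
#' @param smoothMethod smoother used for the PPC, see [smoothPeak()].
#' @return list with data.frames `pairs` (member_1, member_2, n_shared,
#'   PPC, PPC_p, PPS, verdict), `ipir` (adduct, IPIR, pass) and `members`
#'   (annotation summary incl. f).
#' @export
scoreMs1 <- function(group, ppcCutoff = 0.7, ppsBand = c(0.3, 3),
                     smoothMethod = "smoothing-spline") {
    stopifnot(nrow(group) >= 1L,
              length(unique(group$metabolite)) == 1L)
    lab <- paste0(group$adduct,
                  ifelse(group$isotopologue > 0,
                         paste0(" +", group$isotopologue), ""))
    n <- nrow(group)
    pairs <- list()
    if (n >= 2L) {
        for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
            pc <- .peakPpc(group$peak[[i]], group$peak[[j]],
                           sameChannel = TRUE, smoothMethod = smoothMethod)
            pps <- ppsScore(group$f[i], group$f[j])
            pairs[[length(pairs) + 1L]] <- data.frame(
                member_1 = lab[i], member_2 = lab[j], n_shared = pc$n,
                PPC = pc$ppc, PPC_p = pc$p, PPS = pps,
                verdict = scoreVerdict(pc$ppc, pps, ppcCutoff, ppsBand),
                stringsAsFactors = FALSE)
        }
    }
    pairs <- if (length(pairs)) do.call(rbind, pairs)
             else data.frame(member_1 = character(), member_2 = character(),
                             n_shared = integer(), PPC = numeric(),
                             PPC_p = numeric(), PPS = numeric(),
                             verdict = character())
    hasSBr <- function(formula) {
        if (is.na(formula) || !nzchar(formula)) return(FALSE)
        counts <- parseFormula(formula)
        sum(counts[intersect(c("S", "Br"), names(counts))]) > 0
    }
    ipir <- list()
    for (ad in unique(group$adduct)) {
        m0 <- group[group$adduct == ad & group$isotopologue == 0L, ]
        m1 <- group[group$adduct == ad & group$isotopologue == 1L, ]
        if (nrow(m0) == 1L && nrow(m1) == 1L) {
            r <- m0$apex_intensity / m1$apex_intensity
            suppressed <- hasSBr(m0$formula)
            ipir[[length(ipir) + 1L]] <- data.frame(
                adduct = ad, IPIR = r,
                pass = if (suppressed) NA else r > 1,
                stringsAsFactors = FALSE)
        }
    }
    ipir <- if (length(ipir)) do.call(rbind, ipir)
            else data.frame(adduct = character(), IPIR = numeric(),
                            pass = logical())
    members <- group[, setdiff(names(group), "peak"), drop = FALSE]
    list(pairs = pairs, ipir = ipir, members = members)
}

#' Write MS1 annotation results to CSV
#'
#' One row per annotation; when scores are supplied, the group-level IPIR
#' and the best pairwise PPC/PPS of each member are joined on.
#'
#' @param annotations output of [annotateMs1()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeMs1Results <- function(annotations, path) {
    out <- annotations[, setdiff(names(annotations), "peak"), drop = FALSE]
    utils::write.csv(out, path, row.names = FALSE, na = "")
    invisible(path)
}
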