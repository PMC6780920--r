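## Ground-truth synthetic runs: multiplexed MS1 + per-energy AIF channels
## rendered as (optionally tailed) chromatographic peaks, with m/z jitter
## and uniform noise centroids, written as deterministic mzML.

## Unit-apex peak shape. tau = 0: Gaussian. tau > 0: exponentially
## modified Gaussian (right tail), normalized to unit maximum on a fine
## grid so apex_intensity is honoured. Keep tau >= 0.2 * sigma to stay in
## the numerically stable regime of the erfc formulation.
.peakShape <- function(t, mu, sigma, tau) {
    if (tau <= 0) return(exp(-((t - mu)^2) / (2 * sigma^2)))
    k <- sigma / tau
    erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)
    h <- function(x) exp(0.5 * k^2 - (x - mu) / tau) *
        erfc((k - (x - mu) / sigma) / sqrt(2))
    grid <- seq(mu - 4 * sigma, mu + 4 * sigma + 6 * tau, length.out = 2001L)
    h(t) / max(h(grid))
}

## Continuous-apex RT of the shape (equals mu for a Gaussian).
.shapeApexRt <- function(mu, sigma, tau) {
    if (tau <= 0) return(mu)
    grid <- seq(mu - 4 * sigma, mu + 4 * sigma + 6 * tau, length.out = 4001L)
    grid[which.max(.peakShape(grid, mu, sigma, tau))]
}

#' Ground-truth table for a simulated run
#'
#' Expands an MS/MS library into the trace table [simulateRun()] renders:
#' one precursor trace (channel `"0"`) plus a +1 isotopologue trace per
#' entry, and one trace per library fragment in each fragmentation
#' channel. Defaults emulate a multiplexed electrospray LC-HRMS
#' acquisition: stepped energies 0/5/10/20 eV, ~100x signal over the noise
#' floor, isotope ratio ~8 (a typical CHNO small metabolite), fragment
#' yields of half the precursor response.
#'
#' @param lib an `msms_library`; defaults to 3 compounds of
#'   [demoMsmsLibrary()].
#' @param energies fragmentation channel labels (besides `"0"`).
#' @param rtApex named vector of apex retention times (minutes) per
#'   metabolite; unnamed entries fall back to an even spread.
#' @param apexIntensity precursor apex intensity (counts), recycled.
#' @param isoRatio ground-truth IPIR (monoisotopic / +1 apex), recycled.
#' @param fpRatio fragment/precursor apex ratio: a single number, a vector
#'   recycled over fragments, or a data.frame (`name`, `fragment_mz`,
#'   `energy`, `fp`) for full control. `fp = 0` omits the trace.
#' @param sigma chromatographic peak sigma (minutes), recycled.
#' @param tau exponential tail constant (minutes), 0 for symmetric peaks.
#' @return data.frame with one row per rendered trace: `metabolite`,
#'   `adduct`, `energy`, `role` (precursor/isotopologue/fragment), `mz`,
#'   `rt_apex` (continuous apex), `sigma`, `tau`, `apex_intensity`,
#'   `fp_ratio`, `iso_ratio`.
#' @export
makeTruth <- function(lib = demoMsmsLibrary()[1:3, ],
                      energies = c("5", "10", "20"),
                      rtApex = NULL, apexIntensity = 5e5, isoRatio = 8,
                      fpRatio = 0.5, sigma = 0.03, tau = 0) {
    n <- nrow(lib)
    if (is.null(rtApex))
        rtApex <- stats::setNames(seq(0.9, 0.9 + 0.3 * (n - 1),
                                      by = 0.3)[seq_len(n)], lib$name)
    apexIntensity <- rep_len(apexIntensity, n)
    isoRatio <- rep_len(isoRatio, n)
    sigma <- rep_len(sigma, n)
    tau <- rep_len(tau, n)
    fpTable <- is.data.frame(fpRatio)
    rows <- list()
    addRow <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)
    fragCounter <- 0L
    for (i in seq_len(n)) {
        rt <- unname(rtApex[lib$name[i]])
        apexRt <- .shapeApexRt(rt, sigma[i], tau[i])
        addRow(metabolite = lib$name[i], adduct = lib$adduct[i],
               energy = "0", role = "precursor", mz = lib$precursor_mz[i],
               rt_apex = apexRt, sigma = sigma[i], tau = tau[i],
               apex_intensity = apexIntensity[i], fp_ratio = NA_real_,
               iso_ratio = isoRatio[i])
        if (isoRatio[i] > 0)
            addRow(metabolite = lib$name[i], adduct = lib$adduct[i],
                   energy = "0", role = "isotopologue",
                   mz = isotopologueMz(lib$precursor_mz[i]),
                   rt_apex = apexRt, sigma = sigma[i], tau = tau[i],
                   apex_intensity = apexIntensity[i] / isoRatio[i],
                   fp_ratio = NA_real_, iso_ratio = isoRatio[i])
        fr <- lib$fragments[[i]]
        for (en in energies) for (k in seq_len(nrow(fr))) {
            fp <- if (fpTable) {
                hit <- fpRatio$name == lib$name[i] &
                    abs(fpRatio$fragment_mz - fr$mz[k]) < 1e-4 &
                    fpRatio$energy == en
                if (any(hit)) fpRatio$fp[which(hit)[1]] else 0
            } else {
                fragCounter <- fragCounter + 1L
                rep_len(fpRatio, fragCounter)[fragCounter]
            }
            if (fp <= 0) next
            addRow(metabolite = lib$name[i], adduct = lib$adduct[i],
                   energy = en, role = "fragment", mz = fr$mz[k],
                   rt_apex = apexRt, sigma = sigma[i], tau = tau[i],
                   apex_intensity = apexIntensity[i] * fp, fp_ratio = fp,
                   iso_ratio = NA_real_)
        }
    }
    do.call(rbind, rows)
}

#' @rdname makeTruth
#' @export
demoTruth <- function() makeTruth()

#' Simulate a multiplexed DIA run with known ground truth
#'
#' Renders every trace of a [makeTruth()] table as a chromatographic peak
#' sampled on its channel's interleaved retention-time grid: a Gaussian, or
#' an exponentially modified Gaussian when `tau > 0` (right tail, so the
#' asymmetry factor exceeds 1). Centroid m/z values are jittered uniformly
#' within `mzJitterPpm`; each scan also receives `noisePeaksPerScan` noise
#' centroids uniform in m/z with exponential intensities at `noiseFloor`.
#' The generator is fully seeded: the same arguments and seed give a
#' byte-identical mzML file.
#'
#' @param truth trace table from [makeTruth()] / [demoTruth()].
#' @param path output mzML path, or NULL to skip writing.
#' @param rtRange run retention-time range in minutes.
#' @param channelPeriod scan period per channel in minutes (default 1/60
#'   min = 1 s, i.e. a 4-event multiplex at 250 ms per event).
#' @param mzJitterPpm uniform centroid m/z jitter bound (ppm).
#' @param intensityCv multiplicative detector noise on signal centroids
#'   (coefficient of variation; default 0.02).
#' @param noiseFloor mean intensity of noise centroids (counts).
#' @param noisePeaksPerScan noise centroids per scan.
#' @param mzRange m/z range for noise centroids.
#' @param polarity scan polarity.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return invisibly, a list with `scans` (the [ScanSet-class]), `truth`
#'   (the table, with a `truth_csv` written next to `path` when writing),
#'   and `path`.
#' @export
#' @examples
#' run <- simulateRun(demoTruth(), seed = 7)
#' run$scans
simulateRun <- function(truth, path = NULL, rtRange = c(0.5, 2.5),
                        channelPeriod = 1 / 60, mzJitterPpm = 2,
                        intensityCv = 0.02,
                        noiseFloor = 50, noisePeaksPerScan = 10L,
                        mzRange = c(50, 750), polarity = "positive",
                        seed = 1L) {
    stopifnot(channelPeriod > 0, all(truth$sigma > 0),
              all(truth$apex_intensity > 0))
    set.seed(seed)
    energies <- unique(truth$energy)
    if (!"0" %in% energies) energies <- c("0", energies)
    energies <- energies[order(suppressWarnings(as.numeric(energies)))]
    if (nrow(truth) > 1) {
        sameTrace <- outer(truth$energy, truth$energy, "==") &
            abs(outer(truth$mz, truth$mz, "-")) < 0.01
        diag(sameTrace) <- FALSE
        dRt <- abs(outer(truth$rt_apex, truth$rt_apex, "-"))
        if (any(sameTrace & dRt < channelPeriod))
            warning("truth peaks overlap within one scan period ",
                    "(allowed; intended for valley-split tests)")
    }
    nCh <- length(energies)
    rows <- list(); peaks <- list()
    scanId <- 0L
    times <- seq(rtRange[1], rtRange[2], by = channelPeriod)
    for (ci in seq_along(energies)) {
        en <- energies[ci]
        tr <- truth[truth$energy == en, , drop = FALSE]
        offs <- (ci - 1L) * channelPeriod / nCh
        for (t0 in times) {
            t <- t0 + offs
            scanId <- scanId + 1L
            mzv <- numeric(); iv <- numeric()
            for (r in seq_len(nrow(tr))) {
                y <- tr$apex_intensity[r] *
                    .peakShape(t, .shapeMu(tr[r, ]), tr$sigma[r], tr$tau[r])
                if (y < 1) next
                if (intensityCv > 0)
                    y <- max(y * (1 + stats::rnorm(1, 0, intensityCv)), 0)
                jit <- stats::runif(1, -mzJitterPpm, mzJitterPpm) * 1e-6
                mzv <- c(mzv, tr$mz[r] * (1 + jit))
                iv <- c(iv, y)
            }
            if (noisePeaksPerScan > 0) {
                nm <- stats::runif(noisePeaksPerScan, mzRange[1], mzRange[2])
                ni <- stats::rexp(noisePeaksPerScan, rate = 1 / noiseFloor)
                mzv <- c(mzv, nm); iv <- c(iv, ni)
            }
            ord <- order(mzv)
            rows[[scanId]] <- data.frame(
                scanId = scanId, rt = t,
                msLevel = if (en == "0") 1L else 2L,
                energy = en, polarity = polarity,
                stringsAsFactors = FALSE)
            peaks[[scanId]] <- cbind(mz = mzv[ord], intensity = iv[ord])
        }
    }
    h <- do.call(rbind, rows)
    ord <- order(h$rt)
    h <- h[ord, , drop = FALSE]
    h$scanId <- seq_len(nrow(h))
    scans <- ScanSet(h, peaks[ord])
    if (!is.null(path)) {
        writeMzML(scans, path)
        truthCsv <- paste0(tools::file_path_sans_ext(path), "_truth.csv")
        utils::write.csv(truth, truthCsv, row.names = FALSE, na = "")
    }
    invisible(list(scans = scans, truth = truth, path = path))
}

## rt_apex in the truth table is the continuous apex; recover the EMG
## location parameter mu used to render the trace.
.shapeMu <- function(tr) {
    if (tr$tau <= 0) return(tr$rt_apex)
    ## invert .shapeApexRt numerically: apex(mu) = mu + const(sigma, tau)
    shift <- .shapeApexRt(0, tr$sigma, tr$tau)
    tr$rt_apex - shift
}
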