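## Fixture builders used across the suite. Everything is generated in code;
## no data files.

## A ScanChannel holding the given intensity traces sampled on `rts`
## (minutes). `traces` is a list of list(mz = <numeric>, y = <vector over
## rts>); each scan gets one centroid per trace with y > 0.
channelFromTraces <- function(traces, rts, energy = "0",
                              msLevel = if (energy == "0") 1L else 2L,
                              polarity = "positive", scanId0 = 0L) {
    peaks <- lapply(seq_along(rts), function(i) {
        mz <- vapply(traces, `[[`, 0, "mz")
        y <- vapply(traces, function(tr) tr$y[i], 0)
        keep <- y > 0
        m <- cbind(mz = mz[keep], intensity = y[keep])
        m[order(m[, 1]), , drop = FALSE]
    })
    h <- data.frame(scanId = scanId0 + seq_along(rts), rt = rts,
                    msLevel = msLevel, energy = energy,
                    polarity = polarity, stringsAsFactors = FALSE)
    new("ScanChannel", header = h, peaks = peaks, energy = energy,
        msLevel = msLevel, polarity = polarity)
}

gaussTrace <- function(mz, rts, mu, sigma, A) {
    list(mz = mz, y = A * exp(-((rts - mu)^2) / (2 * sigma^2)))
}

## One detected EICPeak from an explicit intensity profile.
peakFromProfile <- function(y, mz = 100, rts = NULL, ...) {
    if (is.null(rts)) rts <- seq_along(y) / 60
    ch <- channelFromTraces(list(list(mz = mz, y = y)), rts)
    pks <- detectPeaks(extractEic(ch, mz), ...)
    stopifnot(length(pks) == 1L)
    pks[[1]]
}

## Textbook Pearson correlation, the independent oracle for the PPC.
pearsonOracle <- function(x, y) {
    n <- length(x)
    sx <- sum(x); sy <- sum(y)
    num <- sum(x * y) - sx * sy / n
    den <- sqrt((sum(x^2) - sx^2 / n) * (sum(y^2) - sy^2 / n))
    num / den
}

## Minimal mzXML writer (32-bit network-order m/z-int pairs) used to test
## the mzXML reading path.
writeMzXmlFixture <- function(path, scans) {
    b64 <- function(mz, int) {
        v <- as.vector(rbind(mz, int))
        gsub("[\r\n]", "", jsonlite::base64_enc(
            writeBin(as.numeric(v), raw(), size = 4L, endian = "big")))
    }
    one <- function(s) {
        ce <- if (!is.na(s$ce)) sprintf(' collisionEnergy="%s"', s$ce) else ""
        prec <- if (s$level == 2)
            "<precursorMz precursorIntensity=\"0\">400</precursorMz>\n" else ""
        sprintf(paste0(
            '<scan num="%d" msLevel="%d" peaksCount="%d" polarity="%s" ',
            'retentionTime="PT%.3fS"%s>\n%s',
            '<peaks precision="32" byteOrder="network" ',
            'contentType="m/z-int" compressionType="none" ',
            'compressedLen="0">%s</peaks>\n</scan>'),
            s$num, s$level, length(s$mz), s$pol, s$rtSec, ce, prec,
            b64(s$mz, s$int))
    }
    doc <- sprintf(paste0(
        '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
        '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/',
        'mzXML_3.2">\n<msRun scanCount="%d">\n%s\n</msRun>\n</mzXML>'),
        length(scans), paste(vapply(scans, one, ""), collapse = "\n"))
    writeLines(doc, path)
    path
}

## Small single-metabolite truth for fast replicated simulations.
tinyTruth <- function(fp = c(0.5, 0.5), energies = "10", isoRatio = 8,
                      tau = 0) {
    makeTruth(demoMsmsLibrary()[1, ], energies = energies,
              rtApex = c(glutamine = 1.0), isoRatio = isoRatio,
              fpRatio = fp, tau = tau)
}

tinySim <- function(truth, seed, ...) {
    simulateRun(truth, path = NULL, rtRange = c(0.7, 1.3), seed = seed, ...)
}
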