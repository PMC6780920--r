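## Shared small fixture: glutamine spiked as [M+H]+ and [M+NH4]+ with low
## m/z jitter, plus its +1 isotopologues.
glnTwoAdductTruth <- function() {
    m <- monoisotopicMass("C5H10N2O3")
    data.frame(metabolite = "glutamine", adduct = c("[M+H]+", "[M+NH4]+"),
               energy = "0", role = "precursor",
               mz = c(adductMz(m, "[M+H]+"), adductMz(m, "[M+NH4]+")),
               rt_apex = 1.0, sigma = 0.03, tau = 0,
               apex_intensity = c(4e5, 1e5), fp_ratio = NA,
               iso_ratio = NA)
}

withIso <- function(truth, isoRatio = 8) {
    iso <- truth
    iso$role <- "isotopologue"
    iso$mz <- isotopologueMz(iso$mz)
    iso$apex_intensity <- iso$apex_intensity / isoRatio
    rbind(truth, iso)
}

test_that("spiked adducts are annotated with sub-ppm accuracy", {
    run <- simulateRun(withIso(glnTwoAdductTruth()), path = NULL,
                       rtRange = c(0.7, 1.3), mzJitterPpm = 0.5, seed = 21)
    ch <- splitByEnergy(run$scans)[["0"]]
    ann <- annotateMs1(ch, demoMs1Library())
    gln <- ann[ann$metabolite == "glutamine", ]
    expect_setequal(gln$adduct[gln$isotopologue == 0],
                    c("[M+H]+", "[M+NH4]+"))
    expect_true(all(abs(gln$ppm_error) < 1))
    expect_equal(gln$rt_apex_min, rep(1.0, nrow(gln)), tolerance = 0.01)
    ## absent metabolites are not annotated
    expect_false(any(ann$metabolite %in%
                     c("tyrosine", "betaine", "methionine")))
})

test_that("every reported ppm error respects the configured tolerance", {
    for (seed in c(3, 7)) {
        run <- simulateRun(demoTruth(), path = NULL, seed = seed,
                           mzJitterPpm = 4)
        ch <- splitByEnergy(run$scans)[["0"]]
        ann <- annotateMs1(ch, demoMs1Library(), ppmTol = 5)
        expect_gt(nrow(ann), 0)
        expect_true(all(abs(ann$ppm_error) <= 5))
    }
})

test_that("a +1 peak without its monoisotopic anchor is not annotated", {
    truth <- glnTwoAdductTruth()[1, ]
    truth$mz <- isotopologueMz(truth$mz)   # only the +1 trace is present
    run <- simulateRun(truth, path = NULL, rtRange = c(0.7, 1.3),
                       noisePeaksPerScan = 0L, seed = 5)
    ch <- splitByEnergy(run$scans)[["0"]]
    ann <- annotateMs1(ch, demoMs1Library()[1, ])
    expect_equal(nrow(ann), 0L)
})

test_that("library retention times gate annotations when rtTol is set", {
    run <- simulateRun(glnTwoAdductTruth(), path = NULL,
                       rtRange = c(0.7, 1.3), seed = 9)
    ch <- splitByEnergy(run$scans)[["0"]]
    lib <- demoMs1Library()[1, ]          # library rt 1.10, peak at 1.00
    expect_gt(nrow(annotateMs1(ch, lib, rtTol = 0.2)), 0)
    expect_equal(nrow(annotateMs1(ch, lib, rtTol = 0.05)), 0L)
})

test_that("grouping partitions annotations by metabolite", {
    run <- simulateRun(demoTruth(), path = NULL, seed = 13)
    ch <- splitByEnergy(run$scans)[["0"]]
    ann <- annotateMs1(ch, demoMs1Library())
    groups <- groupMs1(ann)
    expect_setequal(names(groups), unique(ann$metabolite))
    expect_equal(sum(vapply(groups, nrow, 0L)), nrow(ann))
    for (g in groups) {
        expect_length(unique(g$metabolite), 1L)
        expect_gte(attr(g, "rt_spread"), 0)
    }
    expect_length(groupMs1(ann[0, ]), 0L)
})

test_that("co-eluting adducts and isotopologues score PPC 1, PPS 1, IPIR r", {
    truth <- withIso(glnTwoAdductTruth(), isoRatio = 8.2)
    run <- simulateRun(truth, path = NULL, rtRange = c(0.7, 1.3),
                       intensityCv = 0, noisePeaksPerScan = 0L, seed = 2)
    ch <- splitByEnergy(run$scans)[["0"]]
    ann <- annotateMs1(ch, demoMs1Library()[1, ])
    sc <- scoreMs1(groupMs1(ann)[["glutamine"]])
    expect_true(all(sc$pairs$PPC > 0.99))
    expect_true(all(abs(sc$pairs$PPS - 1) < 0.35))
    expect_equal(sc$ipir$IPIR, rep(8.2, 2), tolerance = 0.02)
    expect_true(all(sc$ipir$pass))
})

test_that("non-overlapping peaks yield an undefined PPC with a reason", {
    rts <- as.numeric(1:20)
    chA <- channelFromTraces(list(
        gaussTrace(100, rts, 5, 1.2, 1e4),
        gaussTrace(150, rts, 15, 1.2, 1e4)), rts)
    pks <- c(detectPeaks(extractEic(chA, 100), minIntensity = 1),
             detectPeaks(extractEic(chA, 150), minIntensity = 1))
    expect_length(pks, 2L)
    ann <- data.frame(metabolite = "x", formula = "C2H6O",
                      adduct = c("[M+H]+", "[M+Na]+"), isotopologue = 0L,
                      theoretical_mz = c(100, 150),
                      observed_mz = c(100, 150), ppm_error = 0,
                      rt_apex_min = c(5, 15), apex_intensity = 1e4,
                      area = 1, f = c(1, 1), n_scans = 10L)
    ann$peak <- pks
    sc <- scoreMs1(ann)
    expect_true(is.na(sc$pairs$PPC))
    expect_identical(sc$pairs$verdict, "insufficient scans")
})

test_that("IPIR verdict is suppressed for S- or Br-containing formulas", {
    truth <- makeTruth(demoMsmsLibrary()[demoMsmsLibrary()$name ==
                                         "glutathione", ],
                       energies = character(0),
                       rtApex = c(glutathione = 1.0), isoRatio = 6)
    run <- simulateRun(truth, path = NULL, rtRange = c(0.7, 1.3), seed = 4)
    ch <- splitByEnergy(run$scans)[["0"]]
    ann <- annotateMs1(ch, demoMs1Library())
    sc <- scoreMs1(groupMs1(ann)[["glutathione"]])
    expect_equal(nrow(sc$ipir), 1L)
    expect_true(is.na(sc$ipir$pass))   # sulfur in C10H17N3O6S
    expect_equal(sc$ipir$IPIR, 6, tolerance = 0.1)
})

test_that("PPC is symmetric, bounded, and PPS obeys the reciprocal identity", {
    set.seed(77)
    for (i in 1:15) {
        n <- sample(6:20, 1)
        x <- runif(n, 0, 1e4); y <- runif(n, 0, 1e4)
        a <- ppcScore(x, y); b <- ppcScore(y, x)
        expect_equal(a$ppc, b$ppc)
        expect_true(abs(a$ppc) <= 1)
        expect_equal(ppcScore(x, x)$ppc, 1)
        f1 <- runif(1, 0.2, 4); f2 <- runif(1, 0.2, 4)
        expect_equal(ppsScore(f1, f2) * ppsScore(f2, f1), 1)
    }
    expect_true(is.na(ppsScore(1.2, 0)))
})

test_that("isotope-ratio recovery stays within a few percent (seeded)", {
    r <- 8
    est <- vapply(1:5, function(s) {
        run <- tinySim(tinyTruth(fp = 0, energies = character(0),
                                 isoRatio = r), seed = 100 + s)
        ch <- splitByEnergy(run$scans)[["0"]]
        sc <- scoreMs1(groupMs1(annotateMs1(ch,
                                            demoMs1Library()[1, ]))[[1]])
        sc$ipir$IPIR
    }, 0)
    expect_lt(abs(median(est) - r) / r, 0.05)
})
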