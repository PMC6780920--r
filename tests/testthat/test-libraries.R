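ms1Csv <- function(path, rows) {
    writeLines(c("name,formula,neutral_mass,polarity,rt", rows), path)
    path
}
msmsCsv <- function(path, rows,
                    hdr = "name,adduct,precursor_mz,fragment_mz,ce,polarity") {
    writeLines(c(hdr, rows), path)
    path
}

test_that("MS1 library masses come from the formula when absent", {
    f <- withr::local_tempfile(fileext = ".csv")
    lib <- loadMs1Library(ms1Csv(f, c(
        "glutamine,C5H10N2O3,,positive,1.2",
        "urea,CH4N2O,60.032363,any,",
        "taurine,,125.014664,negative,0.8")))
    expect_equal(nrow(lib), 3L)
    expect_equal(round(lib$neutral_mass[lib$name == "glutamine"], 4),
                 146.0691)
    expect_equal(lib$polarity, c("positive", "any", "negative"))
    expect_true(is.na(lib$rt[2]))
})

test_that("MS1 library loading enforces its contract", {
    f <- withr::local_tempfile(fileext = ".csv")
    expect_warning(lib <- loadMs1Library(ms1Csv(f, character())), "empty")
    expect_equal(nrow(lib), 0L)
    expect_error(loadMs1Library(ms1Csv(f, c(
        "glutamine,C5H10N2O3,,positive,1.2",
        "glutamine,C5H10N2O3,,positive,1.3"))), "duplicate")
    expect_error(loadMs1Library(ms1Csv(f, "x,C2H6O,abc,any,")),
                 "non-numeric")
    writeLines(c("compound,mass", "x,100"), f)
    expect_error(loadMs1Library(f), "name")
    expect_error(loadMs1Library(ms1Csv(f, "orphan,,,any,")),
                 "neither")
})

test_that("MS/MS library pools, sorts and 1-ppm-deduplicates fragments", {
    f <- withr::local_tempfile(fileext = ".csv")
    lib <- loadMsmsLibrary(msmsCsv(f, c(
        "glutamine,[M+H]+,147.0764,130.0499,5,positive",
        "glutamine,[M+H]+,147.0764,84.0444,5,positive",
        "glutamine,[M+H]+,147.0764,84.04441,10,positive",  # 0.1 ppm dup
        "phenylacetylglutamine,[M+H]+,265.1183,84.0444,10,positive",
        "phenylacetylglutamine,[M+H]+,265.1183,130.0499,10,positive",
        "phenylacetylglutamine,[M+H]+,265.1183,136.0756,10,positive",
        "phenylacetylglutamine,[M+H]+,265.1183,147.0763,10,positive")))
    expect_equal(nrow(lib), 2L)
    gln <- lib$fragments[[which(lib$name == "glutamine")]]
    expect_equal(nrow(gln), 2L)
    expect_false(is.unsorted(gln$mz))
    pag <- lib$fragments[[which(lib$name == "phenylacetylglutamine")]]
    expect_equal(nrow(pag), 4L)
})

test_that("fragment/precursor relations are enforced at load", {
    f <- withr::local_tempfile(fileext = ".csv")
    ## survivor ion at the precursor m/z is fine
    lib <- loadMsmsLibrary(msmsCsv(f,
        "glutamine,[M+H]+,147.0764,147.0764,0,positive"))
    expect_equal(lib$n_fragments, 1L)
    expect_error(loadMsmsLibrary(msmsCsv(f,
        "glutamine,[M+H]+,147.0764,150.0000,0,positive")), "0.5 Da")
    expect_error(loadMsmsLibrary(msmsCsv(f,
        "glutamine,[M+H]+,148.9000,146.06914,84.0444,0,positive",
        hdr = "name,adduct,precursor_mz,neutral_mass,fragment_mz,ce,polarity")),
        "disagrees")
})

test_that("the wide fragments layout loads like the long one", {
    f1 <- withr::local_tempfile(fileext = ".csv")
    f2 <- withr::local_tempfile(fileext = ".csv")
    long <- loadMsmsLibrary(msmsCsv(f1, c(
        "glutamine,[M+H]+,147.0764,84.0444,,positive",
        "glutamine,[M+H]+,147.0764,130.0499,,positive")))
    writeLines(c("name,adduct,precursor_mz,fragments,polarity",
                 "glutamine,[M+H]+,147.0764,84.0444;130.0499,positive"), f2)
    wide <- loadMsmsLibrary(f2)
    expect_equal(wide$fragments[[1]]$mz, long$fragments[[1]]$mz)
})

test_that("library round trips are lossless", {
    d <- withr::local_tempdir()
    ms1 <- demoMs1Library()
    p1 <- file.path(d, "ms1.csv")
    writeMs1Library(ms1, p1)
    back1 <- loadMs1Library(p1)
    expect_equal(as.data.frame(back1), as.data.frame(ms1),
                 tolerance = 1e-9)
    msms <- demoMsmsLibrary()
    p2 <- file.path(d, "msms.csv")
    writeMsmsLibrary(msms, p2)
    back2 <- loadMsmsLibrary(p2)      # loader sorts by (name, adduct)
    expect_setequal(back2$name, msms$name)
    j <- match(msms$name, back2$name)
    expect_equal(back2$precursor_mz[j], msms$precursor_mz,
                 tolerance = 1e-9)
    for (i in seq_len(nrow(msms)))
        expect_equal(back2$fragments[[j[i]]]$mz,
                     sort(msms$fragments[[i]]$mz), tolerance = 1e-9)
})

test_that("curation checks flag sub-50 fragment sets and ubiquitous ions", {
    f <- withr::local_tempfile(fileext = ".csv")
    many <- vapply(1:8, function(i)
        sprintf("cmp%d,[M+H]+,%.4f,72.0444,,positive", i, 150 + i),
        "")
    lib <- loadMsmsLibrary(msmsCsv(f, c(
        many,
        "lowmass,[M+H]+,61.0,49.9,,positive",
        "lowmass2,[M+H]+,61.0,48.2,,positive",
        "clean,[M+H]+,147.0764,84.0444,,positive",
        "clean2,[M+H]+,166.0863,103.0542,,positive",
        "clean2b,[M+H]+,166.0864,120.0808,,positive")))
    rep <- validateLibrary(lib, ubiquityK = 5L)
    expect_true(all(c("cmp1", "lowmass", "lowmass2") %in% rep$name))
    expect_setequal(unique(rep$flag[rep$name == "lowmass"]),
                    "all_fragments_below_50")
    expect_true("single_ubiquitous_fragment" %in%
                rep$flag[rep$name == "cmp1"])
    expect_false("clean" %in% rep$name)
    pruned <- validateLibrary(lib, ubiquityK = 5L, strict = TRUE)
    expect_false(any(pruned$name %in% rep$name))
    ## re-validation of the pruned library is clean (idempotent)
    expect_equal(nrow(validateLibrary(pruned, ubiquityK = 5L)), 0L)
})

test_that("the demo libraries reproduce the standard fragment m/z values", {
    msms <- demoMsmsLibrary()
    gln <- msms$fragments[[which(msms$name == "glutamine")]]$mz
    expect_equal(round(sort(gln), 4), c(84.0444, 130.0499))
    phe <- msms$fragments[[which(msms$name == "phenylalanine")]]$mz
    expect_equal(round(sort(phe), 4), c(103.0542, 120.0808))
    pag <- msms$fragments[[
        which(msms$name == "phenylacetylglutamine")]]$mz
    expect_equal(round(sort(pag), 4),
                 c(84.0444, 130.0499, 136.0757, 147.0764))
    expect_equal(round(msms$precursor_mz[msms$name == "glutamine"], 4),
                 147.0764)
})
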