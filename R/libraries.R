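## CSV metabolite libraries: the neutral-mass MS1 library and the AIF MS/MS
## library, plus the curation validity checks.
##
## Frozen dialects (RFC 4180, UTF-8, Da and minutes):
##   MS1:   name, formula, neutral_mass, polarity, rt
##          (formula or neutral_mass may be empty, not both)
##   MS/MS: name, adduct, precursor_mz, fragment_mz, ce, polarity
##          (long layout: one row per fragment; a wide layout with a single
##          semicolon-separated `fragments` column is also accepted)

.normPolarity <- function(x) {
    x <- tolower(trimws(ifelse(is.na(x), "", x)))
    x[x %in% c("", "any", "neutral", "both")] <- "any"
    bad <- !x %in% c("any", "positive", "negative")
    if (any(bad))
        stop("invalid polarity value(s): ", paste(unique(x[bad]),
                                                  collapse = ", "))
    x
}

#' Load a neutral-mass MS1 library
#'
#' Reads the MS1 CSV dialect (`name, formula, neutral_mass, polarity, rt`).
#' When `neutral_mass` is missing for a row it is computed from `formula`
#' via [monoisotopicMass()]. Duplicate (name, polarity) combinations are
#' rejected.
#'
#' @param path CSV file path.
#' @return data.frame of class `ms1_library` with columns `name`, `formula`,
#'   `neutral_mass` (Da), `polarity` (`any`/`positive`/`negative`), `rt`
#'   (minutes, NA when unannotated).
#' @export
loadMs1Library <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"name" %in% names(d)) stop("missing mandatory column: name")
    if (!any(c("formula", "neutral_mass") %in% names(d)))
        stop("missing mandatory column: formula or neutral_mass")
    if (!nrow(d)) {
        warning("library is empty (header only)")
        return(.asMs1Library(data.frame(name = character(),
                                        formula = character(),
                                        neutral_mass = numeric(),
                                        polarity = character(),
                                        rt = numeric())))
    }
    for (col in c("formula", "neutral_mass", "polarity", "rt"))
        if (!col %in% names(d)) d[[col]] <- NA
    if (is.character(d$neutral_mass)) {
        conv <- suppressWarnings(as.numeric(d$neutral_mass))
        bad <- which(!is.na(d$neutral_mass) & nzchar(trimws(d$neutral_mass)) &
                     is.na(conv))
        if (length(bad))
            stop("non-numeric neutral_mass in row(s): ",
                 paste(bad, collapse = ", "))
        d$neutral_mass <- conv
    }
    need <- is.na(d$neutral_mass)
    if (any(need)) {
        noFormula <- need & (is.na(d$formula) | !nzchar(trimws(d$formula)))
        if (any(noFormula))
            stop("row(s) with neither neutral_mass nor formula: ",
                 paste(which(noFormula), collapse = ", "))
        d$neutral_mass[need] <- vapply(d$formula[need], monoisotopicMass,
                                       numeric(1))
    }
    if (any(d$neutral_mass <= 0)) stop("neutral_mass must be > 0")
    d$polarity <- .normPolarity(d$polarity)
    d$rt <- suppressWarnings(as.numeric(d$rt))
    if (any(!is.na(d$rt) & d$rt < 0)) stop("rt must be >= 0")
    key <- paste(d$name, d$polarity)
    if (anyDuplicated(key))
        stop("duplicate library entries: ",
             paste(unique(key[duplicated(key)]), collapse = "; "))
    .asMs1Library(d[, c("name", "formula", "neutral_mass", "polarity", "rt")])
}

.asMs1Library <- function(d) {
    rownames(d) <- NULL
    class(d) <- c("ms1_library", "data.frame")
    d
}

#' @rdname loadMs1Library
#' @param lib a library data.frame.
#' @export
writeMs1Library <- function(lib, path) {
    utils::write.csv(as.data.frame(lib)[, c("name", "formula",
                                            "neutral_mass", "polarity",
                                            "rt")],
                     path, row.names = FALSE, na = "")
    invisible(path)
}

## Deduplicate a sorted fragment table within `ppm` relative tolerance.
.dedupeFragments <- function(fr, ppm = 1) {
    fr <- fr[order(fr$mz), , drop = FALSE]
    keep <- rep(TRUE, nrow(fr))
    last <- -Inf
    for (i in seq_len(nrow(fr))) {
        if (1e6 * (fr$mz[i] - last) / last <= ppm && is.finite(last))
            keep[i] <- FALSE
        else last <- fr$mz[i]
    }
    rownames(fr) <- NULL
    fr[keep, , drop = FALSE]
}

#' Load an AIF MS/MS library
#'
#' Reads the MS/MS CSV dialect (`name, adduct, precursor_mz, fragment_mz,
#' ce, polarity`; long layout, one row per fragment), or the wide variant
#' with a semicolon-separated `fragments` column. Fragments are pooled per
#' (name, adduct), sorted ascending and deduplicated within 1 ppm. A
#' fragment more than 0.5 Da above its precursor is a row error; a fragment
#' equal to the precursor (the in-source survivor ion) is accepted. When a
#' `neutral_mass` column is present the precursor m/z is cross-checked
#' against the adduct computation within 5 ppm.
#'
#' @param path CSV file path.
#' @param registry adduct registry for the neutral-mass cross-check.
#' @return data.frame of class `msms_library`, one row per (name, adduct),
#'   with columns `name`, `adduct`, `precursor_mz`, `polarity`,
#'   `n_fragments` and a list column `fragments` (data.frames with `mz`,
#'   `ce`).
#' @export
loadMsmsLibrary <- function(path, registry = defaultAdducts()) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    for (col in c("name", "adduct", "precursor_mz"))
        if (!col %in% names(d)) stop("missing mandatory column: ", col)
    if ("fragments" %in% names(d) && !"fragment_mz" %in% names(d)) {
        ## wide layout -> long
        frs <- strsplit(as.character(d$fragments), ";")
        d <- d[rep(seq_len(nrow(d)), lengths(frs)), , drop = FALSE]
        d$fragment_mz <- as.numeric(trimws(unlist(frs)))
        d$fragments <- NULL
    }
    if (!"fragment_mz" %in% names(d))
        stop("missing mandatory column: fragment_mz (or fragments)")
    if (!"ce" %in% names(d)) d$ce <- NA
    if (!"polarity" %in% names(d)) d$polarity <- NA
    if (!nrow(d)) {
        warning("library is empty (header only)")
        out <- data.frame(name = character(), adduct = character(),
                          precursor_mz = numeric(), polarity = character(),
                          n_fragments = integer())
        out$fragments <- list()
        class(out) <- c("msms_library", "data.frame")
        return(out)
    }
    d$precursor_mz <- as.numeric(d$precursor_mz)
    d$fragment_mz <- as.numeric(d$fragment_mz)
    bad <- which(d$fragment_mz > d$precursor_mz + 0.5)
    if (length(bad))
        stop("fragment m/z exceeds precursor by more than 0.5 Da in row(s): ",
             paste(bad, collapse = ", "))
    d$polarity <- .normPolarity(d$polarity)
    if ("neutral_mass" %in% names(d)) {
        theo <- mapply(function(m, a) adductMz(m, a, registry),
                       as.numeric(d$neutral_mass), d$adduct)
        off <- which(abs(ppmError(d$precursor_mz, theo)) > 5)
        if (length(off))
            stop("precursor_mz disagrees with neutral_mass + adduct ",
                 "(> 5 ppm) in row(s): ", paste(off, collapse = ", "))
    }
    key <- paste(d$name, d$adduct, sep = "\r")
    entries <- lapply(split(seq_len(nrow(d)), key), function(i) {
        fr <- .dedupeFragments(data.frame(mz = d$fragment_mz[i],
                                          ce = d$ce[i]))
        list(name = d$name[i[1]], adduct = d$adduct[i[1]],
             precursor_mz = d$precursor_mz[i[1]],
             polarity = d$polarity[i[1]], fragments = fr)
    })
    entries <- entries[order(vapply(entries, `[[`, "", "name"),
                             vapply(entries, `[[`, "", "adduct"))]
    out <- data.frame(
        name = vapply(entries, `[[`, "", "name"),
        adduct = vapply(entries, `[[`, "", "adduct"),
        precursor_mz = vapply(entries, `[[`, 0, "precursor_mz"),
        polarity = vapply(entries, `[[`, "", "polarity"),
        n_fragments = vapply(entries, function(e) nrow(e$fragments), 0L),
        stringsAsFactors = FALSE)
    out$fragments <- lapply(entries, `[[`, "fragments")
    rownames(out) <- NULL
    class(out) <- c("msms_library", "data.frame")
    out
}

#' @rdname loadMsmsLibrary
#' @param lib an `msms_library`.
#' @export
writeMsmsLibrary <- function(lib, path) {
    long <- do.call(rbind, lapply(seq_len(nrow(lib)), function(i) {
        fr <- lib$fragments[[i]]
        data.frame(name = lib$name[i], adduct = lib$adduct[i],
                   precursor_mz = lib$precursor_mz[i],
                   fragment_mz = fr$mz, ce = fr$ce,
                   polarity = lib$polarity[i], stringsAsFactors = FALSE)
    }))
    utils::write.csv(long, path, row.names = FALSE, na = "")
    invisible(path)
}

#' Curation validity checks for an MS/MS library
#'
#' Applies the library-curation rules: flags entries whose every fragment
#' lies below m/z 50, and entries supported by a single fragment that is
#' ubiquitous — i.e. the same m/z (within `ppmTol`) occurs in more than
#' `ubiquityK` other entries. Validation reports; it only removes entries
#' when `strict = TRUE`.
#'
#' @param lib an `msms_library` from [loadMsmsLibrary()].
#' @param ubiquityK how many other entries may share a lone fragment before
#'   it counts as ubiquitous (default 5).
#' @param ppmTol m/z match tolerance for the ubiquity check (default 5 ppm).
#' @param strict if TRUE, return the library pruned of flagged entries
#'   (report attached as attribute `"report"`); otherwise return the report.
#' @return data.frame report (`name`, `adduct`, `flag`, `detail`), or the
#'   pruned library when `strict`.
#' @export
validateLibrary <- function(lib, ubiquityK = 5L, ppmTol = 5,
                            strict = FALSE) {
    stopifnot(inherits(lib, "msms_library"))
    allFrag <- unlist(lapply(lib$fragments, `[[`, "mz"))
    fragOwner <- rep(seq_len(nrow(lib)),
                     vapply(lib$fragments, nrow, 0L))
    rep_rows <- list()
    for (i in seq_len(nrow(lib))) {
        fr <- lib$fragments[[i]]$mz
        if (length(fr) && all(fr < 50))
            rep_rows[[length(rep_rows) + 1L]] <- data.frame(
                name = lib$name[i], adduct = lib$adduct[i],
                flag = "all_fragments_below_50",
                detail = paste(sprintf("%.4f", fr), collapse = ";"))
        if (length(fr) == 1L) {
            shared <- sum(fragOwner != i &
                          abs(ppmError(allFrag, fr)) <= ppmTol)
            if (shared > ubiquityK)
                rep_rows[[length(rep_rows) + 1L]] <- data.frame(
                    name = lib$name[i], adduct = lib$adduct[i],
                    flag = "single_ubiquitous_fragment",
                    detail = sprintf("%.4f shared by %d other entries",
                                     fr, shared))
        }
    }
    report <- if (length(rep_rows)) do.call(rbind, rep_rows)
              else data.frame(name = character(), adduct = character(),
                              flag = character(), detail = character())
    if (!strict) return(report)
    drop <- paste(lib$name, lib$adduct) %in%
        paste(report$name, report$adduct)
    pruned <- lib[!drop, , drop = FALSE]
    rownames(pruned) <- NULL
    class(pruned) <- class(lib)
    attr(pruned, "report") <- report
    pruned
}

## ---- demo libraries (computed from formulas, no stored data) ----

.demoCompounds <- function() {
    ## name, neutral formula, fragment cation formulas, demo RT (min)
    list(
        list(name = "glutamine", formula = "C5H10N2O3", rt = 1.10,
             frags = c("C4H6NO", "C5H8NO3")),
        list(name = "phenylalanine", formula = "C9H11NO2", rt = 1.55,
             frags = c("C8H7", "C8H10N")),
        list(name = "phenylacetylglutamine", formula = "C13H16N2O4",
             rt = 2.05,
             frags = c("C4H6NO", "C5H8NO3", "C8H10NO", "C5H11N2O3")),
        list(name = "glutathione", formula = "C10H17N3O6S", rt = 1.35,
             frags = c("C2H6NS", "C4H6NO3", "C5H6NO2S", "C5H8NO3",
                       "C4H6NO")),
        list(name = "methionine", formula = "C5H11NO2S", rt = 1.75,
             frags = c("C4H10NS", "C3H6NS", "C4H6NO2")),
        list(name = "tyrosine", formula = "C9H11NO3", rt = 1.25,
             frags = c("C8H10NO", "C7H7O", "C7H7")),
        list(name = "betaine", formula = "C5H11NO2", rt = 0.85,
             frags = c("C4H10N", "C3H8N")),
        list(name = "creatinine", formula = "C4H7N3O", rt = 0.95,
             frags = c("C3H6N3", "C2H6N3")),
        list(name = "tryptophan", formula = "C11H12N2O2", rt = 2.35,
             frags = c("C10H8N", "C9H8N")),
        list(name = "histidine", formula = "C6H9N3O2", rt = 0.75,
             frags = c("C5H8N3", "C4H6N2")),
        list(name = "citrulline", formula = "C6H13N3O3", rt = 1.05,
             frags = c("C5H9N2O", "C6H11N2O2")),
        list(name = "glutamic acid", formula = "C5H9NO4", rt = 1.15,
             frags = c("C4H6NO", "C5H8NO3")),
        list(name = "serine", formula = "C3H7NO3", rt = 0.65,
             frags = c("C2H6NO", "C3H6NO2")),
        list(name = "carnitine", formula = "C7H15NO3", rt = 0.90,
             frags = c("C4H5O2", "C7H14NO2")),
        list(name = "alanine", formula = "C3H7NO2", rt = 0.55,
             frags = c("C3H6NO"))
    )
}

#' Demo metabolite libraries
#'
#' A small positive-mode library of common urinary/cellular metabolites
#' (glutamine, phenylalanine, phenylacetylglutamine, glutathione,
#' methionine, tyrosine, betaine, ...) built at call time from molecular
#' formulas: neutral masses via [monoisotopicMass()], fragment m/z via
#' [fragmentCationMz()]. `demoMs1Library()` returns the neutral-mass
#' library; `demoMsmsLibrary()` the matching `[M+H]+` AIF library.
#'
#' @return an `ms1_library` / `msms_library` data.frame.
#' @export
#' @examples
#' demoMs1Library()
demoMs1Library <- function() {
    cmp <- .demoCompounds()
    .asMs1Library(data.frame(
        name = vapply(cmp, `[[`, "", "name"),
        formula = vapply(cmp, `[[`, "", "formula"),
        neutral_mass = vapply(cmp, function(x) monoisotopicMass(x$formula),
                              0),
        polarity = "positive",
        rt = vapply(cmp, `[[`, 0, "rt"),
        stringsAsFactors = FALSE))
}

#' @rdname demoMs1Library
#' @export
demoMsmsLibrary <- function() {
    cmp <- .demoCompounds()
    out <- data.frame(
        name = vapply(cmp, `[[`, "", "name"),
        adduct = "[M+H]+",
        precursor_mz = vapply(cmp, function(x)
            adductMz(monoisotopicMass(x$formula), "[M+H]+"), 0),
        polarity = "positive",
        n_fragments = vapply(cmp, function(x) length(x$frags), 0L),
        stringsAsFactors = FALSE)
    out$fragments <- lapply(cmp, function(x)
        .dedupeFragments(data.frame(mz = vapply(x$frags, fragmentCationMz,
                                                0, USE.NAMES = FALSE),
                                    ce = NA)))
    class(out) <- c("msms_library", "data.frame")
    out
}
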