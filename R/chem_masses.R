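## Exact-mass arithmetic: formulas, adducts, fragment cations, ppm errors.

## Monoisotopic atomic masses (Da), IUPAC values, >= 6 decimals.
.ATOMIC_MASS <- c(
    H  = 1.00782503207,
    D  = 2.01410177785,
    C  = 12.0,
    N  = 14.0030740048,
    O  = 15.9949146196,
    F  = 18.99840322,
    Na = 22.9897692809,
    Mg = 23.9850417,
    Si = 27.9769265325,
    P  = 30.97376163,
    S  = 31.97207100,
    Cl = 34.96885268,
    K  = 38.96370668,
    Ca = 39.96259098,
    Fe = 55.9349375,
    Se = 73.9224764,
    Br = 78.9183371,
    I  = 126.904473
)

## Physical constants (Da)
.ELECTRON_MASS <- 0.00054858
.PROTON_MASS <- 1.007276
.C13_OFFSET <- 1.003355   # 13C - 12C, the dominant +1 channel for CHNO

#' Parse a molecular formula
#'
#' Turns a Hill-style formula string such as `"C5H10N2O3"` into a named
#' integer vector of element counts. Element symbols must be in the built-in
#' monoisotopic mass table; anything else is rejected by name.
#'
#' @param formula a formula string, or an already-named numeric vector of
#'   element counts (returned unchanged after validation).
#' @return named integer vector of element counts.
#' @export
#' @examples
#' parseFormula("C5H10N2O3")
parseFormula <- function(formula) {
    if (is.numeric(formula)) {
        counts <- formula
    } else {
        stopifnot(is.character(formula), length(formula) == 1L,
                  nzchar(formula))
        m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
        toks <- regmatches(formula, list(m))[[1]]
        if (sum(attr(m, "match.length")) != nchar(formula))
            stop("cannot parse formula: '", formula, "'")
        sym <- sub("[0-9]*$", "", toks)
        n <- as.integer(ifelse(grepl("[0-9]$", toks),
                               sub("^[A-Za-z]+", "", toks), "1"))
        counts <- tapply(n, sym, sum)
        counts <- stats::setNames(as.integer(counts), names(counts))
    }
    bad <- setdiff(names(counts), names(.ATOMIC_MASS))
    if (length(bad))
        stop("unknown element(s): ", paste(bad, collapse = ", "))
    if (any(counts < 0)) stop("element counts must be non-negative")
    if (sum(counts) == 0) stop("formula must contain at least one atom")
    counts
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of element counts times exact monoisotopic atomic masses from the
#' built-in IUPAC table.
#'
#' @param formula formula string or named count vector (see [parseFormula()]).
#' @return neutral monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopicMass("C5H10N2O3")  # glutamine, 146.0691
monoisotopicMass <- function(formula) {
    counts <- parseFormula(formula)
    sum(counts * .ATOMIC_MASS[names(counts)])
}

#' Built-in adduct registry
#'
#' The electrospray adducts used by default for MS1 annotation. `delta` is
#' the mass shift in Da added to the neutral monoisotopic mass before
#' dividing by |charge|; it already accounts for the electron, so
#' `[M+H]+` adds the proton mass 1.007276 Da. Users may extend the registry
#' with [registerAdduct()] or supply their own data.frame with the same
#' columns (`label`, `delta`, `charge`, `polarity`).
#'
#' @return data.frame with columns `label`, `delta`, `charge`, `polarity`.
#' @export
#' @examples
#' defaultAdducts()
defaultAdducts <- function() {
    data.frame(
        label = c("[M+H]+", "[M+NH4]+", "[M+Na]+", "[M-H]-"),
        delta = c(1.007276, 18.033823, 22.989218, -1.007276),
        charge = c(1L, 1L, 1L, -1L),
        polarity = c("positive", "positive", "positive", "negative"),
        stringsAsFactors = FALSE)
}

#' @rdname defaultAdducts
#' @param registry an adduct registry data.frame.
#' @param label adduct label, e.g. `"[M+K]+"`.
#' @param delta mass shift in Da (electron already accounted for).
#' @param charge signed integer charge; its sign must match `polarity`.
#' @param polarity `"positive"` or `"negative"`.
#' @export
registerAdduct <- function(registry, label, delta, charge, polarity) {
    charge <- as.integer(charge)
    if (charge == 0L) stop("adduct charge must be non-zero")
    polarity <- match.arg(polarity, c("positive", "negative"))
    if ((charge > 0L) != (polarity == "positive"))
        stop("adduct polarity inconsistent with charge sign")
    rbind(registry,
          data.frame(label = label, delta = delta, charge = charge,
                     polarity = polarity, stringsAsFactors = FALSE))
}

.lookupAdduct <- function(adduct, registry = defaultAdducts()) {
    i <- match(adduct, registry$label)
    if (is.na(i))
        stop("unknown adduct '", adduct, "'; known: ",
             paste(registry$label, collapse = ", "))
    registry[i, ]
}

#' Adduct m/z from a neutral mass
#'
#' m/z = (neutral mass + adduct delta) / |charge|.
#'
#' @param neutralMass neutral monoisotopic mass in Da (>= 0).
#' @param adduct adduct label present in `registry`.
#' @param registry adduct registry, see [defaultAdducts()].
#' @return m/z in Da per unit charge.
#' @export
#' @examples
#' adductMz(146.06914, "[M+H]+")   # glutamine [M+H]+, 147.0764
adductMz <- function(neutralMass, adduct, registry = defaultAdducts()) {
    stopifnot(all(neutralMass >= 0))
    a <- .lookupAdduct(adduct, registry)
    (neutralMass + a$delta) / abs(a$charge)
}

#' m/z of a singly charged fragment cation
#'
#' Monoisotopic mass of the fragment formula minus one electron mass
#' (0.000549 Da), matching how AIF library fragment m/z values are tabulated.
#'
#' @param formula fragment formula (the `+` suffix may be included).
#' @return fragment m/z in Da.
#' @export
#' @examples
#' fragmentCationMz("C4H6NO")  # 84.0444, the glutamine/glutathione fragment
fragmentCationMz <- function(formula) {
    if (is.character(formula)) formula <- sub("\\+$", "", formula)
    monoisotopicMass(formula) - .ELECTRON_MASS
}

#' Isotopologue m/z offset
#'
#' m/z of the +k isotopologue, offset by k x 1.003355 / |charge| from the
#' monoisotopic peak (the 13C channel, dominant for CHNO metabolites).
#'
#' @param mz monoisotopic m/z.
#' @param k isotopologue index (default 1).
#' @param charge absolute charge (default 1).
#' @return isotopologue m/z.
#' @export
isotopologueMz <- function(mz, k = 1L, charge = 1L) {
    mz + k * .C13_OFFSET / abs(charge)
}

#' Signed relative mass error in ppm
#'
#' 1e6 x (observed - theoretical) / theoretical.
#'
#' @param observed observed m/z (vectorized).
#' @param theoretical theoretical m/z (> 0).
#' @return signed error in ppm.
#' @export
#' @examples
#' ppmError(147.0771, 147.0764)  # ~ +4.76 ppm
ppmError <- function(observed, theoretical) {
    stopifnot(all(theoretical > 0))
    1e6 * (observed - theoretical) / theoretical
}
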