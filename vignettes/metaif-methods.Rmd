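---
title: "Annotation and scoring of multiplexed AIF metabolomics data: methods"
author: "metaif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metaif methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaif)
```

## The problem

In all-ion-fragmentation (AIF) acquisitions the quadrupole passes a wide
m/z range (or everything) into the collision cell, and the instrument
cycles through a full-scan MS¹ event plus one MS/MS event per collision
energy. The result is a single file of interleaved scans in which every
MS/MS spectrum is a mixture of fragments from all co-eluting precursors.
Annotation therefore has two parts: a bookkeeping part — demultiplexing
scans into per-energy channels — and an inference part — deciding, for
each library precursor, which fragment signals in a fragmentation channel
actually belong to it. `metaif` resolves the inference chromatographically:
a fragment belongs to a precursor if its extracted-ion-chromatogram (EIC)
peak co-elutes with the precursor's peak, and the association is then
graded with shape and correlation statistics rather than accepted on mass
match alone.

## The procedure

1. **Demultiplexing.** Scans are partitioned by their recorded
   collision-energy label (`splitByEnergy()`). Energy 0 at any recorded MS
   level is the MS¹ channel: converters differ in whether AIF scans are
   labelled level 1 or 2, so keying on the energy label alone is the robust
   choice. Files lacking per-spectrum energy metadata can be demultiplexed
   positionally with a user-supplied cycle (e.g. `c(0, 5, 10, 20)`).
   Polarity is a filter applied before splitting, because
   polarity-switching instruments interleave both modes in one file.

2. **Targeted extraction.** For a target m/z, each scan contributes its
   most intense centroid within the tolerance window, or a zero
   placeholder (`extractEic()`). The window is the tighter of a relative
   (5 ppm) and an absolute (0.005 Da) tolerance; for metabolite-range
   masses (< 1000 Da) the ppm term binds, and the absolute cap only takes
   over above m/z 1000. Per-scan signed ppm deviations are retained for QC
   plotting (`plotEic()`).

3. **Peak detection** (`detectPeaks()`). Maximal runs of consecutive
   above-threshold points are split at interior local minima that drop
   below a fraction (default 0.5) of the smaller flanking apex. This
   EIC-first targeted design replaces untargeted whole-plane peak picking:
   the downstream contract (a list of per-target chromatographic peaks) is
   identical, and the targeted workflow never needs features away from
   library masses.

4. **Scoring.** Matched peaks are spline-smoothed and evaluated with:

   * the asymmetry factor `f = (t_Rf − t_Rmax) / (t_Rmax − t_Ri)`,
     computed on the raw scan span; peaks with fewer than 3 scans or an
     apex on an edge score 0 by convention, flagging them as
     quantitatively unusable;
   * IPIR `= I_k / I_{k+1}`, apex intensity of the monoisotopic over the
     +1 isotopologue trace. For CHNO formulas the monoisotopic peak
     dominates, so IPIR > 1 is required; S or Br contribute strong heavier
     isotopes, so the rule is suppressed (verdict NA) when the formula
     contains either;
   * PPC, the Pearson correlation of the two smoothed traces over their
     shared scans, with a two-sided p-value (`stats::cor.test`). The
     defining formula is written with centred sums; its algebra is exactly
     the standard Pearson estimator with means, and that is what is
     implemented, even though such formulas are sometimes glossed in words
     as "intensity sums";
   * PPS `= f_1 / f_2`, the ratio of asymmetry factors of the two peaks;
   * the product/precursor ratio `F/P = I_max,F / I_max,P` on raw apex
     intensities, with the precursor apex always taken from the MS¹
     channel.

   The decision rule (`scoreVerdict()`) accepts a pair iff PPC ≥ 0.7 and
   0.3 ≤ PPS ≤ 3, both boundaries inclusive — so a pair with PPS exactly
   3.00 is rejected only if its PPC also fails. F/P carries no cutoff; it
   is reported to guide the choice of collision energy (the energy at
   which a diagnostic fragment yields best).

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `ppmTol` | 5 | ppm | relative EIC tolerance |
| `mzWindow` | 0.005 | Da | absolute EIC tolerance cap |
| `rtTol` | 0.08 | min | precursor–fragment apex alignment |
| `minFragments` | 1 (or `"all"`) | — | fragments required to keep a group |
| `ppcCutoff` | 0.7 | — | PPC acceptance cutoff |
| `ppsBand` | [0.3, 3] | — | inclusive PPS acceptance band |
| `minScans` | 3 | scans | minimum peak span |
| `valleyFraction` | 0.5 | — | valley split depth |
| `isoRtTol` | 0.08 | min | isotopologue co-elution gate |
| `ubiquityK` | 5 | entries | library ubiquitous-fragment check |

The mass and retention-time tolerances are the standard operating values
for high-resolution quadrupole-TOF/Orbitrap data. `minScans`,
`valleyFraction` and the ubiquity threshold have no canonical literature
value; the defaults are deliberately permissive (3 scans is the smallest
span for which an interior apex exists at all) and are exposed rather than
hard-coded.

## Exact-mass arithmetic

Neutral masses are sums over a bundled IUPAC monoisotopic atomic-mass
table (≥ 6 decimals). Adduct m/z is `(M + δ) / |z|` with δ taken from a
user-extensible registry; the built-in deltas ([M+H]⁺ +1.007276,
[M+NH4]⁺ +18.033823, [M+Na]⁺ +22.989218, [M−H]⁻ −1.007276) already
account for the electron. Fragment-cation m/z subtracts one electron mass
(0.000549 Da) from the fragment formula's neutral mass — without this the
computed values miss the tabulated ones at the fourth decimal. The +1
isotopologue offset is fixed at +1.003355 Da (¹³C−¹²C), the dominant +1
channel for CHNO metabolites; heavier channels and multiply charged
species are out of scope.

## Numerical choices and degenerate inputs

* **Smoothing.** PPC is computed on smoothing-spline fits
  (`stats::smooth.spline`, GCV) evaluated at the original scan times, with
  negative fitted values clamped to 0. The natural cubic interpolating
  spline is also available, but it is exact at the knots, so it only
  matters for off-grid resampling and plots; it is not used for scores.
  Peaks with fewer than 4 scans pass through unsmoothed and are flagged.
* **Scan pairing.** Within one channel, shared scans are matched by scan
  id. Precursor and fragment live on different channels, so their scans
  are paired by nearest retention time, accepted within half the median
  scan period of the fragment grid, with duplicate assignments dropped.
* **Ties.** Several peaks for one target: ranked by apex intensity, rank 1
  annotated, alternates retained as an attribute. Several fragment peaks
  within the RT tolerance: smallest apex distance wins, ties broken by
  intensity.
* **Degenerate scores.** PPC with < 3 shared scans or a zero-variance
  trace is NA with a reason, and the verdict is "insufficient scans"
  rather than a rejection — correlation estimated from 2 points is
  meaningless, not negative evidence. PPS with a degenerate denominator
  (f = 0) is NA and fails the shape rule.
* **Empty inputs.** Empty runs, empty libraries and all-zero EICs return
  empty results (with warnings where the emptiness is suspicious), never
  errors.

## The synthetic-run generator

`simulateRun()` renders a ground-truth trace table on interleaved
per-channel RT grids and writes deterministic mzML (uncompressed 64-bit
arrays, no timestamps: one seed, one byte stream). Default conditions
emulate a four-event multiplexed electrospray acquisition:

* channel period 1/60 min — a 1 s duty cycle, i.e. four 250 ms scan
  events;
* chromatographic σ = 0.03 min (FWHM ≈ 4.2 s), giving ≈ 15 scans per peak
  per channel — enough that peak shape is quantitatively defined, which is
  the regime the scoring statistics assume;
* centroid m/z jitter uniform within ±2 ppm, comfortably inside the 5 ppm
  tolerance of a calibrated Orbitrap/q-TOF;
* 2% multiplicative detector noise on signal centroids, plus 10 uniform
  noise centroids per scan with exponential intensities at a floor of 50
  counts (spiked peaks default to 10⁴× that);
* isotope ratio 8 (a typical C5–C10 CHNO metabolite) and fragment yields
  of 0.5 at every energy.

Tailed peaks use an exponentially modified Gaussian with tail constant τ,
normalized to unit apex, because it gives controllable asymmetry with a
well-defined apex; the truth table records the continuous apex RT. What
the generator does **not** emulate — isotope fine structure, adduct
equilibria, ion suppression, detector saturation, retention drift between
channels — bounds what passing tests show: they validate the
demultiplexing, extraction, alignment and scoring machinery on data whose
ground truth is known exactly, not the chromatographic realism of any
particular instrument.

## Validation problem sizes

The test suite runs the full pipeline on simulated runs of ~480 scans
(four channels, 2 min of chromatography) for the end-to-end checks, and on
~70-scan single-metabolite runs for replicated properties: 50 seeded
replicates for the fragment-constraint monotonicity check (the
all-fragments annotation set is nested in the ≥ 1-fragment set), 50 for
isotope-ratio recovery (median within 5% of truth), 1000 random vector
pairs for the equivalence of the PPC with a hand-written textbook Pearson
estimator, and 25 paired runs for the PPS reciprocal identity. These sizes
keep the whole suite under a minute while leaving every statistic with
enough replication to be meaningful.

## Known limitations

* Targeted only: nothing is annotated that is not in a library.
* Singly charged species and the +1 isotopologue channel only.
* No spectral-library similarity scoring (cosine/dot product), no
  SWATH-style window deconvolution, and no decoy-based FDR; the scores
  grade chromatographic co-elution, which is a different (and
  complementary) evidence axis.
* HCD "%" and CID "eV" energy labels are kept as opaque strings; channels
  from different instruments are never merged.
* The mzML writer exists for fixtures and channel export; it writes
  centroid spectra with numeric energy labels and is not a general-purpose
  converter.
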