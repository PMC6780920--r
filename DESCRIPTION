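Package: metaif
Title: Annotation and Quality Scoring of Multiplexed All-Ion-Fragmentation
    Metabolomics Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Targeted annotation of liquid chromatography high-resolution
    mass spectrometry runs acquired as multiplexed full-scan MS1 and
    all-ion-fragmentation (AIF) MS/MS at stepped collision energies.
    Demultiplexes interleaved scans into per-collision-energy channels,
    extracts ion chromatograms against neutral-mass and MS/MS CSV
    libraries, detects and smooths chromatographic peaks, aligns
    precursor and fragment peaks by retention time, and scores every
    assignment with the asymmetry factor, isotope peak intensity ratio
    (IPIR), peak-to-peak Pearson correlation (PPC), peak-to-peak shape
    ratio (PPS) and product/precursor ion intensity ratio. Includes a
    deterministic synthetic-run generator with ground truth for
    validation, batch processing, and quality-control plots.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    mzR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: MassSpectrometry, Metabolomics, Software
RoxygenNote: 7.3.3
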