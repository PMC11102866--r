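Package: nucseen
Title: Quantitative Analysis of Pioneer Factor Engagement with Nucleosomes
Version: 0.1.0
Authors@R:
    person("nucseen", "maintainers", email = "nucseen@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative readouts used to characterize how a
    pioneer transcription factor engages nucleosomes: tiled-motif nucleosome
    library design and spike-in normalized SeEN-seq enrichment profiles on the
    Widom 601 backbone; in vitro MNase dyad-density mapping with superhelical
    location (SHL) coordinate arithmetic; single-molecule FRET trace quality
    control, two-state dwell-time segmentation and exponential kinetics with a
    discrete-sampling correction; and structural geometry (Kabsch superposition,
    per-residue C-alpha RMSD, van der Waals clash detection, minor-groove anchor
    contacts, DNA unwrap angles). Seeded synthetic-data generators emulate every
    input with ground-truth sidecars for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
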