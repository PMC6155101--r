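Package: barreljoint
Title: Joint-Based Macroscopic Descriptors for Beta-Barrel Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a coarse-grained, joint-based description of beta-barrel
    protein geometry from C-alpha coordinates. The first and last residues of
    each beta-strand define joint points; signed torsion angles over sliding
    windows of four consecutive joints yield an alternating series of
    strand-level (beta-type) and loop-level (gamma-type) dihedral angles that
    summarise strand packing, twist handedness and parallel/antiparallel
    arrangement. Includes readers for PDB SHEET records, STRIDE output and
    plain segment tables, sign/dyad/triad/quadrant pattern statistics with
    strand-number grouping, an idealized barrel and flat-sheet generator for
    property-based validation, and tidy tabular outputs throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    tibble,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
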