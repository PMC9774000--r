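Package: shiftstrain
Title: Discriminating Amyloid Fibril Strains from NMR Chemical Shift Assignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares an experimental solid-state NMR chemical-shift assignment
    of an amyloid fibril against a panel of candidate fibril core structures and
    ranks the candidates. Implements three strain-discrimination metrics -- the
    summed absolute Calpha/Cbeta chemical-shift difference (Sigma_CS), the count
    of secondary-shift sign disagreements (Sigma_A), and the summed absolute
    backbone dihedral difference (Sigma_PsiPhi) -- together with the per-residue
    diagnostic Delta-alpha-beta. Readers are provided for NMR-STAR v3 assigned
    chemical-shift loops, ShiftX2 prediction tables, TALOS-N torsion predictions,
    and PDB/mmCIF coordinates; backbone phi/psi torsions are computed from
    structure geometry. A synthetic-data module generates ideal-geometry cross-beta
    backbones with programmable kinks, kink-shifted decoy structures, and noisy
    shift tables, so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
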