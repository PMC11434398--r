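Package: radchel
Title: Structural and Electronic Descriptors for Radiometal-Chelator Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts the descriptor set used to characterise radiometal-chelator
    complexes: frontier-orbital (HOMO/SOMO-LUMO) gaps and delta-SCF electronic
    descriptors (vertical ionization energy, electron affinity, fundamental gap,
    chemical hardness and softness) from orbital spectra and total energies;
    gyration-tensor shape descriptors (radius of gyration, asphericity,
    acylindricity, relative shape anisotropy), minimal projection area, Kabsch
    RMSD/RMSF, solvation-shell water counts and geometric hydrogen-bond
    statistics from molecular-dynamics trajectories; hierarchical agglomerative
    conformational clustering on an RMSD metric; and harmonic bond/angle force
    constants from Cartesian Hessians by the Seminario projection method.
    Includes readers and writers for XYZ, multi-model PDB (plain or gzipped),
    TRIPOS mol2, plain-text orbital-energy lists and packed lower-triangular
    Hessians, a per-compound pipeline producing a merged descriptor table, and a
    synthetic-data generator that emulates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
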