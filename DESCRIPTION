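Package: zfthermo
Title: Thermodynamics and Dissociation Pathways of Zn(II) Binding to
    Classical Zinc Fingers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for Zn(II)-binding thermodynamics of classical
    beta-beta-alpha (CCHH) zinc finger peptides. Fits spectrophotometric
    pH-titration curves to a two-proton thiol dissociation model, computes
    free Zn(II) (pZn) in chelator metal buffers by solving conditional
    mass-balance equations, fits chelator-competition ellipticity series to
    the Hill equation to extract dissociation constants, fits single-site
    isothermal titration calorimetry isotherms and performs the
    proton-linkage enthalpy decomposition into buffer, thiol-deprotonation,
    Zn-ligand bond and folding contributions. Also post-processes (steered)
    molecular dynamics trajectories: smooth Zn-ligand contact numbers via a
    rational switching function, dissociation-pathway classification and
    census, rupture-force and pulling-work statistics, geometric
    hydrogen-bond detection, RMSD/RMSF, and probability-based free-energy
    surfaces. Synthetic-data generators with known ground truth emulate
    every input so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
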