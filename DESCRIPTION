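Package: cardiosim
Title: Sex-Specific Cardiac Electrophysiology on Anatomically Detailed
    Synthetic Ventricles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale computational cardiac electrophysiology: the
    O'Hara-Rudy human ventricular myocyte model with transmural cell types,
    an apex-to-base IKs gradient and male/female ion-channel expression
    scaling; a synthetic-anatomy generator producing paired detailed
    (trabeculated, with false tendons) and smoothed biventricular
    tetrahedral meshes plus cable and slab fixtures; rule-based myofiber
    orientation with gradient-based trabecula detection; an anisotropic
    monodomain finite-element reaction-diffusion solver with region-wise
    diffusion (fast-endocardial layer, border zone, dense scar);
    pseudo-ECG forward computation at limb field points; activation,
    repolarization and ECG-interval biomarkers with sex and geometry
    difference statistics; and a Josephson-style programmed electrical
    stimulation protocol with reentry detection for ventricular
    tachycardia inducibility studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
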