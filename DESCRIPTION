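Package: psdcorrect
Title: Patient-Specific Susceptibility Distortion Correction for Stereotactic Radiosurgery MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify and correct patient-specific geometric distortion
    (PSD) in MRI used for Gamma Knife stereotactic radiosurgery planning.
    Implements B0 field-map estimation from dual-echo phase images, conversion
    of off-resonance to voxel displacement along the frequency-encoding axis,
    Jacobian intensity-compensated unwarping, a patch-based 3D convolutional
    network that predicts the field map from anatomy, a synthetic susceptibility
    head phantom (Fourier dipole forward model) for fully self-contained
    experiments, and the geometric (Dice, Hausdorff, centroid, volume) and
    dosimetric (DVH, target coverage, Paddick conformity and gradient indices,
    homogeneity index, paired Wilcoxon comparison) evaluation suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
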