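Package: fdopar
Title: Reference-Tissue Patlak Quantitation of Dynamic FDOPA PET in the
    Hemiparkinsonian Rat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying presynaptic dopaminergic function from
    dynamic [18F]FDOPA positron emission tomography in the unilaterally
    6-OHDA-lesioned rat. Implements dynamic frame-scheme handling, decay
    correction and SUV normalization of regional time-activity curves,
    volume-of-interest extraction from 4D images, the reference-tissue
    (cerebellum) Patlak graphical analysis yielding the influx constant Ki,
    ipsilateral/contralateral asymmetry ratios, and the associated
    statistical battery (paired t, one-way ANOVA with Dunnett's many-to-one
    comparisons, linear regression against striatal monoamine content and
    rotational behavior). A compartmental tracer simulator and lesion-cohort
    generator with known ground truth make every stage testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    RNifti,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
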