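Package: ictexture
Title: Bilateral CT Texture Asymmetry for Noninvasive Intracranial
    Hypertension Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies bilateral texture asymmetry on axial head CT in
    unilateral hypertensive intracerebral hemorrhage and uses it to
    classify intracranial hypertension (ICP >= 20 mmHg). Implements
    gray-level co-occurrence (GLCM, 24 features) and gray-level
    run-length (GLRLM, 16 features) texture matrices from first
    principles, symmetric 20x20-pixel region-of-interest placement about
    the cranial midline, morphological measurements (hematoma volume,
    midline shift, ventriculocranial ratio), the hemorrhagic-versus-
    contralateral variation-rate statistic with min-max standardization,
    and region-wise random-forest classifiers with recursive feature
    elimination under cross-validation. A phantom head-CT generator with
    ground-truth ICP, hematoma and ventricle masks supports end-to-end
    evaluation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
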