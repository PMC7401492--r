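Package: ppcmv
Title: Parapapillary Choroidal Microvasculature Density from En Face OCT
    Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated quantification of parapapillary choroidal
    microvasculature (PPCMv) density on en face optical coherence
    tomography angiography (OCT-A) choriocapillaris images centered on
    the optic disc. Implements a three-stage pipeline: localization of
    large retinal-vessel shadows by locally adaptive (Niblack-style)
    thresholding on local first-order statistics, capillary segmentation
    with a modified Otsu algorithm whose histogram excludes shadow and
    disc pixels, and density computation inside concentric annular
    regions of interest around the disc with superior/inferior
    hemifields. Includes Bland-Altman agreement analysis against manual
    measurements, a synthetic en face image generator with pixel-level
    ground truth, and a batch command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'agreement.R'
    'cli.R'
    'config.R'
    'density.R'
    'io.R'
    'methods.R'
    'ppcmv-package.R'
    'preprocess.R'
    'roi.R'
    'segment.R'
    'shadow.R'
    'synthetic.R'
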