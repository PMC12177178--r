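Package: axolat
Title: Laterality Quantification of Descending Corticobulbar Axon Projections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the hemispheric laterality of long-range axon
    projections in whole-brain 3D segmentation volumes, as produced by
    light-sheet imaging of cleared mouse brains. Provides midline-plane
    geometry from three operator points, a sagittal corticospinal-tract
    exclusion band, probability-volume binarization, voxel-cloud
    downsampling to an isotropic grid, hindbrain masking, lateralization
    indices, per-nucleus contralateral fractions against a label atlas,
    mediolateral density profiles, averaged density maps, SWC single-neuron
    collateral classification, retrograde soma counting with double-label
    detection, exact small-sample Mann-Whitney group comparisons, and a
    ground-truthed synthetic phantom generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
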