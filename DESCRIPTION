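Package: tricoreg
Title: Correlative Co-Registration of MicroCT, Light-Microscopy and TEM Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Brings three microscopy modalities of one specimen -- a microCT
    reference volume, a serial-section light-microscopy (LM) stack with its
    label volumes, and individual transmission-electron-microscopy (TEM)
    images -- into a single physical 3D coordinate frame. Provides intensity
    preprocessing (inversion, Gaussian smoothing), automatic affine 3D
    co-registration driven by a Pearson correlation metric with a
    multi-resolution coordinate search, transform propagation to companion
    stacks and segmentation label volumes, template-based 2D similarity
    registration for embedding TEM slices at their native resolution, scene
    export, and a seeded multimodal phantom generator with known ground-truth
    transforms for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    jsonlite,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'grid.R'
    'preprocess.R'
    'transforms.R'
    'synthetic.R'
    'colormap.R'
    'embed2d.R'
    'resample.R'
    'metric.R'
    'register3d.R'
    'stack_io.R'
    'cli.R'
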