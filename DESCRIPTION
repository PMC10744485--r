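Package: BiplanarCT
Title: Reconstruction of Vertebral CT Volumes from Biplanar X-Rays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end workbench for reconstructing 3D vertebral CT volumes
    from two synthetic X-ray views. Provides a procedural vertebral-column
    phantom generator, segmentation-mask-driven region-of-interest cropping of
    NIfTI volumes, digitally-reconstructed-radiograph (DRR) synthesis by
    parallel-ray compositing with a six-point opacity transfer function, an
    X-ray preprocessing and paired-sample packaging chain with reproducible
    train/test splitting and augmentation, a two-view feature-fusion
    least-squares GAN (dense 2D encoders, pseudo-3D expansion, fused 3D
    decoders, conditional patch discriminator) trained with reconstruction,
    projection, feature-matching and identity losses, and a volumetric
    evaluation suite (slice-wise and volume MAE/MSE, cosine similarity,
    per-plane and volumetric PSNR, slice-averaged SSIM) including a biplanar
    angle-sensitivity sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    EBImage,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'autograd.R'
    'nn-ops.R'
    'discriminator.R'
    'utils-interp.R'
    'drr.R'
    'generator.R'
    'metrics.R'
    'evaluation.R'
    'losses.R'
    'phantom.R'
    'xray-prep.R'
    'train.R'
    'volume-roi.R'
    'pipeline.R'
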