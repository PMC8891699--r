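Package: munetr
Title: Joint Skull Stripping and Bilateral Hippocampus Segmentation for Rat Brain MRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compact multi-task U-Net ensembles for simultaneous skull
    stripping and segmentation of the ipsilateral and contralateral
    hippocampus in rat brain MRI after experimental traumatic brain injury.
    Provides the encoder-decoder network (2D and 3D variants) with a
    generalized-Dice plus brain-Dice objective trained by rectified Adam
    with online scaling augmentation and early stopping; nested six-fold
    cross-validation with six-member majority-vote ensembling and a
    registration-experiment planner; morphological post-processing; a
    six-metric millimetre-aware evaluation suite (Dice, 95th-percentile
    Hausdorff distance, volume similarity, compactness score, precision,
    recall); paired permutation tests, bootstrap confidence intervals and a
    heteroscedastic repeated-measures model of hippocampal volume; and a
    synthetic phantom cohort generator emulating lesion, atrophy and
    ventricular-enlargement phenotypes so the full pipeline runs end-to-end
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Rcpp, RNifti, jsonlite, optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), knitr, rmarkdown, oro.nifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
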