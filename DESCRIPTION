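Package: autolirads
Title: Automated LI-RADS Scoring of Multi-Phase Liver Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end automation of LI-RADS (Liver Imaging Reporting and
    Data System) category assignment for liver lesions on multi-phase
    contrast-enhanced abdominal imaging. Provides a synthetic multi-phase
    phantom generator with known arterial-phase hyperenhancement, washout
    and enhancing-capsule dynamics; intensity normalization,
    standardization, 2.5D window construction and patient-level k-fold
    splitting; a hybrid soft-dice + focal segmentation loss with a
    scheduled Lovasz-Softmax addition; a compact attention-augmented
    nested encoder-decoder segmentation network and a shared-backbone
    multi-task feature characterizer trained with a phase-routed adaptive
    loss, both running on a small pure-R reverse-mode engine; a
    deterministic LI-RADS LR-3/4/5 rule engine over (APHE, washout,
    capsule, size); and an evaluation suite with local and global DICE,
    pixel-, lesion- and patient-level precision-recall sweeps, and
    category confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
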