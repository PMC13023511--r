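Package: drrtrack
Title: Markerless Tumor Motion Forecasting from Digitally Reconstructed
    Radiograph Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating and forecasting respiratory lung-tumor
    motion without implanted markers. Provides a synthetic thorax phantom
    with a parametric quasi-periodic breathing model, Beer-Lambert
    projection of attenuation volumes into coronal digitally reconstructed
    radiographs (DRRs), amplitude-aware position normalization, an
    encoder-decoder vision transformer trained with teacher forcing for
    autoregressive multi-horizon forecasting of the tumor centre of mass,
    encoder-only vision transformer and convolutional-LSTM baselines,
    multi-patient pre-training with patient-specific low-rank-adaptation
    fine-tuning, and RMSE-in-millimetre evaluation with horizon sweeps and
    paired nonparametric comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
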