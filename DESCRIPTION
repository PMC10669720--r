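Package: murmurcaps
Title: Capsule Neural Networks for Heart Murmur Classification from
    Phonocardiograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end toolkit for classifying phonocardiogram (PCG)
    recordings as normal or abnormal (murmur-bearing). Raw heart-sound
    audio is segmented into fixed-duration clips, downsampled with
    anti-aliased polyphase filtering, peak-normalized, and converted to
    mel-frequency cepstral coefficient (MFCC) spectra. Classification
    uses a capsule neural network: convolutional feature extraction,
    primary capsules with the squash nonlinearity, iterative dynamic
    routing by agreement, digit capsules, a margin loss on capsule
    lengths, and a fully connected reconstruction decoder. Includes a
    training loop (Adam, plateau/decay/fixed learning-rate policies,
    gap-based early stopping), evaluation utilities (confusion matrix,
    precision/recall/F1/accuracy/specificity, ROC and AUC), a synthetic
    phonocardiogram generator for offline testing, and command-line
    entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
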