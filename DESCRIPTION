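Package: ssepcs
Title: Central Sulcus Delineation from Somatosensory Evoked Potential Grid
    Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for unsupervised delineation of the central sulcus from
    median-nerve somatosensory evoked potentials (SSEPs) recorded over
    subdural electrode grids. Implements trigger detection from surface EMG,
    zero-phase high-pass filtering, epoch averaging on the 10-50 ms
    post-stimulus window, Savitzky-Golay smoothing, corrupted-channel
    rejection, Fisher discriminant profiling of anterior (M1) versus
    posterior (S1) channels over time, per-time-point ROC/AUC, spatial heat
    maps of the SSEP amplitude field, and spectral clustering of whole SSEP
    waveforms (Gaussian affinity, random-walk normalized Laplacian, eigengap
    model selection, k-means on the second eigenvector) into anterior and
    posterior channel groups. A forward simulator generates grid sessions
    with known ground truth, including phase-reversed anterior morphology,
    spatial amplitude decay around a central sulcus line, stimulation
    artifacts on an EMG channel, trial noise and corrupted channels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'ssepcs-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'preprocess.R'
    'cluster.R'
    'discriminate.R'
    'geometry.R'
    'simulate.R'
    'io-fixture.R'
    'io-edf.R'
    'visualize.R'
    'pipeline.R'
    'trial-counts.R'
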