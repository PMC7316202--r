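Package: pulsewave
Title: Beat-by-Beat ECG/PPG Fiducial Detection and Cuffless Blood
    Pressure Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Haar-wavelet delineation of concurrent electrocardiogram
    (ECG) and photoplethysmogram (PPG) recordings on a beat-by-beat
    basis.  Detects P, Q, R, S, T and QRS onset/offset on ECG and the
    systolic peak, dicrotic notch, diastolic peak and end-of-beat
    landmarks on transmission-intensity PPG using adaptive windows
    sized from the running R-R (or pulse) interval, wavelet-transform
    modulus maxima and per-window validity conditions.  Pairs
    simultaneous beats, extracts 32 timing features (pulse arrival
    times and intra-channel intervals), aggregates them robustly, and
    fits a log-linear regression of systolic and diastolic blood
    pressure on selected features, with mean-error, mean-absolute-error
    and error-standard-deviation reporting, Bland-Altman pairs, BHS
    cumulative-error grading and the AAMI mean-error criterion.  A
    synthetic paired-signal generator with exact ground-truth
    landmarks makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
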