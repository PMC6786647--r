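Package: sibilantflow
Title: Tongue Kinematics, Constriction Flow and Vortex-Sound Analytics for the Fricative [s]
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-steady model of sibilant [s] production in a word context:
    trapezoidal tongue-height schedules, constriction area and mean jet
    velocity, a vortex-ring acoustic amplitude estimate, and the signal
    statistics (Hann STFT spectrogram, band-limited overall sound pressure
    level, spectrogram-threshold onset/offset detection, windowed-RMS
    convection speed) that relate tongue movement to sound generation.
    Includes a seeded generator of synthetic microphone, hot-wire and
    flow-meter records so the full analysis pipeline is testable end to end,
    plus lightweight WAV and two-column text I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
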