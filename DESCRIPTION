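Package: gridtask
Title: Classification of Task-Anchored and Task-Independent Grid Cell Firing
    on Virtual Linear Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing medial entorhinal spatial firing recorded
    while animals run repeated trials on a virtual linear track. Spatial
    periodicity of each neuron is estimated with Lomb-Scargle periodograms
    computed in the distance domain, compared against a field-shuffle false
    alarm threshold, and classified as task-anchored (periodogram peak at an
    integer number of oscillations per trial), task-independent (non-integer
    peak) or aperiodic, at the level of whole sessions, rolling windows and
    individual trials. Also included are trial-wise firing rate maps and
    spatial information, open-arena grid-cell identification (grid score,
    stability, time-shift shuffles), behavioural scoring of stopping (hit,
    try, run), stop-density profiles with shuffled baselines, coding-agreement
    statistics between simultaneously recorded cells, a template-matching
    trial classifier, a spike-train and behaviour simulator with known ground
    truth, and a validation harness measuring classifier accuracy and bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
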