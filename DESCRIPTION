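Package: fishclip
Title: Event Detection and Clip Extraction for Camera-Based Fish Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for turning continuous underwater surveillance video of
    salmonids in small streams into short, reviewable clips. Videos are
    thinned to one still per fixed time interval, each still is scored by a
    two-class fish/no-fish classifier (a trained model, a deterministic
    image heuristic, or replayed scores from CSV), and maximal runs of
    adjacent above-threshold frames within each video file are grouped into
    detection events. Events are padded with a configurable time buffer,
    clamped to video bounds, and written out as frame-accurate video
    segments. Also builds the probability-frequency table (rounded percent
    bins by recording date) and the manual-review queue used to evaluate the
    classifier, and ships a seeded synthetic-scene generator so the whole
    pipeline is testable without field footage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    keras,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
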