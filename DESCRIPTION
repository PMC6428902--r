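Package: sophab
Title: Deterministic Simulator of the SOP Model of Stimulus Processing and Habituation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time, fully deterministic simulator of the Sometimes
    Opponent Processes (SOP) model of stimulus processing, instantiated for
    the study of habituation. Stimulus and context representations are
    tracked as proportions of elements in inactive (I), primary (A1) and
    secondary (A2) activity states; context-stimulus associations develop by
    concurrent-activity learning rules and feed back on processing through
    retrieval-generated priming. The package ships protocol constructors and
    checks for the ten classical behavioral characteristics of habituation
    (within-session decrement, spontaneous recovery, potentiation,
    frequency and intensity effects, below-zero habituation, stimulus
    generalization, dishabituation and its habituation, long-term
    habituation), a YAML/JSON protocol schema, tidy CSV/JSON exports and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
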