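Package: clops
Title: Continual Learning for Streamed Cardiac Signals with Importance-Guided Replay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Replay-based continual learning for sequentially streamed
    single-lead ECG classification. Task-instance parameters (learnable
    per-example loss coefficients) rank examples by difficulty and guide
    storage into a replay buffer; BALD uncertainty scores from Monte-Carlo
    dropout guide which buffered examples are replayed, so a small 1-D
    convolutional classifier trained across shifting tasks resists
    catastrophic forgetting. Includes a synthetic ECG stream generator for
    four continual-learning scenarios (class-, time-, domain- and
    institute-incremental), backward-transfer metrics over the task
    evaluation matrix, and Hellinger-similarity task curricula.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
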