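# Frozen scaled-down study conditions shared by the acceptance tests and
# reused across criteria so each heavy run is computed once per session.

study_net <- function() {
  classifier_spec(channels = c(8L, 16L, 16L), kernel = 7L, hidden = 16L,
                  dropout = 0.3)
}

study_stream <- function(seed) {
  make_stream("class_il", synthetic_config(
    n_classes = 8L, L = 500L, fs = 100, n_train = 64L, n_val = 24L,
    n_test = 48L, noise_sd = 0.3, label_noise = 0.05, seed = 100L + seed))
}

study_train_config <- function(seed, strategy, ...) {
  train_config(tau = 20L, B = 16L, B_r = 16L, T = 20L, seed = seed,
               lr = 2e-3, eta_beta = 0.1, net = study_net(),
               strategy = strategy, ...)
}

.study_cache <- new.env(parent = emptyenv())

study_run <- function(seed, strategy, task_order = NULL) {
  if (!is.null(task_order) &&
      identical(as.integer(task_order), seq_along(task_order)))
    task_order <- NULL          # stream order: share the cached run
  key <- paste(seed, strategy, paste(task_order, collapse = "-"), sep = "|")
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- run_stream(
      study_stream(seed),
      study_train_config(seed, strategy, task_order = task_order))
  }
  .study_cache[[key]]
}

study_seeds <- 1:5
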