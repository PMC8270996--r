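# Shared fixtures: small streams and classifiers that keep unit tests fast.

tiny_spec <- function(dropout = 0.3) {
  classifier_spec(channels = c(4L, 8L), kernel = 7L, hidden = 8L,
                  dropout = dropout)
}

tiny_stream <- function(n_classes = 4L, seed = 7L, n_train = 8L, n_val = 4L,
                        n_test = 6L, scenario = "class_il", ...) {
  cfg <- synthetic_config(n_classes = n_classes, L = 240L, fs = 60,
                          n_train = n_train, n_val = n_val, n_test = n_test,
                          noise_sd = 0.1, label_noise = 0, artifact_frac = 0,
                          seed = seed, ...)
  make_stream(scenario, cfg)
}

tiny_config <- function(tau = 3L, eta_beta = 0.05, ...) {
  train_config(tau = tau, B = 4L, B_r = 4L, T = 4L, eta_beta = eta_beta,
               net = tiny_spec(), ...)
}

# a simple hand-made task for buffer tests
toy_task <- function(n = 8L, task_id = 1L, classes = 0:1) {
  ids <- sprintf("a%02d", seq_len(n))
  task_dataset(task_id,
               signal = matrix(rnorm(n * 10), n, 10),
               label = rep_len(classes, n),
               instance_id = ids,
               patient_id = paste0("p", seq_len(n)),
               split = rep("train", n),
               class_set = classes)
}
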