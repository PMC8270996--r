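#' Construct a task dataset
#'
#' One task of a continual-learning stream: a matrix of fixed-length signals
#' with labels, instance ids, patient ids and split assignments.
#'
#' @param task_id integer task id (1-based position in the stream).
#' @param signal numeric matrix, one row per instance.
#' @param label integer vector of global class ids.
#' @param instance_id character vector, unique within the stream.
#' @param patient_id character vector; splits must be patient-disjoint.
#' @param split character vector over `{"train","val","test"}`.
#' @param class_set integer vector of class ids present in this task
#'   (defaults to the observed labels).
#' @return a `task_dataset` list.
#' @export
task_dataset <- function(task_id, signal, label, instance_id, patient_id,
                         split, class_set = NULL) {
  n <- nrow(signal)
  stopifnot(length(label) == n, length(instance_id) == n,
            length(patient_id) == n, length(split) == n)
  if (anyDuplicated(instance_id)) stop("instance ids must be unique")
  if (!all(split %in% c("train", "val", "test"))) stop("invalid split label")
  if (!all(is.finite(signal))) stop("signals contain non-finite values")
  for (s1 in c("train", "val")) for (s2 in setdiff(c("val", "test"), s1)) {
    if (length(intersect(patient_id[split == s1], patient_id[split == s2])))
      stop("splits are not patient-disjoint")
  }
  cs <- sort(unique(as.integer(label)))
  if (is.null(class_set)) class_set <- cs
  class_set <- sort(unique(as.integer(class_set)))
  if (!all(cs %in% class_set)) stop("labels outside the declared class set")
  rownames(signal) <- instance_id
  structure(list(task_id = as.integer(task_id), signal = signal,
                 label = as.integer(label), instance_id = instance_id,
                 patient_id = patient_id, split = split,
                 class_set = class_set),
            class = "task_dataset")
}

new_task_stream <- function(scenario, tasks, L, fs, n_classes) {
  head_policy <- if (scenario == "class_il") "per_task" else "shared"
  ids <- unlist(lapply(tasks, `[[`, "instance_id"))
  if (anyDuplicated(ids)) stop("instance ids must be unique across the stream")
  structure(list(scenario = scenario, head_policy = head_policy,
                 tasks = tasks, L = as.integer(L), fs = fs,
                 n_classes = as.integer(n_classes),
                 class_union = sort(unique(unlist(lapply(tasks, `[[`, "class_set"))))),
            class = "task_stream")
}

#' @export
print.task_stream <- function(x, ...) {
  cat(sprintf("task_stream: %s, %d tasks, head policy '%s', L = %d @ %g Hz\n",
              x$scenario, length(x$tasks), x$head_policy, x$L, x$fs))
  for (tk in x$tasks)
    cat(sprintf("  task %d: %d instances, classes {%s}\n", tk$task_id,
                length(tk$label), paste(tk$class_set, collapse = ",")))
  invisible(x)
}

# Generate one task's worth of segments for the given classes.
# Returns the pieces of a task_dataset; label noise flips within class_set.
synth_task_instances <- function(config, classes, task_tag, noise_sd, fs,
                                 L, prevalence = NULL) {
  splits <- c(train = config$n_train, val = config$n_val, test = config$n_test)
  n_tot <- sum(splits)
  split <- rep(names(splits), times = splits)
  pal <- config$morphologies
  # balanced round-robin labels unless a prevalence vector is supplied
  label <- integer(0)
  for (s in names(splits)) {
    ns <- splits[[s]]
    if (is.null(prevalence)) {
      lab <- rep_len(classes, ns)
    } else {
      lab <- sample(classes, ns, replace = TRUE, prob = prevalence)
    }
    label <- c(label, lab)
  }
  true_label <- label
  if (config$label_noise > 0 && length(classes) > 1) {
    flip <- runif(n_tot) < config$label_noise
    label[flip] <- vapply(label[flip], function(l) {
      alt <- setdiff(classes, l)
      alt[sample.int(length(alt), 1L)]
    }, integer(1))
  }
  artifact <- runif(n_tot) < config$artifact_frac
  sig <- matrix(0, n_tot, L)
  tgrid <- (seq_len(L) - 1) / fs
  for (i in seq_len(n_tot)) {
    if (artifact[i]) {
      # motion-artifact segment: baseline wander + heavy noise, no beats
      sig[i, ] <- runif(1, 0.5, 1.5) *
        sin(2 * pi * runif(1, 0.2, 0.7) * tgrid + runif(1, 0, 2 * pi)) +
        rnorm(L, 0, runif(1, 0.5, 1))
      next
    }
    p <- jitter_params(pal[pal$class == true_label[i], ], config$jitter,
                       config$jitter_sd, config$amp_jitter)
    nsd <- noise_sd * if (config$jitter)
      runif(1, 1 - config$noise_jitter, 1 + config$noise_jitter) else 1
    sig[i, ] <- as.numeric(synthesize_segment(p, nsd, L, fs))
  }
  instance_id <- sprintf("%s_i%04d", task_tag, seq_len(n_tot))
  list(signal = sig, label = label, instance_id = instance_id,
       patient_id = sprintf("%s_p%04d", task_tag, seq_len(n_tot)),
       split = split)
}

#' Assemble a synthetic continual-learning task stream
#'
#' Builds the ordered sequence of tasks for one of the four scenarios:
#'
#' * `class_il` — consecutive disjoint class pairs in label order
#'   (`n_classes` must be even); per-task classification heads.
#' * `time_il` — 3 "terms" sharing the class set but with drifting class
#'   prevalence and noise level; shared head.
#' * `domain_il` — 12 lead-like tasks, each a fixed scalar-gain projection of
#'   the same latent traces plus lead-specific noise; shared head.
#' * `institute_il` — 3 tasks with disjoint label vocabularies, different
#'   native sampling rates (resampled to the common grid) and noise levels;
#'   shared head.
#'
#' @param scenario one of `"class_il"`, `"time_il"`, `"domain_il"`,
#'   `"institute_il"`.
#' @param config a [synthetic_config()].
#' @param prevalence optional 3 x n_classes matrix of per-term class
#'   prevalences for `time_il` (rows normalised internally).
#' @param lead_gains optional length-12 gain vector for `domain_il`.
#' @return a `task_stream`.
#' @export
make_stream <- function(scenario = c("class_il", "time_il", "domain_il",
                                     "institute_il"),
                        config = synthetic_config(),
                        prevalence = NULL, lead_gains = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    tasks <- switch(
      scenario,
      class_il = {
        if (config$n_classes %% 2L != 0L)
          stop("class_il needs an even number of classes")
        pairs <- split(0:(config$n_classes - 1L),
                       rep(seq_len(config$n_classes / 2L), each = 2L))
        lapply(seq_along(pairs), function(k) {
          d <- synth_task_instances(config, pairs[[k]], sprintf("t%02d", k),
                                    config$noise_sd, config$fs, config$L)
          task_dataset(k, d$signal, d$label, d$instance_id, d$patient_id,
                       d$split, class_set = pairs[[k]])
        })
      },
      time_il = {
        classes <- 0:(config$n_classes - 1L)
        if (is.null(prevalence)) {
          # smooth seasonal drift in class mix across the three terms
          prevalence <- t(vapply(1:3, function(tm)
            exp(1.2 * cos(2 * pi * (classes / config$n_classes - (tm - 1) / 3))),
            numeric(config$n_classes)))
        }
        prevalence <- prevalence / rowSums(prevalence)
        noise <- config$noise_sd * c(1, 1.4, 1.8)
        lapply(1:3, function(k) {
          d <- synth_task_instances(config, classes, sprintf("term%d", k),
                                    noise[k], config$fs, config$L,
                                    prevalence = prevalence[k, ])
          task_dataset(k, d$signal, d$label, d$instance_id, d$patient_id,
                       d$split, class_set = classes)
        })
      },
      domain_il = {
        classes <- 0:(config$n_classes - 1L)
        gains <- lead_gains %||%
          c(1, 0.85, 0.7, 0.55, 0.45, 0.35, -0.35, -0.45, -0.55, -0.7, -0.85, -1)
        if (length(gains) != 12L) stop("domain_il expects 12 lead gains")
        lead_noise <- config$noise_sd * seq(0.6, 1.6, length.out = 12L)
        base <- synth_task_instances(config, classes, "lat",
                                     0, config$fs, config$L)
        lapply(1:12, function(k) {
          sig <- gains[k] * base$signal +
            matrix(rnorm(length(base$signal), 0, lead_noise[k]),
                   nrow(base$signal))
          task_dataset(k, sig, base$label,
                       sub("^lat", sprintf("lead%02d", k), base$instance_id),
                       base$patient_id, base$split, class_set = classes)
        })
      },
      institute_il = {
        groups <- split(0:(config$n_classes - 1L),
                        rep_len(1:3, config$n_classes))
        fs_native <- config$fs * c(1, 0.8, 1.25)
        noise <- config$noise_sd * c(1, 1.5, 0.8)
        lapply(1:3, function(k) {
          Ln <- as.integer(round(config$L * fs_native[k] / config$fs))
          d <- synth_task_instances(config, groups[[k]], sprintf("inst%d", k),
                                    noise[k], fs_native[k], Ln)
          # resample each trace to the stream's common grid
          tn <- (seq_len(Ln) - 1) / fs_native[k]
          tc <- (seq_len(config$L) - 1) / config$fs
          sig <- t(apply(d$signal, 1, function(x)
            approx(tn, x, xout = tc, rule = 2)$y))
          task_dataset(k, sig, d$label, d$instance_id, d$patient_id,
                       d$split, class_set = groups[[k]])
        })
      }
    )
    new_task_stream(scenario, tasks, config$L, config$fs, config$n_classes)
  })
}

# Subset helper: rows of a task by split.
task_split <- function(task, split) {
  idx <- which(task$split == split)
  list(idx = idx, signal = task$signal[idx, , drop = FALSE],
       label = task$label[idx], instance_id = task$instance_id[idx])
}
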