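# Synthetic ECG generator, scenario streams, and stream/WFDB round trips.

test_that("wavelet generator honours identity, determinism and beat placement", {
  zero <- list(rate_bpm = 60, rr_cv = 0, qrs_width = 0.08, st_offset = 0,
               p_amp = 0, r_amp = 0, t_amp = 0)
  sig <- synthesize_segment(zero, noise_sd = 0, L = 300, fs = 60, seed = 1)
  expect_identical(as.numeric(sig), rep(0, 300))
  pal <- default_morphologies(12)
  s1 <- synthesize_segment(pal[1, ], 0.1, 500, 100, seed = 4)
  s2 <- synthesize_segment(pal[1, ], 0.1, 500, 100, seed = 4)
  expect_identical(s1, s2)
  s3 <- synthesize_segment(pal[1, ], 0.1, 500, 100, seed = 5)
  expect_false(identical(as.numeric(s1), as.numeric(s3)))
  # 60 bpm, no RR jitter, 250 Hz, 10 s: exactly 10 R centers, 250 apart
  reg <- list(rate_bpm = 60, rr_cv = 0, qrs_width = 0.08, st_offset = 0,
              p_amp = 0.1, r_amp = 1, t_amp = 0.3)
  on <- attr(synthesize_segment(reg, 0, 2500, 250, seed = 2), "onsets")
  expect_length(on, 10L)
  expect_true(all(diff(on) == 250))
  expect_error(synthesize_segment(list(rate_bpm = 0), 0, 100, 10), "positive")
  expect_error(synthesize_segment(reg, 0, 0, 10), "positive")
  expect_error(synthesize_segment(reg, 0, 100, -1), "positive")
})

test_that("class-incremental streams are consecutive disjoint pairs", {
  st <- tiny_stream(n_classes = 12, n_train = 4L, n_val = 2L, n_test = 2L)
  expect_length(st$tasks, 6L)
  expect_identical(st$head_policy, "per_task")
  for (k in 1:6)
    expect_identical(st$tasks[[k]]$class_set, c(2L * k - 2L, 2L * k - 1L))
  expect_error(tiny_stream(n_classes = 5), "even")
  # signals finite, unique ids across stream
  ids <- unlist(lapply(st$tasks, `[[`, "instance_id"))
  expect_false(anyDuplicated(ids) > 0)
})

test_that("domain-incremental tasks are 12 projections of shared latents", {
  cfg <- synthetic_config(n_classes = 4, L = 240, fs = 60, n_train = 6,
                          n_val = 2, n_test = 2, noise_sd = 0.05,
                          label_noise = 0, artifact_frac = 0, seed = 9)
  st <- make_stream("domain_il", cfg)
  expect_length(st$tasks, 12L)
  expect_identical(st$head_policy, "shared")
  # same labels and patients in every lead task
  for (k in 2:12) {
    expect_identical(st$tasks[[k]]$label, st$tasks[[1]]$label)
    expect_identical(st$tasks[[k]]$patient_id, st$tasks[[1]]$patient_id)
  }
  # per instance, all leads correlate strongly (in magnitude) with lead 1
  for (i in c(1, 5)) {
    for (k in c(2, 7, 12)) {
      r <- cor(st$tasks[[1]]$signal[i, ], st$tasks[[k]]$signal[i, ])
      expect_gt(abs(r), 0.6)
    }
  }
})

test_that("time-incremental terms recover their configured prevalences", {
  prev <- rbind(c(0.6, 0.2, 0.1, 0.1),
                c(0.1, 0.6, 0.2, 0.1),
                c(0.1, 0.1, 0.2, 0.6))
  cfg <- synthetic_config(n_classes = 4, L = 240, fs = 60, n_train = 400,
                          n_val = 2, n_test = 2, noise_sd = 0.05,
                          label_noise = 0, artifact_frac = 0, seed = 10)
  st <- make_stream("time_il", cfg, prevalence = prev)
  expect_length(st$tasks, 3L)
  for (k in 1:3) {
    tr <- which(st$tasks[[k]]$split == "train")
    emp <- tabulate(st$tasks[[k]]$label[tr] + 1L, nbins = 4) / length(tr)
    tol <- 4 * sqrt(prev[k, ] * (1 - prev[k, ]) / length(tr))
    expect_true(all(abs(emp - prev[k, ]) < pmax(tol, 0.02)))
  }
})

test_that("institute-incremental tasks have disjoint vocabularies on a common grid", {
  st <- tiny_stream(n_classes = 6, scenario = "institute_il")
  expect_length(st$tasks, 3L)
  sets <- lapply(st$tasks, `[[`, "class_set")
  for (j in 1:2) for (k in (j + 1):3)
    expect_length(intersect(sets[[j]], sets[[k]]), 0L)
  expect_true(all(vapply(st$tasks, function(t) ncol(t$signal), integer(1)) ==
                    st$L))
})

test_that("splits are patient-disjoint across the generator and the validator", {
  st <- tiny_stream()
  for (tk in st$tasks) {
    for (sp in c("train", "val", "test")) {
      other <- setdiff(c("train", "val", "test"), sp)
      pats <- tk$patient_id[tk$split == sp]
      expect_length(intersect(pats, tk$patient_id[tk$split %in% other]), 0L)
    }
  }
  # the constructor rejects a patient appearing in two splits
  expect_error(task_dataset(1, matrix(0, 2, 4), c(0, 1), c("i1", "i2"),
                            c("p1", "p1"), c("train", "test")),
               "patient-disjoint")
})

test_that("stream round trip through disk is bitwise exact", {
  st <- tiny_stream(seed = 21)
  d1 <- file.path(tempdir(), "stream_a")
  d2 <- file.path(tempdir(), "stream_b")
  write_stream(st, d1)
  st2 <- read_stream(d1)
  expect_identical(st2$scenario, st$scenario)
  for (k in seq_along(st$tasks)) {
    expect_identical(unname(st2$tasks[[k]]$signal), unname(st$tasks[[k]]$signal))
    expect_identical(st2$tasks[[k]]$label, st$tasks[[k]]$label)
    expect_identical(st2$tasks[[k]]$split, st$tasks[[k]]$split)
  }
  # write(read(write(S))) == write(S) byte for byte
  write_stream(st2, d2)
  for (f in c("manifest.csv", "signals.bin", "stream.json"))
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  # truncated signal container is reported as corrupt
  bin <- file.path(d1, "signals.bin")
  writeBin(readBin(bin, "raw", file.size(bin) - 8), bin)
  expect_error(read_stream(d1), "corrupt")
})

test_that("WFDB records round trip through the format-16 writer and reader", {
  dir <- file.path(tempdir(), "wfdb_fix")
  t <- seq(0, 2, length.out = 500)
  sigs <- list(rec1 = sin(2 * pi * 3 * t), rec2 = 0.5 * cos(2 * pi * 5 * t))
  for (nm in names(sigs)) write_wfdb(dir, nm, sigs[[nm]], fs = 250)
  for (nm in names(sigs)) {
    rec <- read_wfdb(file.path(dir, nm))
    expect_equal(rec$fs, 250)
    expect_equal(rec$n, 500L)
    # quantisation error bounded by half an ADC count
    expect_lt(max(abs(rec$signal - sigs[[nm]])), 0.5 / 200 + 1e-12)
  }
  task <- wfdb_task(file.path(dir, names(sigs)), label = c(0L, 1L))
  expect_s3_class(task, "task_dataset")
  expect_equal(dim(task$signal), c(2L, 500L))
})
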