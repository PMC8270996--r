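# Orchestration: schedules, strategies, evaluation-matrix protocol,
# reproducibility, and leakage guarantees. All runs here are tiny.

test_that("schedule constraint tau_s >= tau_mc > tau is enforced", {
  expect_error(train_config(tau = 20, tau_mc = 15), "schedule")
  expect_error(train_config(tau = 20, tau_mc = 25, tau_s = 22), "schedule")
  cfg <- train_config(tau = 20)
  expect_identical(cfg$tau_mc, 21L)
  expect_identical(cfg$tau_s, 21L)
  expect_error(train_config(b = 0), "fraction")
  expect_error(train_config(strategy = "gem"), "'arg'")
})

test_that("run_stream fills a complete lower triangle and is reproducible", {
  st <- tiny_stream(n_classes = 4, seed = 31)
  cc <- tiny_config(seed = 5)
  r1 <- run_stream(st, cc)
  expect_equal(dim(r1$R), c(2L, 2L))
  expect_true(all(!is.na(r1$R[upper.tri(r1$R, diag = TRUE)])))
  expect_true(is.na(r1$R[2, 1]))
  expect_true(all(r1$R >= 0 & r1$R <= 1, na.rm = TRUE))
  # same config and seed: bit-identical logged metrics and R matrix
  r2 <- run_stream(st, cc)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$R, r2$R)
  expect_identical(r1$s_table$s, r2$s_table$s)
  # different seed differs
  r3 <- run_stream(st, tiny_config(seed = 6))
  expect_false(identical(r1$R, r3$R))
})

test_that("fine-tuning carries no buffer events and no task-instance parameters", {
  st <- tiny_stream(n_classes = 4, seed = 32)
  r <- run_stream(st, tiny_config(strategy = "fine_tuning", seed = 1))
  expect_equal(nrow(r$buffer), 0L)
  expect_null(r$s_table)
})

test_that("the buffer only ever holds training instances of earlier tasks", {
  st <- tiny_stream(n_classes = 6, seed = 33)
  r <- run_stream(st, tiny_config(seed = 2))
  # no test or val instance is ever stored
  for (tk in st$tasks) {
    stored <- r$buffer$instance_id[r$buffer$task_id == tk$task_id]
    expect_true(all(stored %in% tk$instance_id[tk$split == "train"]))
  }
  # the last task is never in the buffer (storage happens after training,
  # and nothing trains after it stores)
  last <- st$tasks[[length(st$tasks)]]$task_id
  expect_setequal(unique(r$buffer$task_id),
                  setdiff(vapply(st$tasks, `[[`, integer(1), "task_id"), NULL))
  # slot sizes follow ceiling(b * N_k)
  n_tr <- vapply(st$tasks, function(t) sum(t$split == "train"), integer(1))
  for (k in unique(r$buffer$task_id))
    expect_equal(sum(r$buffer$task_id == k),
                 min(ceiling(tiny_config()$b * n_tr[k]), n_tr[k]))
})

test_that("beta trajectories freeze into s = tau when their learning rate is zero", {
  st <- tiny_stream(n_classes = 4, seed = 34)
  cc <- tiny_config(eta_beta = 0, seed = 3)
  r <- run_stream(st, cc)
  expect_true(all(abs(r$s_table$s - cc$tau) < 1e-12))
})

test_that("training reduces the current-task loss", {
  st <- tiny_stream(n_classes = 2, seed = 35, n_train = 24L)
  r <- run_stream(st, tiny_config(tau = 8L, seed = 4))
  losses <- r$history$loss$train_loss
  expect_lt(losses[length(losses)], losses[1])
})

test_that("task_order reorders training and curriculum vectors are honoured", {
  st <- tiny_stream(n_classes = 6, seed = 36)
  r <- run_stream(st, tiny_config(seed = 7, task_order = c(3L, 1L, 2L)))
  expect_identical(r$task_order, c(3L, 1L, 2L))
  expect_identical(rownames(r$R), c("3", "1", "2"))
  expect_error(run_stream(st, tiny_config(task_order = c(1L, 2L))),
               "permutation")
})

test_that("multi-task learning trains once on pooled data, filling only the final column", {
  st <- tiny_stream(n_classes = 4, seed = 37)
  r <- run_stream(st, tiny_config(strategy = "mtl", seed = 8))
  expect_true(all(!is.na(r$R[, 2])))
  expect_true(all(is.na(r$R[, 1])))
  expect_true(is.na(r$metrics$bwt))
  expect_true(!is.na(r$metrics$average_auc))
})

test_that("run export writes the expected delimited artifacts", {
  st <- tiny_stream(n_classes = 4, seed = 38)
  r <- run_stream(st, tiny_config(seed = 9))
  d <- file.path(tempdir(), "run_export")
  export_run(r, d)
  expect_true(all(file.exists(file.path(
    d, c("rmatrix.csv", "metrics.json", "s_values.csv", "buffer.csv",
         "history.csv")))))
  met <- jsonlite::read_json(file.path(d, "metrics.json"))
  expect_equal(met$average_auc, r$metrics$average_auc, tolerance = 1e-12)
  rm <- read.csv(file.path(d, "rmatrix.csv"), row.names = 1)
  expect_equal(unname(as.matrix(rm)), unname(r$R), ignore_attr = TRUE)
})

test_that("shared-head scenarios train and evaluate through one head", {
  st <- tiny_stream(n_classes = 4, seed = 39, scenario = "time_il",
                    n_train = 12L)
  r <- run_stream(st, tiny_config(tau = 2L, seed = 10))
  expect_equal(dim(r$R), c(3L, 3L))
  expect_true(all(!is.na(r$R[upper.tri(r$R, diag = TRUE)])))
})

test_that("ablation strategies run and apply their storage rules", {
  st <- tiny_stream(n_classes = 4, seed = 40)
  for (strat in c("random_storage", "random_acquisition", "random_both",
                  "loss_area_storage")) {
    r <- run_stream(st, tiny_config(seed = 11, strategy = strat))
    expect_s3_class(r, "clops_run")
    expect_gt(nrow(r$buffer), 0)
  }
  # loss-area storage stores the smallest-area (easiest) instances
  r <- run_stream(st, tiny_config(seed = 12, strategy = "loss_area_storage"))
  expect_true(all(r$buffer$task_id %in% 1:2))
})
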