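# Replay buffer: storage cardinalities and ranking, BALD, acquisition.

test_that("store_task keeps the ceiling(b*N) top-s instances with lexicographic ties", {
  set.seed(1)
  task <- toy_task(8)
  s <- setNames(seq(0.1, 0.8, by = 0.1), task$instance_id)
  buf <- store_task(replay_buffer(), task, s, b = 0.25)
  slot <- buf$slots[["1"]]
  expect_length(slot$instance_id, 2L)             # ceiling(0.25 * 8)
  expect_setequal(slot$instance_id, c("a08", "a07"))
  # all-equal scores: the two lexicographically smallest ids win
  buf2 <- store_task(replay_buffer(), task, setNames(rep(1, 8), task$instance_id), 0.25)
  expect_identical(sort(buf2$slots[["1"]]$instance_id), c("a01", "a02"))
  # smallest = TRUE stores the bottom of the ranking (loss-area strategy)
  buf3 <- store_task(replay_buffer(), task, s, 0.25, smallest = TRUE)
  expect_setequal(buf3$slots[["1"]]$instance_id, c("a01", "a02"))
  # random scores against a brute-force sort oracle
  set.seed(5)
  for (rep in 1:5) {
    task50 <- toy_task(50)
    sc <- setNames(runif(50), task50$instance_id)
    got <- store_task(replay_buffer(), task50, sc, 0.3)$slots[["1"]]$instance_id
    expect_setequal(got, names(sort(sc, decreasing = TRUE))[1:ceiling(0.3 * 50)])
  }
  expect_error(store_task(replay_buffer(), task, s[-1], 0.25), "missing")
  expect_error(store_task(replay_buffer(), task, s, 0), "fraction")
})

test_that("bald_mcd equals entropy of mean minus mean entropy", {
  # identical slices: zero disagreement
  p <- c(0.2, 0.5, 0.3)
  G <- array(rep(p, each = 2 * 6), c(2, 6, 3))
  for (t in 1:6) G[, t, ] <- matrix(p, 2, 3, byrow = TRUE)
  expect_equal(bald_mcd(G), c(0, 0), tolerance = 1e-9, ignore_attr = TRUE)
  # analytic two-sample case: H(1/2,1/2) = ln 2, per-sample entropies 0
  G2 <- array(c(1, 0, 0, 1), c(1, 2, 2))
  expect_equal(as.numeric(bald_mcd(G2)), log(2), tolerance = 1e-12)
  # random tensor against a brute-force entropy oracle
  set.seed(8)
  M <- 5; T <- 20; C <- 4
  G3 <- array(runif(M * T * C), c(M, T, C))
  for (m in 1:M) for (t in 1:T) G3[m, t, ] <- G3[m, t, ] / sum(G3[m, t, ])
  ent <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  ref <- vapply(1:M, function(m) {
    pbar <- colMeans(G3[m, , ])
    ent(pbar) - mean(apply(G3[m, , ], 1, ent))
  }, numeric(1))
  expect_equal(as.numeric(bald_mcd(G3)), ref, tolerance = 1e-10)
  expect_true(all(bald_mcd(G3) >= -1e-12))
  # a non-simplex slice is rejected
  G3[1, 1, ] <- c(2, 0, 0, 0)
  expect_error(bald_mcd(G3), "simplex")
})

test_that("duplicating a posterior sample never lifts BALD above H(pbar)", {
  set.seed(9)
  for (rep in 1:20) {
    C <- sample(2:5, 1); T <- sample(2:10, 1)
    G <- array(runif(T * C), c(1, T, C))
    for (t in 1:T) G[1, t, ] <- G[1, t, ] / sum(G[1, t, ])
    Gdup <- array(NA_real_, c(1, T + 1, C))
    Gdup[1, 1:T, ] <- G[1, , ]
    Gdup[1, T + 1, ] <- G[1, T, ]
    pbar <- colMeans(Gdup[1, , ])
    H_pbar <- -sum(pbar * log(pbar))
    expect_lte(as.numeric(bald_mcd(Gdup)), H_pbar + 1e-12)
    expect_gte(as.numeric(bald_mcd(Gdup)), -1e-12)
  }
})

test_that("acquire takes the per-task top-BALD fraction deterministically", {
  set.seed(2)
  buf <- replay_buffer()
  for (k in 1:3)
    buf <- store_task(buf, toy_task(8, task_id = k),
                      setNames(runif(8), sprintf("a%02d", 1:8)), b = 0.5)
  ids <- unlist(lapply(buf$slots, `[[`, "instance_id"))
  bald <- setNames(runif(length(ids)), ids)
  pool <- acquire(buf, bald, a = 0.5)
  expect_length(pool, 3L)
  for (nm in names(pool)) {
    slot <- buf$slots[[nm]]
    expect_length(pool[[nm]]$instance_id, 2L)   # ceiling(0.5 * 4)
    ref <- slot$instance_id[order(-bald[slot$instance_id], slot$instance_id)][1:2]
    expect_identical(pool[[nm]]$instance_id, ref)
  }
  # a = 1 returns the whole buffer
  pool_all <- acquire(buf, bald, a = 1)
  expect_identical(unname(vapply(pool_all, function(p) length(p$instance_id), integer(1))),
                   rep(4L, 3))
  # empty buffer is an empty pool, not an error
  expect_length(acquire(replay_buffer(), bald, 0.5), 0L)
  expect_error(acquire(buf, bald[-1], 0.5), "missing")
})

test_that("random storage and acquisition honour the same cardinalities", {
  task <- toy_task(10)
  set.seed(3)
  buf <- random_store(replay_buffer(), task, b = 0.2)
  expect_length(buf$slots[["1"]]$instance_id, 2L)
  pool <- random_acquire(buf, a = 0.5)
  expect_length(pool[["1"]]$instance_id, 1L)
  # fixed seed: identical selections
  set.seed(99); s1 <- random_store(replay_buffer(), task, 0.2)$slots[["1"]]$instance_id
  set.seed(99); s2 <- random_store(replay_buffer(), task, 0.2)$slots[["1"]]$instance_id
  expect_identical(s1, s2)
  # uniformity: over many draws each instance appears ~ b of the time
  set.seed(17)
  counts <- integer(10); names(counts) <- task$instance_id
  n_rep <- 1000
  for (i in seq_len(n_rep)) {
    sel <- random_store(replay_buffer(), task, 0.2)$slots[["1"]]$instance_id
    counts[sel] <- counts[sel] + 1L
  }
  p_hat <- counts / n_rep
  tol <- 3 * sqrt(0.2 * 0.8 / n_rep)
  expect_true(all(abs(p_hat - 0.2) < tol))
})

test_that("buffer manifest reflects slots and per-task allotments accumulate", {
  set.seed(4)
  buf <- replay_buffer()
  for (k in 1:2)
    buf <- store_task(buf, toy_task(9, task_id = k),
                      setNames(runif(9), sprintf("a%02d", 1:9)), b = 0.25,
                      epoch = 10 * k)
  man <- buffer_manifest(buf)
  expect_equal(nrow(man), 2 * ceiling(0.25 * 9))
  expect_setequal(unique(man$task_id), 1:2)
  expect_true(all(man$stored_epoch %in% c(10, 20)))
  # re-storing a task replaces its slot without touching the other task
  buf2 <- store_task(buf, toy_task(9, task_id = 2),
                     setNames(runif(9), sprintf("a%02d", 1:9)), b = 0.5)
  expect_length(buf2$slots[["1"]]$instance_id, 3L)
  expect_length(buf2$slots[["2"]]$instance_id, 5L)
})
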