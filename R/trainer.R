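# Sequential training over a task stream under a chosen continual-learning
# strategy, with the importance-guided storage / uncertainty-guided
# acquisition schedule.

STRATEGIES <- c("clops", "fine_tuning", "mtl", "random_storage",
                "random_acquisition", "random_both", "loss_area_storage")

#' Training configuration
#'
#' @param tau epochs per task.
#' @param tau_mc first global epoch at which BALD is recomputed over the
#'   buffer (default `tau + 1`: the first epoch after the first task).
#' @param tau_s first global epoch at which the replay pool is refreshed by
#'   acquisition (default `tau_mc`). The schedule must satisfy
#'   `tau_s >= tau_mc > tau`; with the defaults, scoring and acquisition
#'   recur every `mc_every` epochs after the first task, so buffered
#'   instances are replayed from the first epoch of the second task on.
#' @param B current-task mini-batch size.
#' @param B_r replayed instances added to each mini-batch (default `B`).
#' @param lr Adam learning rate for the network.
#' @param eta_beta learning rate for the task-instance coefficients
#'   (default: the network learning rate).
#' @param lambda regularisation coefficient of the coefficient decay
#'   (default 10).
#' @param b storage fraction in `(0, 1]` (default 0.25).
#' @param a acquisition fraction in `(0, 1]` (default 0.5).
#' @param T Monte-Carlo dropout samples for BALD (default 20).
#' @param mc_every epochs between BALD/acquisition refreshes once the
#'   schedule is active (default 1: every epoch).
#' @param strategy one of `"clops"`, `"fine_tuning"`, `"mtl"`,
#'   `"random_storage"`, `"random_acquisition"`, `"random_both"`,
#'   `"loss_area_storage"`.
#' @param seed run seed; fixed-seed runs are reproducible bitwise in their
#'   logged metrics.
#' @param task_order `NULL` (stream order), `"random"`, or an explicit
#'   vector of task ids (e.g. a curriculum from [build_curriculum()]).
#' @param net a [classifier_spec()].
#' @param beta_floor optional lower clamp on the coefficients
#'   (default `-Inf`, off).
#' @return a `train_config` list.
#' @export
train_config <- function(tau = 20L, tau_mc = tau + 1L, tau_s = tau_mc,
                         B = 16L, B_r = B, lr = 1e-3, eta_beta = lr,
                         lambda = 10, b = 0.25, a = 0.5, T = 20L,
                         mc_every = 1L,
                         strategy = "clops", seed = 1L, task_order = NULL,
                         net = classifier_spec(), beta_floor = -Inf) {
  strategy <- match.arg(strategy, STRATEGIES)
  if (tau < 1L) stop("tau must be positive")
  if (!(tau_s >= tau_mc && tau_mc > tau))
    stop("invalid schedule: need tau_s >= tau_mc > tau")
  if (b <= 0 || b > 1 || a <= 0 || a > 1)
    stop("fractions b and a must be in (0, 1]")
  if (T < 1L) stop("T must be >= 1")
  structure(list(tau = as.integer(tau), tau_mc = as.integer(tau_mc),
                 tau_s = as.integer(tau_s), B = as.integer(B),
                 B_r = as.integer(B_r), lr = lr, eta_beta = eta_beta,
                 lambda = lambda, b = b, a = a, T = as.integer(T),
                 mc_every = as.integer(mc_every), strategy = strategy,
                 seed = as.integer(seed), task_order = task_order,
                 net = net, beta_floor = beta_floor),
            class = "train_config")
}

strategy_traits <- function(strategy) {
  list(
    use_beta = !strategy %in% c("fine_tuning", "mtl"),
    use_buffer = !strategy %in% c("fine_tuning", "mtl"),
    storage = switch(strategy, clops = "guided",
                     random_acquisition = "guided",
                     random_storage = "random", random_both = "random",
                     loss_area_storage = "loss_area", "none"),
    acquisition = switch(strategy, clops = "guided",
                         random_storage = "guided",
                         loss_area_storage = "guided",
                         random_acquisition = "random",
                         random_both = "random", "none")
  )
}

task_head_id <- function(stream, task) {
  if (stream$head_policy == "per_task") as.character(task$task_id) else "shared"
}

build_stream_heads <- function(stream, mtl = FALSE) {
  if (!mtl && stream$head_policy == "per_task") {
    heads <- lapply(stream$tasks, `[[`, "class_set")
    names(heads) <- vapply(stream$tasks, function(t) as.character(t$task_id),
                           character(1))
    heads
  } else {
    list(shared = stream$class_union)
  }
}

# Per-instance cross-entropy of a head on given rows (no dropout).
instance_ce <- function(model, head, X, labels) {
  p <- predict_proba(model, X, head)
  loc <- match(labels, model$heads[[head]])
  -log(pmax(p[cbind(seq_len(nrow(p)), loc)], 1e-12))
}

eval_task_auc_model <- function(model, stream, task, split) {
  head <- task_head_id(stream, task)
  sp <- task_split(task, split)
  probs <- predict_proba(model, sp$signal, head)
  cols <- match(task$class_set, model$heads[[head]])
  sub <- probs[, cols, drop = FALSE]
  sub <- sub / rowSums(sub)
  task_auc(sub, sp$label, classes = task$class_set)
}

# BALD over the whole buffer: one stacked trunk pass per MC sample, then
# each slot's own head (slots can differ in class set under per-task heads).
compute_buffer_bald <- function(model, stream, buffer, T) {
  slots <- buffer$slots
  if (!length(slots)) return(numeric(0))
  X <- do.call(rbind, lapply(slots, `[[`, "signal"))
  counts <- vapply(slots, function(s) nrow(s$signal), integer(1))
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  heads <- vapply(names(slots), function(nm)
    if (stream$head_policy == "per_task") nm else "shared", character(1))
  Gs <- lapply(seq_along(slots), function(j)
    array(NA_real_, c(counts[j], T, length(model$heads[[heads[j]]]))))
  # single deterministic trunk pass; stochasticity enters via the dropout
  # masks on the penultimate representation
  h0 <- trunk_forward(model, X, dropout_active = FALSE)$h
  p <- model$spec$dropout
  for (t in seq_len(T)) {
    mask <- if (p > 0)
      matrix((runif(length(h0)) >= p) / (1 - p), nrow(h0), ncol(h0))
    else 1
    h <- h0 * mask
    for (j in seq_along(slots))
      Gs[[j]][, t, ] <- softmax_rows(head_logits(
        model, heads[j], h[starts[j]:ends[j], , drop = FALSE]))
  }
  out <- numeric(0)
  for (j in seq_along(slots)) {
    sc <- bald_mcd(Gs[[j]])
    names(sc) <- slots[[j]]$instance_id
    out <- c(out, sc)
  }
  out
}

flatten_pool <- function(pool) {
  rows <- list()
  for (ent in pool) {
    for (i in seq_along(ent$instance_id))
      rows[[length(rows) + 1L]] <- list(task_id = ent$task_id, idx = i,
                                        ent = ent)
  }
  rows
}

# One optimisation step over a combined current+replay mini-batch.
# Returns per-instance current losses and the logged batch loss.
train_step <- function(model, opt, stream, task, cb_rows, betas_cb, pool,
                       config, traits) {
  head_cur <- task_head_id(stream, task)
  Xc <- task$signal[cb_rows, , drop = FALSE]
  yc <- task$label[cb_rows]
  Bk <- length(cb_rows)
  rep_entries <- if (traits$use_buffer && length(pool)) flatten_pool(pool) else list()
  m <- 0L
  Xr <- NULL; yr <- integer(0); rheads <- character(0)
  if (length(rep_entries)) {
    m <- config$B_r
    pick <- sample.int(length(rep_entries), m,
                       replace = length(rep_entries) < m)
    Xr <- do.call(rbind, lapply(rep_entries[pick], function(e)
      e$ent$signal[e$idx, , drop = FALSE]))
    yr <- vapply(rep_entries[pick], function(e) e$ent$label[e$idx], integer(1))
    rheads <- vapply(rep_entries[pick], function(e)
      if (stream$head_policy == "per_task") as.character(e$task_id)
      else "shared", character(1))
  }
  X <- rbind(Xc, Xr)
  fwd <- trunk_forward(model, X, dropout_active = model$spec$dropout > 0)
  h <- fwd$h
  dh <- matrix(0, nrow(h), ncol(h))
  grads <- list()
  add_head_grad <- function(head, rows, labels, w) {
    logits <- head_logits(model, head, h[rows, , drop = FALSE])
    P <- softmax_rows(logits)
    loc <- match(labels, model$heads[[head]])
    ce <- -log(pmax(P[cbind(seq_along(rows), loc)], 1e-12))
    Y <- matrix(0, length(rows), ncol(P))
    Y[cbind(seq_along(rows), loc)] <- 1
    dlog <- (P - Y) * w
    wn <- sprintf("head.%s.W", head); bn <- sprintf("head.%s.b", head)
    grads[[wn]] <<- (grads[[wn]] %||% 0) +
      crossprod(h[rows, , drop = FALSE], dlog)
    grads[[bn]] <<- (grads[[bn]] %||% 0) + colSums(dlog)
    dh[rows, ] <<- dh[rows, , drop = FALSE] +
      dlog %*% t(model$params[[wn]])
    ce
  }
  w_cur <- if (traits$use_beta) betas_cb / Bk else rep(1 / Bk, Bk)
  ce_cur <- add_head_grad(head_cur, seq_len(Bk), yc, w_cur)
  ce_rep <- numeric(0)
  if (m > 0L) {
    rrows <- Bk + seq_len(m)
    for (hd in unique(rheads)) {
      sel <- which(rheads == hd)
      ce_rep <- c(ce_rep, add_head_grad(hd, rrows[sel], yr[sel], 1 / m))
    }
  }
  grads <- c(grads, trunk_backward(model, fwd$cache, dh))
  model$params <- adam_step(model$params, grads, opt, lr = config$lr)
  lam <- if (traits$use_beta) config$lambda else 0
  bts <- if (traits$use_beta) betas_cb else rep(1, Bk)
  list(model = model, ce_cur = ce_cur,
       batch_loss = current_task_loss(ce_cur, bts, lam) + replay_loss(ce_rep))
}

#' Run a continual-learning experiment over a task stream
#'
#' Trains the classifier on the stream's tasks in order under the configured
#' strategy. After each task the buffer is updated per the strategy's
#' storage rule and the evaluation matrix column `R[j <= k, k]` is filled
#' with test AUCs. During training on task `k > 1`, every mini-batch is
#' augmented with `B_r` instances drawn uniformly from the acquisition pool,
#' which is refreshed on the `tau_mc`/`tau_s` schedule via `T`-sample BALD
#' scoring of the whole buffer. The `mtl` strategy instead pools all tasks'
#' training data, trains once with a shared head, and fills only the final
#' column of R.
#'
#' @param stream a `task_stream`.
#' @param config a [train_config()].
#' @return a `clops_run` log: evaluation matrix `R`, `metrics`
#'   (average_auc, bwt, bwt_t, bwt_lambda), the storage-score table
#'   `s_table`, the buffer manifest, per-epoch `history`, and the resolved
#'   task order.
#' @export
run_stream <- function(stream, config) {
  stopifnot(inherits(stream, "task_stream"), inherits(config, "train_config"))
  set.seed(config$seed)
  traits <- strategy_traits(config$strategy)
  tids <- vapply(stream$tasks, `[[`, integer(1), "task_id")
  order_pos <- if (is.null(config$task_order)) seq_along(stream$tasks)
    else if (identical(config$task_order, "random")) sample(seq_along(stream$tasks))
    else {
      pos <- match(as.integer(config$task_order), tids)
      if (anyNA(pos) || length(pos) != length(tids))
        stop("task_order must be a permutation of the stream's task ids")
      pos
    }
  tasks <- stream$tasks[order_pos]
  N <- length(tasks)
  if (config$strategy == "mtl")
    return(run_mtl(stream, tasks, config))
  model <- build_classifier(config$net, stream$L, build_stream_heads(stream))
  opt <- adam_init(model$params)
  R <- matrix(NA_real_, N, N,
              dimnames = list(vapply(tasks, `[[`, integer(1), "task_id"),
                              vapply(tasks, `[[`, integer(1), "task_id")))
  buffer <- replay_buffer()
  pool <- list()
  bald <- NULL
  global_epoch <- 0L
  s_rows <- list()
  hist_loss <- list()
  hist_auc <- list()
  for (k in seq_len(N)) {
    task <- tasks[[k]]
    head_cur <- task_head_id(stream, task)
    tr <- which(task$split == "train")
    n_tr <- length(tr)
    betas <- rep(1, n_tr)
    beta_traj <- matrix(NA_real_, n_tr, config$tau + 1L)
    beta_traj[, 1L] <- 1
    loss_traj <- matrix(NA_real_, n_tr, config$tau + 1L)
    loss_traj[, 1L] <- instance_ce(model, head_cur,
                                   task$signal[tr, , drop = FALSE],
                                   task$label[tr])
    for (epoch in seq_len(config$tau)) {
      global_epoch <- global_epoch + 1L
      if (traits$use_buffer && length(buffer$slots)) {
        if (global_epoch >= config$tau_mc &&
            (global_epoch - config$tau_mc) %% config$mc_every == 0L)
          bald <- compute_buffer_bald(model, stream, buffer, config$T)
        if (global_epoch >= config$tau_s && !is.null(bald))
          pool <- switch(traits$acquisition,
                         guided = acquire(buffer, bald, config$a),
                         random = random_acquire(buffer, config$a),
                         list())
      }
      perm <- sample(n_tr)
      batches <- split(perm, ceiling(seq_along(perm) / config$B))
      ep_losses <- numeric(0)
      for (bt in batches) {
        st <- train_step(model, opt, stream, task, tr[bt], betas[bt], pool,
                         config, traits)
        model <- st$model
        if (traits$use_beta)
          betas[bt] <- update_betas(betas[bt], st$ce_cur, config$lambda,
                                    config$eta_beta, config$beta_floor)
        loss_traj[bt, epoch + 1L] <- st$ce_cur
        ep_losses <- c(ep_losses, st$batch_loss)
      }
      beta_traj[, epoch + 1L] <- betas
      hist_loss[[length(hist_loss) + 1L]] <- data.frame(
        global_epoch = global_epoch, position = k, task_id = task$task_id,
        train_loss = mean(ep_losses))
      for (j in seq_len(k))
        hist_auc[[length(hist_auc) + 1L]] <- data.frame(
          global_epoch = global_epoch, eval_task = tasks[[j]]$task_id,
          val_auc = eval_task_auc_model(model, stream, tasks[[j]], "val"))
    }
    # end of task: record scores, store into buffer, fill R column
    ids_tr <- task$instance_id[tr]
    if (traits$use_beta) {
      s <- apply(beta_traj, 1L, storage_score)
      names(s) <- ids_tr
      s_rows[[length(s_rows) + 1L]] <- data.frame(
        instance_id = ids_tr, task_id = task$task_id,
        label = task$label[tr], s = unname(s), stringsAsFactors = FALSE)
    }
    if (traits$use_buffer) {
      buffer <- switch(traits$storage,
        guided = store_task(buffer, task, s, config$b, epoch = global_epoch),
        random = random_store(buffer, task, config$b, epoch = global_epoch),
        loss_area = {
          area <- apply(loss_traj, 1L, loss_area_score)
          names(area) <- ids_tr
          store_task(buffer, task, area, config$b, smallest = TRUE,
                     epoch = global_epoch)
        })
    }
    for (j in seq_len(k))
      R[j, k] <- eval_task_auc_model(model, stream, tasks[[j]], "test")
  }
  metrics <- list(
    average_auc = average_auc(R),
    bwt = if (N >= 2L) bwt(R) else NA_real_,
    bwt_t = if (N >= 2L) vapply(seq_len(N - 1L), function(t) bwt_t(R, t),
                                numeric(1)) else numeric(0),
    bwt_lambda = if (N >= 2L) bwt_lambda(R) else NA_real_)
  structure(list(
    scenario = stream$scenario, strategy = config$strategy,
    task_order = vapply(tasks, `[[`, integer(1), "task_id"),
    R = R, metrics = metrics,
    s_table = if (length(s_rows)) do.call(rbind, s_rows) else NULL,
    buffer = buffer_manifest(buffer, bald),
    history = list(loss = do.call(rbind, hist_loss),
                   val_auc = do.call(rbind, hist_auc)),
    config = config), class = "clops_run")
}

run_mtl <- function(stream, tasks, config) {
  model <- build_classifier(config$net, stream$L,
                            build_stream_heads(stream, mtl = TRUE))
  opt <- adam_init(model$params)
  N <- length(tasks)
  parts <- lapply(tasks, task_split, split = "train")
  X <- do.call(rbind, lapply(parts, `[[`, "signal"))
  y <- unlist(lapply(parts, `[[`, "label"))
  n <- nrow(X)
  hist_loss <- list()
  for (epoch in seq_len(config$tau)) {
    perm <- sample(n)
    batches <- split(perm, ceiling(seq_along(perm) / config$B))
    ep <- numeric(0)
    for (bt in batches) {
      fwd <- trunk_forward(model, X[bt, , drop = FALSE],
                           dropout_active = model$spec$dropout > 0)
      logits <- head_logits(model, "shared", fwd$h)
      P <- softmax_rows(logits)
      loc <- match(y[bt], model$heads$shared)
      ce <- -log(pmax(P[cbind(seq_along(bt), loc)], 1e-12))
      Y <- matrix(0, length(bt), ncol(P))
      Y[cbind(seq_along(bt), loc)] <- 1
      dlog <- (P - Y) / length(bt)
      grads <- list("head.shared.W" = crossprod(fwd$h, dlog),
                    "head.shared.b" = colSums(dlog))
      dh <- dlog %*% t(model$params[["head.shared.W"]])
      grads <- c(grads, trunk_backward(model, fwd$cache, dh))
      model$params <- adam_step(model$params, grads, opt, lr = config$lr)
      ep <- c(ep, mean(ce))
    }
    hist_loss[[epoch]] <- data.frame(global_epoch = epoch, position = NA,
                                     task_id = NA, train_loss = mean(ep))
  }
  R <- matrix(NA_real_, N, N,
              dimnames = list(vapply(tasks, `[[`, integer(1), "task_id"),
                              vapply(tasks, `[[`, integer(1), "task_id")))
  # shared-head evaluation regardless of the stream's head policy
  for (j in seq_len(N)) {
    task <- tasks[[j]]
    sp <- task_split(task, "test")
    probs <- predict_proba(model, sp$signal, "shared")
    cols <- match(task$class_set, model$heads$shared)
    sub <- probs[, cols, drop = FALSE]
    sub <- sub / rowSums(sub)
    R[j, N] <- task_auc(sub, sp$label, classes = task$class_set)
  }
  structure(list(
    scenario = stream$scenario, strategy = "mtl",
    task_order = vapply(tasks, `[[`, integer(1), "task_id"),
    R = R,
    metrics = list(average_auc = average_auc(R), bwt = NA_real_,
                   bwt_t = numeric(0), bwt_lambda = NA_real_),
    s_table = NULL, buffer = buffer_manifest(replay_buffer()),
    history = list(loss = do.call(rbind, hist_loss), val_auc = NULL),
    config = config), class = "clops_run")
}

#' @export
print.clops_run <- function(x, ...) {
  cat(sprintf("clops_run: %s strategy on %s stream (%d tasks)\n",
              x$strategy, x$scenario, ncol(x$R)))
  cat(sprintf("  average AUC = %.3f", x$metrics$average_auc))
  if (!is.na(x$metrics$bwt))
    cat(sprintf(", BWT = %+.3f, BWT_lambda = %+.3f",
                x$metrics$bwt, x$metrics$bwt_lambda))
  cat("\n")
  invisible(x)
}

#' Export a run log to delimited files
#'
#' Writes `rmatrix.csv`, `metrics.json`, `s_values.csv`, `buffer.csv` and
#' `history.csv` into a directory.
#'
#' @param run a `clops_run`.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
export_run <- function(run, path) {
  stopifnot(inherits(run, "clops_run"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write.csv(run$R, file.path(path, "rmatrix.csv"))
  jsonlite::write_json(run$metrics, file.path(path, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(run$s_table))
    write.csv(run$s_table, file.path(path, "s_values.csv"), row.names = FALSE)
  write.csv(run$buffer, file.path(path, "buffer.csv"), row.names = FALSE)
  write.csv(run$history$loss, file.path(path, "history.csv"),
            row.names = FALSE)
  invisible(path)
}
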