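# Replay buffer: importance-guided storage and BALD-guided acquisition.

#' Create an empty replay buffer
#'
#' The buffer holds one slot per completed task. Task `k`'s slot receives
#' exactly `min(ceiling(b * N_k), N_k)` instances when the task is stored;
#' slots never evict other tasks' entries, so the total buffer size is the
#' sum of the per-task allotments.
#'
#' @return a `replay_buffer`.
#' @export
replay_buffer <- function() {
  structure(list(slots = list()), class = "replay_buffer")
}

#' @export
print.replay_buffer <- function(x, ...) {
  cat(sprintf("replay_buffer: %d task slot(s), %d instance(s)\n",
              length(x$slots),
              sum(vapply(x$slots, function(s) length(s$instance_id), integer(1)))))
  invisible(x)
}

slot_from_task <- function(task, idx, scores, epoch) {
  list(task_id = task$task_id,
       instance_id = task$instance_id[idx],
       signal = task$signal[idx, , drop = FALSE],
       label = task$label[idx],
       s = unname(scores[task$instance_id[idx]]),
       stored_epoch = epoch)
}

#' Store a task's top-scoring training instances into the buffer
#'
#' Ranks instances by their storage score and stores the top
#' `ceiling(b * N)` (`smallest = FALSE`, the default: largest `s`, i.e. the
#' easiest instances) or the bottom (`smallest = TRUE`, used by the
#' loss-area alternative). Ties are broken lexicographically by instance id,
#' making storage deterministic.
#'
#' @param buffer a `replay_buffer`.
#' @param task a `task_dataset`; only its training split is eligible.
#' @param scores named numeric vector, instance id -> score, covering every
#'   training instance of the task.
#' @param b storage fraction in `(0, 1]`.
#' @param smallest store smallest scores instead of largest.
#' @param epoch bookkeeping tag written to the buffer manifest.
#' @return the updated buffer.
#' @export
store_task <- function(buffer, task, scores, b, smallest = FALSE, epoch = NA) {
  stopifnot(inherits(buffer, "replay_buffer"), inherits(task, "task_dataset"))
  if (b <= 0 || b > 1) stop("storage fraction b must be in (0, 1]")
  tr <- which(task$split == "train")
  ids <- task$instance_id[tr]
  if (!all(ids %in% names(scores)))
    stop("missing storage score for some training instances")
  n <- length(tr)
  cap <- min(ceiling(b * n), n)
  s <- scores[ids]
  key <- if (smallest) s else -s
  pick <- tr[order(key, ids)[seq_len(cap)]]
  buffer$slots[[as.character(task$task_id)]] <-
    slot_from_task(task, pick, scores, epoch)
  buffer
}

#' Random-storage ablation
#'
#' Identical cardinality contract to [store_task()] but with a uniform
#' random selection (without replacement) under the current RNG stream.
#'
#' @inheritParams store_task
#' @return the updated buffer.
#' @export
random_store <- function(buffer, task, b, epoch = NA) {
  stopifnot(inherits(buffer, "replay_buffer"), inherits(task, "task_dataset"))
  if (b <= 0 || b > 1) stop("storage fraction b must be in (0, 1]")
  tr <- which(task$split == "train")
  cap <- min(ceiling(b * length(tr)), length(tr))
  pick <- sort(sample(tr, cap))
  scores <- setNames(rep(NA_real_, length(tr)), task$instance_id[tr])
  buffer$slots[[as.character(task$task_id)]] <-
    slot_from_task(task, pick, scores, epoch)
  buffer
}

#' BALD score from Monte-Carlo dropout posterior samples
#'
#' The mutual-information-style disagreement of the `T` posterior samples:
#' entropy of the mean posterior minus the mean per-sample entropy
#' (natural-log entropies). It is non-negative by Jensen's inequality and
#' zero when all samples agree.
#'
#' @param G posterior tensor of dim `M x T x C`; every `[m, t, ]` slice must
#'   be a probability vector (checked to 1e-6).
#' @return numeric vector of length `M`, named after `rownames(G)` when
#'   present.
#' @export
bald_mcd <- function(G) {
  d <- dim(G)
  if (length(d) != 3L) stop("G must be an M x T x C array")
  if (any(G < -1e-9) || any(abs(apply(G, c(1L, 2L), sum) - 1) > 1e-6))
    stop("posterior slices must lie on the probability simplex")
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
  pbar <- apply(G, c(1L, 3L), mean)                    # M x C
  if (is.null(dim(pbar))) pbar <- matrix(pbar, nrow = d[1])
  H_mean <- -rowSums(xlogx(pbar))
  H_each <- -apply(xlogx(G), c(1L, 2L), sum)           # M x T
  if (is.null(dim(H_each))) H_each <- matrix(H_each, nrow = d[1])
  out <- H_mean - rowMeans(H_each)
  names(out) <- dimnames(G)[[1]]
  out
}

pool_entry <- function(slot, idx) {
  list(task_id = slot$task_id,
       instance_id = slot$instance_id[idx],
       signal = slot$signal[idx, , drop = FALSE],
       label = slot$label[idx],
       bald = NULL)
}

#' Acquire the most uncertain instances from each buffer slot
#'
#' Per task independently, ranks the slot's instances by BALD score and
#' selects the top `ceiling(a * slot size)`; ties break lexicographically by
#' instance id. An empty buffer yields an empty pool.
#'
#' @param buffer a `replay_buffer`.
#' @param bald_scores named numeric vector, instance id -> BALD score,
#'   covering every buffered instance.
#' @param a acquisition fraction in `(0, 1]`.
#' @return an `acquisition_pool`: per-task list of selected instances.
#' @export
acquire <- function(buffer, bald_scores, a) {
  stopifnot(inherits(buffer, "replay_buffer"))
  if (a <= 0 || a > 1) stop("acquisition fraction a must be in (0, 1]")
  pool <- list()
  for (nm in names(buffer$slots)) {
    slot <- buffer$slots[[nm]]
    if (!all(slot$instance_id %in% names(bald_scores)))
      stop("missing BALD score for some buffered instances")
    k <- ceiling(a * length(slot$instance_id))
    sc <- bald_scores[slot$instance_id]
    idx <- order(-sc, slot$instance_id)[seq_len(k)]
    ent <- pool_entry(slot, idx)
    ent$bald <- unname(sc[idx])
    pool[[nm]] <- ent
  }
  structure(pool, class = "acquisition_pool")
}

#' Random-acquisition ablation
#'
#' Identical cardinality contract to [acquire()], selection uniform without
#' replacement under the current RNG stream.
#'
#' @inheritParams acquire
#' @return an `acquisition_pool`.
#' @export
random_acquire <- function(buffer, a) {
  stopifnot(inherits(buffer, "replay_buffer"))
  if (a <= 0 || a > 1) stop("acquisition fraction a must be in (0, 1]")
  pool <- list()
  for (nm in names(buffer$slots)) {
    slot <- buffer$slots[[nm]]
    n <- length(slot$instance_id)
    k <- ceiling(a * n)
    idx <- sort(sample.int(n, k))
    pool[[nm]] <- pool_entry(slot, idx)
  }
  structure(pool, class = "acquisition_pool")
}

#' Buffer manifest as a data frame
#'
#' @param buffer a `replay_buffer`.
#' @param bald_scores optional named vector of the latest BALD scores.
#' @return data.frame with task_id, instance_id, s, bald, stored_epoch.
#' @export
buffer_manifest <- function(buffer, bald_scores = NULL) {
  rows <- lapply(buffer$slots, function(slot) {
    data.frame(task_id = slot$task_id, instance_id = slot$instance_id,
               s = slot$s,
               bald = if (is.null(bald_scores)) NA_real_
                      else unname(bald_scores[slot$instance_id]),
               stored_epoch = slot$stored_epoch, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(task_id = integer(0), instance_id = character(0),
                      s = numeric(0), bald = numeric(0),
                      stored_epoch = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
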