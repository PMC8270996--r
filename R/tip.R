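# Task-instance parameters: learnable per-example loss coefficients, their
# gradient updates, and the trapezoidal storage scores over their
# trajectories.

#' Weighted current-task objective
#'
#' The current-task loss over a mini-batch of size `B_k`:
#' `(1/B_k) * sum_i [ beta_i * L_i + lambda * (beta_i - 1)^2 ]`.
#' The quadratic regulariser keeps the coefficients from collapsing to zero
#' as training progresses.
#'
#' @param losses non-negative per-instance losses (length `B_k`).
#' @param betas task-instance coefficients, same length.
#' @param lambda regularisation coefficient (default 10).
#' @return scalar loss.
#' @export
current_task_loss <- function(losses, betas, lambda = 10) {
  if (length(losses) != length(betas)) stop("losses and betas differ in length")
  if (length(losses) < 1L) stop("empty batch")
  if (any(losses < 0)) stop("losses must be non-negative")
  mean(betas * losses + lambda * (betas - 1)^2)
}

#' Unweighted replay objective
#'
#' Mean loss over the replayed instances of a mini-batch (instances drawn
#' from earlier tasks' buffer slots). Replayed instances are deliberately
#' not weighted; an empty replay set contributes zero, so the total batch
#' objective reduces to [current_task_loss()] on the first task.
#'
#' @param losses non-negative per-instance losses over replayed instances
#'   (possibly length 0).
#' @return scalar loss.
#' @export
replay_loss <- function(losses) {
  if (length(losses) == 0L) return(0)
  if (any(losses < 0)) stop("losses must be non-negative")
  mean(losses)
}

#' Gradient-descent update of the task-instance coefficients
#'
#' One step of `beta_i <- beta_i - eta * dL/dbeta_i` under the objective of
#' [current_task_loss()], whose exact per-coefficient gradient is
#' `(L_i + 2*lambda*(beta_i - 1)) / B_k`. With `lambda = 0` and a positive
#' loss, a coefficient strictly decreases — hard instances drag their
#' coefficient down.
#'
#' @param betas current coefficients.
#' @param losses per-instance losses (treated as constants in this step).
#' @param lambda regularisation coefficient.
#' @param eta learning rate for the coefficients.
#' @param floor optional lower clamp (default `-Inf`, i.e. off).
#' @return updated coefficients.
#' @export
update_betas <- function(betas, losses, lambda = 10, eta = 1e-3,
                         floor = -Inf) {
  if (length(losses) != length(betas)) stop("losses and betas differ in length")
  if (!all(is.finite(betas)) || !all(is.finite(losses)))
    stop("betas and losses must be finite")
  out <- betas - eta * (losses + 2 * lambda * (betas - 1)) / length(betas)
  pmax(out, floor)
}

#' Storage score: area under a coefficient trajectory
#'
#' Trapezoidal-rule area under the per-epoch trajectory `beta(0..tau)` with
#' unit epoch spacing; a constant trajectory at 1 over `tau` epochs scores
#' exactly `tau`. High areas mark easy instances, low areas hard ones.
#'
#' @param trajectory numeric vector of length `tau + 1` (epoch-end values
#'   with the initial value prepended).
#' @param dt epoch spacing (default 1).
#' @return scalar area.
#' @export
storage_score <- function(trajectory, dt = 1) {
  n <- length(trajectory)
  if (n < 2L) stop("trajectory needs at least two points")
  sum((trajectory[-1] + trajectory[-n]) / 2) * dt
}

#' Area under a per-instance loss trajectory
#'
#' Same trapezoid as [storage_score()], applied to a per-epoch loss
#' trajectory. A small area marks an easy instance; the alternative storage
#' strategy stores the smallest-area instances.
#'
#' @inheritParams storage_score
#' @return scalar area.
#' @export
loss_area_score <- function(trajectory, dt = 1) storage_score(trajectory, dt)
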