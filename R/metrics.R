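# Evaluation-matrix bookkeeping and backward-transfer metrics.
#
# The R matrix holds R[j, i]: the test AUC on task j after completing
# training on the i-th task of the sequence, defined for i >= j (upper
# entries are NA).

check_rmatrix <- function(R) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) stop("R must be a square matrix")
  low <- R[lower.tri(R, diag = TRUE)]
  if (any(is.na(t(R)[lower.tri(R, diag = TRUE)])))
    stop("R must be complete for all i >= j")
  if (any(low < -1e-9, na.rm = TRUE) || any(low > 1 + 1e-9, na.rm = TRUE))
    stop("AUC entries must lie in [0, 1]")
  invisible(R)
}

#' Average AUC at the end of the task sequence
#'
#' Mean over tasks of the final-column entries `R[j, N]`.
#'
#' @param R evaluation matrix (rows: evaluated task j, columns: after
#'   training task i).
#' @return scalar.
#' @export
average_auc <- function(R) {
  N <- ncol(R)
  if (any(is.na(R[, N]))) stop("final column of R is incomplete")
  mean(R[, N])
}

#' Backward transfer
#'
#' `BWT = (1/(N-1)) * sum_{j<N} (R[j, N] - R[j, j])`. Positive values mean
#' constructive interference (training on later tasks improved earlier
#' ones); negative values quantify catastrophic forgetting.
#'
#' @inheritParams average_auc
#' @return scalar.
#' @export
bwt <- function(R) {
  check_rmatrix(R)
  N <- ncol(R)
  if (N < 2L) stop("BWT needs at least two tasks")
  j <- seq_len(N - 1L)
  mean(R[j, N] - diag(R)[j])
}

#' t-step backward transfer
#'
#' `BWT_t = (1/(N-t)) * sum_{j<=N-t} (R[j, j+t] - R[j, j])`: performance on
#' a previously seen task after training on `t` subsequent tasks.
#'
#' @inheritParams average_auc
#' @param t number of subsequent tasks, `1 <= t <= N-1`.
#' @return scalar.
#' @export
bwt_t <- function(R, t) {
  check_rmatrix(R)
  N <- ncol(R)
  if (t < 1L || t > N - 1L) stop("t must be in 1..N-1")
  j <- seq_len(N - t)
  mean(R[cbind(j, j + t)] - diag(R)[j])
}

#' Lambda backward transfer
#'
#' Extends [bwt_t()] to all horizons: for each earlier task the mean delta
#' over every later evaluation, averaged over tasks:
#' `(1/(N-1)) * sum_{j<N} (1/(N-j)) * sum_{t=1}^{N-j} (R[j, j+t] - R[j, j])`.
#'
#' @inheritParams average_auc
#' @return scalar.
#' @export
bwt_lambda <- function(R) {
  check_rmatrix(R)
  N <- ncol(R)
  if (N < 2L) stop("BWT_lambda needs at least two tasks")
  per_task <- vapply(seq_len(N - 1L), function(j)
    mean(R[j, (j + 1L):N] - R[j, j]), numeric(1))
  mean(per_task)
}

#' ROC AUC for a task's test predictions
#'
#' Binary tasks use the standard ROC AUC (probability of the higher class);
#' multi-class tasks use the macro one-vs-rest average over the classes
#' present in the labels.
#'
#' @param scores probability matrix, one column per class; column names are
#'   the class ids.
#' @param labels vector of class ids.
#' @param classes class ids corresponding to the columns (defaults to
#'   column names).
#' @return scalar AUC in `[0, 1]`, or `NA` if undefined (a single class
#'   observed).
#' @export
task_auc <- function(scores, labels, classes = NULL) {
  if (is.null(dim(scores))) scores <- cbind(1 - scores, scores)
  classes <- classes %||% as.integer(colnames(scores))
  if (length(classes) != ncol(scores)) stop("classes do not match score columns")
  present <- intersect(classes, unique(labels))
  if (length(present) < 2L) return(NA_real_)
  if (length(classes) == 2L) {
    pos <- classes[2]
    return(as.numeric(pROC::auc(
      response = factor(labels, levels = classes),
      predictor = scores[, 2],
      levels = as.character(classes), direction = "<", quiet = TRUE)))
  }
  aucs <- vapply(present, function(cl) {
    y <- factor(labels == cl, levels = c(FALSE, TRUE))
    as.numeric(pROC::auc(response = y, predictor = scores[, match(cl, classes)],
                         levels = c("FALSE", "TRUE"), direction = "<",
                         quiet = TRUE))
  }, numeric(1))
  mean(aucs)
}
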