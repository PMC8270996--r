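# Task difficulty and similarity from Gaussian fits to the storage-score
# distributions, and greedy (anti-)curricula over the similarity chain.

#' Fit a Gaussian to a task's storage scores
#'
#' Sample mean and standard deviation (denominator n-1) of the task's `s`
#' values; task difficulty is the reciprocal mean, `d = 1/mu`.
#'
#' @param s numeric vector of storage scores (>= 2 values).
#' @param task_id optional id carried along.
#' @return a `task_gaussian` list with `mu`, `sigma`, `difficulty`.
#' @export
fit_task_gaussian <- function(s, task_id = NA_integer_) {
  if (length(s) < 2L) stop("need at least two storage scores")
  mu <- mean(s)
  sigma <- sd(s)
  if (!is.finite(mu) || mu == 0) stop("degenerate distribution: mean is zero")
  if (sigma == 0) stop("degenerate distribution: zero variance")
  structure(list(task_id = task_id, mu = mu, sigma = sigma,
                 difficulty = 1 / mu), class = "task_gaussian")
}

#' Similarity of two tasks from their Gaussian fits
#'
#' One minus the Hellinger distance between the fitted Gaussians:
#' `S = 1 - sqrt(1 - BC)` with Bhattacharyya coefficient
#' `BC = sqrt(2*s_j*s_k / (s_j^2 + s_k^2)) * exp(-(mu_j - mu_k)^2 / (4*(s_j^2 + s_k^2)))`.
#' S lies in `[0, 1]`, is symmetric, and equals 1 for identical Gaussians.
#'
#' @param gj,gk `task_gaussian` fits (or lists with `mu`, `sigma > 0`).
#' @return scalar similarity.
#' @export
similarity <- function(gj, gk) {
  if (gj$sigma <= 0 || gk$sigma <= 0) stop("sigma must be positive")
  s2 <- gj$sigma^2 + gk$sigma^2
  bc <- sqrt(2 * gj$sigma * gk$sigma / s2) * exp(-((gj$mu - gk$mu)^2) / (4 * s2))
  1 - sqrt(max(0, 1 - bc))
}

#' Pairwise task similarity matrix from a storage-score table
#'
#' @param s_table data.frame with columns `task_id` and `s` (one row per
#'   instance), e.g. the `s_table` of a [run_stream()] log.
#' @return list with `S` (symmetric N x N matrix, unit diagonal),
#'   `difficulty` (named vector `1/mu`) and `fits`.
#' @export
similarity_matrix <- function(s_table) {
  stopifnot(all(c("task_id", "s") %in% names(s_table)))
  ids <- sort(unique(s_table$task_id))
  fits <- lapply(ids, function(k)
    fit_task_gaussian(s_table$s[s_table$task_id == k], task_id = k))
  N <- length(ids)
  S <- diag(1, N)
  dimnames(S) <- list(ids, ids)
  if (N > 1) for (j in 1:(N - 1)) for (k in (j + 1):N) {
    S[j, k] <- S[k, j] <- similarity(fits[[j]], fits[[k]])
  }
  list(S = S,
       difficulty = setNames(vapply(fits, `[[`, numeric(1), "difficulty"),
                             ids),
       fits = fits)
}

#' Build a task curriculum along the similarity chain
#'
#' Greedy chain: start from the easiest task (`curriculum`) or the hardest
#' (`anti_curriculum`), then repeatedly append the not-yet-visited task most
#' similar to the most recently added one. Ties break on the smaller task
#' id. `random` draws a permutation from the current RNG stream.
#'
#' @param S symmetric similarity matrix with task ids as dimnames.
#' @param difficulty named vector of task difficulties (`1/mu`).
#' @param mode `"curriculum"`, `"anti_curriculum"` or `"random"`.
#' @return integer vector of task ids, a permutation of all tasks.
#' @export
build_curriculum <- function(S, difficulty,
                             mode = c("curriculum", "anti_curriculum",
                                      "random")) {
  mode <- match.arg(mode)
  ids <- as.integer(rownames(S))
  if (length(difficulty) != length(ids)) stop("S and difficulty sizes differ")
  if (mode == "random") return(ids[sample.int(length(ids))])
  d <- difficulty[as.character(ids)]
  start <- if (mode == "curriculum") ids[order(d, ids)[1]]
           else ids[order(-d, ids)[1]]
  chain <- start
  left <- setdiff(ids, start)
  while (length(left)) {
    sims <- S[as.character(chain[length(chain)]), as.character(left)]
    nxt <- left[order(-sims, left)[1]]
    chain <- c(chain, nxt)
    left <- setdiff(left, nxt)
  }
  chain
}
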