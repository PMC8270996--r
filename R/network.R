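# Small 1-D convolutional classifier with a stochastic-dropout posterior.
# Forward/backward passes are written directly on BLAS matrix ops (im2col
# convolutions), which keeps desk-scale training fast without external
# deep-learning dependencies.

#' Specification of the 1-D convolutional classifier
#'
#' The trunk is a stack of convolution blocks (same-padded conv, ReLU,
#' max-pool 2) followed by global average pooling, one fully connected ReLU
#' layer and a single dropout site on that penultimate representation — the
#' stochastic layer used for Monte-Carlo posterior sampling. One linear
#' softmax head per task (or a single shared head) sits on top.
#'
#' @param channels integer vector, output channels of each conv block.
#' @param kernel odd kernel width shared by all blocks.
#' @param hidden width of the fully connected layer.
#' @param dropout dropout probability in `[0, 1)` applied before the heads;
#'   values > 0 are required for Monte-Carlo sampling to be stochastic.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(channels = c(16L, 32L, 64L), kernel = 7L,
                            hidden = 32L, dropout = 0.3) {
  if (kernel %% 2L != 1L) stop("kernel width must be odd")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (length(channels) < 1L || any(channels < 1L)) stop("invalid channels")
  structure(list(channels = as.integer(channels), kernel = as.integer(kernel),
                 hidden = as.integer(hidden), dropout = dropout),
            class = "classifier_spec")
}

he_init <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)

#' Build a classifier for a set of task heads
#'
#' @param spec a [classifier_spec()].
#' @param input_length signal length in samples.
#' @param heads named list: head id -> integer vector of global class ids.
#'   A shared-head model uses a single entry named `"shared"`.
#' @param seed optional seed for weight initialisation.
#' @return a `clops_model` list with flat named parameter list `$params`.
#' @export
build_classifier <- function(spec, input_length, heads, seed = NULL) {
  stopifnot(inherits(spec, "classifier_spec"), length(heads) >= 1L)
  if (is.null(names(heads)) || any(names(heads) == ""))
    stop("heads must be a named list")
  with_seed(seed, {
    params <- list()
    cin <- 1L
    for (i in seq_along(spec$channels)) {
      cout <- spec$channels[i]
      params[[sprintf("conv%d.W", i)]] <- he_init(spec$kernel * cin, cout)
      params[[sprintf("conv%d.b", i)]] <- numeric(cout)
      cin <- cout
    }
    params[["fc.W"]] <- he_init(cin, spec$hidden)
    params[["fc.b"]] <- numeric(spec$hidden)
    for (h in names(heads)) {
      C <- length(heads[[h]])
      params[[sprintf("head.%s.W", h)]] <- he_init(spec$hidden, C)
      params[[sprintf("head.%s.b", h)]] <- numeric(C)
    }
    structure(list(spec = spec, input_length = as.integer(input_length),
                   heads = lapply(heads, as.integer), params = params),
              class = "clops_model")
  })
}

# Feature maps are held as flat matrices of dim (B * L) x C with the batch
# index running fastest along rows (row r <-> instance b = (r-1) %% B + 1 at
# position l = (r-1) %/% B + 1). Same-padding then makes every im2col kernel
# offset a contiguous row slice, which keeps the reshaping cost negligible.

im2col1d <- function(x, B, L, K) {
  Cin <- ncol(x)
  pad <- (K - 1L) %/% 2L
  zp <- matrix(0, B * pad, Cin)
  xp <- rbind(zp, x, zp)
  out <- matrix(0, B * L, K * Cin)
  for (k in seq_len(K))
    out[, ((k - 1L) * Cin + 1L):(k * Cin)] <-
      xp[(k - 1L) * B + seq_len(B * L), , drop = FALSE]
  out
}

col2im1d <- function(dcol, B, L, Cin, K) {
  pad <- (K - 1L) %/% 2L
  dxp <- matrix(0, B * (L + 2L * pad), Cin)
  for (k in seq_len(K)) {
    rows <- (k - 1L) * B + seq_len(B * L)
    dxp[rows, ] <- dxp[rows, , drop = FALSE] +
      dcol[, ((k - 1L) * Cin + 1L):(k * Cin), drop = FALSE]
  }
  dxp[pad * B + seq_len(B * L), , drop = FALSE]
}

maxpool_fwd <- function(x, B, L) {
  L2 <- L %/% 2L
  keep <- seq_len(B * 2L * L2)
  odd <- ((keep - 1L) %/% B) %% 2L == 0L
  i1 <- keep[odd]; i2 <- keep[!odd]
  x1 <- x[i1, , drop = FALSE]; x2 <- x[i2, , drop = FALSE]
  m <- x1 >= x2
  out <- x2; out[m] <- x1[m]
  list(out = out, mask = m, i1 = i1, i2 = i2, n_in = B * L, L2 = L2)
}

maxpool_bwd <- function(pool, dout, C) {
  dx <- matrix(0, pool$n_in, C)
  d1 <- dout; d1[!pool$mask] <- 0
  d2 <- dout; d2[pool$mask] <- 0
  dx[pool$i1, ] <- d1
  dx[pool$i2, ] <- d2
  dx
}

add_bias <- function(a, b) a + rep(b, each = nrow(a))

# Trunk forward pass. dropout_active toggles the stochastic mask (training
# and MC sampling); without it the pass is deterministic.
trunk_forward <- function(model, X, dropout_active = FALSE) {
  spec <- model$spec
  B <- nrow(X)
  x <- matrix(as.vector(X), B * ncol(X), 1L)   # (b,l)-flat, single channel
  L <- ncol(X)
  caches <- vector("list", length(spec$channels))
  cin <- 1L
  for (i in seq_along(spec$channels)) {
    xcol <- im2col1d(x, B, L, spec$kernel)
    a <- add_bias(xcol %*% model$params[[sprintf("conv%d.W", i)]],
                  model$params[[sprintf("conv%d.b", i)]])
    r <- a; r[r < 0] <- 0
    pool <- maxpool_fwd(r, B, L)
    caches[[i]] <- list(xcol = xcol, relu_mask = a > 0, pool = pool,
                        L = L, cin = cin)
    x <- pool$out
    L <- pool$L2
    cin <- spec$channels[i]
  }
  Llast <- L
  feat <- rowsum(x, rep_len(seq_len(B), B * Llast)) / Llast   # B x C_last
  z <- add_bias(feat %*% model$params[["fc.W"]], model$params[["fc.b"]])
  h <- z; h[h < 0] <- 0
  p <- spec$dropout
  mask <- if (dropout_active && p > 0)
    matrix((runif(length(h)) >= p) / (1 - p), nrow(h), ncol(h))
  else matrix(1, nrow(h), ncol(h))
  list(h = h * mask, cache = list(conv = caches, feat = feat, z = z,
                                  mask = mask, Llast = Llast, B = B))
}

# Trunk backward pass; dh is the gradient w.r.t. the (post-dropout)
# penultimate representation. Returns a named list of parameter gradients.
trunk_backward <- function(model, cache, dh) {
  spec <- model$spec
  grads <- list()
  dh <- dh * cache$mask
  dz <- dh * (cache$z > 0)
  grads[["fc.W"]] <- crossprod(cache$feat, dz)
  grads[["fc.b"]] <- colSums(dz)
  dfeat <- dz %*% t(model$params[["fc.W"]])
  B <- cache$B; Llast <- cache$Llast
  dx <- (dfeat / Llast)[rep_len(seq_len(B), B * Llast), , drop = FALSE]
  for (i in rev(seq_along(spec$channels))) {
    cc <- cache$conv[[i]]
    dr <- maxpool_bwd(cc$pool, dx, spec$channels[i])
    da <- dr; da[!cc$relu_mask] <- 0
    grads[[sprintf("conv%d.W", i)]] <- crossprod(cc$xcol, da)
    grads[[sprintf("conv%d.b", i)]] <- colSums(da)
    if (i > 1L) {
      dcol <- da %*% t(model$params[[sprintf("conv%d.W", i)]])
      dx <- col2im1d(dcol, B, cc$L, cc$cin, spec$kernel)
    }
  }
  grads
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

resolve_head <- function(model, head) {
  if (is.null(head)) {
    if (length(model$heads) == 1L) return(names(model$heads))
    stop("model has several heads; specify one")
  }
  head <- as.character(head)
  if (!head %in% names(model$heads)) stop("unknown head id: ", head)
  head
}

head_logits <- function(model, head, h) {
  sweep(h %*% model$params[[sprintf("head.%s.W", head)]], 2L,
        model$params[[sprintf("head.%s.b", head)]], "+")
}

#' Class-probability predictions (dropout inactive)
#'
#' @param model a `clops_model`.
#' @param X signal matrix, one row per instance.
#' @param head head id (task id or `"shared"`); may be omitted for
#'   single-head models.
#' @return matrix of probabilities, one row per instance; columns are the
#'   head's global class ids. Rows lie on the probability simplex and the
#'   pass is deterministic.
#' @export
predict_proba <- function(model, X, head = NULL) {
  head <- resolve_head(model, head)
  h <- trunk_forward(model, X, dropout_active = FALSE)$h
  p <- softmax_rows(head_logits(model, head, h))
  colnames(p) <- as.character(model$heads[[head]])
  p
}

#' Monte-Carlo dropout posterior samples
#'
#' Runs `T` stochastic forward passes with the dropout site active,
#' producing the posterior sample tensor consumed by [bald_mcd()].
#'
#' @param model a `clops_model` (its spec needs `dropout > 0` for the
#'   samples to differ).
#' @param X signal matrix, M rows.
#' @param T number of Monte-Carlo passes (>= 1).
#' @param head head id; may be omitted for single-head models.
#' @param seed optional seed making the tensor reproducible without
#'   disturbing the caller's RNG stream.
#' @return array of dim `M x T x C`; every `[m, t, ]` slice is a probability
#'   vector.
#' @export
mc_sample <- function(model, X, T = 20L, head = NULL, seed = NULL) {
  if (!is.numeric(T) || T < 1) stop("T must be a positive integer")
  T <- as.integer(T)
  head <- resolve_head(model, head)
  C <- length(model$heads[[head]])
  # the dropout site sits on the penultimate representation, so the trunk
  # below it is deterministic: run it once and apply T stochastic masks
  h0 <- trunk_forward(model, X, dropout_active = FALSE)$h
  p <- model$spec$dropout
  with_seed(seed, {
    G <- array(NA_real_, c(nrow(X), T, C))
    for (t in seq_len(T)) {
      mask <- if (p > 0)
        matrix((runif(length(h0)) >= p) / (1 - p), nrow(h0), ncol(h0))
      else 1
      G[, t, ] <- softmax_rows(head_logits(model, head, h0 * mask))
    }
    dimnames(G) <- list(rownames(X), NULL, as.character(model$heads[[head]]))
    G
  })
}

# ---- Adam optimiser ---------------------------------------------------------

adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$t <- 0L
  st
}

adam_step <- function(params, grads, st, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params
}
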