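# Minimal neural-network core ---------------------------------------------
#
# The transformer encoder and the classification head are trained with a
# small self-contained core: parameters live in nested lists of matrices and
# vectors ("trees"), every layer provides an explicit forward and backward
# pass, and optimisation is Adam. Matrix products go through BLAS, so desk
# scale models (a few blocks, d_model <= 512) train in seconds to minutes on
# one CPU. All computations are in double precision and deterministic given
# the RNG seed.

# ---- parameter trees -----------------------------------------------------

tree_map <- function(f, ...) {
  ts <- list(...)
  if (is.list(ts[[1]])) {
    out <- vector("list", length(ts[[1]]))
    names(out) <- names(ts[[1]])
    for (i in seq_along(ts[[1]])) {
      out[[i]] <- do.call(tree_map, c(list(f), lapply(ts, `[[`, i)))
    }
    out
  } else {
    do.call(f, ts)
  }
}

tree_n_params <- function(params) {
  total <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else total <<- total + length(x)
    invisible(NULL)
  }
  walk(params)
  total
}

tree_checksum <- function(params) {
  total <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else total <<- total + sum(abs(x))
    invisible(NULL)
  }
  walk(params)
  total
}

adam_new <- function(params) {
  zero <- function(p) p * 0
  list(m = tree_map(zero, params), v = tree_map(zero, params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g,
                      state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) {
    p - lr * (m / c1) / (sqrt(v / c2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

# ---- primitive layers ----------------------------------------------------

init_mat <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
}

linear_init <- function(d_in, d_out, sd = 0.02) {
  list(W = init_mat(d_in, d_out, sd), b = numeric(d_out))
}

linear_fwd <- function(x, p) {
  add_bias_cpp(x %*% p$W, p$b)
}

linear_bwd <- function(dy, x, p) {
  list(dx = dy %*% t(p$W),
       grads = list(W = crossprod(x, dy), b = colSums(dy)))
}

ln_init <- function(d) list(g = rep(1, d), b = numeric(d))

ln_fwd <- function(x, p, eps = 1e-5) {
  out <- ln_fwd_cpp(x, p$g, p$b, eps)
  list(y = out$y, cache = list(xhat = out$xhat, inv = out$inv))
}

ln_bwd <- function(dy, cache, p) {
  out <- ln_bwd_cpp(dy, cache$xhat, as.numeric(cache$inv), p$g)
  list(dx = out$dx,
       grads = list(g = as.numeric(out$dg), b = as.numeric(out$db)))
}

# GELU, sigmoid approximation (fast and smooth; the exact erf form differs
# by < 1e-2 and makes no practical difference at these scales)
gelu_fwd <- function(x) x / (1 + exp(-1.702 * x))

gelu_bwd <- function(dy, x) {
  s <- 1 / (1 + exp(-1.702 * x))
  dy * (s + 1.702 * x * s * (1 - s))
}

softmax_rows <- function(x) {
  rowmax <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - rowmax)
  e / rowSums(e)
}

dropout_fwd <- function(x, p_drop, training) {
  if (!training || p_drop <= 0) return(list(y = x, mask = NULL))
  mask <- (stats::runif(length(x)) >= p_drop) / (1 - p_drop)
  dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}

dropout_bwd <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# softmax cross-entropy over rows; targets are 1-based class indices
ce_fwd <- function(logits, targets, clamp = 1e-12) {
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(nrow(p)), targets)
  loss <- mean(-log(pmax(p[idx], clamp)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / nrow(p), probs = p)
}

# ---- multi-head self-attention ------------------------------------------
#
# x is a (B*L) x d matrix in batch-major row order; mask is a B x L logical
# matrix flagging real (non-padding) positions. Queries and keys are
# restricted to real positions, so padding never leaks into attention.

mha_init <- function(d, sd = 0.02) {
  list(Wq = linear_init(d, d, sd), Wk = linear_init(d, d, sd),
       Wv = linear_init(d, d, sd), Wo = linear_init(d, d, sd))
}

mha_fwd <- function(x, p, n_heads, B, L, mask) {
  scale <- 1 / sqrt(ncol(x) / n_heads)
  Q <- linear_fwd(x, p$Wq)
  K <- linear_fwd(x, p$Wk)
  V <- linear_fwd(x, p$Wv)
  real <- lapply(seq_len(B), function(b) {
    ((b - 1) * L + 1):(b * L)
  })
  real <- lapply(seq_len(B), function(b) real[[b]][mask[b, ]])
  at <- attn_fwd_cpp(Q, K, V, real, n_heads, scale)
  y <- linear_fwd(at$O, p$Wo)
  list(y = y, cache = list(x = x, Q = Q, K = K, V = V, O = at$O,
                           P = at$P, real = real, n_heads = n_heads,
                           scale = scale))
}

mha_bwd <- function(dy, cache, p) {
  wo <- linear_bwd(dy, cache$O, p$Wo)
  d3 <- attn_bwd_cpp(cache$Q, cache$K, cache$V, wo$dx, cache$P,
                     cache$real, cache$n_heads, cache$scale)
  gq <- linear_bwd(d3$dQ, cache$x, p$Wq)
  gk <- linear_bwd(d3$dK, cache$x, p$Wk)
  gv <- linear_bwd(d3$dV, cache$x, p$Wv)
  list(dx = gq$dx + gk$dx + gv$dx,
       grads = list(Wq = gq$grads, Wk = gk$grads,
                    Wv = gv$grads, Wo = wo$grads))
}
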