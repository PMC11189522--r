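# Cluster classification head ---------------------------------------------
#
# The task head consumes the encoder's per-residue hidden states: an input
# projection to the head width, two pre-norm self-attention layers, masked
# mean pooling, a stack of dense layers with GELU, and a softmax over the
# cluster classes. With the published-scale defaults (d_model 512, head
# width 192, hidden dims 512/256, 45 classes) the head holds ~0.64 M
# parameters. The encoder backbone is frozen by default during task
# training, so the head learns on cached encoder states.

#' Classification-head hyperparameters
#'
#' @param n_classes Number of cluster classes (default 45).
#' @param n_attention_layers Number of self-attention layers (default 2).
#' @param n_dense_layers Number of dense layers including the output layer
#'   (default 3).
#' @param d_head Width of the head's attention layers.
#' @param n_heads Attention heads in the head; must divide `d_head`.
#' @param hidden_dims Widths of the `n_dense_layers - 1` hidden dense
#'   layers; defaults to `c(512, 256)` truncated/recycled to the right
#'   length.
#' @param dropout Dropout on the pooled representation during training.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(n_classes = 45, n_attention_layers = 2,
                              n_dense_layers = 3, d_head = 192,
                              n_heads = 4, hidden_dims = NULL,
                              dropout = 0.1) {
  stopifnot(n_classes >= 1, n_attention_layers >= 1, n_dense_layers >= 1,
            d_head >= 1, n_heads >= 1, dropout >= 0, dropout < 1)
  if (d_head %% n_heads != 0) rlang::abort("d_head must be divisible by n_heads")
  n_hidden <- n_dense_layers - 1
  if (is.null(hidden_dims)) {
    hidden_dims <- rep_len(c(512, 256), max(n_hidden, 1))[seq_len(n_hidden)]
  }
  if (length(hidden_dims) != n_hidden) {
    rlang::abort("hidden_dims must have length n_dense_layers - 1")
  }
  structure(
    list(n_classes = n_classes, n_attention_layers = n_attention_layers,
         n_dense_layers = n_dense_layers, d_head = d_head,
         n_heads = n_heads, hidden_dims = as.integer(hidden_dims),
         dropout = dropout),
    class = "classifier_config"
  )
}

#' Build an untrained classification head
#'
#' @param config A [classifier_config()].
#' @param d_model Width of the incoming per-residue states (the encoder's
#'   `d_model`, or the alphabet size for one-hot inputs).
#' @param seed Integer seed for initialisation.
#' @return An object of class `plm_head` (parameters + config + parameter
#'   count).
#' @export
build_classifier <- function(config = classifier_config(), d_model, seed = 1) {
  stopifnot(inherits(config, "classifier_config"), d_model >= 1)
  with_seed(seed, {
    d <- config$d_head
    attn <- lapply(seq_len(config$n_attention_layers), function(i) {
      list(ln = ln_init(d), mha = mha_init(d))
    })
    dims <- c(d, config$hidden_dims, config$n_classes)
    dense <- lapply(seq_len(length(dims) - 1), function(i) {
      linear_init(dims[i], dims[i + 1])
    })
    params <- list(proj = linear_init(d_model, d), attn = attn,
                   dense = dense)
    structure(
      list(params = params, config = config, d_model = d_model,
           n_parameters = tree_n_params(params)),
      class = "plm_head"
    )
  })
}

#' @export
print.plm_head <- function(x, ...) {
  cat("Classification head:", x$config$n_attention_layers,
      "attention layers +", x$config$n_dense_layers, "dense layers ->",
      x$config$n_classes, "classes (",
      format(x$n_parameters, big.mark = ","), "parameters )\n")
  invisible(x)
}

# forward through the head; h is (B*L) x d_model, mask B x L
head_fwd <- function(params, cfg, h, B, L, mask, training = FALSE) {
  x <- linear_fwd(h, params$proj)
  attn_caches <- vector("list", cfg$n_attention_layers)
  for (i in seq_len(cfg$n_attention_layers)) {
    p <- params$attn[[i]]
    a <- ln_fwd(x, p$ln)
    at <- mha_fwd(a$y, p$mha, cfg$n_heads, B, L, mask)
    attn_caches[[i]] <- list(ln = a, mha = at$cache, x_in = x)
    x <- x + at$y
  }
  # masked mean pool
  pooled <- matrix(0, B, cfg$d_head)
  n_real <- rowSums(mask)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * L + 1):(b * L)
    pooled[b, ] <- colSums(x[rows[mask[b, ]], , drop = FALSE]) / n_real[b]
  }
  dr <- dropout_fwd(pooled, cfg$dropout, training)
  z <- dr$y
  dense_caches <- vector("list", length(params$dense))
  for (i in seq_along(params$dense)) {
    pre <- linear_fwd(z, params$dense[[i]])
    dense_caches[[i]] <- list(z_in = z, pre = pre)
    z <- if (i < length(params$dense)) gelu_fwd(pre) else pre
  }
  list(logits = z,
       cache = list(attn = attn_caches, x_attn_out = x, pooled_mask = mask,
                    n_real = n_real, dr = dr$mask, dense = dense_caches,
                    h = h, B = B, L = L))
}

# backward from dlogits; returns grads tree and (optionally) dh
head_bwd <- function(dlogits, cache, params, cfg, need_dh = FALSE) {
  dz <- dlogits
  gdense <- vector("list", length(params$dense))
  for (i in rev(seq_along(params$dense))) {
    cb <- cache$dense[[i]]
    if (i < length(params$dense)) dz <- gelu_bwd(dz, cb$pre)
    bw <- linear_bwd(dz, cb$z_in, params$dense[[i]])
    gdense[[i]] <- bw$grads
    dz <- bw$dx
  }
  dpooled <- dropout_bwd(dz, cache$dr)
  B <- cache$B; L <- cache$L
  dx <- matrix(0, B * L, cfg$d_head)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * L + 1):(b * L)
    real <- rows[cache$pooled_mask[b, ]]
    dx[real, ] <- matrix(dpooled[b, ] / cache$n_real[b],
                         length(real), cfg$d_head, byrow = TRUE)
  }
  gattn <- vector("list", cfg$n_attention_layers)
  for (i in rev(seq_len(cfg$n_attention_layers))) {
    cb <- cache$attn[[i]]
    at <- mha_bwd(dx, cb$mha, params$attn[[i]]$mha)
    ln <- ln_bwd(at$dx, cb$ln$cache, params$attn[[i]]$ln)
    gattn[[i]] <- list(ln = ln$grads, mha = at$grads)
    dx <- dx + ln$dx
  }
  bw <- linear_bwd(dx, cache$h, params$proj)
  out <- list(grads = list(proj = bw$grads, attn = gattn, dense = gdense))
  if (need_dh) out$dh <- bw$dx
  out
}
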