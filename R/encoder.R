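# Transformer encoder with masked-language-model pre-training -------------
#
# A BERT-style bidirectional encoder over amino-acid tokens: learned token
# and position embeddings, pre-norm transformer blocks (self-attention +
# GELU feed-forward, residual connections), a final layer norm, and a linear
# MLM head over the vocabulary. Defaults (5 blocks, d_model 512, 8 heads,
# feed-forward 2048) give ~16.5 M parameters; the published family-scale
# model of this architecture reports ~20 M, the exact widths being
# unpublished.

#' Encoder hyperparameters
#'
#' @param n_blocks Number of transformer blocks (default 5).
#' @param d_model Hidden width; must be divisible by `n_heads`.
#' @param n_heads Number of attention heads.
#' @param d_feedforward Feed-forward inner width.
#' @param dropout Dropout probability applied to attention and feed-forward
#'   outputs during training.
#' @param max_length Maximum token-sequence length (positions are learned).
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(n_blocks = 5, d_model = 512, n_heads = 8,
                           d_feedforward = 2048, dropout = 0.1,
                           max_length = 1024) {
  stopifnot(n_blocks >= 1, d_model >= 1, n_heads >= 1,
            d_feedforward >= 1, dropout >= 0, dropout < 1, max_length >= 3)
  if (d_model %% n_heads != 0) {
    rlang::abort("d_model must be divisible by n_heads")
  }
  structure(
    list(n_blocks = n_blocks, d_model = d_model, n_heads = n_heads,
         d_feedforward = d_feedforward, dropout = dropout,
         max_length = as.integer(max_length)),
    class = "encoder_config"
  )
}

encoder_init <- function(cfg, tok, seed = 1) {
  with_seed(seed, {
    d <- cfg$d_model
    blocks <- lapply(seq_len(cfg$n_blocks), function(i) {
      list(ln1 = ln_init(d), attn = mha_init(d), ln2 = ln_init(d),
           ff1 = linear_init(d, cfg$d_feedforward),
           ff2 = linear_init(cfg$d_feedforward, d))
    })
    list(tok_emb = init_mat(tok$vocab_size, d),
         pos_emb = init_mat(cfg$max_length, d),
         blocks = blocks,
         ln_f = ln_init(d),
         mlm_head = linear_init(d, tok$vocab_size))
  })
}

# pad a list of integer id vectors into B x L id and mask matrices (PAD = 0)
pad_batch <- function(ids_list) {
  B <- length(ids_list)
  L <- max(lengths(ids_list))
  ids <- matrix(0L, B, L)
  mask <- matrix(FALSE, B, L)
  for (b in seq_len(B)) {
    n <- length(ids_list[[b]])
    ids[b, seq_len(n)] <- ids_list[[b]]
    mask[b, seq_len(n)] <- TRUE
  }
  list(ids = ids, mask = mask)
}

# forward pass; returns final hidden states ((B*L) x d) and caches for
# backward when training = TRUE
encoder_fwd <- function(params, cfg, ids, mask, training = FALSE) {
  B <- nrow(ids); L <- ncol(ids)
  flat <- as.integer(t(ids))
  x <- params$tok_emb[flat + 1L, , drop = FALSE] +
    params$pos_emb[rep(seq_len(L), B), , drop = FALSE]
  caches <- vector("list", cfg$n_blocks)
  for (i in seq_len(cfg$n_blocks)) {
    p <- params$blocks[[i]]
    a <- ln_fwd(x, p$ln1)
    at <- mha_fwd(a$y, p$attn, cfg$n_heads, B, L, mask)
    dr1 <- dropout_fwd(at$y, cfg$dropout, training)
    x1 <- x + dr1$y
    f <- ln_fwd(x1, p$ln2)
    h1 <- linear_fwd(f$y, p$ff1)
    g1 <- gelu_fwd_cpp(h1)
    h2 <- linear_fwd(g1$y, p$ff2)
    dr2 <- dropout_fwd(h2, cfg$dropout, training)
    x2 <- x1 + dr2$y
    caches[[i]] <- if (training) {
      list(ln1 = a, attn = at$cache, dr1 = dr1$mask, x1 = x1,
           ln2 = f, h1 = h1, g1 = g1, dr2 = dr2$mask)
    }
    x <- x2
  }
  fin <- ln_fwd(x, params$ln_f)
  list(h = fin$y,
       cache = if (training) list(flat = flat, B = B, L = L,
                                  blocks = caches, ln_f = fin$cache,
                                  x_pre_ln_f = x))
}

# backward from dh (gradient at final hidden states); returns the gradient
# tree for every encoder parameter
encoder_bwd <- function(dh, cache, params, cfg, tok_vocab_size) {
  fin <- ln_bwd(dh, cache$ln_f, params$ln_f)
  dx <- fin$dx
  gblocks <- vector("list", cfg$n_blocks)
  for (i in rev(seq_len(cfg$n_blocks))) {
    p <- params$blocks[[i]]
    cb <- cache$blocks[[i]]
    # feed-forward branch
    dff <- dropout_bwd(dx, cb$dr2)
    b2 <- linear_bwd(dff, cb$g1$y, p$ff2)
    dg1 <- gelu_bwd_cpp(b2$dx, cb$h1, cb$g1$s)
    b1 <- linear_bwd(dg1, cb$ln2$y, p$ff1)
    l2 <- ln_bwd(b1$dx, cb$ln2$cache, p$ln2)
    dx1 <- dx + l2$dx
    # attention branch
    dat <- dropout_bwd(dx1, cb$dr1)
    at <- mha_bwd(dat, cb$attn, p$attn)
    l1 <- ln_bwd(at$dx, cb$ln1$cache, p$ln1)
    dx <- dx1 + l1$dx
    gblocks[[i]] <- list(ln1 = l1$grads, attn = at$grads, ln2 = l2$grads,
                         ff1 = b1$grads, ff2 = b2$grads)
  }
  # embeddings
  d <- ncol(dh)
  dtok <- matrix(0, tok_vocab_size, d)
  rs <- rowsum(dx, cache$flat)
  dtok[as.integer(rownames(rs)) + 1L, ] <- rs
  dpos <- matrix(0, nrow(params$pos_emb), d)
  rp <- rowsum(dx, rep(seq_len(cache$L), cache$B))
  dpos[seq_len(cache$L), ] <- rp
  list(tok_emb = dtok, pos_emb = dpos, blocks = gblocks, ln_f = fin$grads)
}

# ln2 cache needs the post-norm activations for the ff1 backward
# (stored as cb$ln2$y above)

#' Random train/validation split
#'
#' Fixed floor convention: `n_train = floor(train_fraction * n)`, the rest
#' is held out.
#'
#' @param n Number of items.
#' @param train_fraction Fraction in `(0, 1)`.
#' @param seed Integer seed.
#' @return A list with integer index vectors `train` and `val`.
#' @export
#' @examples
#' lengths(random_split(100, 0.95, seed = 1))  # 95 / 5
random_split <- function(n, train_fraction, seed) {
  stopifnot(train_fraction > 0, train_fraction < 1, n >= 2)
  n_train <- floor(train_fraction * n)
  if (n_train < 1 || n_train >= n) {
    rlang::abort("split leaves an empty train or validation set")
  }
  with_seed(seed, {
    perm <- sample.int(n)
    list(train = sort(perm[seq_len(n_train)]),
         val = sort(perm[(n_train + 1):n]))
  })
}

#' Stratified train/test split by label
#'
#' Within each label, `floor(train_fraction * n_label)` items (at least one)
#' go to training and the rest to testing, so no class is left without
#' training examples at small n.
#'
#' @param labels Vector of class labels, one per item.
#' @param train_fraction Fraction in `(0, 1)`.
#' @param seed Integer seed.
#' @return A list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction, seed) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  with_seed(seed, {
    train <- integer(0)
    for (lv in sort(unique(labels))) {
      idx <- which(labels == lv)
      n_tr <- max(1L, floor(train_fraction * length(idx)))
      take <- if (length(idx) == 1) idx else sample(idx, n_tr)
      train <- c(train, take)
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Pre-train the encoder with masked language modelling
#'
#' Splits the corpus into pre-training and validation parts (default 95/5),
#' then trains the encoder plus a linear MLM head by cross-entropy on the
#' corrupted positions only ([mask_for_mlm()]). Validation corruption is
#' frozen once at the start so the validation loss trajectory is comparable
#' across epochs. The whole run is deterministic given `seed`.
#'
#' @param seqs A sequence tibble with at least 20 rows.
#' @param config An [encoder_config()].
#' @param epochs Number of passes over the pre-training split.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate (published-scale default 1e-4; desk-scale
#'   runs typically use 1e-3).
#' @param mask_rate MLM corruption rate (default 0.15, 80/10/10 scheme).
#' @param train_fraction Pre-training fraction of the corpus (default 0.95).
#' @param seed Integer seed controlling the split, initialisation, batch
#'   order and corruption.
#' @param verbose Print per-epoch losses.
#' @return An object of class `plm_encoder`: trained parameters, config,
#'   tokenizer and a `history` tibble (`epoch`, `train_loss`, `val_loss`).
#' @export
pretrain_mlm <- function(seqs, config = encoder_config(), epochs = 20,
                         batch_size = 32, lr = 1e-3, mask_rate = 0.15,
                         train_fraction = 0.95, seed = 1, verbose = FALSE) {
  seqs <- validate_seq_tbl(seqs)
  if (nrow(seqs) < 20) {
    rlang::abort("pretrain_mlm needs at least 20 sequences")
  }
  tok <- aa_tokenizer(config$max_length)
  ids_all <- lapply(seqs$residues, tokenize, tok = tok)
  split <- random_split(nrow(seqs), train_fraction, seed = seed)
  params <- encoder_init(config, tok, seed = seed)
  opt <- adam_new(params)

  # frozen validation corruption
  val_ids <- ids_all[split$val]
  val_masked <- with_seed(stage_seed(seed, "val-mask"), {
    lapply(val_ids, mask_for_mlm, tok = tok, rate = mask_rate)
  })

  history <- vector("list", epochs)
  with_seed(stage_seed(seed, "pretrain"), {
    n_tr <- length(split$train)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_tr)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      ep_loss <- 0; ep_n <- 0
      for (bt in batches) {
        idx <- split$train[bt]
        masked <- lapply(ids_all[idx], mask_for_mlm, tok = tok,
                         rate = mask_rate)
        step <- mlm_step(params, config, tok, masked, training = TRUE)
        if (is.null(step)) next  # batch with no corrupted positions
        upd <- adam_step(params, step$grads, opt, lr)
        params <- upd$params; opt <- upd$state
        ep_loss <- ep_loss + step$loss * step$n_targets
        ep_n <- ep_n + step$n_targets
      }
      val <- mlm_step(params, config, tok, val_masked, training = FALSE)
      history[[ep]] <- tibble::tibble(
        epoch = ep,
        train_loss = if (ep_n) ep_loss / ep_n else NA_real_,
        val_loss = if (is.null(val)) NA_real_ else val$loss
      )
      if (verbose) {
        message(sprintf("epoch %d train %.4f val %.4f", ep,
                        history[[ep]]$train_loss, history[[ep]]$val_loss))
      }
    }
  })
  structure(
    list(params = params, config = config, tokenizer = tok,
         history = dplyr::bind_rows(history),
         n_parameters = tree_n_params(params)),
    class = "plm_encoder"
  )
}

# one MLM forward (+ backward when training) over a list of masked items
mlm_step <- function(params, cfg, tok, masked, training) {
  pb <- pad_batch(lapply(masked, `[[`, "ids"))
  L <- ncol(pb$ids)
  rows <- unlist(lapply(seq_along(masked), function(b) {
    (b - 1L) * L + masked[[b]]$positions
  }))
  targets <- unlist(lapply(masked, `[[`, "targets"))
  if (!length(rows)) return(NULL)
  fw <- encoder_fwd(params, cfg, pb$ids, pb$mask, training = training)
  hsel <- fw$h[rows, , drop = FALSE]
  logits <- linear_fwd(hsel, params$mlm_head)
  ce <- ce_fwd(logits, targets + 1L)  # ids are 0-based
  out <- list(loss = ce$loss, n_targets = length(targets))
  if (training) {
    hb <- linear_bwd(ce$dlogits, hsel, params$mlm_head)
    dh <- matrix(0, nrow(fw$h), ncol(fw$h))
    dh[rows, ] <- hb$dx
    grads <- encoder_bwd(dh, fw$cache, params, cfg, tok$vocab_size)
    grads$mlm_head <- hb$grads
    out$grads <- grads
  }
  out
}

#' @export
print.plm_encoder <- function(x, ...) {
  cat("Masked-LM encoder:", x$config$n_blocks, "blocks, d_model",
      x$config$d_model, "-", format(x$n_parameters, big.mark = ","),
      "parameters\n")
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat("  final losses: train", round(last$train_loss, 4),
        "val", round(last$val_loss, 4), "\n")
  }
  invisible(x)
}

#' @importFrom generics glance
#' @export
glance.plm_encoder <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    n_blocks = x$config$n_blocks, d_model = x$config$d_model,
    n_parameters = x$n_parameters, epochs = nrow(x$history),
    train_loss = last$train_loss, val_loss = last$val_loss
  )
}

#' @importFrom generics tidy
#' @export
tidy.plm_encoder <- function(x, ...) x$history

#' Number of trainable parameters
#'
#' @param x A `plm_encoder` or `plm_head` object.
#' @return Integer parameter count.
#' @export
n_parameters <- function(x) {
  stopifnot(inherits(x, c("plm_encoder", "plm_head")))
  x$n_parameters
}

#' Per-sequence embeddings from a trained encoder
#'
#' Runs the encoder in inference mode and mean-pools the final hidden states
#' over all non-padding positions, yielding one `d_model`-wide vector per
#' sequence.
#'
#' @param encoder A [pretrain_mlm()] object.
#' @param seqs A sequence tibble.
#' @param batch_size Minibatch size for the forward passes.
#' @return A numeric matrix with one row per sequence (rownames = ids).
#' @export
embed_sequences <- function(encoder, seqs, batch_size = 32) {
  stopifnot(inherits(encoder, "plm_encoder"))
  seqs <- validate_seq_tbl(seqs)
  tok <- encoder$tokenizer
  ids <- lapply(seqs$residues, tokenize, tok = tok)
  out <- matrix(0, nrow(seqs), encoder$config$d_model,
                dimnames = list(seqs$id, NULL))
  batches <- split(seq_len(nrow(seqs)),
                   ceiling(seq_len(nrow(seqs)) / batch_size))
  for (bt in batches) {
    pb <- pad_batch(ids[bt])
    fw <- encoder_fwd(encoder$params, encoder$config, pb$ids, pb$mask)
    L <- ncol(pb$ids)
    for (j in seq_along(bt)) {
      real <- ((j - 1) * L + 1):(j * L)
      real <- real[pb$mask[j, ]]
      out[bt[j], ] <- colMeans(fw$h[real, , drop = FALSE])
    }
  }
  out
}
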