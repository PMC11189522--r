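# Analytic gradients of the hand-written layers are validated against
# central finite differences through the full masked-LM loss and the full
# classification-head loss (dropout off so the losses are deterministic
# functions of the parameters).

# path elements that look like numbers index by position (the block and
# attention-layer lists are unnamed)
as_key <- function(k) if (grepl("^[0-9]+$", k)) as.integer(k) else k

set_leaf <- function(tree, path, value) {
  if (!length(path)) return(value)
  k <- as_key(path[1])
  tree[[k]] <- set_leaf(tree[[k]], path[-1], value)
  tree
}

get_leaf <- function(tree, path) {
  for (k in path) {
    tree <- tree[[as_key(k)]]
    if (is.null(tree)) stop("bad parameter path: ", paste(path, collapse = "/"))
  }
  tree
}

test_that("encoder + MLM head gradients match finite differences", {
  ns <- asNamespace("ssnplm")
  tok <- aa_tokenizer(32)
  cfg <- encoder_config(n_blocks = 2, d_model = 8, n_heads = 2,
                        d_feedforward = 16, dropout = 0, max_length = 32)
  params <- ns$encoder_init(cfg, tok, seed = 7)
  ids <- lapply(c("ACDEFGHIK", "MNPQRSTVWYAC", "GG"), tokenize, tok = tok)
  masked <- lapply(ids, function(x) {
    list(ids = replace(x, 3, 1L), positions = c(2L, 3L),
         targets = x[c(2, 3)])
  })
  loss_fn <- function(p) ns$mlm_step(p, cfg, tok, masked, FALSE)$loss
  st <- ns$mlm_step(params, cfg, tok, masked, training = TRUE)

  paths <- list("tok_emb", "pos_emb",
                c("blocks", "1", "attn", "Wq", "W"),
                c("blocks", "1", "attn", "Wo", "b"),
                c("blocks", "2", "ff1", "W"),
                c("blocks", "1", "ln1", "g"),
                c("ln_f", "b"),
                c("mlm_head", "W"))
  set.seed(2)
  for (path in paths) {
    leaf <- get_leaf(params, path)
    g_an <- get_leaf(st$grads, path)
    for (i in sample(length(leaf), 3)) {
      eps <- 1e-5
      up <- leaf; up[i] <- up[i] + eps
      dn <- leaf; dn[i] <- dn[i] - eps
      num <- (loss_fn(set_leaf(params, path, up)) -
                loss_fn(set_leaf(params, path, dn))) / (2 * eps)
      expect_equal(g_an[i], num, tolerance = 1e-4)
    }
  }
})

test_that("classification head gradients match finite differences", {
  ns <- asNamespace("ssnplm")
  hcfg <- classifier_config(n_classes = 4, d_head = 8, n_heads = 2,
                            hidden_dims = c(8, 8), dropout = 0)
  hd <- build_classifier(hcfg, d_model = 8, seed = 3)
  set.seed(14)
  states <- lapply(c(5, 7, 3), function(L) matrix(rnorm(L * 8), L, 8))
  y <- c(1L, 3L, 2L)
  loss_fn <- function(p) {
    ps <- ns$pad_states(states)
    fw <- ns$head_fwd(p, hcfg, ps$h, ps$B, ps$L, ps$mask)
    ns$ce_fwd(fw$logits, y)$loss
  }
  ps <- ns$pad_states(states)
  fw <- ns$head_fwd(hd$params, hcfg, ps$h, ps$B, ps$L, ps$mask,
                    training = TRUE)
  ce <- ns$ce_fwd(fw$logits, y)
  bw <- ns$head_bwd(ce$dlogits, fw$cache, hd$params, hcfg, need_dh = TRUE)
  for (path in list(c("proj", "W"), c("attn", "1", "mha", "Wv", "W"),
                    c("attn", "2", "ln", "g"), c("dense", "1", "W"),
                    c("dense", "3", "b"))) {
    leaf <- get_leaf(hd$params, path)
    g_an <- get_leaf(bw$grads, path)
    for (i in sample(length(leaf), 3)) {
      eps <- 1e-5
      up <- leaf; up[i] <- up[i] + eps
      dn <- leaf; dn[i] <- dn[i] - eps
      num <- (loss_fn(set_leaf(hd$params, path, up)) -
                loss_fn(set_leaf(hd$params, path, dn))) / (2 * eps)
      expect_equal(g_an[i], num, tolerance = 1e-4)
    }
  }
  # gradient w.r.t. the incoming hidden states (used when the backbone is
  # co-trained)
  i <- 17  # element (2, 4) of the 5 x 8 first state matrix
  eps <- 1e-6
  bump <- function(d) {
    s <- states; s[[1]][i] <- s[[1]][i] + d
    ps <- ns$pad_states(s)
    fw <- ns$head_fwd(hd$params, hcfg, ps$h, ps$B, ps$L, ps$mask)
    ns$ce_fwd(fw$logits, y)$loss
  }
  expect_equal(bw$dh[2, 4], (bump(eps) - bump(-eps)) / (2 * eps),
               tolerance = 1e-4)
})
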