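# shared tiny fitted model for the contract tests (20 sequences, 1 block)
tiny_setup <- local({
  co <- NULL
  function() {
    if (is.null(co)) {
      corpus <- generate_families(4, 5, length = 40, p_sub = 0.1, seed = 42)
      enc <- pretrain_mlm(
        corpus,
        encoder_config(n_blocks = 1, d_model = 16, n_heads = 2,
                       d_feedforward = 32, max_length = 48),
        epochs = 2, seed = 42
      )
      co <<- list(corpus = corpus, enc = enc)
    }
    co
  }
})

test_that("pretrain_mlm splits 95/5, records losses, and is seed-reproducible", {
  s <- tiny_setup()
  expect_equal(nrow(s$enc$history), 2)
  expect_true(all(is.finite(s$enc$history$train_loss)))
  # 95/5 split convention
  expect_equal(lengths(random_split(100, 0.95, seed = 1)),
               c(train = 95L, val = 5L))
  # identical seed, identical first-epoch loss
  enc2 <- pretrain_mlm(
    s$corpus,
    encoder_config(n_blocks = 1, d_model = 16, n_heads = 2,
                   d_feedforward = 32, max_length = 48),
    epochs = 1, seed = 42
  )
  expect_equal(enc2$history$train_loss[1], s$enc$history$train_loss[1])
  expect_error(pretrain_mlm(s$corpus[1:5, ]), "at least 20")
})

test_that("embeddings have the contract shape and are order-equivariant", {
  s <- tiny_setup()
  emb <- embed_sequences(s$enc, s$corpus)
  expect_equal(dim(emb), c(20, 16))
  expect_equal(rownames(emb), s$corpus$id)
  # identical sequences embed identically
  dup <- seq_tbl(c("d1", "d2"), rep(s$corpus$residues[1], 2))
  e2 <- embed_sequences(s$enc, dup)
  expect_equal(unname(e2[1, ]), unname(e2[2, ]))
  # permuting the input permutes the rows identically
  set.seed(2)
  perm <- sample(20)
  e3 <- embed_sequences(s$enc, s$corpus[perm, ])
  expect_equal(unname(e3), unname(emb[perm, ]))
})

test_that("classifier output is a softmax over n_classes with deterministic argmax", {
  s <- tiny_setup()
  hd45 <- build_classifier(classifier_config(n_classes = 45, d_head = 16,
                                             n_heads = 2,
                                             hidden_dims = c(16, 16)),
                           d_model = 16)
  preds <- predict_clusters(s$enc, hd45, s$corpus[1:4, ])
  expect_equal(lengths(preds$probabilities), rep(45L, 4))
  for (p in preds$probabilities) {
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-6)
  }
  expect_equal(preds$predicted_cluster,
               vapply(preds$probabilities, which.max, 0L))
  # argmax ties break towards the smallest cluster id
  tied <- ssnplm:::probs_to_predictions(
    "x", matrix(c(0.4, 0.4, 0.2), 1))
  expect_equal(tied$predicted_cluster, 1L)
})

test_that("head and encoder parameter counts sit in their design bands and scale", {
  hd <- build_classifier(classifier_config(), d_model = 512)
  expect_gt(n_parameters(hd), 0.6e6 * 0.8)
  expect_lt(n_parameters(hd), 0.6e6 * 1.2)

  ns <- asNamespace("ssnplm")
  tok <- aa_tokenizer(64)
  n_par <- function(blocks) {
    ssnplm:::tree_n_params(
      ns$encoder_init(encoder_config(n_blocks = blocks, d_model = 32,
                                     n_heads = 2, d_feedforward = 64,
                                     max_length = 64), tok, seed = 1))
  }
  emb_and_head <- {
    # embeddings + final LN + MLM head are block-independent
    tok_v <- 26
    tok_v * 32 + 64 * 32 + 2 * 32 + 32 * tok_v + tok_v
  }
  expect_equal(n_par(4) - emb_and_head, 2 * (n_par(2) - emb_and_head))
  # published-architecture default lands in the tens of millions
  p_default <- ssnplm:::tree_n_params(
    ns$encoder_init(encoder_config(), aa_tokenizer(1024), seed = 1))
  expect_gt(p_default, 14e6)
  expect_lt(p_default, 22e6)
})

test_that("ECE perplexity matches its closed forms and bounds", {
  mk_preds <- function(probmat) {
    ssnplm:::probs_to_predictions(paste0("s", seq_len(nrow(probmat))),
                                  probmat)
  }
  n <- 50; k <- 45
  labels <- tibble::tibble(id = paste0("s", 1:n),
                           cluster_id = rep_len(1:k, n))
  onehot <- matrix(0, n, k)
  onehot[cbind(1:n, labels$cluster_id)] <- 1
  expect_equal(ece_perplexity(mk_preds(onehot), labels), 1)

  uniform <- matrix(1 / k, n, k)
  expect_equal(ece_perplexity(mk_preds(uniform), labels), k)

  half <- matrix((1 - 0.5) / (k - 1), n, k)
  half[cbind(1:n, labels$cluster_id)] <- 0.5
  expect_equal(ece_perplexity(mk_preds(half), labels), 2)

  # bounds: 1 <= ECE <= 1 / min_i p_i(y_i), for random prediction sets
  set.seed(33)
  for (r in 1:20) {
    pm <- matrix(stats::rexp(n * k), n, k)
    pm <- pm / rowSums(pm)
    e <- ece_perplexity(mk_preds(pm), labels)
    p_true <- pm[cbind(1:n, labels$cluster_id)]
    expect_gte(e, 1)
    expect_lte(e, 1 / min(p_true) + 1e-9)
  }
  expect_error(ece_perplexity(mk_preds(uniform),
                              labels[1:10, ]), "missing label")
})

test_that("accuracy is the fraction of correct argmax predictions", {
  labels <- tibble::tibble(id = paste0("s", 1:4), cluster_id = c(1, 2, 3, 4))
  pm <- diag(4)
  pm[4, ] <- c(1, 0, 0, 0)  # one wrong
  preds <- ssnplm:::probs_to_predictions(labels$id, pm)
  expect_equal(accuracy(preds, labels), 0.75)
  expect_equal(accuracy(preds[1:3, ], labels), 1)
  pm0 <- matrix(0, 4, 4)
  pm0[cbind(1:4, c(2, 3, 4, 1))] <- 1  # every argmax off by one class
  expect_equal(accuracy(ssnplm:::probs_to_predictions(labels$id, pm0),
                        labels), 0)
  rep <- eval_report(preds, labels)
  expect_equal(rep$n, 4)
  expect_equal(rep$accuracy, 0.75)
})

test_that("accuracy and ECE are rank-anticorrelated across model qualities", {
  set.seed(44)
  n <- 60; k <- 6
  labels <- tibble::tibble(id = paste0("s", 1:n),
                           cluster_id = rep_len(1:k, n))
  quality <- c(0.95, 0.8, 0.6, 0.4, 0.25, 0.17)
  acc <- ece <- numeric(length(quality))
  for (q in seq_along(quality)) {
    pm <- matrix((1 - quality[q]) / (k - 1), n, k)
    hit <- stats::runif(n) < quality[q] + 0.02
    tgt <- ifelse(hit, labels$cluster_id, sample(k, n, TRUE))
    pm[cbind(1:n, tgt)] <- quality[q]
    pm <- pm / rowSums(pm)
    preds <- ssnplm:::probs_to_predictions(labels$id, pm)
    acc[q] <- accuracy(preds, labels)
    ece[q] <- ece_perplexity(preds, labels)
  }
  expect_lt(stats::cor(acc, ece, method = "spearman"), 0)
})

test_that("stratified splits follow the floor convention and cover classes", {
  y <- rep(1:10, each = 10)
  sp <- stratified_split(y, 0.8, seed = 3)
  expect_equal(length(sp$train), 80)
  expect_equal(length(sp$test), 20)
  expect_equal(unname(table(y[sp$train])), rep(8L, 10), ignore_attr = TRUE)

  y101 <- c(y, 1L)
  sp101 <- stratified_split(y101, 0.8, seed = 3)
  expect_equal(length(sp101$train), 80)  # floor(0.8 * 11) = 8 for class 1
  expect_equal(length(sp101$test), 21)
})

test_that("frozen-backbone training leaves encoder parameters untouched", {
  s <- tiny_setup()
  before <- ssnplm:::tree_checksum(s$enc$params)
  hd <- build_classifier(classifier_config(n_classes = 4, d_head = 16,
                                           n_heads = 2,
                                           hidden_dims = c(16, 16)),
                         d_model = 16)
  fit <- train_classifier(s$enc, hd, s$corpus, family_labels(s$corpus),
                          epochs = 2, seed = 1)
  expect_identical(ssnplm:::tree_checksum(fit$encoder$params), before)
  expect_s3_class(glance(fit), "tbl_df")
  expect_true(all(c("n", "accuracy", "ece") %in% names(glance(fit))))

  # co-training does move the encoder
  fit2 <- train_classifier(s$enc, hd, s$corpus, family_labels(s$corpus),
                           epochs = 1, freeze_backbone = FALSE, seed = 1)
  expect_false(isTRUE(all.equal(
    ssnplm:::tree_checksum(fit2$encoder$params), before)))
})

test_that("a single-class problem converges to accuracy 1 and ECE near 1", {
  s <- tiny_setup()
  labels <- tibble::tibble(id = s$corpus$id, cluster_id = 1L)
  hd <- build_classifier(classifier_config(n_classes = 1, d_head = 16,
                                           n_heads = 2, hidden_dims = c(8, 8)),
                         d_model = 16)
  fit <- train_classifier(s$enc, hd, s$corpus, labels, epochs = 2, seed = 1)
  expect_equal(fit$report$accuracy, 1)
  expect_equal(fit$report$ece, 1, tolerance = 1e-6)

  bad <- tibble::tibble(id = s$corpus$id, cluster_id = 2L)
  expect_error(train_classifier(s$enc, hd, s$corpus, bad, seed = 1),
               "outside")
})

test_that("one-hot encoding and baseline keep the head contracts", {
  m <- one_hot_encode("AC", max_length = 4)
  expect_equal(dim(m), c(4, 21))
  expect_equal(rowSums(m), c(1, 1, 0, 0))
  expect_equal(which(m[1, ] == 1), c(A = 1L))

  s <- tiny_setup()
  oh <- one_hot_baseline(s$corpus, family_labels(s$corpus),
                         classifier_config(n_classes = 4, d_head = 16,
                                           n_heads = 2,
                                           hidden_dims = c(16, 16)),
                         epochs = 2, seed = 1)
  expect_true(all(c("n", "accuracy", "ece") %in% names(oh$report)))
  pr <- predict(oh, s$corpus[1:2, ])
  expect_equal(sum(pr$probabilities[[1]]), 1, tolerance = 1e-6)
})
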