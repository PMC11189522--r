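# Task training, prediction and baselines ---------------------------------

# encoder states for each sequence, as a list of L_i x d matrices
encoder_states <- function(encoder, seqs, batch_size = 32) {
  tok <- encoder$tokenizer
  ids <- lapply(seqs$residues, tokenize, tok = tok)
  states <- vector("list", nrow(seqs))
  batches <- split(seq_len(nrow(seqs)),
                   ceiling(seq_len(nrow(seqs)) / batch_size))
  for (bt in batches) {
    pb <- pad_batch(ids[bt])
    fw <- encoder_fwd(encoder$params, encoder$config, pb$ids, pb$mask)
    L <- ncol(pb$ids)
    for (j in seq_along(bt)) {
      rows <- ((j - 1) * L + 1):(j * L)
      states[[bt[j]]] <- fw$h[rows[pb$mask[j, ]], , drop = FALSE]
    }
  }
  states
}

# pad a list of state matrices into ((B*L) x d, mask)
pad_states <- function(states) {
  B <- length(states)
  L <- max(vapply(states, nrow, 0L))
  d <- ncol(states[[1]])
  h <- matrix(0, B * L, d)
  mask <- matrix(FALSE, B, L)
  for (b in seq_len(B)) {
    n <- nrow(states[[b]])
    h[((b - 1) * L + 1):((b - 1) * L + n), ] <- states[[b]]
    mask[b, seq_len(n)] <- TRUE
  }
  list(h = h, mask = mask, B = B, L = L)
}

head_probs <- function(params, cfg, states, batch_size = 32) {
  n <- length(states)
  probs <- matrix(0, n, cfg$n_classes)
  for (bt in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    ps <- pad_states(states[bt])
    fw <- head_fwd(params, cfg, ps$h, ps$B, ps$L, ps$mask)
    probs[bt, ] <- softmax_rows(fw$logits)
  }
  probs
}

probs_to_predictions <- function(ids, probs) {
  pred <- max.col(probs, ties.method = "first")
  tibble::tibble(
    id = ids,
    predicted_cluster = as.integer(pred),
    max_probability = probs[cbind(seq_len(nrow(probs)), pred)],
    probabilities = lapply(seq_len(nrow(probs)), function(i) probs[i, ])
  )
}

# shared head-training loop on per-sequence state matrices
train_head_states <- function(head, states, y, train_idx, epochs, lr,
                              batch_size, seed, verbose = FALSE) {
  params <- head$params
  cfg <- head$config
  opt <- adam_new(params)
  history <- numeric(epochs)
  with_seed(stage_seed(seed, "train-head"), {
    for (ep in seq_len(epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      ep_loss <- 0
      for (bt in batches) {
        ps <- pad_states(states[bt])
        fw <- head_fwd(params, cfg, ps$h, ps$B, ps$L, ps$mask,
                       training = TRUE)
        ce <- ce_fwd(fw$logits, y[bt])
        bw <- head_bwd(ce$dlogits, fw$cache, params, cfg)
        upd <- adam_step(params, bw$grads, opt, lr)
        params <- upd$params; opt <- upd$state
        ep_loss <- ep_loss + ce$loss * length(bt)
      }
      history[ep] <- ep_loss / length(train_idx)
      if (verbose) message(sprintf("head epoch %d loss %.4f", ep, history[ep]))
    }
  })
  head$params <- params
  list(head = head,
       history = tibble::tibble(epoch = seq_len(epochs),
                                train_loss = history))
}

check_labels <- function(labels, n_classes) {
  stopifnot(all(c("id", "cluster_id") %in% names(labels)))
  y <- as.integer(labels$cluster_id)
  if (any(is.na(y))) rlang::abort("missing cluster label")
  if (any(y < 1 | y > n_classes)) {
    rlang::abort(paste0("cluster label outside 1..", n_classes))
  }
  y
}

#' Train the cluster classifier on labelled sequences
#'
#' Splits the labelled sequences into train and test parts (stratified by
#' label, default 80/20), trains the head by cross-entropy, and evaluates
#' accuracy and ECE perplexity on the held-out part. With
#' `freeze_backbone = TRUE` (default) the encoder is untouched and its
#' per-residue states are computed once and cached; with `FALSE` the encoder
#' is co-trained through the head.
#'
#' @param encoder A [pretrain_mlm()] encoder.
#' @param head A [build_classifier()] head whose `d_model` matches the
#'   encoder.
#' @param seqs Sequence tibble of labelled sequences.
#' @param labels Tibble (`id`, `cluster_id`) with labels in
#'   `1..n_classes`; every sequence in `seqs` must be labelled.
#' @param train_fraction Training fraction of the labelled data
#'   (default 0.8).
#' @param epochs,lr,batch_size Head optimisation settings (Adam).
#' @param freeze_backbone Keep encoder parameters fixed (default TRUE).
#' @param seed Integer seed (split, batch order, dropout).
#' @param verbose Print per-epoch losses.
#' @return An object of class `plm_classifier` with the trained head, the
#'   (possibly updated) encoder, the split, a training `history`, held-out
#'   `test_predictions` and an evaluation `report`
#'   (`n`, `accuracy`, `ece`).
#' @export
train_classifier <- function(encoder, head, seqs, labels,
                             train_fraction = 0.8, epochs = 40, lr = 1e-3,
                             batch_size = 32, freeze_backbone = TRUE,
                             seed = 1, verbose = FALSE) {
  stopifnot(inherits(encoder, "plm_encoder"), inherits(head, "plm_head"))
  seqs <- validate_seq_tbl(seqs)
  if (head$d_model != encoder$config$d_model) {
    rlang::abort("head d_model does not match encoder d_model")
  }
  lab <- labels[match(seqs$id, labels$id), ]
  if (any(is.na(lab$cluster_id))) {
    rlang::abort("every training sequence must carry a cluster label")
  }
  y <- check_labels(lab, head$config$n_classes)
  split <- stratified_split(y, train_fraction, seed = seed)

  if (freeze_backbone) {
    states <- encoder_states(encoder, seqs, batch_size)
    fit <- train_head_states(head, states, y, split$train, epochs, lr,
                             batch_size, seed, verbose)
    head <- fit$head
    history <- fit$history
  } else {
    fit <- cotrain_encoder_head(encoder, head, seqs, y, split$train,
                                epochs, lr, batch_size, seed, verbose)
    encoder <- fit$encoder
    head <- fit$head
    history <- fit$history
    states <- encoder_states(encoder, seqs, batch_size)
  }

  probs <- head_probs(head$params, head$config, states[split$test],
                      batch_size)
  preds <- probs_to_predictions(seqs$id[split$test], probs)
  truth <- tibble::tibble(id = seqs$id[split$test],
                          cluster_id = y[split$test])
  report <- tibble::tibble(
    n = length(split$test),
    accuracy = accuracy(preds, truth),
    ece = ece_perplexity(preds, truth)
  )
  structure(
    list(head = head, encoder = encoder, frozen = freeze_backbone,
         split = list(train = seqs$id[split$train],
                      test = seqs$id[split$test]),
         history = history, test_predictions = preds, test_labels = truth,
         report = report),
    class = "plm_classifier"
  )
}

# co-training path: gradients flow through the head into the encoder
cotrain_encoder_head <- function(encoder, head, seqs, y, train_idx,
                                 epochs, lr, batch_size, seed, verbose) {
  tok <- encoder$tokenizer
  ecfg <- encoder$config
  hcfg <- head$config
  ids <- lapply(seqs$residues, tokenize, tok = tok)
  params <- list(enc = encoder$params, head = head$params)
  opt <- adam_new(params)
  history <- numeric(epochs)
  with_seed(stage_seed(seed, "train-cotrain"), {
    for (ep in seq_len(epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      ep_loss <- 0
      for (bt in batches) {
        pb <- pad_batch(ids[bt])
        fw <- encoder_fwd(params$enc, ecfg, pb$ids, pb$mask,
                          training = TRUE)
        hf <- head_fwd(params$head, hcfg, fw$h, nrow(pb$ids),
                       ncol(pb$ids), pb$mask, training = TRUE)
        ce <- ce_fwd(hf$logits, y[bt])
        hb <- head_bwd(ce$dlogits, hf$cache, params$head, hcfg,
                       need_dh = TRUE)
        ge <- encoder_bwd(hb$dh, fw$cache, params$enc, ecfg,
                          tok$vocab_size)
        ge$mlm_head <- tree_map(function(p) p * 0, params$enc$mlm_head)
        upd <- adam_step(params, list(enc = ge, head = hb$grads), opt, lr)
        params <- upd$params; opt <- upd$state
        ep_loss <- ep_loss + ce$loss * length(bt)
      }
      history[ep] <- ep_loss / length(train_idx)
      if (verbose) message(sprintf("cotrain epoch %d loss %.4f", ep,
                                   history[ep]))
    }
  })
  encoder$params <- params$enc
  head$params <- params$head
  list(encoder = encoder, head = head,
       history = tibble::tibble(epoch = seq_len(epochs),
                                train_loss = history))
}

#' Predict cluster membership for new sequences
#'
#' Deterministic inference: one class distribution per sequence,
#' `predicted_cluster` = argmax (ties broken towards the smallest cluster
#' id).
#'
#' @param encoder A trained [pretrain_mlm()] encoder.
#' @param head A trained [build_classifier()] head.
#' @param seqs Sequence tibble.
#' @param batch_size Minibatch size.
#' @return A tibble (`id`, `predicted_cluster`, `max_probability`,
#'   `probabilities` list-column; each distribution sums to 1).
#' @export
predict_clusters <- function(encoder, head, seqs, batch_size = 32) {
  stopifnot(inherits(encoder, "plm_encoder"), inherits(head, "plm_head"))
  seqs <- validate_seq_tbl(seqs)
  states <- encoder_states(encoder, seqs, batch_size)
  probs <- head_probs(head$params, head$config, states, batch_size)
  probs_to_predictions(seqs$id, probs)
}

#' @export
predict.plm_classifier <- function(object, new_data, ...) {
  if (is.null(object$encoder)) {  # one-hot baseline fit
    new_data <- validate_seq_tbl(new_data)
    states <- lapply(new_data$residues, function(r) {
      one_hot_encode(r, max_length = nchar(r))
    })
    probs <- head_probs(object$head$params, object$head$config, states)
    return(probs_to_predictions(new_data$id, probs))
  }
  predict_clusters(object$encoder, object$head, new_data)
}

#' @export
print.plm_classifier <- function(x, ...) {
  cat("Cluster classifier (",
      if (x$frozen) "frozen backbone" else "co-trained backbone", ")\n",
      sep = "")
  cat("  held-out n =", x$report$n,
      " accuracy =", round(x$report$accuracy, 4),
      " ECE =", round(x$report$ece, 4), "\n")
  invisible(x)
}

#' @importFrom generics glance
#' @export
glance.plm_classifier <- function(x, ...) x$report

#' @importFrom generics tidy
#' @export
tidy.plm_classifier <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(
      dplyr::inner_join(x$test_predictions, x$test_labels, by = "id"),
      cluster_id
    ),
    n = dplyr::n(),
    accuracy = mean(.data$predicted_cluster == .data$cluster_id),
    mean_p_true = mean(purrr::map2_dbl(.data$probabilities,
                                       .data$cluster_id, `[`)),
    .groups = "drop"
  )
}

# One-hot baseline ---------------------------------------------------------

#' One-hot encoding of a protein sequence
#'
#' @param residues Residue string.
#' @param max_length Number of rows of the encoding; rows beyond the
#'   sequence end are all zero.
#' @return A `max_length` x 21 binary matrix (columns = the 20 standard
#'   residues plus X, alphabetical).
#' @export
#' @examples
#' one_hot_encode("AC", max_length = 4)
one_hot_encode <- function(residues, max_length) {
  residues <- normalize_residues(residues)
  v <- strsplit(residues, "")[[1]]
  if (length(v) > max_length) v <- v[seq_len(max_length)]
  m <- matrix(0, max_length, 21,
              dimnames = list(NULL, aa_alphabet()))
  if (length(v)) m[cbind(seq_along(v), match(v, aa_alphabet()))] <- 1
  m
}

#' Train the identical task head on one-hot sequence encodings
#'
#' The baseline without representation learning: the same head architecture
#' is trained on raw one-hot encodings (per-position indicator vectors over
#' the 21-letter alphabet) instead of learned encoder states, with the same
#' split convention and evaluation.
#'
#' @param seqs,labels As in [train_classifier()].
#' @param config A [classifier_config()]; the head is built at
#'   `d_model = 21`.
#' @param train_fraction,epochs,lr,batch_size,seed,verbose As in
#'   [train_classifier()].
#' @return A `plm_classifier`-style fit (class `onehot_classifier` as well)
#'   with the same `report` fields.
#' @export
one_hot_baseline <- function(seqs, labels, config = classifier_config(),
                             train_fraction = 0.8, epochs = 40, lr = 1e-3,
                             batch_size = 32, seed = 1, verbose = FALSE) {
  seqs <- validate_seq_tbl(seqs)
  lab <- labels[match(seqs$id, labels$id), ]
  if (any(is.na(lab$cluster_id))) {
    rlang::abort("every training sequence must carry a cluster label")
  }
  y <- check_labels(lab, config$n_classes)
  split <- stratified_split(y, train_fraction, seed = seed)
  # per-sequence one-hot states, trimmed to the sequence length (zero rows
  # beyond the end carry no information and are masked out of the head)
  states <- lapply(seqs$residues, function(r) {
    one_hot_encode(r, max_length = nchar(r))
  })
  head <- build_classifier(config, d_model = 21,
                           seed = stage_seed(seed, "onehot-init"))
  fit <- train_head_states(head, states, y, split$train, epochs, lr,
                           batch_size, seed, verbose)
  probs <- head_probs(fit$head$params, config, states[split$test],
                      batch_size)
  preds <- probs_to_predictions(seqs$id[split$test], probs)
  truth <- tibble::tibble(id = seqs$id[split$test],
                          cluster_id = y[split$test])
  report <- tibble::tibble(
    n = length(split$test),
    accuracy = accuracy(preds, truth),
    ece = ece_perplexity(preds, truth)
  )
  structure(
    list(head = fit$head, encoder = NULL, frozen = TRUE,
         split = list(train = seqs$id[split$train],
                      test = seqs$id[split$test]),
         history = fit$history, test_predictions = preds,
         test_labels = truth, report = report),
    class = c("onehot_classifier", "plm_classifier")
  )
}
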