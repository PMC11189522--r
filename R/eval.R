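# Evaluation: accuracy and ECE perplexity ---------------------------------

join_preds_labels <- function(preds, labels) {
  stopifnot(all(c("id", "probabilities", "predicted_cluster") %in%
                  names(preds)))
  stopifnot(all(c("id", "cluster_id") %in% names(labels)))
  out <- dplyr::inner_join(preds, labels, by = "id")
  if (nrow(out) < nrow(preds)) {
    missing <- setdiff(preds$id, labels$id)
    rlang::abort(paste0("missing label for prediction(s): ",
                        paste(utils::head(missing, 5), collapse = ", ")))
  }
  if (nrow(out) < 1) rlang::abort("no predictions to evaluate")
  out
}

#' Exponential cross-entropy (ECE) perplexity
#'
#' The exponential of the mean natural-log cross-entropy of the true labels
#' under the predicted distributions,
#' `exp(1/n * sum_i -log p_i(y_i))`. A perplexity: 1 means deterministic
#' correct predictions; K means predictions indistinguishable from a uniform
#' draw over K classes. The true-label probability is clamped at `clamp`
#' before the log so confident wrong predictions stay finite.
#'
#' @param preds Prediction tibble from [predict_clusters()] (columns `id`,
#'   `probabilities`).
#' @param labels Tibble (`id`, `cluster_id`); every prediction must have a
#'   label.
#' @param clamp Lower bound on the true-label probability (default 1e-12).
#' @return The ECE perplexity (a single number >= 1 up to clamping).
#' @export
#' @examples
#' p <- tibble::tibble(id = "s1", predicted_cluster = 1L,
#'                     max_probability = 1,
#'                     probabilities = list(c(1, 0, 0)))
#' ece_perplexity(p, tibble::tibble(id = "s1", cluster_id = 1))  # 1
ece_perplexity <- function(preds, labels, clamp = 1e-12) {
  df <- join_preds_labels(preds, labels)
  p_true <- purrr::map2_dbl(df$probabilities, df$cluster_id,
                            function(p, y) p[[y]])
  exp(mean(-log(pmax(p_true, clamp))))
}

#' Classification accuracy
#'
#' Fraction of predictions whose `predicted_cluster` equals the true label.
#'
#' @inheritParams ece_perplexity
#' @return A fraction in `[0, 1]`.
#' @export
accuracy <- function(preds, labels) {
  df <- join_preds_labels(preds, labels)
  mean(df$predicted_cluster == df$cluster_id)
}

#' Evaluation report for a prediction set
#'
#' @inheritParams ece_perplexity
#' @return A one-row tibble (`n`, `accuracy`, `ece`).
#' @export
eval_report <- function(preds, labels) {
  df <- join_preds_labels(preds, labels)
  tibble::tibble(
    n = nrow(df),
    accuracy = accuracy(preds, labels),
    ece = ece_perplexity(preds, labels)
  )
}
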