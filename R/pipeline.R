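# End-to-end semi-supervised pipeline --------------------------------------
#
# simulate/read -> redundancy reduction -> SSN -> cluster labels ->
# MLM pre-training on all sequences -> task training on the labelled
# representatives -> evaluation. One global seed is fanned out to every
# stochastic stage by stage-name hashing, so a single integer reproduces a
# whole run; every intermediate artefact is written to the run directory
# together with a machine-readable manifest.

#' Pipeline configuration
#'
#' @param out_dir Output directory for run artefacts (created if needed).
#' @param input_fasta Path to an input FASTA, or `NULL` to simulate.
#' @param simulate Named list of [generate_families()] arguments (used when
#'   `input_fasta` is `NULL`).
#' @param redundancy_threshold Identity cutoff for [reduce_redundancy()].
#' @param identity_threshold Edge threshold for [build_ssn()].
#' @param k Number of top clusters forming the label space.
#' @param encoder An [encoder_config()].
#' @param classifier A [classifier_config()]; its `n_classes` must equal
#'   `k`.
#' @param pretrain Named list of [pretrain_mlm()] settings
#'   (`epochs`, `lr`, `mask_rate`, `train_fraction`, `batch_size`).
#' @param train Named list of [train_classifier()] settings
#'   (`epochs`, `lr`, `train_fraction`, `batch_size`, `freeze_backbone`).
#' @param seed Global integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            input_fasta = NULL,
                            simulate = list(),
                            redundancy_threshold = 0.80,
                            identity_threshold = 0.40,
                            k = 45,
                            encoder = encoder_config(),
                            classifier = classifier_config(n_classes = k),
                            pretrain = list(),
                            train = list(),
                            seed = 1) {
  if (classifier$n_classes != k) {
    rlang::abort("classifier n_classes must equal k (the top-cluster count)")
  }
  structure(
    list(out_dir = out_dir, input_fasta = input_fasta, simulate = simulate,
         redundancy_threshold = redundancy_threshold,
         identity_threshold = identity_threshold, k = k,
         encoder = encoder, classifier = classifier,
         pretrain = pretrain, train = train, seed = seed),
    class = "pipeline_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort_stage(stage, conditionMessage(e))
  })
}

#' Run the semi-supervised pipeline end to end
#'
#' @param cfg A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return An object of class `ssnplm_run` with the fitted encoder and
#'   classifier, the network partition, the label set, the evaluation
#'   `report` and the paths of all written artefacts.
#' @export
run_semisupervised <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[ssnplm] ", ...)
  paths <- list()

  # --- input ---------------------------------------------------------------
  seqs <- run_stage("input", {
    if (!is.null(cfg$input_fasta)) {
      read_fasta(cfg$input_fasta)
    } else {
      args <- cfg$simulate
      args$seed <- args$seed %||% stage_seed(cfg$seed, "simulate")
      do.call(generate_families, args)
    }
  })
  if ("family" %in% names(seqs)) {
    paths$truth <- file.path(cfg$out_dir, "truth.tsv")
    readr::write_tsv(seqs[, c("id", "family")], paths$truth)
  }
  paths$corpus <- file.path(cfg$out_dir, "corpus.fasta")
  write_fasta(seqs, paths$corpus)
  say("input: ", nrow(seqs), " sequences")

  # --- redundancy reduction ------------------------------------------------
  red <- run_stage("reduce", {
    reduce_redundancy(seqs, threshold = cfg$redundancy_threshold)
  })
  paths$representatives <- file.path(cfg$out_dir, "representatives.fasta")
  write_fasta(red$representatives, paths$representatives)
  say("reduce: ", nrow(red$representatives), " representatives")

  # --- SSN + clusters ------------------------------------------------------
  net <- run_stage("ssn", {
    build_ssn(red$representatives,
              identity_threshold = cfg$identity_threshold)
  })
  part <- run_stage("clusters", find_clusters(net))
  paths$graphml <- file.path(cfg$out_dir, "network.graphml")
  export_graph(net, part, paths$graphml, format = "graphml")
  paths$edges <- file.path(cfg$out_dir, "edges.tsv")
  export_graph(net, part, paths$edges, format = "edge-tsv")
  paths$clusters <- file.path(cfg$out_dir, "clusters.tsv")
  readr::write_tsv(part$clusters[, c("cluster_id", "size", "n_edges",
                                     "convergence_ratio")], paths$clusters)
  say("ssn: ", length(net$nodes), " nodes, ", nrow(net$edges), " edges; ",
      nrow(part$clusters), " clusters, ", length(part$singletons),
      " singletons")

  # --- labels --------------------------------------------------------------
  labels <- run_stage("labels", {
    if (nrow(part$clusters) < cfg$k) {
      rlang::abort(paste0(
        "only ", nrow(part$clusters), " clusters survive but k = ", cfg$k,
        "; choose a smaller k"
      ))
    }
    top_k_labels(part, cfg$k)
  })
  paths$labels <- file.path(cfg$out_dir, "labels.tsv")
  readr::write_tsv(labels, paths$labels)
  say("labels: ", nrow(labels), " labelled representatives over ",
      cfg$k, " clusters")

  # --- MLM pre-training on the full corpus ---------------------------------
  encoder <- run_stage("pretrain", {
    args <- cfg$pretrain
    args$seqs <- seqs
    args$config <- cfg$encoder
    args$seed <- stage_seed(cfg$seed, "pretrain")
    do.call(pretrain_mlm, args)
  })
  paths$encoder <- file.path(cfg$out_dir, "encoder.rds")
  saveRDS(encoder, paths$encoder)
  say("pretrain: final val loss ",
      round(encoder$history$val_loss[nrow(encoder$history)], 4))

  # --- task training on labelled representatives ---------------------------
  fit <- run_stage("train", {
    labelled <- red$representatives[red$representatives$id %in% labels$id, ]
    head <- build_classifier(cfg$classifier,
                             d_model = cfg$encoder$d_model,
                             seed = stage_seed(cfg$seed, "head-init"))
    args <- cfg$train
    args$encoder <- encoder
    args$head <- head
    args$seqs <- labelled
    args$labels <- labels
    args$seed <- stage_seed(cfg$seed, "train")
    do.call(train_classifier, args)
  })
  paths$classifier <- file.path(cfg$out_dir, "classifier.rds")
  saveRDS(fit, paths$classifier)
  paths$predictions <- file.path(cfg$out_dir, "predictions.tsv")
  readr::write_tsv(
    fit$test_predictions[, c("id", "predicted_cluster", "max_probability")],
    paths$predictions
  )
  paths$report <- file.path(cfg$out_dir, "report.json")
  jsonlite::write_json(as.list(fit$report), paths$report, auto_unbox = TRUE,
                       digits = NA)
  say("train: held-out accuracy ", round(fit$report$accuracy, 4),
      ", ECE ", round(fit$report$ece, 4))

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    package = "ssnplm",
    package_version = as.character(utils::packageVersion("ssnplm")),
    r_version = R.version.string,
    seed = cfg$seed,
    stage_seeds = list(
      simulate = stage_seed(cfg$seed, "simulate"),
      pretrain = stage_seed(cfg$seed, "pretrain"),
      head_init = stage_seed(cfg$seed, "head-init"),
      train = stage_seed(cfg$seed, "train")
    ),
    parameters = list(
      redundancy_threshold = cfg$redundancy_threshold,
      identity_threshold = cfg$identity_threshold,
      k = cfg$k,
      simulate = cfg$simulate,
      encoder = unclass(cfg$encoder),
      classifier = unclass(cfg$classifier),
      pretrain = cfg$pretrain,
      train = cfg$train
    )
  )
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")

  structure(
    list(seqs = seqs, reduction = red, ssn = net, partition = part,
         labels = labels, encoder = encoder, fit = fit,
         report = fit$report, paths = paths, manifest = manifest),
    class = "ssnplm_run"
  )
}

#' @export
print.ssnplm_run <- function(x, ...) {
  cat("Semi-supervised run:", nrow(x$seqs), "sequences ->",
      length(x$ssn$nodes), "representatives ->", nrow(x$partition$clusters),
      "clusters\n")
  cat("  held-out accuracy", round(x$report$accuracy, 4), "ECE",
      round(x$report$ece, 4), "\n")
  invisible(x)
}

#' @importFrom generics glance
#' @export
glance.ssnplm_run <- function(x, ...) {
  dplyr::bind_cols(glance(x$partition), x$report)
}
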