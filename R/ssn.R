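# Sequence similarity network ---------------------------------------------
#
# Nodes are (redundancy-reduced) representative sequences; an undirected edge
# joins two nodes whose pairwise alignment identity reaches the threshold
# (default 0.40, the usual gloss of the EFI-EST alignment-score cutoff).
# Connected components of size >= 2 are "main clusters", ranked by size;
# size-1 components are singletons. Each cluster carries a convergence ratio,
# realised edges over possible edges, a standard tightness diagnostic: values
# near 1 suggest an isofunctional cluster, low values (e.g. < 0.30) a mixed
# one.

#' Build a sequence similarity network
#'
#' Computes all-vs-all pairwise alignment identities and keeps the pairs at
#' or above `identity_threshold` as edges. Global-mode identity is the
#' default for edges: over full-length alignments the identity of unrelated
#' sequences concentrates near the random background (~0.15 for uniform
#' random proteins), well below the 0.40 threshold, whereas short local
#' footprints can reach spuriously high identities.
#'
#' @param reps A sequence tibble, normally redundancy-reduced
#'   ([reduce_redundancy()]); duplicated residue strings are reported with a
#'   message but tolerated.
#' @param identity_threshold Edge threshold in `(0, 1]`, default 0.40.
#' @param align An [align_params()] object (default global BLOSUM62 11/1).
#' @return An object of class `ssn`: node ids, an edge tibble
#'   (`from`, `to`, `identity`) and the parameters used.
#' @export
build_ssn <- function(reps, identity_threshold = 0.40,
                      align = align_params(mode = "global")) {
  reps <- validate_seq_tbl(reps)
  if (nrow(reps) < 1) rlang::abort("build_ssn needs at least one sequence")
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (anyDuplicated(reps$residues)) {
    message("build_ssn: duplicate residue strings found; ",
            "input does not look redundancy-reduced")
  }

  n <- nrow(reps)
  edges <- vector("list", max(n - 1, 0))
  if (n >= 2) {
    set <- Biostrings::AAStringSet(reps$residues)
    for (i in seq_len(n - 1)) {
      res <- identity_many(set[(i + 1):n], set[[i]], align)
      keep <- which(res$identity >= identity_threshold)
      if (length(keep)) {
        edges[[i]] <- tibble::tibble(
          from = reps$id[i],
          to = reps$id[i + keep],
          identity = res$identity[keep]
        )
      }
    }
  }
  edges <- dplyr::bind_rows(edges)
  if (!nrow(edges)) {
    edges <- tibble::tibble(from = character(), to = character(),
                            identity = numeric())
  }
  structure(
    list(nodes = reps$id, edges = edges,
         identity_threshold = identity_threshold, align = align),
    class = "ssn"
  )
}

#' @export
print.ssn <- function(x, ...) {
  cat("Sequence similarity network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges (identity >=", x$identity_threshold, ")\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.ssn <- function(x, ...) x$edges

as_igraph <- function(ssn) {
  igraph::graph_from_data_frame(
    ssn$edges[, c("from", "to", "identity")],
    directed = FALSE,
    vertices = data.frame(name = ssn$nodes)
  )
}

#' Cluster analysis of a similarity network
#'
#' Finds connected components. Components with at least two nodes become
#' clusters, ranked 1..K by decreasing size with ties broken by the
#' lexicographically smallest member id; single-node components are
#' singletons. Each cluster's convergence ratio is its realised edge count
#' divided by `size * (size - 1) / 2`.
#'
#' @param ssn An [build_ssn()] object.
#' @return An object of class `ssn_partition` with a `clusters` tibble
#'   (`cluster_id`, `size`, `n_edges`, `convergence_ratio`, `members`
#'   list-column), a `singletons` character vector and a `membership` tibble
#'   (`id`, `cluster_id`, NA for singletons).
#' @export
find_clusters <- function(ssn) {
  stopifnot(inherits(ssn, "ssn"))
  g <- as_igraph(ssn)
  comp <- igraph::components(g)
  members <- split(ssn$nodes, comp$membership[ssn$nodes])
  sizes <- lengths(members)
  singles <- sort(unlist(members[sizes == 1], use.names = FALSE)) %||% character()
  members <- members[sizes >= 2]

  if (length(members)) {
    min_id <- vapply(members, function(m) min(m), "")
    ord <- order(-lengths(members), min_id)
    members <- unname(lapply(members[ord], sort))
    n_edges <- vapply(members, function(m) {
      sum(ssn$edges$from %in% m & ssn$edges$to %in% m)
    }, integer(1))
    sizes <- unname(lengths(members))
    clusters <- tibble::tibble(
      cluster_id = seq_along(members),
      size = as.integer(sizes),
      n_edges = as.integer(n_edges),
      convergence_ratio = n_edges / (sizes * (sizes - 1) / 2),
      members = unname(members)
    )
  } else {
    clusters <- tibble::tibble(
      cluster_id = integer(), size = integer(), n_edges = integer(),
      convergence_ratio = numeric(), members = list()
    )
  }
  membership <- tibble::tibble(
    id = c(unlist(clusters$members, use.names = FALSE), singles),
    cluster_id = c(rep(clusters$cluster_id, clusters$size),
                   rep(NA_integer_, length(singles)))
  )
  membership <- membership[match(ssn$nodes, membership$id), ]
  structure(
    list(clusters = clusters, singletons = singles, membership = membership),
    class = "ssn_partition"
  )
}

#' @export
print.ssn_partition <- function(x, ...) {
  cat("SSN partition:", nrow(x$clusters), "main clusters,",
      length(x$singletons), "singletons\n")
  if (nrow(x$clusters)) {
    print(utils::head(x$clusters[, c("cluster_id", "size", "n_edges",
                                     "convergence_ratio")], 10))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.ssn_partition <- function(x, ...) x$membership

#' @importFrom generics glance
#' @export
glance.ssn_partition <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$membership),
    n_clusters = nrow(x$clusters),
    n_singletons = length(x$singletons),
    largest_cluster = if (nrow(x$clusters)) max(x$clusters$size) else 0L
  )
}

#' Convergence ratio of one cluster
#'
#' @param partition An [find_clusters()] result.
#' @param cluster_id Cluster rank (1 = largest).
#' @return The cluster's convergence ratio in `(0, 1]`. Singletons have no
#'   convergence ratio; requesting an unknown cluster id is an error.
#' @export
convergence_ratio <- function(partition, cluster_id) {
  stopifnot(inherits(partition, "ssn_partition"))
  i <- match(cluster_id, partition$clusters$cluster_id)
  if (is.na(i)) {
    rlang::abort(paste0("no cluster with id ", cluster_id,
                        " (singletons have no convergence ratio)"))
  }
  partition$clusters$convergence_ratio[i]
}

#' Supervised label set from the top K clusters
#'
#' Restricts cluster membership to the K largest clusters, the label space
#' used for classifier training (the published analysis used the top 45
#' clusters). Sequences in smaller clusters and singletons carry no label and
#' are excluded from supervised training.
#'
#' @param partition An [find_clusters()] result.
#' @param k Positive integer number of clusters to keep.
#' @return A tibble (`id`, `cluster_id`) with `cluster_id` in `1..min(k, K)`.
#' @export
top_k_labels <- function(partition, k = 45) {
  stopifnot(inherits(partition, "ssn_partition"), k >= 1)
  keep <- partition$clusters[partition$clusters$cluster_id <= k, ]
  tibble::tibble(
    id = unlist(keep$members, use.names = FALSE) %||% character(),
    cluster_id = rep(keep$cluster_id, keep$size)
  )
}

#' Export a similarity network for Cytoscape
#'
#' Writes either GraphML (node attribute `cluster`: the cluster id or
#' `"singleton"`; edge attribute `identity`) or a TSV edge list with columns
#' `source`, `target`, `identity` (6 decimal places).
#'
#' @param ssn An [build_ssn()] object.
#' @param partition The matching [find_clusters()] result.
#' @param path Output file path.
#' @param format `"graphml"` or `"edge-tsv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(ssn, partition, path,
                         format = c("graphml", "edge-tsv", "edge_tsv")) {
  stopifnot(inherits(ssn, "ssn"), inherits(partition, "ssn_partition"))
  format <- match.arg(format)
  if (format == "graphml") {
    g <- as_igraph(ssn)
    memb <- partition$membership$cluster_id[
      match(igraph::V(g)$name, partition$membership$id)]
    igraph::V(g)$cluster <- ifelse(is.na(memb), "singleton",
                                   as.character(memb))
    igraph::write_graph(g, path, format = "graphml")
  } else {
    out <- tibble::tibble(
      source = ssn$edges$from,
      target = ssn$edges$to,
      identity = sprintf("%.6f", ssn$edges$identity)
    )
    readr::write_tsv(out, path)
  }
  invisible(path)
}
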