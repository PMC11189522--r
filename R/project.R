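# 2-D projection of sequence embeddings ------------------------------------

#' Project embeddings to two dimensions
#'
#' Deterministic spectral neighbour embedding (Laplacian eigenmap): a
#' symmetrised k-nearest-neighbour graph with heat-kernel weights is built
#' on the rows, and the two smallest non-trivial eigenvectors of its
#' normalised graph Laplacian give the coordinates. Like other
#' neighbour-embedding projections (UMAP, t-SNE) it preserves local
#' neighbourhoods, and identical inputs always give identical output;
#' `seed` is accepted for interface uniformity with the stochastic stages.
#'
#' @param x Numeric matrix of embeddings (>= 10 rows), e.g. from
#'   [embed_sequences()]; rownames, if present, become the `id` column.
#' @param n_neighbors Neighbourhood size (default 10); `nrow(x)` must
#'   exceed it.
#' @param seed Unused by the deterministic spectral solver; kept so callers
#'   can thread one seed through every stage.
#' @return A tibble (`id`, `dim1`, `dim2`) with one row per input row.
#' @export
project_2d <- function(x, n_neighbors = 10, seed = 1) {
  x <- as.matrix(x)
  if (nrow(x) < 10) rlang::abort("project_2d needs at least 10 rows")
  if (nrow(x) <= n_neighbors) {
    rlang::abort("fewer rows than the neighbourhood size")
  }
  n <- nrow(x)
  D <- as.matrix(stats::dist(x))
  # k nearest neighbours (excluding self)
  knn_d <- apply(D, 1, function(r) sort(r)[n_neighbors + 1])
  sigma2 <- stats::median(knn_d)^2
  if (sigma2 <= 0) sigma2 <- 1  # degenerate: many duplicate rows
  W <- exp(-D^2 / sigma2)
  keep <- D <= matrix(knn_d, n, n) | D <= matrix(knn_d, n, n, byrow = TRUE)
  W[!keep] <- 0
  diag(W) <- 0
  deg <- pmax(rowSums(W), .Machine$double.eps)
  inv_sqrt <- 1 / sqrt(deg)
  Lsym <- diag(n) - (inv_sqrt * W) %*% diag(inv_sqrt)
  e <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  # two smallest non-trivial eigenvectors
  u <- e$vectors[, c(n - 1, n - 2), drop = FALSE]
  coords <- u * inv_sqrt
  # fix the sign convention so output is reproducible across BLAS builds
  for (j in 1:2) {
    k <- which.max(abs(coords[, j]))
    if (coords[k, j] < 0) coords[, j] <- -coords[, j]
  }
  tibble::tibble(
    id = rownames(x) %||% as.character(seq_len(n)),
    dim1 = coords[, 1],
    dim2 = coords[, 2]
  )
}
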