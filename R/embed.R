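# 2D embeddings of the standardized feature matrix.  Embeddings are pure
# views: they never alter, filter or reorder the feature table.

#' Principal component embedding to 2D
#'
#' Projects the standardized feature matrix on its top two principal axes.
#' Deterministic; each component's sign is fixed so its largest-magnitude
#' loading is positive.  If the matrix has rank < 2 the second component is
#' zeroed with a warning.
#'
#' @param mat standardized matrix from [zscore_features()].
#' @return An `embedding_2d`: data.frame `(x, y)` with attributes `method`,
#'   `explained` (variance fractions of all components) and `loadings`.
#' @export
pca_2d <- function(mat) {
  if (nrow(mat) < 3) stop("need at least 3 cells", call. = FALSE)
  if (ncol(mat) < 2) stop("need at least 2 features", call. = FALSE)
  pc <- prcomp(mat, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  rank2 <- length(pc$sdev) >= 2 && pc$sdev[2] > 1e-12 * pc$sdev[1]
  scores <- pc$x
  load <- pc$rotation
  for (j in 1:2) {
    if (j > ncol(load)) break
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  y <- if (rank2) scores[, 2] else {
    warning("matrix has rank < 2; second component zeroed")
    rep(0, nrow(mat))
  }
  out <- data.frame(x = scores[, 1], y = y)
  structure(out, method = "pca", explained = expl,
            loadings = load[, seq_len(min(2, ncol(load))), drop = FALSE],
            class = c("embedding_2d", "data.frame"))
}

#' UMAP embedding to 2D
#'
#' Uniform manifold approximation and projection of the standardized
#' feature matrix, reproducible for a fixed seed.  Hyperparameter defaults
#' are the community standards (`n_neighbors = 15`, `min_dist = 0.1`,
#' seed 0) and are recorded on the result.
#'
#' @param mat standardized matrix from [zscore_features()].
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param seed integer seed.
#' @return An `embedding_2d` data.frame `(x, y)` with attributes `method`,
#'   `hyperparameters`.
#' @export
umap_2d <- function(mat, n_neighbors = 15, min_dist = 0.1, seed = 0) {
  if (nrow(mat) < n_neighbors + 1)
    stop("too few cells: need at least n_neighbors + 1", call. = FALSE)
  emb <- uwot::umap(mat, n_neighbors = n_neighbors, min_dist = min_dist,
                    n_threads = 1, n_sgd_threads = 1, seed = seed,
                    batch = FALSE)
  out <- data.frame(x = emb[, 1], y = emb[, 2])
  structure(out, method = "umap",
            hyperparameters = list(n_neighbors = n_neighbors,
                                   min_dist = min_dist, seed = seed),
            class = c("embedding_2d", "data.frame"))
}

#' Per-feature colour values for an embedding
#'
#' Returns the feature values aligned with the embedding's point order so
#' plots can colour each cell by any geometric parameter.
#'
#' @param embedding an `embedding_2d` computed from `table`'s matrix.
#' @param table the source `cell_feature_table`.
#' @param features feature columns to export.
#' @return data.frame with `x`, `y` and one column per feature, rows in
#'   embedding point order.
#' @export
embedding_colors <- function(embedding, table, features = feature_names()) {
  if (nrow(embedding) != nrow(table))
    stop("embedding and table have different numbers of cells",
         call. = FALSE)
  cbind(as.data.frame(embedding),
        as.data.frame(table)[, intersect(features, names(table)),
                             drop = FALSE])
}

# neighbourhood-preservation score of an embedding (Venna & Kaski):
# 1 is perfect, ~0.5 is chance.  Used by the test-suite as an oracle.
embedding_trustworthiness <- function(X, Y, k = 10) {
  n <- nrow(X)
  dX <- as.matrix(dist(X))
  dY <- as.matrix(dist(Y))
  diag(dX) <- Inf
  diag(dY) <- Inf
  s <- 0
  for (i in seq_len(n)) {
    rX <- rank(dX[i, ], ties.method = "first")
    nnY <- order(dY[i, ])[seq_len(k)]
    viol <- rX[nnY] - k
    s <- s + sum(viol[viol > 0])
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * s
}
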