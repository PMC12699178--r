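# Clustergram over cells, quantile subgroup selection, and back-mapping of
# selected cells into the source label volume.

#' Z-score a feature matrix
#'
#' Standardizes the selected feature columns to mean 0, sd 1.  Constant
#' columns become all-zero with a warning.  The same standardized matrix
#' feeds clustering and the 2D embeddings, so there is a single
#' standardization pathway.
#'
#' @param table a `cell_feature_table` (or data.frame).
#' @param features character vector of numeric columns; the default is the
#'   five clustergram features.
#' @return Numeric matrix (cells x features) with `center`/`scale`
#'   attributes; standardization is idempotent up to those attributes.
#' @export
zscore_features <- function(table,
                            features = c("volume", "roundness", "elongation",
                                         "ellipticity", "longest_axis")) {
  if (length(features) == 0) stop("empty feature list", call. = FALSE)
  if (!all(features %in% names(table)))
    stop("unknown features: ",
         paste(setdiff(features, names(table)), collapse = ", "),
         call. = FALSE)
  if (nrow(table) < 2) stop("need at least 2 cells", call. = FALSE)
  m <- as.matrix(as.data.frame(table)[, features, drop = FALSE])
  ctr <- colMeans(m)
  scl <- apply(m, 2, sd)
  const <- scl < 1e-12
  if (any(const)) {
    warning("constant feature column(s): ",
            paste(features[const], collapse = ", "), "; set to zero")
    scl[const] <- 1
  }
  z <- sweep(sweep(m, 2, ctr), 2, scl, "/")
  z[, const] <- 0
  attr(z, "center") <- ctr
  attr(z, "scale") <- scl
  z
}

#' Hierarchical clustergram of cells
#'
#' Agglomerative clustering (Euclidean metric, Ward linkage) of the
#' standardized feature matrix, cut into `n_clusters` groups.  Cluster
#' labels are canonical — renumbered by the smallest row index they contain
#' — so the partition is invariant to input row order.
#'
#' @param mat standardized matrix from [zscore_features()].
#' @param n_clusters number of clusters (>= 2); default 6.
#' @return A list of class `cluster_assignment`: `cluster` (integer per
#'   cell), `tree` (the `hclust` object), `order` (dendrogram leaf order),
#'   `n_clusters`, `height` (cut heights of the merge tree).
#' @export
hierarchical_clustergram <- function(mat, n_clusters = 6) {
  if (n_clusters < 2) stop("n_clusters must be >= 2", call. = FALSE)
  if (n_clusters > nrow(mat))
    stop("n_clusters exceeds the number of cells", call. = FALSE)
  tree <- hclust(dist(mat, method = "euclidean"), method = "ward.D2")
  cl <- cutree(tree, k = n_clusters)
  cl <- canonical_clusters(cl)
  structure(list(cluster = cl, tree = tree, order = tree$order,
                 n_clusters = n_clusters, height = tree$height),
            class = "cluster_assignment")
}

canonical_clusters <- function(cl) {
  first <- vapply(split(seq_along(cl), cl), min, numeric(1))
  as.integer(match(cl, as.integer(names(sort(first)))))
}

#' Select the top/bottom quantile of cells on one feature
#'
#' Picks the `ceiling(q * N)` cells with highest (`direction = "top"`) or
#' lowest (`"bottom"`) value of the feature; ties at the cut break by
#' ascending `cell_id`.  The selection depends only on the feature's order,
#' so any monotone transform of the feature leaves it unchanged.
#'
#' @param table a `cell_feature_table`.
#' @param feature feature column name.
#' @param q fraction in (0, 1); the study convention is the top 10 percent
#'   (`q = 0.1`).
#' @param direction `"top"` or `"bottom"`.
#' @return Integer vector of selected `cell_id`s (named by `tip_id` when
#'   present).
#' @export
select_quantile <- function(table, feature, q = 0.1, direction = "top") {
  direction <- match.arg(direction, c("top", "bottom"))
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)", call. = FALSE)
  if (nrow(table) == 0) stop("empty table", call. = FALSE)
  v <- table[[feature]]
  if (is.null(v)) stop("unknown feature: ", feature, call. = FALSE)
  k <- ceiling(q * nrow(table))
  ord <- if (direction == "top") order(-v, table$cell_id)
         else order(v, table$cell_id)
  sel <- ord[seq_len(k)]
  out <- table$cell_id[sel]
  if (!is.null(table$tip_id)) names(out) <- table$tip_id[sel]
  out
}

#' Map selected cells back into the source volume
#'
#' Keeps exactly the voxels of the selected labels (original label values
#' retained) and zeroes everything else — the spatial back-mapping used to
#' see where cells of a cluster or quantile live in the tissue.
#'
#' @param labels a [label_volume()].
#' @param ids integer label ids to keep (may be empty).
#' @return A [label_volume()] mask.
#' @export
backmap <- function(labels, ids) {
  stopifnot(inherits(labels, "label_volume"))
  ids <- unique(as.integer(ids))
  present <- sort(unique(labels[labels > 0L]))
  missing <- setdiff(ids, present)
  if (length(missing))
    stop("unknown label id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- unclass_vol(labels)
  out[!(out %in% ids)] <- 0L
  label_volume(out, voxel_size(labels))
}

#' Cluster proportions per tip and per stage
#'
#' Percentage of each tip's cells falling in each cluster, plus per-stage
#' values as unweighted means over that stage's tips.
#'
#' @param assignment a `cluster_assignment` aligned with `table` rows.
#' @param table the `cell_feature_table` that was clustered.
#' @return List with `per_tip` (tip_id, stage, cluster, n, pct) and
#'   `per_stage` (stage, cluster, pct) data.frames; per-tip percentages sum
#'   to 100.
#' @export
cluster_proportions <- function(assignment, table) {
  cl <- assignment$cluster
  if (length(cl) != nrow(table))
    stop("assignment does not cover the table", call. = FALSE)
  tips <- unique(table$tip_id)
  ks <- seq_len(assignment$n_clusters)
  per_tip <- do.call(rbind, lapply(tips, function(tp) {
    idx <- table$tip_id == tp
    n <- vapply(ks, function(k) sum(cl[idx] == k), numeric(1))
    data.frame(tip_id = tp,
               stage = if (!is.null(table$stage)) table$stage[idx][1]
                       else NA_character_,
               cluster = ks, n = n, pct = 100 * n / sum(idx))
  }))
  per_stage <- aggregate(pct ~ stage + cluster, data = per_tip, FUN = mean)
  per_stage <- per_stage[order(per_stage$stage, per_stage$cluster), ]
  rownames(per_stage) <- NULL
  list(per_tip = per_tip, per_stage = per_stage)
}
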