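# 3D cell reconstruction from membrane probability maps:
# gap closing -> distance-transform markers -> marker-controlled watershed
# -> physical-volume gate.  All morphology and distances are computed in
# physical micrometres with anisotropy-corrected structuring elements; the
# volume is never resampled.

#' Close gaps in a membrane probability map
#'
#' Grayscale morphological closing with an anisotropy-corrected ellipsoidal
#' structuring element of the given physical radius.  Restores membrane
#' signal across staining dropouts smaller than the element.  The closing is
#' extensive: the output is pointwise `>=` the input.
#'
#' @param prob a [prob_volume()].
#' @param radius physical radius (um) of the structuring element; must
#'   resolve to at least one voxel along every axis, otherwise the input is
#'   returned unchanged with a warning.
#' @return A [prob_volume()].
#' @export
close_membrane_gaps <- function(prob, radius) {
  stopifnot(inherits(prob, "prob_volume"))
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  if (radius == 0) return(prob)
  vs <- voxel_size(prob)
  if (any(floor(radius / vs) < 1)) {
    warning("closing radius smaller than one voxel along some axis; no-op")
    return(prob)
  }
  off <- se_offsets(radius, vs)
  dims <- dim(prob)
  v <- as.numeric(prob)
  dil <- cpp_gray_filter(v, dims, off, maximum = TRUE)
  ero <- cpp_gray_filter(dil, dims, off, maximum = FALSE)
  dim(ero) <- dims
  prob_volume(pmax(ero, unclass_vol(prob)), vs)
}

#' Seed watershed markers from the interior distance transform
#'
#' Thresholds the probability map to an interior mask (`prob < threshold`),
#' computes its exact anisotropic Euclidean distance transform in physical
#' units, and extracts the h-maxima of the distance map (regional maxima
#' after suppressing relief shallower than `h`) as 26-connected marker
#' components.  Marker components that touch the volume border are merged
#' into a single marker, so the tissue exterior floods as one basin and is
#' removed later by the volume gate.
#'
#' @param prob a [prob_volume()].
#' @param threshold interior threshold in (0, 1).
#' @param h minimum relief (um) separating two markers; default 1 um.
#' @param merge_border merge border-touching markers into one (default).
#' @return A [label_volume()] of markers.
#' @export
seed_markers <- function(prob, threshold = 0.5, h = 1.0,
                         merge_border = TRUE) {
  stopifnot(inherits(prob, "prob_volume"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  if (h < 0) stop("h must be >= 0", call. = FALSE)
  vs <- voxel_size(prob)
  dims <- dim(prob)
  interior <- unclass_vol(prob) < threshold
  if (!any(interior))
    stop("no interior voxels below threshold; cannot seed markers",
         call. = FALSE)
  edt <- sqrt(cpp_edt_sq(as.logical(interior), dims, vs))
  dmax <- max(edt)
  if (h >= dmax)
    stop(sprintf(paste0("h (%.3g um) exceeds the maximal interior distance ",
                        "(%.3g um); no markers"), h, dmax), call. = FALSE)
  hmax <- cpp_grayrec(edt - h, edt, dims)
  eps <- 1e-7 * max(1, dmax)
  rmax <- (hmax - cpp_grayrec(hmax - eps, hmax, dims)) > eps / 2
  markers <- cpp_label26(as.logical(rmax & interior), dims)
  dim(markers) <- dims
  if (merge_border) {
    border <- unique(c(markers[c(1, dims[1]), , ], markers[, c(1, dims[2]), ],
                       markers[, , c(1, dims[3])]))
    border <- border[border > 0]
    if (length(border) > 1)
      markers[markers %in% border] <- min(border)
  }
  # renumber consecutively
  ids <- sort(unique(markers[markers > 0]))
  if (length(ids) && !identical(ids, seq_along(ids)))
    markers[markers > 0] <- match(markers[markers > 0], ids)
  label_volume(markers, vs)
}

#' Marker-controlled watershed on a probability relief
#'
#' Floods the membrane probability map from the markers (Meyer's algorithm,
#' 26-connectivity).  Each marker grows into one label; voxels where two
#' basins meet become watershed lines and stay at label 0, so per-cell
#' moments are never biased by shared boundary voxels.
#'
#' @param prob a [prob_volume()] (the relief).
#' @param markers a [label_volume()] of seeds on the same grid.
#' @return A [label_volume()].
#' @export
watershed_cells <- function(prob, markers) {
  stopifnot(inherits(prob, "prob_volume"), inherits(markers, "label_volume"))
  check_same_grid(prob, markers)
  if (!any(markers > 0)) stop("markers are empty", call. = FALSE)
  out <- cpp_watershed(as.numeric(prob), as.integer(markers), dim(prob))
  dim(out) <- dim(prob)
  label_volume(out, voxel_size(prob))
}

#' Gate labels by physical volume
#'
#' Removes labels whose physical volume lies outside `[vmin, vmax]` (closed
#' interval) and renumbers the survivors consecutively from 1 in order of
#' decreasing volume.  Voxel sets of surviving labels are untouched.
#'
#' @param labels a [label_volume()].
#' @param vmin,vmax volume bounds in um^3 (`0 <= vmin < vmax`).
#' @return A [label_volume()].
#' @export
filter_labels <- function(labels, vmin = 50, vmax = 500) {
  stopifnot(inherits(labels, "label_volume"))
  if (vmin < 0 || vmin >= vmax)
    stop("need 0 <= vmin < vmax", call. = FALSE)
  counts <- label_counts(labels)
  vols <- counts * voxel_volume(labels)
  keep <- which(counts > 0 & vols >= vmin & vols <= vmax)
  out <- unclass_vol(labels)
  if (length(keep) == 0) {
    out[] <- 0L
    return(label_volume(out, voxel_size(labels)))
  }
  keep <- keep[order(-vols[keep], keep)]
  remap <- integer(max(labels))
  remap[keep] <- seq_along(keep)
  pos <- out > 0L
  out[pos] <- remap[out[pos]]
  label_volume(out, voxel_size(labels))
}

#' Segmentation configuration
#'
#' @param radius gap-closing radius (um).
#' @param threshold interior probability threshold.
#' @param h marker relief (um).
#' @param vmin,vmax cell volume gate (um^3); the default 50-500 um^3 window
#'   spans the plausible epithelial cell range and removes lumen and
#'   exterior basins.
#' @return A named list.
#' @export
segment_config <- function(radius = 0.6, threshold = 0.5, h = 1.0,
                           vmin = 50, vmax = 500) {
  list(radius = radius, threshold = threshold, h = h, vmin = vmin,
       vmax = vmax)
}

#' Full segmentation pipeline
#'
#' `close_membrane_gaps()` -> `seed_markers()` -> `watershed_cells()` ->
#' `filter_labels()`, with parameters from a [segment_config()].  Fully
#' deterministic.
#'
#' @param prob a [prob_volume()].
#' @param config a [segment_config()].
#' @return A [label_volume()].
#' @examples
#' tt <- generate_tip_tissue(tissue_spec("trunk", n_cells = 2, seed = 3))
#' seg <- segment_pipeline(tt$prob, segment_config(vmin = 10, vmax = 1000))
#' @export
segment_pipeline <- function(prob, config = segment_config()) {
  closed <- close_membrane_gaps(prob, config$radius)
  markers <- seed_markers(closed, config$threshold, config$h)
  ws <- watershed_cells(closed, markers)
  filter_labels(ws, config$vmin, config$vmax)
}

unclass_vol <- function(v) {
  out <- unclass(v)
  attr(out, "voxel_size") <- NULL
  out
}

#' Match segmented labels to ground-truth labels by voxel overlap
#'
#' Greedy one-to-one matching on intersection-over-union; used for
#' segmentation quality scores against the generator truth.
#'
#' @param seg,truth [label_volume()] objects on the same grid.
#' @param iou_min minimal IoU for a valid match.
#' @return List with `matches` (data.frame truth_id, seg_id, iou),
#'   `precision`, `recall`, `f1`.
#' @export
match_labels <- function(seg, truth, iou_min = 0.5) {
  check_same_grid(seg, truth)
  s <- as.integer(seg)
  t <- as.integer(truth)
  both <- s > 0L & t > 0L
  ns <- max(s)
  nt <- max(t)
  if (ns == 0 || nt == 0)
    return(list(matches = data.frame(truth_id = integer(), seg_id = integer(),
                                     iou = numeric()),
                precision = 0, recall = 0, f1 = 0))
  inter <- table(factor(t[both], levels = seq_len(nt)),
                 factor(s[both], levels = seq_len(ns)))
  cs <- tabulate(s[s > 0L], ns)
  ct <- tabulate(t[t > 0L], nt)
  iou <- as.matrix(inter) / (outer(ct, cs, "+") - as.matrix(inter))
  matches <- data.frame(truth_id = integer(), seg_id = integer(),
                        iou = numeric())
  used_s <- logical(ns)
  used_t <- logical(nt)
  ord <- order(-iou)
  for (k in ord) {
    if (iou[k] < iou_min) break
    i <- (k - 1) %% nt + 1
    j <- (k - 1) %/% nt + 1
    if (used_t[i] || used_s[j]) next
    used_t[i] <- TRUE
    used_s[j] <- TRUE
    matches <- rbind(matches, data.frame(truth_id = i, seg_id = j,
                                         iou = iou[k]))
  }
  tp <- nrow(matches)
  precision <- tp / ns
  recall <- tp / nt
  f1 <- if (tp == 0) 0 else 2 * precision * recall / (precision + recall)
  list(matches = matches, precision = precision, recall = recall, f1 = f1)
}
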