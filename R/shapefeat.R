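# Per-cell geometric parameters from a label volume.
#
# Axes use the solid-ellipsoid second-moment convention: the covariance of
# voxel-centre coordinates of a solid ellipsoid with semi-axes (a, b, c) has
# eigenvalues (a^2, b^2, c^2) / 5, so a digitized ellipsoid reports its true
# full diameters via length_i = 2 * sqrt(5 * lambda_i).

#' Principal axes of a voxel mask
#'
#' Eigen-decomposes the physical-coordinate covariance of the voxel centres
#' and reports full axis lengths `2 * sqrt(5 * lambda)` in descending order,
#' so a digitized solid ellipsoid with semi-axes (a, b, c) um reports
#' (2a, 2b, 2c) um.
#'
#' @param mask logical 3D array (one cell).
#' @param voxel_size `(z, y, x)` voxel edges (um).
#' @return Numeric length-3 `(longest, intermediate, minor)` um, with
#'   attribute `degenerate = TRUE` when the mask was too flat to support a
#'   third axis (the axis is then floored at one voxel extent).
#' @export
principal_axes <- function(mask, voxel_size) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  voxel_size <- check_voxel_size(voxel_size)
  st <- cpp_label_stats(array(as.integer(mask), dim(mask)), dim(mask),
                        voxel_size, c(0, 0, 0))
  axes_from_cov(st$cov[1, ], voxel_size)
}

axes_from_cov <- function(cov6, voxel_size) {
  C <- matrix(c(cov6[1], cov6[4], cov6[5],
                cov6[4], cov6[2], cov6[6],
                cov6[5], cov6[6], cov6[3]), 3, 3)
  lam <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
  degenerate <- any(lam <= 0)
  lam <- pmax(lam, 0)
  axes <- 2 * sqrt(5 * lam)
  floor_axis <- min(voxel_size)
  if (any(axes < floor_axis)) {
    degenerate <- TRUE
    axes <- pmax(axes, floor_axis)
  }
  structure(axes, degenerate = degenerate)
}

#' Elongation of a cell
#'
#' Longest axis divided by the mean of the intermediate and minor axes.
#' Equals 1 for a sphere and grows without bound for rods.
#'
#' @param L,I,M longest, intermediate, minor full axis lengths (um),
#'   `L >= I >= M > 0`.  Vectorized.
#' @return Dimensionless elongation `>= 1`.
#' @examples
#' elongation(6, 4, 2) # 2
#' @export
elongation <- function(L, I, M) {
  if (any(M <= 0) || any(L < I - 1e-9) || any(I < M - 1e-9))
    stop("axis ordering violated: need L >= I >= M > 0", call. = FALSE)
  L / ((I + M) / 2)
}

#' Ellipticity of a cell
#'
#' Flattening-style ratio `1 - minor / longest`: 0 for a sphere,
#' approaching 1 for extremely flat or elongated cells.
#'
#' @param L,M longest and minor full axis lengths (um), `L >= M > 0`.
#' @return Dimensionless value in `[0, 1)`.
#' @export
ellipticity <- function(L, M) {
  if (any(M <= 0) || any(L < M - 1e-9))
    stop("need L >= M > 0", call. = FALSE)
  1 - M / L
}

#' Surface area of a voxel mask
#'
#' Triangulates the mask boundary (marching tetrahedra on a lightly
#' smoothed indicator, iso-level 0.5) in physical coordinates and sums the
#' triangle areas.  The smoothing suppresses voxelization staircase bias;
#' its scale is tied to the voxel size, not to the object.
#'
#' @param mask logical 3D array.
#' @param voxel_size `(z, y, x)` voxel edges (um).
#' @return Surface area in um^2.
#' @examples
#' # sphere of radius 3 um: 4*pi*9 = 113.1 um^2
#' @export
surface_area <- function(mask, voxel_size) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  voxel_size <- check_voxel_size(voxel_size)
  dims <- dim(mask)
  # pad so the surface never touches the array border
  pd <- array(0, dims + 4L)
  pd[2 + seq_len(dims[1]), 2 + seq_len(dims[2]), 2 + seq_len(dims[3])] <-
    as.numeric(mask)
  sigma_phys <- 0.7 * max(voxel_size)
  sm <- cpp_gauss3d(pd, dim(pd), sigma_phys / voxel_size)
  cpp_mt_area(sm, dim(pd), voxel_size, 0.5)
}

#' Roundness of a cell
#'
#' `3 * volume / area` in micrometres: equals the radius for a perfect
#' sphere and is strictly smaller for any other shape of equal volume
#' (spheres minimise area at fixed volume).
#'
#' @param volume cell volume (um^3).
#' @param area cell surface area (um^2).
#' @return Roundness in um.  Vectorized.
#' @export
roundness <- function(volume, area) {
  if (any(volume <= 0) || any(area <= 0))
    stop("volume and area must be > 0", call. = FALSE)
  3 * volume / area
}

#' Compute the per-cell feature table
#'
#' One record per label with the seven geometric parameters (volume,
#' roundness, elongation, ellipticity, longest/intermediate/minor axis) plus
#' centroid and metadata.  Degenerate labels (too few or coplanar voxels)
#' are flagged in the `degenerate` column, never dropped.
#'
#' @param labels a [label_volume()].
#' @param tip_id identifier of the source tip.
#' @param stage branch-cycle stage label (or `NA`).
#' @return A `cell_feature_table` (data.frame) with provenance attributes
#'   (`source`, `config_hash`).
#' @examples
#' tt <- generate_tip_tissue(tissue_spec("trunk", n_cells = 2, seed = 3))
#' ft <- compute_features(tt$truth$labels, tip_id = "demo", stage = "trunk")
#' ft[, c("cell_id", "volume", "elongation")]
#' @export
compute_features <- function(labels, tip_id = "tip", stage = NA_character_) {
  stopifnot(inherits(labels, "label_volume"))
  vs <- voxel_size(labels)
  dims <- dim(labels)
  if (!any(labels > 0)) stop("label volume is empty", call. = FALSE)
  st <- cpp_label_stats(as.integer(labels), dims, vs, c(0, 0, 0))
  K <- length(st$count)
  arr <- unclass_vol(labels)
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    n <- st$count[k]
    if (n == 0) next
    ax <- axes_from_cov(st$cov[k, ], vs)
    vol <- n * prod(vs)
    bb <- st$bbox[k, ] + 1L
    sub <- arr[bb[1]:bb[2], bb[3]:bb[4], bb[5]:bb[6], drop = FALSE]
    area <- surface_area(array(sub == k, dim(sub)), vs)
    rows[[k]] <- data.frame(
      cell_id = k, tip_id = tip_id, stage = stage,
      volume = vol, roundness = roundness(vol, area),
      elongation = elongation(ax[1], ax[2], ax[3]),
      ellipticity = ellipticity(ax[1], ax[3]),
      longest_axis = ax[1], intermediate_axis = ax[2], minor_axis = ax[3],
      centroid_z = st$centroid[k, 1], centroid_y = st$centroid[k, 2],
      centroid_x = st$centroid[k, 3],
      degenerate = isTRUE(attr(ax, "degenerate")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cell_feature_table", "data.frame")
  attr(out, "provenance") <- list(
    source = tip_id,
    voxel_size = vs,
    config_hash = digest::digest(list(vs, dims)))
  out
}

#' The seven geometric parameter names
#' @return Character vector of feature column names.
#' @export
feature_names <- function() {
  c("volume", "roundness", "elongation", "ellipticity", "longest_axis",
    "intermediate_axis", "minor_axis")
}

#' @export
print.cell_feature_table <- function(x, ...) {
  cat(sprintf("<cell_feature_table> %d cells, %d tips\n", nrow(x),
              length(unique(x$tip_id))))
  NextMethod()
}

# rbind keeping the class
#' Concatenate feature tables from several tips
#' @param ... `cell_feature_table` objects.
#' @return A combined `cell_feature_table`.
#' @export
bind_feature_tables <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("cell_feature_table", "data.frame")
  out
}
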