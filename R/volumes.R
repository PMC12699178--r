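#' Volume containers
#'
#' Light S3 containers for 3D grids.  A `prob_volume` holds membrane
#' probabilities in `[0, 1]`; a `label_volume` holds non-negative integer
#' cell labels (0 = background / membrane / watershed line).  Both carry
#' their physical voxel size as a `(z, y, x)` vector in micrometres, and all
#' downstream computations work in physical units; volumes are never
#' resampled to isotropy.
#'
#' @param values 3D numeric array, dim `(nz, ny, nx)`, values in `[0, 1]`.
#' @param labels 3D integer array, dim `(nz, ny, nx)`, values `>= 0`.
#' @param voxel_size numeric length-3, `(z, y, x)` voxel edge lengths (um),
#'   all positive.
#' @return An object of class `prob_volume` or `label_volume`: the array
#'   with a `voxel_size` attribute.
#' @examples
#' v <- prob_volume(array(0, c(4, 4, 4)), voxel_size = c(0.333, 0.2, 0.2))
#' voxel_size(v)
#' @export
prob_volume <- function(values, voxel_size) {
  values <- check_grid3d(values, "values")
  voxel_size <- check_voxel_size(voxel_size)
  rng <- range(values)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("probability values must lie in [0, 1]", call. = FALSE)
  values[] <- pmin(pmax(values, 0), 1)
  structure(values, voxel_size = voxel_size,
            class = c("prob_volume", "ubm_volume"))
}

#' @rdname prob_volume
#' @export
label_volume <- function(labels, voxel_size) {
  labels <- check_grid3d(labels, "labels")
  voxel_size <- check_voxel_size(voxel_size)
  if (min(labels) < 0) stop("labels must be >= 0", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(labels, voxel_size = voxel_size,
            class = c("label_volume", "ubm_volume"))
}

#' @param x a volume object.
#' @rdname prob_volume
#' @export
voxel_size <- function(x) attr(x, "voxel_size")

#' @rdname prob_volume
#' @export
voxel_volume <- function(x) prod(attr(x, "voxel_size"))

#' @export
print.ubm_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<%s> %d x %d x %d voxels (z, y, x), voxel %s um\n",
              class(x)[1], d[1], d[2], d[3],
              paste(signif(voxel_size(x), 4), collapse = " x ")))
  invisible(x)
}

check_grid3d <- function(a, what) {
  if (!is.array(a) || length(dim(a)) != 3L)
    stop(what, " must be a 3D array", call. = FALSE)
  if (any(dim(a) < 3L))
    stop(what, " must have at least 3 voxels along every axis",
         call. = FALSE)
  a
}

check_voxel_size <- function(vs) {
  vs <- as.numeric(vs)
  if (length(vs) != 3L || any(!is.finite(vs)) || any(vs <= 0))
    stop("voxel_size must be 3 positive numbers (z, y, x)", call. = FALSE)
  vs
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("grids have different dimensions: ",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  if (max(abs(voxel_size(a) - voxel_size(b))) > 1e-9)
    stop("grids have different voxel sizes", call. = FALSE)
  invisible(TRUE)
}

# number of labelled voxels per label id 1..K
label_counts <- function(labels) {
  tabulate(labels[labels > 0L], nbins = max(labels, 0L))
}
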