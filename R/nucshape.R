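# 2D nuclear-contour morphometrics: the classic shape-descriptor panel
# (area, perimeter, circularity, aspect ratio, roundness, solidity) computed
# analytically from the polygon, for quantifying nuclear-envelope wrinkling.

#' Closed planar contour
#'
#' An ordered, closed, simple polygon in micrometres.  Orientation is
#' canonicalized to counter-clockwise (positive signed area).
#'
#' @param x,y vertex coordinates (um), at least 3 vertices, not repeated at
#'   the end.
#' @param id optional sample identifier.
#' @param group optional cohort label (e.g. a genotype).
#' @param check_simple run the O(n^2) self-intersection check (skip for
#'   contours that are simple by construction).
#' @return A `contour_2d` data.frame with attributes `id`, `group`.
#' @export
contour_2d <- function(x, y, id = NULL, group = NULL, check_simple = TRUE) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need at least 3 (x, y) vertices", call. = FALSE)
  if (x[1] == x[length(x)] && y[1] == y[length(y)]) {
    x <- x[-length(x)]
    y <- y[-length(y)]
  }
  if (check_simple && !polygon_is_simple(x, y))
    stop("contour is self-intersecting", call. = FALSE)
  if (polygon_signed_area(x, y) < 0) {
    x <- rev(x)
    y <- rev(y)
  }
  structure(data.frame(x = x, y = y), id = id, group = group,
            class = c("contour_2d", "data.frame"))
}

polygon_signed_area <- function(x, y) {
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_perimeter <- function(x, y) {
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(sqrt((xn - x)^2 + (yn - y)^2))
}

# segment-pair intersection scan; vectorized over the second segment
polygon_is_simple <- function(x, y) {
  n <- length(x)
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  for (i in seq_len(n - 2)) {
    j <- (i + 2):n
    if (i == 1) j <- j[j != n] # first and last segments are adjacent
    if (!length(j)) next
    d1 <- (xn[i] - x[i]) * (y[j] - y[i]) - (yn[i] - y[i]) * (x[j] - x[i])
    d2 <- (xn[i] - x[i]) * (yn[j] - y[i]) - (yn[i] - y[i]) * (xn[j] - x[i])
    d3 <- (xn[j] - x[j]) * (y[i] - y[j]) - (yn[j] - y[j]) * (x[i] - x[j])
    d4 <- (xn[j] - x[j]) * (yn[i] - y[j]) - (yn[j] - y[j]) * (xn[i] - x[j])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

# central second moments of the filled polygon (Green's theorem)
polygon_moments <- function(x, y) {
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  a <- x * yn - xn * y
  A <- sum(a) / 2
  cx <- sum((x + xn) * a) / (6 * A)
  cy <- sum((y + yn) * a) / (6 * A)
  x0 <- x - cx; x1 <- xn - cx
  y0 <- y - cy; y1 <- yn - cy
  a <- x0 * y1 - x1 * y0
  Ixx <- sum(a * (x0^2 + x0 * x1 + x1^2)) / 12
  Iyy <- sum(a * (y0^2 + y0 * y1 + y1^2)) / 12
  Ixy <- sum(a * (2 * x0 * y0 + x0 * y1 + x1 * y0 + 2 * x1 * y1)) / 24
  list(area = A, centroid = c(cx, cy),
       cov = matrix(c(Ixx, Ixy, Ixy, Iyy), 2, 2) / A)
}

#' Shape descriptors of a nuclear contour
#'
#' The standard shape-descriptor panel: area (shoelace), perimeter,
#' circularity `4 pi A / P^2`, fitted-ellipse major/minor axes from the
#' second moments of the filled polygon (for an ellipse the covariance
#' eigenvalues are `(semi-axis)^2 / 4`), aspect ratio `major / minor`,
#' roundness `4 A / (pi major^2)` and solidity `A / hull area` (convex hull
#' of the vertices — adequate for densely sampled contours).  Solidity < 1
#' signals boundary wrinkling.
#'
#' @param contour a [contour_2d()].
#' @return data.frame with one row: `area`, `perimeter`, `circularity`,
#'   `major`, `minor`, `aspect_ratio`, `roundness`, `solidity`.
#' @examples
#' hexagon <- contour_2d(cos(2 * pi * 0:5 / 6), sin(2 * pi * 0:5 / 6))
#' contour_metrics(hexagon)$circularity # pi * sqrt(3) / 6
#' @export
contour_metrics <- function(contour) {
  stopifnot(inherits(contour, "contour_2d"))
  x <- contour$x
  y <- contour$y
  m <- polygon_moments(x, y)
  A <- abs(m$area)
  P <- polygon_perimeter(x, y)
  lam <- sort(eigen(m$cov, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
  lam <- pmax(lam, 0)
  major <- 4 * sqrt(lam[1])
  minor <- 4 * sqrt(lam[2])
  hull <- chull(x, y)
  hull_area <- abs(polygon_signed_area(x[hull], y[hull]))
  data.frame(area = A, perimeter = P, circularity = 4 * pi * A / P^2,
             major = major, minor = minor, aspect_ratio = major / minor,
             roundness = 4 * A / (pi * major^2),
             solidity = A / hull_area)
}

#' Compare nuclear wrinkling between two cohorts
#'
#' Welch's two-tailed t-test (unequal variances) per shape descriptor
#' between two groups of contours.  Degenerate pairs (zero variance in both
#' groups) report p = 1 when the means agree, 0 otherwise.
#'
#' @param group_a,group_b lists of [contour_2d()] (>= 2 contours each).
#' @param metrics descriptor columns to compare.
#' @return data.frame: metric, mean_a, mean_b, statistic, p_value.
#' @export
wrinkling_compare <- function(group_a, group_b,
                              metrics = c("circularity", "solidity", "area",
                                          "aspect_ratio", "perimeter",
                                          "roundness")) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("need at least 2 contours per group", call. = FALSE)
  ma <- do.call(rbind, lapply(group_a, contour_metrics))
  mb <- do.call(rbind, lapply(group_b, contour_metrics))
  out <- lapply(metrics, function(mt) {
    a <- ma[[mt]]
    b <- mb[[mt]]
    if (var(a) + var(b) < 1e-24) {
      p <- if (abs(mean(a) - mean(b)) < 1e-12) 1 else 0
      stat <- 0
    } else {
      tt <- t.test(a, b, var.equal = FALSE)
      p <- tt$p.value
      stat <- unname(tt$statistic)
    }
    data.frame(metric = mt, mean_a = mean(a), mean_b = mean(b),
               statistic = stat, p_value = p)
  })
  do.call(rbind, out)
}
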