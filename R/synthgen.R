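# Synthetic tip-tissue generator with exact per-cell ground truth.
#
# Cells are digitized ellipsoids seeded on the surface of a stage-specific
# lumen (sphere, two-sphere union, or capsule), long axis along the surface
# normal (columnar epithelium), with Poisson-disc spacing so neighbours stay
# separated by roughly one membrane thickness.  The membrane probability map
# is a smoothed indicator of the inter-cell gap plus any touching-label
# interfaces, which is what a pixel classifier trained on membrane staining
# would emit.

#' Stage-specific generator defaults
#'
#' Lumen geometry and per-stage semi-axis distributions for the five
#' epithelial compartments of the branch cycle.  Semi-axis log-normal
#' medians are calibrated to published stage-mean principal axis lengths of
#' ureteric-bud cells (half the full axis length); the dispersion is a free
#' parameter of the generator, kept modest (sdlog 0.08) so synthetic cohorts
#' emphasise the stage-to-stage shape shifts.
#'
#' @param stage one of `"initial_bud"`, `"ampulla"`, `"asymmetric_ampulla"`,
#'   `"t_bud"`, `"trunk"`.
#' @return A list with elements `lumen` (list of geometric primitives) and
#'   `axis_distribution` (list with `meanlog` (length 3) and `sdlog`).
#' @export
stage_defaults <- function(stage) {
  stage <- match.arg(stage, ubm_stages())
  # semi-axis medians: stage-mean axis RATIOS with the overall scale set so
  # the ellipsoid volume matches the stage-mean cell volume (real cells are
  # space-filling polyhedra, so published axis means and volume means are
  # not simultaneously attainable by a true ellipsoid; the ratios carry the
  # stage signal)
  semi <- switch(stage,
    initial_bud         = c(4.140, 2.652, 1.740),
    ampulla             = c(5.013, 2.727, 1.758),
    asymmetric_ampulla  = c(5.091, 2.432, 1.756),
    t_bud               = c(4.902, 2.642, 1.855),
    trunk               = c(5.289, 3.408, 2.395))
  lumen <- switch(stage,
    initial_bud = list(sphere(c(0, 0, 0), 10)),
    ampulla = list(sphere(c(0, 0, 0), 13.5)),
    # two merged lobes of unequal radius (asymmetry ratio ~0.64)
    asymmetric_ampulla = list(sphere(c(0, 0, 0), 11),
                              sphere(c(0, 0, 13), 7)),
    # two separate lobes flanking the (unrendered) parent trunk
    t_bud = list(sphere(c(0, 0, -14), 11), sphere(c(0, 0, 14), 11)),
    trunk = list(capsule(c(0, 0, -12), c(0, 0, 12), 9)))
  list(lumen = lumen,
       axis_distribution = list(meanlog = log(semi), sdlog = 0.08))
}

ubm_stages <- function() {
  c("initial_bud", "ampulla", "asymmetric_ampulla", "t_bud", "trunk")
}

#' Lumen primitives
#'
#' @param center,p1,p2 physical points `(z, y, x)` in um.
#' @param r radius in um.
#' @name lumen-primitives
#' @export
sphere <- function(center, r) {
  stopifnot(length(center) == 3, r > 0)
  structure(list(center = as.numeric(center), r = r), class = "ubm_sphere")
}

#' @rdname lumen-primitives
#' @export
capsule <- function(p1, p2, r) {
  stopifnot(length(p1) == 3, length(p2) == 3, r > 0)
  structure(list(p1 = as.numeric(p1), p2 = as.numeric(p2), r = r),
            class = "ubm_capsule")
}

prim_sdf <- function(prim, pts) {
  # pts: n x 3 matrix (z, y, x)
  if (inherits(prim, "ubm_sphere")) {
    sqrt(rowSums(sweep(pts, 2, prim$center)^2)) - prim$r
  } else {
    ax <- prim$p2 - prim$p1
    len2 <- sum(ax^2)
    rel <- sweep(pts, 2, prim$p1)
    t <- pmin(pmax((rel %*% ax) / len2, 0), 1)
    d <- rel - outer(as.vector(t), ax)
    sqrt(rowSums(d^2)) - prim$r
  }
}

lumen_sdf <- function(lumen, pts) {
  do.call(pmin, lapply(lumen, prim_sdf, pts = pts))
}

prim_area <- function(prim) {
  if (inherits(prim, "ubm_sphere")) 4 * pi * prim$r^2
  else 2 * pi * prim$r * sqrt(sum((prim$p2 - prim$p1)^2)) + 4 * pi * prim$r^2
}

prim_sample_surface <- function(prim, n) {
  if (inherits(prim, "ubm_sphere")) {
    u <- matrix(rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    list(pts = sweep(u * prim$r, 2, prim$center, "+"), normals = u)
  } else {
    ax <- prim$p2 - prim$p1
    len <- sqrt(sum(ax^2))
    axu <- ax / len
    a_cyl <- 2 * pi * prim$r * len
    a_cap <- 4 * pi * prim$r^2
    on_cyl <- runif(n) < a_cyl / (a_cyl + a_cap)
    # orthonormal frame
    e1 <- if (abs(axu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * axu) * axu
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(axu[2] * e1[3] - axu[3] * e1[2],
            axu[3] * e1[1] - axu[1] * e1[3],
            axu[1] * e1[2] - axu[2] * e1[1])
    pts <- matrix(0, n, 3)
    nrm <- matrix(0, n, 3)
    ncy <- sum(on_cyl)
    if (ncy) {
      t <- runif(ncy)
      th <- runif(ncy, 0, 2 * pi)
      radial <- outer(cos(th), e1) + outer(sin(th), e2)
      pts[on_cyl, ] <- sweep(outer(t, ax) + prim$r * radial, 2, prim$p1, "+")
      nrm[on_cyl, ] <- radial
    }
    nca <- n - ncy
    if (nca) {
      u <- matrix(rnorm(3 * nca), nca, 3)
      u <- u / sqrt(rowSums(u^2))
      at_p2 <- (u %*% axu) > 0
      ctr <- ifelse(matrix(rep(at_p2, 3), nca, 3),
                    matrix(rep(prim$p2, each = nca), nca, 3),
                    matrix(rep(prim$p1, each = nca), nca, 3))
      pts[!on_cyl, ] <- ctr + u * prim$r
      nrm[!on_cyl, ] <- u
    }
    list(pts = pts, normals = nrm)
  }
}

#' Specification of a synthetic epithelial tip tissue
#'
#' Bundles everything [generate_tip_tissue()] needs: branch-cycle stage,
#' lumen geometry, number of cells, per-cell semi-axis distribution, voxel
#' anisotropy, membrane thickness and the random seed.  Defaults come from
#' [stage_defaults()]; any component can be overridden.
#'
#' @param stage branch-cycle stage (see [stage_defaults()]).
#' @param n_cells number of cells to place on the lumen surface.
#' @param lumen_params optional list of [sphere()] / [capsule()] primitives
#'   replacing the stage default lumen.
#' @param axis_distribution optional list `(meanlog, sdlog)` for the
#'   log-normal semi-axis draw; `sdlog = 0` gives identical cells with
#'   semi-axes `exp(meanlog)`.
#' @param voxel_size voxel edges `(z, y, x)` in um; default matches a
#'   0.333 um confocal z-step with 0.2 um lateral sampling.
#' @param membrane_thickness physical thickness (um) of the rendered
#'   membrane signal (also the target inter-cell gap).
#' @param pad clearance (um) between the outermost cell surface and the
#'   volume border.
#' @param seed integer seed; everything downstream is reproducible from it.
#' @return A `tissue_spec` object.
#' @examples
#' spec <- tissue_spec("ampulla", n_cells = 12, seed = 1)
#' @export
tissue_spec <- function(stage, n_cells = 20, lumen_params = NULL,
                        axis_distribution = NULL,
                        voxel_size = c(0.333, 0.2, 0.2),
                        membrane_thickness = 0.4, pad = 3, seed = 1) {
  stage <- match.arg(stage, ubm_stages())
  defs <- stage_defaults(stage)
  voxel_size <- check_voxel_size(voxel_size)
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (membrane_thickness <= 0) stop("membrane_thickness must be > 0",
                                    call. = FALSE)
  ad <- if (is.null(axis_distribution)) defs$axis_distribution
        else axis_distribution
  if (length(ad$meanlog) != 3 || ad$sdlog < 0)
    stop("axis_distribution needs meanlog (length 3) and sdlog >= 0",
         call. = FALSE)
  structure(list(stage = stage, n_cells = as.integer(n_cells),
                 lumen = if (is.null(lumen_params)) defs$lumen
                         else lumen_params,
                 axis_distribution = ad, voxel_size = voxel_size,
                 membrane_thickness = membrane_thickness, pad = pad,
                 seed = as.integer(seed)),
            class = "tissue_spec")
}

sample_cell_axes <- function(n, ad) {
  m <- matrix(rlnorm(3 * n, meanlog = rep(ad$meanlog, each = n),
                     sdlog = ad$sdlog), n, 3)
  t(apply(m, 1, sort, decreasing = TRUE))
}

# Greedy Poisson-disc placement on the lumen surface.  Cell i gets tangent
# clearance ~ its intermediate semi-axis; neighbours are kept one membrane
# thickness apart so the rendered membrane fills the gap.
place_cells <- function(spec, axes) {
  n <- spec$n_cells
  areas <- vapply(spec$lumen, prim_area, numeric(1))
  accepted_pts <- matrix(0, n, 3)
  accepted_nrm <- matrix(0, n, 3)
  n_acc <- 0L
  batch <- max(2000L, 200L * n)
  max_tries <- 30L
  for (try in seq_len(max_tries)) {
    per_prim <- pmax(1L, round(batch * areas / sum(areas)))
    cand <- lapply(seq_along(spec$lumen), function(i)
      prim_sample_surface(spec$lumen[[i]], per_prim[i]))
    pts <- do.call(rbind, lapply(cand, `[[`, "pts"))
    nrm <- do.call(rbind, lapply(cand, `[[`, "normals"))
    # reject points inside another lobe (union surface only)
    keep <- lumen_sdf(spec$lumen, pts) > -1e-6
    pts <- pts[keep, , drop = FALSE]
    nrm <- nrm[keep, , drop = FALSE]
    ord <- sample.int(nrow(pts))
    for (i in ord) {
      if (n_acc >= n) break
      b_new <- axes[n_acc + 1L, 2L]
      if (n_acc > 0) {
        d <- sqrt(rowSums(sweep(accepted_pts[seq_len(n_acc), , drop = FALSE],
                                2, pts[i, ])^2))
        dmin <- 0.98 * (axes[seq_len(n_acc), 2L] + b_new) +
          spec$membrane_thickness
        if (any(d < dmin)) next
      }
      n_acc <- n_acc + 1L
      accepted_pts[n_acc, ] <- pts[i, ]
      accepted_nrm[n_acc, ] <- nrm[i, ]
    }
    if (n_acc >= n) break
  }
  if (n_acc < n)
    stop(sprintf(paste0("packing failure: only %d of %d cells fit on the ",
                        "lumen surface without overlap"), n_acc, n),
         call. = FALSE)
  list(centers = accepted_pts, normals = accepted_nrm)
}

# rotation matrix whose columns are the world directions of the (a, b, c)
# axes: a radial (surface normal), b and c tangent
cell_orientation <- function(normal) {
  u <- rnorm(3)
  u <- u - sum(u * normal) * normal
  nu <- sqrt(sum(u^2))
  if (nu < 1e-8) {
    u <- c(normal[2], -normal[1], 0)
    nu <- sqrt(sum(u^2))
  }
  u <- u / nu
  w <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  cbind(normal, u, w)
}

#' Generate a synthetic tip tissue with known ground truth
#'
#' Places `spec$n_cells` ellipsoidal cells on the lumen surface of the
#' requested branch-cycle stage, digitizes them into a label volume, and
#' renders a membrane probability map (high between adjacent cells and on
#' free tissue surfaces, low inside cells).  Everything is reproducible from
#' `spec$seed`.
#'
#' @param spec a [tissue_spec()].
#' @return A list of class `tip_tissue`:
#'   \describe{
#'     \item{prob}{[prob_volume()] membrane probability map.}
#'     \item{truth}{list with `labels` ([label_volume()], one positive label
#'       per cell), `table` (per-cell truth: analytic ellipsoid volume,
#'       semi-axes, centre, long-axis direction, digitized voxel volume) and
#'       `lumen_mask` (logical array of the lumen interior).}
#'     \item{spec}{the input spec.}
#'   }
#' @examples
#' tt <- generate_tip_tissue(tissue_spec("trunk", n_cells = 2, seed = 3))
#' range(tt$prob)
#' @export
generate_tip_tissue <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  set.seed(spec$seed)
  axes <- sample_cell_axes(spec$n_cells, spec$axis_distribution)
  pl <- place_cells(spec, axes)
  rot <- t(vapply(seq_len(spec$n_cells), function(i)
    as.vector(cell_orientation(pl$normals[i, ])), numeric(9)))

  vs <- spec$voxel_size
  lo <- apply(pl$centers - axes[, 1], 2, min) - spec$pad
  hi <- apply(pl$centers + axes[, 1], 2, max) + spec$pad
  dims <- pmax(3L, as.integer(ceiling((hi - lo) / vs)) + 1L)
  origin <- lo

  lab <- cpp_raster_ellipsoids(dims, vs, origin, pl$centers, axes, rot)
  dim(lab) <- dims

  # membrane: a band of physical thickness `membrane_thickness` hugging the
  # outside of every cell (so the watershed crest falls mid-gap between
  # neighbours), plus any directly touching label interfaces
  inside <- lab > 0L
  d_out <- sqrt(cpp_edt_sq(as.logical(!inside), dims, vs))
  memb <- (!inside & d_out <= spec$membrane_thickness) |
    cpp_touch_boundary(lab, dims)
  sigma_phys <- 0.12
  prob <- cpp_gauss3d(memb + 0, dims, sigma_phys / vs)
  prob <- prob / max(prob)
  prob[prob > 1] <- 1
  dim(prob) <- dims

  # lumen interior mask (for lobe-structure checks)
  pts_x <- origin[3] + (seq_len(dims[3]) - 1) * vs[3]
  pts_y <- origin[2] + (seq_len(dims[2]) - 1) * vs[2]
  pts_z <- origin[1] + (seq_len(dims[1]) - 1) * vs[1]
  grid <- cbind(rep(pts_z, times = dims[2] * dims[3]),
                rep(rep(pts_y, each = dims[1]), times = dims[3]),
                rep(pts_x, each = dims[1] * dims[2]))
  lumen_mask <- array(lumen_sdf(spec$lumen, grid) < 0, dims)

  counts <- label_counts(lab)
  truth <- data.frame(
    cell_id = seq_len(spec$n_cells),
    volume = 4 / 3 * pi * axes[, 1] * axes[, 2] * axes[, 3],
    volume_digitized = counts * prod(vs),
    semi_a = axes[, 1], semi_b = axes[, 2], semi_c = axes[, 3],
    centroid_z = pl$centers[, 1], centroid_y = pl$centers[, 2],
    centroid_x = pl$centers[, 3],
    axis_z = pl$normals[, 1], axis_y = pl$normals[, 2],
    axis_x = pl$normals[, 3])

  structure(list(
    prob = prob_volume(prob, vs),
    truth = list(labels = label_volume(lab, vs), table = truth,
                 lumen_mask = lumen_mask),
    spec = spec), class = "tip_tissue")
}

#' Degrade a membrane probability map
#'
#' Punches disc-shaped dropout patches into the membrane signal (emulating
#' local staining failures) and adds clipped Gaussian noise.  Gaps are
#' contiguous patches, not salt-and-pepper, because real membrane dropouts
#' are local.
#'
#' @param prob a [prob_volume()].
#' @param gap_rate fraction of membrane voxels (prob >= 0.5) to knock out,
#'   in `[0, 1)`.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param gap_radius physical radius (um) of each dropout patch.
#' @param seed integer seed.
#' @return A degraded [prob_volume()] on the same grid.
#' @export
degrade_membrane <- function(prob, gap_rate, noise_sd = 0, gap_radius = 0.5,
                             seed = 1) {
  stopifnot(inherits(prob, "prob_volume"))
  if (gap_rate < 0 || gap_rate >= 1)
    stop("gap_rate must be in [0, 1)", call. = FALSE)
  if (gap_rate == 0 && noise_sd == 0) return(prob)
  set.seed(seed)
  vs <- voxel_size(prob)
  vals <- unclass(prob)
  attr(vals, "voxel_size") <- NULL
  dims <- dim(vals)
  if (gap_rate > 0) {
    memb_idx <- which(vals >= 0.5)
    target <- round(gap_rate * length(memb_idx))
    removed <- 0L
    off <- se_offsets(gap_radius, vs)
    lin_off <- off[, 1] + dims[1] * (off[, 2] + dims[2] * off[, 3])
    guard <- 0L
    while (removed < target && guard < 100000L) {
      guard <- guard + 1L
      ctr <- memb_idx[sample.int(length(memb_idx), 1L)]
      # clip patches straddling the border by index-range check
      z <- (ctr - 1) %% dims[1]
      y <- ((ctr - 1) %/% dims[1]) %% dims[2]
      x <- (ctr - 1) %/% (dims[1] * dims[2])
      okz <- z + off[, 1] >= 0 & z + off[, 1] < dims[1]
      oky <- y + off[, 2] >= 0 & y + off[, 2] < dims[2]
      okx <- x + off[, 3] >= 0 & x + off[, 3] < dims[3]
      tgt <- ctr + lin_off[okz & oky & okx]
      hit <- tgt[vals[tgt] >= 0.5]
      vals[tgt] <- 0
      removed <- removed + length(hit)
    }
  }
  if (noise_sd > 0)
    vals <- vals + rnorm(length(vals), sd = noise_sd)
  vals[] <- pmin(pmax(vals, 0), 1)
  prob_volume(vals, vs)
}

#' Generate a wrinkled nuclear contour
#'
#' Closed star-shaped polygon `r(theta) = R (1 + eps * sin(k theta + phase))`
#' sampled at `n_points` vertices, emulating a wrinkled nuclear envelope.
#' `eps = 0` gives a circle; the wrinkle amplitude `eps` drives solidity and
#' circularity down monotonically.
#'
#' @param R base radius (um).
#' @param eps wrinkle amplitude, `0 <= eps < 1`.
#' @param k integer wrinkle count (lobes around the perimeter).
#' @param n_points number of vertices (>= 32).
#' @param seed optional; randomises the wrinkle phase (deterministic per
#'   seed).  `NULL` gives phase 0.
#' @return A [contour_2d()].
#' @examples
#' c0 <- generate_wrinkled_contour(5, eps = 0.2, k = 8, n_points = 256)
#' contour_metrics(c0)$solidity
#' @export
generate_wrinkled_contour <- function(R, eps, k, n_points = 256,
                                      seed = NULL) {
  if (eps < 0 || eps >= 1) stop("eps must be in [0, 1)", call. = FALSE)
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  if (n_points < 32) stop("n_points must be >= 32", call. = FALSE)
  phase <- 0
  if (!is.null(seed)) {
    set.seed(seed)
    phase <- runif(1, 0, 2 * pi)
  }
  theta <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  r <- R * (1 + eps * sin(k * theta + phase))
  if (any(r <= 0))
    stop("contour self-intersects (radius reaches zero); reduce eps",
         call. = FALSE)
  contour_2d(r * cos(theta), r * sin(theta), check_simple = FALSE)
}

#' Generate a cohort of nuclear contours
#'
#' Draws `n` wrinkled contours with jittered radius, amplitude and wrinkle
#' count, optionally rescaled so the expected polygon area is independent of
#' the wrinkle amplitude (`pi R^2 (1 + eps^2 / 2)` for the star contour), so
#' that cohorts differing in wrinkling have equal planted areas.
#'
#' @param n cohort size.
#' @param R_mean,R_sd radius distribution (um).
#' @param eps_mean,eps_sd wrinkle amplitude distribution (truncated at 0).
#' @param k_range integer range of wrinkle counts.
#' @param n_points vertices per contour.
#' @param normalize_area logical; decouple area from wrinkling (default).
#' @param seed integer seed.
#' @return List of [contour_2d()] objects.
#' @export
generate_contour_cohort <- function(n, R_mean = 5, R_sd = 0.4, eps_mean,
                                    eps_sd = 0.02, k_range = c(6, 10),
                                    n_points = 256, normalize_area = TRUE,
                                    seed = 1) {
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    eps <- min(max(rnorm(1, eps_mean, eps_sd), 0), 0.8)
    R <- max(rnorm(1, R_mean, R_sd), 0.5)
    if (normalize_area) R <- R / sqrt(1 + eps^2 / 2)
    k <- sample(seq(k_range[1], k_range[2]), 1)
    out[[i]] <- generate_wrinkled_contour(R, eps, k, n_points,
                                          seed = sample.int(1e8, 1))
  }
  out
}

#' Generate a traction scene (known tractions + forward displacements)
#'
#' Builds a traction field from cosine-tapered disc patches and computes the
#' surface displacement field through the Boussinesq half-space Green's
#' tensor for the given gel (spectral forward model).  The displacement is
#' exactly the forward model of the truth, so inversion routines can be
#' validated against it.
#'
#' @param patches data.frame with columns `cy`, `cx` (patch centre, um),
#'   `radius` (um), `ty`, `tx` (traction vector, Pa).
#' @param gel a [gel_spec()].
#' @param spacing grid spacing (um).
#' @param n grid size (n x n nodes).
#' @return A list of class `traction_scene`: `traction` (truth
#'   [traction_field()]), `displacement` ([displacement_field()]), `gel`.
#' @export
generate_traction_scene <- function(patches, gel, spacing, n) {
  stopifnot(is.data.frame(patches),
            all(c("cy", "cx", "radius", "ty", "tx") %in% names(patches)))
  if (any(patches$radius < 2 * spacing))
    stop("grid too coarse for requested patch (radius < 2 * spacing); ",
         "aliasing would corrupt the forward model", call. = FALSE)
  coords <- (seq_len(n) - 1) * spacing
  ty <- tx <- matrix(0, n, n)
  for (i in seq_len(nrow(patches))) {
    r <- sqrt(outer((coords - patches$cy[i])^2,
                    (coords - patches$cx[i])^2, "+"))
    w <- cosine_taper_profile(r, patches$radius[i])
    ty <- ty + patches$ty[i] * w
    tx <- tx + patches$tx[i] * w
  }
  tr <- traction_field(ty, tx, spacing)
  disp <- fttc_forward(tr, gel)
  structure(list(traction = tr, displacement = disp, gel = gel),
            class = "traction_scene")
}

# radial profile: 1 inside 0.6 R, cosine ramp to 0 at R
cosine_taper_profile <- function(r, R) {
  w <- matrix(0, nrow(r), ncol(r))
  w[r <= 0.6 * R] <- 1
  ramp <- r > 0.6 * R & r < R
  w[ramp] <- 0.5 * (1 + cos(pi * (r[ramp] - 0.6 * R) / (0.4 * R)))
  w
}

# integer voxel offsets of an ellipsoidal structuring element of physical
# radius r under anisotropic spacing
se_offsets <- function(r, spacing) {
  nr <- floor(r / spacing)
  g <- expand.grid(dz = -nr[1]:nr[1], dy = -nr[2]:nr[2], dx = -nr[3]:nr[3])
  keep <- (g$dz * spacing[1])^2 + (g$dy * spacing[2])^2 +
    (g$dx * spacing[3])^2 <= r^2 + 1e-12
  m <- as.matrix(g[keep, , drop = FALSE])
  storage.mode(m) <- "integer"
  m
}
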