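# Fourier-transform traction cytometry: forward Boussinesq model, Tikhonov-
# regularized inversion, RMS traction, doublet intercellular force, PIV
# displacement estimation and delamination speed.
#
# Spectral Green's tensor of a tangential point force on an elastic
# half-space surface (Young's modulus E, Poisson ratio nu), wave vector
# k = (ky, kx):
#   G(k) = 2 (1 + nu) / (E k^3) *
#          [ (1-nu) k^2 + nu kx^2 ,     -nu ky kx       ]
#          [     -nu ky kx        , (1-nu) k^2 + nu ky^2 ]
# so that u~(k) = G(k) t~(k); units um / Pa for k in rad/um.

#' Gel specification
#'
#' @param young_modulus Young's modulus E in Pa (e.g. 19660 for the
#'   19.66 kPa doublet gels, 25000 for monolayer gels).
#' @param poisson_ratio Poisson ratio; default 0.5 (incompressible
#'   polyacrylamide convention).
#' @return A `gel_spec` list.
#' @export
gel_spec <- function(young_modulus, poisson_ratio = 0.5) {
  if (young_modulus <= 0) stop("young_modulus must be > 0", call. = FALSE)
  if (poisson_ratio < 0 || poisson_ratio > 0.5)
    stop("poisson_ratio must be in [0, 0.5]", call. = FALSE)
  structure(list(young_modulus = young_modulus,
                 poisson_ratio = poisson_ratio), class = "gel_spec")
}

#' Regular-grid vector fields
#'
#' @param uy,ux,ty,tx component matrices (row = y, column = x).
#' @param spacing grid spacing (um).
#' @param lambda regularization parameter used to obtain a traction field
#'   (recorded for provenance).
#' @return `displacement_field` (um) or `traction_field` (Pa).
#' @export
displacement_field <- function(uy, ux, spacing) {
  check_field(uy, ux, spacing)
  structure(list(uy = uy, ux = ux, spacing = spacing),
            class = "displacement_field")
}

#' @rdname displacement_field
#' @export
traction_field <- function(ty, tx, spacing, lambda = NA_real_) {
  check_field(ty, tx, spacing)
  structure(list(ty = ty, tx = tx, spacing = spacing, lambda = lambda),
            class = "traction_field")
}

check_field <- function(a, b, spacing) {
  if (!is.matrix(a) || !identical(dim(a), dim(b)))
    stop("components must be matrices of identical dimension",
         call. = FALSE)
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  invisible(TRUE)
}

# wave numbers (rad/um) in FFT layout
fft_k <- function(n, spacing) {
  i <- seq_len(n) - 1
  f <- ifelse(i <= n / 2, i, i - n) / (n * spacing)
  2 * pi * f
}

boussinesq_g <- function(ky, kx, gel) {
  E <- gel$young_modulus
  nu <- gel$poisson_ratio
  k2 <- ky^2 + kx^2
  k <- sqrt(k2)
  f <- 2 * (1 + nu) / (E * k2 * k)
  list(gyy = f * ((1 - nu) * k2 + nu * kx^2),
       gxx = f * ((1 - nu) * k2 + nu * ky^2),
       gyx = -f * nu * ky * kx)
}

#' Forward Boussinesq model: tractions to surface displacements
#'
#' Computes the substrate surface displacement field generated by a
#' traction field through the spectral half-space Green's tensor.  The
#' zero-frequency component is set to zero (displacements are defined up to
#' a rigid shift).
#'
#' @param traction a [traction_field()] (Pa).
#' @param gel a [gel_spec()].
#' @return A [displacement_field()] (um).
#' @export
fttc_forward <- function(traction, gel) {
  stopifnot(inherits(traction, "traction_field"), inherits(gel, "gel_spec"))
  ny <- nrow(traction$ty)
  nx <- ncol(traction$ty)
  KY <- matrix(fft_k(ny, traction$spacing), ny, nx)
  KX <- matrix(fft_k(nx, traction$spacing), ny, nx, byrow = TRUE)
  Ty <- fft(traction$ty)
  Tx <- fft(traction$tx)
  G <- boussinesq_g(KY, KX, gel)
  Uy <- G$gyy * Ty + G$gyx * Tx
  Ux <- G$gyx * Ty + G$gxx * Tx
  Uy[1, 1] <- 0
  Ux[1, 1] <- 0
  displacement_field(Re(fft(Uy, inverse = TRUE)) / (ny * nx),
                     Re(fft(Ux, inverse = TRUE)) / (ny * nx),
                     traction$spacing)
}

#' Fourier-transform traction cytometry (inverse problem)
#'
#' Recovers the traction field from a surface displacement field by
#' inverting the Boussinesq Green's tensor in Fourier space with
#' zeroth-order Tikhonov regularization:
#' `t~ = (G' G + lam^2 I)^-1 G' u~` per wave vector.  The zero-frequency
#' traction is set to zero (no net drift).  At `lam = 0` (and no taper)
#' this is the exact inverse of [fttc_forward()] up to the band limit.
#'
#' @param displacement a [displacement_field()] (um).
#' @param gel a [gel_spec()].
#' @param lam regularization parameter (same units as the Green's tensor,
#'   um/Pa).  `NULL` selects it automatically by the L-curve corner on a
#'   20-point log grid.
#' @param taper cosine-taper fraction applied to each field edge before the
#'   FFT (default 0.1) to suppress periodic-boundary artifacts on
#'   non-periodic crops; use 0 for synthetic spectrally periodic fields.
#' @return A [traction_field()] (Pa) with the `lambda` used recorded.
#' @export
fttc <- function(displacement, gel, lam = NULL, taper = 0.1) {
  stopifnot(inherits(displacement, "displacement_field"),
            inherits(gel, "gel_spec"))
  uy <- displacement$uy
  ux <- displacement$ux
  if (any(!is.finite(uy)) || any(!is.finite(ux)))
    stop("displacement field contains non-finite values", call. = FALSE)
  ny <- nrow(uy)
  nx <- ncol(uy)
  if (taper > 0) {
    w <- outer(tukey_window(ny, taper), tukey_window(nx, taper))
    uy <- uy * w
    ux <- ux * w
  }
  KY <- matrix(fft_k(ny, displacement$spacing), ny, nx)
  KX <- matrix(fft_k(nx, displacement$spacing), ny, nx, byrow = TRUE)
  G <- boussinesq_g(KY, KX, gel)
  Uy <- fft(uy)
  Ux <- fft(ux)
  if (is.null(lam)) lam <- lcurve_lambda(G, Uy, Ux)
  # (G'G + lam^2 I)^-1 G' u, with G symmetric 2x2 per wave vector
  a <- G$gyy * G$gyy + G$gyx * G$gyx + lam^2
  b <- G$gyx * (G$gyy + G$gxx)
  d <- G$gxx * G$gxx + G$gyx * G$gyx + lam^2
  det <- a * d - b * b
  ry <- G$gyy * Uy + G$gyx * Ux
  rx <- G$gyx * Uy + G$gxx * Ux
  Ty <- (d * ry - b * rx) / det
  Tx <- (a * rx - b * ry) / det
  Ty[1, 1] <- 0
  Tx[1, 1] <- 0
  Ty[!is.finite(Ty)] <- 0
  Tx[!is.finite(Tx)] <- 0
  traction_field(Re(fft(Ty, inverse = TRUE)) / (ny * nx),
                 Re(fft(Tx, inverse = TRUE)) / (ny * nx),
                 displacement$spacing, lambda = lam)
}

tukey_window <- function(n, frac) {
  w <- rep(1, n)
  m <- floor(frac * n)
  if (m > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(m) / m))
    w[seq_len(m)] <- ramp
    w[n + 1 - seq_len(m)] <- ramp
  }
  w
}

# L-curve corner: maximal curvature of (log residual, log solution norm)
# over a log-spaced lambda grid
lcurve_lambda <- function(G, Uy, Ux, n_grid = 20) {
  gmax <- max(abs(G$gyy[-1]), abs(G$gxx[-1]), na.rm = TRUE)
  lams <- 10^seq(log10(gmax * 1e-6), log10(gmax * 10), length.out = n_grid)
  rho <- eta <- numeric(n_grid)
  for (i in seq_along(lams)) {
    lam <- lams[i]
    a <- G$gyy * G$gyy + G$gyx * G$gyx + lam^2
    b <- G$gyx * (G$gyy + G$gxx)
    d <- G$gxx * G$gxx + G$gyx * G$gyx + lam^2
    det <- a * d - b * b
    ry <- G$gyy * Uy + G$gyx * Ux
    rx <- G$gyx * Uy + G$gxx * Ux
    Ty <- (d * ry - b * rx) / det
    Tx <- (a * rx - b * ry) / det
    Ty[1, 1] <- 0; Tx[1, 1] <- 0
    Ty[!is.finite(Ty)] <- 0; Tx[!is.finite(Tx)] <- 0
    Ry <- G$gyy * Ty + G$gyx * Tx - Uy
    Rx <- G$gyx * Ty + G$gxx * Tx - Ux
    Ry[1, 1] <- 0; Rx[1, 1] <- 0
    rho[i] <- sqrt(sum(Mod(Ry)^2 + Mod(Rx)^2))
    eta[i] <- sqrt(sum(Mod(Ty)^2 + Mod(Tx)^2))
  }
  lr <- log(pmax(rho, 1e-300))
  le <- log(pmax(eta, 1e-300))
  # discrete curvature
  kap <- rep(-Inf, n_grid)
  for (i in 2:(n_grid - 1)) {
    d1r <- (lr[i + 1] - lr[i - 1]) / 2
    d1e <- (le[i + 1] - le[i - 1]) / 2
    d2r <- lr[i + 1] - 2 * lr[i] + lr[i - 1]
    d2e <- le[i + 1] - 2 * le[i] + le[i - 1]
    den <- (d1r^2 + d1e^2)^1.5
    if (den > 0) kap[i] <- (d1r * d2e - d2r * d1e) / den
  }
  lams[which.max(kap)]
}

#' Root-mean-square traction
#'
#' `sqrt(mean |t|^2)` over the field of view, or over an optional logical
#' mask — the standard monolayer summary statistic.
#'
#' @param traction a [traction_field()].
#' @param mask optional logical matrix selecting nodes.
#' @return RMS traction in Pa.
#' @export
rms_traction <- function(traction, mask = NULL) {
  stopifnot(inherits(traction, "traction_field"))
  m2 <- traction$ty^2 + traction$tx^2
  if (!is.null(mask)) {
    if (!any(mask)) stop("mask is empty", call. = FALSE)
    m2 <- m2[mask]
  }
  sqrt(mean(m2))
}

#' Intercellular force in a cell doublet
#'
#' The unbalanced integral of traction under one cell of a pair:
#' `F_ab = -sum_{region_a} t dA`, converted Pa um^2 -> N (x 1e-12).  By
#' force balance this equals the force the neighbour exerts across the
#' cell-cell junction; `F_ab = -F_ba` up to noise, and the imbalance is
#' flagged when it exceeds 10 percent of the larger magnitude.
#'
#' @param traction a [traction_field()].
#' @param region_a,region_b disjoint logical matrices (cell footprints).
#' @param pixel_area area per node (um^2); default `spacing^2`.
#' @return List: `force_a`, `force_b` (N, length-2 `(y, x)` vectors),
#'   `magnitude` (N, mean of the two), `balanced` (logical flag).
#' @export
intercellular_force <- function(traction, region_a, region_b,
                                pixel_area = NULL) {
  stopifnot(inherits(traction, "traction_field"))
  if (any(region_a & region_b))
    stop("regions must be disjoint", call. = FALSE)
  if (!any(region_a) || !any(region_b))
    stop("empty region", call. = FALSE)
  if (is.null(pixel_area)) pixel_area <- traction$spacing^2
  fa <- -c(sum(traction$ty[region_a]), sum(traction$tx[region_a])) *
    pixel_area * 1e-12
  fb <- -c(sum(traction$ty[region_b]), sum(traction$tx[region_b])) *
    pixel_area * 1e-12
  na <- sqrt(sum(fa^2))
  nb <- sqrt(sum(fb^2))
  imbalance <- sqrt(sum((fa + fb)^2))
  balanced <- imbalance <= 0.1 * max(na, nb)
  if (!balanced)
    warning("doublet force imbalance exceeds 10% of the larger force")
  list(force_a = fa, force_b = fb, magnitude = (na + nb) / 2,
       balanced = balanced)
}

#' PIV displacement field from a bead image pair
#'
#' Normalized cross-correlation block matching with parabolic sub-pixel
#' peak refinement.  Featureless windows are flagged invalid and inpainted
#' from their neighbours.
#'
#' @param img_exp,img_ref matrices (experimental and reference bead
#'   images), identical size.
#' @param window correlation window size (px, >= 8).
#' @param step grid step between window origins (px).
#' @param max_shift largest integer shift searched (px).
#' @param pixel_size um per pixel (default 1: vectors in px).
#' @return A list: `grid` (data.frame cy, cx in px), field
#'   ([displacement_field()] with spacing `step * pixel_size`), `valid`
#'   (logical per node before inpainting).
#' @export
piv_displacement <- function(img_exp, img_ref, window = 32, step = 16,
                             max_shift = 8, pixel_size = 1) {
  if (!identical(dim(img_exp), dim(img_ref)))
    stop("images must have identical size", call. = FALSE)
  if (window < 8) stop("window must be >= 8 px", call. = FALSE)
  res <- cpp_piv(img_ref, img_exp, window, step, max_shift)
  ncols <- length(unique(res$cx))
  nrows <- length(res$cx) / ncols
  uy <- matrix(res$uy, nrows, ncols, byrow = TRUE)
  ux <- matrix(res$ux, nrows, ncols, byrow = TRUE)
  valid <- matrix(res$valid == 1, nrows, ncols, byrow = TRUE)
  # inpaint invalid nodes from valid neighbours
  guard <- 0
  while (any(!is.finite(uy)) && guard < 100) {
    guard <- guard + 1
    bad <- which(!is.finite(uy), arr.ind = TRUE)
    for (r in seq_len(nrow(bad))) {
      i <- bad[r, 1]; j <- bad[r, 2]
      ni <- max(1, i - 1):min(nrows, i + 1)
      nj <- max(1, j - 1):min(ncols, j + 1)
      vy <- uy[ni, nj]; vx <- ux[ni, nj]
      if (any(is.finite(vy))) {
        uy[i, j] <- mean(vy[is.finite(vy)])
        ux[i, j] <- mean(vx[is.finite(vx)])
      }
    }
  }
  if (any(!is.finite(uy))) {
    uy[!is.finite(uy)] <- 0
    ux[!is.finite(ux)] <- 0
  }
  list(grid = data.frame(cy = res$cy, cx = res$cx),
       field = displacement_field(uy * pixel_size, ux * pixel_size,
                                  step * pixel_size),
       valid = valid)
}

#' Delamination speed from two binary masks
#'
#' Mean outward advance of a spreading cell mass per unit time: the
#' distance transform of the earlier mask is averaged over the boundary of
#' the later mask and divided by the elapsed time.
#'
#' @param mask_t0,mask_t1 logical matrices; `mask_t0` must be contained in
#'   `mask_t1` (the mass only spreads).
#' @param dt elapsed time (s), e.g. 5280 s for an 88-minute window.
#' @param pixel_size um per pixel.
#' @return Mean boundary advance speed in um/s.
#' @export
delamination_speed <- function(mask_t0, mask_t1, dt, pixel_size = 1) {
  if (!identical(dim(mask_t0), dim(mask_t1)))
    stop("masks must have identical size", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (any(mask_t0 & !mask_t1))
    stop("mask shrank between timepoints; delamination assumes outward ",
         "spread", call. = FALSE)
  dims <- c(1L, dim(mask_t0))
  d2 <- cpp_edt_sq(as.logical(!mask_t0), dims,
                   c(1, pixel_size, pixel_size))
  dmap <- matrix(sqrt(d2), nrow(mask_t0), ncol(mask_t0))
  # boundary pixels of the later mask (4-connectivity erosion residue)
  shift2 <- function(m, dy, dx) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    ys <- seq_len(nrow(m)) - dy
    xs <- seq_len(ncol(m)) - dx
    oky <- ys >= 1 & ys <= nrow(m)
    okx <- xs >= 1 & xs <= ncol(m)
    out[oky, okx] <- m[ys[oky], xs[okx]]
    out
  }
  er <- mask_t1 & shift2(mask_t1, 1, 0) & shift2(mask_t1, -1, 0) &
    shift2(mask_t1, 0, 1) & shift2(mask_t1, 0, -1)
  boundary <- mask_t1 & !er
  if (!any(boundary)) return(0)
  mean(dmap[boundary]) / dt
}
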