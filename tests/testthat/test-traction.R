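# FTTC, force bookkeeping, PIV and delamination speed.

doublet_scene <- function(T0 = 200) {
  generate_traction_scene(
    data.frame(cy = c(128, 128), cx = c(88, 168), radius = 8,
               ty = c(0, 0), tx = c(T0, -T0)),
    gel_spec(19660), spacing = 2, n = 128)
}

test_that("FTTC inverts the forward Boussinesq model", {
  sc <- doublet_scene()
  # zero displacement -> zero traction
  z <- fttc(displacement_field(matrix(0, 32, 32), matrix(0, 32, 32), 2),
            gel_spec(25000), lam = 0, taper = 0)
  expect_equal(max(abs(z$ty), abs(z$tx)), 0)
  # round trip at lam = 0
  tr <- fttc(sc$displacement, sc$gel, lam = 0, taper = 0)
  rel <- sqrt(mean((tr$ty - sc$traction$ty)^2 +
                     (tr$tx - sc$traction$tx)^2)) / rms_traction(sc$traction)
  expect_lt(rel, 0.05)
  # linearity
  d2 <- displacement_field(2 * sc$displacement$uy, 2 * sc$displacement$ux, 2)
  tr2 <- fttc(d2, sc$gel, lam = 0, taper = 0)
  expect_equal(tr2$ty, 2 * tr$ty, tolerance = 1e-9)
  # NaN input rejected
  bad <- sc$displacement
  bad$uy[1, 1] <- NaN
  expect_error(fttc(bad, sc$gel), "non-finite")
})

test_that("regularization monotonically damps the recovered traction", {
  sc <- doublet_scene()
  lams <- 10^seq(-10, -6, length.out = 8)
  rms <- vapply(lams, function(l)
    rms_traction(fttc(sc$displacement, sc$gel, lam = l, taper = 0)),
    numeric(1))
  expect_true(all(diff(rms) <= 1e-9))
  # automatic L-curve pick lands near the truth on clean data
  auto <- fttc(sc$displacement, sc$gel, taper = 0)
  expect_gt(auto$lambda, 0)
  expect_lt(abs(rms_traction(auto) / rms_traction(sc$traction) - 1), 0.05)
})

test_that("RMS traction follows its definition", {
  t100 <- traction_field(matrix(60, 10, 10), matrix(80, 10, 10), 1)
  expect_equal(rms_traction(t100), 100)
  expect_equal(rms_traction(traction_field(matrix(0, 5, 5),
                                           matrix(0, 5, 5), 1)), 0)
  chk <- matrix(c(100, -100), 10, 10)
  expect_equal(rms_traction(traction_field(chk, 0 * chk, 1)), 100)
  msk <- matrix(FALSE, 10, 10)
  msk[1:3, ] <- TRUE
  expect_equal(rms_traction(t100, msk), 100)
  expect_error(rms_traction(t100, matrix(FALSE, 10, 10)), "empty")
})

test_that("doublet intercellular force is recovered and antisymmetric", {
  sc <- doublet_scene()
  tr <- fttc(sc$displacement, sc$gel, lam = 0, taper = 0)
  co <- (seq_len(128) - 1) * 2
  ra <- sqrt(outer((co - 128)^2, (co - 88)^2, "+")) <= 12
  rb <- sqrt(outer((co - 128)^2, (co - 168)^2, "+")) <= 12
  planted <- abs(sum(sc$traction$tx[ra])) * 4 * 1e-12
  ic <- intercellular_force(tr, ra, rb)
  expect_lt(abs(ic$magnitude / planted - 1), 0.10)
  expect_true(ic$balanced)
  # swapping regions negates the vector
  ic2 <- intercellular_force(tr, rb, ra)
  expect_equal(ic2$force_a, ic$force_b, tolerance = 1e-15)
  # an isolated, internally balanced cell carries no net force
  single <- generate_traction_scene(
    data.frame(cy = c(128, 128), cx = c(118, 138), radius = 8,
               ty = c(0, 0), tx = c(200, -200)),
    gel_spec(19660), spacing = 2, n = 128)
  cell <- sqrt(outer((co - 128)^2, (co - 128)^2, "+")) <= 24
  tot <- sum(sqrt(single$traction$ty^2 + single$traction$tx^2)) * 4 * 1e-12
  net <- abs(sum(single$traction$tx[cell])) * 4 * 1e-12
  expect_lt(net, 0.05 * tot)
  expect_error(intercellular_force(tr, ra, ra), "disjoint")
})

test_that("PIV recovers rigid and smooth displacements to sub-pixel", {
  set.seed(6)
  render_beads <- function(ny, nx, pos) {
    img <- matrix(0, ny, nx)
    for (k in seq_len(nrow(pos))) {
      cy <- pos[k, 1]; cx <- pos[k, 2]
      ys <- max(1, floor(cy - 3)):min(ny, ceiling(cy + 3))
      xs <- max(1, floor(cx - 3)):min(nx, ceiling(cx + 3))
      img[ys, xs] <- img[ys, xs] +
        exp(-(outer((ys - cy)^2, (xs - cx)^2, "+")) / 2.5)
    }
    img
  }
  pos <- cbind(runif(300, 5, 155), runif(300, 5, 155))
  ref <- render_beads(160, 160, pos)
  # identical images: zero field
  p0 <- piv_displacement(ref, ref, max_shift = 5)
  expect_equal(max(abs(p0$field$uy), abs(p0$field$ux)), 0)
  # rigid shift (3, 0)
  exp_img <- render_beads(160, 160, cbind(pos[, 1] + 3, pos[, 2]))
  pr <- piv_displacement(exp_img, ref, max_shift = 6)
  expect_lt(max(abs(pr$field$uy - 3)), 0.2)
  expect_lt(max(abs(pr$field$ux)), 0.2)
  # smooth synthetic warp: RMS error < 0.3 px
  wy <- function(y, x) 2 * sin(2 * pi * x / 160)
  wx <- function(y, x) 1.5 * cos(2 * pi * y / 160)
  warped <- render_beads(160, 160, cbind(pos[, 1] + wy(pos[, 1], pos[, 2]),
                                         pos[, 2] + wx(pos[, 1], pos[, 2])))
  pw <- piv_displacement(warped, ref, max_shift = 6)
  gy <- matrix(pw$grid$cy, nrow(pw$field$uy), ncol(pw$field$uy), byrow = TRUE)
  gx <- matrix(pw$grid$cx, nrow(pw$field$ux), ncol(pw$field$ux), byrow = TRUE)
  err <- sqrt(mean((pw$field$uy - wy(gy, gx))^2 +
                     (pw$field$ux - wx(gy, gx))^2))
  expect_lt(err, 0.3)
})

test_that("delamination speed equals the mean boundary advance", {
  disc <- function(r, n = 220) {
    y <- matrix(seq_len(n), n, n)
    x <- t(y)
    (y - n / 2)^2 + (x - n / 2)^2 <= r^2
  }
  sp <- delamination_speed(disc(50), disc(100), dt = 5280, pixel_size = 1)
  expect_equal(sp, 50 / 5280, tolerance = 0.02)
  # identical masks: zero speed
  expect_equal(delamination_speed(disc(50), disc(50), 5280), 0)
  # shrinkage violates the direction assumption
  expect_error(delamination_speed(disc(100), disc(50), 5280), "shrank")
  # anisotropic advance: ellipse growth, mean of per-angle advances
  n <- 260
  y <- matrix(seq_len(n), n, n); x <- t(y)
  e0 <- ((y - n / 2) / 40)^2 + ((x - n / 2) / 40)^2 <= 1
  e1 <- ((y - n / 2) / 60)^2 + ((x - n / 2) / 90)^2 <= 1
  # oracle: average over the t1 boundary of the distance to the t0 circle
  th <- seq(0, 2 * pi, length.out = 20000)
  rb <- sqrt((60 * sin(th))^2 + (90 * cos(th))^2)
  # arc-length weights for the ellipse boundary
  dy <- 60 * cos(th); dx <- -90 * sin(th)
  w <- sqrt(dy^2 + dx^2)
  adv <- sum((rb - 40) * w) / sum(w)
  sp2 <- delamination_speed(e0, e1, dt = 1000, pixel_size = 1)
  expect_equal(sp2, adv / 1000, tolerance = 0.05)
})
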