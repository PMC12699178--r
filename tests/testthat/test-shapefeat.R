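# Ellipsoid-moment shape descriptors.

test_that("principal axes recover digitized ellipsoid diameters", {
  vs <- c(0.25, 0.25, 0.25)
  m <- digitize_ellipsoid(c(5, 3, 2), vs)
  ax <- principal_axes(m, vs)
  expect_equal(as.numeric(ax), c(10, 6, 4), tolerance = 0.03)
  # sphere: all axes equal the diameter
  sp <- digitize_ellipsoid(c(3, 3, 3), vs)
  expect_equal(as.numeric(principal_axes(sp, vs)), c(6, 6, 6),
               tolerance = 0.03)
  # rotation invariance (30 degrees about z)
  mr <- digitize_ellipsoid(c(5, 3, 2), vs, rot = rot3("z", pi / 6))
  expect_equal(as.numeric(principal_axes(mr, vs)), c(10, 6, 4),
               tolerance = 0.03)
  expect_error(principal_axes(array(FALSE, c(4, 4, 4)), vs), "empty")
})

test_that("degenerate masks are floored and flagged", {
  m <- array(FALSE, c(5, 9, 9))
  m[3, 2:8, 2:8] <- TRUE # a single-voxel-thick plate
  ax <- principal_axes(m, c(0.25, 0.25, 0.25))
  expect_true(attr(ax, "degenerate"))
  expect_gte(min(ax), 0.25)
})

test_that("elongation and ellipticity follow their definitions", {
  expect_equal(elongation(6, 4, 2), 2)
  expect_equal(elongation(3, 3, 3), 1)
  # mean axis lengths of trunk cells give ~1.823 / ~0.547; the printed
  # stage means (1.83, 0.53) are means of per-cell ratios, so only
  # ballpark agreement is expected
  expect_equal(elongation(10.29, 6.63, 4.66), 1.823, tolerance = 1e-3)
  expect_equal(ellipticity(10.29, 4.66), 0.547, tolerance = 1e-3)
  expect_equal(ellipticity(10, 4), 0.6)
  expect_equal(ellipticity(5, 5), 0)
  expect_error(elongation(2, 4, 6), "ordering")
  expect_error(ellipticity(2, 4), "L >= M")
})

test_that("surface area matches closed forms", {
  vs <- c(0.25, 0.25, 0.25)
  sp <- digitize_ellipsoid(c(3, 3, 3), vs)
  expect_lt(abs(surface_area(sp, vs) / (4 * pi * 9) - 1), 0.05)
  cube <- array(FALSE, c(24, 24, 24))
  cube[5:20, 5:20, 5:20] <- TRUE # 4 um side
  expect_lt(abs(surface_area(cube, vs) / 96 - 1), 0.08)
  # invariant under axis permutation
  m <- digitize_ellipsoid(c(4, 2.5, 1.5), vs)
  a1 <- surface_area(m, vs)
  a2 <- surface_area(aperm(m, c(2, 3, 1)), vs)
  expect_equal(a1, a2, tolerance = 1e-6)
})

test_that("roundness behaves like a sphere-referenced radius", {
  vs <- c(0.25, 0.25, 0.25)
  sp <- digitize_ellipsoid(c(3, 3, 3), vs)
  vol <- sum(sp) * prod(vs)
  r <- roundness(vol, surface_area(sp, vs))
  expect_equal(r, 3, tolerance = 0.06)
  # doubling all linear dimensions doubles roundness
  expect_equal(roundness(8 * vol, 4 * 100), 2 * roundness(vol, 100))
  # elongating at fixed volume strictly decreases roundness (mesh oracle)
  rs <- vapply(c(1, 1.4, 1.9, 2.5), function(s) {
    semi <- c(3 * s, 3 / sqrt(s), 3 / sqrt(s))
    m <- digitize_ellipsoid(semi, vs)
    roundness(sum(m) * prod(vs), surface_area(m, vs))
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("compute_features fills one valid record per cell", {
  tt <- small_bud()
  ft <- compute_features(tt$truth$labels, tip_id = "bud1",
                         stage = "initial_bud")
  expect_identical(nrow(ft), nrow(tt$truth$table))
  expect_true(all(abs(ft$volume / tt$truth$table$volume - 1) < 0.05))
  # invariants on every record
  expect_true(all(ft$longest_axis >= ft$intermediate_axis - 1e-9))
  expect_true(all(ft$intermediate_axis >= ft$minor_axis - 1e-9))
  expect_true(all(ft$minor_axis > 0))
  expect_true(all(ft$elongation >= 1 - 1e-9))
  expect_true(all(ft$ellipticity >= 0 & ft$ellipticity < 1))
  expect_true(all(ft$volume > 0))
  expect_false(any(ft$degenerate))
  # re-run identical
  expect_equal(as.data.frame(compute_features(tt$truth$labels,
                                              tip_id = "bud1",
                                              stage = "initial_bud")),
               as.data.frame(ft))
})

test_that("the table reports means of per-cell ratios, not ratios of means", {
  tt <- small_bud()
  ft <- compute_features(tt$truth$labels)
  mean_of_ratios <- mean(ft$elongation)
  ratio_of_means <- elongation(mean(ft$longest_axis),
                               mean(ft$intermediate_axis),
                               mean(ft$minor_axis))
  expect_gt(abs(mean_of_ratios - ratio_of_means), 1e-6)
})

test_that("axes and volume recover within 5% on random ellipsoids", {
  set.seed(42)
  vs <- c(0.25, 0.25, 0.25)
  errs <- replicate(25, {
    semi <- sort(exp(runif(3, log(1.5), log(6))), decreasing = TRUE)
    rot <- qr.Q(qr(matrix(rnorm(9), 3)))
    m <- digitize_ellipsoid(semi, vs, rot = rot)
    ax <- principal_axes(m, vs)
    c(abs(ax / (2 * semi) - 1), abs(sum(m) * prod(vs) /
                                      (4 / 3 * pi * prod(semi)) - 1))
  })
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.05)
  expect_lt(median(errs[3, ]), 0.05)
  expect_lt(median(errs[4, ]), 0.05)
})

test_that("features are rotation invariant within tolerance", {
  vs <- c(0.25, 0.25, 0.25)
  semi <- c(4, 2.5, 1.8)
  m0 <- digitize_ellipsoid(semi, vs)
  m1 <- digitize_ellipsoid(semi, vs, rot = rot3("y", 0.4) %*% rot3("z", 1.1))
  for (m in list(m0, m1)) {
    lab <- label_volume(array(as.integer(m), dim(m)), vs)
    ft <- compute_features(lab)
    ft0 <- compute_features(label_volume(array(as.integer(m0), dim(m0)), vs))
    expect_equal(ft$volume, ft0$volume, tolerance = 0.05)
    expect_equal(ft$roundness, ft0$roundness, tolerance = 0.05)
    expect_equal(ft$elongation, ft0$elongation, tolerance = 0.05)
    expect_equal(ft$longest_axis, ft0$longest_axis, tolerance = 0.05)
  }
})
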