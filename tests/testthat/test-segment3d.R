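# Watershed reconstruction of cells from membrane probability maps.

test_that("gap closing is extensive, idempotent and restores planted gaps", {
  tt <- small_bud()
  # radius 0: identity
  expect_identical(close_membrane_gaps(tt$prob, 0), tt$prob)
  # sub-voxel radius: no-op with warning
  expect_warning(out <- close_membrane_gaps(tt$prob, 0.1), "no-op")
  expect_identical(out, tt$prob)
  # a flat membrane slab with one 0.5 um disc hole: closing at 0.6 um
  # restores every hole voxel above threshold
  vs <- c(0.333, 0.2, 0.2)
  slab <- array(0, c(21, 61, 61))
  slab[10:11, , ] <- 1
  yy <- (seq_len(61) - 31) * 0.2
  hole <- outer(yy^2, yy^2, "+") <= 0.25^2
  for (z in 10:11) slab[z, , ][hole] <- 0
  pv <- prob_volume(slab, vs)
  cl <- close_membrane_gaps(pv, 0.6)
  expect_true(all(cl >= pv - 1e-12)) # extensive
  expect_true(all(cl[10, , ][hole] >= 0.5))
  expect_true(all(cl[11, , ][hole] >= 0.5))
  # voxels farther than the closing reach from any membrane are untouched
  dist2 <- ubmorph:::cpp_edt_sq(as.logical(tt$prob < 0.5), dim(tt$prob),
                                voxel_size(tt$prob))
  dg <- degrade_membrane(tt$prob, gap_rate = 0.05, gap_radius = 0.25,
                         seed = 2)
  cltt <- close_membrane_gaps(dg, 0.6)
  far <- sqrt(dist2) > 1.1
  expect_lt(max(cltt[far]), 0.5)
  # punched membrane voxels are mostly restored in a real tissue (band-edge
  # voxels stay below threshold; the downstream F1 test covers function)
  gap_vox <- which(tt$prob >= 0.5 & dg < 0.5)
  expect_gt(mean(cltt[gap_vox] >= 0.5), 0.5)
  # idempotence
  cl2 <- close_membrane_gaps(cl, 0.6)
  expect_equal(as.numeric(cl2), as.numeric(cl), tolerance = 1e-12)
})

test_that("markers come from distance-map h-maxima", {
  s <- two_sphere_sealed()
  mk <- seed_markers(s$prob, threshold = 0.5, h = 1.0)
  expect_identical(max(mk), 2L)
  # single sphere: exactly one marker
  vs <- voxel_size(s$prob)
  one <- array(1, dim(s$prob))
  one[s$d1 <= 2.5] <- 0
  mk1 <- seed_markers(prob_volume(one, vs))
  expect_identical(max(mk1), 1L)
  # h above the maximal interior distance: error
  expect_error(seed_markers(s$prob, h = 10), "exceeds")
  # all-membrane input: empty-marker error
  expect_error(seed_markers(prob_volume(array(1, c(8, 8, 8)), vs)),
               "no interior")
  expect_error(seed_markers(s$prob, threshold = 1.5), "threshold")
})

test_that("watershed recovers the two-sphere fixture volumes", {
  shell <- two_sphere_shell()
  seg <- segment_pipeline(shell, segment_config(radius = 0, vmin = 20,
                                                vmax = 200))
  expect_identical(max(seg), 2L)
  v_true <- 4 / 3 * pi * 2.5^3
  vols <- ubmorph:::label_counts(seg) * voxel_volume(seg)
  expect_true(all(abs(vols / v_true - 1) < 0.10))
  # partition: labels disjoint, total labelled volume below domain volume
  expect_lte(sum(vols), prod(dim(seg)) * voxel_volume(seg))
})

test_that("re-running watershed on its own output is stable", {
  shell <- two_sphere_shell()
  mk <- seed_markers(shell)
  ws1 <- watershed_cells(shell, mk)
  ws2 <- watershed_cells(shell, ws1)
  # previously labelled voxels never change basin
  expect_identical(as.integer(ws2)[as.integer(ws1) > 0],
                   as.integer(ws1)[as.integer(ws1) > 0])
})

test_that("filter_labels gates by physical volume and renumbers", {
  vs <- c(0.5, 0.5, 0.5) # voxel volume 0.125
  lab <- array(0L, c(20, 20, 40))
  lab[2:5, 2:5, 2:16] <- 1L   # 240 vox = 30 um^3
  lab[10:17, 10:17, 2:14] <- 2L # 832 vox = 104 um^3
  lab[2:17, 2:17, 20:38] <- 3L  # 4864 vox = 608 um^3
  lv <- label_volume(lab, vs)
  f <- filter_labels(lv, 50, 500)
  expect_identical(max(f), 1L)
  expect_identical(which(f == 1L), which(lab == 2L)) # voxel-set preserved
  # vmin = 0, vmax = Inf: identity up to renumbering (by descending volume)
  f2 <- filter_labels(lv, 0, Inf)
  expect_identical(max(f2), 3L)
  expect_identical(which(f2 == 1L), which(lab == 3L))
  expect_identical(which(f2 == 3L), which(lab == 1L))
  expect_error(filter_labels(lv, 10, 5), "vmin")
})

test_that("the pipeline finds every cell of a pristine tissue", {
  tt <- small_bud()
  seg <- segment_pipeline(tt$prob, segment_config(radius = 0))
  expect_identical(max(seg), nrow(tt$truth$table))
  m <- match_labels(seg, tt$truth$labels)
  expect_identical(m$f1, 1)
  # deterministic
  seg2 <- segment_pipeline(tt$prob, segment_config(radius = 0))
  expect_identical(as.integer(seg), as.integer(seg2))
  # watershed recovers the generator partition up to a thin boundary shell:
  # matched cells overlap their truth labels almost completely
  expect_gt(min(m$matches$iou), 0.75)
  # all-membrane input fails before flooding
  expect_error(segment_pipeline(prob_volume(array(1, c(8, 8, 8)),
                                            voxel_size(tt$prob))),
               "no interior")
})

test_that("segmentation stays accurate under membrane dropouts", {
  tt <- small_bud()
  dg <- degrade_membrane(tt$prob, gap_rate = 0.05, noise_sd = 0.05, seed = 13)
  seg <- segment_pipeline(dg, segment_config(radius = 0.6))
  m <- match_labels(seg, tt$truth$labels)
  expect_gte(m$f1, 0.9)
  for (k in seq_len(nrow(m$matches))) {
    tv <- tt$truth$table$volume[m$matches$truth_id[k]]
    sv <- sum(seg == m$matches$seg_id[k]) * voxel_volume(seg)
    expect_lt(abs(sv / tv - 1), 0.25)
  }
})
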