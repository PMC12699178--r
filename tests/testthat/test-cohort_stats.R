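# Nonparametric cohort statistics and aggregation helpers.

test_that("pooled means combine per-tip rows exactly", {
  bi <- morphometry_reference("bi_tips")
  expect_equal(round(pooled_mean(bi$volume, bi$n_cells), 2), 201.25)
  expect_equal(pooled_mean(c(5, 5, 5), c(1, 9, 3)), 5)
  expect_equal(pooled_mean(c(0, 2), c(1, 1)), 1)
  expect_error(pooled_mean(1:3, 1:2), "length")
  expect_error(pooled_mean(1:2, c(1, 0)), "counts")
})

test_that("Kruskal-Wallis / Conover-Iman match rank-formula oracles", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6))
  kc <- kruskal_conover(g)
  # independent H oracle
  H_or <- kw_h_oracle(unlist(g), rep(c("a", "b"), each = 3))
  expect_equal(kc$omnibus$statistic, H_or, tolerance = 1e-12)
  expect_equal(kc$omnibus$statistic, 3.857143, tolerance = 1e-6)
  # Conover t from its defining formula at maximal separation:
  # Rbar = (2, 5), S2 = 3.5, scale = S2 * (N-1-H)/(N-k)
  t_expect <- (2 - 5) / sqrt(3.5 * (5 - H_or) / 4 * (2 / 3))
  expect_equal(kc$pairwise$statistic["a", "b"], t_expect, tolerance = 1e-10)
  # identical constant groups: H = 0, p = 1
  k0 <- kruskal_conover(list(a = rep(2, 4), b = rep(2, 5)))
  expect_equal(k0$omnibus$statistic, 0)
  expect_equal(k0$omnibus$p_value, 1)
  expect_equal(k0$pairwise$p_value["a", "b"], 1)
  expect_error(kruskal_conover(list(a = 1:3)), "2 groups")
  expect_error(kruskal_conover(list(a = 1:3, b = 2)), "2 values")
})

test_that("exact permutation p-values equal brute-force enumeration", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6))
  kc <- kruskal_conover(g, p_method = "permutation")
  # oracle: enumerate all 20 assignments directly
  pool <- unlist(g)
  splits <- combn(6, 3, simplify = FALSE)
  H_obs <- kw_h_oracle(pool, rep(1:2, each = 3))
  H_all <- vapply(splits, function(ix)
    kw_h_oracle(c(pool[ix], pool[-ix]), rep(1:2, each = 3)), numeric(1))
  expect_equal(kc$omnibus$p_value, mean(H_all >= H_obs - 1e-12))
  expect_equal(kc$omnibus$p_value, 0.1) # 2/20
  # three tiny groups, pairwise statistic permutation
  g3 <- list(a = c(1.2, 0.8), b = c(3.1, 2.7), c = c(9.5, 8.2))
  kp <- kruskal_conover(g3, p_method = "permutation")
  expect_true(all(kp$pairwise$p_value >= 0 & kp$pairwise$p_value <= 1))
  expect_equal(diag(kp$pairwise$p_value), rep(1, 3), ignore_attr = TRUE)
  # permutation p of the most separated pair is the minimal attainable
  # two-sided value for n = (2, 2, 2): 90 equally likely assignments
  expect_gte(kp$pairwise$p_value["a", "c"], 1 / 90)
})

test_that("Holm adjustment is monotone and never below raw p", {
  set.seed(7)
  g <- lapply(1:4, function(i) rnorm(12, mean = i * 0.3))
  names(g) <- paste0("g", 1:4)
  kc <- kruskal_conover(g)
  up <- upper.tri(kc$pairwise$p_value)
  expect_true(all(kc$pairwise$p_adjusted[up] >= kc$pairwise$p_value[up]))
  ord <- order(kc$pairwise$p_value[up])
  expect_true(!is.unsorted(kc$pairwise$p_adjusted[up][ord]))
  # matrices symmetric with unit diagonal
  expect_identical(kc$pairwise$p_value, t(kc$pairwise$p_value))
  expect_equal(unname(diag(kc$pairwise$p_value)), rep(1, 4))
})

test_that("omnibus test is calibrated under the null", {
  set.seed(11)
  rej <- mean(replicate(400, {
    g <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30))
    kruskal_conover(g)$omnibus$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.03)
})

test_that("Levene agrees with the reference implementation", {
  set.seed(1)
  x <- rnorm(40)
  y <- rnorm(35, sd = 2)
  lv <- levene_pairwise(list(x = x, y = y), center = "mean")
  ct <- car::leveneTest(c(x, y), factor(rep(1:2, c(40, 35))), center = mean)
  expect_equal(lv$statistic["x", "y"], ct$`F value`[1], tolerance = 1e-10)
  expect_equal(lv$p_value["x", "y"], ct$`Pr(>F)`[1], tolerance = 1e-10)
  # Brown-Forsythe variant
  lvm <- levene_pairwise(list(x = x, y = y), center = "median")
  ctm <- car::leveneTest(c(x, y), factor(rep(1:2, c(40, 35))),
                         center = median)
  expect_equal(lvm$p_value["x", "y"], ctm$`Pr(>F)`[1], tolerance = 1e-10)
  # identical groups: W = 0, p = 1
  l0 <- levene_pairwise(list(a = rep(1, 5), b = rep(3, 6)))
  expect_equal(l0$statistic["a", "b"], 0)
  expect_equal(l0$p_value["a", "b"], 1)
})

test_that("Levene detects planted variance ratios", {
  set.seed(5)
  ps <- replicate(30, {
    g <- list(a = rnorm(100, sd = 1), b = rnorm(100, sd = 3))
    levene_pairwise(g)$p_value["a", "b"]
  })
  expect_true(all(ps < 0.005))
})

test_that("Mann-Whitney exact enumeration matches known values", {
  mw <- mannwhitney_pairwise(list(a = c(1, 2), b = c(3, 4)))
  expect_equal(mw$statistic["a", "b"], 0)
  expect_equal(mw$p_value["a", "b"], 1 / 3, tolerance = 1e-12)
  # U_A + U_B = n_A * n_B
  set.seed(2)
  g <- list(a = rnorm(6), b = rnorm(7))
  mm <- mannwhitney_pairwise(g)
  expect_equal(mm$statistic["a", "b"] + mm$statistic["b", "a"], 42)
  # cross-check against wilcox.test exact p on tie-free data
  wt <- wilcox.test(g$a, g$b, exact = TRUE)
  expect_equal(mm$p_value["a", "b"], wt$p.value, tolerance = 1e-10)
  # identical samples -> p = 1
  mi <- mannwhitney_pairwise(list(a = c(2, 2, 2), b = c(2, 2, 2)))
  expect_equal(mi$p_value["a", "b"], 1)
})

test_that("volume-range restriction uses closed bounds", {
  tb <- data.frame(cell_id = 1:3, volume = c(40, 60, 300))
  class(tb) <- c("cell_feature_table", "data.frame")
  kept <- restrict_volume_range(tb, 50, 298)
  expect_identical(kept$cell_id, 2L)
  # boundary value is retained
  tb2 <- data.frame(cell_id = 1:2, volume = c(50, 49.999))
  expect_identical(restrict_volume_range(tb2, 50, 500)$cell_id, 1L)
  expect_identical(nrow(restrict_volume_range(tb, 0, Inf)), 3L)
  expect_equal(attr(restrict_volume_range(tb, 50, 298),
                    "provenance")$volume_range, c(50, 298))
  expect_error(restrict_volume_range(tb, 10, 5), "lo < hi")
  rng <- shared_volume_ranges()
  expect_equal(rng$initial_bud, c(50, 298))
  expect_equal(rng$t_bud, c(50, 500))
})

test_that("distribution summaries report the documented statistics", {
  ds <- distribution_summary(c(1, 2, 3))
  expect_equal(ds$mean, 2)
  expect_equal(ds$median, 2)
  expect_equal(ds$sd, 1)
  expect_equal(sum(ds$histogram$count), 3)
  # symmetric sample: skewness near 0 (sampling oracle)
  set.seed(9)
  dn <- distribution_summary(rnorm(1e4))
  expect_lt(abs(dn$skewness), 0.05)
  # shared bin edges across groups
  gs <- distribution_summaries(list(a = rnorm(100), b = rnorm(100, 2)))
  expect_identical(gs$a$histogram$mid, gs$b$histogram$mid)
  expect_equal(sum(gs$a$histogram$count), 100)
})
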