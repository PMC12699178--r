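# Stage-level statistics: pooled summaries, rank-based omnibus and post hoc
# tests, variance tests, shared-range comparisons, distribution summaries.
# Standard tests go through base R (kruskal.test, wilcox.test, oneway.test);
# the Conover-Iman post hoc is implemented here and validated against an
# exhaustive permutation oracle in the test-suite.

#' Count-weighted pooled mean
#'
#' Combines per-tip means into the cohort mean, weighting each tip by its
#' cell count: `sum(count_i * mean_i) / sum(count_i)`.
#'
#' @param means per-tip means.
#' @param counts per-tip cell counts (positive integers).
#' @return The pooled mean.
#' @examples
#' pooled_mean(c(222.24, 233.62, 107.09), c(501, 257, 200)) # 201.25
#' @export
pooled_mean <- function(means, counts) {
  if (length(means) != length(counts))
    stop("means and counts differ in length", call. = FALSE)
  if (any(counts <= 0)) stop("counts must be > 0", call. = FALSE)
  sum(counts * means) / sum(counts)
}

as_group_list <- function(groups) {
  if (is.data.frame(groups))
    stop("pass a named list of numeric vectors", call. = FALSE)
  if (!is.list(groups)) stop("groups must be a list", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  lapply(groups, as.numeric)
}

#' Kruskal-Wallis omnibus with Conover-Iman post hoc
#'
#' Tie-corrected Kruskal-Wallis H across all groups, followed by the
#' Conover-Iman pairwise t-statistics on the joint ranks,
#' `t = (Rbar_i - Rbar_j) / sqrt(S2 * ((N - 1 - H) / (N - k)) *
#' (1/n_i + 1/n_j))` with `S2 = (sum R^2 - N (N+1)^2 / 4) / (N - 1)`,
#' referred to a t distribution on `N - k` degrees of freedom and adjusted
#' by Holm step-down.  For small cohorts an exact permutation p-value
#' (enumeration of all group relabelings) is available.
#'
#' @param groups named list of numeric vectors (one per stage), each with
#'   at least 2 values.
#' @param p_adjust adjustment for the pairwise matrix (see
#'   [stats::p.adjust()]); default `"holm"`.
#' @param p_method `"asymptotic"` (default) or `"permutation"` (exact
#'   enumeration; feasible only for small total N).
#' @return List of class `kruskal_conover`: `omnibus` (statistic, p_value,
#'   df, method), `pairwise` (statistic, p_value, p_adjusted matrices with
#'   unit diagonal), `N`, `k`.
#' @export
kruskal_conover <- function(groups, p_adjust = "holm",
                            p_method = c("asymptotic", "permutation")) {
  p_method <- match.arg(p_method)
  groups <- as_group_list(groups)
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2))
    stop("every group needs at least 2 values", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kw <- suppressWarnings(kruskal.test(x, g))
  H <- unname(kw$statistic)
  if (!is.finite(H)) H <- 0 # all values tied
  N <- length(x)
  k <- length(groups)
  r <- rank(x)
  Rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  scale2 <- S2 * (N - 1 - H) / (N - k)
  stat <- p <- matrix(NA_real_, k, k, dimnames = list(names(groups),
                                                      names(groups)))
  diag(stat) <- 0
  diag(p) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(pmax(scale2, 0) * (1 / n[i] + 1 / n[j]))
    t_ij <- if (se == 0) 0 else (Rbar[i] - Rbar[j]) / se
    stat[i, j] <- stat[j, i] <- t_ij
    p[i, j] <- p[j, i] <- 2 * pt(abs(t_ij), df = N - k, lower.tail = FALSE)
  }
  omnibus_p <- unname(kw$p.value)
  if (!is.finite(omnibus_p)) omnibus_p <- 1
  if (p_method == "permutation") {
    perm <- kw_permutation(groups)
    omnibus_p <- perm$omnibus
    p[] <- perm$pairwise
    diag(p) <- 1
  }
  upper <- upper.tri(p)
  padj <- p
  padj[upper] <- p.adjust(p[upper], method = p_adjust)
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  structure(list(
    omnibus = list(statistic = H, p_value = omnibus_p, df = k - 1,
                   method = paste0("Kruskal-Wallis (", p_method, ")")),
    pairwise = list(statistic = stat, p_value = p, p_adjusted = padj,
                    method = paste("Conover-Iman,", p_adjust)),
    N = N, k = k), class = "kruskal_conover")
}

# Exact permutation reference distribution: enumerate all distinct
# assignments of the pooled values to the group sizes.
kw_permutation <- function(groups, max_perm = 2e5) {
  x <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  k <- length(n)
  N <- sum(n)
  total <- prod(choose(cumsum(n)[k:1], n[k:1]))
  if (total > max_perm)
    stop("too many permutations for exact enumeration (", total, ")",
         call. = FALSE)
  idx_all <- seq_len(N)
  assigns <- list(list(rest = idx_all, take = list()))
  for (gi in seq_len(k - 1)) {
    nxt <- list()
    for (a in assigns) {
      cmb <- combn(a$rest, n[gi], simplify = FALSE)
      for (cc in cmb)
        nxt[[length(nxt) + 1]] <- list(rest = setdiff(a$rest, cc),
                                       take = c(a$take, list(cc)))
    }
    assigns <- nxt
  }
  conover_t <- function(xs, gs) {
    r <- rank(xs)
    Rbar <- tapply(r, gs, mean)
    ti <- tapply(r, gs, length)
    S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
    Hn <- kw_h(r, gs)
    sc <- S2 * (N - 1 - Hn) / (N - k)
    tt <- matrix(0, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      se <- sqrt(pmax(sc, 0) * (1 / ti[i] + 1 / ti[j]))
      tt[i, j] <- tt[j, i] <- if (se == 0) 0 else
        abs(Rbar[i] - Rbar[j]) / se
    }
    tt
  }
  g_obs <- factor(rep(seq_len(k), n))
  H_obs <- kw_h(rank(x), g_obs)
  t_obs <- conover_t(x, g_obs)
  geH <- 0
  geT <- matrix(0, k, k)
  for (a in assigns) {
    perm_idx <- c(unlist(a$take), a$rest)
    inv <- integer(N)
    inv[perm_idx] <- seq_len(N)
    xs <- x[perm_idx]
    Hp <- kw_h(rank(xs), g_obs)
    if (Hp >= H_obs - 1e-12) geH <- geH + 1
    tp <- conover_t(xs, g_obs)
    geT <- geT + (tp >= t_obs - 1e-12)
  }
  npm <- length(assigns)
  list(omnibus = geH / npm, pairwise = geT / npm)
}

# tie-corrected Kruskal-Wallis H from precomputed ranks
kw_h <- function(r, g) {
  N <- length(r)
  Rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(n * (Rbar - (N + 1) / 2)^2)
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr <= 0) return(0)
  H / corr
}

#' Pairwise Levene tests of variance
#'
#' Classic Levene W (mean-centred absolute deviations, one-way F test) for
#' every pair of groups; `center = "median"` gives the Brown-Forsythe
#' variant.  When all deviations vanish in both groups the pair is reported
#' as p = 1.
#'
#' @param groups named list of numeric vectors (>= 2 values each).
#' @param center `"mean"` (classic) or `"median"` (Brown-Forsythe).
#' @return List with symmetric `statistic` and `p_value` matrices (diagonal
#'   0 / 1).
#' @export
levene_pairwise <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- as_group_list(groups)
  if (any(lengths(groups) < 2))
    stop("every group needs at least 2 values", call. = FALSE)
  k <- length(groups)
  cf <- if (center == "mean") mean else median
  stat <- p <- matrix(NA_real_, k, k,
                      dimnames = list(names(groups), names(groups)))
  diag(stat) <- 0
  diag(p) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    di <- abs(groups[[i]] - cf(groups[[i]]))
    dj <- abs(groups[[j]] - cf(groups[[j]]))
    if (max(di, dj) < 1e-300) {
      stat[i, j] <- stat[j, i] <- 0
      p[i, j] <- p[j, i] <- 1
      next
    }
    d <- c(di, dj)
    g <- factor(rep(c("a", "b"), c(length(di), length(dj))))
    ft <- oneway.test(d ~ g, var.equal = TRUE)
    stat[i, j] <- stat[j, i] <- unname(ft$statistic)
    p[i, j] <- p[j, i] <- unname(ft$p.value)
  }
  list(statistic = stat, p_value = p, method = paste0("Levene (", center,
                                                      "-centred)"))
}

#' Pairwise Mann-Whitney tests
#'
#' Two-sided rank-sum test for every pair of groups.  When both samples
#' have at most `exact_max` values the p-value is computed by exhaustive
#' enumeration of all splits (ties handled by mid-counts, two-sided by
#' doubling the smaller tail, capped at 1); otherwise the normal
#' approximation with tie and continuity correction is used
#' ([stats::wilcox.test()]).
#'
#' @param groups named list of numeric vectors.
#' @param exact_max largest per-group size for exact enumeration.
#' @return List with symmetric `statistic` (U of the first group) and
#'   `p_value` matrices.
#' @export
mannwhitney_pairwise <- function(groups, exact_max = 8) {
  groups <- as_group_list(groups)
  if (any(lengths(groups) < 1))
    stop("every group needs at least 1 value", call. = FALSE)
  k <- length(groups)
  stat <- p <- matrix(NA_real_, k, k,
                      dimnames = list(names(groups), names(groups)))
  diag(p) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    res <- mw_test(groups[[i]], groups[[j]], exact_max)
    stat[i, j] <- res$U
    stat[j, i] <- length(groups[[i]]) * length(groups[[j]]) - res$U
    p[i, j] <- p[j, i] <- res$p
  }
  list(statistic = stat, p_value = p, method = "Mann-Whitney (two-sided)")
}

mw_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

mw_test <- function(a, b, exact_max) {
  na <- length(a)
  nb <- length(b)
  U <- mw_u(a, b)
  if (na <= exact_max && nb <= exact_max) {
    pool <- c(a, b)
    splits <- combn(na + nb, na, simplify = FALSE)
    us <- vapply(splits, function(ix) mw_u(pool[ix], pool[-ix]), numeric(1))
    p_lo <- mean(us <= U + 1e-12)
    p_hi <- mean(us >= U - 1e-12)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    p <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    if (!is.finite(p)) p <- 1
  }
  list(U = U, p = p)
}

#' Restrict a feature table to a shared volume range
#'
#' Keeps cells whose volume lies in the closed interval `[lo, hi]`.  Used
#' before pairwise Mann-Whitney comparisons so cohorts are compared within
#' a common cell-volume window; the bounds are recorded in the table's
#' provenance.
#'
#' @param table a `cell_feature_table`.
#' @param lo,hi volume bounds (um^3), `lo < hi`.
#' @return The filtered table.
#' @export
restrict_volume_range <- function(table, lo, hi) {
  if (lo >= hi) stop("need lo < hi", call. = FALSE)
  out <- table[table$volume >= lo & table$volume <= hi, , drop = FALSE]
  prov <- attr(table, "provenance")
  prov$volume_range <- c(lo, hi)
  attr(out, "provenance") <- prov
  class(out) <- class(table)
  out
}

#' Shared volume windows for stage-vs-cohort comparisons
#'
#' The per-stage cell-volume windows (um^3) used when comparing cohorts
#' within a common range.
#'
#' @return Named list of `c(lo, hi)` per stage.
#' @export
shared_volume_ranges <- function() {
  list(initial_bud = c(50, 298), ampulla = c(50, 490),
       asymmetric_ampulla = c(50, 272), t_bud = c(50, 500))
}

#' Distribution summary of a feature
#'
#' Mean, median, sd, adjusted Fisher-Pearson skewness, and a histogram on
#' the supplied (or data-driven) bin edges.  When called through
#' [distribution_summaries()] all groups share the same bin edges so their
#' histograms overlay.
#'
#' @param x numeric vector (>= 2 values).
#' @param breaks histogram bin edges; default `pretty` over the range.
#' @return List with `mean`, `median`, `sd`, `skewness`, `histogram`
#'   (data.frame mid, count).
#' @export
distribution_summary <- function(x, breaks = NULL) {
  if (length(x) < 2) stop("need at least 2 values", call. = FALSE)
  if (is.null(breaks)) breaks <- pretty(range(x), n = 20)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  list(mean = mean(x), median = median(x), sd = sd(x),
       skewness = e1071::skewness(x, type = 2),
       histogram = data.frame(mid = h$mids, count = h$counts))
}

#' @rdname distribution_summary
#' @param groups named list of numeric vectors; bins are shared across
#'   groups.
#' @export
distribution_summaries <- function(groups, breaks = NULL) {
  groups <- as_group_list(groups)
  if (is.null(breaks)) breaks <- pretty(range(unlist(groups)), n = 20)
  lapply(groups, distribution_summary, breaks = breaks)
}
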