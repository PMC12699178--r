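# Shared fixtures, memoised so expensive volumes are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# digitize a (possibly rotated) solid ellipsoid into a logical mask
digitize_ellipsoid <- function(semi, voxel_size, rot = diag(3), pad = 1) {
  ext <- max(semi) + pad
  nz <- ceiling(2 * ext / voxel_size[1])
  ny <- ceiling(2 * ext / voxel_size[2])
  nx <- ceiling(2 * ext / voxel_size[3])
  z <- (seq_len(nz) - (nz + 1) / 2) * voxel_size[1]
  y <- (seq_len(ny) - (ny + 1) / 2) * voxel_size[2]
  x <- (seq_len(nx) - (nx + 1) / 2) * voxel_size[3]
  Z <- array(z, c(nz, ny, nx))
  Y <- array(rep(y, each = nz), c(nz, ny, nx))
  X <- array(rep(x, each = nz * ny), c(nz, ny, nx))
  U <- rot[1, 1] * Z + rot[2, 1] * Y + rot[3, 1] * X
  V <- rot[1, 2] * Z + rot[2, 2] * Y + rot[3, 2] * X
  W <- rot[1, 3] * Z + rot[2, 3] * Y + rot[3, 3] * X
  (U / semi[1])^2 + (V / semi[2])^2 + (W / semi[3])^2 <= 1
}

rot3 <- function(axis, angle) {
  c1 <- cos(angle); s1 <- sin(angle)
  if (axis == "z") matrix(c(1, 0, 0, 0, c1, -s1, 0, s1, c1), 3, 3)
  else if (axis == "y") matrix(c(c1, 0, s1, 0, 1, 0, -s1, 0, c1), 3, 3)
  else matrix(c(c1, -s1, 0, s1, c1, 0, 0, 0, 1), 3, 3)
}

# two 5 um spheres with a continuous 0.4 um membrane between them,
# everything else membrane ("sealed"): for marker counting
two_sphere_sealed <- function() memo_fixture("tss_sealed", {
  vs <- c(0.2, 0.2, 0.2)
  n <- c(40, 40, 68)
  ctr1 <- c(4, 4, 4); ctr2 <- c(4, 4, 9.4) # gap 0.4 between surfaces
  z <- (seq_len(n[1]) - 0.5) * vs[1]
  y <- (seq_len(n[2]) - 0.5) * vs[2]
  x <- (seq_len(n[3]) - 0.5) * vs[3]
  Z <- array(z, n); Y <- array(rep(y, each = n[1]), n)
  X <- array(rep(x, each = n[1] * n[2]), n)
  d1 <- sqrt((Z - ctr1[1])^2 + (Y - ctr1[2])^2 + (X - ctr1[3])^2)
  d2 <- sqrt((Z - ctr2[1])^2 + (Y - ctr2[2])^2 + (X - ctr2[3])^2)
  p <- array(1, n)
  p[d1 <= 2.5 | d2 <= 2.5] <- 0
  list(prob = prob_volume(p, vs), d1 = d1, d2 = d2)
})

# same two spheres but with a finite membrane shell and open exterior: for
# watershed volume recovery.  The 0.4 um band is centred 0.1 um outside the
# sphere surface so that, after the one-voxel watershed line is excluded,
# each basin ends at the truth surface.
two_sphere_shell <- function() memo_fixture("tss_shell", {
  s <- two_sphere_sealed()
  vs <- voxel_size(s$prob)
  d <- pmin(s$d1, s$d2)
  prob_volume(array((d > 2.4 & d <= 2.8) + 0, dim(s$prob)), vs)
})

small_bud <- function() memo_fixture("bud10",
  generate_tip_tissue(tissue_spec("initial_bud", n_cells = 10, seed = 5)))

small_trunk <- function() memo_fixture("trunk2",
  generate_tip_tissue(tissue_spec("trunk", n_cells = 2, seed = 3)))

# independent shoelace implementation (oracle)
shoelace_oracle <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + x[i] * y[j] - x[j] * y[i]
  }
  abs(s) / 2
}

# independent tie-corrected Kruskal-Wallis H (oracle)
kw_h_oracle <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) *
                 (mean(ri) - (N + 1) / 2)^2))
  tie <- table(r)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

cpp_label26_test <- function(mask) {
  ubmorph:::cpp_label26(as.logical(mask), dim(mask))
}
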