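# Grid data model, trilinear sampling, boolean mask algebra, margin
# expansion and centroids, each checked against independent brute-force
# oracles on small random instances.

trilinear_oracle <- function(values, grid, pt) {
  idx <- (pt - grid$origin) / grid$spacing
  i0 <- pmin(pmax(floor(idx), 0), grid$shape - 2)
  f <- idx - i0
  out <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
         (if (dz) f[3] else 1 - f[3])
    out <- out + w * values[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  out
}

test_that("grid3d enforces its invariants", {
  g <- grid3d(c(4, 5, 6), c(1, 2, 3), c(-1, 0, 1))
  expect_equal(g$shape, c(4L, 5L, 6L))
  expect_error(grid3d(c(4, 5, 0)), "shape")
  expect_error(grid3d(c(4, 5, 5), spacing = c(0, 1, 1)),
               "non-positive spacing")
  expect_error(grid3d(c(4, 5, 5), origin = c(NA, 0, 0)), "origin")
})

test_that("trilinear sampling reproduces voxel values and convexity", {
  g <- small_grid(8, spacing = c(2, 2, 2), origin = c(-3, 0, 5))
  vol <- random_volume(g, unit = "Gy", seed = 11)
  centers <- dosewarp:::voxel_centers(g)
  pick <- centers[c(1, 37, 200, 511), , drop = FALSE]
  got <- sample_trilinear(vol, pick)
  expect_equal(got, as.numeric(vol$values)[c(1, 37, 200, 511)])

  const <- scalar_volume(array(7.5, g$shape), g, "Gy")
  set.seed(2)
  inner <- cbind(runif(20, -1, 8), runif(20, 2, 11), runif(20, 7, 16))
  expect_equal(sample_trilinear(const, inner), rep(7.5, 20))
})

test_that("trilinear sampling matches the 8-neighbour oracle on random points", {
  g <- small_grid(9, spacing = c(1.5, 2, 2.5), origin = c(-4, -4, -4))
  vol <- random_volume(g, unit = "HU", seed = 3)
  set.seed(4)
  lo <- g$origin
  hi <- g$origin + (g$shape - 1) * g$spacing
  pts <- cbind(runif(120, lo[1], hi[1]), runif(120, lo[2], hi[2]),
               runif(120, lo[3], hi[3]))
  got <- sample_trilinear(vol, pts)
  want <- vapply(seq_len(nrow(pts)), function(i)
    trilinear_oracle(vol$values, g, pts[i, ]), numeric(1))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("out-of-grid sampling follows the unit policy", {
  g <- small_grid(5)
  dose <- random_volume(g, unit = "Gy", seed = 5)
  far <- matrix(c(100, 100, 100), 1)
  expect_equal(sample_trilinear(dose, far), 0)
  ct <- scalar_volume(dose$values, g, "HU")
  edge_val <- sample_trilinear(ct, matrix(c(4, 4, 4), 1))
  expect_equal(sample_trilinear(ct, far), edge_val)
})

test_that("boolean mask operations match a voxel-loop oracle", {
  g <- small_grid(20)
  a <- random_mask(g, 0.4, seed = 21, name = "a")
  b <- random_mask(g, 0.4, seed = 22, name = "b")
  expect_equal(mask_boolean(a, b, "union")$member, a$member | b$member)
  expect_equal(mask_boolean(a, b, "intersection")$member,
               a$member & b$member)
  expect_equal(mask_boolean(a, b, "difference")$member,
               a$member & !b$member)
  expect_equal(mask_boolean(a, a, "union")$member, a$member)
  expect_true(all(mask_boolean(a, b, "difference")$member <= a$member))
  g2 <- grid3d(c(20, 20, 20), spacing = c(2, 2, 2))
  expect_error(mask_boolean(a, random_mask(g2, 0.4, seed = 1)),
               "grid mismatch")
})

test_that("volume decomposition is conserved exactly", {
  g <- small_grid(15, spacing = c(1.7, 2.1, 0.9))
  liver <- random_mask(g, 0.7, seed = 31, name = "liver")
  target <- random_mask(g, 0.2, seed = 32, name = "T")
  expect_identical(
    sum(mask_boolean(liver, target, "difference")$member) +
      sum(mask_boolean(liver, target, "intersection")$member),
    sum(liver$member))
  expect_equal(
    volume_cc(mask_boolean(liver, target, "difference")) +
      volume_cc(mask_boolean(liver, target, "intersection")),
    volume_cc(liver))
})

test_that("margin expansion equals brute-force Euclidean dilation", {
  g <- grid3d(c(15, 15, 15), spacing = c(1, 1, 1))
  m <- array(FALSE, c(15, 15, 15))
  m[8, 8, 8] <- TRUE
  single <- structure_mask(m, g, "seed")
  got <- expand_margin(single, 5)
  ia <- dosewarp:::index_arrays(g$shape)
  dist <- sqrt((ia$x - 7)^2 + (ia$y - 7)^2 + (ia$z - 7)^2)
  expect_equal(got$member, dist <= 5 + 1e-9)

  # random mask on an anisotropic grid, exhaustive distance oracle
  g2 <- grid3d(c(12, 12, 12), spacing = c(1, 1.5, 2))
  rm <- random_mask(g2, 0.05, seed = 41)
  got2 <- expand_margin(rm, 3)
  centers <- dosewarp:::voxel_centers(g2)
  member_pts <- centers[as.vector(rm$member), , drop = FALSE]
  want <- apply(centers, 1, function(p)
    any(sqrt(colSums((t(member_pts) - p)^2)) <= 3 + 1e-9))
  expect_equal(as.vector(got2$member), want)
})

test_that("margin expansion is the identity at zero and monotone in margin", {
  g <- small_grid(12, spacing = c(2, 2, 2))
  m <- random_mask(g, 0.1, seed = 51)
  expect_equal(expand_margin(m, 0)$member, m$member)
  e3 <- expand_margin(m, 3)$member
  e5 <- expand_margin(m, 5)$member
  expect_true(all(m$member <= e3))
  expect_true(all(e3 <= e5))
  expect_error(expand_margin(m, -1), "non-negative")
})

test_that("centroid is the mean of member voxel centres", {
  g <- grid3d(c(10, 10, 10), spacing = c(1, 1, 1), origin = c(0, 0, 0))
  m <- array(FALSE, c(10, 10, 10))
  m[3, 4, 5] <- TRUE
  expect_equal(unname(mask_centroid(structure_mask(m, g))), c(2, 3, 4))

  cube <- array(FALSE, c(10, 10, 10))
  cube[3:6, 3:6, 3:6] <- TRUE
  expect_equal(unname(mask_centroid(structure_mask(cube, g))),
               c(3.5, 3.5, 3.5))

  rm <- random_mask(g, 0.3, seed = 61)
  centers <- dosewarp:::voxel_centers(g)
  expect_equal(unname(mask_centroid(rm)),
               colMeans(centers[as.vector(rm$member), , drop = FALSE]),
               tolerance = 1e-9)
  empty <- structure_mask(array(FALSE, c(10, 10, 10)), g)
  expect_error(mask_centroid(empty), "empty mask")
})

test_that("ITV/PTV construction nests the target volumes", {
  g <- small_grid(24, spacing = c(2, 2, 2))
  ia <- dosewarp:::index_arrays(g$shape)
  sphere <- function(c0, r) {
    structure_mask(sqrt((ia$x * 2 - c0[1])^2 + (ia$y * 2 - c0[2])^2 +
                        (ia$z * 2 - c0[3])^2) <= r, g, "GTV")
  }
  gtv_a <- sphere(c(20, 20, 16), 8)
  gtv_b <- sphere(c(20, 20, 26), 8)   # 10 mm SI shift
  tg <- build_targets(gtv_a, gtv_b, margin_mm = 5)
  expect_true(all(gtv_a$member <= tg$itv$member))
  expect_true(all(gtv_b$member <= tg$itv$member))
  expect_true(all(tg$itv$member <= tg$ptv$member))
  expect_lt(volume_cc(gtv_a), volume_cc(tg$itv))
  expect_lt(volume_cc(tg$itv), volume_cc(tg$ptv))

  # identical extreme phases: ITV reduces to the GTV
  same <- build_targets(gtv_a, gtv_a, margin_mm = 5)
  expect_equal(same$itv$member, gtv_a$member)

  # disjoint copies under union mode: volumes add
  gtv_c <- sphere(c(20, 20, 38), 4)
  gtv_d <- sphere(c(20, 20, 10), 4)
  expect_equal(volume_cc(build_targets(gtv_c, gtv_d)$itv),
               volume_cc(gtv_c) + volume_cc(gtv_d))

  # intersection mode honours the alternative ITV reading
  inter <- build_targets(gtv_a, gtv_b, itv_mode = "intersection")
  expect_true(all(inter$itv$member <= gtv_a$member))
})
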