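# Shared fixtures: small grids, a down-scaled phantom, and a smooth blob
# pair with a known rigid shift. Everything is generated in code under
# fixed seeds.

small_grid <- function(n = 10L, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  grid3d(rep(n, 3L), spacing, origin)
}

random_volume <- function(grid, unit = "Gy", seed = 1, smooth = 0) {
  set.seed(seed)
  v <- array(runif(prod(grid$shape), 0, 50), dim = grid$shape)
  if (smooth > 0) v <- dosewarp:::gauss_smooth(v, rep(smooth, 3))
  scalar_volume(v, grid, unit = unit)
}

random_mask <- function(grid, p = 0.3, seed = 1, name = "roi") {
  set.seed(seed)
  structure_mask(array(runif(prod(grid$shape)) < p, dim = grid$shape),
                 grid, name)
}

# Down-scaled liver phantom (40^3 at 4 mm) used wherever the full 96^3
# default would be wastefully slow.
tiny_spec <- function(...) {
  phantom_spec(shape = c(40L, 40L, 40L), spacing = c(4, 4, 4),
               body_radii = c(70, 62, 74), liver_radii = c(40, 32, 36),
               liver_center = c(5, 0, 5), tumor_center = c(5, 0, 20),
               tumor_radius = 13, ...)
}

tiny_motion <- function(...) {
  motion_model(amplitude = c(lr = 1, ap = 1.5, si = 8), ...)
}

# Smooth body-like blob with an intensity gradient spanning the
# registration HU window, optionally shifted along SI.
blob_volume <- function(n = 32L, spacing = 3, shift_si = 0, radius = 45) {
  g <- grid3d(rep(n, 3L), rep(spacing, 3L), rep(-spacing * (n - 1) / 2, 3L))
  pts <- dosewarp:::voxel_centers(g)
  r2 <- pts[, 1]^2 + pts[, 2]^2 + (pts[, 3] - shift_si)^2
  hu <- 300 - 500 * r2 / radius^2
  hu[r2 > radius^2] <- -1000
  scalar_volume(array(hu, g$shape), g, "HU")
}

blob_interior <- function(vol, radius = 40) {
  pts <- dosewarp:::voxel_centers(vol$grid)
  array(sqrt(pts[, 1]^2 + pts[, 2]^2 + pts[, 3]^2) < radius, vol$grid$shape)
}

expect_same_volume <- function(a, b, tol = 0) {
  expect_equal(a$values, b$values, tolerance = tol)
  expect_equal(a$grid$spacing, b$grid$spacing)
  expect_equal(a$grid$origin, b$grid$origin)
}
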