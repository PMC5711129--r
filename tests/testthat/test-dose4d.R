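# Dose warping, accumulation, AIP, phase subsets and difference summaries.

test_that("warping with a zero field is the identity", {
  g <- small_grid(10, spacing = c(3, 3, 3))
  dose <- random_volume(g, "Gy", seed = 1)
  zero <- vector_field(array(0, g$shape), array(0, g$shape),
                       array(0, g$shape), g)
  expect_equal(warp_dose(dose, zero)$values, dose$values)
})

test_that("a one-voxel uniform shift reproduces the shifted volume in the interior", {
  g <- small_grid(10, spacing = c(2, 2, 3))
  dose <- random_volume(g, "Gy", seed = 2)
  u <- vector_field(array(0, g$shape), array(0, g$shape),
                    array(3, g$shape), g)   # +1 voxel along SI
  got <- warp_dose(dose, u)
  # output(x) = dose(x + one voxel SI): interior slices shift down by one
  expect_equal(got$values[, , 1:9], dose$values[, , 2:10])
  expect_equal(got$values[, , 10], array(0, c(10, 10)))
})

test_that("warping matches the per-voxel displaced-sampling oracle on a random smooth field", {
  g <- small_grid(16, spacing = c(2, 2, 2))
  dose <- random_volume(g, "Gy", seed = 3, smooth = 1)
  set.seed(4)
  mk <- function() dosewarp:::gauss_smooth(array(rnorm(prod(g$shape), sd = 3),
                                                 g$shape), rep(2, 3))
  dvf <- vector_field(mk(), mk(), mk(), g)
  got <- warp_dose(dose, dvf)
  pts <- dosewarp:::voxel_centers(g) +
    cbind(as.vector(dvf$ux), as.vector(dvf$uy), as.vector(dvf$uz))
  want <- sample_trilinear(dose, pts, policy = "constant", fill = 0)
  expect_equal(as.numeric(got$values), want, tolerance = 1e-9)
  # convexity: warped dose stays within [0, max(input)]
  expect_gte(min(got$values), 0)
  expect_lte(max(got$values), max(dose$values) + 1e-12)
})

test_that("accumulation is the weighted voxel mean", {
  g <- small_grid(8)
  d0 <- scalar_volume(array(0, g$shape), g, "Gy")
  d10 <- scalar_volume(array(10, g$shape), g, "Gy")
  expect_equal(accumulate_dose(list(d10, d10, d10))$values, d10$values)
  expect_equal(accumulate_dose(list(d0, d10), c(0.5, 0.5))$values,
               array(5, g$shape))
  doses <- lapply(1:10, function(i) random_volume(g, "Gy", seed = 40 + i))
  acc <- accumulate_dose(doses)
  want <- Reduce(`+`, lapply(doses, `[[`, "values")) / 10
  expect_equal(acc$values, want, tolerance = 1e-12)
  vox_min <- Reduce(pmin, lapply(doses, `[[`, "values"))
  vox_max <- Reduce(pmax, lapply(doses, `[[`, "values"))
  expect_true(all(acc$values >= vox_min - 1e-12 &
                  acc$values <= vox_max + 1e-12))
  expect_error(accumulate_dose(doses, rep(0.2, 10)), "sum to 1")
  expect_error(accumulate_dose(doses, rep(0.1, 9)), "one entry per dose")
})

test_that("phase subsets list exactly the standard reduced schemes", {
  expect_equal(phase_subset("p2")$members, c("0%", "50%"))
  expect_equal(phase_subset("p3")$members, c("30%", "60%", "90%"))
  expect_equal(phase_subset("p5even")$members,
               c("0%", "20%", "40%", "60%", "80%"))
  expect_equal(phase_subset("p5odd")$members,
               c("10%", "30%", "50%", "70%", "90%"))
  expect_equal(phase_subset("p10")$members, phase_labels(10))
  expect_equal(sum(phase_subset("p3")$weights), 1)
  expect_error(phase_subset("p7"))
})

test_that("the AIP is the unweighted phase mean", {
  g <- small_grid(8)
  a <- scalar_volume(array(0, g$shape), g, "HU")
  b <- scalar_volume(array(100, g$shape), g, "HU")
  expect_equal(average_intensity_projection(list(a, b))$values,
               array(50, g$shape))
  expect_equal(average_intensity_projection(list(b, b))$values, b$values)
  cts <- lapply(1:10, function(i) random_volume(g, "HU", seed = 60 + i))
  want <- Reduce(`+`, lapply(cts, `[[`, "values")) / 10
  expect_equal(average_intensity_projection(cts)$values, want,
               tolerance = 1e-12)
})

test_that("maximum point difference is the masked max-abs percentage", {
  g <- small_grid(9)
  roi <- random_mask(g, 0.3, seed = 70, name = "liver")
  zeros <- structure(list(values = array(0, g$shape), grid = g,
                          unit = "Gy"), class = "scalar_volume")
  expect_equal(max_point_difference_pct(zeros, roi, 42), 0)
  one <- array(0, g$shape)
  idx <- which(roi$member)[1]
  one[idx] <- 42
  v1 <- structure(list(values = one, grid = g, unit = "Gy"),
                  class = "scalar_volume")
  expect_equal(max_point_difference_pct(v1, roi, 42), 100)
  a <- random_volume(g, "Gy", seed = 71)
  b <- random_volume(g, "Gy", seed = 72)
  diff <- dose_difference_map(a, b)
  expect_equal(max_point_difference_pct(diff, roi, 42),
               100 * max(abs((a$values - b$values)[roi$member])) / 42)
  empty <- structure_mask(array(FALSE, g$shape), g)
  expect_error(max_point_difference_pct(diff, empty, 42), "empty ROI")
})

test_that("accumulating true-field warps reproduces the analytic oracle", {
  spec <- tiny_spec()
  mm <- tiny_motion()
  ref <- generate_phase_masks(spec, mm, "50%")
  tg <- build_targets(ref$gtv, generate_phase_masks(spec, mm, "0%")$gtv, 5)
  dose <- generate_static_dose(spec, dose_model(), tg$ptv)
  warped <- lapply(phase_labels(10), function(ph)
    warp_dose(dose, true_displacement_field(spec, mm, ph)))
  acc <- accumulate_dose(warped)
  oracle <- ground_truth_accumulated_dose(mm, dose, spec = spec)
  err <- abs(acc$values - oracle$values)
  liver <- ref$liver$member
  # pure interpolation budget: < 0.5% of prescription at >= 99% of liver
  expect_gte(mean(err[liver] <= 0.005 * 42), 0.99)
})
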