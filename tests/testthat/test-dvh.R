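# DVH computation, Dx extraction, HI, BED and motion-vector arithmetic.
# Printed worked-example values are asserted at their printed precision.

test_that("the cumulative DVH is exact for uniform and two-level doses", {
  g <- small_grid(10)
  m <- structure_mask(array(TRUE, g$shape), g, "roi")
  uni <- scalar_volume(array(10, g$shape), g, "Gy")
  dvh <- compute_dvh(uni, m, bin_width = 0.01)
  expect_equal(dvh$fraction[1], 1)
  expect_true(all(diff(dvh$fraction) <= 0))
  expect_equal(dvh$fraction[dvh$dose <= 10 + 1e-9], rep(1, 1001))
  expect_equal(dvh$fraction[dvh$dose > 10 + 1e-9][1], 0)

  two <- array(10, g$shape)
  two[1:5, , ] <- 20
  dv2 <- compute_dvh(scalar_volume(two, g, "Gy"), m, 0.01)
  expect_equal(dv2$fraction[abs(dv2$dose - 5) < 1e-9], 1)
  expect_equal(dv2$fraction[abs(dv2$dose - 15) < 1e-9], 0.5)
  expect_equal(dv2$fraction[abs(dv2$dose - 20.01) < 1e-9], 0)
  expect_error(compute_dvh(uni, structure_mask(array(FALSE, g$shape), g)),
               "empty mask")
})

test_that("DVH fractions match a count-above-threshold oracle at every edge", {
  g <- small_grid(12)
  dose <- random_volume(g, "Gy", seed = 7)
  m <- random_mask(g, 0.5, seed = 8)
  dvh <- compute_dvh(dose, m, bin_width = 0.25)
  v <- dose$values[m$member]
  want <- vapply(dvh$dose, function(d) mean(v >= d), numeric(1))
  expect_equal(dvh$fraction, want)
  expect_equal(attr(dvh, "total_volume_cc"), volume_cc(m))
})

test_that("Dx agrees with a sorted-percentile oracle within one bin width", {
  g <- small_grid(10)
  m <- structure_mask(array(TRUE, g$shape), g)
  uni <- scalar_volume(array(10, g$shape), g, "Gy")
  dvh <- compute_dvh(uni, m)
  expect_equal(dose_at_volume(dvh, c(2, 50, 98)), rep(10, 3),
               tolerance = 0.011)

  two <- array(10, g$shape)
  two[1:5, , ] <- 20
  dv2 <- compute_dvh(scalar_volume(two, g, "Gy"), m)
  expect_equal(dose_at_volume(dv2, 98), 10, tolerance = 0.011)
  expect_equal(dose_at_volume(dv2, 2), 20, tolerance = 0.011)

  dose <- random_volume(g, "Gy", seed = 9)
  dvr <- compute_dvh(dose, m, bin_width = 0.02)
  v <- sort(dose$values, decreasing = TRUE)
  for (x in c(2, 50, 95, 98)) {
    oracle <- v[ceiling(length(v) * x / 100)]
    expect_lt(abs(dose_at_volume(dvr, x) - oracle), 0.02 + 1e-9)
  }
  # monotone in x
  dx <- dose_at_volume(dvr, c(2, 50, 95, 98))
  expect_true(all(diff(dx) <= 0))
  expect_error(dose_at_volume(dvr, 0), "x_percent")
})

test_that("mean dose is the member-voxel average", {
  g <- small_grid(6)
  m2 <- array(FALSE, g$shape)
  m2[1, 1, 1] <- m2[2, 1, 1] <- TRUE
  v <- array(0, g$shape)
  v[2, 1, 1] <- 10
  expect_equal(mean_dose(scalar_volume(v, g, "Gy"),
                         structure_mask(m2, g)), 5)
  dose <- random_volume(g, "Gy", seed = 10)
  m <- random_mask(g, 0.4, seed = 11)
  expect_equal(mean_dose(dose, m), mean(dose$values[m$member]),
               tolerance = 1e-12)
})

test_that("the homogeneity index reproduces printed worked examples", {
  expect_equal(round(homogeneity_index(46.7, 36.8), 2), 1.27)
  expect_equal(round(homogeneity_index(55.6, 46.3), 2), 1.20)
  expect_equal(homogeneity_index(12, 12), 1)
  expect_error(homogeneity_index(10, 0), "positive")
})

test_that("the HI percentage ratio reproduces printed worked examples", {
  expect_equal(round(hi_ratio_percent(1.27, 1.51), 1), 84.1)
  expect_equal(round(hi_ratio_percent(1.37, 1.64), 1), 83.5)
  expect_equal(hi_ratio_percent(1.2, 1.2), 100)
  expect_error(hi_ratio_percent(1.2, 0), "positive")
})

test_that("BED reproduces printed worked examples and its limits", {
  expect_equal(round(bed(45.3, 6, 10), 1), 79.5)
  expect_equal(round(bed(55.3, 5, 10), 1), 116.5)
  expect_equal(bed(0, 6, 10), 0)
  # alpha/beta -> Inf reduces BED to the physical dose
  expect_lt(abs(bed(48, 6, 1e6) - 48), 0.01)
})

test_that("DVH-based BED reduces to the closed form for uniform dose", {
  g <- small_grid(8)
  m <- structure_mask(array(TRUE, g$shape), g, "GTV")
  sch <- fractionation(6, 10)
  uni <- scalar_volume(array(45.3, g$shape), g, "Gy")
  out <- bed_from_dvh(compute_dvh(uni, m), sch)
  expect_equal(round(out$bed_mean, 1), 79.5)
  sch5 <- fractionation(5, 10)
  uni2 <- scalar_volume(array(55.3, g$shape), g, "Gy")
  expect_equal(round(bed_from_dvh(compute_dvh(uni2, m), sch5)$bed_mean, 1),
               116.5)
  zero <- scalar_volume(array(0, g$shape), g, "Gy")
  expect_equal(bed_from_dvh(compute_dvh(zero, m), sch)$bed_mean, 0,
               tolerance = 0.01)
  # volume-weighted over the differential DVH for a mixed dose
  mix <- array(40, g$shape)
  mix[1:4, , ] <- 50
  got <- bed_from_dvh(compute_dvh(scalar_volume(mix, g, "Gy"), m), sch)
  want <- 0.5 * bed(40, 6, 10) + 0.5 * bed(50, 6, 10)
  expect_equal(got$bed_mean, want, tolerance = 0.02)
  expect_error(fractionation(6, 0), "positive")
})

test_that("fractional-volume ratios behave on reference and scaled curves", {
  g <- small_grid(10)
  m <- structure_mask(array(TRUE, g$shape), g, "PTV")
  dose <- random_volume(g, "Gy", seed = 12, smooth = 1)
  dvh <- compute_dvh(dose, m)
  same <- dvh_fractional_volume_ratio(dvh, dvh)
  expect_equal(attr(same, "max_abs_deviation"), 0)
  scaled <- dvh
  scaled$fraction <- dvh$fraction * 0.9
  attr_sp <- attributes(dvh)
  for (a in setdiff(names(attr_sp), c("names", "row.names")))
    attr(scaled, a) <- attr_sp[[a]]
  r <- dvh_fractional_volume_ratio(scaled, dvh)
  expect_equal(unique(round(r$ratio, 9)), 0.9)
  expect_equal(attr(r, "max_abs_deviation"), 0.1, tolerance = 1e-9)
})

test_that("the centroid motion vector reproduces printed magnitudes", {
  # SI/AP/LR components printed with their r3D magnitudes
  b <- motion_vector(c(0, 0, 0), c(1.0, 0.5, 10.5))
  expect_equal(round(b$r3d_mm, 1), 10.6)
  expect_equal(b$si_mm, 10.5)
  d <- motion_vector(c(0, 0, 0), c(1.2, 1.8, 16.5))
  expect_equal(round(d$r3d_mm, 1), 16.6)
  zero <- motion_vector(c(3, 4, 5), c(3, 4, 5))
  expect_equal(zero$r3d_mm, 0)
})

test_that("percentile ordering and HI >= 1 hold on random dose/structure pairs", {
  g <- small_grid(12)
  for (s in 1:5) {
    dose <- random_volume(g, "Gy", seed = 80 + s, smooth = s %% 3)
    m <- random_mask(g, 0.5, seed = 90 + s)
    met <- dose_metrics(dose, m, scheme = fractionation(6, 10))
    expect_gte(met$d2_gy + 1e-9, met$d50_gy)
    expect_gte(met$d50_gy + 1e-9, met$d95_gy)
    expect_gte(met$d95_gy + 1e-9, met$d98_gy)
    expect_gte(met$hi, 1 - 1e-9)
  }
})
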