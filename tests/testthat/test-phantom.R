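# Synthetic 4D phantom generator: analytic displacements, phase CTs and
# masks, conformal static dose, and the analytic accumulated-dose oracle.

test_that("forward displacement vanishes at the reference phase and scales with the waveform", {
  mm <- motion_model(amplitude = c(1.0, 1.6, 10.5))
  pts <- rbind(c(20, 0, 10), c(-40, 20, -30), c(0, 0, 0))
  expect_equal(forward_displacement(mm, "50%", pts),
               matrix(0, 3, 3), ignore_attr = TRUE)
  # at the tumour centre of the default phantom the envelope is 1 and the
  # 0% waveform weight is 1, so the displacement equals the amplitude
  d0 <- forward_displacement(mm, "0%", rbind(c(20, 0, 35)))
  expect_equal(as.numeric(d0), c(1.0, 1.6, 10.5), tolerance = 1e-12)
  expect_error(forward_displacement(mm, "55%", pts), "unknown phase")
})

test_that("the waveform satisfies its boundary constraints", {
  for (wf in c("cosine", "cos4")) {
    mm <- motion_model(waveform = wf)
    expect_equal(unname(mm$w[["50%"]]), 0)
    expect_equal(max(mm$w), 1)
    expect_equal(unname(mm$w[["0%"]]), 1)
  }
})

test_that("phase CT generation is deterministic and respects zero amplitude", {
  spec <- tiny_spec()
  mm <- tiny_motion()
  a <- generate_phase_ct(spec, mm, "20%", seed = 9)
  b <- generate_phase_ct(spec, mm, "20%", seed = 9)
  expect_identical(a$values, b$values)
  c2 <- generate_phase_ct(spec, mm, "20%", seed = 10)
  expect_false(identical(a$values, c2$values))

  spec0 <- tiny_spec(noise_sd = 0)
  still <- motion_model(amplitude = c(0, 0, 0))
  expect_identical(generate_phase_ct(spec0, still, "0%", 1)$values,
                   generate_phase_ct(spec0, still, "50%", 1)$values)
})

test_that("the displaced tumour blob is recoverable from the phase CT", {
  spec <- tiny_spec(noise_sd = 0)
  mm <- tiny_motion()
  ct0 <- generate_phase_ct(spec, mm, "0%", seed = 1)
  ctr <- generate_phase_ct(spec, mm, "50%", seed = 1)
  blob <- function(ct) {
    m <- structure_mask(ct$values > 80, ct$grid, "blob")
    mask_centroid(m)
  }
  shift <- blob(ct0) - blob(ctr)
  expect_equal(unname(shift), unname(mm$amplitude),
               tolerance = 0.5 * max(spec$grid$spacing))
})

test_that("phase masks keep the tumour inside the liver with stable volume", {
  spec <- tiny_spec()
  mm <- tiny_motion()
  vols <- numeric(0)
  for (ph in phase_labels(10)) {
    ms <- generate_phase_masks(spec, mm, ph)
    expect_true(all(ms$gtv$member <= ms$liver$member))
    expect_true(all(ms$liver$member <= ms$body$member))
    vols <- c(vols, volume_cc(ms$gtv))
  }
  expect_lt(diff(range(vols)) / mean(vols), 0.05)
  ref <- generate_phase_masks(spec, mm, "50%")
  pts <- dosewarp:::voxel_centers(spec$grid)
  r <- sqrt((pts[, 1] - 5)^2 + pts[, 2]^2 + (pts[, 3] - 20)^2)
  expect_equal(ref$gtv$member,
               array(r <= spec$tumor_radius, spec$grid$shape))
})

test_that("the tumour centroid trajectory tracks amplitude times waveform", {
  spec <- tiny_spec()
  mm <- tiny_motion()
  ref <- mask_centroid(generate_phase_masks(spec, mm, "50%")$gtv)
  half_voxel <- max(spec$grid$spacing) / 2
  for (ph in c("0%", "20%", "70%")) {
    ck <- mask_centroid(generate_phase_masks(spec, mm, ph)$gtv)
    want <- mm$w[[ph]] * mm$amplitude
    expect_lt(max(abs((ck - ref) - want)), half_voxel)
  }
})

test_that("the static dose has the prescribed core, coverage and tail", {
  spec <- tiny_spec()
  mm <- tiny_motion()
  ref <- generate_phase_masks(spec, mm, "50%")
  tg <- build_targets(ref$gtv, generate_phase_masks(spec, mm, "0%")$gtv, 5)
  dm <- dose_model(prescription = 42, n_fractions = 6)
  dose <- generate_static_dose(spec, dm, tg$ptv)
  expect_equal(max(dose$values), 42 / 0.8)
  # deep inside the PTV the dose is the maximum dose
  expect_equal(dose$values[round((5 - spec$grid$origin[1]) / 4) + 1,
                           round(-spec$grid$origin[2] / 4) + 1,
                           round((20 - spec$grid$origin[3]) / 4) + 1],
               52.5)
  d95 <- dose_at_volume(compute_dvh(dose, tg$ptv), 95)
  expect_lt(abs(d95 - 42) / 42, 0.02)
  expect_true(all(dose$values >= 0))

  # pure conformal component: Gaussian tail far from the PTV
  dm0 <- dose_model(halo_fraction = 0)
  dose0 <- generate_static_dose(spec, dm0, tg$ptv)
  pts <- dosewarp:::voxel_centers(spec$grid)
  far <- sqrt((pts[, 1] - 5)^2 + pts[, 2]^2 + (pts[, 3] - 20)^2) >
    (spec$tumor_radius + 13 + 5 * dm0$penumbra_sigma)
  expect_lt(max(dose0$values[array(far, spec$grid$shape)]),
            0.001 * max(dose0$values))
  expect_error(generate_static_dose(spec, dm,
    structure_mask(array(FALSE, spec$grid$shape), spec$grid)), "empty PTV")
})

test_that("ground-truth accumulation is exact in its degenerate cases", {
  spec <- tiny_spec()
  mm <- tiny_motion()
  ref <- generate_phase_masks(spec, mm, "50%")
  tg <- build_targets(ref$gtv, generate_phase_masks(spec, mm, "0%")$gtv, 5)
  dose <- generate_static_dose(spec, dose_model(), tg$ptv)

  still <- motion_model(amplitude = c(0, 0, 0))
  acc0 <- ground_truth_accumulated_dose(still, dose, spec = spec)
  expect_equal(acc0$values, dose$values, tolerance = 1e-12)

  # single phase with weight 1: equals direct sampling at displaced points
  acc1 <- ground_truth_accumulated_dose(mm, dose, phases = "0%",
                                        weights = 1, spec = spec)
  pts <- dosewarp:::voxel_centers(spec$grid)
  d <- forward_displacement(mm, "0%", pts, spec)
  want <- sample_trilinear(dose, pts + d, policy = "constant", fill = 0)
  expect_equal(as.numeric(acc1$values), want, tolerance = 1e-9)

  expect_error(ground_truth_accumulated_dose(mm, dose,
    weights = rep(0.2, 10), spec = spec), "sum to 1")
})

test_that("equal-weighted accumulation blurs the superior field edge", {
  spec <- tiny_spec()
  mm <- tiny_motion()
  ref <- generate_phase_masks(spec, mm, "50%")
  tg <- build_targets(ref$gtv, generate_phase_masks(spec, mm, "0%")$gtv, 5)
  dose <- generate_static_dose(spec, dose_model(), tg$ptv)
  acc <- ground_truth_accumulated_dose(mm, dose, spec = spec)
  g <- spec$grid
  ix <- round((5 - g$origin[1]) / 4) + 1
  iy <- round(-g$origin[2] / 4) + 1
  width_2080 <- function(v) {
    p <- v[ix, iy, ]
    zmm <- g$origin[3] + (seq_along(p) - 1) * 4
    pm <- max(p)
    cross <- function(level, from) {
      i <- min(which(seq_along(p) > from & p <= level * pm))
      # linear interpolation on the falling segment [i-1, i]
      zmm[i - 1] + (p[i - 1] - level * pm) / (p[i - 1] - p[i]) * 4
    }
    i80 <- max(which(p >= 0.8 * pm))
    cross(0.2, i80) - cross(0.8, i80 - 1)
  }
  expect_gt(width_2080(acc$values), width_2080(dose$values))
})
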