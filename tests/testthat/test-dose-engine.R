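test_that("radiological depth matches closed-form expectations", {
  d <- c(40, 20, 20)
  sp <- c(4, 4, 4)
  uni <- voxel_grid(array(1, dim = d), sp)
  # 100 mm geometric path in unit density, along +x well inside the grid
  src <- c(20, 38, 38)
  pt <- c(120, 38, 38)
  expect_lt(abs(radiological_depth(uni, src, pt) - 100) / 100, 0.01)
  # half density halves the water-equivalent depth
  half <- voxel_grid(array(0.5, dim = d), sp)
  expect_lt(abs(radiological_depth(half, src, pt) - 50) / 50, 0.01)
  # a 20 mm near-void slab removes ~20 * (1 - RED_gas) mm
  red_gas <- 0.05
  slab <- uni
  slab$data[16:20, , ] <- red_gas   # x in [60, 76) -> 20 mm on the ray
  expected <- 100 - 20 * (1 - red_gas)
  expect_lt(abs(radiological_depth(slab, src, pt) - expected), 2)
  # ray fully outside the grid contributes nothing
  expect_equal(radiological_depth(uni, c(0, -500, 0), c(100, -500, 0)), 0)
})

test_that("fraction dose is deterministic and normalised to the prescription", {
  p <- generate_planning_phantom(small_spec(noise = FALSE), seed = 1)
  red <- apply_hured_curve(build_hured_curve(), p$hu)
  a <- compute_fraction_dose(red, beam_config(), p$labels$masks$ptv)
  b <- compute_fraction_dose(red, beam_config(), p$labels$masks$ptv)
  expect_identical(a$dose$data, b$dose$data)
  expect_equal(median(a$dose$data[p$labels$masks$ptv]), 2)
  expect_true(all(a$dose$data >= 0))
  expect_true(all(is.finite(a$dose$data)))
  expect_error(compute_fraction_dose(red, beam_config(),
                                     array(FALSE, dim = dim(red$data))),
               "PTV")
})

test_that("zero attenuation gives a uniform field inside the aperture", {
  p <- generate_planning_phantom(small_spec(noise = FALSE), seed = 1)
  red <- apply_hured_curve(build_hured_curve(), p$hu)
  d0 <- compute_fraction_dose(red, beam_config(mu_eff = 0),
                              p$labels$masks$ptv)
  # deep inside the aperture (central half of the PTV, away from the
  # penumbra) the unattenuated field is flat
  sp <- p$spec
  dgrid <- dim(red$data)
  co <- arrayInd(seq_len(prod(dgrid)), dgrid) - 1
  w <- sweep(co, 2, red$spacing, `*`)
  core <- ((w[, 1] - sp$ptv$centre[1]) / (0.45 * sp$ptv$semi[1]))^2 +
    ((w[, 2] - sp$ptv$centre[2]) / (0.45 * sp$ptv$semi[2]))^2 +
    ((w[, 3] - sp$ptv$centre[3]) / (0.45 * sp$ptv$semi[3]))^2 <= 1
  core_dose <- d0$dose$data[array(core, dim = dgrid)]
  expect_lt(diff(range(core_dose)) / median(core_dose), 0.02)
})

test_that("depth dose is monotone along a single beam in homogeneous density", {
  d <- c(48, 32, 24)
  sp <- c(4, 4, 4)
  red <- voxel_grid(array(1, dim = d), sp)
  ptv <- array(FALSE, dim = d)
  ptv[20:28, 12:20, 8:16] <- TRUE
  # single beam: gantry angle 0 places the source on the +x side, so dose
  # along the central axis must fall off with increasing depth (-x)
  dose <- compute_fraction_dose(red, beam_config(n_beams = 1, mu_eff = 0.005),
                                ptv)
  iso_idx <- round((dose$isocentre / sp)) + 1
  profile <- dose$dose$data[6:43, iso_idx[2], iso_idx[3]]
  expect_true(all(diff(profile) >= -1e-9))
})

test_that("bowel-gas expansion never decreases PTV near-maximum dose", {
  p <- generate_planning_phantom(mid_spec(noise = FALSE), seed = 2)
  curve <- build_hured_curve()
  red_p <- apply_hured_curve(curve, p$hu)
  plan <- compute_fraction_dose(red_p, beam_config(), p$labels$masks$ptv)
  d2 <- numeric(0)
  d003 <- numeric(0)
  for (target in c(0, 20, 40, 60, 80)) {
    fx <- generate_fraction(p, target, seed = 9, hu_noise = FALSE)
    red_f <- apply_hured_curve(curve, fx$hu)
    fd <- compute_fraction_dose(red_f, beam_config(), fx$labels$masks$ptv,
                                scale = plan$scale)
    ep <- endpoint_set(compute_dvh(fd$dose, p$labels$masks$ptv),
                       compute_dvh(fd$dose, p$labels$masks$wb))
    d2 <- c(d2, ep$D2)
    d003 <- c(d003, ep$D0.03cc)
  }
  expect_true(all(diff(d2) >= -1e-9))
  # the bowel hotspot next to the pockets heats up strictly
  expect_true(all(diff(d003) >= -1e-9))
  expect_gt(d003[length(d003)], d003[1])
})
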