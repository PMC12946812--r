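rot_matrix <- function(ax, ay, az) {
  rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

test_that("rigid landmark alignment recovers known motions", {
  pts <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 80, 0), c(20, 30, 60))
  # identity
  t0 <- rigid_align(pts, pts)
  expect_equal(t0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(t0$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(t0$residual_mm, 0, tolerance = 1e-9)
  # pure translation: moving = fixed + (5,0,0) needs translation (-5,0,0)
  t1 <- rigid_align(sweep(pts, 2, c(5, 0, 0), `+`), pts)
  expect_equal(t1$translation, c(-5, 0, 0), tolerance = 1e-6)
  expect_equal(t1$rotation, diag(3), tolerance = 1e-9)
  # random rigid motion, recovered to numerical precision
  set.seed(8)
  rot <- rot_matrix(0.2, -0.35, 0.5)
  trans <- c(4, -7, 2)
  moved <- t(rot %*% t(pts)) + matrix(trans, 4, 3, byrow = TRUE)
  t2 <- rigid_align(pts, moved)
  expect_equal(t2$rotation, rot, tolerance = 1e-9)
  expect_equal(t2$translation, trans, tolerance = 1e-9)
  expect_lt(t2$residual_mm, 1e-9)
  # inverse composes to identity
  inv <- invert_rigid(t2)
  expect_equal(apply_rigid(inv, apply_rigid(t2, pts)), pts,
               tolerance = 1e-9)
  # degenerate landmarks
  line <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(rigid_align(line, line), "collinear")
  expect_error(rigid_align(pts[1:2, ], pts[1:2, ]), "at least 3")
})

test_that("pull-back warping honours identity, constants and shifts", {
  set.seed(5)
  d <- c(12, 10, 8)
  sp <- c(4, 4, 4)
  dose <- voxel_grid(array(runif(prod(d), 0, 2), dim = d), sp)
  zero <- array(0, dim = c(d, 3))
  expect_equal(warp_dose(dose, zero)$data, dose$data, tolerance = 1e-12)

  # constant fields are invariant under any in-grid smooth deformation
  const <- voxel_grid(array(1.7, dim = d), sp)
  smooth <- zero
  smooth[, , , 1] <- 3 * sin(seq(0, pi, length.out = d[1]))
  inner <- suppressWarnings(warp_dose(const, smooth))
  core <- inner$data[2:10, 2:9, 2:7]
  expect_true(all(abs(core - 1.7) < 1e-9))

  # an exact one-voxel translation equals an index shift
  shift <- zero
  shift[, , , 1] <- sp[1]
  w <- suppressWarnings(warp_dose(dose, shift))
  expect_equal(w$data[1:(d[1] - 1), , ], dose$data[2:d[1], , ],
               tolerance = 1e-12)
  expect_equal(w$data[d[1], , ], matrix(0, d[2], d[3]))  # out-of-grid fill

  # DVF geometry mismatch is an error
  expect_error(warp_dose(dose, zero[1:6, , , , drop = FALSE]), "mismatch")
})

test_that("inverse warp restores a smooth deformation within tolerance", {
  set.seed(6)
  d <- c(20, 20, 16)
  sp <- c(4, 4, 4)
  co <- arrayInd(seq_len(prod(d)), d) - 1
  # smooth dose field so interpolation error stays small
  vals <- 2 * exp(-((co[, 1] - 10)^2 + (co[, 2] - 10)^2 +
                      (co[, 3] - 8)^2) / 60)
  dose <- voxel_grid(array(vals, dim = d), sp)
  u <- array(0, dim = c(d, 3))
  u[, , , 1] <- array(1.5 * sin(co[, 1] / 6) * cos(co[, 2] / 5), dim = d)
  u[, , , 2] <- array(1.2 * cos(co[, 3] / 4), dim = d)
  fwd <- suppressWarnings(warp_dose(dose, u))
  back <- suppressWarnings(warp_dose(fwd, -u))
  inner <- abs(back$data - dose$data)[3:18, 3:18, 3:14]
  expect_lt(sqrt(mean(inner^2)), 0.02 * max(dose$data))
})

test_that("accumulation is an element-wise sum with linearity", {
  d <- c(6, 5, 4)
  sp <- c(4, 4, 4)
  uniform <- voxel_grid(array(2, dim = d), sp)
  acc <- accumulate_dose(rep(list(uniform), 25))
  expect_true(all(abs(acc$dose$data - 50) < 1e-12))
  expect_equal(nrow(acc$ledger), 25)

  single <- accumulate_dose(list(uniform))
  expect_equal(single$dose$data, uniform$data)

  set.seed(9)
  doses <- lapply(1:7, function(i) {
    voxel_grid(array(runif(prod(d)), dim = d), sp)
  })
  total <- accumulate_dose(doses)$dose$data
  # brute-force per-voxel loop oracle
  oracle <- array(0, dim = d)
  for (dd in doses) for (i in seq_len(prod(d))) oracle[i] <- oracle[i] + dd$data[i]
  expect_equal(total, oracle, tolerance = 1e-12)
  # linearity: accumulate(a) + accumulate(b) = accumulate(a, b)
  a <- accumulate_dose(doses[1:3])$dose$data
  b <- accumulate_dose(doses[4:7])$dose$data
  expect_equal(a + b, total, tolerance = 1e-12)
  # geometry mismatch
  bad <- voxel_grid(array(1, dim = d), c(2, 2, 2))
  expect_error(accumulate_dose(list(uniform, bad)), "geometry")
})

test_that("QA gates pass ground truth and reject bad registrations", {
  p <- generate_planning_phantom(small_spec(), seed = 4)
  fx <- generate_fraction(p, 30, seed = 5)
  curve <- build_hured_curve()
  fd <- compute_fraction_dose(apply_hured_curve(curve, fx$hu),
                              beam_config(), fx$labels$masks$ptv)
  w_ref <- warp_dose(fd$dose, fx$dvf, p$hu)

  # ground-truth DVF: TRE ~ 0, gamma 100%
  qa <- qa_check(fx$dvf, p$landmarks, fx$landmarks, w_ref, w_ref)
  expect_true(qa$pass)
  expect_lt(qa$tre_mm, 1e-9)
  expect_equal(qa$gamma_pass_pct, 100)

  # +5 mm everywhere exceeds the 3 mm TRE gate
  bad_dvf <- fx$dvf
  bad_dvf[, , , 1] <- bad_dvf[, , , 1] + 5
  qa_bad <- qa_check(bad_dvf, p$landmarks, fx$landmarks, w_ref, w_ref)
  expect_false(qa_bad$pass)
  expect_gt(qa_bad$tre_mm, 3)
  expect_true(qa_bad$excluded)

  # uniform 8% dose-scale error on a flat region fails the gamma gate
  flat <- voxel_grid(array(2, dim = dim(p$hu$data)), p$hu$spacing)
  off <- voxel_grid(flat$data * 1.08, p$hu$spacing)
  qa_gamma <- qa_check(fx$dvf, p$landmarks, fx$landmarks, off, flat)
  expect_false(qa_gamma$pass)
  expect_lt(qa_gamma$gamma_pass_pct, 90)

  # a retry hook that repairs the dose passes on the second attempt
  fixed <- qa_check(fx$dvf, p$landmarks, fx$landmarks, off, flat,
                    retry_hook = function(attempt) list(warped_dose = flat))
  expect_true(fixed$pass)
  expect_equal(fixed$retries, 1L)
})
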