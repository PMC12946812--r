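uniform_dose <- function(gy, n_vox = 1000, spacing = c(4, 5, 5)) {
  # 4 x 5 x 5 mm voxels = 0.1 cc each
  d <- c(10, 10, 10)
  voxel_grid(array(gy, dim = d), spacing)
}

test_that("uniform dose produces the textbook DVH", {
  g <- uniform_dose(2)
  mask <- array(TRUE, dim = dim(g$data))   # 100 cc structure
  dvh <- compute_dvh(g, mask)
  expect_equal(dvh$structure_cc, 100)
  expect_equal(volume_at_dose(dvh, 1), 100)
  expect_equal(volume_at_dose(dvh, 2), 100)
  expect_equal(volume_at_dose(dvh, 2.1), 0)
  expect_error(compute_dvh(g, array(FALSE, dim = dim(g$data))), "empty")

  g50 <- voxel_grid(array(50, dim = c(10, 10, 20)), c(5, 5, 4))
  mask50 <- array(TRUE, dim = dim(g50$data))  # 200 cc
  dvh50 <- compute_dvh(g50, mask50)
  expect_equal(volume_at_dose(dvh50, 45), 200)
  expect_equal(dose_at_volume(dvh50, 2, "pct"), 50, tolerance = 0.06)
  expect_equal(dose_at_volume(dvh50, 98, "pct"), 50, tolerance = 0.06)
})

test_that("a linear ramp yields a linear cumulative curve and mid-ramp D50%", {
  n <- 50
  vals <- seq(0.5, 49.5, length.out = n)       # analytic ramp, 0.5..49.5 Gy
  g <- voxel_grid(array(rep(vals, times = 20), dim = c(n, 5, 4)),
                  c(2, 5, 5))
  mask <- array(TRUE, dim = dim(g$data))
  dvh <- compute_dvh(g, mask)
  # V(d) drops linearly: compare against the analytic survival fraction
  sel <- dvh$dose > 1 & dvh$dose < 49
  analytic <- dvh$structure_cc * (49.5 - dvh$dose[sel]) / 49 # ramp density
  expect_lt(max(abs(dvh$volume_cc[sel] - analytic)),
            dvh$structure_cc / n + 1e-9)
  expect_equal(dose_at_volume(dvh, 50, "pct"), 25, tolerance = 0.5)

  # halving the bin width moves endpoints by less than one (coarse) bin
  fine <- compute_dvh(g, mask, bin_width = 0.025)
  for (q in c(2, 50, 98)) {
    expect_lt(abs(dose_at_volume(dvh, q, "pct") -
                    dose_at_volume(fine, q, "pct")), 0.05)
  }
  expect_error(dose_at_volume(dvh, 150, "cc"), "exceeds")
})

test_that("endpoint sets obey ordering and scaling invariants", {
  set.seed(10)
  d <- c(12, 12, 10)
  dose <- voxel_grid(array(rgamma(prod(d), 40, 1), dim = d), c(4, 4, 4))
  ptv <- array(FALSE, dim = d); ptv[3:10, 3:10, 3:8] <- TRUE
  wb <- !ptv
  ep <- endpoint_set(compute_dvh(dose, ptv), compute_dvh(dose, wb))
  expect_gte(ep$D2, ep$D50)
  expect_gte(ep$D50, ep$D98)
  expect_gte(ep$D0.03cc, ep$D150cc)
  expect_gte(ep$V45, 0)
  expect_lte(ep$V45, sum(wb) * voxel_cc(dose))

  # scaling the dose by c scales D-endpoints by c and maps V45 to V(45/c)
  c_fac <- 1.25
  scaled <- voxel_grid(dose$data * c_fac, dose$spacing)
  eps <- endpoint_set(compute_dvh(scaled, ptv), compute_dvh(scaled, wb))
  for (nm in c("D2", "D50", "D98", "D0.03cc", "D150cc")) {
    expect_equal(eps[[nm]], c_fac * ep[[nm]], tolerance = 0.01)
  }
  expect_equal(eps$V45, volume_at_dose(compute_dvh(dose, wb), 45 / c_fac),
               tolerance = 0.02)
})

test_that("endpoint differencing reproduces the worked relative deviation", {
  planned <- list(Dmax = 51.79)
  delivered <- list(Dmax = 54.08)
  d <- dose_diffs(planned, delivered)
  expect_equal(d$delta, 54.08 - 51.79)
  expect_equal(round(d$delta_pct, 1), 4.4)

  same <- list(D2 = 52, D50 = 50)
  z <- dose_diffs(same, same)
  expect_true(all(z$delta == 0) && all(z$delta_pct == 0))

  d2 <- dose_diffs(list(D = 50), list(D = 49))
  expect_equal(d2$delta, -1)
  expect_equal(d2$delta_pct, -2)
  expect_error(dose_diffs(list(a = 1), list(b = 1)), "keys")
})

test_that("cohort summaries tally medians and threshold exceedances", {
  pats <- sprintf("P%02d", 1:10)
  tbl <- data.frame(patient = pats, endpoint = "D2",
                    delta = rep(1, 10), delta_pct = rep(2, 10))
  cs <- cohort_summary(tbl)
  expect_equal(cs$summary$median_delta, 1)
  ex <- cs$exceedance
  expect_equal(ex$n_exceed[ex$metric == "delta_gy" & ex$threshold == 1], 10)
  expect_equal(ex$n_exceed[ex$metric == "delta_gy" & ex$threshold == 2], 0)
  expect_equal(ex$n_exceed[ex$metric == "delta_pct" & ex$threshold == 2], 10)

  single <- cohort_summary(data.frame(patient = "P01", endpoint = "D2",
                                      delta = 0.7, delta_pct = 1.4))
  expect_equal(single$summary$median_delta, 0.7)

  # random deviations: counts match a direct tally
  set.seed(11)
  rnd <- data.frame(patient = pats, endpoint = "D0.03cc",
                    delta = rnorm(10, 1.5, 1), delta_pct = rnorm(10, 3, 2))
  cr <- cohort_summary(rnd)
  for (th in c(0.5, 1, 2, 3)) {
    expect_equal(cr$exceedance$n_exceed[cr$exceedance$metric == "delta_gy" &
                                          cr$exceedance$threshold == th],
                 sum(abs(rnd$delta) >= th))
  }
  expect_equal(cr$summary$median_delta, median(rnd$delta))
})
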