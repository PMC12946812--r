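test_that("Spearman correlation handles monotone, reversed and degenerate input", {
  x <- c(1, 3, 7, 9, 15, 20, 24, 30)
  y <- x^2 + 5
  s <- spearman_bca(x, y, n_boot = 200, seed = 1)
  expect_equal(s$rho, 1)
  s_rev <- spearman_bca(rev(x), y, n_boot = 200, seed = 1)
  expect_equal(s_rev$rho, -1)
  expect_error(spearman_bca(rep(1, 8), y), "constant")
  # seeded bootstrap is reproducible
  set.seed(99)
  xr <- rnorm(20); yr <- 0.5 * xr + rnorm(20)
  a <- spearman_bca(xr, yr, seed = 7)
  b <- spearman_bca(xr, yr, seed = 7)
  expect_identical(a$ci, b$ci)
  expect_true(a$ci[1] <= a$rho && a$rho <= a$ci[2])
})

test_that("Spearman null behaviour matches a Monte-Carlo oracle", {
  set.seed(4)
  rhos <- replicate(300, {
    spearman_bca(rnorm(28), rnorm(28), n_boot = 0 + 50, seed = 1)$rho
  })
  expect_lt(abs(mean(rhos)), 0.05)
  # null sd of Spearman's rho is ~ 1/sqrt(n - 1)
  expect_lt(abs(sd(rhos) - 1 / sqrt(27)), 0.05)
})

test_that("OLS slope is reported per 10% expansion with HC3 errors", {
  x <- c(-10, 0, 5, 12, 20, 28, 35, 50)
  y <- 0.03 * x                         # exact line: 0.30 Gy per 10%
  fit <- ols_slope_per10(x, y)
  expect_equal(fit$slope, 0.30, tolerance = 1e-12)
  expect_lt(abs(fit$p), 1e-9)

  flat <- ols_slope_per10(x, rep(1.5, 8))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$p, 1)
  expect_error(ols_slope_per10(rep(3, 5), rnorm(5)), "variance")

  # HC3 interval equals the sandwich/lmtest reference implementation
  set.seed(5)
  xr <- runif(28, -10, 60)
  yr <- 0.031 * xr + rnorm(28, 0, 0.4)
  ours <- ols_slope_per10(xr, yr)
  ref <- lm(yr ~ I(xr / 10))
  vc <- sandwich::vcovHC(ref, type = "HC3")
  expect_equal(ours$se, sqrt(vc[2, 2]), tolerance = 1e-12)
  expect_equal(ours$slope, unname(coef(ref)[2]), tolerance = 1e-12)
})

test_that("fixed-effects estimator equals dummy-variable OLS exactly", {
  # 4-patient toy panel with patient-specific intercepts and a time trend
  set.seed(6)
  panel <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(patient = paste0("P", i), fraction = 1:6,
               dvbc_pct = runif(6, -10, 50))
  }))
  alpha <- rep(c(0.1, -0.4, 0.8, 0.3), each = 6)
  panel$delta <- alpha + 0.04 * panel$dvbc_pct + 0.01 * panel$fraction +
    rnorm(24, 0, 0.1)
  fe <- fe_model(panel)
  dummy <- lm(delta ~ I(dvbc_pct / 10) + fraction + factor(patient),
              data = panel)
  expect_equal(fe$slope, unname(coef(dummy)[2]), tolerance = 1e-8)
  expect_equal(fe$trend, unname(coef(dummy)[3]), tolerance = 1e-8)

  # noise-free constructed panel recovers the injected slope exactly
  clean <- panel
  clean$delta <- alpha + 0.04 * clean$dvbc_pct
  fe_clean <- fe_model(clean)
  expect_equal(fe_clean$slope, 0.40, tolerance = 1e-10)

  # degenerate designs error out
  const <- panel
  const$dvbc_pct <- rep(rep(c(5, 10, 15, 20), each = 6))
  expect_error(fe_model(const), "within-patient variance")
  expect_error(fe_model(panel[panel$patient == "P1", ]), ">= 2 patients")
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.002, 0.04, 0.3, 0.01, 0.8)
  adj <- bh_fdr(p)
  expect_gte(min(adj - p), 0)
  # permutation invariance
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_fdr(p[perm]), adj[perm])
  expect_error(bh_fdr(c(0.5, 1.2)), "p")
})

test_that("the association table recovers injected slopes and adjusts p-values", {
  sim <- simulate_assoc_panel(n_patients = 20, n_fractions = 25, seed = 42)
  pt <- sim$patient_tbl
  pan <- sim$panel_tbl
  # widen to the five-endpoint layout expected by the table builder
  for (e in primary_endpoints()) {
    pt[[paste0("delta_", e)]] <- pt$delta
    pan[[paste0("delta_", e)]] <- pan$delta
  }
  tbl <- build_assoc_table(pt, pan, n_boot = 200, seed = 1)
  expect_equal(nrow(tbl), 5)
  expect_true(all(tbl$fe_lo <= sim$truth$fe_slope &
                    sim$truth$fe_slope <= tbl$fe_hi))
  expect_true(all(tbl$ols_lo <= sim$truth$ols_slope &
                    sim$truth$ols_slope <= tbl$ols_hi))
  expect_true(all(tbl$p_ols_fdr >= tbl$p_ols))
  expect_true(all(tbl$p_spearman_fdr >= tbl$p_spearman))

  pooled <- build_assoc_table(pt, pan, n_boot = 200, seed = 1,
                              fdr_family = "pooled")
  expect_true(all(pooled$p_ols_fdr >= tbl$p_ols))
})
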