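test_that("default planning phantom hits the PTV realism target", {
  p <- generate_planning_phantom(seed = 7)
  ptv_cc <- mask_volume_cc(p$labels$masks$ptv, p$hu)
  expect_lt(abs(ptv_cc - 1170) / 1170, 0.02)
  # structural invariants are enforced by the label-map validator; spot-check
  m <- p$labels$masks
  expect_false(any(m$ptv & m$wb))
  expect_false(any(m$ptv & m$bladder))
  expect_false(any(m$gas & !m$wb))
  expect_false(any(m$wb & !m$body))
})

test_that("phantom generation is deterministic and gas seeds are optional", {
  sp <- mid_spec()
  a <- generate_planning_phantom(sp, seed = 11)
  b <- generate_planning_phantom(sp, seed = 11)
  expect_identical(a$hu$data, b$hu$data)
  expect_identical(a$labels$masks$gas, b$labels$masks$gas)
  c <- generate_planning_phantom(sp, seed = 12)
  expect_false(identical(a$hu$data, c$hu$data))

  no_gas <- phantom_spec(grid_dim = c(32, 32, 24), scale = 0.5,
                         gas_pockets = data.frame(dx = numeric(0),
                                                  dy = numeric(0),
                                                  dz = numeric(0),
                                                  r = numeric(0)))
  p0 <- generate_planning_phantom(no_gas, seed = 1)
  expect_equal(sum(p0$labels$masks$gas), 0)
})

test_that("fraction generation realises the requested BC volume change", {
  p <- generate_planning_phantom(seed = 5)
  for (target in c(-30, -10, 20, 50, 80)) {
    fx <- generate_fraction(p, target, seed = 100 + target)
    expect_lt(abs(fx$realized_dvbc - target), 3)
    # displaced gas stays inside the whole-bowel label
    expect_false(any(fx$labels$masks$gas & !fx$labels$masks$wb))
  }
  expect_error(generate_fraction(p, -100), "exceed")
  expect_error(generate_fraction(p, 5000), "infeasible")
})

test_that("zero-change fraction is an identity deformation", {
  p <- generate_planning_phantom(mid_spec(noise = FALSE), seed = 5)
  fx <- generate_fraction(p, 0, seed = 5, bladder_delta_pct = 0,
                          hu_noise = FALSE)
  expect_identical(fx$labels$masks$gas, p$labels$masks$gas)
  expect_identical(fx$hu$data, p$hu$data)
  expect_lt(max(abs(fx$dvf)), min(p$hu$spacing))
})

test_that("true DVF reproduces fraction labels within one voxel and keeps bone rigid", {
  p <- generate_planning_phantom(mid_spec(), seed = 3)
  fx <- generate_fraction(p, 50, seed = 11, bladder_delta_pct = 3)
  # pull-back of the fraction gas mask with the ground-truth DVF must
  # recover the planning gas mask up to one voxel of interpolation error
  gm <- voxel_grid(array(as.numeric(fx$labels$masks$gas),
                         dim = dim(p$hu$data)), p$hu$spacing, p$hu$origin)
  rec <- warp_dose(gm, fx$dvf, p$hu)$data > 0.5
  mism <- which(xor(rec, p$labels$masks$gas))
  if (length(mism) > 0) {
    d <- dim(p$hu$data)
    mi <- arrayInd(mism, d)
    gi <- arrayInd(which(p$labels$masks$gas), d)
    mind <- vapply(seq_len(nrow(mi)), function(i) {
      min(apply(abs(t(gi) - mi[i, ]), 2, max))
    }, numeric(1))
    expect_lte(max(mind), 1 + 1e-9)
  }
  # landmarks (bone) are outside the deformation support
  disp <- sample_dvf(fx$dvf, p$hu, p$landmarks)
  expect_lte(max(sqrt(rowSums(disp^2))), 3)
})

test_that("generated cohorts respect the anatomical stability caps", {
  cfg <- cohort_config(n_patients = 3, n_fractions = 5,
                       dvbc_mean_range = c(-5, 45), seed = 9,
                       spec = mid_spec())
  recs <- generate_cohort(cfg, keep_grids = TRUE)
  expect_length(recs, 3)
  for (rec in recs) {
    expect_length(rec$anatomies, 5)
    vb_plan <- sum(rec$planning$labels$masks$bladder)
    vbody_plan <- sum(rec$planning$labels$masks$body)
    for (fx in rec$anatomies) {
      vb <- sum(fx$labels$masks$bladder)
      expect_lte(abs(vb - vb_plan) / vb_plan * 100, cfg$bladder_cap_pct)
      vbody <- sum(fx$labels$masks$body)
      expect_lte(abs(vbody - vbody_plan) / vbody_plan * 100,
                 cfg$body_cap_pct)
    }
  }
  # identical seeds reproduce the full sampling plan
  recs2 <- generate_cohort(cfg)
  expect_equal(recs2[[2]]$fractions, recs[[2]]$fractions)
  expect_equal(recs2[[1]]$planning_seed, recs[[1]]$planning_seed)
})

test_that("cohort manifest serialises the sampling plan", {
  cfg <- cohort_config(n_patients = 2, n_fractions = 3, seed = 4,
                       spec = small_spec())
  recs <- generate_cohort(cfg)
  path <- tempfile(fileext = ".json")
  write_cohort_manifest(recs, path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(m), 2)
  expect_equal(m$patient_id, c("P01", "P02"))
  expect_equal(m$fractions[[1]]$target_dvbc, recs[[1]]$fractions$target_dvbc)
})
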