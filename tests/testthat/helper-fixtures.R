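# shared fixtures: scaled-down phantoms and independent oracles

# half-size pelvis on a 32^3-ish grid: fast enough for end-to-end runs
small_spec <- function(noise = TRUE) {
  ns <- if (noise) list(gas = 30, soft = 12, urine = 8, bone = 30) else
    list(gas = 0, soft = 0, urine = 0, bone = 0)
  phantom_spec(grid_dim = c(32, 32, 24), scale = 0.5, hu_noise_sd = ns)
}

# ~0.62-scale pelvis: fine enough for cap / realisation checks
mid_spec <- function(noise = TRUE) {
  ns <- if (noise) list(gas = 30, soft = 12, urine = 8, bone = 30) else
    list(gas = 0, soft = 0, urine = 0, bone = 0)
  phantom_spec(grid_dim = c(48, 48, 36), scale = 0.62, hu_noise_sd = ns)
}

# pure-R trilinear interpolation (independent of the compiled kernel)
r_trilinear <- function(grid, pts, fill = 0) {
  d <- dim(grid$data)
  ix <- (pts[, 1] - grid$origin[1]) / grid$spacing[1]
  iy <- (pts[, 2] - grid$origin[2]) / grid$spacing[2]
  iz <- (pts[, 3] - grid$origin[3]) / grid$spacing[3]
  out <- rep(fill, nrow(pts))
  ok <- ix >= 0 & iy >= 0 & iz >= 0 &
    ix <= d[1] - 1 & iy <= d[2] - 1 & iz <= d[3] - 1
  x0 <- pmin(floor(ix[ok]), d[1] - 2) + 1
  y0 <- pmin(floor(iy[ok]), d[2] - 2) + 1
  z0 <- pmin(floor(iz[ok]), d[3] - 2) + 1
  fx <- ix[ok] - (x0 - 1); fy <- iy[ok] - (y0 - 1); fz <- iz[ok] - (z0 - 1)
  g <- grid$data
  at <- function(dx, dy, dz) g[cbind(x0 + dx, y0 + dy, z0 + dz)]
  out[ok] <-
    at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    at(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    at(1, 1, 0) * fx * fy * (1 - fz) +
    at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    at(1, 0, 1) * fx * (1 - fy) * fz +
    at(0, 1, 1) * (1 - fx) * fy * fz +
    at(1, 1, 1) * fx * fy * fz
  out
}

# brute-force gamma oracle: same definition as the package implementation
# (global normalisation, sub-voxel offset search) but written as plain
# vectorised R over the full offset set, with no sorting or early exit
gamma_oracle <- function(reference, evaluated, criteria, roi_mask = NULL) {
  d <- dim(reference$data)
  ref_max <- max(reference$data)
  tol <- criteria$dose_pct / 100 * ref_max
  cutoff <- criteria$cutoff_pct / 100 * ref_max
  if (is.null(roi_mask)) roi_mask <- array(TRUE, dim = d)
  r <- criteria$search_factor * criteria$dta_mm
  st <- criteria$dta_mm * criteria$step_frac
  gseq <- seq(-r, r, by = st)
  off <- as.matrix(expand.grid(gseq, gseq, gseq))
  off <- off[sqrt(rowSums(off^2)) <= r + 1e-9, , drop = FALSE]
  dist2 <- rowSums(off^2) / criteria$dta_mm^2
  idx <- which(roi_mask & reference$data >= cutoff)
  world <- (arrayInd(idx, d) - 1) %*% diag(reference$spacing) +
    matrix(reference$origin, length(idx), 3, byrow = TRUE)
  gam <- array(NA_real_, dim = d)
  for (j in seq_along(idx)) {
    pts <- sweep(off, 2, world[j, ], `+`)
    ev <- r_trilinear(evaluated, pts, fill = NA)
    gg <- dist2 + ((ev - reference$data[idx[j]]) / tol)^2
    gam[idx[j]] <- sqrt(min(gg, na.rm = TRUE))
  }
  list(gamma = gam,
       pass_rate = sum(gam <= 1, na.rm = TRUE) / length(idx) * 100)
}

# axis-aligned dose ramp on an isotropic grid (steep gradient along x)
ramp_grid <- function(n = 16, spacing = 2, max_dose = 10) {
  vals <- seq(0, max_dose, length.out = n)
  voxel_grid(array(rep(vals, times = n * n), dim = c(n, n, n)),
             spacing = rep(spacing, 3))
}
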