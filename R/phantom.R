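#' Phantom specification
#'
#' Describes the synthetic pelvic phantom: grid geometry, analytic organ
#' geometry (all in world mm) and representative HU per tissue.  The default
#' layout realises a desk-scale pelvis on a 64 x 64 x 48 grid at 4 mm
#' isotropic spacing: an elliptic body contour, a ~1170 cc PTV ellipsoid,
#' a bladder sphere, a rectum tube, bony columns (two femoral heads and a
#' sacral promontory, which double as rigid registration landmarks) and a
#' whole-bowel (WB) region superior-anterior to the PTV that hosts the
#' bowel-cavity gas pockets.
#'
#' Axes: x lateral, y anterior (small) to posterior (large), z inferior to
#' superior.  Organ masks are carved for disjointness with priority
#' PTV > bladder > rectum > bone > WB; gas is always the intersection of the
#' pocket spheres with the final WB mask, so gas is a subset of WB by
#' construction.
#'
#' @param grid_dim integer length-3 voxel counts (default `c(64, 64, 48)`).
#' @param spacing mm per axis (default 4 mm isotropic).
#' @param scale global geometry scale: every organ size and offset from the
#'   grid centre is multiplied by `scale`, so a half-size pelvis fits a
#'   32 x 32 x 24 grid (`scale = 0.5`) with all spatial relations intact.
#' @param ptv_semi_axes PTV ellipsoid semi-axes (mm) *before* scaling;
#'   defaults give ~1170 cc at `scale = 1`.
#' @param gas_pockets data.frame with columns `dx`, `dy`, `dz` (offsets
#'   from the grid centre, mm, before scaling) and `r` (radius, mm, before
#'   scaling); zero rows means no gas.
#' @param hu named list of representative HU values per tissue.
#' @param hu_noise_sd named list of Gaussian HU noise SDs (0 disables noise).
#' @param taper_mm distance (mm, before scaling) over which the
#'   pocket/bladder expansion displacement field decays to zero.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = c(64L, 64L, 48L),
                         spacing = c(4, 4, 4),
                         scale = 1,
                         ptv_semi_axes = c(85, 55, 59.75),
                         gas_pockets = default_gas_pockets(),
                         hu = list(air = -1000, gas = -950, soft = 35,
                                   urine = 12, bone = 700),
                         hu_noise_sd = list(gas = 30, soft = 12,
                                            urine = 8, bone = 30),
                         taper_mm = 45) {
  grid_dim <- as.integer(grid_dim)
  spacing <- as.numeric(spacing)
  extent <- (grid_dim - 1) * spacing
  ctr <- extent / 2
  s <- scale
  at <- function(dx, dy, dz) ctr + s * c(dx, dy, dz)
  gp <- gas_pockets
  if (!is.null(gp) && nrow(gp) > 0) {
    gp <- data.frame(x = ctr[1] + s * gp$dx, y = ctr[2] + s * gp$dy,
                     z = ctr[3] + s * gp$dz, r = s * gp$r)
  } else {
    gp <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                     r = numeric(0))
  }
  spec <- list(
    grid_dim = grid_dim,
    spacing = spacing,
    origin = c(0, 0, 0),
    scale = s,
    body = list(centre = ctr[1:2], semi = s * c(120, 96)),
    ptv = list(centre = at(0, 16, 6), semi = s * ptv_semi_axes),
    bladder = list(centre = at(0, -56, -54), r = s * 36),
    rectum = list(centre_xy = ctr[1:2] + s * c(0, 64), r = s * 11,
                  z_range = ctr[3] + s * c(-84, -39)),
    bone = list(
      femur_l = list(centre = at(-92, 0, -44), r = s * 20),
      femur_r = list(centre = at(92, 0, -44), r = s * 20),
      sacrum = list(centre = at(0, 72, 51), r = s * 16)),
    wb = list(centre = at(0, -18, 56), semi = s * c(88, 62, 40)),
    gas_pockets = gp,
    hu = hu,
    hu_noise_sd = hu_noise_sd,
    taper_mm = s * taper_mm,
    # constructor arguments, kept for exact serialisation round-trips
    params = list(scale = s, ptv_semi_axes = ptv_semi_axes,
                  gas_pockets = gas_pockets, taper_mm = taper_mm)
  )
  class(spec) <- "phantom_spec"
  spec
}

#' @rdname phantom_spec
#' @export
default_gas_pockets <- function() {
  data.frame(dx = c(-26, 29, 0), dy = c(-31, -26, -46),
             dz = c(41, 36, 46), r = c(15, 13, 11))
}

coord_arrays <- function(spec) {
  d <- spec$grid_dim
  sp <- spec$spacing
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  list(x = array(rep(xs, times = d[2] * d[3]), dim = d),
       y = array(rep(rep(ys, each = d[1]), times = d[3]), dim = d),
       z = array(rep(zs, each = d[1] * d[2]), dim = d))
}

sphere_mask <- function(co, centre, r) {
  (co$x - centre[1])^2 + (co$y - centre[2])^2 + (co$z - centre[3])^2 <= r^2
}

ellipsoid_mask <- function(co, centre, semi) {
  ((co$x - centre[1]) / semi[1])^2 + ((co$y - centre[2]) / semi[2])^2 +
    ((co$z - centre[3]) / semi[3])^2 <= 1
}

#' Label map
#'
#' Named logical organ masks sharing one grid geometry.  Validates the
#' structural invariants: every organ inside the body contour; PTV, bladder,
#' WB and rectum pairwise disjoint; gas a subset of WB.
#'
#' @param masks named list of logical arrays.
#' @param spacing,origin grid geometry (mm).
#' @param validate check invariants (default TRUE).
#' @return object of class `label_map`.
#' @export
label_map <- function(masks, spacing, origin = c(0, 0, 0), validate = TRUE) {
  lm <- structure(list(masks = masks, spacing = as.numeric(spacing),
                       origin = as.numeric(origin)),
                  class = "label_map")
  if (validate) validate_label_map(lm)
  lm
}

validate_label_map <- function(lm) {
  m <- lm$masks
  organs <- setdiff(names(m), "body")
  for (o in organs) {
    if (any(m[[o]] & !m$body)) {
      stop("organ '", o, "' extends outside the body contour", call. = FALSE)
    }
  }
  pairs <- utils::combn(intersect(c("ptv", "bladder", "wb", "rectum"),
                                  names(m)), 2)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    if (any(m[[a]] & m[[b]])) {
      stop("organs '", a, "' and '", b, "' overlap", call. = FALSE)
    }
  }
  if (!is.null(m$gas) && any(m$gas & !m$wb)) {
    stop("gas pockets extend outside the whole-bowel label", call. = FALSE)
  }
  invisible(lm)
}

#' @export
print.label_map <- function(x, ...) {
  cc <- prod(x$spacing) / 1000
  cat("<label_map>\n")
  for (n in names(x$masks)) {
    cat(sprintf("  %-8s %8.1f cc\n", n, sum(x$masks[[n]]) * cc))
  }
  invisible(x)
}

build_labels <- function(spec, pocket_radii_scale = 1, bladder_r = NULL) {
  co <- coord_arrays(spec)
  body <- ((co$x - spec$body$centre[1]) / spec$body$semi[1])^2 +
    ((co$y - spec$body$centre[2]) / spec$body$semi[2])^2 <= 1
  ptv <- ellipsoid_mask(co, spec$ptv$centre, spec$ptv$semi)
  if (is.null(bladder_r)) bladder_r <- spec$bladder$r
  bladder <- sphere_mask(co, spec$bladder$centre, bladder_r)
  rectum <- (co$x - spec$rectum$centre_xy[1])^2 +
    (co$y - spec$rectum$centre_xy[2])^2 <= spec$rectum$r^2 &
    co$z >= spec$rectum$z_range[1] & co$z <= spec$rectum$z_range[2]
  bone <- sphere_mask(co, spec$bone$femur_l$centre, spec$bone$femur_l$r) |
    sphere_mask(co, spec$bone$femur_r$centre, spec$bone$femur_r$r) |
    sphere_mask(co, spec$bone$sacrum$centre, spec$bone$sacrum$r)
  wb <- ellipsoid_mask(co, spec$wb$centre, spec$wb$semi)

  # mandatory organs may not collide before carving
  if (any(ptv & bladder)) {
    stop("phantom geometry error: PTV and bladder overlap", call. = FALSE)
  }
  if (any(ptv & bone) || any(bladder & bone)) {
    stop("phantom geometry error: bone collides with PTV or bladder",
         call. = FALSE)
  }
  # carve for disjointness, PTV > bladder > rectum > bone > WB
  rectum <- rectum & !ptv & !bladder
  bone <- bone & !ptv & !bladder & !rectum
  wb <- wb & !ptv & !bladder & !rectum & !bone
  ptv <- ptv & body; bladder <- bladder & body
  rectum <- rectum & body; bone <- bone & body; wb <- wb & body

  gas <- array(FALSE, dim = spec$grid_dim)
  gp <- spec$gas_pockets
  if (!is.null(gp) && nrow(gp) > 0) {
    sc <- rep_len(pocket_radii_scale, nrow(gp))
    for (i in seq_len(nrow(gp))) {
      gas <- gas | sphere_mask(co, c(gp$x[i], gp$y[i], gp$z[i]),
                               gp$r[i] * sc[i])
    }
    gas <- gas & wb
  }
  label_map(list(body = body, ptv = ptv, bladder = bladder, wb = wb,
                 rectum = rectum, bone = bone, gas = gas),
            spacing = spec$spacing, origin = spec$origin)
}

build_hu <- function(spec, labels, noise = TRUE) {
  m <- labels$masks
  hu <- array(spec$hu$air, dim = spec$grid_dim)
  hu[m$body] <- spec$hu$soft
  hu[m$bladder] <- spec$hu$urine
  hu[m$bone] <- spec$hu$bone
  hu[m$gas] <- spec$hu$gas
  if (noise) {
    add_noise <- function(mask, sd) {
      n <- sum(mask)
      if (n > 0 && sd > 0) hu[mask] <<- hu[mask] + stats::rnorm(n, 0, sd)
    }
    add_noise(m$body & !m$bladder & !m$bone & !m$gas, spec$hu_noise_sd$soft)
    add_noise(m$bladder, spec$hu_noise_sd$urine)
    add_noise(m$bone, spec$hu_noise_sd$bone)
    add_noise(m$gas, spec$hu_noise_sd$gas)
  }
  voxel_grid(hu, spacing = spec$spacing, origin = spec$origin)
}

phantom_landmarks <- function(spec) {
  lm <- rbind(sacral_promontory = spec$bone$sacrum$centre,
              femoral_head_left = spec$bone$femur_l$centre,
              femoral_head_right = spec$bone$femur_r$centre)
  colnames(lm) <- c("x", "y", "z")
  lm
}

#' Generate the planning phantom
#'
#' Builds the planning-CT stand-in: an HU grid plus organ label map, with
#' bony landmark coordinates for rigid alignment and TRE checks.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed (drives the HU noise); identical seeds give
#'   bit-identical phantoms.
#' @param hu_noise logical, add Gaussian HU texture (default TRUE).
#' @return list of class `rt_planning` with elements `hu` (`voxel_grid`),
#'   `labels` (`label_map`), `landmarks` (3 x 3 world mm) and `spec`.
#' @export
generate_planning_phantom <- function(spec = phantom_spec(), seed = 1,
                                      hu_noise = TRUE) {
  labels <- build_labels(spec)
  hu <- with_seed(seed, build_hu(spec, labels, noise = hu_noise))
  structure(list(hu = hu, labels = labels,
                 landmarks = phantom_landmarks(spec),
                 spec = spec, seed = as.integer(seed)),
            class = "rt_planning")
}

# Radial expansion displacement about `centre`: sphere radius a -> b with a
# volume-preserving far field r' = (rho^3 + b^3 - a^3)^(1/3), linear stretch
# inside the sphere, smoothstep-tapered to zero at a + taper_mm.  Returns the
# mm displacement of the world points in `co` (arrays), as three arrays.
radial_expansion_field <- function(co, centre, a, b, taper_mm) {
  dx <- co$x - centre[1]; dy <- co$y - centre[2]; dz <- co$z - centre[3]
  rho <- sqrt(dx^2 + dy^2 + dz^2)
  rt <- a + taper_mm
  mag <- numeric(length(rho))
  inside <- rho <= a & rho > 1e-9
  mag[inside] <- (b / a - 1) * rho[inside]
  outer_band <- rho > a & rho < rt
  if (any(outer_band)) {
    ro <- rho[outer_band]
    rp <- (ro^3 + b^3 - a^3)^(1 / 3)
    s <- (ro - a) / taper_mm
    w <- 1 - s^2 * (3 - 2 * s)
    mag[outer_band] <- w * (rp - ro)
  }
  scale <- ifelse(rho > 1e-9, mag / rho, 0)
  list(ux = array(dx * scale, dim = dim(co$x)),
       uy = array(dy * scale, dim = dim(co$x)),
       uz = array(dz * scale, dim = dim(co$x)))
}

# secant root-finder on a step-like voxel-count function; returns the
# evaluated candidate with the smallest |f|
secant_best <- function(f, x0, x1, n_iter = 10, lo = -Inf, hi = Inf) {
  f0 <- f(x0)
  f1 <- f(x1)
  best_x <- if (abs(f0) < abs(f1)) x0 else x1
  best_f <- min(abs(f0), abs(f1))
  for (it in seq_len(n_iter)) {
    if (best_f < 0.5 || abs(f1 - f0) < 0.5) break
    x2 <- x1 - f1 * (x1 - x0) / (f1 - f0)
    x2 <- max(lo, min(x2, hi))
    x0 <- x1; f0 <- f1
    x1 <- x2; f1 <- f(x1)
    if (abs(f1) < best_f) {
      best_x <- x1
      best_f <- abs(f1)
    }
  }
  # the step structure of voxel counts can stall the secant; refine with a
  # local scan around the best candidate
  if (best_f >= 0.5) {
    span <- max(abs(best_x) * 0.05, 1e-3)
    for (x in seq(max(lo, best_x - span), min(hi, best_x + span),
                  length.out = 25)) {
      fx <- abs(f(x))
      if (fx < best_f) {
        best_x <- x
        best_f <- fx
      }
    }
  }
  list(x = best_x, abs_f = best_f)
}

#' Generate one treatment-fraction anatomy
#'
#' Realises a daily anatomy whose bowel-cavity (BC) gas volume differs from
#' the planning anatomy by a requested relative amount.  Pocket radii are
#' scaled (secant iteration on the voxelised volume) until the realised gas
#' volume matches `planning_volume * (1 + target_dvbc/100)`; the analytic
#' radial-expansion displacement of every pocket (plus the bladder-volume
#' jitter) is summed into the ground-truth deformation vector field mapping
#' planning points to fraction points.  Bone is rigid: the landmark
#' displacement is zero by construction of the taper.
#'
#' @param planning an `rt_planning` from [generate_planning_phantom()].
#' @param target_dvbc requested relative BC volume change, percent
#'   (> -100).
#' @param seed integer RNG seed for the fraction's HU noise.
#' @param bladder_delta_pct bladder volume change, percent (|x| must respect
#'   the 5% stability cap upstream).
#' @param hu_noise logical, add HU texture.
#' @param vol_tol_pct accepted mismatch between realised and requested BC
#'   volume, percent of planning volume (default 1).
#' @return list of class `rt_fraction` with `hu`, `labels`, `dvf`
#'   (4-D array, mm), `landmarks`, `target_dvbc`, `realized_dvbc`,
#'   `bladder_delta_pct`.
#' @export
generate_fraction <- function(planning, target_dvbc, seed = 1,
                              bladder_delta_pct = 0, hu_noise = TRUE,
                              vol_tol_pct = 1) {
  stopifnot(inherits(planning, "rt_planning"))
  if (target_dvbc <= -100) stop("target_dvbc must exceed -100%", call. = FALSE)
  spec <- planning$spec
  vc <- prod(spec$spacing) / 1000
  n_plan <- sum(planning$labels$masks$gas)
  gp <- spec$gas_pockets
  has_gas <- !is.null(gp) && nrow(gp) > 0 && n_plan > 0

  co <- coord_arrays(spec)
  # solve the bladder radius against the voxelised volume so the realised
  # change respects the stability cap even on coarse grids
  bladder_r <- spec$bladder$r
  if (abs(bladder_delta_pct) > 1e-12) {
    n_b_plan <- sum(planning$labels$masks$bladder)
    n_b_target <- n_b_plan * (1 + bladder_delta_pct / 100)
    sol <- secant_best(
      function(r) sum(sphere_mask(co, spec$bladder$centre, r)) - n_b_target,
      spec$bladder$r,
      spec$bladder$r * (1 + bladder_delta_pct / 100)^(1 / 3),
      lo = 0.5 * spec$bladder$r, hi = 1.5 * spec$bladder$r)
    bladder_r <- sol$x
  }

  scale <- 1
  if (has_gas && abs(target_dvbc) > 1e-12) {
    target_n <- n_plan * (1 + target_dvbc / 100)
    # the WB mask does not depend on the pocket scale, so the voxelised gas
    # volume can be evaluated from sphere masks alone
    wb_final <- build_labels(spec, pocket_radii_scale = 1,
                             bladder_r = bladder_r)$masks$wb
    vol_at <- function(s) {
      sc <- rep_len(s, nrow(gp))
      g <- array(FALSE, dim = spec$grid_dim)
      for (i in seq_len(nrow(gp))) {
        g <- g | sphere_mask(co, c(gp$x[i], gp$y[i], gp$z[i]),
                             gp$r[i] * sc[i])
      }
      sum(g & wb_final)
    }
    sol <- secant_best(function(s) vol_at(s) - target_n,
                       1, (1 + target_dvbc / 100)^(1 / 3),
                       n_iter = 12, lo = 0.05, hi = 4)
    scale <- rep(sol$x, nrow(gp))
    best_f <- sol$abs_f
    # coarse grids quantise the uniform-scale volume curve in jumps of many
    # voxels; refine pocket-by-pocket for sub-percent realisation
    if (best_f > max(1, 0.005 * n_plan)) {
      for (i in seq_len(nrow(gp))) {
        for (si in seq(scale[i] * 0.92, scale[i] * 1.08,
                       length.out = 33)) {
          cand <- scale
          cand[i] <- si
          fx <- abs(vol_at(cand) - target_n)
          if (fx < best_f) {
            scale[i] <- si
            best_f <- fx
          }
        }
      }
    }
    # a few voxels of slack distinguishes lattice quantisation (tolerated,
    # the realised value is recorded) from physically impossible targets
    if (best_f > max(3 / 100 * max(n_plan, target_n), 3)) {
      stop("infeasible bowel-gas target: requested ", target_dvbc,
           "% cannot be realised inside the whole-bowel label", call. = FALSE)
    }
  }

  labels <- build_labels(spec, pocket_radii_scale = scale,
                         bladder_r = bladder_r)
  hu <- with_seed(seed, build_hu(spec, labels, noise = hu_noise))

  d <- spec$grid_dim
  dvf <- array(0, dim = c(d, 3))
  if (has_gas) {
    sc <- rep_len(scale, nrow(gp))
    for (i in seq_len(nrow(gp))) {
      fld <- radial_expansion_field(co, c(gp$x[i], gp$y[i], gp$z[i]),
                                    gp$r[i], gp$r[i] * sc[i], spec$taper_mm)
      dvf[, , , 1] <- dvf[, , , 1] + fld$ux
      dvf[, , , 2] <- dvf[, , , 2] + fld$uy
      dvf[, , , 3] <- dvf[, , , 3] + fld$uz
    }
  }
  if (abs(bladder_delta_pct) > 1e-12) {
    fld <- radial_expansion_field(co, spec$bladder$centre, spec$bladder$r,
                                  bladder_r, spec$taper_mm)
    dvf[, , , 1] <- dvf[, , , 1] + fld$ux
    dvf[, , , 2] <- dvf[, , , 2] + fld$uy
    dvf[, , , 3] <- dvf[, , , 3] + fld$uz
  }

  realized <- if (n_plan > 0) {
    (sum(labels$masks$gas) - n_plan) / n_plan * 100
  } else NA_real_
  structure(list(hu = hu, labels = labels, dvf = dvf,
                 landmarks = planning$landmarks,
                 target_dvbc = target_dvbc, realized_dvbc = realized,
                 bladder_delta_pct = bladder_delta_pct,
                 gas_volume_cc = sum(labels$masks$gas) * vc,
                 seed = as.integer(seed)),
            class = "rt_fraction")
}

#' Cohort configuration
#'
#' Sampling scheme for a synthetic treatment course: per-patient mean
#' bowel-cavity volume change drawn uniformly from `dvbc_mean_range`, with
#' per-fraction Gaussian noise `dvbc_frac_sd`, plus per-fraction bladder
#' jitter (truncated normal) kept strictly inside the 5% bladder-volume
#' stability cap; the external contour is held fixed (8% cap trivially met).
#'
#' @param n_patients,n_fractions cohort size (defaults 28 x 25).
#' @param dvbc_mean_range percent; range of per-patient mean BC change.
#' @param dvbc_frac_sd percent; fraction-level SD about the patient mean.
#' @param bladder_sd_pct SD of bladder volume jitter (percent).
#' @param bladder_cap_pct hard cap on |bladder change| enforced by
#'   resampling (default 5; draws beyond `0.76 * cap` are resampled so the
#'   voxelised volume stays inside the cap).
#' @param body_cap_pct external-contour cap (informational; contour fixed).
#' @param seed base RNG seed; fully determines the cohort.
#' @param spec [phantom_spec()] shared by all patients.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 28, n_fractions = 25,
                          dvbc_mean_range = c(-10, 60), dvbc_frac_sd = 12,
                          bladder_sd_pct = 2.2, bladder_cap_pct = 5,
                          body_cap_pct = 8, seed = 1, spec = phantom_spec()) {
  structure(list(n_patients = as.integer(n_patients),
                 n_fractions = as.integer(n_fractions),
                 dvbc_mean_range = dvbc_mean_range,
                 dvbc_frac_sd = dvbc_frac_sd,
                 bladder_sd_pct = bladder_sd_pct,
                 bladder_cap_pct = bladder_cap_pct,
                 body_cap_pct = body_cap_pct,
                 seed = as.integer(seed), spec = spec),
            class = "cohort_config")
}

#' Generate a synthetic cohort of course records
#'
#' Draws the full sampling plan (per-patient BC-change means, per-fraction
#' targets, bladder jitters, per-fraction seeds) and returns one course
#' record per patient.  By default records are skeletons: the anatomies are
#' regenerable on demand from the stored seeds via
#' [generate_planning_phantom()] / [generate_fraction()], which keeps memory
#' bounded at clinical cohort sizes; `keep_grids = TRUE` materialises them.
#'
#' @param config a [cohort_config()].
#' @param keep_grids materialise all anatomies (only sensible on small
#'   grids).
#' @return list of course records; each has `patient_id`, `planning_seed`,
#'   `dvbc_mean`, and a `fractions` data.frame with columns `fraction`,
#'   `target_dvbc`, `bladder_delta_pct`, `seed` (plus `planning` /
#'   `anatomies` when materialised).
#' @export
generate_cohort <- function(config, keep_grids = FALSE) {
  records <- with_seed(config$seed, draw_cohort_plan(config))
  # materialise after the whole sampling plan is drawn, so the phantom
  # generators' internal seeding cannot perturb the plan
  if (keep_grids) {
    for (p in seq_along(records)) {
      rec <- records[[p]]
      rec$planning <- generate_planning_phantom(config$spec,
                                                rec$planning_seed)
      rec$anatomies <- lapply(seq_len(config$n_fractions), function(i) {
        generate_fraction(rec$planning, rec$fractions$target_dvbc[i],
                          rec$fractions$seed[i],
                          rec$fractions$bladder_delta_pct[i])
      })
      records[[p]] <- rec
    }
  }
  records
}

draw_cohort_plan <- function(config) {
  lo <- config$dvbc_mean_range[1]
  hi <- config$dvbc_mean_range[2]
  # bladder draws resampled until the cap holds with margin for voxelisation
  draw_bladder <- function() {
    repeat {
      v <- stats::rnorm(1, 0, config$bladder_sd_pct)
      if (abs(v) <= 0.76 * config$bladder_cap_pct) return(v)
    }
  }
  records <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    planning_seed <- sample.int(.Machine$integer.max %/% 2, 1)
    dvbc_mean <- stats::runif(1, lo, hi)
    targets <- pmin(pmax(dvbc_mean +
                           stats::rnorm(config$n_fractions, 0,
                                        config$dvbc_frac_sd), -60), 110)
    fr <- data.frame(
      fraction = seq_len(config$n_fractions),
      target_dvbc = targets,
      bladder_delta_pct = vapply(seq_len(config$n_fractions),
                                 function(i) draw_bladder(), numeric(1)),
      seed = sample.int(.Machine$integer.max %/% 2, config$n_fractions)
    )
    records[[p]] <- list(patient_id = sprintf("P%02d", p),
                         planning_seed = planning_seed,
                         dvbc_mean = dvbc_mean, fractions = fr)
  }
  records
}

#' Write a cohort manifest as JSON
#'
#' @param records output of [generate_cohort()].
#' @param path JSON file path.
#' @export
write_cohort_manifest <- function(records, path) {
  manifest <- lapply(records, function(r) {
    list(patient_id = r$patient_id, planning_seed = r$planning_seed,
         dvbc_mean = r$dvbc_mean, fractions = r$fractions)
  })
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
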