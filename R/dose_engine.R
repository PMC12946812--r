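#' Beam configuration for the density-aware dose engine
#'
#' The engine is a transparent stand-in for a clinical convolution
#' algorithm: `n_beams` coplanar beams at equispaced gantry angles, each an
#' exponential-attenuation primary with a rectangular jaw aperture fitted to
#' the PTV projection plus a margin, and a sigmoid lateral penumbra.  It is
#' deliberately simple and deterministic; its only job is to make density
#' changes (notably bowel gas) perturb dose in the physically expected
#' direction.
#'
#' @param n_beams number of coplanar beams (default 12).
#' @param mu_eff effective attenuation per mm of water-equivalent depth
#'   (default 0.005 /mm, a 6 MV-like falloff).
#' @param penumbra_sigma lateral penumbra width (mm).
#' @param margin aperture margin beyond the PTV projection (mm).
#' @param sad source-axis distance (mm).
#' @param isocentre world mm; default NULL = PTV mask centroid.
#' @return list of class `beam_config`.
#' @export
beam_config <- function(n_beams = 12, mu_eff = 0.005, penumbra_sigma = 6,
                        margin = 7, sad = 1000, isocentre = NULL) {
  stopifnot(n_beams >= 1, mu_eff >= 0)
  structure(list(n_beams = as.integer(n_beams), mu_eff = mu_eff,
                 penumbra_sigma = penumbra_sigma, margin = margin,
                 sad = sad, isocentre = isocentre),
            class = "beam_config")
}

beam_frames <- function(beams, iso) {
  angles <- 2 * pi * (seq_len(beams$n_beams) - 1) / beams$n_beams
  n <- beams$n_beams
  sources <- matrix(0, n, 3)
  e1s <- matrix(0, n, 3)
  e2s <- matrix(0, n, 3)
  for (b in seq_len(n)) {
    d <- c(-cos(angles[b]), -sin(angles[b]), 0) # source -> iso direction
    sources[b, ] <- iso - beams$sad * d
    e1s[b, ] <- c(-d[2], d[1], 0)               # in-plane lateral
    e2s[b, ] <- c(0, 0, 1)                      # cranio-caudal
  }
  list(sources = sources, e1s = e1s, e2s = e2s)
}

#' Water-equivalent radiological depth
#'
#' Line integral of relative electron density from `source` to each query
#' point, computed by uniform sub-voxel stepping (step <= spacing / 2) with
#' trilinear density sampling, restricted to the part of the ray inside the
#' grid.
#'
#' @param red_grid `voxel_grid` of relative electron density.
#' @param source world mm, length 3.
#' @param points n x 3 matrix of world mm (or length-3 vector).
#' @param step step length in mm (default `min(spacing) / 2`).
#' @return numeric vector of water-equivalent depths (mm).
#' @export
radiological_depth <- function(red_grid, source, points, step = NULL) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (is.null(step)) step <- min(red_grid$spacing) / 2
  cpp_ray_depth(red_grid$data, dim(red_grid$data), red_grid$spacing,
                red_grid$origin, as.numeric(source),
                matrix(as.numeric(points), ncol = 3), step)
}

#' Compute one fraction's dose distribution
#'
#' Superposes all beams — `dose(v) = sum_b aperture_b(v) *
#' exp(-mu_eff * depth_b(v))` — then scales globally.  On the planning call
#' (`scale = NULL`) the scale is solved so the median PTV dose equals
#' `prescription_gy`; per-fraction recalculations must pass the planning
#' scale back in, mirroring fixed monitor units at delivery.
#'
#' @param red_grid `voxel_grid` of relative electron density.
#' @param beams a [beam_config()].
#' @param ptv_mask logical array (PTV) used for the aperture fit and for
#'   normalisation.
#' @param prescription_gy per-fraction prescription (default 2 Gy,
#'   i.e. 50 Gy in 25 fractions).
#' @param scale fixed output scaling; NULL solves it from the PTV median.
#' @return list of class `dose_grid`: `dose` (`voxel_grid`, Gy), `scale`,
#'   `beams`.
#' @export
compute_fraction_dose <- function(red_grid, beams, ptv_mask,
                                  prescription_gy = 2, scale = NULL) {
  stopifnot(inherits(red_grid, "voxel_grid"), is.logical(ptv_mask))
  if (!any(ptv_mask)) stop("empty PTV mask: cannot normalise", call. = FALSE)
  iso <- beams$isocentre
  d <- dim(red_grid$data)
  idx <- arrayInd(which(ptv_mask), d) - 1L
  ptv_w <- sweep(sweep(idx, 2, red_grid$spacing, `*`), 2, red_grid$origin, `+`)
  if (is.null(iso)) iso <- colMeans(ptv_w)
  fr <- beam_frames(beams, iso)
  rel <- sweep(ptv_w, 2, iso, `-`)
  w1 <- numeric(beams$n_beams)
  w2 <- numeric(beams$n_beams)
  for (b in seq_len(beams$n_beams)) {
    w1[b] <- max(abs(rel %*% fr$e1s[b, ])) + beams$margin
    w2[b] <- max(abs(rel %*% fr$e2s[b, ])) + beams$margin
  }
  raw <- cpp_beam_dose(red_grid$data, d, red_grid$spacing, red_grid$origin,
                       fr$sources, fr$e1s, fr$e2s, w1, w2, iso,
                       beams$penumbra_sigma, beams$mu_eff,
                       min(red_grid$spacing) / 2)
  raw <- array(raw, dim = d)
  if (is.null(scale)) {
    med <- stats::median(raw[ptv_mask])
    if (med <= 0) stop("degenerate dose: PTV median is zero", call. = FALSE)
    scale <- prescription_gy / med
  }
  dose <- voxel_grid(raw * scale, spacing = red_grid$spacing,
                     origin = red_grid$origin)
  structure(list(dose = dose, scale = scale, isocentre = iso,
                 beams = beams), class = "dose_grid")
}
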