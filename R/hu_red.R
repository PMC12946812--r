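#' Three-segment HU to relative electron density calibration
#'
#' Builds a piecewise-linear HU to relative-electron-density (RED) curve in
#' which three tissue-equivalent HU segments — air (-1000 <= HU < -200),
#' soft tissue (-200 <= HU < 300) and bone (300 <= HU <= 1500) — each carry
#' a multiplicative scaling factor on a common base anchor curve.  The
#' defaults are the scanner-derived factors 0.995 (air), 0.977 (soft
#' tissue) and 0.972 (bone).  Segment factors are cross-faded linearly over
#' `+/- blend_hu` around the -200 and 300 HU breakpoints so the curve stays
#' continuous; monotonicity over [-1000, 1500] is verified at build time.
#'
#' @param factors numeric length-3 `(s_air, s_soft, s_bone)`, each in
#'   (0, 1.2].
#' @param base_anchors two-column matrix / data.frame `(HU, RED)` of base
#'   curve anchors, strictly monotone in both columns.
#' @param blend_hu half-width (HU) of the linear cross-fade at the segment
#'   breakpoints (default 25).
#' @return object of class `hured_curve`.
#' @export
build_hured_curve <- function(factors = c(0.995, 0.977, 0.972),
                              base_anchors = default_hured_anchors(),
                              blend_hu = 25) {
  factors <- as.numeric(factors)
  stopifnot(length(factors) == 3L)
  if (any(factors <= 0 | factors > 1.2)) {
    stop("segment factors must lie in (0, 1.2]", call. = FALSE)
  }
  ba <- as.matrix(base_anchors)
  if (nrow(ba) < 2 || any(diff(ba[, 1]) <= 0) || any(diff(ba[, 2]) <= 0)) {
    stop("base anchors must be strictly monotone in HU and RED",
         call. = FALSE)
  }
  curve <- structure(list(factors = factors, base_anchors = ba,
                          blend_hu = blend_hu,
                          breakpoints = c(-1000, -200, 300, 1500)),
                     class = "hured_curve")
  red <- hured_lookup(curve, seq(-1000, 1500, by = 1))
  if (any(diff(red) < -1e-12)) {
    stop("calibration curve is not monotone non-decreasing", call. = FALSE)
  }
  if (any(red <= 0) || any(!is.finite(red))) {
    stop("calibration curve must be positive and finite", call. = FALSE)
  }
  curve
}

#' @rdname build_hured_curve
#' @export
default_hured_anchors <- function() {
  cbind(hu = c(-1000, -200, 0, 300, 1500),
        red = c(0.001, 0.820, 1.000, 1.150, 1.850))
}

hured_lookup <- function(curve, hu) {
  hu <- pmin(pmax(hu, -1000), 1500)
  base <- stats::approx(curve$base_anchors[, 1], curve$base_anchors[, 2],
                        xout = hu, rule = 2)$y
  f <- curve$factors
  bl <- curve$blend_hu
  # factor field: piecewise constant with linear cross-fade at -200 and 300
  fac <- rep(f[2], length(hu))
  fac[hu < -200 - bl] <- f[1]
  fac[hu > 300 + bl] <- f[3]
  i <- hu >= -200 - bl & hu <= -200 + bl
  if (any(i)) {
    t <- (hu[i] - (-200 - bl)) / (2 * bl)
    fac[i] <- (1 - t) * f[1] + t * f[2]
  }
  i <- hu >= 300 - bl & hu <= 300 + bl
  if (any(i)) {
    t <- (hu[i] - (300 - bl)) / (2 * bl)
    fac[i] <- (1 - t) * f[2] + t * f[3]
  }
  pmax(base * fac, 1e-4)
}

#' @export
print.hured_curve <- function(x, ...) {
  cat("<hured_curve> segment factors",
      sprintf("air %.3f / soft %.3f / bone %.3f,", x$factors[1],
              x$factors[2], x$factors[3]),
      sprintf("blend +/-%g HU\n", x$blend_hu))
  invisible(x)
}

#' Apply a calibration curve to an HU grid
#'
#' Element-wise HU -> RED mapping; HU values are clamped to [-1000, 1500]
#' before lookup, so out-of-range voxels are handled without error.
#'
#' @param curve a [build_hured_curve()] object.
#' @param hu_grid `voxel_grid` of HU (or a plain numeric vector).
#' @return a `voxel_grid` of RED with the geometry of `hu_grid` (or a
#'   numeric vector for vector input).
#' @export
apply_hured_curve <- function(curve, hu_grid) {
  stopifnot(inherits(curve, "hured_curve"))
  if (inherits(hu_grid, "voxel_grid")) {
    red <- hured_lookup(curve, as.vector(hu_grid$data))
    voxel_grid(array(red, dim = dim(hu_grid$data)),
               spacing = hu_grid$spacing, origin = hu_grid$origin)
  } else {
    hured_lookup(curve, as.numeric(hu_grid))
  }
}

#' Derive segment scaling factors from paired dose grids
#'
#' For each tissue-equivalent HU range, the factor is the mean over in-range
#' voxels of `reference / recalculated` dose — the multiplicative correction
#' that nulls the mean dose difference in that range.
#'
#' @param pairs list of lists, each with `reference` and `recalculated`
#'   (`voxel_grid` of Gy) and `hu` (`voxel_grid` of HU).
#' @param min_dose voxels with reference dose below this (Gy) are ignored
#'   (avoids 0/0 outside the field).
#' @return named numeric `(s_air, s_soft, s_bone)`.
#' @export
derive_segment_factors <- function(pairs, min_dose = 1e-6) {
  stopifnot(length(pairs) >= 1)
  ranges <- list(s_air = c(-1000, -200), s_soft = c(-200, 300),
                 s_bone = c(300, 1500))
  out <- vapply(names(ranges), function(nm) {
    r <- ranges[[nm]]
    ratios <- unlist(lapply(pairs, function(p) {
      hu <- as.vector(p$hu$data)
      # half-open [lo, hi) except the bone segment which is closed
      sel <- if (nm == "s_bone") hu >= r[1] & hu <= r[2] else
        hu >= r[1] & hu < r[2]
      ref <- as.vector(p$reference$data)[sel]
      rec <- as.vector(p$recalculated$data)[sel]
      keep <- ref > min_dose & rec > min_dose
      ref[keep] / rec[keep]
    }))
    if (length(ratios) == 0) {
      stop("no evaluable voxels in HU range [", r[1], ", ", r[2],
           "]; factor undefined", call. = FALSE)
    }
    mean(ratios)
  }, numeric(1))
  out
}

#' Serialise a calibration curve to / from JSON
#'
#' @param curve a `hured_curve`.
#' @param path JSON file path.
#' @return `read_hured_curve` returns the reconstructed curve.
#' @export
write_hured_curve <- function(curve, path) {
  jsonlite::write_json(list(factors = curve$factors,
                            base_anchors = as.data.frame(curve$base_anchors),
                            blend_hu = curve$blend_hu),
                       path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_hured_curve
#' @export
read_hured_curve <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_hured_curve(factors = x$factors,
                    base_anchors = cbind(x$base_anchors$hu,
                                         x$base_anchors$red),
                    blend_hu = x$blend_hu)
}

#' Sample a curve for plotting / export
#'
#' @param curve a `hured_curve`.
#' @param hu HU values to sample (default every integer in [-1000, 1500]).
#' @return data.frame with columns `hu`, `red`.
#' @export
sample_hured_curve <- function(curve, hu = seq(-1000, 1500, by = 1)) {
  data.frame(hu = hu, red = hured_lookup(curve, hu))
}
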