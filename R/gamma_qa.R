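#' Gamma-analysis criteria
#'
#' Global-normalisation gamma: the dose criterion is a percentage of the
#' global maximum of the *reference* distribution, so the comparison is not
#' symmetric in its arguments.  Voxels below the low-dose cutoff are
#' excluded from the pass-rate denominator.
#'
#' @param dose_pct dose-difference criterion, % of reference global max
#'   (default 2).
#' @param dta_mm distance-to-agreement criterion, mm (default 2).
#' @param cutoff_pct low-dose cutoff, % of reference global max (default
#'   10).
#' @param search_factor search radius as a multiple of `dta_mm` (default 3).
#' @param step_frac sub-voxel search step as a fraction of `dta_mm`
#'   (default 1/5).
#' @return list of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_pct = 2, dta_mm = 2, cutoff_pct = 10,
                           search_factor = 3, step_frac = 1 / 5) {
  stopifnot(dose_pct > 0, dta_mm > 0, cutoff_pct > 0, search_factor >= 1)
  structure(list(dose_pct = dose_pct, dta_mm = dta_mm,
                 cutoff_pct = cutoff_pct, search_factor = search_factor,
                 step_frac = step_frac),
            class = "gamma_criteria")
}

gamma_offsets <- function(criteria) {
  r <- criteria$search_factor * criteria$dta_mm
  st <- criteria$dta_mm * criteria$step_frac
  g <- seq(-r, r, by = st)
  off <- as.matrix(expand.grid(x = g, y = g, z = g))
  dist <- sqrt(rowSums(off^2))
  keep <- dist <= r + 1e-9
  off <- off[keep, , drop = FALSE]
  off[order(dist[keep]), , drop = FALSE]
}

#' Per-voxel gamma map and pass rate
#'
#' For each reference voxel inside the ROI and above the low-dose cutoff,
#' `gamma = min over the search neighbourhood of sqrt((dDose/DD)^2 +
#' (dist/DTA)^2)`, with the dose difference expressed in percent of the
#' reference global maximum and the evaluated dose sampled trilinearly on a
#' sub-voxel grid.  A voxel passes when `gamma <= 1`.
#'
#' @param reference,evaluated `voxel_grid` dose distributions sharing
#'   geometry.
#' @param criteria a [gamma_criteria()].
#' @param roi_mask logical array restricting evaluation (default whole
#'   grid).
#' @return list of class `gamma_result`: `gamma` (`voxel_grid`, NA outside
#'   the evaluated set), `pass_rate` (%), `n_evaluated`, `n_pass`.
#' @export
gamma_map <- function(reference, evaluated, criteria = gamma_criteria(),
                      roi_mask = NULL) {
  stop_if_geometry_mismatch(reference, evaluated, "dose grids")
  ref_max <- max(reference$data)
  if (ref_max <= 0) stop("reference maximum must be positive", call. = FALSE)
  d <- dim(reference$data)
  if (is.null(roi_mask)) roi_mask <- array(TRUE, dim = d)
  cutoff_abs <- criteria$cutoff_pct / 100 * ref_max
  n_eval <- sum(roi_mask & reference$data >= cutoff_abs)
  if (n_eval == 0) {
    stop("no voxels remain after ROI and low-dose cutoff", call. = FALSE)
  }
  g <- cpp_gamma(reference$data, evaluated$data, d, reference$spacing,
                 reference$origin, as.vector(roi_mask),
                 criteria$dose_pct / 100 * ref_max, criteria$dta_mm,
                 cutoff_abs, gamma_offsets(criteria))
  g <- array(g, dim = d)
  n_pass <- sum(g <= 1, na.rm = TRUE)
  structure(list(gamma = voxel_grid(g, reference$spacing, reference$origin),
                 pass_rate = n_pass / n_eval * 100,
                 n_evaluated = n_eval, n_pass = n_pass,
                 criteria = criteria),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm: pass rate %.1f%% (%d / %d voxels)\n",
              x$criteria$dose_pct, x$criteria$dta_mm, x$pass_rate,
              x$n_pass, x$n_evaluated))
  invisible(x)
}

#' Target registration error
#'
#' Euclidean landmark distances in world mm.
#'
#' @param points_a,points_b n x 3 matrices of corresponding landmarks.
#' @return list with `per_point` (mm) and `mean` (mm).
#' @export
tre <- function(points_a, points_b) {
  points_a <- matrix(as.numeric(points_a), ncol = 3)
  points_b <- matrix(as.numeric(points_b), ncol = 3)
  if (nrow(points_a) != nrow(points_b)) {
    stop("landmark counts differ", call. = FALSE)
  }
  d <- sqrt(rowSums((points_a - points_b)^2))
  list(per_point = d, mean = mean(d), max = max(d))
}
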