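#' Cumulative dose-volume histogram
#'
#' Direct voxel sampling: the cumulative curve `V(d)` is the absolute volume
#' (cc) of mask voxels receiving at least `d` Gy, tabulated at bin edges
#' `0, w, 2w, ...` past the maximum dose.  Structure volume is voxel count
#' times voxel volume.
#'
#' @param dose_grid `voxel_grid` of Gy.
#' @param mask non-empty logical array sharing the dose geometry.
#' @param bin_width histogram bin width, Gy (default 0.05).
#' @return list of class `dvh`: `dose` (bin edges, Gy), `volume_cc`,
#'   `volume_pct`, `structure_cc`, `bin_width`.
#' @export
compute_dvh <- function(dose_grid, mask, bin_width = 0.05) {
  stopifnot(inherits(dose_grid, "voxel_grid"), is.logical(mask))
  if (!identical(dim(mask), dim(dose_grid$data))) {
    stop("mask and dose grid geometry mismatch", call. = FALSE)
  }
  if (!any(mask)) stop("empty structure mask", call. = FALSE)
  doses <- dose_grid$data[mask]
  vc <- voxel_cc(dose_grid)
  vol <- length(doses) * vc
  edges <- seq(0, max(doses) + bin_width, by = bin_width)
  # V(d) = volume receiving >= d; vectorised via the ECDF of voxel doses
  below <- stats::ecdf(doses)
  cum_cc <- vol * (1 - below(edges - 1e-12))
  structure(list(dose = edges, volume_cc = cum_cc,
                 volume_pct = cum_cc / vol * 100,
                 structure_cc = vol, bin_width = bin_width),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> structure %.1f cc, dose range [0, %.2f] Gy, bin %.3g Gy\n",
              x$structure_cc, max(x$dose), x$bin_width))
  invisible(x)
}

#' Dose at volume (Dx% / Dxcc)
#'
#' Minimum dose received by the hottest `q` percent (or cc) of the
#' structure, by linear interpolation of the cumulative curve.  Sub-voxel
#' queries such as D0.03cc interpolate between the last occupied bin and
#' the empty tail.
#'
#' @param dvh a [compute_dvh()] object.
#' @param q volume query.
#' @param unit `"pct"` (percent of structure volume) or `"cc"`.
#' @return dose in Gy.
#' @export
dose_at_volume <- function(dvh, q, unit = c("pct", "cc")) {
  unit <- match.arg(unit)
  q_cc <- if (unit == "pct") q / 100 * dvh$structure_cc else q
  if (q_cc > dvh$structure_cc + 1e-9) {
    stop("queried volume exceeds structure volume", call. = FALSE)
  }
  if (q_cc <= 0) stop("queried volume must be positive", call. = FALSE)
  v <- dvh$volume_cc
  d <- dvh$dose
  # cumulative curve is non-increasing in dose; invert with interpolation.
  # The strict inequality makes a full-volume query return the structure
  # minimum dose rather than the curve origin.
  i <- which(v < q_cc)[1]
  if (is.na(i)) return(d[length(d)])
  if (i == 1) return(d[1])
  v_hi <- v[i - 1]
  v_lo <- v[i]
  if (v_hi == v_lo) return(d[i])
  d[i - 1] + (v_hi - q_cc) / (v_hi - v_lo) * (d[i] - d[i - 1])
}

#' Volume at dose (Vd)
#'
#' Absolute structure volume (cc) receiving at least `d` Gy, interpolated
#' on the cumulative curve.
#'
#' @param dvh a [compute_dvh()] object.
#' @param d dose in Gy (>= 0).
#' @return volume in cc.
#' @export
volume_at_dose <- function(dvh, d) {
  stopifnot(d >= 0)
  if (d >= max(dvh$dose)) return(0)
  stats::approx(dvh$dose, dvh$volume_cc, xout = d, rule = 2)$y
}

#' Extract the study endpoint set
#'
#' PTV D2%, D50%, D98% and whole-bowel D0.03cc, D150cc (all Gy) plus
#' whole-bowel V45 (cc).
#'
#' @param ptv_dvh,wb_dvh DVHs of the PTV and whole bowel.
#' @param v_dose threshold (Gy) for the bowel volume metric (default 45).
#' @return named list of class `endpoint_set`.
#' @export
endpoint_set <- function(ptv_dvh, wb_dvh, v_dose = 45) {
  ep <- list(
    D2 = dose_at_volume(ptv_dvh, 2, "pct"),
    D50 = dose_at_volume(ptv_dvh, 50, "pct"),
    D98 = dose_at_volume(ptv_dvh, 98, "pct"),
    D0.03cc = dose_at_volume(wb_dvh, 0.03, "cc"),
    D150cc = dose_at_volume(wb_dvh, min(150, wb_dvh$structure_cc), "cc"),
    V45 = volume_at_dose(wb_dvh, v_dose)
  )
  class(ep) <- "endpoint_set"
  ep
}

#' Endpoint names of the five-endpoint primary family
#' @export
primary_endpoints <- function() c("D2", "D50", "D98", "D0.03cc", "D150cc")

#' Absolute and relative endpoint differences
#'
#' `delta = other - planned` (Gy) and `delta_pct = delta / planned * 100`
#' for every shared dose endpoint (V45 is differenced in cc, no relative
#' form beyond the same definition).
#'
#' @param planned,other `endpoint_set` objects (or named numeric lists).
#' @return data.frame with columns `endpoint`, `planned`, `value`, `delta`,
#'   `delta_pct`.
#' @export
dose_diffs <- function(planned, other) {
  keys <- intersect(names(planned), names(other))
  if (!setequal(names(planned), names(other))) {
    stop("endpoint sets carry different keys", call. = FALSE)
  }
  planned_v <- unlist(planned[keys])
  other_v <- unlist(other[keys])
  data.frame(endpoint = keys, planned = planned_v, value = other_v,
             delta = other_v - planned_v,
             delta_pct = (other_v - planned_v) / planned_v * 100,
             row.names = NULL)
}

boot_median_ci <- function(x, n_boot = 2000, conf = 0.95, seed = 1) {
  if (length(x) == 1) return(c(lo = x, hi = x))
  meds <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    stats::median(sample(x, replace = TRUE))
  }, numeric(1)))
  q <- stats::quantile(meds, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Cohort endpoint-deviation summary
#'
#' Per endpoint: the cohort median of the per-patient deviations (with a
#' percentile-bootstrap 95% CI, 2000 resamples) and counts of patients
#' exceeding the predefined absolute and relative thresholds.
#'
#' @param patient_diffs data.frame with columns `patient`, `endpoint`,
#'   `delta`, `delta_pct` (one row per patient x endpoint; typically the
#'   within-patient median across fractions, or the accumulated-course
#'   deviation).
#' @param delta_thresholds absolute |delta| thresholds in Gy (default
#'   `c(0.5, 1, 2, 3)`).
#' @param delta_pct_thresholds relative |delta| thresholds in percent
#'   (default `c(1, 2, 3)`).
#' @param n_boot,seed bootstrap control.
#' @return list with `summary` (per-endpoint medians + CIs) and
#'   `exceedance` (per endpoint x threshold counts).
#' @export
cohort_summary <- function(patient_diffs,
                           delta_thresholds = c(0.5, 1, 2, 3),
                           delta_pct_thresholds = c(1, 2, 3),
                           n_boot = 2000, seed = 1) {
  stopifnot(nrow(patient_diffs) >= 1)
  eps <- unique(patient_diffs$endpoint)
  n_pat <- length(unique(patient_diffs$patient))
  summ <- do.call(rbind, lapply(eps, function(e) {
    d <- patient_diffs[patient_diffs$endpoint == e, ]
    ci_d <- boot_median_ci(d$delta, n_boot, seed = seed)
    ci_p <- boot_median_ci(d$delta_pct, n_boot, seed = seed + 1)
    data.frame(endpoint = e, n = nrow(d),
               median_delta = stats::median(d$delta),
               delta_lo = ci_d["lo"], delta_hi = ci_d["hi"],
               median_delta_pct = stats::median(d$delta_pct),
               delta_pct_lo = ci_p["lo"], delta_pct_hi = ci_p["hi"],
               row.names = NULL)
  }))
  exceed <- do.call(rbind, lapply(eps, function(e) {
    d <- patient_diffs[patient_diffs$endpoint == e, ]
    rbind(
      data.frame(endpoint = e, metric = "delta_gy",
                 threshold = delta_thresholds,
                 n_exceed = vapply(delta_thresholds, function(th) {
                   sum(abs(d$delta) >= th)
                 }, numeric(1)), n_total = nrow(d)),
      data.frame(endpoint = e, metric = "delta_pct",
                 threshold = delta_pct_thresholds,
                 n_exceed = vapply(delta_pct_thresholds, function(th) {
                   sum(abs(d$delta_pct) >= th)
                 }, numeric(1)), n_total = nrow(d))
    )
  }))
  exceed$proportion <- exceed$n_exceed / exceed$n_total
  list(summary = summ, exceedance = exceed, n_patients = n_pat)
}

#' Export a DVH as two-column CSV
#' @param dvh a [compute_dvh()] object.
#' @param path CSV path.
#' @export
write_dvh_csv <- function(dvh, path) {
  utils::write.csv(data.frame(dose_gy = dvh$dose,
                              volume_cc = dvh$volume_cc),
                   path, row.names = FALSE)
  invisible(path)
}
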