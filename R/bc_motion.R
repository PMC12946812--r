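#' Segment the bowel cavity (BC) from an HU grid
#'
#' In-silico surrogate for the clinical bowel-cavity contour: intraluminal
#' gas inside the whole-bowel label, excluding rectum (and stomach, when a
#' stomach label exists), thresholded at `hu_threshold` and cropped
#' cranio-caudally to the PTV extent plus `band_mm` above and below
#' (inclusive, world mm).
#'
#' @param hu_grid `voxel_grid` of HU.
#' @param labels `label_map` carrying at least `wb` and `ptv` masks.
#' @param hu_threshold gas threshold, HU (default -200, the air-segment
#'   boundary of the calibration curve; clinical BC averages near -900 HU,
#'   safely below).
#' @param band_mm cranio-caudal margin beyond the PTV bounding box
#'   (default 5).
#' @return list of class `bc_mask`: `mask` (logical array), `volume_cc`,
#'   `mean_hu` (NA when empty), `band_mm`.
#' @export
segment_bc <- function(hu_grid, labels, hu_threshold = -200, band_mm = 5) {
  m <- labels$masks
  if (is.null(m$wb) || is.null(m$ptv)) {
    stop("labels must include 'wb' and 'ptv' masks", call. = FALSE)
  }
  if (!any(m$ptv)) stop("PTV mask is empty", call. = FALSE)
  d <- dim(hu_grid$data)
  kz <- arrayInd(which(m$ptv), d)[, 3]
  z_world <- (kz - 1) * hu_grid$spacing[3] + hu_grid$origin[3]
  z_lo <- min(z_world) - band_mm
  z_hi <- max(z_world) + band_mm
  z_all <- (seq_len(d[3]) - 1) * hu_grid$spacing[3] + hu_grid$origin[3]
  in_band <- z_all >= z_lo & z_all <= z_hi
  band <- array(rep(in_band, each = d[1] * d[2]), dim = d)
  mask <- m$wb & hu_grid$data < hu_threshold & band
  if (!is.null(m$rectum)) mask <- mask & !m$rectum
  if (!is.null(m$stomach)) mask <- mask & !m$stomach
  vc <- prod(hu_grid$spacing) / 1000
  structure(list(mask = mask, volume_cc = sum(mask) * vc,
                 mean_hu = if (any(mask)) mean(hu_grid$data[mask]) else
                   NA_real_,
                 band_mm = band_mm),
            class = "bc_mask")
}

#' Per-fraction bowel-cavity volume change series
#'
#' `dvbc = (V_fraction - V_sim) / V_sim * 100` per fraction, plus the
#' patient-level median across all fractions.
#'
#' @param fraction_volumes_cc numeric vector of per-fraction BC volumes
#'   (cc).
#' @param sim_volume_cc BC volume at initial simulation (planning), cc,
#'   > 0.
#' @return list of class `bc_series`: `table` (data.frame with `fraction`,
#'   `volume_cc`, `dvbc_pct`), `sim_volume_cc`, `median_dvbc_pct`.
#' @export
delta_v_bc <- function(fraction_volumes_cc, sim_volume_cc) {
  if (sim_volume_cc <= 0) {
    stop("simulation BC volume must be positive", call. = FALSE)
  }
  dv <- (fraction_volumes_cc - sim_volume_cc) / sim_volume_cc * 100
  structure(list(
    table = data.frame(fraction = seq_along(fraction_volumes_cc),
                       volume_cc = fraction_volumes_cc, dvbc_pct = dv),
    sim_volume_cc = sim_volume_cc,
    median_dvbc_pct = stats::median(dv)
  ), class = "bc_series")
}
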