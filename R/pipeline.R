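#' Full-course run configuration
#'
#' Bundles every knob of the end-to-end pipeline (cohort sampling,
#' calibration curve, beam model, QA gates, statistics seeds) into one
#' serialisable object; `save_run_config()` / `load_run_config()` round-trip
#' it through YAML.
#'
#' @param cohort a [cohort_config()].
#' @param curve_factors HU-RED segment factors (default
#'   `c(0.995, 0.977, 0.972)`).
#' @param beams a [beam_config()].
#' @param gates a [qa_gates()].
#' @param prescription_gy per-fraction prescription (default 2).
#' @param dvf_noise_mm amplitude of Gaussian perturbation added to the
#'   ground-truth DVF before QA (default 0 = use ground truth).
#' @param stats_seed seed for all statistical resampling.
#' @param n_boot bootstrap resamples.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       curve_factors = c(0.995, 0.977, 0.972),
                       beams = beam_config(), gates = qa_gates(),
                       prescription_gy = 2, dvf_noise_mm = 0,
                       stats_seed = 1, n_boot = 2000) {
  structure(list(cohort = cohort, curve_factors = curve_factors,
                 beams = beams, gates = gates,
                 prescription_gy = prescription_gy,
                 dvf_noise_mm = dvf_noise_mm, stats_seed = stats_seed,
                 n_boot = n_boot),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
save_run_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(unclass(x), strip)
    }
    x
  }
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  sp <- x$cohort$spec
  spec <- phantom_spec(grid_dim = unlist(sp$grid_dim),
                       spacing = unlist(sp$spacing),
                       scale = sp$params$scale,
                       ptv_semi_axes = unlist(sp$params$ptv_semi_axes),
                       gas_pockets = as.data.frame(sp$params$gas_pockets),
                       hu = sp$hu, hu_noise_sd = sp$hu_noise_sd,
                       taper_mm = sp$params$taper_mm)
  run_config(
    cohort = cohort_config(n_patients = x$cohort$n_patients,
                           n_fractions = x$cohort$n_fractions,
                           dvbc_mean_range = unlist(x$cohort$dvbc_mean_range),
                           dvbc_frac_sd = x$cohort$dvbc_frac_sd,
                           bladder_sd_pct = x$cohort$bladder_sd_pct,
                           bladder_cap_pct = x$cohort$bladder_cap_pct,
                           body_cap_pct = x$cohort$body_cap_pct,
                           seed = x$cohort$seed, spec = spec),
    curve_factors = unlist(x$curve_factors),
    beams = do.call(beam_config, x$beams[c("n_beams", "mu_eff",
                                           "penumbra_sigma", "margin",
                                           "sad")]),
    gates = do.call(qa_gates, x$gates),
    prescription_gy = x$prescription_gy,
    dvf_noise_mm = x$dvf_noise_mm,
    stats_seed = x$stats_seed, n_boot = x$n_boot
  )
}

pelvic_roi <- function(labels, band_mm = 5) {
  m <- labels$masks
  d <- dim(m$body)
  kz <- arrayInd(which(m$ptv), d)[, 3]
  z <- (kz - 1) * labels$spacing[3] + labels$origin[3]
  z_all <- (seq_len(d[3]) - 1) * labels$spacing[3] + labels$origin[3]
  in_band <- z_all >= min(z) - band_mm & z_all <= max(z) + band_mm
  m$body & array(rep(in_band, each = d[1] * d[2]), dim = d)
}

course_endpoints <- function(dose, labels, scale = 1, bin_width = 0.05) {
  dg <- voxel_grid(dose$data * scale, dose$spacing, dose$origin)
  endpoint_set(compute_dvh(dg, labels$masks$ptv, bin_width),
               compute_dvh(dg, labels$masks$wb, bin_width))
}

endpoints_to_diff_rows <- function(patient, planned, other, label) {
  d <- dose_diffs(planned, other)
  d <- d[d$endpoint %in% primary_endpoints(), ]
  data.frame(patient = patient, kind = label, d, row.names = NULL)
}

#' Run the full synthetic treatment course
#'
#' End-to-end orchestration: for every patient, generate the planning
#' phantom, calibrate HU to density, compute the planned dose (normalised
#' to the prescription), then per fraction generate the daily anatomy,
#' recalculate dose under fixed monitor units, QA-gate the (ground-truth,
#' optionally perturbed) deformation field, warp the fraction dose back to
#' planning geometry and accumulate.  Emits endpoint-deviation summaries
#' (per-fraction medians and accumulated course), the bowel-cavity motion
#' association table, the planned-versus-accumulated NTCP comparison and a
#' per-fraction QA ledger; when `out_dir` is given all tables are written
#' as CSV with a JSON manifest.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); NULL = no files.
#' @param verbose print per-patient progress.
#' @return list of class `course_result` with elements `fraction_summary`,
#'   `accumulated_summary`, `assoc_table` (NULL when < 4 patients),
#'   `ntcp_comparison`, `qa_ledger`, `patient_tbl`, `panel_tbl`.
#' @export
run_course <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  curve <- build_hured_curve(config$curve_factors)
  cohort <- generate_cohort(config$cohort)
  nf <- config$cohort$n_fractions
  spec <- config$cohort$spec

  patient_rows <- list()
  panel_rows <- list()
  fraction_diff_rows <- list()
  accum_diff_rows <- list()
  qa_rows <- list()
  v45_planned <- numeric(0)
  v45_accum <- numeric(0)

  for (rec in cohort) {
    if (verbose) message("patient ", rec$patient_id)
    planning <- generate_planning_phantom(spec, rec$planning_seed)
    red_p <- apply_hured_curve(curve, planning$hu)
    plan <- compute_fraction_dose(red_p, config$beams,
                                  planning$labels$masks$ptv,
                                  config$prescription_gy)
    plan_ep <- course_endpoints(plan$dose, planning$labels, scale = nf)
    bc_plan <- segment_bc(planning$hu, planning$labels)
    roi <- pelvic_roi(planning$labels)

    warped <- vector("list", nf)
    qa_res <- vector("list", nf)
    bc_vols <- numeric(nf)
    for (i in seq_len(nf)) {
      fr <- rec$fractions[i, ]
      fx <- generate_fraction(planning, fr$target_dvbc, fr$seed,
                              fr$bladder_delta_pct)
      red_f <- apply_hured_curve(curve, fx$hu)
      fd <- compute_fraction_dose(red_f, config$beams,
                                  fx$labels$masks$ptv,
                                  config$prescription_gy,
                                  scale = plan$scale)
      bc_vols[i] <- segment_bc(fx$hu, fx$labels)$volume_cc
      w_ref <- warp_dose(fd$dose, fx$dvf, planning$hu,
                         body_mask = planning$labels$masks$body)
      dvf_test <- fx$dvf
      if (config$dvf_noise_mm > 0) {
        dvf_test <- dvf_test +
          with_seed(fr$seed + 7L,
                    array(stats::rnorm(length(dvf_test), 0,
                                       config$dvf_noise_mm),
                          dim = dim(dvf_test)))
      }
      w_test <- if (config$dvf_noise_mm > 0) {
        warp_dose(fd$dose, dvf_test, planning$hu,
                  body_mask = planning$labels$masks$body)
      } else w_ref
      qa_res[[i]] <- qa_check(dvf_test, planning$landmarks, fx$landmarks,
                              w_test, w_ref, config$gates, roi)
      warped[[i]] <- w_test
      fx_ep <- course_endpoints(fd$dose, planning$labels, scale = nf)
      fraction_diff_rows[[length(fraction_diff_rows) + 1]] <-
        cbind(endpoints_to_diff_rows(rec$patient_id, plan_ep, fx_ep,
                                     "fraction"),
              fraction = i, dvbc_pct = NA_real_)
    }
    keep <- vapply(qa_res, `[[`, logical(1), "pass")
    acc <- accumulate_dose(warped[keep], qa_res[keep])
    acc_ep <- course_endpoints(acc$dose, planning$labels,
                               scale = nf / sum(keep))
    bc_series <- delta_v_bc(bc_vols, bc_plan$volume_cc)

    idx0 <- length(fraction_diff_rows) - nf
    for (i in seq_len(nf)) {
      fraction_diff_rows[[idx0 + i]]$dvbc_pct <-
        bc_series$table$dvbc_pct[i]
    }
    accum_diff_rows[[length(accum_diff_rows) + 1]] <-
      endpoints_to_diff_rows(rec$patient_id, plan_ep, acc_ep, "accumulated")
    qa_rows[[length(qa_rows) + 1]] <-
      cbind(patient = rec$patient_id,
            accumulate_dose(warped, qa_res)$ledger)
    v45_planned <- c(v45_planned, plan_ep$V45)
    v45_accum <- c(v45_accum, acc_ep$V45)

    ad <- accum_diff_rows[[length(accum_diff_rows)]]
    prow <- data.frame(patient = rec$patient_id,
                       dvbc_pct = bc_series$median_dvbc_pct)
    for (e in primary_endpoints()) {
      prow[[paste0("delta_", e)]] <- ad$delta[ad$endpoint == e]
    }
    patient_rows[[length(patient_rows) + 1]] <- prow
  }

  patient_tbl <- do.call(rbind, patient_rows)
  fraction_diffs <- do.call(rbind, fraction_diff_rows)
  accum_diffs <- do.call(rbind, accum_diff_rows)

  # fraction-level panel, wide in endpoints
  panel_tbl <- stats::reshape(
    fraction_diffs[, c("patient", "fraction", "dvbc_pct", "endpoint",
                       "delta")],
    idvar = c("patient", "fraction", "dvbc_pct"),
    timevar = "endpoint", direction = "wide", v.names = "delta")
  names(panel_tbl) <- sub("^delta\\.", "delta_", names(panel_tbl))

  # per-patient median across fractions, per endpoint (published summary)
  med_rows <- do.call(rbind, lapply(split(
    fraction_diffs, list(fraction_diffs$patient, fraction_diffs$endpoint),
    drop = TRUE), function(g) {
      data.frame(patient = g$patient[1], endpoint = g$endpoint[1],
                 delta = stats::median(g$delta),
                 delta_pct = stats::median(g$delta_pct))
    }))
  fraction_summary <- cohort_summary(med_rows, n_boot = config$n_boot,
                                     seed = config$stats_seed)
  accumulated_summary <- cohort_summary(
    accum_diffs[, c("patient", "endpoint", "delta", "delta_pct")],
    n_boot = config$n_boot, seed = config$stats_seed)

  assoc_table <- NULL
  if (nrow(patient_tbl) >= 4) {
    assoc_table <- build_assoc_table(patient_tbl, panel_tbl,
                                     n_boot = config$n_boot,
                                     seed = config$stats_seed)
  }

  grades <- assign_synthetic_grade(v45_accum)
  ntcp_cmp <- compare_planned_accumulated(v45_planned, v45_accum,
                                          stratum = paste0("grade", grades))
  qa_ledger <- do.call(rbind, qa_rows)

  result <- structure(list(
    fraction_summary = fraction_summary,
    accumulated_summary = accumulated_summary,
    assoc_table = assoc_table, ntcp_comparison = ntcp_cmp,
    qa_ledger = qa_ledger, patient_tbl = patient_tbl,
    panel_tbl = panel_tbl, config = config
  ), class = "course_result")

  if (!is.null(out_dir)) write_course_result(result, out_dir)
  result
}

#' Write a course result as CSV tables plus a JSON manifest
#'
#' @param result a `course_result` from [run_course()].
#' @param out_dir output directory.
#' @export
write_course_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(result$fraction_summary$summary, "fraction_median_deviations.csv")
  wcsv(result$fraction_summary$exceedance, "fraction_exceedance.csv")
  wcsv(result$accumulated_summary$summary, "accumulated_deviations.csv")
  wcsv(result$accumulated_summary$exceedance, "accumulated_exceedance.csv")
  if (!is.null(result$assoc_table)) wcsv(result$assoc_table,
                                         "association_table.csv")
  wcsv(result$ntcp_comparison$strata, "ntcp_comparison.csv")
  wcsv(result$qa_ledger, "qa_ledger.csv")
  wcsv(result$patient_tbl, "patient_table.csv")
  cfg <- result$config
  manifest <- list(
    package = "rtaccum",
    version = as.character(utils::packageVersion("rtaccum")),
    r_version = R.version.string,
    cohort_seed = cfg$cohort$seed, stats_seed = cfg$stats_seed,
    n_patients = cfg$cohort$n_patients,
    n_fractions = cfg$cohort$n_fractions,
    grid_dim = cfg$cohort$spec$grid_dim,
    spacing = cfg$cohort$spec$spacing,
    curve_factors = cfg$curve_factors,
    prescription_gy = cfg$prescription_gy
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Calibration validation report
#'
#' Agreement metrics between paired reference / evaluated acquisitions:
#' per-pair mean absolute HU error inside the body (when HU grids are
#' supplied) and the 2%/2 mm gamma pass rate between the corresponding
#' dose grids, reported as mean +/- SD across pairs.
#'
#' @param pairs list of lists with elements `hu_reference`,
#'   `hu_evaluated` (optional `voxel_grid`s), `dose_reference`,
#'   `dose_evaluated` (`voxel_grid`s) and optional `roi` mask.
#' @param criteria a [gamma_criteria()] (default 2%/2 mm).
#' @return list of class `calibration_report`: per-pair table plus
#'   `mean_abs_hu`, `sd_abs_hu`, `mean_gamma_pass`, `sd_gamma_pass`.
#' @export
validate_calibration <- function(pairs, criteria = gamma_criteria()) {
  stopifnot(length(pairs) >= 1)
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    hu_err <- NA_real_
    if (!is.null(p$hu_reference) && !is.null(p$hu_evaluated)) {
      diff <- abs(p$hu_evaluated$data - p$hu_reference$data)
      hu_err <- if (!is.null(p$roi)) mean(diff[p$roi]) else mean(diff)
    }
    gp <- gamma_map(p$dose_reference, p$dose_evaluated, criteria,
                    p$roi)$pass_rate
    data.frame(pair = i, mean_abs_hu = hu_err, gamma_pass_pct = gp)
  })
  tbl <- do.call(rbind, rows)
  structure(list(pairs = tbl,
                 mean_abs_hu = mean(tbl$mean_abs_hu),
                 sd_abs_hu = stats::sd(tbl$mean_abs_hu),
                 mean_gamma_pass = mean(tbl$gamma_pass_pct),
                 sd_gamma_pass = stats::sd(tbl$gamma_pass_pct)),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> mean |dHU| %.1f +/- %.1f HU, gamma pass %.1f +/- %.1f %%\n",
              x$mean_abs_hu, x$sd_abs_hu, x$mean_gamma_pass,
              ifelse(is.na(x$sd_gamma_pass), 0, x$sd_gamma_pass)))
  invisible(x)
}
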