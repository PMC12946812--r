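#' Rigid landmark alignment (six degrees of freedom)
#'
#' Least-squares fit of rotation + translation mapping `moving` landmarks
#' onto `fixed` landmarks (Kabsch algorithm on centred coordinates).
#'
#' @param moving,fixed n x 3 matrices of corresponding landmarks (n >= 3,
#'   non-collinear).
#' @return list of class `rigid_transform`: `rotation` (3 x 3),
#'   `translation` (length 3), `residual_mm` (RMS landmark distance after
#'   alignment).
#' @export
rigid_align <- function(moving, fixed) {
  moving <- matrix(as.numeric(moving), ncol = 3)
  fixed <- matrix(as.numeric(fixed), ncol = 3)
  if (nrow(moving) != nrow(fixed)) stop("landmark counts differ",
                                        call. = FALSE)
  if (nrow(moving) < 3) stop("need at least 3 landmark pairs", call. = FALSE)
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  a <- sweep(moving, 2, cm)
  b <- sweep(fixed, 2, cf)
  if (qr(a)$rank < 2) stop("landmarks are collinear or degenerate",
                           call. = FALSE)
  h <- t(a) %*% b
  sv <- svd(h)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
  trans <- cf - as.numeric(rot %*% cm)
  fitted <- t(rot %*% t(moving)) + matrix(trans, nrow(moving), 3,
                                          byrow = TRUE)
  structure(list(rotation = rot, translation = trans,
                 residual_mm = sqrt(mean(rowSums((fitted - fixed)^2)))),
            class = "rigid_transform")
}

#' Apply / invert a rigid transform
#'
#' @param transform a `rigid_transform`.
#' @param points n x 3 matrix of world mm.
#' @return transformed points (`apply_rigid`) or the inverse transform
#'   (`invert_rigid`).
#' @export
apply_rigid <- function(transform, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  t(transform$rotation %*% t(points)) +
    matrix(transform$translation, nrow(points), 3, byrow = TRUE)
}

#' @rdname apply_rigid
#' @export
invert_rigid <- function(transform) {
  rot <- t(transform$rotation)
  structure(list(rotation = rot,
                 translation = -as.numeric(rot %*% transform$translation),
                 residual_mm = transform$residual_mm),
            class = "rigid_transform")
}

dvf_check <- function(dvf, ref) {
  stopifnot(length(dim(dvf)) == 4L, dim(dvf)[4] == 3L)
  if (!identical(dim(dvf)[1:3], dim(ref$data))) {
    stop("DVF and dose grid geometry mismatch", call. = FALSE)
  }
  if (any(!is.finite(dvf))) stop("DVF contains non-finite values",
                                 call. = FALSE)
  invisible(TRUE)
}

#' Warp a fraction dose onto the planning geometry
#'
#' Pull-back (backward) warping: the value at each planning voxel is the
#' trilinear sample of the fraction dose at `planning point + displacement`.
#' Samples falling outside the fraction grid contribute 0 Gy and are
#' counted; more than `warn_outside_frac` of them inside the body triggers a
#' warning.
#'
#' @param fraction_dose `voxel_grid` of Gy on the fraction geometry.
#' @param dvf 4-D displacement array (mm) on the planning geometry, mapping
#'   planning points to fraction points.
#' @param planning_geom `voxel_grid` supplying the planning geometry
#'   (default: same geometry as `fraction_dose`).
#' @param warn_outside_frac warning threshold on the fraction of
#'   out-of-grid samples (default 0.01).
#' @param body_mask optional logical array; when given, the warning
#'   considers only out-of-grid samples originating inside the body (edge
#'   voxels in surrounding air carry no dose information).
#' @return `voxel_grid` of Gy on planning geometry, with attribute
#'   `n_outside`.
#' @export
warp_dose <- function(fraction_dose, dvf, planning_geom = fraction_dose,
                      warn_outside_frac = 0.01, body_mask = NULL) {
  dvf_check(dvf, planning_geom)
  pts <- world_coords(planning_geom)
  disp <- matrix(dvf, ncol = 3)
  res <- interp_trilinear(fraction_dose, pts + disp, fill = 0)
  if (is.null(body_mask)) {
    n_watch <- res$n_outside
    denom <- nrow(pts)
  } else {
    sample_ok <- interp_trilinear(fraction_dose, pts + disp,
                                  fill = NA)$values
    n_watch <- sum(is.na(sample_ok) & as.vector(body_mask))
    denom <- max(1, sum(body_mask))
  }
  if (n_watch > warn_outside_frac * denom) {
    warning(sprintf("%.1f%% of warped samples fell outside the grid",
                    n_watch / denom * 100), call. = FALSE)
  }
  out <- voxel_grid(array(res$values, dim = dim(planning_geom$data)),
                    spacing = planning_geom$spacing,
                    origin = planning_geom$origin)
  attr(out, "n_outside") <- res$n_outside
  out
}

#' Sample a DVF at world points
#'
#' @param dvf 4-D displacement array (mm).
#' @param geom `voxel_grid` giving the DVF geometry.
#' @param points n x 3 world mm.
#' @return n x 3 matrix of displacements (mm).
#' @export
sample_dvf <- function(dvf, geom, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  comp <- function(k) {
    g <- voxel_grid(array(dvf[, , , k], dim = dim(geom$data)),
                    geom$spacing, geom$origin)
    interp_trilinear(g, points, fill = 0)$values
  }
  cbind(comp(1), comp(2), comp(3))
}

#' Registration quality-assurance gates
#'
#' @param tre_max landmark TRE gate, mm (default 3).
#' @param gamma_dose,gamma_dta gamma criteria, % / mm (defaults 2 / 2).
#' @param gamma_pass_min minimum gamma pass rate, % (default 90).
#' @param max_retries retry budget before a fraction is flagged for
#'   exclusion.
#' @return list of class `qa_gates`.
#' @export
qa_gates <- function(tre_max = 3, gamma_dose = 2, gamma_dta = 2,
                     gamma_pass_min = 90, max_retries = 2) {
  stopifnot(tre_max > 0, gamma_dose > 0, gamma_dta > 0, gamma_pass_min > 0)
  structure(list(tre_max = tre_max, gamma_dose = gamma_dose,
                 gamma_dta = gamma_dta, gamma_pass_min = gamma_pass_min,
                 max_retries = as.integer(max_retries)),
            class = "qa_gates")
}

#' QA-gate a deformable registration
#'
#' Checks (i) the landmark target registration error implied by the DVF —
#' planning landmarks displaced by the sampled DVF versus the fraction
#' landmarks — and (ii) the gamma pass rate between the warped dose and the
#' reference (directly recalculated) dose inside the pelvic ROI.  The
#' registration passes when TRE <= `tre_max` and gamma pass >=
#' `gamma_pass_min`.  On failure the retry hook (if any) may supply a
#' refined DVF, up to `max_retries` times; a persistently failing fraction
#' is flagged for exclusion, not an error.
#'
#' @param dvf candidate DVF (4-D mm, planning geometry).
#' @param planning_landmarks,fraction_landmarks n x 3 world mm.
#' @param warped_dose warped fraction dose (`voxel_grid`, planning
#'   geometry).
#' @param reference_dose reference dose for the gamma comparison.
#' @param gates a [qa_gates()].
#' @param roi_mask logical array for the gamma ROI (default whole grid).
#' @param retry_hook optional `function(attempt)` returning a list
#'   `(dvf, warped_dose)` to re-test; default NULL (no-op).
#' @return list of class `qa_result`: `pass`, `tre_mm`, `gamma_pass_pct`,
#'   `retries`, `excluded`.
#' @export
qa_check <- function(dvf, planning_landmarks, fraction_landmarks,
                     warped_dose, reference_dose, gates = qa_gates(),
                     roi_mask = NULL, retry_hook = NULL) {
  attempt <- 0L
  repeat {
    disp <- sample_dvf(dvf, warped_dose, planning_landmarks)
    mapped <- matrix(as.numeric(planning_landmarks), ncol = 3) + disp
    tre_res <- tre(mapped, fraction_landmarks)
    crit <- gamma_criteria(dose_pct = gates$gamma_dose,
                           dta_mm = gates$gamma_dta)
    gm <- gamma_map(reference_dose, warped_dose, crit, roi_mask)
    pass <- tre_res$max <= gates$tre_max &&
      gm$pass_rate >= gates$gamma_pass_min
    if (pass || attempt >= gates$max_retries || is.null(retry_hook)) {
      return(structure(list(pass = pass, tre_mm = tre_res$max,
                            tre_mean_mm = tre_res$mean,
                            gamma_pass_pct = gm$pass_rate,
                            retries = attempt, excluded = !pass),
                       class = "qa_result"))
    }
    attempt <- attempt + 1L
    refined <- retry_hook(attempt)
    if (!is.null(refined$dvf)) dvf <- refined$dvf
    if (!is.null(refined$warped_dose)) warped_dose <- refined$warped_dose
  }
}

#' Voxel-wise dose accumulation
#'
#' Element-wise sum of QA-accepted warped fraction doses on the planning
#' geometry, with a per-fraction ledger.
#'
#' @param warped_doses list of `voxel_grid` doses sharing planning geometry.
#' @param qa_results optional list of `qa_result` objects (same length) to
#'   record in the ledger.
#' @return list of class `accumulated_dose`: `dose` (`voxel_grid`, Gy),
#'   `ledger` (data.frame).
#' @export
accumulate_dose <- function(warped_doses, qa_results = NULL) {
  stopifnot(length(warped_doses) >= 1)
  ref <- warped_doses[[1]]
  total <- array(0, dim = dim(ref$data))
  for (i in seq_along(warped_doses)) {
    stop_if_geometry_mismatch(ref, warped_doses[[i]], "fraction doses")
    total <- total + warped_doses[[i]]$data
  }
  ledger <- data.frame(fraction = seq_along(warped_doses),
                       status = "accepted")
  if (!is.null(qa_results)) {
    ledger$tre_mm <- vapply(qa_results, `[[`, numeric(1), "tre_mm")
    ledger$gamma_pass_pct <- vapply(qa_results, `[[`, numeric(1),
                                    "gamma_pass_pct")
    ledger$retries <- vapply(qa_results, `[[`, integer(1), "retries")
    ledger$status <- ifelse(vapply(qa_results, `[[`, logical(1), "pass"),
                            "accepted", "excluded")
  }
  structure(list(dose = voxel_grid(total, ref$spacing, ref$origin),
                 ledger = ledger),
            class = "accumulated_dose")
}
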