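#' Logistic NTCP model on whole-bowel V45
#'
#' Normal-tissue complication probability for acute bowel toxicity as a
#' logistic function of the absolute whole-bowel volume receiving at least
#' 45 Gy: `NTCP = 1 / (1 + (V50 / V45)^k)`, with published parameters
#' `V50 = 130 cc` (volume at 50% complication probability) and `k = 1.1`
#' (slope).  `V45 = 0` returns 0 by continuous limit.
#'
#' @param v45 whole-bowel V45 in cc (vectorised, >= 0).
#' @param v50 volume at 50% NTCP, cc (default 130).
#' @param k slope parameter (default 1.1).
#' @return probability in `[0, 1)`.
#' @export
ntcp <- function(v45, v50 = 130, k = 1.1) {
  stopifnot(v50 > 0, k > 0)
  if (any(v45 < 0)) stop("V45 must be non-negative", call. = FALSE)
  out <- ifelse(v45 == 0, 0, 1 / (1 + (v50 / v45)^k))
  unname(out)
}

#' Classify V45 into exploratory triage bands
#'
#' Bands `< 300 cc`, `[300, 500] cc` and `> 500 cc` by default (edges
#' belong to the middle band).
#'
#' @param v45 V45 in cc (vectorised).
#' @param edges strictly increasing band edges, cc (default
#'   `c(300, 500)`).
#' @return factor with levels `"<300"`, `"300-500"`, `">500"` (labels
#'   derived from `edges`).
#' @export
classify_band <- function(v45, edges = c(300, 500)) {
  stopifnot(length(edges) == 2, diff(edges) > 0)
  if (any(v45 < 0)) stop("V45 must be non-negative", call. = FALSE)
  labs <- c(paste0("<", edges[1]),
            paste0(edges[1], "-", edges[2]),
            paste0(">", edges[2]))
  out <- ifelse(v45 < edges[1], labs[1],
                ifelse(v45 <= edges[2], labs[2], labs[3]))
  factor(out, levels = labs)
}

#' Planned versus accumulated V45 / NTCP comparison
#'
#' Per patient, NTCP is computed from the planned and the accumulated DVH
#' V45; per stratum (e.g. toxicity grade or triage band) the function
#' reports means +/- SD of V45 and NTCP and a two-sided paired t-test on
#' the planned-versus-accumulated NTCP (and V45).  Strata with fewer than
#' two patients, or with zero-variance paired differences, are flagged
#' (`degenerate`) rather than assigned a spurious p-value.
#'
#' @param v45_planned,v45_accumulated numeric vectors, cc, one per patient.
#' @param stratum factor/character stratum label per patient (default: one
#'   stratum).
#' @param model_v50,model_k NTCP parameters.
#' @return list of class `ntcp_comparison`: `patients` (per-patient
#'   table) and `strata` (per-stratum summary with paired-test p-values).
#' @export
compare_planned_accumulated <- function(v45_planned, v45_accumulated,
                                        stratum = NULL, model_v50 = 130,
                                        model_k = 1.1) {
  n <- length(v45_planned)
  stopifnot(length(v45_accumulated) == n)
  if (is.null(stratum)) stratum <- rep("all", n)
  stopifnot(length(stratum) == n)
  patients <- data.frame(
    patient = seq_len(n), stratum = as.character(stratum),
    v45_planned = v45_planned, v45_accumulated = v45_accumulated,
    ntcp_planned = ntcp(v45_planned, model_v50, model_k),
    ntcp_accumulated = ntcp(v45_accumulated, model_v50, model_k)
  )
  paired_p <- function(a, b) {
    if (length(a) < 2) return(list(p = NA_real_, degenerate = TRUE))
    d <- b - a
    if (stats::sd(d) < 1e-12) {
      return(list(p = NA_real_, degenerate = TRUE))
    }
    list(p = stats::t.test(b, a, paired = TRUE)$p.value, degenerate = FALSE)
  }
  strata <- do.call(rbind, lapply(split(patients, patients$stratum),
                                  function(g) {
    tv <- paired_p(g$v45_planned, g$v45_accumulated)
    tn <- paired_p(g$ntcp_planned, g$ntcp_accumulated)
    data.frame(
      stratum = g$stratum[1], n = nrow(g),
      v45_planned_mean = mean(g$v45_planned),
      v45_planned_sd = stats::sd(g$v45_planned),
      v45_accum_mean = mean(g$v45_accumulated),
      v45_accum_sd = stats::sd(g$v45_accumulated),
      ntcp_planned_mean = mean(g$ntcp_planned),
      ntcp_planned_sd = stats::sd(g$ntcp_planned),
      ntcp_accum_mean = mean(g$ntcp_accumulated),
      ntcp_accum_sd = stats::sd(g$ntcp_accumulated),
      p_v45 = tv$p, p_ntcp = tn$p,
      degenerate = tv$degenerate || tn$degenerate,
      row.names = NULL
    )
  }))
  rownames(strata) <- NULL
  structure(list(patients = patients, strata = strata,
                 model = list(v50 = model_v50, k = model_k)),
            class = "ntcp_comparison")
}

#' @export
print.ntcp_comparison <- function(x, ...) {
  cat("<ntcp_comparison> V50 =", x$model$v50, "cc, k =", x$model$k, "\n")
  print(x$strata, digits = 3)
  invisible(x)
}

#' Assign synthetic toxicity grades from triage bands
#'
#' Grade labels for synthetic cohorts: band membership of the accumulated
#' V45 maps to grades 1/2/3, with optional label noise (probability of
#' moving one grade up or down).  Carries no clinical validity; it exists
#' so comparison tables can be produced at full shape.
#'
#' @param v45_accumulated cc, one per patient.
#' @param edges triage band edges (default `c(300, 500)`).
#' @param label_noise probability of a one-step grade flip.
#' @param seed RNG seed used when `label_noise > 0`.
#' @return integer grades 1..3.
#' @export
assign_synthetic_grade <- function(v45_accumulated, edges = c(300, 500),
                                   label_noise = 0, seed = 1) {
  g <- as.integer(classify_band(v45_accumulated, edges))
  if (label_noise > 0) {
    with_seed(seed, {
      flip <- stats::runif(length(g)) < label_noise
      dir <- sample(c(-1L, 1L), length(g), replace = TRUE)
      g[flip] <- pmin(pmax(g[flip] + dir[flip], 1L), 3L)
    })
  }
  g
}
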