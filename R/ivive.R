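#' Physiological parameters for IVIVE
#'
#' Standard human scalars used to extrapolate suspension-assay intrinsic
#' clearance to whole-body steady-state kinetics. Defaults are conventional
#' adult values; every scalar is overridable, and none of the scalar-free
#' dosimetry identities depend on them.
#'
#' @param body_weight_kg Body weight (default 70 kg).
#' @param gfr_L_per_h Glomerular filtration rate (default 6.7 L/h); renal
#'   clearance is passive, `GFR * f_ub`.
#' @param hepatic_blood_flow_L_per_h Hepatic blood flow Q_h (default 90 L/h).
#' @param liver_mass_g Liver mass (default 1800 g).
#' @param hepatocellularity_millions_per_g Hepatocytes per gram of liver
#'   (default 110 x 10^6 cells/g).
#' @param dose_rate_mg_per_kg_day Continuous oral dose rate for the
#'   steady-state calculation (default 1 mg/kg/day).
#' @return Object of class `physio_params`.
#' @export
physio_params <- function(body_weight_kg = 70, gfr_L_per_h = 6.7,
                          hepatic_blood_flow_L_per_h = 90,
                          liver_mass_g = 1800,
                          hepatocellularity_millions_per_g = 110,
                          dose_rate_mg_per_kg_day = 1) {
  p <- list(body_weight_kg = body_weight_kg, gfr_L_per_h = gfr_L_per_h,
            hepatic_blood_flow_L_per_h = hepatic_blood_flow_L_per_h,
            liver_mass_g = liver_mass_g,
            hepatocellularity_millions_per_g = hepatocellularity_millions_per_g,
            dose_rate_mg_per_kg_day = dose_rate_mg_per_kg_day)
  if (any(vapply(p, function(x) !is.numeric(x) || x <= 0, logical(1))))
    stop("all physiological parameters must be positive numbers")
  structure(p, class = "physio_params")
}

#' Fraction unbound in blood from fraction unbound in plasma
#'
#' `f_ub = f_up / R_b`, where R_b is the blood-to-plasma concentration
#' ratio. Values above 1 are clipped to 1 with a warning; a missing R_b
#' defaults to 1 (plasma and blood treated as equivalent) with a warning.
#'
#' @param fup Fraction unbound in plasma, in (0, 1].
#' @param blood_plasma_ratio Blood-to-plasma partitioning ratio (> 0), or
#'   `NA` to use the default of 1.
#' @return Fraction unbound in blood, in (0, 1].
#' @export
fub_from_fup <- function(fup, blood_plasma_ratio = 1) {
  if (!is.finite(fup) || fup <= 0 || fup > 1)
    stop("fup must be in (0, 1]")
  if (is.na(blood_plasma_ratio)) {
    warning("missing blood_plasma_ratio; defaulting to 1")
    blood_plasma_ratio <- 1
  }
  if (blood_plasma_ratio <= 0)
    stop("blood_plasma_ratio must be > 0")
  fub <- fup / blood_plasma_ratio
  if (fub > 1) {
    warning("f_ub = fup / R_b exceeds 1; clipped to 1")
    fub <- 1
  }
  fub
}

#' Scale per-cell intrinsic clearance to the whole liver
#'
#' `Cl_int,whole = Cl_int * hepatocellularity * liver_mass * 60 * 1e-6` L/h:
#' µL/min per million cells, times millions of cells per gram, times grams,
#' times 60 min/h, times 1e-6 L/µL.
#'
#' @param clint Intrinsic clearance, µL/min/10^6 cells (>= 0).
#' @param physio A [physio_params()].
#' @return Whole-liver intrinsic clearance, L/h.
#' @export
scale_clint <- function(clint, physio = physio_params()) {
  stopifnot(all(clint >= 0))
  clint * physio$hepatocellularity_millions_per_g * physio$liver_mass_g *
    60 * 1e-6
}

#' Well-stirred hepatic clearance
#'
#' Restrictive well-stirred liver model:
#' `Cl_h = Q_h * f_ub * Cl_int,whole / (Q_h + f_ub * Cl_int,whole)`, which
#' approaches the unbound intrinsic clearance when metabolism is slow and
#' saturates at hepatic blood flow `Q_h` when it is fast.
#'
#' @param cl_int_whole Whole-liver intrinsic clearance, L/h (>= 0).
#' @param fub Fraction unbound in blood.
#' @param physio A [physio_params()].
#' @return Hepatic blood clearance, L/h, in `[0, Q_h]`.
#' @export
hepatic_clearance <- function(cl_int_whole, fub, physio = physio_params()) {
  stopifnot(all(cl_int_whole >= 0), all(fub >= 0))
  q <- physio$hepatic_blood_flow_L_per_h
  q * fub * cl_int_whole / (q + fub * cl_int_whole)
}

#' Steady-state blood concentration under continuous unit dosing
#'
#' Forward dosimetry with the generic steady-state TK model: total clearance
#' is passive renal filtration of unbound chemical (`GFR * f_ub`) plus
#' well-stirred hepatic clearance; the steady-state blood concentration under
#' a continuous oral dose is
#' `C_ss = (dose_rate * BW / 24) / (GFR * f_ub + Cl_h)` in mg/L, converted
#' to µM via the molecular weight.
#'
#' @param record One chemical's metadata: a list or one-row data frame with
#'   `chemical_id`, `mol_wt`, `fup` and (optionally) `blood_plasma_ratio`.
#' @param clint Intrinsic clearance, µL/min/10^6 cells.
#' @param physio A [physio_params()].
#' @return List with `chemical_id`, `fub`, `cl_hepatic_L_per_h`,
#'   `cl_renal_L_per_h`, `css_mg_per_L`, `css_uM`.
#' @export
css_steady_state <- function(record, clint, physio = physio_params()) {
  record <- as.list(record)
  stopifnot(is.finite(record$mol_wt), record$mol_wt > 0)
  bpr <- if (is.null(record$blood_plasma_ratio)) 1 else record$blood_plasma_ratio
  fub <- fub_from_fup(record$fup, bpr)
  cl_renal <- physio$gfr_L_per_h * fub
  cl_h <- hepatic_clearance(scale_clint(clint, physio), fub, physio)
  cl_total <- cl_renal + cl_h
  if (cl_total <= 0)
    stop("no elimination pathway: total clearance is 0 for ",
         record$chemical_id)
  css_mg_L <- physio$dose_rate_mg_per_kg_day * physio$body_weight_kg / 24 /
    cl_total
  list(chemical_id = record$chemical_id, fub = fub,
       cl_hepatic_L_per_h = cl_h, cl_renal_L_per_h = cl_renal,
       css_mg_per_L = css_mg_L,
       css_uM = css_mg_L / record$mol_wt * 1000)
}

#' Point of departure from bioactivity curves
#'
#' Filters a chemical's concentration-response curves to reviewed positives
#' (at most `max_flags` caution flags, hitcall at or above `hitcall_min`) and
#' takes the 5th-percentile AC50 of the survivors as the in vitro point of
#' departure. Returns `NA` when no curve survives (no positive activity).
#'
#' @param curves Data frame in the bioactivity-curve schema (see
#'   [read_curve_table()]), already restricted to one chemical.
#' @param hitcall_min Minimum hitcall for an active curve (default 0.9).
#' @param max_flags Maximum tolerated caution flags (default 3, i.e. curves
#'   with four or more flags are censored).
#' @param prob Percentile of the surviving AC50s (default 0.05).
#' @param quantile_type Quantile algorithm (default 7).
#' @return POD in µM, or `NA_real_` when no positive curves survive.
#' @export
derive_pod <- function(curves, hitcall_min = 0.9, max_flags = 3,
                       prob = 0.05, quantile_type = 7) {
  if (is.null(curves) || nrow(curves) == 0) return(NA_real_)
  keep <- curves$n_flags <= max_flags & curves$hitcall >= hitcall_min
  ac50 <- curves$ac50_uM[keep]
  if (!length(ac50)) return(NA_real_)
  unname(stats::quantile(ac50, probs = prob, type = quantile_type))
}

#' Administered equivalent dose by reverse dosimetry
#'
#' The external dose rate producing a steady-state concentration equal to
#' the in vitro point of departure: `AED = POD / C_ss * dose_rate`, with
#' `C_ss` evaluated at the unit dose rate. The identity
#' `AED * C_ss = POD * dose_rate` holds exactly for every chemical,
#' independent of physiological scalars.
#'
#' @param pod_uM Point of departure, µM (> 0).
#' @param css_uM Steady-state concentration at the unit dose rate, µM (> 0).
#' @param dose_rate_mg_per_kg_day Unit dose rate (default 1 mg/kg/day).
#' @return AED in mg/kg/day, or `NA_real_` when `pod_uM` is `NA`.
#' @export
aed_reverse_dosimetry <- function(pod_uM, css_uM,
                                  dose_rate_mg_per_kg_day = 1) {
  if (is.na(pod_uM)) return(NA_real_)
  if (!is.finite(pod_uM) || pod_uM <= 0 || !is.finite(css_uM) || css_uM <= 0)
    stop("pod_uM and css_uM must be positive")
  pod_uM / css_uM * dose_rate_mg_per_kg_day
}

#' Propagate clearance and binding uncertainty into the AED
#'
#' Monte-Carlo reverse dosimetry: jointly resamples posterior intrinsic
#' clearance draws and fraction-unbound samples, recomputes C_ss and the AED
#' for each draw, and reports the median and central 95% interval. When
#' `n_draws` covers the full clint-by-fup grid the computation enumerates the
#' grid exactly instead of resampling, so degenerate inputs collapse to the
#' point AED.
#'
#' @param clint_samples Posterior Cl_int draws, µL/min/10^6 cells (e.g.
#'   [clint_draws()]).
#' @param fup_samples Samples of the fraction unbound in plasma.
#' @param record Chemical metadata as in [css_steady_state()].
#' @param physio A [physio_params()].
#' @param pod_uM Point of departure, µM.
#' @param n_draws Number of Monte-Carlo draws (default 1000).
#' @param seed Integer seed (resampling is deterministic given it).
#' @return List with `aed_median`, `aed_ci95` (length-2), `css_uM_median`
#'   and `n_draws_used`.
#' @export
propagate_uncertainty <- function(clint_samples, fup_samples, record,
                                  physio = physio_params(), pod_uM,
                                  n_draws = 1000, seed = 1L) {
  if (!length(clint_samples) || !length(fup_samples))
    stop("empty sample sets")
  if (is.na(pod_uM)) stop("pod_uM must be available for reverse dosimetry")
  record <- as.list(record)
  n_grid <- length(clint_samples) * length(fup_samples)
  if (n_draws >= n_grid) {
    grid <- expand.grid(ci = seq_along(clint_samples),
                        fi = seq_along(fup_samples))
    ci <- grid$ci; fi <- grid$fi
  } else {
    set.seed(as.integer(seed))
    ci <- sample.int(length(clint_samples), n_draws, replace = TRUE)
    fi <- sample.int(length(fup_samples), n_draws, replace = TRUE)
  }
  css <- vapply(seq_along(ci), function(j) {
    rec <- record
    rec$fup <- fup_samples[fi[j]]
    css_steady_state(rec, clint_samples[ci[j]], physio)$css_uM
  }, numeric(1))
  aed <- pod_uM / css * physio$dose_rate_mg_per_kg_day
  list(aed_median = stats::median(aed),
       aed_ci95 = unname(stats::quantile(aed, c(0.025, 0.975), type = 7)),
       css_uM_median = stats::median(css),
       n_draws_used = length(aed))
}

#' Full IVIVE for a panel of chemicals
#'
#' Runs forward and reverse dosimetry for every chemical: fraction unbound in
#' blood, whole-body hepatic and renal clearance, steady-state concentration
#' at the unit dose, point of departure from the bioactivity curves, and the
#' administered equivalent dose.
#'
#' @param chemicals Data frame in the [read_chemical_table()] schema.
#' @param clint Named numeric vector of Cl_int values (µL/min/10^6 cells),
#'   names matching `chemical_id`.
#' @param curves Optional data frame of bioactivity curves for all chemicals
#'   ([read_curve_table()] schema); when `NULL`, POD and AED are `NA`.
#' @param physio A [physio_params()].
#' @return Data frame with one row per chemical: `chemical_id, fub,
#'   cl_hepatic_L_per_h, cl_renal_L_per_h, css_mg_per_L, css_uM, pod_uM,
#'   aed_mg_per_kg_day`.
#' @export
ivive_panel <- function(chemicals, clint, curves = NULL,
                        physio = physio_params()) {
  miss <- setdiff(chemicals$chemical_id, names(clint))
  if (length(miss))
    stop("no clint estimate for: ", paste(miss, collapse = ", "))
  rows <- lapply(seq_len(nrow(chemicals)), function(i) {
    rec <- as.list(chemicals[i, ])
    res <- css_steady_state(rec, clint[[rec$chemical_id]], physio)
    pod <- if (is.null(curves)) NA_real_
           else derive_pod(curves[curves$chemical_id == rec$chemical_id, ])
    aed <- if (is.na(pod)) NA_real_
           else aed_reverse_dosimetry(pod, res$css_uM,
                                      physio$dose_rate_mg_per_kg_day)
    data.frame(chemical_id = res$chemical_id, fub = res$fub,
               cl_hepatic_L_per_h = res$cl_hepatic_L_per_h,
               cl_renal_L_per_h = res$cl_renal_L_per_h,
               css_mg_per_L = res$css_mg_per_L, css_uM = res$css_uM,
               pod_uM = pod, aed_mg_per_kg_day = aed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
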