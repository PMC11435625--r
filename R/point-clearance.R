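#' Fit a mass-spectrometric calibration curve
#'
#' Estimates the response factor (RF) relating instrument response (peak area
#' or peak-area ratio to internal standard) to concentration by zero-intercept
#' least squares of response on nominal concentration across the calibration
#' standards: RF = sum(x*y) / sum(x^2). The residual scatter is summarised on
#' the log scale, where multiplicative measurement error is additive.
#'
#' @param dataset A [depletion_dataset()] containing calibration rows at two
#'   or more distinct nominal concentrations.
#' @return Object of class `calibration_fit` with fields `chemical_id`,
#'   `response_factor` (response units per µM), `fit_residual_sd` (log scale)
#'   and `n_points`.
#' @export
fit_calibration <- function(dataset) {
  m <- dataset$measurements
  cal <- m[m$condition == "calibration", ]
  if (nrow(cal) < 2 || length(unique(cal$nominal_conc_uM)) < 2)
    stop("calibration error: need >= 2 calibration rows at >= 2 distinct ",
         "nominal concentrations for ", dataset$chemical_id)
  x <- cal$nominal_conc_uM
  y <- cal$response
  rf <- sum(x * y) / sum(x * x)
  if (!is.finite(rf) || rf <= 0)
    stop("calibration error: nonpositive response factor for ",
         dataset$chemical_id)
  pos <- y > 0
  res_sd <- if (sum(pos) >= 2) stats::sd(log(y[pos]) - log(rf * x[pos])) else 0
  structure(list(chemical_id = dataset$chemical_id,
                 response_factor = rf,
                 fit_residual_sd = res_sd,
                 n_points = nrow(cal)),
            class = "calibration_fit")
}

#' Convert raw responses to concentrations
#'
#' Divides each measured response by the calibration response factor to give
#' concentration in µM, and flags (without dropping) values below the limit of
#' quantitation as left-censored.
#'
#' @param dataset A [depletion_dataset()].
#' @param cal A `calibration_fit` for the same chemical (see
#'   [fit_calibration()]).
#' @return The measurement data frame with added columns `conc_uM` and
#'   `censored` (logical, `TRUE` when `conc_uM < loq_uM`).
#' @export
quantify <- function(dataset, cal) {
  if (!identical(cal$chemical_id, dataset$chemical_id))
    stop("calibration fit is for ", cal$chemical_id, ", dataset is ",
         dataset$chemical_id)
  if (!is.finite(cal$response_factor) || cal$response_factor <= 0)
    stop("invalid calibration: response_factor must be > 0")
  m <- dataset$measurements
  m$conc_uM <- m$response / cal$response_factor
  m$censored <- m$conc_uM < dataset$loq_uM
  m
}

#' Log-linear regression of a depletion time course
#'
#' Ordinary least squares of the natural log of concentration on incubation
#' time for one condition, the semilog analysis standard for first-order
#' substrate depletion: the slope is minus the elimination rate constant
#' (per minute). Censored (< LOQ) observations are excluded; the frequentist
#' fit has no censoring mechanism (the Bayesian model does).
#'
#' @param quantified Data frame from [quantify()] restricted to one condition
#'   (or carrying a `condition` column with a single level).
#' @return Object of class `loglinear_fit`: `slope`, `slope_se` (per minute),
#'   `p_value` (two-sided t-test of slope = 0), `p_depletion` (one-sided,
#'   H1: slope < 0), `intercept` (ln µM), `r_squared`, `n_obs`, `condition`.
#' @export
fit_log_linear <- function(quantified) {
  cond <- unique(quantified$condition)
  if (length(cond) > 1)
    stop("fit_log_linear expects a single condition, got: ",
         paste(cond, collapse = ", "))
  keep <- !quantified$censored & quantified$conc_uM > 0
  d <- quantified[keep, ]
  if (nrow(d) < 3 || length(unique(d$time_min)) < 2)
    stop("regression error: insufficient quantifiable data (",
         nrow(d), " uncensored observations)")
  logc <- log(d$conc_uM)
  if (diff(range(logc)) < 1e-12) {   # exactly constant series
    return(structure(list(slope = 0, slope_se = 0, p_value = 1,
                          p_depletion = 1, intercept = mean(logc),
                          r_squared = 0, n_obs = nrow(d),
                          condition = cond),
                     class = "loglinear_fit"))
  }
  fit <- stats::lm(logc ~ time_min, data = d)
  sm <- suppressWarnings(summary(fit))   # perfect fits warn in summary.lm
  cf <- sm$coefficients
  slope <- cf["time_min", "Estimate"]
  se <- cf["time_min", "Std. Error"]
  df <- fit$df.residual
  if (se == 0) {           # exact (noiseless) series: degenerate t statistic
    p2 <- if (slope == 0) 1 else 0
    p1 <- if (slope == 0) 1 else if (slope < 0) 0 else 1
  } else {
    tval <- slope / se
    p2 <- 2 * stats::pt(-abs(tval), df)
    p1 <- stats::pt(tval, df)
  }
  structure(list(slope = slope, slope_se = se, p_value = p2,
                 p_depletion = p1,
                 intercept = cf["(Intercept)", "Estimate"],
                 r_squared = sm$r.squared,
                 n_obs = nrow(d), condition = cond),
            class = "loglinear_fit")
}

#' Intrinsic clearance from a depletion regression
#'
#' Applies the significance gate and converts the first-order depletion rate
#' to intrinsic clearance. A chemical is called significantly cleared when the
#' one-sided test of depletion (slope < 0) rejects at `alpha`; otherwise
#' Cl_int is set to 0. For significant depletion, half-life = ln(2) / k and
#' Cl_int = k * 1000 / density in µL/min/10^6 cells, using the suspension
#' identity that each 10^6 cells occupy 1000/density µL of incubation.
#'
#' @param fit A `loglinear_fit` for the cells condition.
#' @param dataset The [depletion_dataset()] the fit came from (supplies the
#'   cell density).
#' @param alpha Significance level for the depletion gate (default 0.05).
#' @return List with `chemical_id`, `slope`, `half_life_min` (`NA` when not
#'   significant), `clint` (µL/min/10^6 cells, 0 when the gate fails),
#'   `clint_raw` (the ungated regression estimate `max(0, -slope) * 1000 /`
#'   `density`, the quantity to use for parameter-recovery studies where the
#'   detection gate would censor weak but real clearance), `significant`.
#' @export
clint_from_fit <- function(fit, dataset, alpha = 0.05) {
  sig <- is.finite(fit$p_depletion) && fit$p_depletion < alpha && fit$slope < 0
  if (sig) {
    k <- -fit$slope
    half_life <- log(2) / k
    clint <- k * 1000 / dataset$cell_density_millions_per_mL
  } else {
    half_life <- NA_real_
    clint <- 0
  }
  list(chemical_id = dataset$chemical_id, slope = fit$slope,
       half_life_min = half_life, clint = clint,
       clint_raw = max(0, -fit$slope) * 1000 /
         dataset$cell_density_millions_per_mL,
       significant = sig)
}

#' Assess abiotic (non-metabolic) loss in negative controls
#'
#' Runs the same log-linear machinery on the time-matched negative controls
#' (media-only and/or heat-inactivated hepatocytes) to decide whether
#' non-metabolic losses — hydrolysis, volatilisation, adsorption — are
#' significant.
#'
#' @inheritParams quantify
#' @param alpha Significance level (default 0.05).
#' @return List with `fit` (a `loglinear_fit`, or `NULL`), `abiotic_significant`
#'   and `abiotic_rate` (per minute, `max(0, -slope)`); when the dataset has no
#'   control rows, returns all-absent with a warning.
#' @export
assess_abiotic <- function(dataset, cal, alpha = 0.05) {
  q <- quantify(dataset, cal)
  ctrl <- q[q$condition %in% .CONTROL_CONDITIONS, ]
  if (nrow(ctrl) == 0) {
    warning("no control rows for ", dataset$chemical_id,
            "; abiotic loss not assessable")
    return(list(fit = NULL, abiotic_significant = NA, abiotic_rate = NA_real_))
  }
  ctrl$condition <- "control"   # pool no-cell and heat-inactivated rows
  fit <- fit_log_linear(ctrl)
  sig <- is.finite(fit$p_depletion) && fit$p_depletion < alpha && fit$slope < 0
  list(fit = fit, abiotic_significant = sig,
       abiotic_rate = max(0, -fit$slope))
}

#' Point-estimate intrinsic clearance from a depletion experiment
#'
#' The frequentist substrate-depletion pipeline: fit the calibration curve,
#' quantify all responses, regress ln(concentration) on time for the
#' live-cell condition, gate on significance of depletion, convert to
#' half-life and intrinsic clearance, and assess abiotic loss in the
#' controls. This is the standard point analysis against which the Bayesian
#' model ([clint_bayes()]) is compared.
#'
#' @param dataset A [depletion_dataset()].
#' @param alpha Significance level for the depletion gate (default 0.05).
#' @param cal Optional pre-fitted `calibration_fit`; by default fitted from
#'   the dataset's calibration rows.
#' @return Object of class `clint_point` with components `chemical_id`, `cal`,
#'   `quantified`, `fit_cells`, `abiotic` and `estimate` (see
#'   [clint_from_fit()]; plus `abiotic_rate`, `abiotic_significant`, and
#'   `clint_corrected`, the optional control-corrected value
#'   `max(0, k_cells - k_abiotic) * 1000 / density`).
#' @examples
#' truth <- simulation_truth("DTX-EX", k_bio_true = 0.005, noise_sd_true = 0.05)
#' d <- simulate_depletion(truth)$dataset
#' fit <- clint_point(d)
#' print(fit)
#' coef(fit)
#' @export
clint_point <- function(dataset, alpha = 0.05, cal = NULL) {
  if (is.null(cal)) cal <- fit_calibration(dataset)
  q <- quantify(dataset, cal)
  cells <- q[q$condition == "cells", ]
  fit_cells <- fit_log_linear(cells)
  est <- clint_from_fit(fit_cells, dataset, alpha = alpha)
  has_controls <- any(q$condition %in% .CONTROL_CONDITIONS)
  ab <- if (has_controls) assess_abiotic(dataset, cal, alpha = alpha)
        else list(fit = NULL, abiotic_significant = NA, abiotic_rate = NA_real_)
  est$abiotic_significant <- ab$abiotic_significant
  est$abiotic_rate <- ab$abiotic_rate
  k_cells <- max(0, -fit_cells$slope)
  k_ab <- if (is.finite(ab$abiotic_rate)) ab$abiotic_rate else 0
  est$clint_corrected <- if (est$significant)
    max(0, k_cells - k_ab) * 1000 / dataset$cell_density_millions_per_mL
  else 0
  structure(list(chemical_id = dataset$chemical_id, cal = cal,
                 quantified = q, fit_cells = fit_cells, abiotic = ab,
                 estimate = est, alpha = alpha, dataset = dataset),
            class = "clint_point")
}

#' @export
print.clint_point <- function(x, ...) {
  e <- x$estimate
  cat("Point intrinsic-clearance fit:", x$chemical_id, "\n")
  cat(sprintf("  slope %.5g /min (two-sided p = %.3g, depletion p = %.3g)\n",
              x$fit_cells$slope, x$fit_cells$p_value, x$fit_cells$p_depletion))
  if (e$significant)
    cat(sprintf("  significant depletion: t1/2 = %.4g min, Cl_int = %.4g uL/min/10^6 cells\n",
                e$half_life_min, e$clint))
  else
    cat("  no significant depletion: Cl_int = 0\n")
  if (isTRUE(e$abiotic_significant))
    cat(sprintf("  abiotic loss significant: k_abiotic = %.4g /min\n",
                e$abiotic_rate))
  invisible(x)
}

#' @export
coef.clint_point <- function(object, ...) {
  e <- object$estimate
  c(slope = e$slope, clint = e$clint,
    half_life_min = e$half_life_min,
    abiotic_rate = if (is.finite(e$abiotic_rate)) e$abiotic_rate else NA_real_)
}

#' @export
summary.clint_point <- function(object, ...) {
  e <- object$estimate
  out <- data.frame(chemical_id = e$chemical_id,
                    slope = e$slope,
                    slope_se = object$fit_cells$slope_se,
                    p_value = object$fit_cells$p_value,
                    half_life_min = e$half_life_min,
                    clint = e$clint,
                    significant = e$significant,
                    abiotic_rate = e$abiotic_rate,
                    abiotic_significant = e$abiotic_significant,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary.clint_point", class(out))
  out
}

#' @export
predict.clint_point <- function(object, times = NULL, ...) {
  f <- object$fit_cells
  if (is.null(times))
    times <- sort(unique(object$quantified$time_min[
      object$quantified$condition == "cells"]))
  exp(f$intercept + f$slope * times)
}

#' @export
residuals.clint_point <- function(object, ...) {
  q <- object$quantified
  cells <- q[q$condition == "cells" & !q$censored & q$conc_uM > 0, ]
  f <- object$fit_cells
  log(cells$conc_uM) - (f$intercept + f$slope * cells$time_min)
}

#' Summarise a panel of intrinsic-clearance estimates
#'
#' Distribution summary in the form screening campaigns report: the number of
#' chemicals, how many showed no significant depletion (Cl_int = 0), the
#' median across the significantly cleared chemicals, and percentiles over
#' all chemicals.
#'
#' @param estimates Numeric vector of Cl_int values (µL/min/10^6 cells), or a
#'   list of estimates/`clint_point` objects carrying `$clint` or
#'   `$estimate$clint`.
#' @param probs Percentile probabilities over all chemicals (default 0.75 and
#'   0.95).
#' @param quantile_type Quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return List with `n`, `n_zero`, `median_significant` (`NA` when no
#'   chemical is significant) and `quantiles`.
#' @export
summarize_clint <- function(estimates, probs = c(0.75, 0.95),
                            quantile_type = 7) {
  if (is.list(estimates))
    estimates <- vapply(estimates, function(e) {
      if (inherits(e, "clint_point")) e$estimate$clint
      else if (!is.null(e$clint)) e$clint
      else stop("cannot extract clint from element")
    }, numeric(1))
  if (!length(estimates)) stop("empty estimate list")
  zero <- estimates <= 0
  list(n = length(estimates),
       n_zero = sum(zero),
       median_significant = if (all(zero)) NA_real_
                            else stats::median(estimates[!zero]),
       quantiles = stats::quantile(estimates, probs = probs,
                                   type = quantile_type, names = TRUE))
}
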