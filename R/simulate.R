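#' Ground-truth parameters for a simulated depletion experiment
#'
#' Describes one chemical's generating process for the synthetic-data
#' emulator: first-order biotic (metabolic) and abiotic loss rates, the
#' mass-spectrometric response factor, multiplicative (lognormal) measurement
#' noise, the quantitation limit, and the sampling design. Defaults emulate
#' the suspension assay design: triplicates on a 0–240 min grid at
#' C_test = 1 µM and 0.5 x 10^6 cells/mL.
#'
#' @param chemical_id Chemical identifier.
#' @param k_bio_true Biotic first-order loss rate, per minute (>= 0).
#' @param k_abio_true Abiotic first-order loss rate, per minute (>= 0).
#' @param rf_true Response factor, response units per µM (> 0).
#' @param noise_sd_true Log-scale standard deviation of multiplicative
#'   measurement noise.
#' @param loq_uM Limit of quantitation, µM.
#' @param c_test_uM Nominal assay concentration, µM.
#' @param cell_density_millions_per_mL Cell density, 10^6 cells/mL.
#' @param time_grid_min Sampled time points, minutes.
#' @param n_replicates Replicates per time point (default 3).
#' @param cal_levels_uM Nominal concentrations of calibration standards.
#' @param has_internal_standard Whether responses are peak-area ratios to an
#'   internal standard (affects the Bayesian noise prior downstream).
#' @param seed Integer seed making the simulation deterministic.
#' @return Object of class `simulation_truth`.
#' @export
simulation_truth <- function(chemical_id,
                             k_bio_true = 0,
                             k_abio_true = 0,
                             rf_true = 1,
                             noise_sd_true = 0.1,
                             loq_uM = 0.05,
                             c_test_uM = 1,
                             cell_density_millions_per_mL = 0.5,
                             time_grid_min = c(0, 15, 30, 60, 120, 240),
                             n_replicates = 3,
                             cal_levels_uM = c(0.1, 0.25, 0.5, 1, 2),
                             has_internal_standard = TRUE,
                             seed = 1L) {
  stopifnot(k_bio_true >= 0, k_abio_true >= 0, rf_true > 0,
            noise_sd_true >= 0, n_replicates >= 1,
            all(time_grid_min >= 0), length(time_grid_min) >= 2)
  structure(list(chemical_id = chemical_id, k_bio_true = k_bio_true,
                 k_abio_true = k_abio_true, rf_true = rf_true,
                 noise_sd_true = noise_sd_true, loq_uM = loq_uM,
                 c_test_uM = c_test_uM,
                 cell_density_millions_per_mL = cell_density_millions_per_mL,
                 time_grid_min = time_grid_min, n_replicates = n_replicates,
                 cal_levels_uM = cal_levels_uM,
                 has_internal_standard = has_internal_standard,
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

#' True intrinsic clearance implied by a simulation truth
#'
#' @param truth A [simulation_truth()].
#' @return Cl_int in µL/min/10^6 cells (`k_bio_true * 1000 / density`).
#' @export
true_clint <- function(truth) {
  truth$k_bio_true * 1000 / truth$cell_density_millions_per_mL
}

#' Simulate one substrate-depletion experiment
#'
#' Generates a full assay dataset from known ground truth: live-cell rows
#' decaying at `k_bio_true + k_abio_true`, negative-control rows decaying at
#' `k_abio_true` alone, and calibration-standard rows, all with responses
#' `rf_true * conc * exp(noise)` under lognormal measurement noise. The
#' output feeds [clint_point()] and [clint_bayes()] unchanged; censoring is
#' applied downstream where responses imply concentrations below the LOQ.
#'
#' @param truth A [simulation_truth()].
#' @param include_controls Include negative-control rows (default `TRUE`).
#' @param control_condition `"no_cells"` or `"heat_inactivated"`.
#' @return List with `dataset` (a [depletion_dataset()]) and `truth`.
#' @export
simulate_depletion <- function(truth, include_controls = TRUE,
                               control_condition = "no_cells") {
  stopifnot(inherits(truth, "simulation_truth"),
            control_condition %in% .CONTROL_CONDITIONS)
  set.seed(truth$seed)
  noise <- function(n) {
    if (truth$noise_sd_true == 0) rep(1, n)
    else exp(stats::rnorm(n, 0, truth$noise_sd_true))
  }
  grid <- expand.grid(replicate = seq_len(truth$n_replicates),
                      time_min = truth$time_grid_min)
  mk_rows <- function(cond, k) {
    conc <- truth$c_test_uM * exp(-k * grid$time_min)
    data.frame(time_min = grid$time_min, condition = cond,
               replicate = grid$replicate,
               response = truth$rf_true * conc * noise(nrow(grid)),
               has_internal_standard = truth$has_internal_standard,
               nominal_conc_uM = NA_real_, stringsAsFactors = FALSE)
  }
  rows <- mk_rows("cells", truth$k_bio_true + truth$k_abio_true)
  if (include_controls)
    rows <- rbind(rows, mk_rows(control_condition, truth$k_abio_true))
  cal <- data.frame(time_min = 0, condition = "calibration",
                    replicate = 1L,
                    response = truth$rf_true * truth$cal_levels_uM *
                      noise(length(truth$cal_levels_uM)),
                    has_internal_standard = truth$has_internal_standard,
                    nominal_conc_uM = truth$cal_levels_uM,
                    stringsAsFactors = FALSE)
  rows <- rbind(rows, cal)
  ds <- depletion_dataset(truth$chemical_id, rows,
                          c_test_uM = truth$c_test_uM,
                          cell_density_millions_per_mL =
                            truth$cell_density_millions_per_mL,
                          loq_uM = truth$loq_uM)
  list(dataset = ds, truth = truth)
}

#' Simulate a screening panel of chemicals
#'
#' Builds a labelled panel in the shape of a PFAS hepatic-clearance campaign:
#' a fixed fraction of metabolically stable chemicals (`k_bio_true = 0`) and
#' the remainder drawing true Cl_int from a lognormal spread, back-converted
#' to a per-minute rate via the cell density. Defaults mirror a 54-chemical
#' panel with 35 stable members and significant-clearance values centred
#' near 4.5 µL/min/10^6 cells with a spread reaching the tens.
#'
#' @param n_chemicals Number of chemicals (default 54).
#' @param fraction_stable Fraction with `k_bio_true = 0` (default 35/54).
#' @param clint_meanlog,clint_sdlog Lognormal parameters (on the
#'   µL/min/10^6 cells scale) for the cleared chemicals' true Cl_int
#'   (defaults `log(4.5)` and 0.9).
#' @param clint_max Truncation cap on true Cl_int (default 50).
#' @param p_abiotic Probability a chemical also degrades abiotically
#'   (default 0.1); abiotic rates drawn uniform on (0.0005, 0.002) per min.
#' @param noise_sd_true Measurement noise sd passed to each truth.
#' @param seed Master seed; per-chemical seeds are derived by fixed offsets.
#' @param ... Further arguments passed to [simulation_truth()].
#' @return List with `datasets` (named list of [depletion_dataset()]) and
#'   `truths` (named list of [simulation_truth()]).
#' @export
simulate_panel <- function(n_chemicals = 54, fraction_stable = 35 / 54,
                           clint_meanlog = log(4.5), clint_sdlog = 0.9,
                           clint_max = 50, p_abiotic = 0.1,
                           noise_sd_true = 0.1, seed = 1L, ...) {
  stopifnot(n_chemicals >= 1, fraction_stable >= 0, fraction_stable <= 1)
  set.seed(seed)
  n_stable <- round(fraction_stable * n_chemicals)
  stable <- rep(c(TRUE, FALSE), c(n_stable, n_chemicals - n_stable))
  clints <- ifelse(stable, 0,
                   pmin(clint_max, stats::rlnorm(n_chemicals, clint_meanlog,
                                                 clint_sdlog)))
  abio <- stats::rbinom(n_chemicals, 1, p_abiotic) *
    stats::runif(n_chemicals, 5e-4, 2e-3)
  ids <- sprintf("SIM-%03d", seq_len(n_chemicals))
  truths <- vector("list", n_chemicals)
  datasets <- vector("list", n_chemicals)
  for (i in seq_len(n_chemicals)) {
    tr <- simulation_truth(ids[i], noise_sd_true = noise_sd_true,
                           seed = (seed + 101L * i) %% .Machine$integer.max, ...)
    tr$k_abio_true <- abio[i]
    tr$k_bio_true <- clints[i] * tr$cell_density_millions_per_mL / 1000
    truths[[i]] <- tr
    datasets[[i]] <- simulate_depletion(tr)$dataset
  }
  names(truths) <- names(datasets) <- ids
  list(datasets = datasets, truths = truths)
}

#' Simulate a bioactivity curve table for one chemical
#'
#' Emulates the inputs to point-of-departure derivation: a set of
#' concentration-response curves with AC50s drawn log-uniformly, continuous
#' hitcalls (active curves above the 0.9 activity threshold), and caution
#' flag counts.
#'
#' @param chemical_id Chemical identifier.
#' @param n_curves Number of curves.
#' @param active_fraction Fraction of curves simulated as active
#'   (hitcall >= 0.9).
#' @param ac50_range_uM Range (µM) for the log-uniform AC50 draw.
#' @param flag_rate Per-review probability of a caution flag; counts are
#'   binomial with 6 review checks.
#' @param seed Integer seed.
#' @return Data frame in the bioactivity-curve schema
#'   (`chemical_id, ac50_uM, hitcall, n_flags`).
#' @export
simulate_curves <- function(chemical_id, n_curves = 20, active_fraction = 0.5,
                            ac50_range_uM = c(0.1, 100), flag_rate = 0.1,
                            seed = 1L) {
  stopifnot(n_curves >= 0)
  set.seed(seed)
  if (n_curves == 0)
    return(data.frame(chemical_id = character(0), ac50_uM = numeric(0),
                      hitcall = numeric(0), n_flags = integer(0)))
  active <- stats::runif(n_curves) < active_fraction
  hit <- ifelse(active, stats::runif(n_curves, 0.9, 1),
                stats::runif(n_curves, 0, 0.9))
  ac50 <- exp(stats::runif(n_curves, log(ac50_range_uM[1]),
                           log(ac50_range_uM[2])))
  data.frame(chemical_id = chemical_id, ac50_uM = ac50, hitcall = hit,
             n_flags = stats::rbinom(n_curves, 6, flag_rate),
             stringsAsFactors = FALSE)
}
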