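#' Prior specification for the Bayesian depletion model
#'
#' The measurement model's priors: a Bernoulli indicator with 50% prior
#' probability that systematic (biotic) clearance occurred, a Bernoulli
#' indicator with 5% prior probability of abiotic degradation, and
#' uniform rate priors bounded between zero and the largest rate
#' distinguishable within the assay, `-ln(LOQ / C_test) / t_max` per minute
#' (the rate at which the test concentration just reaches the quantitation
#' limit by the final time point). The response-factor and noise priors are
#' weakly informative: lognormal around a data-derived crude response factor,
#' and half-normal on the log-scale noise sd, widened when no internal
#' standard was available (recovery cannot be normalised).
#'
#' @param p_clearance Prior probability of biotic clearance (default 0.5).
#' @param p_abiotic Prior probability of abiotic degradation (default 0.05).
#' @param slope_upper Upper bound of the uniform rate priors, per minute;
#'   `NULL` (default) derives it from the dataset's LOQ and time span.
#' @param rf_logsd Lognormal sd of the response-factor prior (default 1).
#' @param noise_sd_scale Half-normal scale of the noise-sd prior
#'   (default 0.5).
#' @param noise_sd_scale_no_is Widened scale used when the dataset lacks an
#'   internal standard (default 1).
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(p_clearance = 0.5, p_abiotic = 0.05,
                       slope_upper = NULL, rf_logsd = 1,
                       noise_sd_scale = 0.5, noise_sd_scale_no_is = 1) {
  stopifnot(p_clearance >= 0, p_clearance <= 1,
            p_abiotic >= 0, p_abiotic <= 1,
            is.null(slope_upper) || slope_upper > 0,
            rf_logsd > 0, noise_sd_scale > 0)
  structure(list(p_clearance = p_clearance, p_abiotic = p_abiotic,
                 slope_lower = 0, slope_upper = slope_upper,
                 rf_logsd = rf_logsd, noise_sd_scale = noise_sd_scale,
                 noise_sd_scale_no_is = noise_sd_scale_no_is),
            class = "prior_spec")
}

#' Build the Bayesian measurement model for one depletion dataset
#'
#' Assembles the likelihood data and resolved priors. The expected
#' concentration is `C_test * exp(-(z_bio k_bio + z_abio k_abio) t)` in the
#' live-cell condition and `C_test * exp(-z_abio k_abio t)` in the controls,
#' so the abiotic component is shared; calibration rows share the response
#' factor and noise sd. Observed responses are lognormal around
#' `RF * C(t)`, with left-censoring at `RF * LOQ`.
#'
#' @param dataset A [depletion_dataset()].
#' @param priors A [prior_spec()].
#' @param prior_only Drop all observations from the likelihood, leaving the
#'   assay constants and priors; sampling such a model recovers the prior
#'   (a standard check that the sampler targets the stated distribution).
#' @return Object of class `depletion_model` (data arrays plus resolved
#'   prior constants), consumed by [run_mcmc()].
#' @export
build_model <- function(dataset, priors = prior_spec(), prior_only = FALSE) {
  m <- dataset$measurements
  if (!any(m$condition == "cells"))
    stop("model error: no cells-condition rows for ", dataset$chemical_id)
  type <- ifelse(m$condition == "cells", 0L,
                 ifelse(m$condition == "calibration", 2L, 1L))
  cal <- m$condition == "calibration"
  # crude response factor anchoring the RF prior: zero-intercept fit on the
  # calibration standards, falling back to the t = 0 cells responses
  rf_loc <- if (any(cal)) {
    sum(m$nominal_conc_uM[cal] * m$response[cal]) /
      sum(m$nominal_conc_uM[cal]^2)
  } else {
    t0 <- m$condition == "cells" & m$time_min == min(m$time_min)
    mean(m$response[t0]) / dataset$c_test_uM
  }
  if (!is.finite(rf_loc) || rf_loc <= 0)
    stop("model error: cannot anchor response-factor prior for ",
         dataset$chemical_id)
  censored <- m$response < rf_loc * dataset$loq_uM & !cal
  t_max <- max(m$time_min[type != 2L])
  k_max <- priors$slope_upper
  if (is.null(k_max))
    k_max <- -log(dataset$loq_uM / dataset$c_test_uM) / t_max
  has_is <- all(m$has_internal_standard)
  noise_scale <- if (has_is) priors$noise_sd_scale
                 else priors$noise_sd_scale_no_is
  logresp <- ifelse(m$response > 0, log(m$response), log(rf_loc) - 50)
  if (prior_only) {
    keep <- logical(0)
    m <- m[keep, ]; type <- type[keep]; cal <- cal[keep]
    censored <- censored[keep]; logresp <- logresp[keep]
  }
  structure(list(chemical_id = dataset$chemical_id,
                 t = m$time_min, logresp = logresp, type = type,
                 censored = censored,
                 logcal = ifelse(cal, log(m$nominal_conc_uM), 0),
                 log_ctest = log(dataset$c_test_uM),
                 log_loq = log(dataset$loq_uM),
                 p_clearance = priors$p_clearance,
                 p_abiotic = priors$p_abiotic,
                 k_max = k_max,
                 rf_logmean = log(rf_loc), rf_logsd = priors$rf_logsd,
                 noise_scale = noise_scale,
                 has_internal_standard = has_is,
                 cell_density_millions_per_mL =
                   dataset$cell_density_millions_per_mL),
            class = "depletion_model")
}

#' Run multi-chain MCMC for the depletion measurement model
#'
#' Metropolis-within-Gibbs: the Bernoulli clearance indicators are drawn from
#' their full conditionals, the rates, response factor and noise sd by
#' adaptive random-walk Metropolis (step sizes adapt during burn-in only,
#' then freeze to preserve detailed balance). When an indicator is 0 its rate
#' is refreshed from the prior (pseudo-prior handling) so chains mix across
#' model configurations. Chains start from overdispersed initial values
#' derived deterministically from the per-chain seed.
#'
#' @param model A `depletion_model` from [build_model()].
#' @param n_chains Number of chains (default 5).
#' @param n_iter Total iterations per chain (default 10000).
#' @param n_burn Burn-in iterations discarded per chain (default 2000).
#' @param seed Master seed; chain `c` uses `seed + 1009 * (c - 1)`.
#' @return Data frame of post-burn-in samples with columns `z_bio`, `z_abio`,
#'   `k_bio`, `k_abio`, `rf`, `noise_sd`, `chain`, `iteration`.
#' @export
run_mcmc <- function(model, n_chains = 5, n_iter = 10000, n_burn = 2000,
                     seed = 1L) {
  stopifnot(inherits(model, "depletion_model"), n_chains >= 2,
            n_iter > n_burn, n_burn >= 0)
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed((as.integer(seed) + 1009L * (ch - 1L)) %% .Machine$integer.max)
    # overdispersed starts: spread rate inits across the prior range and RF
    # inits across twice the prior sd
    k0 <- stats::runif(2, 0, model$k_max)
    z0 <- stats::rbinom(2, 1, 0.5)
    logrf0 <- model$rf_logmean + stats::rnorm(1, 0, 2 * model$rf_logsd)
    nsd0 <- abs(stats::rnorm(1, 0, 2 * model$noise_scale)) + 0.01
    samp <- mcmc_depletion_cpp(model$t, model$logresp, model$type,
                               model$censored, model$logcal,
                               model$log_ctest, model$log_loq,
                               model$p_clearance, model$p_abiotic,
                               model$k_max,
                               model$rf_logmean, model$rf_logsd,
                               model$noise_scale,
                               as.integer(n_iter), as.integer(n_burn),
                               k0[1], k0[2], z0[1], z0[2], logrf0, nsd0)
    keep <- samp[(n_burn + 1):n_iter, , drop = FALSE]
    df <- as.data.frame(keep)
    df$chain <- ch
    df$iteration <- seq_len(nrow(df))
    chains[[ch]] <- df
  }
  do.call(rbind, chains)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' PSRF = sqrt(((n - 1)/n * W + B/n) / W), where W is the mean within-chain
#' variance and B the between-chain variance of the chain means (times n).
#' Degenerate conventions: all chains constant at the same value gives 1;
#' zero within-chain variance with between-chain spread gives `Inf`.
#'
#' @param x Numeric vector of samples.
#' @param chain Integer vector assigning each sample to a chain.
#' @return Scalar PSRF.
#' @export
psrf <- function(x, chain) {
  groups <- split(x, chain)
  m <- length(groups)
  if (m < 2) stop("PSRF needs >= 2 chains")
  n <- min(lengths(groups))
  if (n < 10) stop("PSRF needs >= 10 samples per chain")
  groups <- lapply(groups, function(g) g[seq_len(n)])
  means <- vapply(groups, mean, numeric(1))
  W <- mean(vapply(groups, stats::var, numeric(1)))
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Summarise posterior samples into a clearance posterior
#'
#' Computes the posterior probability of biotic clearance `p_cleared =
#' mean(z_bio)`, the posterior distribution of intrinsic clearance on the
#' reporting scale (`z_bio * k_bio * 1000 / density`, µL/min/10^6 cells) with
#' its median and central 95% credible interval, the posterior probability of
#' abiotic degradation, and PSRF-based convergence over the continuous
#' parameters.
#'
#' @param samples Data frame from [run_mcmc()].
#' @param model The `depletion_model` the samples came from.
#' @param prob Credible-interval mass (default 0.95).
#' @return List with `chemical_id`, `p_cleared`, `clint_median`,
#'   `clint_ci95` (length-2), `p_abiotic_post`, `psrf` (named vector over
#'   continuous parameters), `psrf_max`, `converged`.
#' @export
summarize_posterior <- function(samples, model, prob = 0.95) {
  if (!nrow(samples)) stop("empty post-burn sample")
  dens <- model$cell_density_millions_per_mL
  clint_draws <- samples$z_bio * samples$k_bio * 1000 / dens
  a <- (1 - prob) / 2
  ci <- unname(stats::quantile(clint_draws, c(a, 1 - a), type = 7))
  psrfs <- vapply(c("k_bio", "k_abio", "rf", "noise_sd"),
                  function(p) psrf(samples[[p]], samples$chain), numeric(1))
  psrf_max <- max(psrfs)
  list(chemical_id = model$chemical_id,
       p_cleared = mean(samples$z_bio),
       clint_median = stats::median(clint_draws),
       clint_ci95 = ci,
       p_abiotic_post = mean(samples$z_abio),
       psrf = psrfs,
       psrf_max = psrf_max,
       converged = is.finite(psrf_max) && psrf_max < 1.1)
}

#' Bayesian intrinsic-clearance fit
#'
#' Fits the full Bayesian measurement model to one depletion dataset:
#' jointly infers the mass-spectrometric response factor, Bernoulli-gated
#' biotic and abiotic first-order loss rates, and measurement noise from the
#' raw responses (live cells, negative controls and calibration standards
#' together), by multi-chain MCMC with Gelman-Rubin convergence checking.
#' Unlike the point pipeline ([clint_point()]), censored observations enter
#' the likelihood through the lognormal CDF rather than being dropped, and
#' the 95% credible interval carries the measurement uncertainty forward
#' into IVIVE via [propagate_uncertainty()].
#'
#' @inheritParams run_mcmc
#' @param dataset A [depletion_dataset()].
#' @param priors A [prior_spec()].
#' @param prob Credible-interval mass (default 0.95).
#' @return Object of class `clint_bayes` with components `posterior` (see
#'   [summarize_posterior()]), `samples`, `model`, and the run settings.
#' @examples
#' truth <- simulation_truth("DTX-EX", k_bio_true = 0.005, noise_sd_true = 0.05)
#' d <- simulate_depletion(truth)$dataset
#' fit <- clint_bayes(d, n_chains = 3, n_iter = 1500, n_burn = 500, seed = 7)
#' print(fit)
#' @export
clint_bayes <- function(dataset, priors = prior_spec(), n_chains = 5,
                        n_iter = 10000, n_burn = 2000, seed = 1L,
                        prob = 0.95) {
  model <- build_model(dataset, priors)
  samples <- run_mcmc(model, n_chains = n_chains, n_iter = n_iter,
                      n_burn = n_burn, seed = seed)
  post <- summarize_posterior(samples, model, prob = prob)
  structure(list(chemical_id = dataset$chemical_id, posterior = post,
                 samples = samples, model = model,
                 settings = list(n_chains = n_chains, n_iter = n_iter,
                                 n_burn = n_burn, seed = seed, prob = prob)),
            class = "clint_bayes")
}

#' @export
print.clint_bayes <- function(x, ...) {
  p <- x$posterior
  cat("Bayesian intrinsic-clearance fit:", x$chemical_id, "\n")
  cat(sprintf("  P(cleared) = %.3f, P(abiotic) = %.3f\n",
              p$p_cleared, p$p_abiotic_post))
  cat(sprintf("  Cl_int median %.4g uL/min/10^6 cells, 95%% CrI [%.4g, %.4g]\n",
              p$clint_median, p$clint_ci95[1], p$clint_ci95[2]))
  cat(sprintf("  PSRF max %.3f (%s)\n", p$psrf_max,
              if (p$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.clint_bayes <- function(object, ...) {
  p <- object$posterior
  c(clint_median = p$clint_median, p_cleared = p$p_cleared,
    p_abiotic = p$p_abiotic_post,
    clint_lo = p$clint_ci95[1], clint_hi = p$clint_ci95[2])
}

#' @export
summary.clint_bayes <- function(object, ...) {
  p <- object$posterior
  out <- data.frame(chemical_id = p$chemical_id, p_cleared = p$p_cleared,
                    clint_median = p$clint_median,
                    clint_ci_lo = p$clint_ci95[1],
                    clint_ci_hi = p$clint_ci95[2],
                    p_abiotic_post = p$p_abiotic_post,
                    psrf_max = p$psrf_max, converged = p$converged,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary.clint_bayes", class(out))
  out
}

#' @export
plot.clint_bayes <- function(x, pars = c("k_bio", "rf", "noise_sd"), ...) {
  s <- x$samples
  old <- graphics::par(mfrow = c(length(pars), 1),
                       mar = c(3.5, 4, 1.5, 0.5))
  on.exit(graphics::par(old))
  for (p in pars) {
    graphics::plot(NULL, xlim = range(s$iteration), ylim = range(s[[p]]),
                   xlab = "iteration (post burn-in)", ylab = p,
                   main = paste(x$chemical_id, "-", p))
    for (ch in unique(s$chain)) {
      sub <- s[s$chain == ch, ]
      graphics::lines(sub$iteration, sub[[p]], col = ch)
    }
  }
  invisible(x)
}

#' Posterior intrinsic-clearance draws
#'
#' @param fit A `clint_bayes` object.
#' @return Numeric vector of Cl_int draws (µL/min/10^6 cells), one per
#'   post-burn-in sample: `z_bio * k_bio * 1000 / density`.
#' @export
clint_draws <- function(fit) {
  stopifnot(inherits(fit, "clint_bayes"))
  fit$samples$z_bio * fit$samples$k_bio * 1000 /
    fit$model$cell_density_millions_per_mL
}

#' Concordance between point and Bayesian clearance calls
#'
#' Compares the frequentist significance gate with the Bayesian posterior
#' clearance probability across a panel: per-chemical agreement classes
#' (`both`, `point_only`, `bayes_only`, `neither`, `indeterminate` for
#' non-converged Bayesian fits) and the rank correlation between posterior
#' median and point Cl_int.
#'
#' @param point List of [clint_point()] fits (or their `$estimate` lists).
#' @param bayes List of [clint_bayes()] fits (or [summarize_posterior()]
#'   lists), matched by chemical id.
#' @param threshold Posterior probability above which the Bayesian analysis
#'   confirms clearance (default 0.95, a deliberately conservative call).
#' @return List with `table` (per-chemical data frame), `counts` (named
#'   class counts) and `rank_correlation` (Spearman, over chemicals with
#'   both estimates).
#' @export
concordance_report <- function(point, bayes, threshold = 0.95) {
  pt <- lapply(point, function(x) if (inherits(x, "clint_point")) x$estimate else x)
  by <- lapply(bayes, function(x) if (inherits(x, "clint_bayes")) x$posterior else x)
  pid <- vapply(pt, `[[`, character(1), "chemical_id")
  bid <- vapply(by, `[[`, character(1), "chemical_id")
  orphans <- c(setdiff(pid, bid), setdiff(bid, pid))
  if (length(orphans))
    stop("mismatched chemical ids: ", paste(orphans, collapse = ", "))
  by <- by[match(pid, bid)]
  rows <- lapply(seq_along(pt), function(i) {
    p <- pt[[i]]; b <- by[[i]]
    cls <- if (!isTRUE(b$converged)) "indeterminate"
    else if (p$significant && b$p_cleared > threshold) "both"
    else if (p$significant) "point_only"
    else if (b$p_cleared > threshold) "bayes_only"
    else "neither"
    data.frame(chemical_id = p$chemical_id, point_clint = p$clint,
               point_significant = p$significant,
               bayes_clint_median = b$clint_median,
               p_cleared = b$p_cleared, converged = isTRUE(b$converged),
               class = cls, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  counts <- table(factor(tab$class, levels = c("both", "point_only",
                                               "bayes_only", "neither",
                                               "indeterminate")))
  rc <- if (nrow(tab) >= 3)
    stats::cor(tab$point_clint, tab$bayes_clint_median, method = "spearman")
  else NA_real_
  list(table = tab, counts = counts, rank_correlation = rc)
}
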