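# hepatoclear

Analysis of in vitro hepatic clearance experiments in pooled human
hepatocyte suspensions, and the in vitro–in vivo extrapolation (IVIVE) that
turns them into screening-level dose estimates. The package was built for
high-throughput toxicokinetic (HTTK) evaluation of data-poor chemicals —
PFAS in particular — where substrate-depletion assays, bioactivity
screening data and reverse dosimetry are combined to rank chemicals for
further testing.

## What it computes

**Point estimation.** A substrate-depletion time course follows first-order
kinetics, C(t) = C_test·e^(−kt). `clint_point()` quantifies raw instrument
responses against a zero-intercept calibration curve, fits ln C against
time by OLS, gates on significance of depletion at α = 0.05, and converts
the rate to intrinsic clearance

    Cl_int = k × 1000 / D    [µL/min/10⁶ cells],  t½ = ln 2 / k,

with D the cell density (10⁶ cells/mL). Time-matched negative controls are
assessed the same way for abiotic (non-metabolic) loss.

**Bayesian measurement model.** `clint_bayes()` fits the raw responses of
all conditions jointly: Bernoulli indicators for "any biotic clearance"
(prior 0.5) and "any abiotic degradation" (prior 0.05), uniform rate priors
bounded by the assay's quantitation limit, a shared mass-spectrometric
response factor, lognormal noise, and left-censoring below the LOQ —
sampled by multi-chain adaptive Metropolis-within-Gibbs (C++ core) with
Gelman–Rubin convergence checking (PSRF < 1.1). The posterior yields
P(cleared), the Cl_int median and 95% credible interval.

**IVIVE / reverse dosimetry.** `css_steady_state()` scales Cl_int to the
whole liver, applies the well-stirred liver model and passive renal
filtration, and returns the steady-state blood concentration under
1 mg/kg/day dosing. `derive_pod()` filters bioactivity curves (hitcall
≥ 0.9, < 4 caution flags) and takes the 5th-percentile AC50 as the point
of departure; `aed_reverse_dosimetry()` returns

    AED = POD / C_ss × 1 mg/kg/day,

and `propagate_uncertainty()` carries posterior clearance and binding
uncertainty through to an AED interval. A synthetic-data module
(`simulate_depletion()`, `simulate_panel()`, `simulate_curves()`) generates
assay-shaped datasets with known ground truth so the whole pipeline is
testable end to end.

## Worked example

```r
library(hepatoclear)

truth <- simulation_truth("SIM-042", k_bio_true = 0.004, k_abio_true = 0.001,
                          noise_sd_true = 0.1, seed = 42)
ds  <- simulate_depletion(truth)$dataset   # cells + controls + calibration
fit <- clint_point(ds)
print(fit)
#> Point intrinsic-clearance fit: SIM-042
#>   slope -0.0056757 /min (two-sided p = 3.82e-12, depletion p = 1.91e-12)
#>   significant depletion: t1/2 = 122.1 min, Cl_int = 11.35 uL/min/10^6 cells
#>   abiotic loss significant: k_abiotic = 0.001057 /min

bfit <- clint_bayes(ds, n_chains = 5, n_iter = 4000, n_burn = 1000, seed = 7)
print(bfit)
#> Bayesian intrinsic-clearance fit: SIM-042
#>   P(cleared) = 1.000, P(abiotic) = 0.741
#>   Cl_int median 8.481 uL/min/10^6 cells, 95% CrI [6.822, 10.81]
#>   PSRF max 1.006 (converged)
```

The generating truth was k_bio = 0.004/min and k_abio = 0.001/min, i.e. a
biotic Cl_int of 8 on top of abiotic loss worth 2. The point estimate
(11.35) reports *total* depletion — rate × 2000 at this density — while the
Bayesian model attributes the control-explained share to the abiotic
component and centres the biotic clearance near 8 with its uncertainty
made explicit.

Dosimetry for the same chemical (molecular weight 400 g/mol, fraction
unbound in plasma 0.01):

```r
rec <- list(chemical_id = "SIM-042", mol_wt = 400, fup = 0.01,
            blood_plasma_ratio = 1)
css    <- css_steady_state(rec, fit$estimate$clint)
curves <- simulate_curves("SIM-042", n_curves = 25, active_fraction = 0.6,
                          seed = 3)
pod <- derive_pod(curves)
aed <- aed_reverse_dosimetry(pod, css$css_uM)
#> Css = 5.22 uM, POD = 0.27 uM, AED = 0.052 mg/kg/day
```

So a continuous exposure of about 0.05 mg/kg/day would be expected to
produce steady-state blood levels at this chemical's in vitro bioactivity
threshold — the screening-level quantity used to rank chemicals against
exposure estimates. `pfas_ivive_examples()` ships a published 18-chemical
PFAS example table on which the identity AED = POD/C_ss is exact at each
row's printed precision.

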