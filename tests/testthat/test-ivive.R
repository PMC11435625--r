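test_that("fraction unbound in blood follows the plasma-to-blood transformation", {
  expect_equal(fub_from_fup(0.25, 1), 0.25)                 # ratio 1: identity
  expect_equal(fub_from_fup(0.044, 0.8), 0.055)             # division
  expect_warning(fb <- fub_from_fup(0.9, 0.5), "clipped")   # boundary
  expect_equal(fb, 1)
  expect_warning(fub_from_fup(0.1, NA), "defaulting to 1")
  expect_error(fub_from_fup(0, 1), "fup")
  expect_error(fub_from_fup(0.1, -1), "blood_plasma_ratio")
})

test_that("liver scaling follows the hepatocellularity x mass x unit conversion", {
  ph <- physio_params()
  expect_equal(scale_clint(0, ph), 0)
  expect_equal(scale_clint(1, ph), 1 * 110 * 1800 * 60 * 1e-6)  # 11.88 L/h
  ph2 <- physio_params(liver_mass_g = 3600)
  expect_equal(scale_clint(1, ph2), 2 * scale_clint(1, ph))     # linearity
})

test_that("well-stirred hepatic clearance obeys its limits and closed form", {
  ph <- physio_params(hepatic_blood_flow_L_per_h = 90)
  expect_equal(hepatic_clearance(0, 0.5, ph), 0)
  # flow-limited asymptote
  expect_equal(hepatic_clearance(1e9, 1, ph), 90, tolerance = 1e-6)
  # direct formula arithmetic
  expect_equal(hepatic_clearance(50, 0.01, ph), 90 * 0.01 * 50 / (90 + 0.5),
               tolerance = 1e-10)
  # never exceeds hepatic blood flow
  cls <- hepatic_clearance(c(0, 1, 10, 100, 1e4, 1e8), 0.8, ph)
  expect_true(all(cls <= 90))
  expect_true(all(diff(cls) >= 0))
})

test_that("steady-state concentration matches the renal-only closed form when clint is 0", {
  rec <- list(chemical_id = "X", mol_wt = 300, fup = 0.05,
              blood_plasma_ratio = 1)
  ph <- physio_params(body_weight_kg = 70, gfr_L_per_h = 6.7)
  res <- css_steady_state(rec, 0, ph)
  expect_equal(res$css_mg_per_L, 70 / 24 / (6.7 * 0.05), tolerance = 1e-12)
  # halving fub doubles Css
  rec2 <- rec; rec2$fup <- 0.025
  expect_equal(css_steady_state(rec2, 0, ph)$css_mg_per_L,
               2 * res$css_mg_per_L, tolerance = 1e-12)
  # engineered GFR*fub = 0.5 L/h gives 70/24/0.5
  rec3 <- list(chemical_id = "Y", mol_wt = 300, fup = 0.1,
               blood_plasma_ratio = 1)
  ph3 <- physio_params(gfr_L_per_h = 5)
  expect_equal(css_steady_state(rec3, 0, ph3)$css_mg_per_L, 70 / 24 / 0.5,
               tolerance = 1e-12)
  # unit coherence: uM x MW / 1000 = mg/L
  expect_equal(res$css_uM * rec$mol_wt / 1000, res$css_mg_per_L,
               tolerance = 1e-12)
})

test_that("Css is nonincreasing in clint and fub", {
  rec <- list(chemical_id = "X", mol_wt = 400, fup = 0.02,
              blood_plasma_ratio = 1)
  ph <- physio_params()
  css <- vapply(c(0, 1, 5, 20, 50),
                function(cl) css_steady_state(rec, cl, ph)$css_uM, numeric(1))
  expect_true(all(diff(css) < 0))
  fups <- c(0.001, 0.01, 0.1, 1)
  css_f <- vapply(fups, function(f) {
    r <- rec; r$fup <- f
    css_steady_state(r, 5, ph)$css_uM
  }, numeric(1))
  expect_true(all(diff(css_f) < 0))
})

test_that("POD derivation filters curves and takes the 5th-percentile AC50", {
  one <- data.frame(chemical_id = "X", ac50_uM = 10, hitcall = 0.95,
                    n_flags = 0)
  expect_equal(derive_pod(one), 10)
  # inactive curves leave no POD
  inactive <- data.frame(chemical_id = "X", ac50_uM = 1:5, hitcall = 0.5,
                         n_flags = 0)
  expect_true(is.na(derive_pod(inactive)))
  # >= 4 caution flags censor a curve
  flagged <- data.frame(chemical_id = "X", ac50_uM = c(1, 10),
                        hitcall = c(0.99, 0.99), n_flags = c(4, 0))
  expect_equal(derive_pod(flagged), 10)
  # quantile-rule oracle on 1..20 (type 7 linear interpolation)
  grid <- data.frame(chemical_id = "X", ac50_uM = 1:20, hitcall = 0.95,
                     n_flags = 0)
  expect_equal(derive_pod(grid), 1.95)
  expect_true(is.na(derive_pod(NULL)))
})

test_that("reverse dosimetry reproduces published AEDs and the exact identity", {
  expect_equal(round(aed_reverse_dosimetry(6.22, 7.51), 2), 0.83)    # PFBS
  expect_equal(round(aed_reverse_dosimetry(16.57, 1657.68), 2), 0.01) # PFHpA
  expect_equal(aed_reverse_dosimetry(5, 5), 1)
  expect_true(is.na(aed_reverse_dosimetry(NA_real_, 5)))
  expect_error(aed_reverse_dosimetry(-1, 5), "positive")
  # identity AED x Css = POD x dose_rate, for arbitrary values
  for (pod in c(0.1, 3, 42)) for (css in c(0.5, 7.51, 900)) {
    expect_equal(aed_reverse_dosimetry(pod, css) * css, pod,
                 tolerance = 1e-12)
  }
})

test_that("every bundled example row satisfies AED = POD/Css at its printed precision", {
  ex <- pfas_ivive_examples()
  expect_equal(nrow(ex), 18)
  with_pod <- ex[ex$pod_uM != "NA", ]
  expect_equal(nrow(with_pod), 16)
  for (i in seq_len(nrow(with_pod))) {
    r <- with_pod[i, ]
    aed <- aed_reverse_dosimetry(as.numeric(r$pod_uM), r$css_uM)
    dec <- printed_decimals(r$aed_mg_per_kg_day)
    expect_equal(round(aed, dec), as.numeric(r$aed_mg_per_kg_day),
                 info = r$name)
  }
  # the metadata side of the fixture passes chemical validation
  expect_equal(nrow(validate_chemical_table(
    cbind(ex[, c("chemical_id", "name", "mol_wt", "cf2", "oecd_category",
                 "fup")], blood_plasma_ratio = 1))), 0)
})

test_that("uncertainty propagation collapses, enumerates and varies correctly", {
  rec <- list(chemical_id = "X", mol_wt = 300, fup = 0.01,
              blood_plasma_ratio = 1)
  ph <- physio_params()
  # degenerate samples collapse to the point AED
  point <- css_steady_state(rec, 5, ph)$css_uM
  pr <- propagate_uncertainty(5, 0.01, rec, ph, pod_uM = 10, seed = 1)
  expect_equal(pr$aed_median, 10 / point, tolerance = 1e-12)
  expect_equal(unname(diff(pr$aed_ci95)), 0, tolerance = 1e-12)
  # clint all zero: AED varies only through fup draws
  pr0 <- propagate_uncertainty(rep(0, 5), c(0.005, 0.01, 0.02), rec, ph,
                               pod_uM = 10, seed = 1)
  css_by_fup <- vapply(c(0.005, 0.01, 0.02), function(f) {
    r <- rec; r$fup <- f
    css_steady_state(r, 0, ph)$css_uM
  }, numeric(1))
  expect_setequal(round(pr0$aed_ci95, 9),
                  round(range(10 / css_by_fup), 9))
  # full-grid enumeration oracle: brute-force double loop
  cls <- c(0, 2, 8); fps <- c(0.004, 0.02)
  pr2 <- propagate_uncertainty(cls, fps, rec, ph, pod_uM = 10,
                               n_draws = 100, seed = 1)
  brute <- as.vector(vapply(fps, function(f) {
    r <- rec; r$fup <- f
    vapply(cls, function(cl) 10 / css_steady_state(r, cl, ph)$css_uM,
           numeric(1))
  }, numeric(length(cls))))
  expect_equal(pr2$n_draws_used, 6)
  expect_equal(pr2$aed_ci95,
               unname(quantile(brute, c(0.025, 0.975), type = 7)),
               tolerance = 1e-12)
  expect_error(propagate_uncertainty(numeric(0), 0.1, rec, ph, 1), "empty")
})

test_that("panel IVIVE joins clearance, binding and bioactivity per chemical", {
  chems <- data.frame(chemical_id = c("A", "B"), name = c("a", "b"),
                      mol_wt = c(300, 400), cf2 = c(4, 6),
                      oecd_category = c("PFCAs", "PFSAs"),
                      fup = c(0.01, 0.02), blood_plasma_ratio = c(1, 1))
  clint <- c(A = 0, B = 5)
  curves <- rbind(simulate_curves("A", 10, active_fraction = 1, seed = 1),
                  simulate_curves("B", 10, active_fraction = 0, seed = 2))
  res <- ivive_panel(chems, clint, curves)
  expect_equal(nrow(res), 2)
  expect_false(is.na(res$pod_uM[1]))
  expect_true(is.na(res$pod_uM[2]) && is.na(res$aed_mg_per_kg_day[2]))
  expect_equal(res$aed_mg_per_kg_day[1] * res$css_uM[1], res$pod_uM[1],
               tolerance = 1e-12)
  expect_error(ivive_panel(chems, c(A = 0)), "B")
})
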