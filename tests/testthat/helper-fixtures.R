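# Shared fixture builders: everything is generated in code at test time.

# minimal valid cells-only measurement frame on the default design
make_cells_rows <- function(times = c(0, 15, 30, 60, 120, 240), reps = 3,
                            response_fun = function(t) rep(1, length(t))) {
  grid <- expand.grid(replicate = seq_len(reps), time_min = times)
  data.frame(time_min = grid$time_min, condition = "cells",
             replicate = grid$replicate,
             response = response_fun(grid$time_min),
             has_internal_standard = TRUE, nominal_conc_uM = NA_real_,
             stringsAsFactors = FALSE)
}

make_cal_rows <- function(levels = c(0.1, 0.5, 1), rf = 2) {
  data.frame(time_min = 0, condition = "calibration", replicate = 1L,
             response = rf * levels, has_internal_standard = TRUE,
             nominal_conc_uM = levels, stringsAsFactors = FALSE)
}

# exponential-decay dataset with exact (noise-free) responses
make_exact_dataset <- function(id = "DTX-T", k = 0.005, rf = 2,
                               times = c(0, 30, 60, 120, 240), reps = 3,
                               loq = 0.001) {
  rows <- rbind(make_cells_rows(times, reps,
                                response_fun = function(t) rf * exp(-k * t)),
                make_cal_rows(rf = rf))
  depletion_dataset(id, rows, loq_uM = loq)
}

pfbs_record <- function() {
  data.frame(chemical_id = "DTXSID5030030", name = "PFBS", mol_wt = 299.95,
             cf2 = 4, oecd_category = "PFSAs", fup = 0.0128,
             blood_plasma_ratio = 1, stringsAsFactors = FALSE)
}
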