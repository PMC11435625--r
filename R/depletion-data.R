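#' @useDynLib hepatoclear, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef lm median pnorm pt quantile rbinom rlnorm rnorm runif
#'   sd setNames var predict
#' @importFrom utils read.csv write.csv head
NULL

.CONDITIONS <- c("cells", "no_cells", "heat_inactivated", "calibration")
.CONTROL_CONDITIONS <- c("no_cells", "heat_inactivated")

.DEPLETION_COLS <- c("chemical_id", "time_min", "condition", "replicate",
                     "response", "has_internal_standard", "nominal_conc_uM")
.CHEMICAL_COLS <- c("chemical_id", "name", "mol_wt", "cf2", "oecd_category",
                    "fup", "blood_plasma_ratio")
.CURVE_COLS <- c("chemical_id", "ac50_uM", "hitcall", "n_flags")

#' Construct a depletion dataset
#'
#' Bundles the time-stamped response measurements for one chemical from a
#' hepatocyte suspension substrate-depletion experiment, together with the
#' assay design constants: nominal test concentration, cell density and the
#' analytical limit of quantitation (LOQ).
#'
#' @param chemical_id Chemical identifier (e.g. a DTXSID).
#' @param measurements Data frame with columns `time_min`, `condition`
#'   (one of `"cells"`, `"no_cells"`, `"heat_inactivated"`, `"calibration"`),
#'   `replicate`, `response`, `has_internal_standard` and, for calibration
#'   rows, `nominal_conc_uM`.
#' @param c_test_uM Nominal assay concentration in µM (default 1).
#' @param cell_density_millions_per_mL Hepatocyte density in 10^6 viable
#'   cells/mL (default 0.5).
#' @param loq_uM Limit of quantitation in µM; must be below `c_test_uM`.
#' @return An object of class `depletion_dataset`.
#' @examples
#' m <- data.frame(time_min = rep(c(0, 60, 240), each = 3),
#'                 condition = "cells", replicate = rep(1:3, 3),
#'                 response = exp(-0.005 * rep(c(0, 60, 240), each = 3)),
#'                 has_internal_standard = TRUE, nominal_conc_uM = NA_real_)
#' d <- depletion_dataset("DTX-EX", m)
#' print(d)
#' @export
depletion_dataset <- function(chemical_id, measurements, c_test_uM = 1,
                              cell_density_millions_per_mL = 0.5,
                              loq_uM = 0.05) {
  stopifnot(is.character(chemical_id), length(chemical_id) == 1L)
  measurements <- as.data.frame(measurements)
  if (!"nominal_conc_uM" %in% names(measurements))
    measurements$nominal_conc_uM <- NA_real_
  if (!"has_internal_standard" %in% names(measurements))
    measurements$has_internal_standard <- TRUE
  needed <- setdiff(.DEPLETION_COLS, "chemical_id")
  miss <- setdiff(needed, names(measurements))
  if (length(miss))
    stop("measurements lack columns: ", paste(miss, collapse = ", "))
  measurements$chemical_id <- chemical_id
  measurements <- measurements[, .DEPLETION_COLS]
  obj <- structure(list(chemical_id = chemical_id,
                        c_test_uM = c_test_uM,
                        cell_density_millions_per_mL = cell_density_millions_per_mL,
                        loq_uM = loq_uM,
                        measurements = measurements),
                   class = "depletion_dataset")
  viol <- validate_depletion_dataset(obj)
  if (length(viol))
    stop("invalid depletion dataset for ", chemical_id, ": ",
         paste(viol, collapse = "; "))
  obj
}

#' Validate a depletion dataset against its invariants
#'
#' Checks each structural rule (valid condition labels, nonnegative times and
#' responses, calibration rows carrying a positive nominal concentration, at
#' least two distinct incubation time points, LOQ below the test
#' concentration) and returns every violation found.
#'
#' @param x A `depletion_dataset` (or a list with the same fields).
#' @return Character vector of violated rules; `character(0)` when valid.
#' @export
validate_depletion_dataset <- function(x) {
  v <- character(0)
  m <- x$measurements
  if (!is.numeric(x$c_test_uM) || x$c_test_uM <= 0)
    v <- c(v, "c_test_uM must be > 0")
  if (!is.numeric(x$loq_uM) || x$loq_uM <= 0)
    v <- c(v, "loq_uM must be > 0")
  else if (x$loq_uM >= x$c_test_uM)
    v <- c(v, "loq_uM must be < c_test_uM")
  if (x$cell_density_millions_per_mL <= 0)
    v <- c(v, "cell_density_millions_per_mL must be > 0")
  if (!all(m$condition %in% .CONDITIONS))
    v <- c(v, paste0("unknown condition labels: ",
                     paste(unique(setdiff(m$condition, .CONDITIONS)),
                           collapse = ", ")))
  if (any(!is.finite(m$time_min)) || any(m$time_min < 0, na.rm = TRUE))
    v <- c(v, "time_min must be finite and >= 0")
  if (any(!is.finite(m$response)) || any(m$response < 0, na.rm = TRUE))
    v <- c(v, "response must be finite and >= 0")
  if (any(m$replicate < 1, na.rm = TRUE))
    v <- c(v, "replicate must be >= 1")
  cal <- m$condition == "calibration"
  if (any(cal) && (any(is.na(m$nominal_conc_uM[cal])) ||
                   any(m$nominal_conc_uM[cal] <= 0, na.rm = TRUE)))
    v <- c(v, "calibration rows must carry nominal_conc_uM > 0")
  n_times <- length(unique(m$time_min[m$condition == "cells"]))
  if (n_times < 2)
    v <- c(v, "need >= 2 distinct time points in the cells condition")
  v
}

#' @export
print.depletion_dataset <- function(x, ...) {
  m <- x$measurements
  cat("Substrate-depletion dataset:", x$chemical_id, "\n")
  cat(sprintf("  C_test %g uM, %g x 10^6 cells/mL, LOQ %g uM\n",
              x$c_test_uM, x$cell_density_millions_per_mL, x$loq_uM))
  for (cond in intersect(.CONDITIONS, unique(m$condition))) {
    sub <- m[m$condition == cond, ]
    cat(sprintf("  %-16s %3d rows, %d time/conc levels\n", cond, nrow(sub),
                length(unique(if (cond == "calibration") sub$nominal_conc_uM
                              else sub$time_min))))
  }
  invisible(x)
}

#' Read depletion time-course tables from CSV
#'
#' Reads a long-format depletion table (one row per measurement; see
#' [write_depletion_table()] for the schema) and splits it into one validated
#' [depletion_dataset()] per chemical.
#'
#' @param path Path to the CSV file.
#' @param c_test_uM,cell_density_millions_per_mL,loq_uM Assay constants applied
#'   to every chemical in the file (the schema stores measurements only).
#' @return Named list of `depletion_dataset` objects, one per `chemical_id`.
#' @export
read_depletion_table <- function(path, c_test_uM = 1,
                                 cell_density_millions_per_mL = 0.5,
                                 loq_uM = 0.05) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.DEPLETION_COLS, names(df))
  if (length(miss))
    stop("schema error: missing columns ", paste(miss, collapse = ", "))
  df$has_internal_standard <- as.logical(df$has_internal_standard)
  out <- lapply(split(df, df$chemical_id), function(sub) {
    depletion_dataset(sub$chemical_id[1],
                      sub[, setdiff(.DEPLETION_COLS, "chemical_id")],
                      c_test_uM = c_test_uM,
                      cell_density_millions_per_mL = cell_density_millions_per_mL,
                      loq_uM = loq_uM)
  })
  out[unique(df$chemical_id)]
}

#' Write depletion datasets to CSV
#'
#' Writes the long/tidy schema consumed by [read_depletion_table()]:
#' columns `chemical_id,time_min,condition,replicate,response,`
#' `has_internal_standard,nominal_conc_uM` (empty field = absent). Column and
#' row order are deterministic, so writing the same datasets twice yields
#' byte-identical files.
#'
#' @param datasets A `depletion_dataset` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_depletion_table <- function(datasets, path) {
  if (inherits(datasets, "depletion_dataset")) datasets <- list(datasets)
  rows <- if (length(datasets))
    do.call(rbind, lapply(datasets, `[[`, "measurements"))
  else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(.DEPLETION_COLS))),
                    .DEPLETION_COLS)
  ok <- tryCatch({
    write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Read a chemical metadata table
#'
#' Schema: `chemical_id,name,mol_wt,cf2,oecd_category,fup,blood_plasma_ratio`.
#' `fup` is the fraction unbound in plasma; `cf2` the longest contiguous chain
#' of fluorinated carbons; `blood_plasma_ratio` the whole-blood to plasma
#' partitioning ratio.
#'
#' @param path Path to the CSV file.
#' @return Data frame of chemical records.
#' @export
read_chemical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.CHEMICAL_COLS, names(df))
  if (length(miss))
    stop("schema error: missing columns ", paste(miss, collapse = ", "))
  df
}

#' Validate a chemical metadata table
#'
#' Report-based validation: never throws on bad content, instead returns one
#' row per violated rule so a screening campaign can triage its inputs.
#'
#' @param records Data frame in the [read_chemical_table()] schema.
#' @return Data frame with columns `chemical_id` and `rule`; zero rows iff
#'   every record is valid.
#' @examples
#' recs <- data.frame(chemical_id = "DTXSID5030030", name = "PFBS",
#'                    mol_wt = 299.95, cf2 = 4, oecd_category = "PFSAs",
#'                    fup = 0.0128, blood_plasma_ratio = 1)
#' validate_chemical_table(recs)  # zero rows
#' @export
validate_chemical_table <- function(records) {
  records <- as.data.frame(records)
  bad <- function(id, rule) data.frame(chemical_id = id, rule = rule,
                                       stringsAsFactors = FALSE)
  out <- list()
  miss <- setdiff(.CHEMICAL_COLS, names(records))
  if (length(miss))
    return(bad(NA_character_, paste("missing columns:",
                                    paste(miss, collapse = ", "))))
  dup <- unique(records$chemical_id[duplicated(records$chemical_id)])
  for (id in dup) out <- c(out, list(bad(id, "duplicate chemical_id")))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (!is.finite(r$mol_wt) || r$mol_wt <= 0)
      out <- c(out, list(bad(r$chemical_id, "mol_wt must be > 0")))
    if (!is.finite(r$fup) || r$fup <= 0 || r$fup > 1)
      out <- c(out, list(bad(r$chemical_id, "fup out of (0,1]")))
    if (!is.na(r$blood_plasma_ratio) && r$blood_plasma_ratio <= 0)
      out <- c(out, list(bad(r$chemical_id, "blood_plasma_ratio must be > 0")))
    if (!is.na(r$cf2) && (r$cf2 < 0 || r$cf2 != round(r$cf2)))
      out <- c(out, list(bad(r$chemical_id, "cf2 must be a nonnegative integer")))
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(chemical_id = character(0), rule = character(0))
}

#' Read a bioactivity curve table
#'
#' Schema: `chemical_id,ac50_uM,hitcall,n_flags`, one row per concentration
#' -response curve from an in vitro screening database: the AC50 in µM, the
#' continuous hitcall in \[0,1\] (probability the curve is a true positive),
#' and the number of caution flags raised during curve review.
#'
#' @param path Path to the CSV file.
#' @return Data frame of curves.
#' @export
read_curve_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.CURVE_COLS, names(df))
  if (length(miss))
    stop("schema error: missing columns ", paste(miss, collapse = ", "))
  df
}
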