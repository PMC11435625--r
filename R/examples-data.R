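#' Literature-reported PFAS IVIVE example values
#'
#' A bundled plain-text table of published in vitro-in vivo extrapolation
#' results for 18 PFAS across structural categories: identity (DTXSID,
#' name), molecular weight, fluorinated chain length (CF2), OECD category,
#' fraction unbound in plasma, intrinsic clearance (µL/min/10^6 cells),
#' steady-state blood concentration at 1 mg/kg/day (µM), the 5th-percentile
#' AC50 point of departure (µM) and the administered equivalent dose
#' (mg/kg/day). Chemicals with no positive bioactivity curves after
#' filtering carry the string `"NA"` in the POD and AED columns.
#'
#' Because the AED is derived from POD and C_ss by the scalar-free identity
#' `AED = POD / C_ss * 1 mg/kg/day`, these rows serve as worked examples for
#' [aed_reverse_dosimetry()]: recomputing the AED from the printed POD and
#' C_ss columns and rounding to each row's printed decimals reproduces the
#' printed AED.
#'
#' @param as_character Keep `pod_uM` and `aed_mg_per_kg_day` as printed
#'   strings (preserving each row's decimal places); default `TRUE`.
#' @return Data frame with 18 rows.
#' @examples
#' ex <- pfas_ivive_examples()
#' pfbs <- ex[ex$name == "PFBS", ]
#' aed_reverse_dosimetry(as.numeric(pfbs$pod_uM), pfbs$css_uM)  # ~0.83
#' @export
pfas_ivive_examples <- function(as_character = TRUE) {
  path <- system.file("extdata", "pfas_ivive_examples.csv",
                      package = "hepatoclear", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                 colClasses = c(pod_uM = "character",
                                aed_mg_per_kg_day = "character"))
  if (!as_character) {
    df$pod_uM <- suppressWarnings(as.numeric(df$pod_uM))
    df$aed_mg_per_kg_day <- suppressWarnings(as.numeric(df$aed_mg_per_kg_day))
  }
  df
}

#' Count decimal places in a printed number
#'
#' Helper for comparisons against published tables whose rounding precision
#' varies row by row.
#'
#' @param x Character vector of printed numbers.
#' @return Integer vector of decimal places (0 when no decimal point).
#' @export
printed_decimals <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || !grepl(".", s, fixed = TRUE)) 0L
    else nchar(sub(".*\\.", "", s))
  }, integer(1), USE.NAMES = FALSE)
}
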