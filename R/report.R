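#' Pivot intrinsic-clearance values by chain length and category
#'
#' Builds the wide comparison table used to contrast structural categories at
#' matched fluorinated-chain length: one row per CF2 value, one column per
#' category, each cell carrying the chemical's Cl_int exactly as estimated
#' (no aggregation; multiple chemicals in one cell are comma-joined).
#'
#' @param estimates Data frame with columns `chemical_id` and `clint` (or a
#'   list of [clint_point()] fits).
#' @param chemicals Data frame in the [read_chemical_table()] schema.
#' @return Data frame: first column `cf2`, remaining columns the categories
#'   (uncategorised chemicals routed to `"uncategorized"`); missing cells
#'   are `NA`.
#' @export
category_pivot <- function(estimates, chemicals) {
  estimates <- .as_estimate_df(estimates)
  if (!nrow(estimates))
    return(data.frame(cf2 = integer(0)))
  unknown <- setdiff(estimates$chemical_id, chemicals$chemical_id)
  if (length(unknown))
    stop("unknown chemical ids: ", paste(unknown, collapse = ", "))
  idx <- match(estimates$chemical_id, chemicals$chemical_id)
  cat <- chemicals$oecd_category[idx]
  cat[is.na(cat) | cat == ""] <- "uncategorized"
  cf2 <- chemicals$cf2[idx]
  cats <- unique(cat)
  rows <- sort(unique(cf2))
  out <- data.frame(cf2 = rows)
  for (cc in cats) {
    col <- vapply(rows, function(r) {
      v <- estimates$clint[cf2 == r & cat == cc]
      if (!length(v)) NA_character_
      else paste(format(v, trim = TRUE), collapse = ",")
    }, character(1))
    out[[cc]] <- col
  }
  out
}

.as_estimate_df <- function(estimates) {
  if (is.data.frame(estimates)) return(estimates)
  do.call(rbind, lapply(estimates, function(e) {
    if (inherits(e, "clint_point")) e <- e$estimate
    data.frame(chemical_id = e$chemical_id, clint = e$clint,
               stringsAsFactors = FALSE)
  }))
}

#' Combined TK/IVIVE report table
#'
#' One row per chemical joining identity, structure, binding, clearance and
#' dosimetry: identifier, name, molecular weight, CF2 chain length, category,
#' fraction unbound in plasma, Cl_int, steady-state concentration at unit
#' dose, point of departure and administered equivalent dose. Chemicals with
#' no positive bioactivity curves carry `NA` POD/AED (rendered as the literal
#' string `NA` when written with [write_full_table()]).
#'
#' @param chemicals Data frame in the [read_chemical_table()] schema.
#' @param estimates Data frame with `chemical_id` and `clint` (or list of
#'   fits).
#' @param ivive Data frame from [ivive_panel()].
#' @return Data frame with columns `chemical_id, name, mol_wt, cf2,
#'   oecd_category, fup, clint, css_uM, pod_uM, aed_mg_per_kg_day`.
#' @export
full_table <- function(chemicals, estimates, ivive) {
  estimates <- .as_estimate_df(estimates)
  if (!nrow(chemicals))
    return(data.frame(chemical_id = character(0), name = character(0),
                      mol_wt = numeric(0), cf2 = integer(0),
                      oecd_category = character(0), fup = numeric(0),
                      clint = numeric(0), css_uM = numeric(0),
                      pod_uM = numeric(0), aed_mg_per_kg_day = numeric(0)))
  ei <- match(chemicals$chemical_id, estimates$chemical_id)
  vi <- match(chemicals$chemical_id, ivive$chemical_id)
  data.frame(chemical_id = chemicals$chemical_id, name = chemicals$name,
             mol_wt = chemicals$mol_wt, cf2 = chemicals$cf2,
             oecd_category = chemicals$oecd_category, fup = chemicals$fup,
             clint = estimates$clint[ei], css_uM = ivive$css_uM[vi],
             pod_uM = ivive$pod_uM[vi],
             aed_mg_per_kg_day = ivive$aed_mg_per_kg_day[vi],
             stringsAsFactors = FALSE)
}

#' Write the combined report table to CSV
#'
#' Absent POD/AED values are rendered as the literal string `NA`.
#'
#' @param tab Data frame from [full_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_full_table <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
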