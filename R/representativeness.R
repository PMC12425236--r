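# Protected-area gap analysis: how much of each species' range a mask
# covers, and whether that coverage clears a range-size-dependent
# "well-represented" bar — 100% for restricted ranges (< 1,000 km2), 10% for
# wide ranges (> 25,000 km2), linearly interpolated in between. The rationale
# is ecological: a species confined to a handful of cells needs its whole
# range secured, while a tenth of a very large range already protects a
# viable area.

#' Percentage of a species' range covered by a mask
#'
#' @param range Binary-mode [species_layer()] with a non-empty range.
#' @param mask Logical matrix on the same grid (e.g. a PA mask or scenario
#'   mask), or an [pa_mask()].
#' @return `100 * |range intersect mask| / |range|`.
#' @export
coverage_pct <- function(range, mask) {
  stopifnot(inherits(range, "scp_species_layer"))
  if (range$mode != "binary")
    stop("coverage_pct requires a binary range", call. = FALSE)
  if (inherits(mask, "scp_pa_mask")) mask <- mask$mask
  if (!identical(dim(mask), c(range$grid$n_rows, range$grid$n_cols)))
    stop("alignment error: mask does not match the range grid", call. = FALSE)
  inrange <- range$values & range$grid$valid_mask
  inrange[is.na(inrange)] <- FALSE
  n_range <- sum(inrange)
  if (n_range == 0)
    stop("undefined coverage: species ", range$species_id,
         " has an empty range", call. = FALSE)
  100 * sum(inrange & mask) / n_range
}

#' Required coverage for a species to count as well-represented
#'
#' Ranges below 1,000 km2 require 100% coverage, ranges above 25,000 km2
#' require 10%, and in between the requirement falls linearly (by default in
#' raw area) from 100% at 1,000 km2 to 10% at 25,000 km2, so the function is
#' continuous and non-increasing in range size.
#'
#' @param area_km2 Nonnegative numeric vector of range sizes.
#' @param interpolation `"area"` (default, linear in km2) or `"log-area"`
#'   (linear in log km2 between the same breakpoints), provided for
#'   sensitivity analysis.
#' @return Required coverage percentage(s) in \[10, 100\].
#' @examples
#' required_pct(c(500, 13000, 40000))  # 100, 55, 10
#' @export
required_pct <- function(area_km2, interpolation = c("area", "log-area")) {
  interpolation <- match.arg(interpolation)
  if (any(!is.finite(area_km2)) || any(area_km2 < 0))
    stop("area_km2 must be nonnegative", call. = FALSE)
  lo <- 1000; hi <- 25000
  frac <- if (interpolation == "area")
    (area_km2 - lo) / (hi - lo)
  else
    (log(pmax(area_km2, lo)) - log(lo)) / (log(hi) - log(lo))
  pmin(pmax(100 - 90 * frac, 10), 100)
}

#' Gap report: representativeness of a mask for a species pool
#'
#' One row per species with its coverage by the mask, the range-size-
#' dependent requirement, and the well-represented flag; plus pool-level
#' summaries (mean coverage and counts of well/poorly represented species).
#'
#' @param ranges List of binary-mode [species_layer()]s on one grid.
#' @param mask Logical matrix, [pa_mask()] or scenario mask.
#' @param interpolation Passed to [required_pct()].
#' @return Object of class `scp_gap_report`: a list with `rows` (data.frame
#'   `species_id, range_km2, breadth, coverage_pct, required_pct,
#'   well_represented`) and `summary` (list `mean_coverage_pct, n_well,
#'   n_poor, n_species`).
#' @export
gap_report <- function(ranges, mask, interpolation = c("area", "log-area")) {
  interpolation <- match.arg(interpolation)
  if (!length(ranges)) stop("at least one species required", call. = FALSE)
  rows <- do.call(rbind, lapply(ranges, function(rg) {
    area <- rg$meta$range_size_km2
    cov <- coverage_pct(rg, mask)
    req <- required_pct(area, interpolation)
    data.frame(species_id = rg$species_id, range_km2 = area,
               breadth = rg$meta$breadth, coverage_pct = cov,
               required_pct = req, well_represented = cov >= req,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    rows = rows,
    summary = list(mean_coverage_pct = mean(rows$coverage_pct),
                   n_well = sum(rows$well_represented),
                   n_poor = sum(!rows$well_represented),
                   n_species = nrow(rows)),
    interpolation = interpolation),
    class = "scp_gap_report")
}

#' @export
print.scp_gap_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("scp_gap_report: %d species, mean coverage %.2f%%, ",
                     "%d well-represented (%.1f%%), %d under-represented\n"),
              s$n_species, s$mean_coverage_pct, s$n_well,
              100 * s$n_well / s$n_species, s$n_poor))
  invisible(x)
}
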