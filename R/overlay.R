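#' Overlay summaries: intact forest, wilderness, protected areas, zones
#'
#' Quantifies defaunation within boolean masks (intact forest landscapes,
#' wilderness defined by human footprint <= 2, IUCN I-IV protected areas)
#' and per categorical zone (countries). Thresholds follow the mapping
#' conventions: defaunated means DI strictly > 0.1, intact DI <= 0.1, and
#' wilderness HF <= 2 (inclusive).
#'
#' @name overlay_summaries
NULL

#' Area and fraction above a DI threshold within a mask
#'
#' @param di_grid DI matrix
#' @param mask logical matrix (NULL = whole grid)
#' @param threshold DI cutoff, counted strictly above (default 0.1)
#' @param cell_area_km2 area of one cell
#' @return list(area_km2_above, fraction_above, area_km2_total, n_valid)
#' @export
area_fraction <- function(di_grid, mask = NULL, threshold = 0.1,
                          cell_area_km2 = 1) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(di_grid), ncol(di_grid))
  check_aligned(di_grid, mask, "DI grid and mask")
  valid <- mask & !is.na(di_grid)
  n <- sum(valid)
  above <- sum(di_grid[valid] > threshold)
  list(area_km2_above = above * cell_area_km2,
       fraction_above = if (n > 0) above / n else NA_real_,
       area_km2_total = n * cell_area_km2, n_valid = n)
}

#' Defaunated / intact split within a named mask
#'
#' @param di_grid DI matrix
#' @param mask logical matrix
#' @param name mask label (e.g. "IF", "WA", "PA")
#' @param threshold defaunation cutoff (strict >)
#' @param cell_area_km2 area of one cell
#' @return one-row data.frame with areas, fractions, mean DI and the 95%
#'   CI half-width over cells
#' @export
overlay_summary <- function(di_grid, mask, name = "mask", threshold = 0.1,
                            cell_area_km2 = 1) {
  af <- area_fraction(di_grid, mask, threshold, cell_area_km2)
  vals <- di_grid[mask & !is.na(di_grid)]
  n <- length(vals)
  data.frame(
    mask = name,
    total_area_km2 = af$area_km2_total,
    defaunated_area_km2 = af$area_km2_above,
    defaunated_fraction = af$fraction_above,
    intact_fraction = if (n > 0) 1 - af$fraction_above else NA_real_,
    mean_di = if (n > 0) mean(vals) else NA_real_,
    ci95_half_width = if (n > 1) 1.96 * sd(vals) / sqrt(n) else
      if (n == 1) 0 else NA_real_,
    n_cells = n,
    stringsAsFactors = FALSE
  )
}

#' Per-zone mean DI with a 95% CI over cells
#'
#' Cells are treated as independent when forming the CI (no spatial
#' autocorrelation adjustment; documented limitation). Empty zones are
#' reported with NA statistics.
#'
#' @param di_grid DI matrix
#' @param zone_grid integer matrix of zone codes (NA = no zone)
#' @param zone_levels optional names for the codes
#' @return data.frame(zone, n_cells, mean_di, sd_di, ci95_half_width)
#' @export
zonal_summary <- function(di_grid, zone_grid, zone_levels = NULL) {
  check_aligned(di_grid, zone_grid, "DI grid and zones")
  codes <- sort(unique(zone_grid[!is.na(zone_grid)]))
  rows <- lapply(codes, function(z) {
    vals <- di_grid[!is.na(zone_grid) & zone_grid == z & !is.na(di_grid)]
    n <- length(vals)
    data.frame(
      zone = if (!is.null(zone_levels)) zone_levels[z] else as.character(z),
      n_cells = n,
      mean_di = if (n > 0) mean(vals) else NA_real_,
      sd_di = if (n > 1) sd(vals) else if (n == 1) 0 else NA_real_,
      ci95_half_width = if (n > 1) 1.96 * sd(vals) / sqrt(n) else
        if (n == 1) 0 else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Wilderness mask from a human-footprint grid
#'
#' Wilderness is low cumulative human pressure: HF <= 2 (inclusive).
#'
#' @param hf_grid human-footprint matrix
#' @return logical matrix (NA cells are FALSE)
#' @export
wilderness_mask <- function(hf_grid) {
  !is.na(hf_grid) & hf_grid <= 2
}
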