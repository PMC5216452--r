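#' Richness hotspots, land-cover weighting and risk maps
#'
#' Consensus maps of all retained species are stacked into per-cell species
#' richness. Hotspots are the top 10% of land cells by richness; future
#' hotspot growth is measured by holding the current cutoff fixed. Risk
#' maps multiply richness by the proportion of each cell available for
#' ornamental cultivation (area-weighted mean of land-cover class
#' proportions, three alternative weighting schemes), and the final
#' high-risk set is a 2-of-3 majority vote across schemes.
#'
#' @name hotspot-risk
NULL

#' Stack binary maps into species richness
#'
#' @param maps List of `binary_range_map`s, all on one grid and scenario.
#' @param scenario Expected scenario label (checked against every map).
#' @return A `richness_map`: integer count per cell.
#' @export
stack_richness <- function(maps, scenario) {
  stopifnot(length(maps) >= 1)
  g <- maps[[1]]$grid
  counts <- rep(0L, n_cells(g))
  for (m in maps) {
    if (!identical(m$scenario, scenario))
      stop(sprintf("map for species %s has scenario '%s', expected '%s'",
                   m$species_id, m$scenario, scenario))
    if (!identical(m$grid$land_mask, g$land_mask))
      stop("maps are on different grids")
    counts <- counts + m$suitable
  }
  structure(list(grid = g, scenario = scenario, counts = as.integer(counts),
                 n_species = length(maps)),
            class = "richness_map")
}

# Nearest-rank top-fraction cutoff over land values: the cutoff is the
# k-th largest value, k = ceil(fraction * N), and every cell tied with it
# is included, so the flagged share can exceed the nominal fraction by the
# tie mass at the cutoff (and equals it exactly for all-distinct values).
# A constant surface is degenerate: everything ties with the cutoff.
percentile_cutoff <- function(values, fraction) {
  n <- length(values)
  k <- max(1L, ceiling(fraction * n))
  s <- sort(values, decreasing = TRUE)
  list(cutoff = s[k], degenerate = s[1] == s[n])
}

#' Delineate top-fraction hotspots
#'
#' The cutoff is the nearest-rank quantile: the `ceil(fraction * N)`-th
#' largest richness value over the `N` land cells. With all-distinct values
#' exactly `ceil(fraction * N)` cells are flagged; ties at the cutoff are
#' all included, so the flagged share can exceed the nominal fraction by
#' the tie mass at the cutoff (deviations beyond one percentage point are
#' logged). A constant map is degenerate: everything ties with the cutoff
#' and the case is logged.
#'
#' @param richness A `richness_map` (needs >= 10 land cells).
#' @param fraction Top fraction (default 0.10).
#' @return A `hotspot_map`: logical surface, `cutoff`, `n_flagged`,
#'   `source = "percentile"`, `degenerate` flag.
#' @export
delineate_hotspots <- function(richness, fraction = 0.10) {
  g <- richness$grid
  land <- land_cells(g)
  if (length(land) < 10) stop("need at least 10 land cells")
  pc <- percentile_cutoff(richness$counts[land], fraction)
  if (pc$degenerate)
    message("delineate_hotspots: constant richness; degenerate all-flagged map")
  flagged <- rep(FALSE, n_cells(g))
  flagged[land] <- richness$counts[land] >= pc$cutoff
  share <- sum(flagged) / length(land)
  if (abs(share - fraction) > 0.01 && !pc$degenerate)
    message(sprintf(
      "delineate_hotspots: flagged share %.3f deviates from nominal %.2f (tie mass at cutoff %d)",
      share, fraction, pc$cutoff))
  structure(list(grid = g, scenario = richness$scenario,
                 flagged = flagged, cutoff = pc$cutoff,
                 n_flagged = sum(flagged), source = "percentile",
                 degenerate = pc$degenerate),
            class = "hotspot_map")
}

#' Future hotspots at the fixed current-climate cutoff
#'
#' Applies the species-count cutoff delineated under current climate to a
#' future richness map and reports the relative change in hotspot area.
#' Area is measured in flagged-cell counts by default; set
#' `use_area_km2 = TRUE` for latitude-corrected spherical areas.
#'
#' @param richness_future A `richness_map` for a future scenario.
#' @param hotspot_current The current-climate `hotspot_map` (same grid).
#' @param use_area_km2 Latitude-correct the area change (default FALSE).
#' @return A `hotspot_map` (`source = "fixed_cutoff"`) with
#'   `area_change_pct`, the percent change relative to the current map.
#' @export
fixed_cutoff_hotspots <- function(richness_future, hotspot_current,
                                  use_area_km2 = FALSE) {
  g <- richness_future$grid
  if (!identical(g$land_mask, hotspot_current$grid$land_mask))
    stop("future richness and current hotspot maps are on different grids")
  cutoff <- hotspot_current$cutoff
  land <- land_cells(g)
  flagged <- rep(FALSE, n_cells(g))
  flagged[land] <- richness_future$counts[land] >= cutoff
  area_of <- function(flag) {
    cells <- which(flag)
    if (!use_area_km2) return(length(cells))
    sum(cell_area_km2(cell_center(cells, g)$lat, g$cell_size))
  }
  a_cur <- area_of(hotspot_current$flagged)
  if (a_cur == 0) stop("current hotspot area is zero; relative change undefined")
  a_fut <- area_of(flagged)
  structure(list(grid = g, scenario = richness_future$scenario,
                 flagged = flagged, cutoff = cutoff,
                 n_flagged = sum(flagged), source = "fixed_cutoff",
                 degenerate = FALSE,
                 area_change_pct = 100 * (a_fut - a_cur) / a_cur),
            class = "hotspot_map")
}

#' Area available for ornamental cultivation per analysis cell
#'
#' Aggregates a fine-resolution categorical land-cover raster to the
#' analysis grid: each analysis cell's value is the mean over its
#' equal-area subcells of the class proportions given by one weighting
#' scheme.
#'
#' @param landcover As returned by [make_landcover()] (fields `classes`,
#'   `subcells_per_side`), or any integer class matrix with those dims.
#' @param scheme Named numeric vector class id -> proportion in [0, 1];
#'   must cover every class present.
#' @param grid The analysis `grid_definition` the fine raster nests in.
#' @return An `available_area_map`: numeric per-cell values in [0, 1].
#' @export
available_area <- function(landcover, scheme, grid) {
  cls <- landcover$classes
  f <- landcover$subcells_per_side
  stopifnot(nrow(cls) == grid$n_rows * f, ncol(cls) == grid$n_cols * f)
  present <- unique(as.vector(cls))
  missing <- setdiff(as.character(present), names(scheme))
  if (length(missing))
    stop("weighting scheme does not cover land-cover class(es): ",
         paste(missing, collapse = ", "))
  if (any(scheme < 0 | scheme > 1)) stop("scheme proportions must be in [0, 1]")
  prop <- matrix(scheme[as.character(cls)], nrow(cls), ncol(cls))
  # block mean over f x f subcells
  row_grp <- (seq_len(nrow(cls)) - 1L) %/% f + 1L
  col_grp <- (seq_len(ncol(cls)) - 1L) %/% f + 1L
  agg <- rowsum(t(rowsum(prop, row_grp)), col_grp) / (f * f)
  values <- as.vector(t(agg))   # back to n_rows x n_cols column-major
  structure(list(grid = grid, values = values),
            class = "available_area_map")
}

#' Naturalization-risk map for one weighting scheme
#'
#' Per-cell risk = species richness x available area; high-risk cells are
#' the top `fraction` of land cells by risk value, using the same
#' nearest-rank rule as [delineate_hotspots()]. Doubling all richness
#' values rescales risk but leaves the flagged set unchanged.
#'
#' @param richness A `richness_map`.
#' @param area An `available_area_map` on the same grid.
#' @param fraction Top fraction (default 0.10).
#' @param scheme_id Label carried through to the output.
#' @return A `risk_map`: `values`, logical `high_risk`, `cutoff`,
#'   `degenerate` flag.
#' @export
risk_map <- function(richness, area, fraction = 0.10, scheme_id = "scheme") {
  g <- richness$grid
  if (!identical(g$land_mask, area$grid$land_mask))
    stop("richness and available-area maps are on different grids")
  values <- richness$counts * area$values
  land <- land_cells(g)
  pc <- percentile_cutoff(values[land], fraction)
  if (pc$degenerate)
    message(sprintf("risk_map (%s): constant risk values; degenerate map",
                    scheme_id))
  high <- rep(FALSE, n_cells(g))
  high[land] <- values[land] >= pc$cutoff
  structure(list(grid = g, scenario = richness$scenario,
                 scheme_id = scheme_id, values = values,
                 high_risk = high, cutoff = pc$cutoff,
                 n_flagged = sum(high), degenerate = pc$degenerate),
            class = "risk_map")
}

#' Majority-vote consensus of the three scheme risk maps
#'
#' A cell is high-risk in the consensus iff at least two of the three
#' scheme maps flag it. The consensus risk value is the mean of the three
#' scheme values (a documented convention; only the flag is canonical).
#'
#' @param maps List of exactly three `risk_map`s (one per scheme, same
#'   grid and scenario).
#' @return A `risk_map` with `scheme_id = "consensus"`.
#' @export
consensus_risk <- function(maps) {
  if (length(maps) != 3) stop("consensus_risk needs exactly 3 scheme maps")
  g <- maps[[1]]$grid
  for (m in maps[-1]) {
    if (!identical(m$grid$land_mask, g$land_mask))
      stop("risk maps are on different grids")
    if (!identical(m$scenario, maps[[1]]$scenario))
      stop("risk maps are for different scenarios")
  }
  votes <- Reduce(`+`, lapply(maps, function(m) as.integer(m$high_risk)))
  high <- votes >= 2
  values <- Reduce(`+`, lapply(maps, `[[`, "values")) / 3
  structure(list(grid = g, scenario = maps[[1]]$scenario,
                 scheme_id = "consensus", values = values,
                 high_risk = high, cutoff = NA_real_,
                 n_flagged = sum(high), degenerate = FALSE),
            class = "risk_map")
}
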