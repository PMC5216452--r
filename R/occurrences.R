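#' Species-pool selection and occurrence cleaning
#'
#' The candidate pool is built by set logic over membership lists: garden
#' plants not native to the study area, naturalized somewhere outside it but
#' nowhere inside it, excluding infraspecific taxa and hybrids. Occurrence
#' records are synonym-mapped, snapped to the analysis grid, stripped of
#' ocean records, and deduplicated to unique cells.
#'
#' @name occurrence-prep
NULL

#' Per-species presence cells on the analysis grid
#'
#' @param species_id Canonical species id.
#' @param cells Integer cell indices (deduplicated; all on land).
#' @param n_raw Record count before cleaning, kept for audit.
#' @param grid A `grid_definition` (cells are validated against its mask).
#' @return An `occurrence_set`.
#' @export
occurrence_set <- function(species_id, cells, n_raw, grid = NULL) {
  cells <- sort(unique(as.integer(cells)))
  if (!is.null(grid)) {
    if (any(cells < 1 | cells > n_cells(grid)))
      stop("cell index out of range for species ", species_id)
    if (any(!grid$land_mask[cells]))
      stop("occurrence cells off the land mask for species ", species_id)
  }
  structure(list(species_id = species_id, cells = cells,
                 n_raw = as.integer(n_raw)),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set '%s'> %d cells (from %d raw records)\n",
              x$species_id, length(x$cells), x$n_raw))
  invisible(x)
}

#' Species membership lists
#'
#' @param garden_pool,native,naturalized_outside,naturalized_inside
#'   Character vectors of canonical species ids.
#' @param taxon_flags Named character vector: species id ->
#'   one of `"species"`, `"variety"`, `"subspecies"`, `"hybrid"`.
#' @return A `species_pool_lists`.
#' @export
species_pool_lists <- function(garden_pool, native = character(),
                               naturalized_outside = character(),
                               naturalized_inside = character(),
                               taxon_flags = character()) {
  ok <- c("species", "variety", "subspecies", "hybrid")
  if (length(taxon_flags) && !all(taxon_flags %in% ok))
    stop("taxon_flags values must be one of: ", paste(ok, collapse = ", "))
  structure(list(garden_pool = unique(garden_pool),
                 native = unique(native),
                 naturalized_outside = unique(naturalized_outside),
                 naturalized_inside = unique(naturalized_inside),
                 taxon_flags = taxon_flags),
            class = "species_pool_lists")
}

#' Select candidate species by pool set logic
#'
#' Returns garden-pool species that are not native to the study area, are
#' naturalized somewhere outside it, are not yet naturalized inside it, and
#' are not flagged as variety, subspecies or hybrid. Output order is sorted,
#' so the result is invariant to input list order.
#'
#' @param lists A `species_pool_lists` (one synonym-resolved namespace).
#' @return Sorted character vector of candidate species ids.
#' @export
select_candidate_species <- function(lists) {
  stopifnot(inherits(lists, "species_pool_lists"))
  flagged_known <- names(lists$taxon_flags)
  all_listed <- unique(c(lists$garden_pool, lists$native,
                         lists$naturalized_outside, lists$naturalized_inside))
  orphans <- setdiff(flagged_known, all_listed)
  if (length(orphans))
    warning("taxon_flags entries not present in any list: ",
            paste(orphans, collapse = ", "))
  excluded_flags <- flagged_known[lists$taxon_flags %in%
                                    c("variety", "subspecies", "hybrid")]
  out <- setdiff(lists$garden_pool, lists$native)
  out <- intersect(out, lists$naturalized_outside)
  out <- setdiff(out, lists$naturalized_inside)
  sort(setdiff(out, excluded_flags))
}

#' Clean raw occurrence records onto the analysis grid
#'
#' Pipeline per record: map the raw name through the synonym table (identity
#' if absent), drop records with unparseable or out-of-extent coordinates
#' (logged, never silent), snap to the grid cell, drop cells off the land
#' mask (ocean records), and collapse to unique cells per species. Synonym
#' mapping happens before deduplication, so records of a synonym pair merge.
#'
#' @param records Data frame with columns `species`, `lon`, `lat`.
#' @param grid A `grid_definition`.
#' @param synonym_map Optional named character vector raw name -> canonical id.
#' @return Named list of `occurrence_set` (one per canonical species), with
#'   attribute `"log"`: a data.frame of per-species raw, invalid, ocean and
#'   retained counts.
#' @export
clean_occurrences <- function(records, grid, synonym_map = NULL) {
  stopifnot(all(c("species", "lon", "lat") %in% names(records)))
  sp <- as.character(records$species)
  if (!is.null(synonym_map)) {
    hit <- sp %in% names(synonym_map)
    sp[hit] <- unname(synonym_map[sp[hit]])
  }
  lon <- suppressWarnings(as.numeric(records$lon))
  lat <- suppressWarnings(as.numeric(records$lat))
  in_extent <- is.finite(lon) & is.finite(lat) &
    lon >= grid$min_lon & lon < grid$min_lon + grid$n_cols * grid$res_deg &
    lat >= grid$min_lat & lat < grid$min_lat + grid$n_rows * grid$res_deg
  cells <- rep(NA_integer_, length(sp))
  cells[in_extent] <- cell_of(lon[in_extent], lat[in_extent], grid)
  on_land <- !is.na(cells) & grid$land_mask[pmax(1L, cells)]
  species <- sort(unique(sp))
  sets <- list(); logs <- list()
  for (s in species) {
    i <- sp == s
    keep <- i & on_land
    sets[[s]] <- occurrence_set(s, cells[keep], n_raw = sum(i), grid = grid)
    logs[[s]] <- data.frame(species = s, n_raw = sum(i),
                            n_invalid = sum(i & !in_extent),
                            n_ocean = sum(i & in_extent & !on_land),
                            n_cells = length(sets[[s]]$cells))
  }
  log_df <- do.call(rbind, logs)
  rownames(log_df) <- NULL
  dropped <- sum(log_df$n_invalid) + sum(log_df$n_ocean)
  if (dropped > 0)
    message(sprintf("clean_occurrences: dropped %d invalid and %d ocean records",
                    sum(log_df$n_invalid), sum(log_df$n_ocean)))
  attr(sets, "log") <- log_df
  sets
}

#' Retain species with more than a minimum number of occurrence cells
#'
#' "More than" is strict: a species needs at least `minimum + 1` unique
#' cells after cleaning. The count basis is deduplicated cells (recorded in
#' the report so the choice is auditable).
#'
#' @param sets List of `occurrence_set`.
#' @param minimum Minimum count (default 50; retained means `> minimum`).
#' @return List with `retained` (list of `occurrence_set`) and `report`
#'   (data.frame: species, n_cells, n_raw, retained).
#' @export
filter_min_occurrences <- function(sets, minimum = 50) {
  if (!length(sets))
    return(list(retained = list(),
                report = data.frame(species = character(), n_cells = integer(),
                                    n_raw = integer(), retained = logical())))
  n <- vapply(sets, function(s) length(s$cells), 0L)
  report <- data.frame(species = vapply(sets, `[[`, "", "species_id"),
                       n_cells = n,
                       n_raw = vapply(sets, `[[`, 0L, "n_raw"),
                       retained = n > minimum, row.names = NULL)
  list(retained = sets[report$retained], report = report)
}
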