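#' Range-size summaries and permutation tests of range change
#'
#' Projected range sizes (suitable-cell counts) are heavily skewed with an
#' excess of zeros, so mean current-vs-future differences are tested with a
#' permutation (sign-flip) test: per species, the current and future labels
#' are swapped with probability one half, the mean difference recomputed,
#' and the observed mean compared with the central 95% and 99.9% of 1000
#' such permuted means. The same test is re-run per zonobiome of origin,
#' species assigned to several zonobiomes entering each of them.
#'
#' @name range-change
NULL

#' Range-size table and summary statistics
#'
#' @param maps Nested list `maps[[species]][[scenario]]` of
#'   `binary_range_map`s (as from [project_all()]), or a data.frame with
#'   columns species, scenario, n_cells.
#' @param thresholds Cell-count cutoffs for the "species above" report.
#' @return List with `table` (data.frame species, scenario, n_cells),
#'   `stats` per scenario (min, max, n_species, count above each cutoff)
#'   and `ecdf` per scenario (an [stats::ecdf()] of the counts).
#' @export
summarize_range_sizes <- function(maps, thresholds = c(100, 320, 1600)) {
  tab <- if (is.data.frame(maps)) maps else do.call(rbind, lapply(
    names(maps), function(sp) do.call(rbind, lapply(
      names(maps[[sp]]), function(sc) data.frame(
        species = sp, scenario = sc, n_cells = maps[[sp]][[sc]]$n_cells)))))
  stats_rows <- list(); ecdfs <- list()
  for (sc in unique(tab$scenario)) {
    n <- tab$n_cells[tab$scenario == sc]
    row <- data.frame(scenario = sc, n_species = length(n),
                      min = min(n), max = max(n))
    for (th in thresholds) row[[paste0("above_", th)]] <- sum(n > th)
    stats_rows[[sc]] <- row
    ecdfs[[sc]] <- stats::ecdf(n)
  }
  list(table = tab, stats = do.call(rbind, stats_rows), ecdf = ecdfs)
}

#' Permutation (sign-flip) test of mean range change
#'
#' Observed statistic: mean over species of
#' `n_cells(future) - n_cells(current)`. Null sample: `n_perm` replicates
#' in which each species' two scenario labels are independently swapped
#' with probability 1/2 before recomputing the mean difference. Bands are
#' two-sided central empirical intervals from order statistics (no normal
#' approximation). Only species present under both scenarios enter; species
#' dropped upstream are excluded, not zero-filled.
#'
#' @param table Data frame with species, scenario, n_cells (e.g.
#'   `summarize_range_sizes(...)$table`).
#' @param scenario_pair Length-2 character vector `(current, future)`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A `permutation_result`: observed_mean_diff, null_sample, bands
#'   (central 95% and 99.9%), verdicts (`outside_95`, `outside_999`),
#'   n_species, seed.
#' @export
permutation_test <- function(table, scenario_pair, n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  stopifnot(length(scenario_pair) == 2)
  cur <- table[table$scenario == scenario_pair[1], c("species", "n_cells")]
  fut <- table[table$scenario == scenario_pair[2], c("species", "n_cells")]
  m <- merge(cur, fut, by = "species", suffixes = c("_cur", "_fut"))
  if (nrow(m) < 2)
    stop("need at least 2 species present under both scenarios")
  d <- m$n_cells_fut - m$n_cells_cur
  observed <- mean(d)
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * length(d), replace = TRUE),
                  nrow = n_perm)
  null_sample <- as.vector(signs %*% d) / length(d)
  band <- function(alpha) {
    s <- sort(null_sample)
    lo <- s[max(1L, floor(n_perm * alpha / 2))]
    hi <- s[min(n_perm, ceiling(n_perm * (1 - alpha / 2)))]
    c(lower = lo, upper = hi)
  }
  b95 <- band(0.05); b999 <- band(0.001)
  structure(list(observed_mean_diff = observed, null_sample = null_sample,
                 bands = list(central_95 = b95, central_999 = b999),
                 outside_95 = observed < b95[1] || observed > b95[2],
                 outside_999 = observed < b999[1] || observed > b999[2],
                 n_species = length(d), seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("<permutation_result> observed %.2f over %d species; ",
                     "95%% band [%.2f, %.2f]%s; 99.9%% band [%.2f, %.2f]%s\n"),
              x$observed_mean_diff, x$n_species,
              x$bands$central_95[1], x$bands$central_95[2],
              if (x$outside_95) " *" else "",
              x$bands$central_999[1], x$bands$central_999[2],
              if (x$outside_999) " ***" else ""))
  invisible(x)
}

#' Zonobiome membership table
#'
#' One row per (species, zonobiome) assignment; a species native to several
#' zonobiomes appears once per zonobiome and enters every corresponding
#' subset test. The canonical eight labelled zonobiomes are boreal (BORE),
#' temperate-arid (T-AR), nemoral (NEMO), laurophyllous (LAUR),
#' Mediterranean (MEDI), subtropical-arid (ST-A), subtropical seasonally
#' dry (ST-W) and tropical (TROP); a ninth (polar/alpine, "POLA") completes
#' the global set. Other labels are accepted.
#'
#' @param species,zonobiome Equal-length character vectors.
#' @return A `zonobiome_table` data.frame.
#' @export
zonobiome_table <- function(species, zonobiome) {
  stopifnot(length(species) == length(zonobiome), length(species) > 0)
  df <- unique(data.frame(species = as.character(species),
                          zonobiome = as.character(zonobiome)))
  class(df) <- c("zonobiome_table", "data.frame")
  df
}

#' Zonobiome-stratified permutation tests
#'
#' Re-runs [permutation_test()] on the species subset of each zonobiome,
#' for each future scenario against the current one. Subsets with fewer
#' than 2 species under both scenarios are skipped with a log entry.
#'
#' @param table Range-size table (species, scenario, n_cells).
#' @param zonobiomes A [zonobiome_table()].
#' @param current Label of the current scenario.
#' @param scenarios Character vector of future scenario labels.
#' @param n_perm,seed As in [permutation_test()].
#' @return List with `results` (named `zonobiome|scenario` list of
#'   `permutation_result`) and `skipped` (data.frame zonobiome, scenario,
#'   reason).
#' @export
zonobiome_tests <- function(table, zonobiomes, current, scenarios,
                            n_perm = 1000, seed = 1) {
  results <- list(); skipped <- list()
  for (zb in sort(unique(zonobiomes$zonobiome))) {
    sp <- zonobiomes$species[zonobiomes$zonobiome == zb]
    sub <- table[table$species %in% sp, ]
    for (sc in scenarios) {
      key <- paste(zb, sc, sep = "|")
      n_both <- length(intersect(sub$species[sub$scenario == current],
                                 sub$species[sub$scenario == sc]))
      if (n_both < 2) {
        skipped[[key]] <- data.frame(zonobiome = zb, scenario = sc,
                                     reason = sprintf("only %d species", n_both))
        next
      }
      results[[key]] <- permutation_test(sub, c(current, sc), n_perm = n_perm,
                                         seed = seed_for(seed, "zb", zb, sc))
    }
  }
  list(results = results,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(zonobiome = character(), scenario = character(),
                    reason = character()))
}
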