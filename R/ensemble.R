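#' Family ensembles, binarization, consensus and scenario projection
#'
#' Because pseudo-absence design differs between the regression (GLM, GAM)
#' and machine-learning (BRT, RF) families, each species gets two ensemble
#' forecasts: a TSS-weighted mean of the family's retained models (those
#' with evaluation TSS >= 0.5). Each probabilistic ensemble is cut at its
#' max-TSS threshold, and a cell counts as suitable only where BOTH family
#' binary maps agree (a conservative AND consensus). Thresholds are fixed at
#' calibration time and reused, never re-estimated, for future scenarios.
#'
#' @name ensemble-project
NULL

#' Per-species binary presence/absence surface
#'
#' @param grid A `grid_definition`.
#' @param suitable Logical vector over cells (forced `FALSE` off-mask).
#' @param species_id,scenario Labels.
#' @return A `binary_range_map` with `n_cells`, the suitable-cell count.
#' @export
binary_range_map <- function(grid, suitable, species_id, scenario) {
  suitable <- as.logical(suitable) & grid$land_mask
  suitable[is.na(suitable)] <- FALSE
  if (length(suitable) != n_cells(grid))
    stop("suitable must have one entry per grid cell")
  structure(list(grid = grid, species_id = species_id, scenario = scenario,
                 suitable = suitable, n_cells = sum(suitable)),
            class = "binary_range_map")
}

#' @export
print.binary_range_map <- function(x, ...) {
  cat(sprintf("<binary_range_map '%s' @ %s> %d suitable cells\n",
              x$species_id, x$scenario, x$n_cells))
  invisible(x)
}

#' Condition signalled when a family retains no models
#' @param species_id,family Labels for the report.
#' @return An object of class `no_retained_models`.
#' @export
no_retained_models <- function(species_id, family) {
  structure(list(species_id = species_id, family = family),
            class = "no_retained_models")
}

#' Build a TSS-weighted family ensemble
#'
#' Models with evaluation TSS below `min_tss` are excluded; the rest
#' contribute with weights proportional to their raw TSS. The ensemble
#' probability surface over the calibration stack is cut at the threshold
#' that maximizes TSS of the ensemble against the pooled calibration
#' presences/absences of the family.
#'
#' @param models List of scored `fitted_sdm` (one family, one species).
#' @param stack Calibration `climate_stack`.
#' @param calibration List with integer cell vectors `presences`, `absences`
#'   (pooled over pseudo-absence replicates for the ML family).
#' @param species_id Species label.
#' @param min_tss Retention cutoff (default 0.5).
#' @return An `ensemble_suitability`, or a [no_retained_models()] object
#'   when every model scores below `min_tss`.
#' @export
build_family_ensemble <- function(models, stack, calibration, species_id,
                                  min_tss = 0.5) {
  fams <- unique(vapply(models, `[[`, "", "family"))
  stopifnot(length(fams) == 1)
  scores <- vapply(models, `[[`, 0, "tss_eval")
  keep <- scores >= min_tss
  if (!any(keep)) return(no_retained_models(species_id, fams))
  models <- models[keep]; scores <- scores[keep]
  w <- scores / sum(scores)
  land <- land_cells(stack$grid)
  Xl <- extract_cells(stack, land)
  prob <- rep(NA_real_, n_cells(stack$grid))
  prob[land] <- Reduce(`+`, Map(function(m, wi) wi * predict(m, Xl),
                                models, w))
  cal_cells <- c(calibration$presences, calibration$absences)
  obs <- c(rep(1L, length(calibration$presences)),
           rep(0L, length(calibration$absences)))
  mt <- max_tss_threshold(prob[cal_cells], obs)
  structure(list(species_id = species_id, family = fams,
                 models = models, weights = w,
                 prob = prob, grid = stack$grid,
                 scenario = stack$scenario,
                 threshold = mt$threshold, tss_ensemble = mt$tss,
                 n_models_retained = length(models),
                 n_models_total = length(keep)),
            class = "ensemble_suitability")
}

#' @export
print.ensemble_suitability <- function(x, ...) {
  cat(sprintf("<ensemble_suitability '%s' %s> %d/%d models, threshold %.3f\n",
              x$species_id, x$family, x$n_models_retained, x$n_models_total,
              x$threshold))
  invisible(x)
}

#' Ensemble probability surface on a (possibly future) stack
#' @param ens An `ensemble_suitability`.
#' @param stack A `climate_stack` on the same grid.
#' @return Numeric vector of probabilities per cell (NA off-mask).
#' @export
predict_ensemble <- function(ens, stack) {
  if (!identical(stack$grid$land_mask, ens$grid$land_mask) ||
      n_cells(stack$grid) != n_cells(ens$grid))
    stop("scenario stack grid does not match the calibration grid")
  land <- land_cells(stack$grid)
  Xl <- extract_cells(stack, land)
  prob <- rep(NA_real_, n_cells(stack$grid))
  prob[land] <- Reduce(`+`, Map(function(m, wi) wi * predict(m, Xl),
                                ens$models, ens$weights))
  prob
}

#' Binarize an ensemble at its calibration-time threshold
#'
#' A cell is suitable iff ensemble probability >= threshold. When `stack`
#' is supplied the ensemble is first projected onto it (threshold reused,
#' not re-estimated).
#'
#' @param ens An `ensemble_suitability`.
#' @param stack Optional scenario `climate_stack`.
#' @return A `binary_range_map`.
#' @export
binarize <- function(ens, stack = NULL) {
  if (is.null(stack)) {
    prob <- ens$prob; scen <- ens$scenario
  } else {
    prob <- predict_ensemble(ens, stack); scen <- stack$scenario
  }
  binary_range_map(ens$grid, !is.na(prob) & prob >= ens$threshold,
                   ens$species_id, scen)
}

#' AND consensus of the two family maps
#'
#' @param binary_regression,binary_ml `binary_range_map`s for one species
#'   and scenario.
#' @return A `binary_range_map`, suitable only where both inputs are.
#' @export
consensus <- function(binary_regression, binary_ml) {
  a <- binary_regression; b <- binary_ml
  if (!identical(a$grid$land_mask, b$grid$land_mask))
    stop("consensus inputs are on different grids")
  if (!identical(a$scenario, b$scenario))
    stop("consensus inputs are for different scenarios")
  if (!identical(a$species_id, b$species_id))
    stop("consensus inputs are for different species")
  binary_range_map(a$grid, a$suitable & b$suitable, a$species_id, a$scenario)
}

#' Fit both family ensembles for one species
#'
#' Runs the full per-species calibration protocol: random pseudo-absences
#' for the regression family (GLM + GAM, 3 splits each), exclusion-buffer
#' pseudo-absences for the machine-learning family (BRT + RF, over
#' `pa_replicates` draws x 3 splits each), then builds the two TSS-weighted
#' ensembles on pooled calibration data.
#'
#' @param occ An `occurrence_set`.
#' @param stack Current-scenario `climate_stack`.
#' @param config A [default_config()] list (uses `n_pseudo_random`,
#'   `exclusion_radius_km`, `pa_replicates`, `calibration_fraction`,
#'   `split_repeats`, `min_tss`, `learner_params`).
#' @param seed Integer master seed.
#' @return List with `regression` and `machine_learning` entries (each an
#'   `ensemble_suitability` or `no_retained_models`), plus `scores`: a
#'   data.frame of every fitted model's TSS (species, algorithm, family,
#'   pa_replicate, split_replicate, tss).
#' @export
species_ensembles <- function(occ, stack, config = default_config(),
                              seed = config$master_seed) {
  sp <- occ$species_id
  grid <- stack$grid
  abs_rand <- pseudo_absences_random(
    grid, n = config$n_pseudo_random,
    seed = seed_for(seed, "pa_random", sp))
  abs_excl <- pseudo_absences_exclusion(
    occ, grid, radius_km = config$exclusion_radius_km,
    replicates = config$pa_replicates, seed = seed)

  models_reg <- list()
  tr <- training_set(occ$cells, abs_rand, stack, family = "regression")
  for (alg in c("GLM", "GAM")) {
    models_reg <- c(models_reg, split_sample_evaluate(
      alg, tr, calibration_fraction = config$calibration_fraction,
      repeats = config$split_repeats, seed = seed_for(seed, "eval", sp, alg),
      params = config$learner_params))
  }
  models_ml <- list()
  for (r in seq_along(abs_excl)) {
    trr <- training_set(occ$cells, abs_excl[[r]], stack,
                        family = "machine_learning", replicate_id = r)
    for (alg in c("BRT", "RF")) {
      models_ml <- c(models_ml, split_sample_evaluate(
        alg, trr, calibration_fraction = config$calibration_fraction,
        repeats = config$split_repeats,
        seed = seed_for(seed, "eval", sp, alg, r),
        params = config$learner_params))
    }
  }
  score_row <- function(m) data.frame(
    species = sp, algorithm = m$algorithm, family = m$family,
    pa_replicate = m$pa_replicate, split_replicate = m$split_replicate,
    tss = m$tss_eval)
  scores <- do.call(rbind, lapply(c(models_reg, models_ml), score_row))
  list(
    regression = build_family_ensemble(
      models_reg, stack,
      calibration = list(presences = occ$cells, absences = abs_rand),
      species_id = sp, min_tss = config$min_tss),
    machine_learning = build_family_ensemble(
      models_ml, stack,
      calibration = list(presences = occ$cells,
                         absences = unique(unlist(abs_excl))),
      species_id = sp, min_tss = config$min_tss),
    scores = scores)
}

#' Project consensus range maps for all species and scenarios
#'
#' Species whose regression or machine-learning family retained no models
#' are excluded from projection entirely and reported, not zero-filled.
#'
#' @param ensembles Named list (by species) as returned by
#'   [species_ensembles()].
#' @param stacks Named list of `climate_stack`s, one per scenario; must
#'   include the calibration scenario.
#' @return List with `maps` (nested: `maps[[species]][[scenario]]` is the
#'   consensus `binary_range_map`), `family_maps` (same nesting, per-family
#'   maps), `summary` (data.frame species, scenario, n_cells) and `dropped`
#'   (data.frame species, family of every exclusion).
#' @export
project_all <- function(ensembles, stacks) {
  stopifnot(length(names(stacks)) == length(stacks))
  maps <- list(); fam_maps <- list(); rows <- list(); dropped <- list()
  for (sp in names(ensembles)) {
    e <- ensembles[[sp]]
    bad <- vapply(e[c("regression", "machine_learning")],
                  inherits, TRUE, "no_retained_models")
    if (any(bad)) {
      for (f in names(bad)[bad])
        dropped[[length(dropped) + 1L]] <- data.frame(species = sp, family = f)
      next
    }
    maps[[sp]] <- list(); fam_maps[[sp]] <- list()
    for (scen in names(stacks)) {
      br <- binarize(e$regression, stacks[[scen]])
      bm <- binarize(e$machine_learning, stacks[[scen]])
      cm <- consensus(br, bm)
      maps[[sp]][[scen]] <- cm
      fam_maps[[sp]][[scen]] <- list(regression = br, machine_learning = bm)
      rows[[length(rows) + 1L]] <-
        data.frame(species = sp, scenario = scen, n_cells = cm$n_cells)
    }
  }
  list(maps = maps, family_maps = fam_maps,
       summary = if (length(rows)) do.call(rbind, rows) else
         data.frame(species = character(), scenario = character(),
                    n_cells = integer()),
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(species = character(), family = character()))
}

#' Jaccard overlap of two binary range maps
#' @param a,b `binary_range_map`s on one grid.
#' @return Intersection over union of suitable cells (1 if both empty).
#' @export
jaccard <- function(a, b) {
  i <- sum(a$suitable & b$suitable)
  u <- sum(a$suitable | b$suitable)
  if (u == 0) 1 else i / u
}
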