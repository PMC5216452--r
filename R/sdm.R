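#' Pseudo-absence design, model fitting and TSS evaluation
#'
#' Presence-only data are completed with pseudo-absences whose design
#' differs by model family: the regression family (GLM, GAM) uses 10,000
#' randomly placed absences; the machine-learning family (BRT, RF) uses as
#' many absences as there are presences, drawn outside a 200-km exclusion
#' buffer around them, with the draw repeated ten times. Case weights make
#' the weighted sum of presences equal the weighted sum of absences
#' (prevalence 0.5). Models are scored by the true skill statistic under a
#' three-fold repeated 80/20 split.
#'
#' @name sdm-fit
NULL

#' Random pseudo-absences
#'
#' Draws `n` cells uniformly from the land cells of the calibration extent:
#' without replacement when enough land cells exist, with replacement
#' otherwise. Presence cells are not excluded (no buffer for this family).
#'
#' @param grid A `grid_definition` (the calibration extent).
#' @param n Number of absences (default 10000).
#' @param seed Integer seed.
#' @return Integer vector of cell indices, length `n`.
#' @export
pseudo_absences_random <- function(grid, n = 10000, seed = 1) {
  land <- land_cells(grid)
  if (!length(land)) stop("empty land mask: no cells to sample absences from")
  set.seed(seed)
  land[sample.int(length(land), n, replace = length(land) < n)]
}

#' Exclusion-buffer pseudo-absences for the machine-learning family
#'
#' Each replicate draws `length(occ$cells)` cells uniformly without
#' replacement from land cells whose centre lies strictly farther than
#' `radius_km` (great-circle) from every presence-cell centre.
#'
#' @param occ An `occurrence_set`.
#' @param grid A `grid_definition`.
#' @param radius_km Exclusion radius (default 200 km).
#' @param replicates Number of independent draws (default 10).
#' @param seed Integer master seed; replicate r uses substream
#'   `seed_for(seed, "pa_exclusion", species, r)`.
#' @return List of `replicates` integer cell vectors, each of length
#'   `length(occ$cells)`, with attribute `"eligible"` (the candidate pool).
#' @export
pseudo_absences_exclusion <- function(occ, grid, radius_km = 200,
                                      replicates = 10, seed = 1) {
  land <- land_cells(grid)
  pres <- occ$cells
  pc <- cell_center(pres, grid)
  lc <- cell_center(land, grid)
  # min distance from each land cell to any presence, blockwise to cap memory
  mind <- rep(Inf, length(land))
  step <- max(1L, floor(2e6 / max(1, length(pres))))
  for (s in seq(1, length(land), by = step)) {
    i <- s:min(length(land), s + step - 1L)
    d <- outer(seq_along(i), seq_along(pres), function(a, b)
      haversine_km(lc$lon[i[a]], lc$lat[i[a]], pc$lon[b], pc$lat[b]))
    mind[i] <- pmin(mind[i], apply(d, 1, min))
  }
  eligible <- land[mind > radius_km]
  if (length(eligible) < length(pres))
    stop(sprintf(
      "species %s: only %d cells lie > %g km from all %d presences (need %d)",
      occ$species_id, length(eligible), radius_km, length(pres), length(pres)))
  out <- lapply(seq_len(replicates), function(r) {
    set.seed(seed_for(seed, "pa_exclusion", occ$species_id, r))
    eligible[sample.int(length(eligible), length(pres))]
  })
  attr(out, "eligible") <- eligible
  out
}

#' Case weights equalizing presence and absence mass
#'
#' Presences get weight 1, absences `n_pres / n_abs`, so both classes carry
#' equal total weight (prevalence 0.5).
#'
#' @param n_pres,n_abs Positive class counts.
#' @return List with `presence` and `absence` scalar weights.
#' @export
make_weights <- function(n_pres, n_abs) {
  if (n_pres < 1 || n_abs < 1) stop("both classes must be non-empty")
  list(presence = 1, absence = n_pres / n_abs)
}

#' Assemble a weighted training set
#'
#' @param presences,absences Integer cell vectors.
#' @param stack A `climate_stack` supplying predictor values.
#' @param family `"regression"` or `"machine_learning"` (bookkeeping).
#' @param replicate_id Pseudo-absence replicate id (bookkeeping).
#' @return A `training_set`: data (predictors), response `y`, weights `w`.
#' @export
training_set <- function(presences, absences, stack,
                         family = c("regression", "machine_learning"),
                         replicate_id = 1L) {
  family <- match.arg(family)
  wts <- make_weights(length(presences), length(absences))
  X <- rbind(extract_cells(stack, presences), extract_cells(stack, absences))
  if (any(!is.finite(X))) stop("training cells have non-finite predictor values")
  structure(list(
    X = X,
    y = c(rep(1, length(presences)), rep(0, length(absences))),
    w = c(rep(wts$presence, length(presences)),
          rep(wts$absence, length(absences))),
    cells = c(presences, absences),
    family = family, replicate_id = as.integer(replicate_id)),
    class = "training_set")
}

SDM_ALGORITHMS <- c(GLM = "regression", GAM = "regression",
                    BRT = "machine_learning", RF = "machine_learning")

#' Default learner hyperparameters
#'
#' The source methods fix no hyperparameters; these defaults are
#' conventional for SDM work and are recorded with every fitted model:
#' GLM with linear + quadratic terms; GAM with thin-plate smooths (k = 4);
#' BRT with 100 trees of depth 3, learning rate 0.1; RF with 100 trees,
#' mtry = 2, node size 5.
#' @return Named list of per-algorithm settings.
#' @export
default_learner_params <- function() {
  list(GAM = list(k = 4),
       BRT = list(ntree = 100, interaction_depth = 3, shrinkage = 0.1,
                  min_node = 10),
       RF = list(ntree = 100, mtry = 2, max_depth = 25, min_node = 5))
}

#' Fit one SDM
#'
#' @param algorithm One of `"GLM"`, `"GAM"`, `"BRT"`, `"RF"`.
#' @param training A `training_set` (all predictor values finite).
#' @param params Hyperparameters, see [default_learner_params()].
#' @param seed Integer seed for the stochastic learners (BRT, RF).
#' @return A `fitted_sdm` with a `predict` contract mapping a predictor
#'   matrix to probabilities in [0, 1].
#' @export
fit_sdm <- function(algorithm, training, params = default_learner_params(),
                    seed = 1) {
  algorithm <- match.arg(algorithm, names(SDM_ALGORITHMS))
  if (length(unique(training$y)) < 2)
    stop("degenerate training set: only one class present")
  X <- training$X
  vars <- colnames(X)
  df <- as.data.frame(X)
  df$.y <- training$y
  fit <- switch(algorithm,
    GLM = {
      rhs <- paste(sprintf("%s + I(%s^2)", vars, vars), collapse = " + ")
      f <- stats::as.formula(paste(".y ~", rhs))
      suppressWarnings(stats::glm(f, data = df, family = stats::binomial(),
                                  weights = training$w))
    },
    GAM = {
      k <- params$GAM$k
      uniq <- vapply(vars, function(v) length(unique(df[[v]])), 0L)
      terms <- ifelse(uniq > k + 1,
                      sprintf("s(%s, k = %d)", vars, k), vars)
      f <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
      suppressWarnings(mgcv::gam(f, data = df, family = stats::binomial(),
                                 weights = training$w, method = "REML"))
    },
    BRT = {
      p <- params$BRT
      .brt_fit_cpp(X, training$y, training$w, p$ntree, p$interaction_depth,
                   p$shrinkage, p$min_node, seed)
    },
    RF = {
      p <- params$RF
      .rf_fit_cpp(X, training$y, training$w, p$ntree, p$mtry, p$max_depth,
                  p$min_node, seed)
    })
  structure(list(algorithm = algorithm, family = SDM_ALGORITHMS[[algorithm]],
                 fit = fit, vars = vars, params = params, seed = seed,
                 pa_replicate = training$replicate_id),
            class = "fitted_sdm")
}

#' Predict suitability probabilities from a fitted SDM
#' @param object A `fitted_sdm`.
#' @param newdata Predictor matrix with the training columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predict.fitted_sdm <- function(object, newdata, ...) {
  X <- newdata[, object$vars, drop = FALSE]
  p <- switch(object$algorithm,
    GLM = stats::predict(object$fit, newdata = as.data.frame(X),
                         type = "response"),
    GAM = as.numeric(stats::predict(object$fit, newdata = as.data.frame(X),
                                    type = "response")),
    BRT = .brt_predict_cpp(object$fit, as.matrix(X)),
    RF = .rf_predict_cpp(object$fit, as.matrix(X)))
  pmin(1, pmax(0, as.numeric(p)))
}

#' True skill statistic
#'
#' `TSS = sensitivity + specificity - 1` for the classification
#' `predicted >= threshold`; ranges over [-1, 1], 0 for no-skill.
#'
#' @param predicted Probabilities in [0, 1].
#' @param observed Binary 0/1 vector (must contain both classes).
#' @param threshold Classification threshold.
#' @return TSS score.
#' @export
tss <- function(predicted, observed, threshold) {
  observed <- as.integer(observed)
  if (length(unique(observed)) < 2)
    stop("TSS needs at least one observed presence and one absence")
  pos <- predicted >= threshold
  sens <- sum(pos & observed == 1) / sum(observed == 1)
  spec <- sum(!pos & observed == 0) / sum(observed == 0)
  sens + spec - 1
}

#' Threshold maximizing the TSS
#'
#' Scans the midpoints of consecutive sorted unique predicted values, plus
#' 0 and 1, and returns the lowest threshold achieving the maximum TSS.
#' Computed by cumulative counts over the sorted predictions, equivalent to
#' (and tested against) a brute-force grid scan.
#'
#' @param predicted Probabilities in [0, 1].
#' @param observed Binary 0/1 vector with both classes.
#' @return List with `threshold` and `tss`.
#' @export
max_tss_threshold <- function(predicted, observed) {
  observed <- as.integer(observed)
  if (length(unique(observed)) < 2)
    stop("TSS needs at least one observed presence and one absence")
  u <- sort(unique(predicted))
  cand <- unique(c(0, if (length(u) > 1)
    (u[-length(u)] + u[-1]) / 2, 1))
  # classification is predicted >= t; count positives with pred >= t fast
  np <- sum(observed == 1); na <- sum(observed == 0)
  ord <- order(predicted)
  ps <- predicted[ord]; os <- observed[ord]
  # for each candidate, index of first prediction >= t
  first_ge <- findInterval(cand, ps, left.open = TRUE) + 1L
  cum_pres <- c(rev(cumsum(rev(os))), 0)        # presences with index >= i
  cum_abs <- c(rev(cumsum(rev(1 - os))), 0)
  sens <- cum_pres[first_ge] / np
  spec <- 1 - cum_abs[first_ge] / na
  scores <- sens + spec - 1
  best <- max(scores)
  thr <- cand[which(scores >= best - 1e-12)[1]]  # lowest optimal threshold
  list(threshold = thr, tss = best)
}

#' Repeated split-sample calibration and TSS evaluation
#'
#' For each of `repeats` stratified random 80/20 splits: fit on the
#' calibration 80%, pick the threshold maximizing TSS on the evaluation 20%,
#' and score the model there. Returns one scored model per repeat; callers
#' loop over pseudo-absence replicates for the machine-learning family.
#'
#' @param algorithm One of `"GLM"`, `"GAM"`, `"BRT"`, `"RF"`.
#' @param training A `training_set`.
#' @param calibration_fraction Fraction used for fitting (default 0.8).
#' @param repeats Number of splits (default 3).
#' @param seed Integer master seed.
#' @param params Learner hyperparameters.
#' @return List of `fitted_sdm`, each with `$tss_eval`, `$threshold_eval`
#'   and `$split_replicate` set.
#' @export
split_sample_evaluate <- function(algorithm, training,
                                  calibration_fraction = 0.8, repeats = 3,
                                  seed = 1,
                                  params = default_learner_params()) {
  n <- length(training$y)
  out <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed_for(seed, "split", algorithm, training$replicate_id, r))
    cal <- logical(n)
    ok <- FALSE
    for (attempt in 1:20) {   # stratified split; both partitions need both classes
      for (cls in unique(training$y)) {
        i <- which(training$y == cls)
        k <- round(length(i) * calibration_fraction)
        cal[i] <- FALSE
        cal[sample(i, k)] <- TRUE
      }
      if (length(unique(training$y[cal])) == 2 &&
          length(unique(training$y[!cal])) == 2) { ok <- TRUE; break }
    }
    if (!ok) stop("could not produce a stratified split with both classes")
    tr <- training
    tr$X <- training$X[cal, , drop = FALSE]
    tr$y <- training$y[cal]; tr$w <- training$w[cal]
    tr$cells <- training$cells[cal]
    m <- fit_sdm(algorithm, tr, params = params,
                 seed = seed_for(seed, "fit", algorithm,
                                 training$replicate_id, r))
    pe <- predict(m, training$X[!cal, , drop = FALSE])
    mt <- max_tss_threshold(pe, training$y[!cal])
    m$tss_eval <- mt$tss
    m$threshold_eval <- mt$threshold
    m$split_replicate <- r
    out[[r]] <- m
  }
  out
}
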