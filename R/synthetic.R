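#' Synthetic climate, species, occurrences and land cover
#'
#' Desk-scale stand-ins for the real inputs (GBIF occurrences, gridded
#' 1950-2000 baseline climate, additive scenario offsets for RCP2.6/4.5/8.5,
#' and a fine-resolution land-cover classification). Every generator is a
#' pure function of its parameters and a seed.
#'
#' @name synthetic-data
NULL

#' Canonical predictor layer names
#'
#' Six bioclimatic predictors: temperature seasonality, maximum temperature
#' of the warmest month, minimum temperature of the coldest month,
#' precipitation seasonality, precipitation of the wettest quarter,
#' precipitation of the driest quarter.
#' @export
CLIMATE_LAYERS <- c("temp_seasonality", "tmax_warmest", "tmin_coldest",
                    "prec_seasonality", "prec_wettest", "prec_driest")

#' Bundle predictor layers into a scenario-tagged climate stack
#'
#' @param grid A `grid_definition`.
#' @param layers Named list of numeric vectors (one value per cell), names
#'   must be exactly [CLIMATE_LAYERS].
#' @param scenario Scenario label, e.g. `"current"`, `"RCP2.6"`.
#' @return A `climate_stack`.
#' @export
climate_stack <- function(grid, layers, scenario = "current") {
  stopifnot(inherits(grid, "grid_definition"))
  if (!identical(sort(names(layers)), sort(CLIMATE_LAYERS)))
    stop("layers must be named exactly: ", paste(CLIMATE_LAYERS, collapse = ", "))
  layers <- layers[CLIMATE_LAYERS]
  for (nm in CLIMATE_LAYERS) {
    v <- as.numeric(layers[[nm]])
    if (length(v) != n_cells(grid))
      stop("layer '", nm, "' must have one value per cell")
    if (any(!is.finite(v[grid$land_mask])))
      stop("layer '", nm, "' has non-finite values on land")
    layers[[nm]] <- v
  }
  structure(list(grid = grid, scenario = scenario, layers = layers),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("<climate_stack '%s'> %d layers on %d x %d grid\n",
              x$scenario, length(x$layers), x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Extract predictor values at cells
#' @param stack A `climate_stack`.
#' @param cells Integer cell indices.
#' @return Numeric matrix, one row per cell, columns in [CLIMATE_LAYERS] order.
#' @export
extract_cells <- function(stack, cells) {
  out <- vapply(stack$layers, function(v) v[cells], numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(stack$layers)))
  out
}

# Spatially autocorrelated Gaussian field: white noise smoothed with a
# separable Gaussian kernel, rescaled to unit variance.
smooth_field <- function(n_rows, n_cols, range_cells = 4) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (range_cells > 0) {
    half <- max(1L, ceiling(2 * range_cells))
    k <- stats::dnorm(-half:half, sd = range_cells)
    k <- k / sum(k)
    pad_conv <- function(m, k) {
      # convolve each column with reflected padding
      h <- (length(k) - 1L) / 2L
      n <- nrow(m)
      idx <- c(pmin(n, pmax(1, (1 - h):0)), 1:n, pmin(n, pmax(1, (n + 1):(n + h))))
      mp <- m[idx, , drop = FALSE]
      apply(mp, 2, function(col) stats::filter(col, k, sides = 2)[(h + 1):(h + n)])
    }
    z <- pad_conv(z, k)
    z <- t(pad_conv(t(z), k))
  }
  z <- z - mean(z)
  z / stats::sd(as.vector(z))
}

#' Generate a spatially autocorrelated land mask
#'
#' The real European study-area mask is an input; for synthetic runs this
#' carves ocean where a smooth random field falls below a quantile, giving
#' contiguous coastlines rather than salt-and-pepper water.
#'
#' @param grid A `grid_definition` (its mask is ignored).
#' @param ocean_fraction Fraction of cells to mark as ocean.
#' @param seed Integer seed.
#' @return A `grid_definition` with the new mask.
#' @export
synth_land_mask <- function(grid, ocean_fraction = 0.2, seed = 1) {
  stopifnot(ocean_fraction >= 0, ocean_fraction < 1)
  set.seed(seed)
  f <- as.vector(smooth_field(grid$n_rows, grid$n_cols, range_cells = 6))
  mask <- f > stats::quantile(f, ocean_fraction)
  grid_definition(grid$min_lon, grid$min_lat, grid$n_rows, grid$n_cols,
                  grid$cell_size, land_mask = mask)
}

#' Generate the current-scenario climate stack
#'
#' Each layer is a deterministic large-scale gradient (different direction
#' per layer) plus spatially autocorrelated noise. Gradient directions are
#' chosen so that no pair of layers shares (or opposes) its gradient, and
#' the generator retries with a perturbed seed until all pairwise Pearson
#' correlations on land satisfy `|r| < max_abs_cor`, mirroring the predictor
#' screening applied to the real bioclim set.
#'
#' @param grid A `grid_definition`.
#' @param seed Integer seed.
#' @param noise_sd Noise standard deviation relative to the gradient range
#'   (0 disables noise; the default 0.35 is moderate).
#' @param range_cells Autocorrelation range of the noise, in cells.
#' @param max_abs_cor Pairwise correlation bound (default 0.75).
#' @param max_retries Retry budget before failing.
#' @return A `climate_stack` (scenario `"current"`) with attribute
#'   `"cor_matrix"`, the pairwise Pearson correlation matrix on land cells.
#' @export
make_climate_stack <- function(grid, seed = 1, noise_sd = 0.35,
                               range_cells = 4, max_abs_cor = 0.75,
                               max_retries = 20) {
  rc <- cell_rowcol(seq_len(n_cells(grid)), grid)
  lonf <- (rc[, "col"] - 0.5) / grid$n_cols
  latf <- (rc[, "row"] - 0.5) / grid$n_rows
  # unit-variance shifted Legendre polynomials: mutually orthogonal under
  # the uniform cell measure, so six distinct spatial patterns can share a
  # grid with structural |r| <= 0.7 even at zero noise
  l1 <- function(u) sqrt(3) * (2 * u - 1)
  l2 <- function(u) sqrt(5) * (6 * u^2 - 6 * u + 1)
  patterns <- list(
    temp_seasonality = l1(lonf),                                 # continentality W-E
    tmax_warmest     = -l1(latf),                                # warm south
    tmin_coldest     = -0.7 * l1(latf) + sqrt(0.51) * l2(latf),  # r = 0.7 with tmax
    prec_seasonality = l1(lonf) * l1(latf),
    prec_wettest     = -0.6 * l1(lonf) + 0.8 * l2(lonf),
    prec_driest      = l2(lonf) * l1(latf)
  )
  base <- list(
    temp_seasonality = list(off = 300, sc = 60),
    tmax_warmest     = list(off = 22,  sc = 6),
    tmin_coldest     = list(off = -6,  sc = 6),
    prec_seasonality = list(off = 60,  sc = 15),
    prec_wettest     = list(off = 600, sc = 130),
    prec_driest      = list(off = 120, sc = 35)
  )
  for (try in seq_len(max_retries)) {
    set.seed(seed + 7919L * (try - 1L))
    layers <- lapply(names(base), function(nm) {
      p <- base[[nm]]
      noise <- if (noise_sd > 0)
        as.vector(smooth_field(grid$n_rows, grid$n_cols, range_cells)) * noise_sd
      else 0
      p$off + p$sc * (patterns[[nm]] + noise)
    })
    names(layers) <- names(base)
    layers <- layers[CLIMATE_LAYERS]
    m <- vapply(layers, function(v) v[grid$land_mask], numeric(sum(grid$land_mask)))
    cm <- stats::cor(m)
    off <- abs(cm[upper.tri(cm)])
    if (all(off < max_abs_cor)) {
      st <- climate_stack(grid, layers, scenario = "current")
      attr(st, "cor_matrix") <- cm
      return(st)
    }
  }
  w <- which(abs(cm) == max(off), arr.ind = TRUE)[1, ]
  stop(sprintf("could not generate climate stack with all |r| < %g in %d tries; worst pair %s ~ %s (r = %.3f)",
               max_abs_cor, max_retries, rownames(cm)[w[1]], colnames(cm)[w[2]],
               cm[w[1], w[2]]))
}

#' Scenario offsets
#'
#' Additive per-layer shifts standing in for downscaled scenario climatologies.
#' The `"current"` scenario must have all-zero offsets. Defaults follow the
#' mild/intermediate/severe ordering of RCP2.6/4.5/8.5: warming on both
#' temperature layers, increased seasonality, drier dry season.
#'
#' @param scenario One of `"current"`, `"RCP2.6"`, `"RCP4.5"`, `"RCP8.5"`, or
#'   any label when `offsets` is given explicitly.
#' @param offsets Named numeric vector of per-layer additive shifts; missing
#'   layers shift by 0.
#' @return A `scenario_delta`.
#' @export
scenario_delta <- function(scenario, offsets = NULL) {
  if (is.null(offsets)) {
    presets <- list(
      "current" = c(),
      "RCP2.6" = c(tmax_warmest = 1.0, tmin_coldest = 1.0,
                   temp_seasonality = 10, prec_driest = -10),
      "RCP4.5" = c(tmax_warmest = 2.0, tmin_coldest = 2.0,
                   temp_seasonality = 20, prec_driest = -20),
      "RCP8.5" = c(tmax_warmest = 4.0, tmin_coldest = 4.0,
                   temp_seasonality = 40, prec_driest = -40)
    )
    if (!scenario %in% names(presets))
      stop("no preset offsets for scenario '", scenario, "'")
    offsets <- presets[[scenario]]
  }
  offsets <- as.numeric(offsets) |> stats::setNames(names(offsets))
  if (length(offsets) && !all(names(offsets) %in% CLIMATE_LAYERS))
    stop("unknown layer in offsets: ",
         paste(setdiff(names(offsets), CLIMATE_LAYERS), collapse = ", "))
  full <- stats::setNames(rep(0, length(CLIMATE_LAYERS)), CLIMATE_LAYERS)
  full[names(offsets)] <- offsets
  if (identical(scenario, "current") && any(full != 0))
    stop("the current scenario must have all-zero offsets")
  structure(list(scenario = scenario, offsets = full), class = "scenario_delta")
}

#' Apply a scenario offset to the current-scenario stack
#' @param stack The current-scenario `climate_stack`.
#' @param delta A `scenario_delta`.
#' @return A `climate_stack` tagged with the delta's scenario.
#' @export
apply_scenario <- function(stack, delta) {
  stopifnot(inherits(stack, "climate_stack"), inherits(delta, "scenario_delta"))
  if (!identical(names(stack$layers), names(delta$offsets)))
    stop("layer names of stack and delta do not match")
  layers <- Map(function(v, d) v + d, stack$layers, delta$offsets)
  climate_stack(stack$grid, layers, scenario = delta$scenario)
}

#' Gaussian-niche virtual species
#'
#' True suitability is a product of independent Gaussian responses,
#' `S(x) = exp(-0.5 * sum_j ((z_j(x) - mu_j) / sigma_j)^2)`, equal to 1
#' exactly at the niche optimum. The true range under a scenario is the set
#' of land cells with `S >= tau`, which makes range-recovery exact.
#'
#' @param species_id Label.
#' @param mu Named 6-vector of niche optima (one per predictor layer).
#' @param sigma Named 6-vector of strictly positive niche breadths.
#' @param tau Suitability cutoff in (0,1) defining the true range.
#' @return A `synthetic_species`.
#' @export
synthetic_species <- function(species_id, mu, sigma, tau = 0.5) {
  stopifnot(length(mu) == 6, length(sigma) == 6, all(sigma > 0),
            tau > 0, tau < 1)
  if (is.null(names(mu))) names(mu) <- CLIMATE_LAYERS
  if (is.null(names(sigma))) names(sigma) <- CLIMATE_LAYERS
  mu <- mu[CLIMATE_LAYERS]; sigma <- sigma[CLIMATE_LAYERS]
  structure(list(species_id = species_id, mu = mu, sigma = sigma, tau = tau),
            class = "synthetic_species")
}

#' True climatic suitability of a virtual species
#' @param species A `synthetic_species`.
#' @param stack A `climate_stack`.
#' @return A `raster_layer` with values in [0, 1].
#' @export
true_suitability <- function(species, stack) {
  stopifnot(inherits(species, "synthetic_species"))
  d2 <- 0
  for (nm in CLIMATE_LAYERS) {
    d2 <- d2 + ((stack$layers[[nm]] - species$mu[[nm]]) / species$sigma[[nm]])^2
  }
  raster_layer(stack$grid, exp(-0.5 * d2),
               name = paste0("suitability_", species$species_id))
}

#' True range of a virtual species under a scenario
#' @param species A `synthetic_species`.
#' @param stack A `climate_stack` for the scenario of interest.
#' @return A `binary_range_map` of land cells with suitability >= `tau`.
#' @export
true_range <- function(species, stack) {
  s <- true_suitability(species, stack)
  suit <- s$values >= species$tau & stack$grid$land_mask
  binary_range_map(stack$grid, suit, species$species_id, stack$scenario)
}

#' Draw a pool of virtual species from the climate itself
#'
#' Optima are the climate values of randomly chosen land cells (so every
#' species has attainable habitat); breadths are `breadth` times each
#' layer's standard deviation over land, jittered by +/-25%.
#'
#' @param stack Current-scenario `climate_stack`.
#' @param n_species Number of species.
#' @param breadth Niche breadth as a multiple of each layer's land SD
#'   (default 0.6: a moderate specialist).
#' @param tau True-range suitability cutoff; the default `NULL` sets each
#'   species' cutoff to its land-mean suitability. That is the contour a
#'   TSS-optimal classifier converges to when presences are sampled
#'   proportionally to suitability against a uniform background, so with
#'   the default the "true range" is the well-posed recovery target rather
#'   than an arbitrary level set.
#' @param seed Integer seed.
#' @return List of `synthetic_species`.
#' @export
make_species_pool <- function(stack, n_species, breadth = 0.6, tau = NULL,
                              seed = 1) {
  set.seed(seed)
  land <- land_cells(stack$grid)
  sds <- vapply(stack$layers, function(v) stats::sd(v[land]), 0)
  anchors <- land[sample.int(length(land), n_species, replace = TRUE)]
  lapply(seq_len(n_species), function(i) {
    mu <- vapply(stack$layers, function(v) v[anchors[i]], 0)
    sig <- sds * breadth * stats::runif(6, 0.75, 1.25)
    sp <- synthetic_species(sprintf("sp%03d", i), mu, sig, tau = 0.5)
    if (is.null(tau)) {
      sp$tau <- mean(true_suitability(sp, stack)$values[land])
    } else {
      sp$tau <- tau
    }
    sp
  })
}

#' Presence-only occurrence sampling
#'
#' Emulates opportunistically collected occurrence records: `n` cells are
#' drawn with replacement with probability proportional to true suitability
#' times an optional effort/bias field, then collapsed to one record per
#' distinct cell (as grid-cell deduplication would do), so the output has at
#' most `n` cells.
#'
#' @param species A `synthetic_species`.
#' @param stack A `climate_stack`.
#' @param n Number of raw draws (>= 1).
#' @param bias Optional `raster_layer` of non-negative sampling effort.
#' @param seed Integer seed.
#' @return An `occurrence_set` (see [occurrence_set()]); `n_raw = n`.
#' @export
sample_occurrences <- function(species, stack, n, bias = NULL, seed = 1) {
  stopifnot(n >= 1)
  land <- land_cells(stack$grid)
  w <- true_suitability(species, stack)$values[land]
  if (!is.null(bias)) {
    stopifnot(inherits(bias, "raster_layer"))
    w <- w * pmax(0, bias$values[land])
  }
  if (all(w <= 0)) stop("all sampling weights are zero for species ",
                        species$species_id)
  set.seed(seed)
  draws <- land[sample.int(length(land), n, replace = TRUE, prob = w)]
  occurrence_set(species$species_id, cells = unique(draws), n_raw = n,
                 grid = stack$grid)
}

#' Occurrence cells to lon/lat records
#'
#' Converts an `occurrence_set` back into point records by placing each
#' record uniformly at random inside its cell (or at the centre), for
#' exercising the CSV cleaning path.
#'
#' @param occ An `occurrence_set`.
#' @param grid A `grid_definition`.
#' @param jitter If `TRUE` (default), place points uniformly within cells.
#' @param seed Integer seed for the jitter.
#' @return Data frame `species`, `lon`, `lat`.
#' @export
occurrences_to_records <- function(occ, grid, jitter = TRUE, seed = 1) {
  ctr <- cell_center(occ$cells, grid)
  if (jitter) {
    set.seed(seed)
    half <- grid$res_deg / 2
    ctr$lon <- ctr$lon + stats::runif(nrow(ctr), -half, half * 0.999)
    ctr$lat <- ctr$lat + stats::runif(nrow(ctr), -half, half * 0.999)
  }
  data.frame(species = occ$species_id, lon = ctr$lon, lat = ctr$lat)
}

#' Synthetic categorical land cover with weighting schemes
#'
#' Each analysis cell is subdivided into `subcells_per_side^2` equal-area
#' subcells carrying one of `n_classes` classes. Classes are spatially
#' clumped (assigned from a smoothed random field cut at equal quantiles).
#' Three class-to-proportion weighting schemes are returned; scheme 1 is the
#' reference, schemes 2 and 3 are perturbations of it, and the designated
#' urban/garden class (class `n_classes`) always carries the highest weight,
#' as in land-cover ratings that put private and public garden space at the
#' top.
#'
#' @param grid A `grid_definition`.
#' @param n_classes Number of land-cover classes (>= 2).
#' @param subcells_per_side Subdivision factor per cell side (default 4:
#'   16 subcells per analysis cell).
#' @param seed Integer seed.
#' @return List with `classes` (integer matrix, fine resolution,
#'   `n_rows*f` x `n_cols*f`), `subcells_per_side`, and `schemes`: a list of
#'   three named numeric vectors mapping class id to proportion in [0, 1].
#' @export
make_landcover <- function(grid, n_classes = 5, subcells_per_side = 4,
                           seed = 1) {
  stopifnot(n_classes >= 2, subcells_per_side >= 1)
  set.seed(seed)
  f <- subcells_per_side
  nr <- grid$n_rows * f; nc <- grid$n_cols * f
  field <- smooth_field(nr, nc, range_cells = 2 * f)
  qs <- stats::quantile(field, probs = seq(0, 1, length.out = n_classes + 1))
  classes <- matrix(cut(field, breaks = unique(qs), labels = FALSE,
                        include.lowest = TRUE), nr, nc)
  base <- seq(0.05, 0.45, length.out = n_classes)  # class n_classes highest
  schemes <- lapply(1:3, function(s) {
    w <- if (s == 1) base else
      pmin(1, pmax(0, base * stats::runif(n_classes, 0.7, 1.3)))
    w[n_classes] <- max(w) + 0.05  # urban/garden class always on top
    stats::setNames(pmin(1, w), as.character(seq_len(n_classes)))
  })
  list(classes = classes, subcells_per_side = f, schemes = schemes)
}
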