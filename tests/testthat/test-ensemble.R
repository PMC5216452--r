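# hand-built fitted models with a fixed prediction contract, to exercise the
# ensemble logic independently of the learners
fake_model <- function(probs_by_cell, tss_eval, family = "regression") {
  m <- structure(list(algorithm = "GLM", family = family,
                      vars = CLIMATE_LAYERS, pa_replicate = 1L,
                      split_replicate = 1L, tss_eval = tss_eval,
                      probs = probs_by_cell),
                 class = c("fake_sdm", "fitted_sdm"))
  m
}
# fake predictions keyed by the (lat, lon) gradient pair, unique per cell
cell_key <- function(tmax, tseas) {
  paste(round(tmax, 6), round(tseas, 6))
}
predict.fake_sdm <- function(object, newdata, ...) {
  object$probs[cell_key(newdata[, "tmax_warmest"],
                        newdata[, "temp_seasonality"])]
}
registerS3method("predict", "fake_sdm", predict.fake_sdm)

toy_world <- function(n = 4) {
  g <- tiny_grid(n, n)
  st <- toy_stack(g)
  key <- cell_key(st$layers$tmax_warmest, st$layers$temp_seasonality)
  stopifnot(!anyDuplicated(key))
  list(g = g, st = st, key = key)
}

test_that("build_family_ensemble weights by TSS and filters at 0.5", {
  w <- toy_world()
  p1 <- setNames(seq(0, 1, length.out = 16), w$key)
  p2 <- setNames(rep(0.5, 16), w$key)
  calib <- list(presences = 13:16, absences = 1:4)
  m1 <- fake_model(p1, 0.9); m2 <- fake_model(p2, 0.6)
  ens <- build_family_ensemble(list(m1, m2), w$st, calib, "spT")
  expect_equal(ens$weights, c(0.6, 0.4))   # 0.9 : 0.6 normalized
  expect_equal(ens$n_models_retained, 2L)
  # convex combination: bounded by member predictions per cell
  expect_true(all(ens$prob >= pmin(p1, p2) - 1e-12 &
                    ens$prob <= pmax(p1, p2) + 1e-12))
  # single retained model: ensemble == that model's predictions
  ens1 <- build_family_ensemble(list(m1, fake_model(p2, 0.49)), w$st, calib, "spT")
  expect_equal(ens1$n_models_retained, 1L)
  expect_equal(unname(ens1$prob), unname(p1))
  # all models below 0.5 -> no_retained_models signal
  none <- build_family_ensemble(list(fake_model(p1, 0.49),
                                     fake_model(p2, 0.2)), w$st, calib, "spT")
  expect_s3_class(none, "no_retained_models")
})

test_that("binarize respects the threshold and is monotone", {
  w <- toy_world()
  p <- setNames(seq(0, 1, length.out = 16), w$key)
  calib <- list(presences = 13:16, absences = 1:4)
  ens <- build_family_ensemble(list(fake_model(p, 0.8)), w$st, calib, "spB")
  ens$threshold <- 0
  expect_equal(binarize(ens)$n_cells, 16L)      # threshold 0: all land
  ens$threshold <- 1.01
  expect_equal(binarize(ens)$n_cells, 0L)       # above max: none
  counts <- vapply(seq(0, 1, by = 0.1), function(t) {
    ens$threshold <- t; binarize(ens)$n_cells
  }, 0L)
  expect_true(all(diff(counts) <= 0))           # raising threshold never adds
})

test_that("consensus is a cellwise AND with validation", {
  g <- tiny_grid(3, 3)
  a <- binary_range_map(g, c(rep(TRUE, 5), rep(FALSE, 4)), "s", "current")
  b <- binary_range_map(g, c(rep(FALSE, 2), rep(TRUE, 7)), "s", "current")
  cc <- consensus(a, b)
  expect_identical(cc$suitable, a$suitable & b$suitable)
  expect_lte(cc$n_cells, min(a$n_cells, b$n_cells))
  expect_identical(consensus(a, a)$suitable, a$suitable)
  disj <- binary_range_map(g, c(rep(FALSE, 5), rep(TRUE, 4)), "s", "current")
  expect_equal(consensus(a, disj)$n_cells, 0L)
  other <- binary_range_map(tiny_grid(3, 3, land_mask = rep(c(TRUE, FALSE), length.out = 9)),
                            rep(TRUE, 9), "s", "current")
  expect_error(consensus(a, other), "different grids")
  expect_error(consensus(a, binary_range_map(g, a$suitable, "s", "RCP8.5")),
               "scenarios")
  expect_error(consensus(a, binary_range_map(g, a$suitable, "zz", "current")),
               "species")
})

test_that("ensembles of real learners project deterministically across scenarios", {
  g <- continental_grid(20, 20)
  st <- noisy_stack(g, seed = 14)
  sp <- species_at_cell(st, land_cells(g)[200], breadth = 0.7, id = "proj")
  occ <- sample_occurrences(sp, st, 150, seed = 2)
  cfg <- default_config(n_pseudo_random = 500, pa_replicates = 2,
                        split_repeats = 2)
  ens <- species_ensembles(occ, st, cfg, seed = 101)
  expect_s3_class(ens$regression, "ensemble_suitability")
  expect_s3_class(ens$machine_learning, "ensemble_suitability")
  expect_equal(sum(ens$regression$weights), 1)
  stacks <- list(current = st,
                 same = climate_stack(g, st$layers, scenario = "same"),
                 warm = apply_scenario(st, scenario_delta("RCP8.5")))
  pr <- project_all(list(proj = ens), stacks)
  maps <- pr$maps$proj
  # projecting the calibration stack reproduces calibration-time maps,
  # and an all-zero delta changes nothing
  expect_identical(maps$current$suitable,
                   consensus(binarize(ens$regression),
                             binarize(ens$machine_learning))$suitable)
  expect_identical(maps$same$suitable, maps$current$suitable)
  # consensus conservatism across every scenario
  for (sc in names(stacks)) {
    fam <- pr$family_maps$proj[[sc]]
    expect_lte(maps[[sc]]$n_cells, fam$regression$n_cells)
    expect_lte(maps[[sc]]$n_cells, fam$machine_learning$n_cells)
  }
  # rerun is bit-identical
  ens2 <- species_ensembles(occ, st, cfg, seed = 101)
  expect_equal(ens2$regression$prob, ens$regression$prob)
  expect_equal(ens2$scores$tss, ens$scores$tss)
})

test_that("project_all drops species with a failed family and reports them", {
  w <- toy_world()
  p <- setNames(seq(0, 1, length.out = 16), w$key)
  calib <- list(presences = 13:16, absences = 1:4)
  good <- build_family_ensemble(list(fake_model(p, 0.8)), w$st, calib, "ok")
  goodml <- build_family_ensemble(list(fake_model(p, 0.8, "machine_learning")),
                                  w$st, calib, "ok")
  ensembles <- list(
    ok = list(regression = good, machine_learning = goodml),
    bad = list(regression = no_retained_models("bad", "regression"),
               machine_learning = goodml))
  pr <- project_all(ensembles, list(current = w$st))
  expect_setequal(names(pr$maps), "ok")
  expect_identical(pr$dropped$species, "bad")
  expect_false("bad" %in% pr$summary$species)  # absent, not zero-filled
})

test_that("jaccard behaves at the boundaries", {
  g <- tiny_grid(3, 3)
  a <- binary_range_map(g, rep(c(TRUE, FALSE), length.out = 9), "s", "c")
  empty <- binary_range_map(g, rep(FALSE, 9), "s", "c")
  expect_equal(jaccard(a, a), 1)
  expect_equal(jaccard(a, empty), 0)
  expect_equal(jaccard(empty, empty), 1)
})
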