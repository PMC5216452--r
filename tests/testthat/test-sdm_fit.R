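test_that("pseudo_absences_random draws uniformly from land", {
  mask <- rep(c(TRUE, FALSE), 50)
  g <- tiny_grid(10, 10, land_mask = mask)
  a <- pseudo_absences_random(g, n = 5, seed = 3)
  expect_length(a, 5)
  expect_true(all(g$land_mask[a]))
  expect_identical(pseudo_absences_random(g, 5, seed = 3), a)
  # n = 5 on a 3-cell grid: sampling with replacement among those cells
  g3 <- tiny_grid(1, 3, land_mask = c(TRUE, TRUE, TRUE))
  a3 <- pseudo_absences_random(g3, 5, seed = 1)
  expect_length(a3, 5)
  expect_true(all(a3 %in% 1:3))
  g0 <- tiny_grid(2, 2, land_mask = rep(FALSE, 4))
  expect_error(pseudo_absences_random(g0, 5), "empty land mask")
  # empirical uniformity at n = 1e5 over 100 cells
  big <- pseudo_absences_random(tiny_grid(10, 10), 1e5, seed = 11)
  p <- chisq.test(tabulate(big, nbins = 100))$p.value
  expect_gt(p, 0.001)
})

test_that("exclusion pseudo-absences honour the 200-km buffer exactly", {
  g <- continental_grid(30, 30)
  occ <- occurrence_set("sp", cell_of(c(-5, -4.4), c(37, 37.5), g), 2, grid = g)
  pas <- pseudo_absences_exclusion(occ, g, radius_km = 200, replicates = 10,
                                   seed = 5)
  expect_length(pas, 10)
  pc <- cell_center(occ$cells, g)
  for (r in pas) {
    expect_length(r, length(occ$cells))
    expect_identical(anyDuplicated(r), 0L)
    ac <- cell_center(r, g)
    # brute-force distance audit: every absence > 200 km from every presence
    for (i in seq_along(r))
      expect_true(all(haversine_km(ac$lon[i], ac$lat[i], pc$lon, pc$lat) > 200))
  }
  # replicates differ but are reproducible under the same master seed
  expect_false(identical(pas[[1]], pas[[2]]))
  expect_identical(pseudo_absences_exclusion(occ, g, 200, 10, seed = 5)[[3]],
                   pas[[3]])
})

test_that("exclusion shortfall errors with species context", {
  g <- tiny_grid(5, 5)   # 10' cells: whole grid inside 200 km
  occ <- occurrence_set("cramped", 13L, 1, grid = g)
  expect_error(pseudo_absences_exclusion(occ, g, 200, 2, seed = 1), "cramped")
})

test_that("a single far cell is the only eligible absence", {
  # land = presences everywhere except one distant cell
  g <- continental_grid(20, 20)   # lon -10..0, lat 35..45 at 30'
  far <- cell_of(-0.25, 44.75, g)
  near <- cell_of(-9.75, 35.25, g)
  mask <- rep(FALSE, 400); mask[c(far, near)] <- TRUE
  g2 <- grid_definition(-10, 35, 20, 20, 30, land_mask = mask)
  occ <- occurrence_set("lonely", near, 1, grid = g2)
  pas <- pseudo_absences_exclusion(occ, g2, 200, replicates = 5, seed = 1)
  for (r in pas) expect_identical(r, far)
})

test_that("make_weights equalizes class mass", {
  w <- make_weights(100, 10000)
  expect_equal(w$absence, 0.01)
  expect_equal(make_weights(7, 7), list(presence = 1, absence = 1))
  set.seed(2)
  for (i in 1:20) {
    np <- sample(1:500, 1); na <- sample(1:20000, 1)
    w <- make_weights(np, na)
    expect_equal(np * w$presence, na * w$absence, tolerance = 1e-9)
  }
  expect_error(make_weights(0, 10), "non-empty")
})

test_that("tss matches the confusion-table formula", {
  # TP=8 FN=2 TN=7 FP=3 -> 0.8 + 0.7 - 1 = 0.5
  obs <- c(rep(1, 10), rep(0, 10))
  pred <- c(rep(0.9, 8), rep(0.1, 2), rep(0.9, 3), rep(0.1, 7))
  expect_equal(tss(pred, obs, 0.5), 0.5)
  expect_equal(tss(obs, obs, 0.5), 1)                 # perfect
  expect_equal(tss(rep(0.7, 20), obs, 0.5), 0)        # constant predictions
  expect_error(tss(pred, rep(1, 20), 0.5), "absence")
})

test_that("max_tss_threshold matches a brute-force grid scan", {
  simple <- max_tss_threshold(c(0.1, 0.9), c(0, 1))
  expect_equal(simple$threshold, 0.5)   # midpoint, TSS 1
  expect_equal(simple$tss, 1)
  set.seed(13)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    obs <- rbinom(n, 1, 0.5)
    if (length(unique(obs)) < 2) obs[1:2] <- c(0, 1)
    pred <- round(runif(n), 3)          # on the 1e-4 grid so scans agree
    got <- max_tss_threshold(pred, obs)
    want <- brute_force_max_tss(pred, obs)
    expect_equal(got$tss, want$tss, tolerance = 1e-9)
    expect_equal(tss(pred, obs, got$threshold), got$tss, tolerance = 1e-9)
  }
})

test_that("max_tss ties resolve to the lowest optimal threshold", {
  # two disjoint optimal bands: (0.2, 0.4] and nothing better later
  pred <- c(0.1, 0.3, 0.5, 0.9)
  obs <- c(0, 1, 0, 1)     # thresholds in (0.1,0.3] and (0.5,0.9] both give 0.5
  got <- max_tss_threshold(pred, obs)
  expect_equal(got$threshold, 0.2)   # lowest midpoint wins
})

test_that("TSS is invariant under monotone transforms with re-optimized threshold", {
  set.seed(21)
  obs <- rbinom(80, 1, 0.5); obs[1:2] <- c(0, 1)
  pred <- runif(80)
  base <- max_tss_threshold(pred, obs)$tss
  for (f in list(function(x) x^3, function(x) plogis(5 * x - 2),
                 function(x) sqrt(x))) {
    expect_equal(max_tss_threshold(f(pred), obs)$tss, base, tolerance = 1e-9)
  }
})

test_that("all four learners separate an easy one-predictor signal", {
  g <- continental_grid(20, 20)
  st <- noisy_stack(g, seed = 4)
  land <- land_cells(g)
  tmax <- st$layers$tmax_warmest
  pres <- land[order(tmax[land], decreasing = TRUE)[1:60]]
  abs_ <- land[order(tmax[land])[1:60]]
  tr <- training_set(pres, abs_, st)
  for (alg in c("GLM", "GAM", "BRT", "RF")) {
    m <- fit_sdm(alg, tr, seed = 9)
    p <- predict(m, tr$X)
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(mean(p[tr$y == 1]), mean(p[tr$y == 0]) + 0.3)
    # refit with same seed reproduces predictions exactly
    p2 <- predict(fit_sdm(alg, tr, seed = 9), tr$X)
    expect_identical(p, p2)
  }
})

test_that("constant predictors give prevalence-level predictions", {
  g <- tiny_grid(8, 8)
  st <- toy_stack(g)
  flat <- climate_stack(g, lapply(st$layers, function(v) rep(1, length(v))))
  tr <- training_set(land_cells(g)[1:20], land_cells(g)[21:60], flat)
  # weighted prevalence is 0.5 by construction of the case weights
  for (alg in c("GLM", "BRT", "RF")) {
    p <- predict(fit_sdm(alg, tr), tr$X)
    expect_equal(mean(p), 0.5, tolerance = 0.1)
  }
  tr1 <- tr; tr1$y <- rep(1, length(tr1$y))
  expect_error(fit_sdm("GLM", tr1), "one class")
})

test_that("split_sample_evaluate returns the protocol's model counts", {
  g <- continental_grid(20, 20)
  st <- noisy_stack(g, seed = 6)
  land <- land_cells(g)
  set.seed(31)
  pres <- sample(land, 50); abs_ <- sample(setdiff(land, pres), 50)
  tr <- training_set(pres, abs_, st, family = "machine_learning")
  ms <- split_sample_evaluate("RF", tr, repeats = 3, seed = 17)
  expect_length(ms, 3)
  expect_identical(vapply(ms, `[[`, 0L, "split_replicate"), 1:3)
  for (m in ms) {
    expect_true(m$tss_eval >= -1 && m$tss_eval <= 1)
    expect_true(m$threshold_eval >= 0 && m$threshold_eval <= 1)
  }
  ms2 <- split_sample_evaluate("RF", tr, repeats = 3, seed = 17)
  expect_equal(vapply(ms2, `[[`, 0, "tss_eval"),
               vapply(ms, `[[`, 0, "tss_eval"))
})
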