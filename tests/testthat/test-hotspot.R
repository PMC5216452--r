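mk_richness <- function(g, counts, scenario = "current") {
  structure(list(grid = g, scenario = scenario, counts = as.integer(counts),
                 n_species = max(counts)),
            class = "richness_map")
}

test_that("stack_richness sums booleans and conserves totals", {
  g <- tiny_grid(4, 4)
  maps <- lapply(1:5, function(i) {
    suit <- rep(FALSE, 16); suit[seq_len(3 * i)] <- TRUE
    binary_range_map(g, suit, paste0("sp", i), "current")
  })
  r <- stack_richness(maps, "current")
  expect_true(all(r$counts >= 0 & r$counts <= 5))
  expect_equal(sum(r$counts), sum(vapply(maps, `[[`, 0L, "n_cells")))
  one <- stack_richness(maps[1], "current")
  expect_true(all(one$counts %in% 0:1))
  # k identical maps give richness k on suitable cells
  same <- stack_richness(maps[c(2, 2, 2)], "current")
  expect_setequal(unique(same$counts), c(0L, 3L))
  expect_error(stack_richness(c(maps[1], list(binary_range_map(
    g, rep(TRUE, 16), "x", "RCP8.5"))), "current"), "scenario")
  # adding a species never decreases richness anywhere
  r6 <- stack_richness(c(maps, maps[3]), "current")
  expect_true(all(r6$counts >= r$counts))
})

test_that("delineate_hotspots implements the nearest-rank 10% rule", {
  g <- tiny_grid(10, 10)
  set.seed(19)
  counts <- sample(1:100)
  h <- delineate_hotspots(mk_richness(g, counts), fraction = 0.10)
  expect_equal(h$cutoff, 91)          # 100 distinct values -> cutoff 91
  expect_equal(h$n_flagged, 10L)
  expect_identical(which(h$flagged), which(counts >= 91))
  expect_error(delineate_hotspots(mk_richness(tiny_grid(3, 3), 1:9)),
               "at least 10")
})

test_that("hotspot ties are included and degenerate maps are logged", {
  g <- tiny_grid(10, 10)
  # 15 cells tied at the top value 7: nearest-rank cutoff is 7, ties all in
  counts <- c(rep(7, 15), rep(3, 85))
  expect_message(h <- delineate_hotspots(mk_richness(g, counts)), "share")
  expect_equal(h$cutoff, 7)
  expect_equal(h$n_flagged, 15L)                 # exceeds 10% by tie mass only
  expect_false(h$degenerate)
  # constant richness: degenerate, cutoff = the single value, all flagged
  expect_message(hd <- delineate_hotspots(mk_richness(g, rep(4, 100))),
                 "degenerate")
  expect_true(hd$degenerate)
  expect_equal(hd$cutoff, 4)
  expect_equal(hd$n_flagged, 100L)
})

test_that("percentile rule respects the mask and flagged-share bound", {
  mask <- c(rep(TRUE, 60), rep(FALSE, 40))
  g <- tiny_grid(10, 10, land_mask = mask)
  set.seed(23)
  counts <- integer(100); counts[mask] <- sample(1:60)
  h <- delineate_hotspots(mk_richness(g, counts), 0.10)
  expect_equal(h$n_flagged, 6L)               # ceil(0.1 * 60)
  expect_true(all(mask[which(h$flagged)]))
})

test_that("fixed_cutoff_hotspots measures relative area change", {
  g <- tiny_grid(10, 10)
  cur <- delineate_hotspots(mk_richness(g, sample(1:100)))
  same <- fixed_cutoff_hotspots(mk_richness(g, sort(sample(1:100)), "RCP4.5"), cur)
  # identical multiset of richness values -> same flagged count, 0% change
  expect_equal(same$area_change_pct, 0)
  plus <- fixed_cutoff_hotspots(
    mk_richness(g, mk_richness(g, 1:100)$counts + 1L, "RCP4.5"),
    delineate_hotspots(mk_richness(g, 1:100)))
  expect_gte(plus$area_change_pct, 0)         # +1 everywhere never shrinks
  expect_equal(plus$n_flagged, 11L)           # cells >= 91 among 2..101
  expect_equal(plus$area_change_pct, 10)
  # km2-weighted option uses latitude-corrected areas
  plus_km <- fixed_cutoff_hotspots(
    mk_richness(g, mk_richness(g, 1:100)$counts + 1L, "RCP4.5"),
    delineate_hotspots(mk_richness(g, 1:100)), use_area_km2 = TRUE)
  expect_false(identical(plus_km$area_change_pct, plus$area_change_pct))
  empty_cur <- delineate_hotspots(mk_richness(g, sample(1:100)))
  empty_cur$flagged[] <- FALSE
  expect_error(fixed_cutoff_hotspots(mk_richness(g, 1:100, "RCP4.5"),
                                     empty_cur), "zero")
})

test_that("available_area aggregates subcell proportions exactly", {
  g <- tiny_grid(2, 2)
  f <- 2
  # uniform class 1 everywhere with proportion 0.3 -> 0.3 in every cell
  lc <- list(classes = matrix(1L, 4, 4), subcells_per_side = f)
  aa <- available_area(lc, c("1" = 0.3), g)
  expect_equal(aa$values, rep(0.3, 4))
  # half subcells at 0.4, half at 0.0 -> 0.2
  cls <- matrix(1L, 4, 4); cls[, 3:4] <- 2L
  lc2 <- list(classes = cls, subcells_per_side = f)
  aa2 <- available_area(lc2, c("1" = 0.4, "2" = 0.0), g)
  expect_equal(aa2$values[c(1, 2)], c(0.4, 0.4))   # col-1 cells pure class 1
  expect_equal(aa2$values[c(3, 4)], c(0.0, 0.0))
  # alternating rows: every analysis cell is half class 1, half class 2
  lc3 <- list(classes = matrix(rep(c(1L, 2L), 2), 4, 4),
              subcells_per_side = 2)
  aa3 <- available_area(lc3, c("1" = 0.4, "2" = 0.0), g)
  expect_equal(aa3$values, rep(0.2, 4))
  # bounded by scheme extremes, unmapped class errors by name
  expect_true(all(aa2$values >= 0 & aa2$values <= 0.4))
  expect_error(available_area(lc2, c("1" = 0.4), g), "class\\(es\\): 2")
  expect_error(available_area(lc2, c("1" = 1.4, "2" = 0), g), "\\[0, 1\\]")
})

test_that("risk_map multiplies, flags by percentile, and is scale-invariant", {
  g <- tiny_grid(10, 10)
  set.seed(29)
  rich <- mk_richness(g, sample(1:100))
  ones <- structure(list(grid = g, values = rep(1, 100)),
                    class = "available_area_map")
  rm1 <- risk_map(rich, ones, scheme_id = "s1")
  hs <- delineate_hotspots(rich)
  # identity weighting: high-risk set equals the climatic hotspot set
  expect_identical(which(rm1$high_risk), which(hs$flagged))
  expect_equal(rm1$values, as.numeric(rich$counts))
  # richness = 0 or area = 0 forces risk 0
  zeros <- structure(list(grid = g, values = rep(0, 100)),
                     class = "available_area_map")
  expect_message(rm0 <- risk_map(rich, zeros), "degenerate")
  expect_true(all(rm0$values == 0))
  # doubling richness leaves the flagged set unchanged
  rich2 <- mk_richness(g, rich$counts * 2L)
  set.seed(31)
  aa <- structure(list(grid = g, values = runif(100)),
                  class = "available_area_map")
  expect_identical(which(risk_map(rich2, aa)$high_risk),
                   which(risk_map(rich, aa)$high_risk))
})

test_that("consensus_risk is an exhaustive 2-of-3 majority vote", {
  g <- tiny_grid(4, 4)
  rich <- mk_richness(g, rep(1, 16))
  mk_risk <- function(flags) {
    structure(list(grid = g, scenario = "current", scheme_id = "s",
                   values = as.numeric(flags), high_risk = flags,
                   cutoff = 0.5, n_flagged = sum(flags), degenerate = FALSE),
              class = "risk_map")
  }
  # all 8 vote patterns on 8 cells: cell i flagged by the schemes whose bit is set
  votes <- expand.grid(a = c(FALSE, TRUE), b = c(FALSE, TRUE),
                       c = c(FALSE, TRUE))
  pad <- function(v) c(v, rep(FALSE, 8))
  maps <- list(mk_risk(pad(votes$a)), mk_risk(pad(votes$b)),
               mk_risk(pad(votes$c)))
  cons <- consensus_risk(maps)
  expect_identical(cons$high_risk[1:8],
                   rowSums(votes) >= 2)        # 0/1 flags -> not; 2/3 -> flag
  expect_equal(cons$values, Reduce(`+`, lapply(maps, `[[`, "values")) / 3)
  # all agree -> identical consensus flags
  same <- consensus_risk(list(maps[[1]], maps[[1]], maps[[1]]))
  expect_identical(same$high_risk, maps[[1]]$high_risk)
  expect_error(consensus_risk(maps[1:2]), "exactly 3")
  # consensus set between intersection and union of scheme sets
  inter <- maps[[1]]$high_risk & maps[[2]]$high_risk & maps[[3]]$high_risk
  un <- maps[[1]]$high_risk | maps[[2]]$high_risk | maps[[3]]$high_risk
  expect_true(all(!inter | cons$high_risk))
  expect_true(all(!cons$high_risk | un))
})
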