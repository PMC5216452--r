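# Shared fixtures, built in code. Small grids keep the suite fast; the
# continental-extent grid is for anything involving the 200-km buffer.

tiny_grid <- function(n_rows = 10, n_cols = 10, cell_size = 10,
                      min_lon = 0, min_lat = 45, land_mask = NULL) {
  grid_definition(min_lon, min_lat, n_rows, n_cols, cell_size,
                  land_mask = land_mask)
}

continental_grid <- function(n_rows = 40, n_cols = 40) {
  grid_definition(-10, 35, n_rows, n_cols, cell_size = 30)
}

# deterministic toy stack: gradients only, no noise
toy_stack <- function(grid, seed = 1) {
  make_climate_stack(grid, seed = seed, noise_sd = 0)
}

noisy_stack <- function(grid, seed = 1) {
  make_climate_stack(grid, seed = seed, noise_sd = 0.35)
}

# a species anchored at a given land cell's climate
species_at_cell <- function(stack, cell, breadth = 0.6, tau = 0.5,
                            id = "spX") {
  mu <- vapply(stack$layers, function(v) v[cell], 0)
  sds <- vapply(stack$layers, function(v) stats::sd(v[land_cells(stack$grid)]), 0)
  synthetic_species(id, mu, sds * breadth, tau = tau)
}

# brute-force TSS threshold scan on a fixed grid (independent oracle)
brute_force_max_tss <- function(predicted, observed, step = 1e-4) {
  cand <- seq(0, 1, by = step)
  scores <- vapply(cand, function(t) tss(predicted, observed, t), 0)
  best <- max(scores)
  list(threshold = cand[which(scores >= best - 1e-12)[1]], tss = best)
}

expect_same_cells <- function(a, b) expect_identical(which(a), which(b))
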