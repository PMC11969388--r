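# Shared fixtures and independent oracles used across test files.

# A deliberately small scenario for fast end-to-end exercises.
tiny_scenario <- function(...) {
  sim_scenario(n_colonies_per_treatment = 1, baseline_duration = 10,
               seed = 11, ...)
}

# An event-only scenario at study-size design (no baseline cost).
event_scenario <- function(...) {
  sim_scenario(baseline_duration = 1, ...)
}

# Independent Spearman oracle: Pearson product-moment formula applied to
# average ranks, written from the definition (no calls into the package).
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  mx <- mean(rx)
  my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Independent Benjamini-Hochberg step-up oracle written from the
# definition: sort ascending, q_(i) = min_{j >= i} min(1, p_(j) * m / j),
# return in input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, p[o] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Centre of occupancy-grid cell (i, j) on the default 25 x 25 / 2 mm grid.
cell_centre <- function(i, j, arena_diameter = 50, bins = 25) {
  bin <- arena_diameter / bins
  c(x = -arena_diameter / 2 + (i - 0.5) * bin,
    y = -arena_diameter / 2 + (j - 0.5) * bin)
}

# Build a trajectory tibble for one ant from coordinate vectors.
make_traj <- function(x, y, frame = seq_along(x) - 1L, ant = "A1",
                      colony = "C1") {
  tibble::tibble(colony_id = colony, ant_id = ant, frame = as.integer(frame),
                 x = x, y = y)
}
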