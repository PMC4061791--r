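# shared helpers for the test suite

# simulate one session and return it as a behavior table (the layout a
# human participant's data file would have)
simulate_behavior <- function(structure, params, seq_seed, session_seed,
                              n_trials = 320, block_size = 80, ...) {
  sq <- generate_sequence(structure, n_trials, block_size, seed = seq_seed)
  res <- run_session(params, sq, seed = session_seed, ...)
  beh <- sq
  beh$response <- res$trace$response
  beh$correct <- res$trace$correct
  attr(beh, "session") <- res
  beh
}

# standard normal density, hand-coded so CDF oracles do not lean on the
# same machinery they are testing
std_normal_density <- function(t) exp(-t^2 / 2) / sqrt(2 * pi)

# cumulative normal CDF on a uniform grid by Simpson integration of the
# hand-coded density, starting far enough left that the truncated tail
# mass is negligible at the tested tolerance
simpson_normal_cdf <- function(z_grid, lower = -20, step = 0.0025) {
  grid <- seq(lower, max(z_grid), by = step)
  f <- std_normal_density(grid)
  n <- length(grid)
  # composite Simpson over consecutive pairs of intervals
  pair_mass <- (f[seq(1, n - 2, by = 2)] + 4 * f[seq(2, n - 1, by = 2)] +
                  f[seq(3, n, by = 2)]) * step / 3
  cdf_at <- c(0, cumsum(pair_mass))          # CDF at grid[1], grid[3], ...
  nodes <- grid[seq(1, n, by = 2)]
  stats::approx(nodes, cdf_at, xout = z_grid)$y
}
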