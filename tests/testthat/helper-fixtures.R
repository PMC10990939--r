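# Shared fixtures for the test suite. Problem sizes are reduced relative to
# the package defaults (24 x 120 cells instead of 40 x 200) where the test
# exercises machinery rather than discretization accuracy; accuracy-critical
# oracle tests use the default grid.

coarse_settings <- function() solver_settings(nx = 24L, ny = 120L)

test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = test_cache)) {
    assign(name, force(expr), envir = test_cache)
  }
  get(name, envir = test_cache)
}

# small transfer table for gly/tmp network tests at delta_T = 10 K
gly_tmp_table <- function() cached("gly_tmp_table", {
  build_transfer_table(
    axes = list(delta_T = 10,
                D = c(8e-10, 1.4e-9),
                S_T = c(1.4e-3, 1.7e-3, 2e-3, 6e-3, 7e-3, 8e-3),
                Q_in = c(0.01, 0.05, 0.1, 0.5, 1, 5, 10) * 1e-12,
                Q_out_bot = c(0.01, 0.05, 0.1, 0.2, 0.5, 1)),
    settings = coarse_settings())
})

# identity table (delta_T = 0)
identity_table <- function() cached("identity_table", {
  build_transfer_table(
    axes = list(delta_T = 0,
                D = c(8e-10, 1.4e-9),
                S_T = c(1.4e-3, 7e-3),
                Q_in = c(0.01, 1, 10) * 1e-12,
                Q_out_bot = c(0.01, 0.5, 1)),
    settings = coarse_settings())
})

# reaction grid at reference rates (full concentration range, coarse decade
# resolution is enough for interpolation tests; coupling tests use the
# default 5-per-decade grid in the acceptance suite)
reaction_grid_fixture <- function() cached("reaction_grid", {
  build_reaction_grid(reference_rate_constants(),
                      conc_axis = 10^seq(-10, 0, by = 0.5), n_times = 10L)
})

# fake chamber-states object for statistic tests
fake_states <- function(ratios, B_value = 1) {
  n <- length(ratios)
  df <- rbind(
    data.frame(m = seq_len(n), n = 1L, species = "A", c_in = 1,
               c_bot = ratios * B_value, c_out_top = 1, c_out_bot = 1),
    data.frame(m = seq_len(n), n = 1L, species = "B", c_in = 1,
               c_bot = B_value, c_out_top = 1, c_out_bot = 1))
  class(df) <- c("chamber_states", class(df))
  df
}
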