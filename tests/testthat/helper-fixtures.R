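# Shared fixtures built in code.

jak2_radii <- c(2.5, 3.0, 3.5, 4.0, 4.5, 5.0, 5.5, 6.0, 6.5, 7.0, 7.5, 8.0,
                8.5, 9.0, 9.5, 10.0, 11.0, 12.0, 13.0, 14.0, 15.0, 16.0)

# Three-milestone, three-cell model with hand-traced statistics; the expected
# values below were frozen from an independent arithmetic walk-through of the
# estimator equations (flux balance, weighted counts, direct solves).
three_milestone_fixture <- function() {
  model <- build_radial_model(c(1, 2, 3))
  traces <- list(
    event_trace(0L, c(0.5, 1.5), c(0L, 0L), 2.0),
    event_trace(1L, c(0.2, 0.7, 1.2, 1.7), c(0L, 1L, 0L, 1L), 2.0),
    event_trace(2L, c(0.3, 0.8, 1.3), c(1L, 2L, 1L), 2.0))
  stats <- lapply(traces, collect_cell_statistics, model = model)
  list(
    model = model, traces = traces, stats = stats,
    pi = c(0.30, 0.36, 0.34),
    T_weight = 5 / 3,
    N = rbind(c(0, 2 / 3, 0), c(1 / 3, 0, 1 / 3), c(0, 1 / 3, 0)),
    R = c(5 / 6, 2 / 3, 1 / 6),
    Q = rbind(c(-0.8, 0.8, 0), c(0.5, -1, 0.5), c(0, 2, -2)),
    mfpt = c(4.5, 3.25, 0),
    p = c(1 / 3, 8 / 15, 2 / 15),
    dG = c(0, -log(8 / 5), -log(2 / 5)))
}

# Random strictly increasing milestone list for property-style tests.
random_milestones <- function(n, rng_max = 20) {
  sort(runif(n, 0.1, rng_max)) + cumsum(rep(1e-3, n))
}

# Minimal kinetics_result stand-ins for aggregation tests.
fake_kinetics <- function(model, residence, mfpt = NULL, dG = NULL) {
  M <- model$n_milestones
  structure(list(
    pi = rep(1 / model$n_cells, model$n_cells),
    mfpt = mfpt %||% c(rep(residence, M - 1), 0),
    residence_time = residence,
    p = rep(1 / M, M),
    dG = dG %||% numeric(M),
    ts_milestones = integer(0),
    model = model), class = "kinetics_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One confined-BD statistics set for a whole model (serial helper used by
# several suites).
sample_model_statistics <- function(model, potential, n_steps, dt, seed,
                                    D = 1) {
  lapply(seq_len(model$n_cells) - 1L, function(cell) {
    b <- cell_bounds(model, cell)
    tr <- simulate_confined_bd(model, potential, cell, mean(b), n_steps, dt,
                               D, seed = derive_seed(seed, 1L, cell))
    collect_cell_statistics(tr, model)
  })
}
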