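test_that("cell equilibrium solves the flux balance", {
  m <- build_radial_model(c(1, 2))
  # collision rates k_{0->1} = 2/10 = 0.2 and k_{1->0} = 1/10 = 0.1 across
  # the shared milestone 0
  s0 <- zero_statistics(m, 0L); s0$N_boundary <- c(2, 0); s0$R <- c(10, 0); s0$T <- 10
  s1 <- zero_statistics(m, 1L); s1$N_boundary <- c(1, 0); s1$R <- c(5, 5); s1$T <- 10
  expect_equal(solve_cell_equilibrium(list(s0, s1), m), c(1, 2) / 3,
               tolerance = 1e-14)

  # identical symmetric statistics in every cell give uniform weights
  m3 <- build_radial_model(1:4)
  stats <- lapply(0:3, function(cell) {
    s <- zero_statistics(m3, cell)
    s$N_boundary[cell_milestones(m3, cell) + 1L] <- 50
    s$R[cell_milestones(m3, cell) + 1L] <- 10 / length(cell_milestones(m3, cell))
    s$T <- 10
    s
  })
  expect_equal(solve_cell_equilibrium(stats, m3), rep(0.25, 4),
               tolerance = 1e-12)

  # a zero-collision boundary disconnects the graph
  stats[[3]]$N_boundary[3] <- 0   # milestone 2 between cells 2 and 3
  stats[[4]]$N_boundary[3] <- 0
  expect_error(solve_cell_equilibrium(stats, m3), "disconnected",
               class = "milekin_numerical_error")

  stats[[2]]$T <- 0
  expect_error(solve_cell_equilibrium(stats, m3), "zero attributable")
})

test_that("combined counts reduce, symmetrize and scale correctly", {
  m1 <- build_radial_model(c(1, 2))
  tr <- simulate_confined_bd(m1, potential_flat(), 1, 1.5, 5e4, 1e-3, seed = 2)
  s <- collect_cell_statistics(tr, m1)
  s0 <- collect_cell_statistics(
    simulate_confined_bd(m1, potential_flat(), 0, 0.5, 5e4, 1e-3, seed = 1), m1)
  # single-cell degenerate case: with all equilibrium weight on one cell the
  # combined counts reduce to that cell's raw statistics
  cc <- combine_counts(list(s0, s), pi = c(0, 1), model = m1)
  expect_equal(cc$N, s$N)
  expect_equal(cc$R, s$R)
  expect_equal(cc$T, s$T)

  m <- build_radial_model(1:3)
  stats <- sample_model_statistics(m, potential_flat(), 5e4, 1e-3, seed = 3)
  pi <- solve_cell_equilibrium(stats, m)
  cc1 <- combine_counts(stats, pi, m)
  rm1 <- build_rate_matrix(cc1, m$absorbing_milestone)
  # scaling every time by 2 (counts fixed) halves every rate
  stats2 <- lapply(stats, function(s) {
    s$R <- 2 * s$R; s$T <- 2 * s$T; s$excluded_time <- 2 * s$excluded_time; s
  })
  cc2 <- combine_counts(stats2, solve_cell_equilibrium(stats2, m), m)
  rm2 <- build_rate_matrix(cc2, m$absorbing_milestone)
  expect_equal(rm2$Q, rm1$Q / 2, tolerance = 1e-12)
})

test_that("rate matrix construction follows N/R with zero row sums", {
  counts <- list(N = rbind(c(0, 5), c(3, 0)), R = c(10, 6))
  rm_ <- build_rate_matrix(counts, absorbing = 1L)
  expect_equal(rm_$Q, rbind(c(-0.5, 0.5), c(0.5, -0.5)), tolerance = 1e-15)
  expect_equal(rm_$Q_hat, matrix(-0.5, 1, 1))
  expect_error(build_rate_matrix(list(N = rbind(c(0, 0), c(2, 0)),
                                      R = c(10, 0)), 1L),
               "zero occupation", class = "milekin_numerical_error")
  expect_error(build_rate_matrix(list(N = matrix(0, 3, 3), R = c(1, 0, 1)), 2L),
               "no recorded collisions")
  # property: random tridiagonal counts always give zero row sums
  set.seed(6)
  for (rep in 1:5) {
    M <- sample(3:8, 1)
    N <- matrix(0, M, M)
    for (i in 1:(M - 1)) { N[i, i + 1] <- runif(1, 1, 50); N[i + 1, i] <- runif(1, 1, 50) }
    rm_ <- build_rate_matrix(list(N = N, R = runif(M, 1, 20)), M - 1L)
    expect_lt(max(abs(rowSums(rm_$Q))), 1e-12)
    expect_true(all(rm_$Q[!diag(M)] >= 0))
  }
})

test_that("MFPT solves Q_hat T = -1 and matches the birth-death closed form", {
  rm_ <- build_rate_matrix(list(N = rbind(c(0, 5), c(3, 0)), R = c(10, 6)), 1L)
  sol <- mfpt(rm_)
  expect_equal(sol$mfpt, c(2, 0))
  expect_equal(sol$residence_time, 2)
  # linearity: doubling Q halves the MFPT
  rm2 <- build_rate_matrix(list(N = rbind(c(0, 10), c(6, 0)), R = c(10, 6)), 1L)
  expect_equal(mfpt(rm2)$mfpt, sol$mfpt / 2)

  set.seed(7)
  for (rep in 1:5) {
    M <- 5
    N <- matrix(0, M, M)
    for (i in 1:(M - 1)) { N[i, i + 1] <- runif(1, 1, 50); N[i + 1, i] <- runif(1, 1, 50) }
    rm_ <- build_rate_matrix(list(N = N, R = runif(M, 0.5, 10)), M - 1L)
    direct <- mfpt(rm_)$mfpt
    oracle <- birth_death_mfpt(rm_$Q)
    expect_equal(direct, oracle, tolerance = 1e-9)
    # monotone: passage times cannot increase towards the absorbing end
    expect_true(all(diff(direct) <= 1e-9))
  }

  # disconnection from the absorbing milestone is reported, not inverted
  Nd <- matrix(0, 3, 3); Nd[1, 2] <- 2; Nd[2, 1] <- 2; Nd[3, 2] <- 1
  rm_d <- build_rate_matrix(list(N = Nd, R = c(1, 1, 1)), 2L)
  expect_error(mfpt(rm_d), "singular", class = "milekin_numerical_error")
})

test_that("birth-death oracle itself is right on a 2-state chain", {
  Q <- rbind(c(-0.5, 0.5), c(0.5, -0.5))
  expect_equal(birth_death_mfpt(Q), c(2, 0))
})

test_that("stationary probabilities solve the left eigenproblem", {
  rm_ <- build_rate_matrix(list(N = rbind(c(0, 5), c(3, 0)), R = c(10, 6)), 1L)
  # symmetric rates: Q is the symmetric 2-state generator
  rms <- build_rate_matrix(list(N = rbind(c(0, 3), c(3, 0)), R = c(6, 6)), 1L)
  expect_equal(stationary_probabilities(rms), c(0.5, 0.5), tolerance = 1e-12)

  # stationarity: p Q = 0 for a generic 3-state matrix
  N3 <- rbind(c(0, 4, 1), c(2, 0, 6), c(3, 5, 0))
  rm3 <- build_rate_matrix(list(N = N3, R = c(3, 4, 5)), 2L)
  p <- stationary_probabilities(rm3)
  expect_lt(max(abs(drop(p %*% rm3$Q))), 1e-12)
  expect_equal(sum(p), 1)

  # relabeling equivariance
  perm <- c(2L, 3L, 1L)
  rm_p <- build_rate_matrix(list(N = N3[perm, perm], R = c(3, 4, 5)[perm]), 2L)
  expect_equal(stationary_probabilities(rm_p), p[perm], tolerance = 1e-10)

  # known generator: statistics harvested from a Gillespie run recover p
  Q_true <- rbind(c(-0.8, 0.8, 0), c(0.5, -1, 0.5), c(0, 2, -2))
  traj <- simulate_ctmc(Q_true, 4e4, seed = 12)
  rm_hat <- build_rate_matrix(counts_from_ctmc(traj, 3), 2L)
  p_hat <- stationary_probabilities(rm_hat)
  p_true <- c(1, 8 / 5, 2 / 5); p_true <- p_true / sum(p_true)
  expect_equal(p_hat, p_true, tolerance = 0.05)

  # reducible matrix is refused
  rm_r <- list(Q = rbind(c(-1, 1, 0), c(1, -1, 0), c(0, 0, 0)),
               Q_hat = NULL, absorbing = 2L)
  class(rm_r) <- "rate_matrix_result"
  expect_error(stationary_probabilities(rm_r), "reducible")
})

test_that("free energy profile and transition-state detection", {
  expect_equal(free_energy_profile(c(0.2, 0.2, 0.6))$dG[2], 0)
  expect_equal(free_energy_profile(c(0.5, 0.5 * exp(-1)))$dG[2], 1)
  expect_equal(free_energy_profile(c(0.5, 0.5 * exp(-1)),
                                   thermal_energy = 0.596)$dG[2], 0.596)
  p <- exp(-c(0, 1.0, 0.5, 2.0, 1.2)); p <- p / sum(p)
  prof <- free_energy_profile(p)
  expect_equal(prof$dG, c(0, 1.0, 0.5, 2.0, 1.2), tolerance = 1e-12)
  expect_equal(prof$ts_milestones, c(1L, 3L))
  # plateaus resolve to their first index
  plat <- exp(-c(0, 1, 1, 0)); plat <- plat / sum(plat)
  expect_equal(free_energy_profile(plat)$ts_milestones, 1L)
  rising <- exp(-c(0, 1, 1, 2)); rising <- rising / sum(rising)
  expect_equal(free_energy_profile(rising)$ts_milestones, integer(0))
  # zero probability: +Inf with a warning, excluded from the search
  expect_warning(prof0 <- free_energy_profile(c(0.3, 0, 0.35, 0.05, 0.3)),
                 "Inf")
  expect_equal(prof0$dG[2], Inf)
  expect_equal(prof0$ts_milestones, 3L)
  expect_error(free_energy_profile(c(0, 1)), "reference")
})

test_that("the full estimator reproduces the frozen three-milestone fixture", {
  fx <- three_milestone_fixture()
  kin <- compute_kinetics(fx$model, fx$stats)
  expect_equal(kin$pi, fx$pi, tolerance = 1e-12)
  expect_equal(kin$counts$T, fx$T_weight, tolerance = 1e-12)
  expect_equal(kin$counts$N, fx$N, tolerance = 1e-12)
  expect_equal(kin$counts$R, fx$R, tolerance = 1e-12)
  expect_equal(kin$rate_matrix$Q, fx$Q, tolerance = 1e-12)
  expect_equal(kin$mfpt, fx$mfpt, tolerance = 1e-12)
  expect_equal(kin$residence_time, 4.5, tolerance = 1e-12)
  expect_equal(kin$p, fx$p, tolerance = 1e-12)
  expect_equal(kin$dG, fx$dG, tolerance = 1e-12)
})

test_that("estimator output is invariant to splitting sampling into segments", {
  fx <- three_milestone_fixture()
  model <- fx$model
  # replace cell 1's trace with one containing a same-milestone re-touch so
  # a seam there has exactly zero boundary effect
  tr <- event_trace(1L, c(0.1, 0.4, 0.9, 1.5), c(0L, 1L, 1L, 0L), 2.0)
  stats_full <- fx$stats
  stats_full[[2]] <- collect_cell_statistics(tr, model)
  seg_a <- event_trace(1L, c(0.1, 0.4), c(0L, 1L), 0.9)
  seg_b <- event_trace(1L, c(0, 0.6), c(1L, 0L), 1.1)
  stats_split <- stats_full
  stats_split[[2]] <- merge_statistics(
    list(collect_cell_statistics(seg_a, model),
         collect_cell_statistics(seg_b, model)))
  kin_full <- compute_kinetics(model, stats_full)
  kin_split <- compute_kinetics(model, stats_split)
  expect_equal(kin_split$rate_matrix$Q, kin_full$rate_matrix$Q,
               tolerance = 1e-14)
  expect_equal(kin_split$mfpt, kin_full$mfpt, tolerance = 1e-14)
  expect_equal(kin_split$p, kin_full$p, tolerance = 1e-14)
  expect_equal(kin_split$pi, kin_full$pi, tolerance = 1e-14)
})

test_that("replica aggregation reports mean and SEM per quantity", {
  model <- build_radial_model(1:3)
  r1 <- fake_kinetics(model, 2.0)
  r2 <- fake_kinetics(model, 4.0)
  agg <- replica_aggregate(list(r1, r2))
  expect_equal(agg$residence_mean, 3.0)
  expect_equal(agg$residence_sem, 1.0)
  expect_equal(agg$mfpt_mean, c(3, 3, 0))
  expect_equal(agg$mfpt_sem, c(1, 1, 0))

  # identical replicas collapse to zero SEM
  agg_id <- replica_aggregate(list(r1, r1, r1))
  expect_equal(agg_id$residence_mean, 2.0)
  expect_equal(agg_id$residence_sem, 0)

  # permutation invariance
  r3 <- fake_kinetics(model, 9.0)
  a <- replica_aggregate(list(r1, r2, r3))
  b <- replica_aggregate(list(r3, r1, r2))
  expect_equal(a$residence_mean, b$residence_mean)
  expect_equal(a$residence_sem, b$residence_sem)
  expect_equal(a$dG_mean, b$dG_mean)

  other <- fake_kinetics(build_radial_model(1:4), 2.0)
  expect_error(replica_aggregate(list(r1, other)), "different")
  expect_error(replica_aggregate(list(r1)), ">= 2")
})

test_that("estimated stationary p matches the exact continuous-time values", {
  # commitor-quadrature oracle on the flat 10-cell model: the edge milestones
  # carry 1.5x / 0.5x the interior weight
  m <- build_radial_model(1:10)
  p_exact <- exact_last_touched_p(potential_flat(), m$milestones)
  expect_equal(p_exact[1], 0.15, tolerance = 1e-6)
  expect_equal(p_exact[5], 0.10, tolerance = 1e-6)
  expect_equal(p_exact[10], 0.05, tolerance = 1e-6)
  stats <- sample_model_statistics(m, potential_flat(), 1e6, 2e-3, seed = 21)
  kin <- compute_kinetics(m, stats)
  expect_equal(kin$p, p_exact, tolerance = 0.05)
})
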