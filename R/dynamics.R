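#' Derive a per-cell random seed from a master seed
#'
#' One master seed per run; per-replica, per-cell streams are derived with a
#' fixed affine counter scheme modulo 2^31 - 1 so cells are independent and
#' every run is reproducible from the master seed alone.
#'
#' @param master_seed integer master seed.
#' @param replica replica counter (1-based).
#' @param cell 0-based cell index, or a reserved stream id (the steered
#'   seeding routine uses `cell = 10007L`).
#' @return a positive integer seed below 2^31.
#' @export
derive_seed <- function(master_seed, replica = 1L, cell = 0L) {
  m <- 2147483647
  s <- (as.numeric(master_seed) %% m) * 48271 +
    as.numeric(replica) * 104729 + as.numeric(cell) * 15485863
  as.integer(s %% m) + 1L
}

#' Construct an event trace
#'
#' A per-cell stream of milestone collision events: ordered `(time,
#' milestone)` pairs plus the total simulated time. [simulate_confined_bd()]
#' produces these; use this constructor to feed externally generated event
#' streams (e.g. parsed MD output) into [collect_cell_statistics()].
#'
#' @param cell 0-based cell index.
#' @param times nondecreasing event times in `[0, total_time]`.
#' @param milestones 0-based milestone index touched at each event.
#' @param total_time total simulated time in the cell.
#' @param seed,dt provenance metadata (optional).
#' @return an object of class `event_trace`.
#' @export
event_trace <- function(cell, times, milestones, total_time,
                        seed = NA_integer_, dt = NA_real_) {
  if (length(times) != length(milestones))
    stop_validation("times and milestones must have equal length")
  if (length(times) && (any(diff(times) < 0) || any(times < 0)))
    stop_validation("event times must be nondecreasing and non-negative")
  if (!is.finite(total_time) || total_time <= 0)
    stop_validation("total_time must be positive")
  if (length(times) && max(times) > total_time)
    stop_validation("event times must not exceed total_time")
  new_event_trace(cell, times, milestones, total_time, seed, dt)
}

new_event_trace <- function(cell, times, milestones, total_time, seed, dt,
                            cv_range = c(NA_real_, NA_real_)) {
  structure(list(cell = as.integer(cell), times = as.numeric(times),
                 milestones = as.integer(milestones),
                 total_time = as.numeric(total_time),
                 seed = as.integer(seed), dt = as.numeric(dt),
                 cv_range = as.numeric(cv_range)),
            class = "event_trace")
}

#' @export
print.event_trace <- function(x, ...) {
  cat(sprintf("EventTrace: cell %d, %d collisions over %g time units (dt=%g, seed=%d)\n",
              x$cell, length(x$times), x$total_time, x$dt, x$seed))
  invisible(x)
}

#' Cell-confined overdamped Brownian dynamics
#'
#' Runs Euler--Maruyama overdamped dynamics
#' `x <- x - D*dt*d(beta U)/dx + sqrt(2*D*dt)*xi` confined to one Voronoi
#' cell. A proposed step crossing a cell boundary is recorded as one
#' collision with that milestone at the end of the offending step and the
#' position is reflected back inside (position reflection implements the
#' velocity reversal of reflective-boundary MD in the overdamped limit). The
#' lower wall of the innermost cell sits at CV 0 and is reflective but is not
#' a milestone, so it generates no events.
#'
#' @param model a `milestoning_model`.
#' @param potential a `potential_spec` (reduced units, see [potentials]).
#' @param cell 0-based cell index to sample.
#' @param start_cv starting CV value, strictly inside the cell.
#' @param n_steps number of integration steps.
#' @param dt time step (time units).
#' @param diffusion_coefficient diffusion constant D (CV units^2 per time
#'   unit).
#' @param seed integer seed; fixed seed gives a bit-identical trace.
#' @return an `event_trace` with the ordered collision events, the total
#'   simulated time, and the range of visited CV values.
#' @export
simulate_confined_bd <- function(model, potential, cell, start_cv, n_steps,
                                 dt, diffusion_coefficient = 1, seed = 1L) {
  check_model(model)
  check_potential(potential)
  cell <- check_cell(model, cell)
  b <- cell_bounds(model, cell)
  if (!is.finite(start_cv) || start_cv <= b[1] || start_cv >= b[2])
    stop_validation(sprintf(
      "start_cv = %g is not strictly inside cell %d = [%g, %g)",
      start_cv, cell, b[1], b[2]))
  if (!is.finite(dt) || dt <= 0 || !is.finite(diffusion_coefficient) ||
      diffusion_coefficient <= 0)
    stop_validation("dt and diffusion_coefficient must be positive")
  if (n_steps < 1) stop_validation("n_steps must be >= 1")
  set.seed(as.integer(seed))
  raw <- bd_confined_cpp(b[1], b[2], cell > 0L, start_cv, n_steps, dt,
                         diffusion_coefficient, potential$code, potential$par)
  # boundary code 0 = lower milestone (cell-1), 1 = upper milestone (cell)
  ms <- ifelse(raw$boundary == 1L, cell, cell - 1L)
  new_event_trace(cell, raw$times, ms, n_steps * dt, seed, dt,
                  cv_range = c(raw$cv_min, raw$cv_max))
}

#' Brute-force first passage times of unconfined dynamics
#'
#' Independent first-passage samples of the same overdamped dynamics without
#' milestoning: from `start_cv` to an absorbing boundary, with a reflecting
#' lower wall. Serves as the model-free oracle for residence times; on a flat
#' potential the mean is the closed form
#' `((b - a)^2 - (x - a)^2) / (2 D)`.
#'
#' @inheritParams simulate_confined_bd
#' @param reflecting_at,absorbing_at boundaries, `reflecting_at < start_cv <=
#'   absorbing_at`.
#' @param n_samples number of independent passage times.
#' @param max_time per-sample time budget; samples exceeding it return `NA`
#'   with a warning.
#' @return numeric vector of `n_samples` first passage times.
#' @export
simulate_unconfined_fpt <- function(potential, start_cv, reflecting_at,
                                    absorbing_at, dt, diffusion_coefficient = 1,
                                    n_samples = 100L, seed = 1L,
                                    max_time = 1e6) {
  check_potential(potential)
  if (!(reflecting_at < absorbing_at))
    stop_validation("degenerate interval: reflecting_at must be < absorbing_at")
  if (start_cv < reflecting_at || start_cv > absorbing_at)
    stop_validation("start_cv must lie in [reflecting_at, absorbing_at]")
  if (!is.finite(dt) || dt <= 0 || diffusion_coefficient <= 0)
    stop_validation("dt and diffusion_coefficient must be positive")
  if (n_samples < 1) stop_validation("n_samples must be >= 1")
  set.seed(as.integer(seed))
  out <- bd_fpt_cpp(start_cv, reflecting_at, absorbing_at, dt,
                    diffusion_coefficient, potential$code, potential$par,
                    as.integer(n_samples), ceiling(max_time / dt))
  if (anyNA(out))
    warning(sprintf("%d of %d first-passage samples exceeded max_time = %g",
                    sum(is.na(out)), n_samples, max_time))
  out
}

#' Exact simulation of a continuous-time Markov jump process
#'
#' Gillespie simulation of the jump chain of a generator matrix `Q`:
#' exponential holding times with rate `|Q_ii|`, jump to `j` with probability
#' `Q_ij / |Q_ii|`. Used as the exact oracle for the milestone-level jump
#' model the MMVT estimator reconstructs.
#'
#' @param generator_matrix square rate matrix: off-diagonal >= 0, rows sum to
#'   zero (a zero row is an absorbing state).
#' @param total_jumps number of jumps to simulate; the simulation stops early
#'   if an absorbing state is reached.
#' @param start 0-based starting state.
#' @param seed integer seed.
#' @return a list with 0-based `states` (visited sequence, length = jumps
#'   + 1), `holding` times (one per visited non-final state), and `absorbed`.
#' @export
simulate_ctmc <- function(generator_matrix, total_jumps, start = 0L,
                          seed = 1L) {
  Q <- validate_generator(generator_matrix)
  n <- nrow(Q)
  if (start < 0 || start >= n || start != floor(start))
    stop_validation("start state out of range")
  if (total_jumps < 1) stop_validation("total_jumps must be >= 1")
  set.seed(as.integer(seed))
  gillespie_cpp(Q, as.integer(start), as.numeric(total_jumps))
}

validate_generator <- function(Q) {
  Q <- as.matrix(Q)
  if (nrow(Q) != ncol(Q) || nrow(Q) < 2L)
    stop_validation("generator must be a square matrix with >= 2 states")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) {
    i <- which(apply(off < 0, 1, any))[1]
    stop_validation(sprintf("negative off-diagonal rate in generator row %d",
                            i - 1L))
  }
  rs <- rowSums(Q)
  bad <- which(abs(rs) > 1e-8 * pmax(1, abs(diag(Q))))
  if (length(bad))
    stop_validation(sprintf("generator row %d does not sum to zero (sum = %g)",
                            bad[1] - 1L, rs[bad[1]]))
  Q
}

#' Seed starting structures by steered pulling
#'
#' Toy stand-in for steered MD: Brownian dynamics on the cell potential under
#' a moving harmonic restraint whose centre travels from the bound region to
#' the outermost milestone, recording the first configuration observed inside
#' each Voronoi cell. Every cell receives one starting CV value strictly
#' inside it.
#'
#' @inheritParams simulate_confined_bd
#' @param pull_speed restraint-centre speed (CV units per time unit), > 0.
#' @param restraint_stiffness harmonic restraint stiffness (kT per CV unit
#'   squared), > 0.
#' @return numeric vector of length `n_cells`; element `k + 1` is the start
#'   value for 0-based cell `k`.
#' @export
smd_standin <- function(model, potential, pull_speed, restraint_stiffness,
                        dt, diffusion_coefficient = 1, seed = 1L) {
  check_model(model)
  check_potential(potential)
  if (!is.finite(pull_speed) || pull_speed <= 0)
    stop_validation("pull_speed must be positive")
  if (!is.finite(restraint_stiffness) || restraint_stiffness <= 0)
    stop_validation("restraint_stiffness must be positive")
  if (!is.finite(dt) || dt <= 0 || diffusion_coefficient <= 0)
    stop_validation("dt and diffusion_coefficient must be positive")
  if (restraint_stiffness * dt * diffusion_coefficient > 0.5)
    stop_validation(paste(
      "restraint_stiffness * dt * D exceeds 0.5: the Euler step is unstable;",
      "reduce dt or soften the restraint"))
  m <- model$milestones
  c_start <- m[1] / 2                 # centre of the bound cell
  c_end <- m[model$n_milestones]
  if (c_end <= c_start)
    stop_validation("zero pull distance: restraint centre does not move")
  n_steps <- ceiling((c_end - c_start) / (pull_speed * dt))
  set.seed(as.integer(seed))
  starts <- smd_cpp(m, c_start, c_start, c_end, restraint_stiffness,
                    n_steps, dt, diffusion_coefficient,
                    potential$code, potential$par)
  if (anyNA(starts))
    stop_validation(sprintf(
      "pull schedule failed to visit cell(s) %s; slow the pull or soften the restraint",
      paste(which(is.na(starts)) - 1L, collapse = ", ")))
  # nudge off the lower boundary so every start is strictly inside its cell
  for (k in seq_along(starts)) {
    b <- cell_bounds(model, k - 1L)
    eps <- 1e-9 * (b[2] - b[1])
    starts[k] <- min(max(starts[k], b[1] + eps), b[2] - eps)
  }
  starts
}

#' Truncate an event trace in time
#'
#' Keeps the events up to `t_max` and sets the total time to `t_max`; used by
#' convergence monitoring to form cumulative time prefixes.
#'
#' @param trace an `event_trace`.
#' @param t_max positive time, at most the trace's total time.
#' @return an `event_trace`.
#' @export
truncate_trace <- function(trace, t_max) {
  check_trace(trace)
  if (!is.finite(t_max) || t_max <= 0 || t_max > trace$total_time)
    stop_validation("t_max must be in (0, total_time]")
  keep <- trace$times <= t_max
  new_event_trace(trace$cell, trace$times[keep], trace$milestones[keep],
                  t_max, trace$seed, trace$dt, trace$cv_range)
}

check_trace <- function(trace) {
  if (!inherits(trace, "event_trace"))
    stop_validation("expected an event_trace object")
  invisible(trace)
}

#' Read and write event traces as JSON lines
#'
#' One header record (cell, seed, dt, total time, units) followed by one
#' `{"t": ..., "m": ...}` record per collision; the reader tolerates a
#' missing trailing newline.
#'
#' @param trace an `event_trace`.
#' @param path file path.
#' @param units unit labels stored in the header.
#' @return `write_trace`: `path` invisibly; `read_trace`: an `event_trace`.
#' @export
write_trace <- function(trace, path,
                        units = list(cv = "angstrom", time = "ps")) {
  check_trace(trace)
  con <- file(path, "w")
  on.exit(close(con))
  header <- jsonlite::toJSON(
    list(cell = trace$cell, seed = trace$seed, dt = trace$dt,
         T = trace$total_time, units = units),
    auto_unbox = TRUE, digits = NA)
  writeLines(header, con)
  if (length(trace$times)) {
    recs <- sprintf('{"t":%s,"m":%d}',
                    vapply(trace$times, function(t)
                      jsonlite::toJSON(t, auto_unbox = TRUE, digits = NA),
                      character(1)),
                    trace$milestones)
    writeLines(recs, con)
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop_validation("empty trace file")
  header <- jsonlite::fromJSON(lines[1])
  times <- numeric(0); ms <- integer(0)
  if (length(lines) > 1L) {
    recs <- lapply(lines[-1], jsonlite::fromJSON)
    times <- vapply(recs, `[[`, numeric(1), "t")
    ms <- vapply(recs, function(r) as.integer(r$m), integer(1))
  }
  new_event_trace(header$cell, times, ms, header$T, header$seed, header$dt)
}
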