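#' Cell equilibrium probabilities from boundary-collision fluxes
#'
#' Solves the cell-level flux balance for the equilibrium weights `pi` of the
#' Voronoi cells: with cell-to-cell collision rates
#' `k[a, b] = N_boundary[a -> b] / T_a`, `pi` satisfies
#' `sum_b pi_b k[b, a] = pi_a sum_b k[a, b]` for every cell `a`, normalized
#' to `sum(pi) = 1`. One balance equation is replaced by the normalization
#' row and the system solved directly.
#'
#' @param stats list of `cell_statistics`, one per cell of the model.
#' @param model the `milestoning_model`.
#' @return numeric vector `pi` (length `n_cells`, nonnegative, sums to 1).
#' @export
solve_cell_equilibrium <- function(stats, model) {
  check_model(model)
  stats <- order_stats(stats, model)
  C <- model$n_cells
  Tv <- vapply(stats, `[[`, numeric(1), "T")
  if (any(Tv <= 0))
    stop_numerical(sprintf("cell %d has zero attributable sampling time",
                           which(Tv <= 0)[1] - 1L))
  # k[a, b]: collision rate of cell a with the boundary shared with cell b
  K <- matrix(0, C, C)
  for (a in seq_len(C)) {
    for (m in cell_milestones(model, a - 1L)) {
      b <- if (m == a - 1L) a + 1L else a - 1L  # neighbour across milestone m
      if (b >= 1L && b <= C)
        K[a, b] <- stats[[a]]$N_boundary[m + 1L] / Tv[a]
    }
  }
  comps <- graph_components(K + t(K) > 0)
  if (max(comps) > 1L)
    stop_numerical(sprintf(
      "cell-adjacency graph is disconnected; components: %s",
      paste(vapply(seq_len(max(comps)), function(g)
        paste0("{", paste(which(comps == g) - 1L, collapse = ","), "}"),
        character(1)), collapse = " ")))
  G <- K
  diag(G) <- -rowSums(K)
  A <- t(G)                       # A %*% pi = 0
  A[C, ] <- 1                     # replace one balance row by normalization
  b <- c(rep(0, C - 1L), 1)
  pi <- drop(solve(A, b))
  if (min(pi) < -1e-8)
    stop_numerical("cell equilibrium solve produced negative probabilities")
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

order_stats <- function(stats, model) {
  cells <- vapply(stats, function(s) {
    if (!inherits(s, "cell_statistics"))
      stop_validation("expected a list of cell_statistics")
    s$cell
  }, integer(1))
  if (!setequal(cells, seq_len(model$n_cells) - 1L) ||
      length(cells) != model$n_cells)
    stop_validation(sprintf(
      "statistics must cover each of cells 0..%d exactly once",
      model$n_cells - 1L))
  stats[order(cells)]
}

graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n)
  g <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    g <- g + 1L
    queue <- s
    comp[s] <- g
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- g
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Combine per-cell statistics into milestone-level counts
#'
#' Forms the equilibrium-weighted model-level quantities of the MMVT
#' estimator: the weighting time `T = (sum_a pi_a / T_a)^-1`, the weighted
#' transition counts `N[i][j] = T * sum_a pi_a N_a[i][j] / T_a`, and the
#' weighted occupation times `R[i] = T * sum_a pi_a R_a[i] / T_a`. With a
#' single cell these reduce to that cell's raw statistics.
#'
#' @param stats list of `cell_statistics` (one per cell).
#' @param pi cell equilibrium probabilities from [solve_cell_equilibrium()].
#' @param model the `milestoning_model`.
#' @return an object of class `combined_counts` with fields `N`, `R`, `T`.
#' @export
combine_counts <- function(stats, pi, model) {
  check_model(model)
  stats <- order_stats(stats, model)
  if (length(pi) != model$n_cells || any(!is.finite(pi)) || any(pi < 0))
    stop_validation("pi must be a nonnegative vector with one entry per cell")
  Tv <- vapply(stats, `[[`, numeric(1), "T")
  if (any(Tv[pi > 0] <= 0))
    stop_numerical("cell with positive weight has zero sampling time")
  Tw <- 1 / sum(pi / Tv)
  M <- model$n_milestones
  N <- matrix(0, M, M)
  R <- numeric(M)
  for (a in seq_along(stats)) {
    w <- pi[a] / Tv[a]
    N <- N + w * stats[[a]]$N
    R <- R + w * stats[[a]]$R
  }
  structure(list(N = Tw * N, R = Tw * R, T = Tw), class = "combined_counts")
}

#' Build the milestone rate matrix
#'
#' `Q[i, j] = N[i, j] / R[i]` for `i != j`, diagonal set so each row sums to
#' zero. `Q_hat` is `Q` with the absorbing milestone's row and column
#' removed (the "upper left corner" when the absorbing milestone is the
#' outermost one).
#'
#' @param counts a `combined_counts` object (or any list with fields `N`
#'   matrix and `R` vector).
#' @param absorbing 0-based index of the absorbing milestone.
#' @return an object of class `rate_matrix_result` with fields `Q`, `Q_hat`,
#'   `absorbing`.
#' @export
build_rate_matrix <- function(counts, absorbing) {
  N <- counts$N; R <- counts$R
  M <- nrow(N)
  if (is.null(M) || ncol(N) != M || length(R) != M)
    stop_validation("counts must hold a square N matrix and matching R vector")
  if (!is.numeric(absorbing) || absorbing < 0 || absorbing >= M ||
      absorbing != floor(absorbing))
    stop_validation("invalid absorbing milestone index")
  out_counts <- rowSums(N)
  in_counts <- colSums(N)
  dead <- which(out_counts == 0 & in_counts == 0 & R == 0)
  if (length(dead))
    stop_numerical(sprintf(
      "milestone %d has no recorded collisions; more sampling is needed",
      dead[1] - 1L))
  zero_R <- which(out_counts > 0 & R <= 0)
  if (length(zero_R))
    stop_numerical(sprintf(
      "milestone %d has outgoing transitions but zero occupation time",
      zero_R[1] - 1L))
  Q <- matrix(0, M, M)
  pos <- R > 0
  Q[pos, ] <- N[pos, , drop = FALSE] / R[pos]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  keep <- setdiff(seq_len(M), absorbing + 1L)
  structure(list(Q = Q, Q_hat = Q[keep, keep, drop = FALSE],
                 absorbing = as.integer(absorbing)),
            class = "rate_matrix_result")
}

#' Mean first passage times from the rate matrix
#'
#' Solves `Q_hat %*% T = -1` for the vector of mean first passage times to
#' the absorbing milestone; the absorbing milestone's own MFPT is zero. The
#' residence time is the MFPT of the bound milestone.
#'
#' @param rm a `rate_matrix_result`.
#' @param bound 0-based index of the bound milestone (default 0).
#' @return list with `mfpt` (length = number of milestones) and
#'   `residence_time`.
#' @export
mfpt <- function(rm, bound = 0L) {
  if (!inherits(rm, "rate_matrix_result"))
    stop_validation("expected a rate_matrix_result")
  M <- nrow(rm$Q)
  if (bound < 0 || bound >= M) stop_validation("invalid bound milestone index")
  Qh <- rm$Q_hat
  if (nrow(Qh) == 0L) {
    v <- numeric(M)
    return(list(mfpt = v, residence_time = v[bound + 1L]))
  }
  if (rcond(Qh) < 1e-14)
    stop_numerical(paste(
      "Q_hat is singular; some milestone is likely disconnected from the",
      "absorbing milestone"))
  Tn <- drop(solve(Qh, rep(-1, nrow(Qh))))
  v <- numeric(M)
  v[setdiff(seq_len(M), rm$absorbing + 1L)] <- Tn
  if (min(v) < -1e-9)
    stop_numerical("negative mean first passage time; rate matrix is invalid")
  list(mfpt = pmax(v, 0), residence_time = v[bound + 1L])
}

#' Stationary probabilities of the milestone jump process
#'
#' Solves the stationary eigenvalue problem `p %*% Q = 0` for the full rate
#' matrix `Q` (left eigenvector of eigenvalue zero), normalized to a
#' nonnegative probability vector.
#'
#' @param rm a `rate_matrix_result`.
#' @return numeric vector `p` (sums to 1).
#' @export
stationary_probabilities <- function(rm) {
  if (!inherits(rm, "rate_matrix_result"))
    stop_validation("expected a rate_matrix_result")
  Q <- rm$Q
  comps <- graph_components((Q + t(Q)) != 0 | diag(nrow(Q)) > 0)
  if (max(comps) > 1L)
    stop_numerical("rate matrix is reducible; stationary vector is not unique")
  e <- eigen(t(Q))
  k <- which.min(abs(e$values))
  if (abs(e$values[k]) > 1e-8 * max(abs(diag(Q))))
    stop_numerical("no zero eigenvalue found; Q is not a generator")
  p <- Re(e$vectors[, k])
  p <- p * sign(sum(p))
  if (min(p) < -1e-8 * max(abs(p)))
    stop_numerical("stationary eigenvector has mixed signs; Q is reducible or invalid")
  p <- pmax(p, 0)
  p / sum(p)
}

#' Free-energy profile from stationary probabilities
#'
#' `dG_i = -kT * log(p_i / p_ref)` with the bound-state milestone as the
#' reference, plus transition-state detection: the 0-based indices of the
#' strict interior local maxima of the profile (a flat plateau resolves to
#' its first index; milestones with `p = 0` get `dG = +Inf` with a warning
#' and are excluded from the search).
#'
#' @param p stationary milestone probabilities.
#' @param reference 0-based reference (bound) milestone index.
#' @param thermal_energy k_B*T in the desired energy units.
#' @return list with `dG` (length of `p`) and `ts_milestones` (integer,
#'   0-based).
#' @export
free_energy_profile <- function(p, reference = 0L, thermal_energy = 1) {
  if (any(!is.finite(p)) || any(p < 0))
    stop_validation("p must be finite and nonnegative")
  if (reference < 0 || reference >= length(p))
    stop_validation("invalid reference milestone index")
  if (p[reference + 1L] <= 0)
    stop_validation("stationary probability at the reference milestone is zero")
  if (any(p == 0))
    warning("zero stationary probability; reporting dG = +Inf for those milestones")
  dG <- -thermal_energy * log(p / p[reference + 1L])
  list(dG = dG, ts_milestones = local_maxima(dG))
}

# strict interior local maxima; plateaus resolve to their first index, and a
# plateau only counts if it eventually drops on the right
local_maxima <- function(y) {
  n <- length(y)
  out <- integer(0)
  if (n < 3L) return(out)
  for (i in 2:(n - 1L)) {
    if (!is.finite(y[i]) || !is.finite(y[i - 1L])) next
    if (y[i] <= y[i - 1L]) next
    j <- i + 1L
    while (j <= n && is.finite(y[j]) && y[j] == y[i]) j <- j + 1L
    if (j > n || !is.finite(y[j])) next
    if (y[j] < y[i]) out <- c(out, i - 1L)
  }
  out
}

#' Full MMVT kinetics from per-cell statistics
#'
#' Runs the complete estimator: cell equilibrium `pi`, weighted combined
#' counts, rate matrix `Q`, mean first passage times (residence time),
#' stationary probabilities `p`, and the free-energy profile with
#' transition-state milestones.
#'
#' @param model a `milestoning_model`.
#' @param stats list of `cell_statistics`, one per cell.
#' @return an object of class `kinetics_result` with fields `pi`, `counts`,
#'   `rate_matrix`, `mfpt`, `residence_time`, `p`, `dG`, `ts_milestones`,
#'   `model`.
#' @export
compute_kinetics <- function(model, stats) {
  check_model(model)
  pi <- solve_cell_equilibrium(stats, model)
  counts <- combine_counts(stats, pi, model)
  rm_ <- build_rate_matrix(counts, model$absorbing_milestone)
  fp <- mfpt(rm_, model$bound_milestone)
  p <- stationary_probabilities(rm_)
  prof <- free_energy_profile(p, model$bound_milestone, model$thermal_energy)
  structure(list(pi = pi, counts = counts, rate_matrix = rm_,
                 mfpt = fp$mfpt, residence_time = fp$residence_time,
                 p = p, dG = prof$dG, ts_milestones = prof$ts_milestones,
                 model = model),
            class = "kinetics_result")
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf("MMVT kinetics: residence time %.6g %s\n",
              x$residence_time, x$model$units$time))
  cat(sprintf("  transition-state milestone(s): %s\n",
              if (length(x$ts_milestones))
                paste(x$ts_milestones, collapse = ", ") else "none"))
  cat(sprintf("  dG range: [%.3g, %.3g] (kT = %g)\n",
              min(x$dG[is.finite(x$dG)]), max(x$dG[is.finite(x$dG)]),
              x$model$thermal_energy))
  invisible(x)
}

#' Aggregate replicas as mean and standard error
#'
#' Per-milestone arithmetic mean and standard error of the mean (SEM) of the
#' MFPT vector and the free-energy profile, and the residence time as mean
#' +/- SEM, across independent replicas of the same model.
#'
#' @param results list of `kinetics_result` from >= 2 replicas.
#' @return an object of class `replica_aggregate` with fields
#'   `residence_mean`, `residence_sem`, `residence_times`, `mfpt_mean`,
#'   `mfpt_sem`, `dG_mean`, `dG_sem`, `ts_milestones` (per replica list),
#'   `n_replicas`, `model`.
#' @export
replica_aggregate <- function(results) {
  if (length(results) < 2L)
    stop_validation("replica aggregation needs >= 2 replicas")
  for (r in results)
    if (!inherits(r, "kinetics_result"))
      stop_validation("expected a list of kinetics_result objects")
  ms <- lapply(results, function(r) r$model$milestones)
  if (!all(vapply(ms[-1], identical, logical(1), ms[[1]])))
    stop_validation("replicas were computed on different milestoning models")
  n <- length(results)
  res <- vapply(results, `[[`, numeric(1), "residence_time")
  mf <- do.call(rbind, lapply(results, `[[`, "mfpt"))
  dg <- do.call(rbind, lapply(results, `[[`, "dG"))
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  structure(list(
    residence_mean = mean(res), residence_sem = sem(res),
    residence_times = res,
    mfpt_mean = colMeans(mf), mfpt_sem = apply(mf, 2, sem),
    dG_mean = colMeans(dg), dG_sem = apply(dg, 2, sem),
    ts_milestones = lapply(results, `[[`, "ts_milestones"),
    n_replicas = n, model = results[[1]]$model),
    class = "replica_aggregate")
}

#' @export
print.replica_aggregate <- function(x, ...) {
  cat(sprintf("Replica aggregate (%d replicas): residence time %.6g +/- %.3g %s\n",
              x$n_replicas, x$residence_mean, x$residence_sem,
              x$model$units$time))
  invisible(x)
}

#' Counts from a simulated milestone jump process
#'
#' Adapter from a [simulate_ctmc()] trajectory to the estimator: transition
#' counts `N[i][j]` are the observed jumps and `R[i]` the total holding
#' times, i.e. the single-cell degenerate case of the combined counts.
#'
#' @param traj result of [simulate_ctmc()].
#' @param n_states number of states (milestones) of the generator.
#' @return a `combined_counts` object.
#' @export
counts_from_ctmc <- function(traj, n_states) {
  st <- traj$states
  hold <- traj$holding
  if (length(st) < 2L) stop_validation("trajectory has no jumps")
  N <- matrix(0, n_states, n_states)
  from <- st[-length(st)] + 1L
  to <- st[-1] + 1L
  for (k in seq_along(from)) N[from[k], to[k]] <- N[from[k], to[k]] + 1
  R <- numeric(n_states)
  for (k in seq_along(hold)) R[from[k]] <- R[from[k]] + hold[k]
  structure(list(N = N, R = R, T = sum(R)), class = "combined_counts")
}

#' Closed-form MFPT of a birth--death chain
#'
#' Independent oracle: for a tridiagonal generator with up-rates `lambda_i`
#' and down-rates `mu_i`, the mean first passage time from state `i` to the
#' absorbing top state `n-1` follows the standard nested-sum formula. Used
#' in tests against the linear-algebra route.
#'
#' @param Q tridiagonal generator matrix (absorbing top state implied).
#' @return numeric vector of MFPTs from each state (last entry 0).
#' @export
birth_death_mfpt <- function(Q) {
  n <- nrow(Q)
  lam <- vapply(seq_len(n - 1L), function(i) Q[i, i + 1L], numeric(1))
  mu <- c(NA_real_, if (n > 2L) vapply(seq(2L, n - 1L),
                                       function(i) Q[i, i - 1L], numeric(1)))
  if (any(lam <= 0)) stop_validation("birth-death oracle needs positive up-rates")
  # expected time from state k to k+1 (0-based k), by first-step recursion:
  # h_1 = 1/lambda_1; h_k = (1 + mu_k * h_{k-1}) / lambda_k
  h <- numeric(n - 1L)
  h[1] <- 1 / lam[1]
  if (n > 2L)
    for (k in seq(2L, n - 1L))
      h[k] <- (1 + mu[k] * h[k - 1L]) / lam[k]
  out <- rev(c(0, cumsum(rev(h))))
  out
}
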