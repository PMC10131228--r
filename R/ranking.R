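#' Define a system to simulate and analyze
#'
#' A system couples a milestoning model with a potential (standing in for
#' one receptor--inhibitor complex), a sampling budget and a master seed.
#'
#' @param name system name (used in rankings).
#' @param model a `milestoning_model`.
#' @param potential a `potential_spec`.
#' @param n_replicas number of independent replicas, >= 1.
#' @param n_steps_per_cell confined-BD steps per cell per replica.
#' @param dt integration time step.
#' @param diffusion_coefficient diffusion constant D.
#' @param master_seed integer master seed; all per-cell streams derive from
#'   it (see [derive_seed()]).
#' @param pull_speed,restraint_stiffness steered-seeding parameters passed to
#'   [smd_standin()].
#' @return an object of class `system_spec`.
#' @export
system_spec <- function(name, model, potential, n_replicas = 3L,
                        n_steps_per_cell = 1e6, dt = 1e-4,
                        diffusion_coefficient = 1, master_seed = 1L,
                        pull_speed = 0.05, restraint_stiffness = 100) {
  check_model(model)
  check_potential(potential)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_validation("system name must be a non-empty string")
  if (n_replicas < 1) stop_validation("replica count must be >= 1")
  if (n_steps_per_cell < 1 || dt <= 0 || diffusion_coefficient <= 0)
    stop_validation("sampling budget entries must be positive")
  structure(list(name = name, model = model, potential = potential,
                 n_replicas = as.integer(n_replicas),
                 n_steps_per_cell = n_steps_per_cell, dt = dt,
                 diffusion_coefficient = diffusion_coefficient,
                 master_seed = as.integer(master_seed),
                 pull_speed = pull_speed,
                 restraint_stiffness = restraint_stiffness),
            class = "system_spec")
}

SMD_STREAM <- 10007L  # reserved derive_seed cell id for the seeding stage

#' Run the full MMVT pipeline for one system
#'
#' For each replica: seed one start per cell with [smd_standin()], run
#' confined Brownian dynamics in every cell, collect statistics, and run the
#' estimator; replicas are then aggregated as mean +/- SEM. Deterministic
#' given the master seed. Per-cell runs are mutually independent, so the
#' reduction is order-independent.
#'
#' @param spec a `system_spec`.
#' @param keep_traces if `TRUE`, the raw per-cell `event_trace`s are
#'   returned as well (memory permitting).
#' @return list with `name`, `replicas` (list of `kinetics_result`),
#'   `aggregate` (a `replica_aggregate`, or the single replica's result when
#'   `n_replicas == 1`), and optionally `traces`.
#' @export
run_system <- function(spec, keep_traces = FALSE) {
  if (!inherits(spec, "system_spec"))
    stop_validation("expected a system_spec")
  model <- spec$model
  replicas <- vector("list", spec$n_replicas)
  traces_all <- if (keep_traces) vector("list", spec$n_replicas) else NULL
  for (r in seq_len(spec$n_replicas)) {
    starts <- with_context(
      sprintf("system '%s' replica %d seeding", spec$name, r),
      smd_standin(model, spec$potential, spec$pull_speed,
                  spec$restraint_stiffness, spec$dt,
                  spec$diffusion_coefficient,
                  seed = derive_seed(spec$master_seed, r, SMD_STREAM)))
    stats <- vector("list", model$n_cells)
    traces <- if (keep_traces) vector("list", model$n_cells) else NULL
    for (cell in seq_len(model$n_cells) - 1L) {
      tr <- with_context(
        sprintf("system '%s' replica %d cell %d", spec$name, r, cell),
        simulate_confined_bd(model, spec$potential, cell, starts[cell + 1L],
                             spec$n_steps_per_cell, spec$dt,
                             spec$diffusion_coefficient,
                             seed = derive_seed(spec$master_seed, r, cell)))
      stats[[cell + 1L]] <- collect_cell_statistics(tr, model)
      if (keep_traces) traces[[cell + 1L]] <- tr
    }
    replicas[[r]] <- with_context(
      sprintf("system '%s' replica %d estimation", spec$name, r),
      compute_kinetics(model, stats))
    if (keep_traces) traces_all[[r]] <- traces
  }
  aggregate <- if (spec$n_replicas >= 2L) replica_aggregate(replicas)
               else replicas[[1]]
  out <- list(name = spec$name, replicas = replicas, aggregate = aggregate)
  if (keep_traces) out$traces <- traces_all
  out
}

with_context <- function(ctx, expr) {
  withCallingHandlers(
    tryCatch(expr, milekin_error = function(e) {
      e$message <- sprintf("[%s] %s", ctx, e$message)
      stop(e)
    }),
    warning = function(w) {
      warning(sprintf("[%s] %s", ctx, conditionMessage(w)), call. = FALSE)
      invokeRestart("muffleWarning")
    })
}

#' Welch's unequal-variance t test
#'
#' Two-sided unpaired t test with Welch--Satterthwaite degrees of freedom,
#' as used to compare residence-time estimates between systems. Implemented
#' from the closed-form expressions; conventions for degenerate inputs: if
#' both samples have zero variance, `p = 1` when the means are equal and
#' `p = 0` (infinite t) otherwise.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @return list with `statistic` (t), `df`, `p_value`.
#' @export
welch_ttest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop_validation("each sample needs >= 2 observations")
  va <- stats::var(a); vb <- stats::var(b)
  na <- length(a); nb <- length(b)
  delta <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (delta == 0) return(list(statistic = 0, df = NA_real_, p_value = 1))
    return(list(statistic = sign(delta) * Inf, df = NA_real_, p_value = 0))
  }
  se2 <- va / na + vb / nb
  t <- delta / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(statistic = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df))
}

#' Rank systems by residence time
#'
#' Orders systems by decreasing mean residence time (longest-lived first),
#' with a stable alphabetical tie-break, and computes all pairwise Welch
#' tests on the per-replica residence times.
#'
#' @param aggregates named list; each element either a `replica_aggregate`
#'   or a list/vector with the per-replica residence times under
#'   `residence_times`.
#' @return list with `table` (data frame: system, residence_mean,
#'   residence_sem, rank, tied) and `pairwise` (data frame: system_a,
#'   system_b, t, df, p_value).
#' @export
rank_systems <- function(aggregates) {
  if (length(aggregates) < 2L)
    stop_validation("ranking needs >= 2 systems")
  nms <- names(aggregates)
  if (is.null(nms) || any(!nzchar(nms)))
    stop_validation("aggregates must be a named list")
  res <- lapply(aggregates, function(x) {
    if (inherits(x, "replica_aggregate")) x$residence_times
    else if (is.list(x) && !is.null(x$residence_times)) x$residence_times
    else as.numeric(x)
  })
  means <- vapply(res, mean, numeric(1))
  sems <- vapply(res, function(x)
    if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_,
    numeric(1))
  ord <- order(-means, nms)
  tab <- data.frame(system = nms[ord], residence_mean = means[ord],
                    residence_sem = sems[ord], rank = seq_along(ord),
                    tied = duplicated(means[ord]) |
                      duplicated(means[ord], fromLast = TRUE),
                    row.names = NULL, stringsAsFactors = FALSE)
  pairs <- utils::combn(sort(nms), 2)
  pw <- data.frame(system_a = pairs[1, ], system_b = pairs[2, ],
                   t = NA_real_, df = NA_real_, p_value = NA_real_,
                   stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    x <- res[[pairs[1, k]]]; y <- res[[pairs[2, k]]]
    if (length(x) >= 2L && length(y) >= 2L) {
      w <- welch_ttest(x, y)
      pw$t[k] <- w$statistic; pw$df[k] <- w$df; pw$p_value[k] <- w$p_value
    }
  }
  list(table = tab, pairwise = pw)
}

#' Export kinetics results
#'
#' Writes the per-milestone results table (milestone index, CV value, MFPT
#' mean/SEM, dG mean/SEM, transition-state flag) as CSV, and a JSON summary
#' with the residence time (mean +/- SEM).
#'
#' @param aggregate a `replica_aggregate` or single `kinetics_result`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return the results data frame, invisibly.
#' @export
write_results <- function(aggregate, csv_path = NULL, json_path = NULL) {
  if (inherits(aggregate, "kinetics_result")) {
    model <- aggregate$model
    df <- data.frame(
      milestone = seq_len(model$n_milestones) - 1L,
      cv_value = model$milestones,
      mfpt_mean = aggregate$mfpt, mfpt_sem = NA_real_,
      dG_mean = aggregate$dG, dG_sem = NA_real_,
      is_TS = (seq_len(model$n_milestones) - 1L) %in% aggregate$ts_milestones)
    summary <- list(residence_time_mean = aggregate$residence_time,
                    residence_time_sem = NA, n_replicas = 1L,
                    time_unit = model$units$time)
  } else if (inherits(aggregate, "replica_aggregate")) {
    model <- aggregate$model
    ts <- sort(unique(unlist(aggregate$ts_milestones)))
    df <- data.frame(
      milestone = seq_len(model$n_milestones) - 1L,
      cv_value = model$milestones,
      mfpt_mean = aggregate$mfpt_mean, mfpt_sem = aggregate$mfpt_sem,
      dG_mean = aggregate$dG_mean, dG_sem = aggregate$dG_sem,
      is_TS = (seq_len(model$n_milestones) - 1L) %in% ts)
    summary <- list(residence_time_mean = aggregate$residence_mean,
                    residence_time_sem = aggregate$residence_sem,
                    n_replicas = aggregate$n_replicas,
                    time_unit = model$units$time)
  } else stop_validation("expected a kinetics_result or replica_aggregate")
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(df)
}
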