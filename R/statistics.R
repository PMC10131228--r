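#' Reduce an event trace to MMVT cell statistics
#'
#' Walks the ordered collision events of one cell and accumulates the
#' sufficient statistics of the MMVT estimator: `N[i][j]`, the number of
#' collisions with milestone `j` after having last touched milestone `i`
#' (`i != j`); `R[i]`, the simulation time spent having last touched
#' milestone `i`; `T`, the total attributable time; and `N_boundary[m]`, the
#' total number of collisions with each bordering milestone (same-milestone
#' re-touches included). Time before the first collision cannot be attributed
#' to any last-touched milestone; it is reported as `excluded_time` and
#' excluded from `T`, so that `sum(R) == T` exactly.
#'
#' @param trace an `event_trace` (see [simulate_confined_bd()]).
#' @param model the `milestoning_model` the trace was generated on.
#' @return an object of class `cell_statistics` with fields `cell`, `N`
#'   (n_milestones x n_milestones matrix), `R`, `T`, `N_boundary`,
#'   `excluded_time`, `n_milestones`.
#' @export
collect_cell_statistics <- function(trace, model) {
  check_trace(trace)
  check_model(model)
  M <- model$n_milestones
  border <- cell_milestones(model, trace$cell)
  ms <- trace$milestones
  if (length(ms) && !all(ms %in% border))
    stop_validation(sprintf(
      "corrupt trace: milestone %d does not border cell %d",
      ms[which(!(ms %in% border))[1]], trace$cell))
  if (length(trace$times)) {
    if (any(diff(trace$times) < 0))
      stop_validation("corrupt trace: event times must be nondecreasing")
    if (trace$times[length(trace$times)] > trace$total_time)
      stop_validation("corrupt trace: event time exceeds total time")
  }
  N <- matrix(0, M, M)
  R <- numeric(M)
  Nb <- numeric(M)
  n <- length(ms)
  if (n == 0L)
    return(new_cell_statistics(trace$cell, N, R, Nb, trace$total_time, M))
  excluded <- trace$times[1]
  # time from each event to the next (or to the end) belongs to its milestone
  dts <- c(diff(trace$times), trace$total_time - trace$times[n])
  agg <- rowsum(dts, ms)
  R[as.integer(rownames(agg)) + 1L] <- agg
  Nb <- tabulate(ms + 1L, nbins = M)
  if (n > 1L) {
    from <- ms[-n]; to <- ms[-1]
    keep <- from != to
    if (any(keep))
      N <- matrix(tabulate(to[keep] * M + from[keep] + 1L, nbins = M * M),
                  M, M)
  }
  new_cell_statistics(trace$cell, N, R, Nb, excluded, M)
}

new_cell_statistics <- function(cell, N, R, N_boundary, excluded_time, M) {
  structure(list(cell = as.integer(cell), N = N, R = R, T = sum(R),
                 N_boundary = N_boundary,
                 excluded_time = as.numeric(excluded_time),
                 n_milestones = as.integer(M)),
            class = "cell_statistics")
}

#' @export
print.cell_statistics <- function(x, ...) {
  cat(sprintf(
    "Cell %d statistics: %d transitions, %d boundary collisions, T = %g (+%g excluded)\n",
    x$cell, sum(x$N), sum(x$N_boundary), x$T, x$excluded_time))
  invisible(x)
}

#' Merge statistics of multiple sampling segments of the same cell
#'
#' Component-wise sums. The last-touched milestone does not carry across
#' segments: each segment excludes its own pre-first-touch time, so merging
#' segments cut at event boundaries reproduces the statistics of the
#' uninterrupted trace exactly.
#'
#' @param parts list of `cell_statistics` for the same cell.
#' @return a `cell_statistics`.
#' @export
merge_statistics <- function(parts) {
  if (!length(parts)) stop_validation("nothing to merge")
  for (p in parts)
    if (!inherits(p, "cell_statistics"))
      stop_validation("merge_statistics expects cell_statistics objects")
  cells <- vapply(parts, `[[`, integer(1), "cell")
  if (length(unique(cells)) != 1L)
    stop_validation(sprintf("cannot merge statistics of different cells (%s)",
                            paste(unique(cells), collapse = ", ")))
  Ms <- vapply(parts, `[[`, integer(1), "n_milestones")
  if (length(unique(Ms)) != 1L)
    stop_validation("cannot merge statistics with different milestone counts")
  N <- Reduce(`+`, lapply(parts, `[[`, "N"))
  R <- Reduce(`+`, lapply(parts, `[[`, "R"))
  Nb <- Reduce(`+`, lapply(parts, `[[`, "N_boundary"))
  ex <- sum(vapply(parts, `[[`, numeric(1), "excluded_time"))
  new_cell_statistics(cells[1], N, R, Nb, ex, Ms[1])
}

#' All-zero statistics for a cell
#'
#' @param model a `milestoning_model`.
#' @param cell 0-based cell index.
#' @return a `cell_statistics` with zero counts and times.
#' @export
zero_statistics <- function(model, cell) {
  check_model(model)
  cell <- check_cell(model, cell)
  M <- model$n_milestones
  new_cell_statistics(cell, matrix(0, M, M), numeric(M), numeric(M), 0, M)
}

#' Convergence monitoring of the MMVT estimate
#'
#' Splits every cell's trace into `window_count` cumulative time prefixes,
#' runs the full estimator on each prefix, and returns the sequence of
#' bound-state mean first passage times together with the relative change of
#' the final window. Prefixes whose statistics are still disconnected are
#' reported as `NA` rather than failing.
#'
#' @param model a `milestoning_model`.
#' @param traces list of `event_trace` objects, one per cell (any order).
#' @param window_count number of cumulative windows, >= 2.
#' @return list with `mfpt` (length `window_count`), `fraction` (prefix time
#'   fractions) and `relative_change` (`|last - previous| / previous`).
#' @export
convergence_series <- function(model, traces, window_count) {
  check_model(model)
  if (!is.numeric(window_count) || window_count < 2)
    stop_validation("window_count must be >= 2")
  window_count <- as.integer(window_count)
  for (tr in traces) check_trace(tr)
  fractions <- seq_len(window_count) / window_count
  mfpt <- rep(NA_real_, window_count)
  for (w in seq_len(window_count)) {
    stats <- lapply(traces, function(tr)
      collect_cell_statistics(truncate_trace(tr, fractions[w] * tr$total_time),
                              model))
    mfpt[w] <- tryCatch(
      compute_kinetics(model, stats)$residence_time,
      milekin_error = function(e) NA_real_)
  }
  last2 <- utils::tail(mfpt, 2)
  rel <- if (anyNA(last2) || last2[1] == 0) NA_real_
         else abs(last2[2] - last2[1]) / abs(last2[1])
  list(mfpt = mfpt, fraction = fractions, relative_change = rel)
}

# ---- serialization -------------------------------------------------------

stats_to_obj <- function(s) {
  nz <- which(s$N != 0, arr.ind = TRUE)
  list(alpha = s$cell,
       N = unname(apply(cbind(nz - 1L, s$N[nz]), 1, as.numeric,
                        simplify = FALSE)),
       R = unname(lapply(which(s$R != 0),
                         function(i) c(i - 1, s$R[i]))),
       T = s$T,
       N_boundary = unname(lapply(which(s$N_boundary != 0),
                                  function(i) c(i - 1, s$N_boundary[i]))),
       excluded_time = s$excluded_time)
}

obj_to_stats <- function(obj, M) {
  N <- matrix(0, M, M); R <- numeric(M); Nb <- numeric(M)
  for (e in obj$N) N[e[1] + 1, e[2] + 1] <- e[3]
  for (e in obj$R) R[e[1] + 1] <- e[2]
  for (e in obj$N_boundary) Nb[e[1] + 1] <- e[2]
  new_cell_statistics(obj$alpha, N, R, Nb, obj$excluded_time %||% 0, M)
}

#' Read and write MMVT statistics files
#'
#' Versioned JSON container (`"schema": "mmvt_stats_v1"`) holding one sparse
#' record per cell. `statistics_table` flattens a statistics list into a
#' data frame for inspection or CSV export.
#'
#' @param stats list of `cell_statistics`.
#' @param path file path.
#' @param n_milestones milestone count stored in (and checked against) the
#'   file header.
#' @return `write_statistics`: `path` invisibly; `read_statistics`: list of
#'   `cell_statistics`; `statistics_table`: a data frame.
#' @export
write_statistics <- function(stats, path, n_milestones) {
  obj <- list(schema = "mmvt_stats_v1",
              n_milestones = as.integer(n_milestones),
              cells = lapply(stats, stats_to_obj))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_statistics
#' @export
read_statistics <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "mmvt_stats_v1"))
    stop_validation(sprintf("unsupported statistics schema '%s'",
                            obj$schema %||% "<missing>"))
  M <- obj$n_milestones
  lapply(obj$cells, function(c_obj) {
    c_obj$N <- lapply(c_obj$N, unlist)
    c_obj$R <- lapply(c_obj$R, unlist)
    c_obj$N_boundary <- lapply(c_obj$N_boundary, unlist)
    obj_to_stats(c_obj, M)
  })
}

#' @rdname write_statistics
#' @export
statistics_table <- function(stats) {
  rows <- lapply(stats, function(s) {
    nz <- which(s$N != 0, arr.ind = TRUE)
    trans <- if (nrow(nz)) data.frame(
      cell = s$cell, record = "N", i = nz[, 1] - 1L, j = nz[, 2] - 1L,
      value = s$N[nz]) else NULL
    occ <- data.frame(cell = s$cell, record = "R",
                      i = seq_along(s$R) - 1L, j = NA_integer_, value = s$R)
    tot <- data.frame(cell = s$cell,
                      record = c("T", "excluded_time"),
                      i = NA_integer_, j = NA_integer_,
                      value = c(s$T, s$excluded_time))
    rbind(trans, occ, tot)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
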