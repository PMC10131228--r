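#' Build a radial milestoning model
#'
#' Defines a one-dimensional Voronoi tessellation of a scalar collective
#' variable (CV) into `M` cells separated by `M` milestones. In the radial
#' picture the milestones are concentric spheres at the given CV values (e.g.
#' ligand--binding-site COM distances in Angstrom). Cell `0` is the bound
#' region `[0, m_0)` and cell `k` is the half-open interval
#' `[m_{k-1}, m_k)`; a CV value exactly at a milestone belongs to the cell
#' above it. The innermost milestone is the bound-state milestone (free-energy
#' reference) and the outermost is the absorbing milestone used for mean
#' first passage times.
#'
#' Milestone and cell indices are 0-based, following the field's convention.
#'
#' @param milestone_values strictly increasing, positive CV values (length
#'   >= 2). One cell is created per milestone (see Details).
#' @param thermal_energy k_B*T in the energy units of the analysis; with the
#'   default `1` all energies are in units of k_B*T.
#' @param cv_unit,time_unit unit labels carried through serialization.
#'
#' @details The number of sampled cells can be one fewer than the number of
#'   milestones in practice (an innermost region too small to sample); the
#'   model always exposes `M` cells and simply receives no statistics for an
#'   unsampled cell, which the estimator reports as an error if that leaves a
#'   milestone without data.
#'
#' @return an object of class `milestoning_model`.
#' @examples
#' m <- build_radial_model(c(2.5, 3.0, 3.5, 4.0))
#' assign_cell(m, 2.7)    # 1
#' milestone_between(m, 1, 2)  # 1
#' @export
build_radial_model <- function(milestone_values, thermal_energy = 1,
                               cv_unit = "angstrom", time_unit = "ps") {
  v <- as.numeric(milestone_values)
  if (length(v) < 2L)
    stop_validation("at least 2 milestone values are required")
  if (any(!is.finite(v)))
    stop_validation(sprintf("milestone value %d is not finite",
                            which(!is.finite(v))[1] - 1L))
  if (any(v <= 0))
    stop_validation(sprintf(
      "milestone values must be positive; entry %d is %g",
      which(v <= 0)[1] - 1L, v[which(v <= 0)[1]]))
  d <- diff(v)
  if (any(d <= 0)) {
    k <- which(d <= 0)[1]
    stop_validation(sprintf(
      "milestones must be strictly increasing; entry %d (%g) does not exceed entry %d (%g)",
      k, v[k + 1], k - 1L, v[k]))
  }
  if (!is.numeric(thermal_energy) || length(thermal_energy) != 1L ||
      !is.finite(thermal_energy) || thermal_energy <= 0)
    stop_validation("thermal_energy must be a positive scalar")
  M <- length(v)
  structure(list(
    milestones = v,
    n_milestones = M,
    n_cells = M,
    bound_milestone = 0L,
    absorbing_milestone = M - 1L,
    thermal_energy = as.numeric(thermal_energy),
    units = list(cv = cv_unit, time = time_unit)
  ), class = "milestoning_model")
}

#' @export
print.milestoning_model <- function(x, ...) {
  cat(sprintf("Milestoning model: %d milestones / %d cells on [0, %g) %s\n",
              x$n_milestones, x$n_cells, max(x$milestones), x$units$cv))
  cat(sprintf("  milestones: %s\n",
              paste(format(x$milestones, trim = TRUE), collapse = ", ")))
  cat(sprintf("  bound milestone %d, absorbing milestone %d, kT = %g\n",
              x$bound_milestone, x$absorbing_milestone, x$thermal_energy))
  invisible(x)
}

#' Map CV values to cell indices
#'
#' @param model a `milestoning_model`.
#' @param cv_value numeric vector of CV values in `[0, outermost milestone)`.
#' @return integer vector of 0-based cell indices.
#' @export
assign_cell <- function(model, cv_value) {
  check_model(model)
  x <- as.numeric(cv_value)
  if (any(!is.finite(x)))
    stop_validation("cv_value must be finite")
  outer <- model$milestones[model$n_milestones]
  bad <- x < 0 | x >= outer
  if (any(bad))
    stop_validation(sprintf(
      "cv value %g is outside [0, %g): past the absorbing milestone or negative",
      x[bad][1], outer))
  # findInterval counts milestones <= x, which is exactly the 0-based cell
  # index under the half-open convention (boundary values go to the upper cell)
  as.integer(findInterval(x, model$milestones))
}

#' Shared milestone between two cells
#'
#' @param model a `milestoning_model`.
#' @param cell_a,cell_b 0-based cell indices.
#' @return the 0-based index of the shared milestone for adjacent cells,
#'   `NA_integer_` otherwise.
#' @export
milestone_between <- function(model, cell_a, cell_b) {
  check_model(model)
  check_cell(model, cell_a)
  check_cell(model, cell_b)
  if (abs(cell_a - cell_b) == 1L) as.integer(min(cell_a, cell_b))
  else NA_integer_
}

#' Cell interval and bordering milestones
#'
#' `cell_bounds` returns the half-open interval `[lo, hi)` of a cell;
#' `cell_milestones` the 0-based indices of the milestones bordering it (one
#' for the innermost cell, two otherwise).
#'
#' @param model a `milestoning_model`.
#' @param cell 0-based cell index.
#' @return `cell_bounds`: numeric `c(lo, hi)`; `cell_milestones`: integer
#'   vector.
#' @export
cell_bounds <- function(model, cell) {
  check_model(model)
  check_cell(model, cell)
  lo <- if (cell == 0L) 0 else model$milestones[cell]
  c(lo, model$milestones[cell + 1L])
}

#' @rdname cell_bounds
#' @export
cell_milestones <- function(model, cell) {
  check_model(model)
  check_cell(model, cell)
  if (cell == 0L) 0L else c(cell - 1L, cell)
}

check_model <- function(model) {
  if (!inherits(model, "milestoning_model"))
    stop_validation("expected a milestoning_model object")
  invisible(model)
}

check_cell <- function(model, cell) {
  if (!is.numeric(cell) || length(cell) != 1L || is.na(cell) ||
      cell != floor(cell) || cell < 0 || cell >= model$n_cells)
    stop_validation(sprintf("invalid cell index (expected 0..%d)",
                            model$n_cells - 1L))
  invisible(as.integer(cell))
}

check_milestone <- function(model, m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) ||
      m != floor(m) || m < 0 || m >= model$n_milestones)
    stop_validation(sprintf("invalid milestone index (expected 0..%d)",
                            model$n_milestones - 1L))
  invisible(as.integer(m))
}

#' Serialize a milestoning model to JSON
#'
#' @param model a `milestoning_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  check_model(model)
  obj <- list(milestones = model$milestones,
              thermal_energy = model$thermal_energy,
              units = model$units)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_radial_model(obj$milestones,
                     thermal_energy = obj$thermal_energy %||% 1,
                     cv_unit = obj$units$cv %||% "angstrom",
                     time_unit = obj$units$time %||% "ps")
}
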