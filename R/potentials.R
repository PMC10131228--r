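#' Potential specifications for the synthetic dynamics
#'
#' Potentials are expressed as reduced energies `beta*U(x)` (units of k_B*T)
#' along the CV. Four families are available:
#'
#' * `potential_flat()`: free diffusion.
#' * `potential_harmonic(stiffness, center)`:
#'   `beta*U = 0.5 * stiffness * (x - center)^2`, stiffness in kT per CV
#'   unit squared.
#' * `potential_double_barrier(barrier_positions, barrier_heights, well_depth,
#'   width)`: two Gaussian barriers (sd = `width`) at the given CV positions
#'   plus a logistic bound well of depth `well_depth` centred at
#'   `barrier_positions[1] - 2 * width`. Emulates an unbinding profile with
#'   two transition states separating the bound state, a metastable
#'   intermediate, and the unbound region.
#' * `potential_tabulated(cv, beta_u)`: piecewise-linear interpolation of the
#'   given knots, clamped (flat) outside their range.
#'
#' @param stiffness harmonic stiffness (kT per CV unit squared), > 0.
#' @param center harmonic centre (CV units).
#' @param barrier_positions increasing CV positions of the two barriers.
#' @param barrier_heights barrier heights in kT, length 2, > 0.
#' @param well_depth depth of the bound well in kT, >= 0.
#' @param width Gaussian barrier standard deviation (CV units), > 0.
#' @param cv,beta_u tabulated knots; `cv` strictly increasing.
#' @return an object of class `potential_spec`.
#' @examples
#' pot <- potential_double_barrier(c(4, 9), c(3, 4), well_depth = 1.5)
#' beta_u(pot, c(1, 4, 6.5, 9, 12))
#' @name potentials
NULL

new_potential <- function(kind, code, par, label) {
  structure(list(kind = kind, code = as.integer(code),
                 par = as.numeric(par), label = label),
            class = "potential_spec")
}

#' @rdname potentials
#' @export
potential_flat <- function() new_potential("flat", 0L, numeric(0), "flat")

#' @rdname potentials
#' @export
potential_harmonic <- function(stiffness, center) {
  if (!is.finite(stiffness) || stiffness <= 0)
    stop_validation("harmonic stiffness must be positive")
  if (!is.finite(center))
    stop_validation("harmonic center must be finite")
  new_potential("harmonic", 1L, c(stiffness, center),
                sprintf("harmonic(k=%g, c=%g)", stiffness, center))
}

#' @rdname potentials
#' @export
potential_double_barrier <- function(barrier_positions, barrier_heights,
                                     well_depth = 0, width = 0.6) {
  p <- as.numeric(barrier_positions)
  h <- as.numeric(barrier_heights)
  if (length(p) != 2L || length(h) != 2L)
    stop_validation("double_barrier needs two positions and two heights")
  if (any(!is.finite(c(p, h, well_depth, width))))
    stop_validation("double_barrier parameters must be finite")
  if (p[1] >= p[2])
    stop_validation("barrier positions must be strictly increasing")
  if (any(h <= 0) || width <= 0 || well_depth < 0)
    stop_validation("barrier heights and width must be positive, well depth non-negative")
  new_potential("double_barrier", 2L,
                c(p[1], h[1], p[2], h[2], well_depth, width),
                sprintf("double_barrier(p=%g,%g h=%g,%g depth=%g)",
                        p[1], p[2], h[1], h[2], well_depth))
}

#' @rdname potentials
#' @export
potential_tabulated <- function(cv, beta_u) {
  x <- as.numeric(cv); y <- as.numeric(beta_u)
  if (length(x) < 2L || length(x) != length(y))
    stop_validation("tabulated potential needs >= 2 (cv, beta_u) knots")
  if (any(!is.finite(c(x, y))))
    stop_validation("tabulated knots must be finite")
  if (any(diff(x) <= 0))
    stop_validation("tabulated cv knots must be strictly increasing")
  new_potential("tabulated", 3L, c(length(x), x, y),
                sprintf("tabulated(%d knots)", length(x)))
}

#' Evaluate a potential
#'
#' `beta_u` returns the reduced energy `beta*U(x)`; `beta_u_grad` its
#' derivative along the CV (the deterministic drift is `-D * beta_u_grad`).
#'
#' @param potential a `potential_spec`.
#' @param x numeric vector of CV values.
#' @return numeric vector.
#' @export
beta_u <- function(potential, x) {
  check_potential(potential)
  pot_energy_cpp(potential$code, potential$par, as.numeric(x))
}

#' @rdname beta_u
#' @export
beta_u_grad <- function(potential, x) {
  check_potential(potential)
  pot_grad_cpp(potential$code, potential$par, as.numeric(x))
}

check_potential <- function(potential) {
  if (!inherits(potential, "potential_spec"))
    stop_validation("expected a potential_spec object")
  invisible(potential)
}

#' @export
print.potential_spec <- function(x, ...) {
  cat("Potential:", x$label, "\n")
  invisible(x)
}

# Config-file (de)serialization of potentials
potential_to_list <- function(potential) {
  check_potential(potential)
  switch(potential$kind,
    flat = list(kind = "flat"),
    harmonic = list(kind = "harmonic", stiffness = potential$par[1],
                    center = potential$par[2]),
    double_barrier = list(kind = "double_barrier",
                          barrier_positions = potential$par[c(1, 3)],
                          barrier_heights = potential$par[c(2, 4)],
                          well_depth = potential$par[5],
                          width = potential$par[6]),
    tabulated = {
      n <- as.integer(potential$par[1])
      list(kind = "tabulated", cv = potential$par[1 + seq_len(n)],
           beta_u = potential$par[1 + n + seq_len(n)])
    })
}

potential_from_list <- function(obj) {
  kind <- obj$kind %||% stop_validation("potential spec needs a 'kind'")
  switch(kind,
    flat = potential_flat(),
    harmonic = potential_harmonic(obj$stiffness, obj$center),
    double_barrier = potential_double_barrier(
      unlist(obj$barrier_positions), unlist(obj$barrier_heights),
      well_depth = obj$well_depth %||% 0, width = obj$width %||% 0.6),
    tabulated = potential_tabulated(unlist(obj$cv), unlist(obj$beta_u)),
    stop_validation(sprintf("unknown potential kind '%s'", kind)))
}
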