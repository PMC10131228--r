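# Independent oracles, implemented by quadrature / closed forms only (no use
# of the estimator code paths they are meant to check).

# Exact continuous-time stationary probability of "last touched milestone i"
# for reversible 1D diffusion on [0, m_M] (reflecting ends) under beta*U:
# p_i = int rho(x) P(backward path hits m_i before the other neighbour) dx,
# with the commitor C(x) = int_x^b e^{beta U} / int_a^b e^{beta U}.
exact_last_touched_p <- function(pot, milestones) {
  rho <- function(x) exp(-beta_u(pot, x))
  eU <- function(x) exp(beta_u(pot, x))
  M <- length(milestones)
  quad <- function(f, a, b) {
    if (b <= a) return(0)
    stats::integrate(f, a, b, rel.tol = 1e-10)$value
  }
  p <- numeric(M)
  for (i in seq_len(M)) {
    m <- milestones[i]
    # everything below the innermost milestone last touched it
    if (i == 1L) p[i] <- p[i] + quad(rho, 0, m)
    # segment below m_i (shared with milestone i-1)
    if (i > 1L) {
      a <- milestones[i - 1L]
      Z <- quad(eU, a, m)
      commit_hi <- Vectorize(function(x) quad(eU, a, x) / Z)
      p[i] <- p[i] + quad(function(x) rho(x) * commit_hi(x), a, m)
    }
    # segment above m_i (shared with milestone i+1)
    if (i < M) {
      b <- milestones[i + 1L]
      Z <- quad(eU, m, b)
      commit_lo <- Vectorize(function(x) quad(eU, x, b) / Z)
      p[i] <- p[i] + quad(function(x) rho(x) * commit_lo(x), m, b)
    }
  }
  p / sum(p)
}

# Exact MFPT of 1D overdamped diffusion from x to the absorbing boundary b
# with a reflecting wall at a: tau(x) = (1/D) int_x^b e^{beta U(y)}
# int_a^y e^{-beta U(z)} dz dy.
exact_diffusion_mfpt <- function(pot, x, a, b, D = 1) {
  inner <- Vectorize(function(y)
    stats::integrate(function(z) exp(-beta_u(pot, z)), a, y,
                     rel.tol = 1e-10)$value)
  stats::integrate(function(y) exp(beta_u(pot, y)) * inner(y), x, b,
                   rel.tol = 1e-8)$value / D
}

# Flat-potential closed form for the same quantity.
flat_mfpt <- function(x, a, b, D = 1) ((b - a)^2 - (x - a)^2) / (2 * D)
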