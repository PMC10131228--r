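---
title: "Markovian milestoning with Voronoi tessellations: model, estimator and synthetic validation"
author: "milekin developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markovian milestoning with Voronoi tessellations: model, estimator and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milekin)
```

## The problem

Tight-binding inhibitors can stay bound to their target for minutes to
hours. The residence time (the mean first passage time, MFPT, from the
bound state to dissociation; its reciprocal is $k_\mathrm{off}$) is
increasingly used alongside affinity to rank drug candidates, but it is far
beyond the reach of plain molecular dynamics. Markovian milestoning with
Voronoi tessellations (MMVT) makes the problem tractable by decomposing a
scalar unbinding coordinate — here the distance between the centre of mass
(COM) of a ligand and the COM of its binding site, in Å — into *Voronoi
cells* separated by *milestones*. Short, mutually independent simulations
confined to each cell by reflective boundaries are then stitched into a
milestone-level continuous-time Markov model from which the residence time,
the stationary milestone probabilities and a free-energy profile along the
unbinding path all follow.

`milekin` implements this analysis end to end. In place of all-atom MD it
ships a synthetic-dynamics layer (overdamped Brownian dynamics on
configurable one-dimensional potentials) so that every estimator can be
validated against exact closed forms and brute-force oracles on a desktop.

## The model

An ordered list of milestone radii $m_0 < m_1 < \dots < m_{M-1}$ defines
$M$ half-open cells: the bound cell $[0, m_0)$ and $[m_{k-1}, m_k)$ for
$k \ge 1$. A CV value exactly at a milestone belongs to the cell above it —
a deterministic tie-break for a measure-zero event. Milestone and cell
indices are 0-based. The innermost milestone is the bound state (the
free-energy reference) and the outermost is absorbing for first-passage
purposes. Published milestoning studies sometimes sample one fewer cell
than they define milestones (an innermost region too narrow to sample); the
model here always exposes $M$ cells, and an unsampled cell simply
contributes no statistics — the estimator refuses to proceed if that leaves
a milestone without data, rather than silently regularizing.

The CV is treated as a generic scalar coordinate with no 3-D Jacobian: the
estimator consumes only milestone-touch statistics, which this preserves.

## The estimator

Confined sampling in cell $\alpha$ yields the sufficient statistics

* $N^\alpha_{ij}$ — collisions with milestone $j$ after last touching
  milestone $i \ne j$,
* $R^\alpha_i$ — simulation time spent having last touched milestone $i$,
* $T_\alpha$ — total attributable time, and
* $N_{\alpha\beta}$ — total collisions (same-milestone re-touches
  included) with the boundary shared with cell $\beta$.

The cell equilibrium weights $\pi_\alpha$ solve the flux balance
$\sum_\beta \pi_\beta\,N_{\beta\alpha}/T_\beta =
 \pi_\alpha \sum_\beta N_{\alpha\beta}/T_\alpha$ with
$\sum_\alpha \pi_\alpha = 1$; the linear system is solved directly after
replacing one balance row by the normalization (avoiding eigen-solver
ambiguity), with a connectivity check first. The model-level quantities are
the $\pi$-weighted combinations

$$T = \Big(\sum_\alpha \tfrac{\pi_\alpha}{T_\alpha}\Big)^{-1},\qquad
  N_{ij} = T \sum_\alpha \tfrac{\pi_\alpha}{T_\alpha} N^\alpha_{ij},\qquad
  R_i = T \sum_\alpha \tfrac{\pi_\alpha}{T_\alpha} R^\alpha_i ,$$

and the rate matrix is $Q_{ij} = N_{ij}/R_i$ with
$Q_{ii} = -\sum_{j \ne i} Q_{ij}$. With $\hat{Q}$ the matrix obtained by
deleting the absorbing milestone's row and column, the MFPT vector solves
$\hat{Q}\,\mathbf{T}^N = -\mathbf{1}$; the residence time is the entry of
the bound milestone. The stationary milestone probabilities $p$ solve the
left eigenproblem $p\,Q = 0$ (normalized, nonnegative — the only
convention that is stationary under the dynamics), and the free-energy
profile is $\Delta G_i = -k_BT \ln(p_i/p_\mathrm{ref})$ with the bound
milestone as reference. Transition-state milestones are the strict interior
local maxima of $\Delta G$; a flat plateau resolves to its first index, and
milestones with $p_i = 0$ are reported as $+\infty$ with a warning and
excluded from the search.

Although the holding times of the milestone process are not exponential,
solving $\hat Q\,\mathbf{T}^N = -\mathbf{1}$ with $Q = N/R$ is algebraically
identical to the semi-Markov renewal equation
$T_i = R_i/\sum_j N_{ij} + \sum_j P_{ij} T_j$, so the MFPT is exact
whenever the harvested $N$ and $R$ are — a property the test suite
exploits.

Replicas (independent repetitions of all per-cell sampling under a distinct
seed) are combined as per-milestone arithmetic mean ± standard error of the
mean, matching the way milestoning studies report three-replica error bars;
a bootstrap is deliberately not the default. Pairwise comparisons of
residence times between systems use Welch's unequal-variance $t$ test with
Welch–Satterthwaite degrees of freedom (two-sided). Degenerate inputs are
fixed by convention: two zero-variance samples with equal means give
$p = 1$, unequal means give $p = 0$.

Unsampled-but-structurally-possible transitions are kept at rate zero, and
connectivity failures raise errors instead of pseudo-inverses: a milestoning
model that has not converged should fail loudly, not produce a number. All
linear solves are dense and direct with a condition check ($M$ is at most a
few dozen).

## The synthetic-dynamics layer

The generator replaces per-cell MD with overdamped (Brownian)
Euler–Maruyama dynamics,
$x \leftarrow x - D\,\Delta t\,\partial_x(\beta U) + \sqrt{2D\Delta t}\,\xi$,
on reduced potentials $\beta U(x)$. Reflective cell boundaries become
position reflection of the offending step — the overdamped image of the
velocity reversal used in reflective-boundary MD, with identical
milestone-touch statistics in that limit. One collision is recorded per
boundary-crossing attempt per step, stamped at the end of the offending
step (an $O(\Delta t)$ timing bias). Consecutive same-milestone touches are
recorded in the trace; the statistics module keeps them out of $N$ but in
the boundary totals, since the off-diagonal rate construction uses
transitions between distinct milestones only.

**Bridge correction.** A discrete trajectory can cross a milestone and
return within a single step, leaving no end-of-step signature. A pre-study
on the flat-potential closed form showed that naive end-of-step detection
undercounts distinct transitions enough to bias residence times by
4–6%, essentially independently of $\Delta t$ in the practical range — and
identically so for a direct, cell-free estimator, i.e. the bias is a
property of discrete crossing detection, not of the cell reconstruction.
Both the confined integrator and the brute-force first-passage oracle
therefore apply the standard Brownian-bridge correction: a step from $x$ to
$x'$ that stays inside the cell still registers a touch of boundary $b$
with probability $\exp(-(b-x)(b-x')/(D\,\Delta t))$. The residual bias
after correction is below ~2% for $\sqrt{2D\Delta t}$ up to ~9% of the
cell width.

**Time before the first touch.** The time a trajectory spends before its
first milestone touch is attributable to no last-touched milestone. It is
excluded from both $R^\alpha$ and $T_\alpha$ (so $\sum_i R^\alpha_i =
T_\alpha$ exactly) and reported separately as `excluded_time`. Published
milestoning implementations do not document their convention; ours is
isolated behind one bookkeeping function so it can be flipped for
comparison.

**Potentials.** Four families, all in units of $k_BT$: flat; harmonic;
`double_barrier` — two Gaussian barriers (positions, heights, common width,
default 0.6 Å s.d.) plus a logistic bound well (depth, centred two widths
below the first barrier), emulating an unbinding profile with two
transition states separating the bound pose, a metastable intermediate and
the unbound region; and tabulated piecewise-linear knots. The double-barrier
family is the stand-in for the kinase–inhibitor systems that motivate the
package: raising its barrier heights is the synthetic analogue of a
stronger binder.

**Oracles.** Three independent routes check the pipeline: (i) an exact
Gillespie simulator for continuous-time Markov jump processes with known
generators — statistics harvested from it and pushed through the estimator
must recover $-\hat Q_\mathrm{true}^{-1}\mathbf{1}$; (ii) brute-force
unconfined first-passage sampling, against the closed form
$\tau(x) = ((b-a)^2 - (x-a)^2)/(2D)$ on a flat potential and against the
double-integral quadrature otherwise; (iii) a commitor-based quadrature for
the exact continuous-time stationary last-touched probabilities (the flat
10-milestone model gives the characteristic $1.5 : 1 : \dots : 1 : 0.5$
edge weighting, which the estimator reproduces).

**Steered seeding.** Starting configurations are produced by a toy
steered-pulling routine: Brownian dynamics under a harmonic restraint whose
centre moves from the bound cell to the outermost milestone, saving the
first configuration observed in each cell. The restraint stiffness is
validated against the Euler stability limit
($k\,D\,\Delta t \le 0.5$), and an under-resolved pull (cells never
visited) is an error naming the unseeded cells, not a silent gap.

**Seeds.** One master seed per run; per-replica, per-cell streams derive
from it by a fixed affine counter scheme modulo $2^{31}-1$, so runs are
bit-reproducible and cells are independent. Identical results are produced
regardless of per-cell execution order.

## Parameter defaults and numerical choices

| Parameter | Default | Why |
|---|---|---|
| CV units | Å (labels only) | matches the COM–COM radial CV |
| time units | ps (labels only) | MD convention |
| $D$ | 1 Å²/time unit | sets the time scale; all results scale as $1/D$ |
| $\Delta t$ (flat cells, width 1 Å) | 2.5e-3 | pre-study: $\sigma/h \approx 7\%$, bias < 2%, maximal statistics per step budget |
| $\Delta t$ (shaped potentials) | 1e-3–1.5e-3 | keeps drift per step $D\,\Delta t\,\max|\partial_x \beta U|$ well under the step noise |
| barrier width | 0.6 Å | barriers resolved by ~2 milestones at 1 Å spacing |
| replicas | 3 | the convention for milestoning error bars |
| restraint stiffness | 100 kT/Å² | tracks the pull centre to ~0.1 Å |

The acceptance simulations use these values; they were fixed once, from the
pre-study and from the closed-form oracles, before the acceptance tests
were frozen, and are not adjusted per seed.

## What a green test does and does not establish

The synthetic world is one-dimensional, overdamped, memoryless in the CV
and isotropic in everything else. A green suite establishes that the
estimator algebra is exact, that the confined-sampling reconstruction is
statistically consistent with brute-force dynamics on the same potential,
and that rank ordering by residence time is faithful when the underlying
barriers differ. It does not establish anything about force fields,
solvent, orthogonal slow degrees of freedom, or the Markovianity of a real
protein–ligand CV — on real systems those enter through the quality of the
input statistics, not through this analysis layer.

Two quantitative caveats surfaced by the synthetic tests carry over to real
applications:

* the milestone free-energy profile $-k_BT\ln(p_i/p_\mathrm{ref})$ is a
  milestone-resolution approximation to the underlying potential of mean
  force; at 1 Å spacing on a 3 kT harmonic well it deviates by up to
  ~0.35 kT even with exact statistics (the last-touched occupancies are
  commitor-weighted integrals, not point evaluations of $e^{-\beta U}$);
* estimated residence times inherit a small convexity bias at low sampling
  (the MFPT is a nonlinear function of noisy rates), which is why
  convergence monitoring (`convergence_series`) operates on cumulative time
  prefixes rather than trusting a single estimate.

## Design decisions that were genuinely open

* **$M$ cells for $M$ milestones.** The bound region is modelled as its own
  cell so that cell count equals milestone count; the alternative
  (innermost region unsampled) is representable by supplying no statistics
  for cell 0 — but then milestone 0 lacks occupancy data and the estimator
  stops, which we prefer to imputing.
* **Eq-level conventions.** The cell-balance system is solved as a linear
  system with a normalization row; the milestone-level stationary vector is
  taken as the left null eigenvector of $Q$. Both are validated against the
  known-generator and quadrature oracles.
* **Segment merging.** Statistics of restart segments add component-wise;
  the last-touched label deliberately does not carry across segments, so
  each segment re-excludes its own pre-first-touch time. Cutting at a
  same-milestone re-touch makes the seam effect exactly zero, which is how
  the invariance is tested.
* **Welch rather than pooled $t$.** Replica variances of different systems
  have no reason to be equal.

## Known limitations

Only the 1-D radial CV case is implemented (no general multidimensional
Voronoi anchors); there is no bimolecular association ($k_{on}$) pathway,
no committor analysis, and no Bayesian sampling of the rate matrix. The
double-barrier well shifts the effective barrier tops by a fraction of the
barrier width; transition-state locations are therefore asserted only to
±1 milestone. CLI subcommands cover model building, simulation, analysis,
ranking and convergence monitoring; they are thin wrappers over the
exported functions, which remain the primary interface.
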