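---
title: "Mass tensor molecular dynamics with variable cell shape: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass tensor molecular dynamics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mtmd)
```

## The problem

The time step of a molecular dynamics simulation is limited by the fastest
vibration in the system — typically covalent bond stretching.  Mass tensor
molecular dynamics (MTMD) enlarges the stable time step by replacing the
constant atomic masses with a position-dependent, matrix-valued mass
$M(q)$ that assigns large inertia to fast internal modes while leaving
translations and other slow, structurally relevant motions untouched.  No
constraints are imposed and the degrees of freedom are unchanged.

The essential correctness condition is that $\det M(q)$ is held constant.
Integrating the momenta out of the canonical distribution of
$H = \tfrac12 p^T M(q)^{-1} p + U(q)$ leaves a configurational weight
$\propto e^{-\beta U(q)} \sqrt{\det M(q)}$; a constant determinant cancels
the square root against the partition function, so every equilibrium
*configurational* observable is exactly that of ordinary MD.  Dynamical
observables are modified in a controlled way: modes given extra mass slow
down by $\sqrt{m_\text{new}/m_\text{old}}$, everything else is ideally
untouched.

This package implements MTMD generalized to variable cell shape
(Parrinello–Rahman dynamics in the NpH ensemble), with the cell matrix $h$
(columns = lattice vectors) a dynamical variable of fictitious mass $W$
and external pressure $P$.  With scaled coordinates $s$ (Cartesian
positions $R = h s$) the Hamiltonian is

$$H(s, h, p_s, p_h) = \tfrac12 p_s^T G^{-1}(s,h)\, p_s
  + \frac{1}{2W}\mathrm{Tr}(p_h^T p_h) + U(s,h) + P \det h,$$

where $G = H^T M H$ (with $H$ the per-atom block repetition of $h$) acts
as a mass-weighted metric tensor.  The conserved quantity is the enthalpy.

## Mass models

All mass matrices in this package are block diagonal with one block per
molecule, symmetric positive definite, and determinant-constrained.

**Diatomic mode decomposition.**  For diatomics each $6\times6$ block
decomposes exactly into three translational, two rotational and one
vibrational mode along the current bond direction $\hat d$:

$$M_\text{mol} = \tfrac{m_\text{trans}}{2}
  \begin{pmatrix}1&1\\1&1\end{pmatrix}\otimes I_3
  + \tfrac{m_\text{rot}}{2}
  \begin{pmatrix}1&-1\\-1&1\end{pmatrix}\otimes (I_3 - \hat d\hat d^T)
  + \tfrac{m_\text{vib}}{2}
  \begin{pmatrix}1&-1\\-1&1\end{pmatrix}\otimes \hat d\hat d^T.$$

The block determinant $m_\text{trans}^3 m_\text{rot}^2 m_\text{vib}$ is
geometry-independent, so the determinant constraint holds with no
rescaling.  With all three masses equal to the atomic mass the block
reduces to $mI_6$ and the integrator reduces to ordinary (variable-cell)
MD.  See `diatomic_mass_model()`, `diatomic_block()`.

**Internal-coordinate Hessian construction.**  For general molecules the
fast modes are identified from a reference Hessian.  Bonds are detected
from covalent radii (see below), and all bonds, angles and dihedrals
constructible from them form a redundant internal coordinate set $\{q_i\}$
with Wilson B matrix $B_{ij} = \partial q_i / \partial x_j$.  A Cartesian
Hessian $H_{x,0}$, computed once at a local minimum, is forward-transformed
with the thresholded pseudoinverse (singular values below $10^{-2}$ of the
largest are dropped),

$$H_{q,0} = B_0^{+T} H_{x,0} B_0^{+},$$

which is exact at a minimum because the gradient-weighted second-derivative
(K-matrix) term vanishes there.  Along the trajectory the mass matrix is
assembled per molecule as

$$M(q) = \left(w\, B^T(q)\, H_{q,0}\, B(q) + M_p\right) c(q),$$

with $B(q)$ evaluated at the *current* geometry, a constant positive
definite base matrix $M_p$ (physical or mass-repartitioned), and the
scalar $c(q) = (D_0 / \det A(q))^{1/3N}$ restoring
$\det M = D_0 = \det A(q_0)$ exactly, so $c(q_0) = 1$.  The K-matrix is
deliberately omitted in the backward direction: it would require third
derivatives in the equations of motion and can introduce negative
curvatures, while its omission keeps the Hessian term positive
semidefinite.  See `internal_hessian_mass_model()`,
`reference_hessian_internal()`.

Key tunables, with units and defaults:

* `w` (u Å²/eV, default 0.5): weight of the Hessian term.  0.5 is the
  molecular-crystal recipe; 0.2 suits hydrogen-bonded liquids.  Higher
  values reduce the maximum frequency further but saturate, and make the
  implicit solves harder.
* `Mp` (`"physical"` or `"repartitioned"`): repartitioning replaces all
  atomic masses by their mean (total mass conserved), which already slows
  the fastest (light-atom) modes but retards molecular diffusion; keep
  `"physical"` when dynamical properties such as self-diffusion matter.
* `zero_offdiag`: diagonal-only variant of $H_{q,0}$; the off-diagonal
  couplings contribute little because internal coordinates largely
  decouple the modes by construction.

Derivatives of $M$ (needed by the equations of motion) flow through the
Wilson-B second derivatives $\partial^2 q_i/\partial x_j \partial x_k$ and
through $\partial c/\partial s = -(c/3N)\,\mathrm{tr}(A^{-1}\partial A/\partial s)$;
the inverse-metric derivatives use
$\partial G^{-1} = -G^{-1}(\partial G)G^{-1}$.  All internal-coordinate
derivatives are produced by forward-mode hyper-dual automatic
differentiation in compiled code — exact to machine precision, verified
against finite differences in the test suite (`dGinv_derivatives()` is a
dense reference path used for validation).

## The integrator

The generalized Störmer–Verlet (leapfrog) scheme evaluates the momentum
derivatives of $H$ at the advanced momenta and the position derivatives at
the advanced positions, giving a second-order, time-reversible, symplectic
map even for the non-separable MTMD Hamiltonian.  Two stages are implicit:

1. the first momentum half-kick (implicit in $p_s^{(n+1/2)}$), solved by
   plain fixed-point iteration — the operators involved are constant
   during the iteration, so each sweep is cheap; roughly 10–12 iterations
   at moderate time steps, approaching 30 near the maximum stable step;
2. the position update (implicit in $s^{(n+1)}$ because $G^{-1}$ must be
   re-evaluated at the trial positions), solved with one fixed-point step
   followed by Newton–Raphson; about 4 mass-matrix evaluations per step in
   total.  The Newton matrix is block-diagonal plus a rank-one term from
   $c(q)$, solved with per-molecule factorizations and the
   Sherman–Morrison identity, with a damped fixed-point fallback.

The cell update is explicit ($h$ must be advanced before the position
solve), and exactly one force evaluation per step is needed — evaluations
at the advanced positions are reused by the next step.  Solver tolerances
default to $10^{-12}$ *relative to the variable scale* ("down to machine
precision"); iteration caps are 30 (fixed point) and 10 (Newton), both
configurable — runs at very large steps are best given a higher
fixed-point cap (~60), since convergence there legitimately needs close to
30 sweeps.  Divergence, cell inversion or non-finite coordinates mark the
trajectory with a `"stability failure"` status rather than aborting, so
time-step scans can treat failures as data.

A uniform-scaling constraint (`uniform_scaling = TRUE`) projects every
cell-momentum increment onto the one-dimensional subspace spanned by $h$
(Frobenius inner product), preventing the severe cell shearing that
Parrinello–Rahman dynamics can develop at high temperature; initial cell
momenta are drawn inside the allowed subspace.

Internally all quantities are in u, Å and eV; the derived time unit is
$\sqrt{\mathrm{u\,\AA^2/eV}} = 10.1805$ fs, and femtoseconds are converted
only at the interfaces, so the equations of motion carry no unit
constants.  Pressure is GPa at the interface
($1\,\mathrm{GPa} = 6.2415\times10^{-3}\,\mathrm{eV/\AA^3}$).

An **explicit, non-symplectic** companion integrator is provided for
comparison: a leapfrog in velocities that integrates the Lagrangian
equations of motion directly, with the velocity-dependent force terms
taken from a half-step predictor.  It is cheap (no implicit solves) and
accurate over short horizons, but it is not tied to a shadow Hamiltonian:
over tens of thousands of steps its energy drifts monotonically upward
while the symplectic scheme stays in a bounded band, and it destabilizes
at steps the symplectic scheme tolerates.  It exists to make that contrast
measurable (`run_dynamics(..., integrator = "explicit")`).

## Choosing the time step

`mass_weighted_frequencies()` computes the eigenvalues $\omega_j^2$ of
$M^{-1/2} H M^{-1/2}$ (equivalently the generalized eigenproblem of
$(H, M)$) and applies the conventional rule of one tenth of the fastest
oscillation period, `dt_rule` $= (1/f_\text{max})/10$.  For harmonic
dynamics the hard stability boundary of the leapfrog family is
$\omega\,\Delta t < 2$; `max_stable_dt()` scans a time-step grid
empirically, accepting a step when the run completes with all solvers
converged and the conserved-quantity excursion stays *bounded*: the
full-horizon excursion must not exceed the excursion of the initial fifth
of the run (the bounded discretization band, which scales as $\Delta t^2$
away from the stability edge) by more than 1 meV/atom.  The criterion
rejects secular drift, resonant growth and energy jumps while tolerating
the large-but-bounded oscillation that a symplectic integrator legitimately
shows near the edge.

## Analysis machinery

* `mode_filtered_spectrum()` — per-molecule scalar signals isolate the
  mode classes: center-of-mass coordinates (translation), the cosine of
  the molecular axis against the laboratory z axis (rotation; smooth in
  time, unlike the angle itself), and bond lengths (vibration).  The
  second time derivative is taken with central differences and
  detrended, Hann-windowed periodograms are averaged over molecules; the
  peak is read off power smoothed with a 5-bin moving mean.  Peak
  *positions* are robust to these estimator choices; peak shapes are not
  asserted anywhere.
* `rdf()` — ideal-gas-normalized pair-distance histogram with per-frame
  minimum-image distances.
* `diffusion_fit()` — origin-averaged mean squared displacement from the
  unwrapped positions (coordinates are never wrapped during dynamics, so
  no unwrapping heuristic is needed), least-squares fit of
  $\langle|R(t)-R(0)|^2\rangle = 6Dt + b$; a log–log slope near 2 flags
  ballistic (non-diffusive) windows.
* `transition_detector()` — orientational order parameter for two-molecule
  polymorph studies: the angle between the two molecular main axes
  (centroid-to-centroid directions of two atom groups), trailing rolling
  mean over 100 frames, events at upward crossings of 80°, with exclusions
  for intramolecular kinks above 30° and for a user-supplied cell-shape
  predicate (the "expected cell shape" of a polymorph is system-specific,
  so it is exposed as a hook rather than hard-coded).

## Synthetic fixtures and what they do (and do not) show

`build_n2_liquid()` / `build_n2_gas()` construct periodic nitrogen boxes
at the liquid (512 molecules / 32 Å box) and gas (512 / 480 Å) reference
densities, scaled to smaller molecule counts at constant density.  The
four-parameter force field (harmonic bond $r_0 = 1.0977$ Å,
$K_r = 138.331$ eV/Å²; Lennard-Jones $\epsilon = 0.003456$ eV,
$r_m = 3.614$ Å between atoms of different molecules) is bundled as
`n2_force_field()`.  Three fixture-level choices are documented design
decisions:

* the Lennard-Jones cutoff (10 Å default, 7.5 Å in the 16 Å box) uses the
  standard potential shift to zero at the cutoff so the conserved quantity
  is continuous when pairs cross it;
* the cell mass is $W = 100$ u for the nitrogen boxes, placing the cell
  breathing mode near 1 ps — an order of magnitude slower than the fastest
  retained molecular modes ($W = 20$ u, a value suited to a 64-molecule
  water cell, makes the nitrogen cell mode fast enough to limit the
  largest usable time steps);
* initialization temperatures (100 K liquid, 1630 K gas) are calibrated so
  the kinetic temperature equilibrates near the target conditions (~90 K,
  ~1500 K) once the vibrational modes, started at their equilibrium bond
  length, absorb their equipartition share of potential energy.

`build_toy_crystal()` builds a two-molecule crystal surrogate of bent
four-atom molecules (H–O–O–H connectivity: two O–H bonds, one O–O bond,
two angles, one dihedral, mixed masses), relaxes it at fixed cell to a
gradient below $10^{-6}$ eV/Å — so the K-matrix omission is exact at the
reference — and bundles the finite-difference Hessian.  It exercises the
full redundant coordinate set, the six mass-model variants (physical,
repartitioned, bonds-only, bonds+angles, full with and without
off-diagonal couplings) and the drift comparison.

These fixtures emulate the *numerics* of the method faithfully: implicit
solves, determinant constraint, spectra, stability boundaries.  They do
not emulate first-principles energetics — no electrostatics, polarization
or bond breaking — so passing tests demonstrate correctness of the
machinery, not transferability of any force field; quantitative
polymorph-transition rates or liquid-water structure require a
quantum-mechanical engine behind the same interfaces.

## Numerical choices and degenerate inputs

* Covalent radii: a bundled standard consensus table with detection scale
  1.2 (both configurable).  Bonding is detected once at setup; no
  re-detection along trajectories (the mass model assumes a fixed bonding
  pattern, and its breakdown — e.g. a hydrogen detaching at high
  temperature — is the known failure mode of the method).
* Angles via `acos` of the clamped cosine; dihedrals via `atan2`, giving
  full-range sign stability.  Angles within $10^{-3}$ rad of $\pi$ at the
  reference geometry are excluded at enumeration time (the B matrix is
  singular there), as are dihedrals containing such an angle.
* Minimum image is applied in bond detection and in nonbonded pair sums;
  internal coordinates and bonded terms use unwrapped positions of whole
  molecules (`make_molecules_whole()`), and dynamics never wraps
  coordinates.
* $H_{q,0}$ is symmetrized and negative near-zero eigenvalues (numerical
  noise; the exact transform is positive semidefinite at a minimum) are
  clipped at zero.  A nonzero reference gradient triggers a warning, not
  an error.
* The determinant-constraint exponent uses the full dimension $3N$ and the
  global matrix (product of block determinants), computed via
  log-determinants.
* `fd_hessian()` defaults to a $10^{-3}$ Å step, balancing truncation
  against round-off for eV/Å² curvatures, and uses gradient differences
  when a gradient function is available.

## Problem sizes used in the shipped studies

The packaged experiments run 64 nitrogen molecules (128 atoms): spectra
from 6 ps (standard MD, 1 fs steps) and 16 ps (MTMD, 4 fs steps) of
production after short equilibration; stability scans over 5000-step
horizons; the drift comparison over 20 000 steps of the two-molecule toy
crystal.  At these sizes the full set completes in minutes on one CPU
core, and the measured quantities (peak positions, stability boundaries)
are already insensitive to the molecule count because they are set by
intramolecular and local-collision physics.

## Known limitations

* Mass models require identical molecules (equal block sizes); mixed
  systems would need a block-size-general engine.
* The minimum-image convention uses fractional rounding, valid for
  near-orthorhombic cells; the uniform-scaling constraint keeps all
  shipped runs cubic.
* The nitrogen Lennard-Jones well is shallow ($\epsilon/k_B \approx 40$ K),
  so the "liquid" box at 90 K and 1 atm slowly expands over long horizons;
  over the few-ps windows used for spectra the density drift is small.
* The explicit integrator is one reasonable realization of a
  velocity-space leapfrog; only its qualitative long-horizon drift, not
  its precise error constant, is meaningful.
* No thermostats or barostat chains beyond the Parrinello–Rahman NpH
  scheme; no multiple-time-step schemes; no bond constraints (the method's
  point is to avoid them).
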